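#' Read a motif-to-regulator annotation table
#'
#' TSV with columns `motif`, `symbol`, `class`, mapping each target-list
#' motif name to the gene symbol(s) of the transcription factor or miRNA it
#' represents. A motif may map to several symbols (miRNA family motifs such
#' as `TTTGCAC,MIR-19A,MIR-19B` encode multiple regulators): one row per
#' symbol, producing one network node each. Unclassified motifs carry an
#' empty symbol and class `unclassified`.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `motif_annotation` with columns `motif`,
#'   `symbol`, `class`.
#' @export
read_motif_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  need <- c("motif", "symbol", "class")
  if (!all(need %in% names(df))) {
    stop_ictair("annotation table must have columns: ",
                paste(need, collapse = ", "))
  }
  motif_annotation(df$motif, df$symbol, df$class)
}

#' Construct a motif annotation table
#'
#' @param motif Character vector of motif (gene set) names.
#' @param symbol Regulator gene symbols; empty string for unclassified
#'   motifs.
#' @param class One of `"TF"`, `"miRNA"`, `"unclassified"` per row.
#' @return A data frame of class `motif_annotation`.
#' @export
motif_annotation <- function(motif, symbol, class) {
  df <- data.frame(motif = as.character(motif),
                   symbol = as.character(symbol),
                   class = as.character(class),
                   stringsAsFactors = FALSE)
  if (!all(df$class %in% c("TF", "miRNA", "unclassified"))) {
    stop_ictair("annotation class must be TF, miRNA or unclassified")
  }
  if (any(df$class == "unclassified" & nzchar(df$symbol))) {
    stop_ictair("unclassified motifs must have an empty regulator symbol")
  }
  if (any(df$class != "unclassified" & !nzchar(df$symbol))) {
    stop_ictair("classified motifs must carry a regulator symbol")
  }
  if (anyDuplicated(df[c("motif", "symbol")])) {
    stop_ictair("duplicate motif/symbol annotation row(s)")
  }
  structure(df, class = c("motif_annotation", "data.frame"))
}

#' Build the regulator-to-regulator network from refined target lists
#'
#' Applies the relational rule: if motif A (annotated to regulator symbol
#' `r_A`) has another motif's regulator symbol `r_B` among its target genes,
#' then `r_A` regulates `r_B` — a directed edge `r_A -> r_B`. Motifs
#' redundant on the same regulator symbol are collapsed to a single node
#' carrying the union of its motifs' edges, and duplicate edges are merged.
#' An edge from a regulator to itself (its own symbol appears in its target
#' list) is flagged autoregulatory.
#'
#' @param refined_sets List of [gene_set()] objects (typically icTAIR
#'   output), names matching annotation motifs.
#' @param annotations A [motif_annotation()] table covering every set.
#' @param restrict_to Optional character vector of motif names; when given,
#'   only those motifs are eligible as regulators and as targets, and
#'   unclassified motifs are excluded.
#' @return A list of class `regulator_network` with `nodes` (data frame
#'   `symbol`, `class`, `motifs`) and `edges` (data frame `from`, `to`,
#'   `autoregulatory`, sorted lexicographically).
#' @export
build_network <- function(refined_sets, annotations, restrict_to = NULL) {
  stopifnot(inherits(annotations, "motif_annotation"))
  set_names <- vapply(refined_sets, `[[`, character(1L), "name")
  missing_ann <- setdiff(set_names, annotations$motif)
  if (length(missing_ann)) {
    stop_ictair("no annotation for motif(s): ",
                paste(missing_ann, collapse = ", "))
  }
  eligible <- set_names
  if (!is.null(restrict_to)) eligible <- intersect(eligible, restrict_to)
  ann <- annotations[annotations$motif %in% eligible &
                       annotations$class != "unclassified", , drop = FALSE]

  # regulator-level collapse: one node per symbol, union of motifs
  nodes <- do.call(rbind, lapply(split(ann, ann$symbol), function(a) {
    data.frame(symbol = a$symbol[1L], class = a$class[1L],
               motifs = paste(sort(unique(a$motif)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) {
    nodes <- data.frame(symbol = character(0), class = character(0),
                        motifs = character(0), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL

  members_of <- stats::setNames(lapply(refined_sets, `[[`, "members"),
                                set_names)
  edges <- list()
  for (i in seq_len(nrow(ann))) {
    r_a <- ann$symbol[i]
    targets <- members_of[[ann$motif[i]]]
    hit <- nodes$symbol[nodes$symbol %in% targets]
    for (r_b in hit) {
      edges[[length(edges) + 1L]] <- c(from = r_a, to = r_b)
    }
  }
  edges <- if (length(edges)) {
    e <- unique(do.call(rbind, edges))
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
    e$autoregulatory <- e$from == e$to
    e
  } else {
    data.frame(from = character(0), to = character(0),
               autoregulatory = logical(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "regulator_network")
}

#' @export
print.regulator_network <- function(x, ...) {
  cat(sprintf("<regulator_network> %d nodes, %d edges (%d autoregulatory)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$autoregulatory)))
  invisible(x)
}

#' Out- and in-degree per network node
#'
#' @param network A `regulator_network` from [build_network()].
#' @return A data frame with columns `node`, `out_degree`, `in_degree`,
#'   ordered by node name.
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "regulator_network"))
  nodes <- network$nodes$symbol
  data.frame(
    node = nodes,
    out_degree = vapply(nodes,
                        function(n) sum(network$edges$from == n), 0L),
    in_degree = vapply(nodes,
                       function(n) sum(network$edges$to == n), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write network edges to TSV
#'
#' One edge per row: `source TAB target TAB is_autoregulatory`, sorted
#' lexicographically; an empty network yields a header-only file.
#'
#' @param network A `regulator_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edges <- function(network, path) {
  stopifnot(inherits(network, "regulator_network"))
  e <- network$edges
  lines <- c("source\ttarget\tis_autoregulatory",
             if (nrow(e)) paste(e$from, e$to, tolower(e$autoregulatory),
                                sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
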