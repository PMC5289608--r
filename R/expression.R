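#' Construct an expression matrix
#'
#' Wraps a genes-by-samples numeric matrix of log-scale relative expression
#' together with its channel convention. One-channel (absolute-intensity)
#' data must be median-centered per gene before activity scoring; two-channel
#' (ratio-to-reference) data is already relative. See
#' [normalize_expression()].
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty `rownames` (gene symbols) and `colnames` (sample IDs).
#'   Missing or non-finite values are rejected.
#' @param channel_mode One of `"one_channel"`, `"two_channel"`,
#'   `"pre_normalized"`.
#' @return A numeric matrix of class `expression_matrix` with attribute
#'   `channel_mode`.
#' @export
expression_matrix <- function(values,
                              channel_mode = c("one_channel", "two_channel",
                                               "pre_normalized")) {
  channel_mode <- match.arg(channel_mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ictair("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_ictair("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_ictair("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop_ictair("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop_ictair("expression matrix contains missing or non-finite values; ",
                "impute or filter upstream")
  }
  structure(values, channel_mode = channel_mode,
            class = c("expression_matrix", class(values)))
}

channel_mode <- function(x) attr(x, "channel_mode") %||% "pre_normalized"

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), channel_mode(x)))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs, a first column of gene symbols, and a
#' fully numeric body. Missing values, non-numeric cells, duplicate gene rows
#' and duplicate sample IDs are errors: silent imputation or collapsing would
#' change expression ranks and hence every downstream score.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path,
                            channel_mode = c("one_channel", "two_channel",
                                             "pre_normalized")) {
  channel_mode <- match.arg(channel_mode)
  if (!file.exists(path)) stop_ictair("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop_ictair("expression TSV needs a gene column and at ",
                                 "least one sample column")
  samples <- names(df)[-1L]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop_ictair("duplicate sample identifier(s) in ", path, ": ",
                paste(dup, collapse = ", "))
  }
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_ictair("duplicate gene row(s) in ", path, ": ",
                paste(dup, collapse = ", "))
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(!is.finite(storage) | is.na(storage))
  if (length(bad)) {
    stop_ictair(sprintf(
      "non-numeric or missing value(s) in %s (e.g. gene '%s', sample '%s')",
      path, genes[(bad[1L] - 1L) %% nrow(body) + 1L],
      colnames(body)[(bad[1L] - 1L) %/% nrow(body) + 1L]))
  }
  dimnames(storage) <- list(genes, samples)
  expression_matrix(storage, channel_mode)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 15 significant digits so that a read/write
#' round-trip preserves them to full double precision for practical purposes.
#'
#' @param x An [expression_matrix()] (or plain named numeric matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  write_named_matrix(x, path, first_col = "gene")
}

# Shared TSV writer for genes-/regulators-by-samples matrices.
write_named_matrix <- function(x, path, first_col) {
  body <- apply(unclass(x), 2L, function(col) sprintf("%.15g", col))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(x))
  lines <- c(paste(c(first_col, colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  if (nrow(x) == 0L) lines <- lines[1L]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Median-center one-channel expression data
#'
#' Activity scoring operates on relative (log-ratio-like) expression. For
#' one-channel data each gene row has its across-sample median subtracted;
#' two-channel data is already expressed relative to its internal reference
#' and passes through unchanged, as does pre-normalized input. The result is
#' always flagged `pre_normalized`.
#'
#' @param x An [expression_matrix()].
#' @return An [expression_matrix()] with `channel_mode = "pre_normalized"`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 2, 3), 1,
#'        dimnames = list("G1", c("s1", "s2", "s3"))), "one_channel")
#' normalize_expression(m)[1, ]  # -1 0 1
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  vals <- unclass(x)
  attr(vals, "channel_mode") <- NULL
  if (channel_mode(x) == "one_channel") {
    vals <- vals - apply(vals, 1L, stats::median)
  }
  expression_matrix(vals, "pre_normalized")
}
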