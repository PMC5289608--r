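#' Construct a gene set (regulator target list)
#'
#' A gene set holds the target gene list of one regulator: a unique name
#' (typically an MSigDB c3 motif identifier such as `"V$NFY_Q6"`), a free-text
#' description, and an ordered set of member gene symbols. Gene symbols are
#' opaque, case-sensitive strings; no aliasing or identifier mapping is
#' performed.
#'
#' @param name Non-empty set name, unique within a collection.
#' @param members Character vector of gene symbols; duplicates are removed
#'   (first occurrence kept) with a warning, and at least one member must
#'   remain.
#' @param description Free-text description; preserved verbatim on write but
#'   otherwise ignored.
#' @return An object of class `gene_set` with elements `name`, `description`
#'   and `members`.
#' @examples
#' gene_set("V$NFY_Q6", c("CCNB1", "CDC2", "TOP2A"))
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_ictair("gene set name must be a single non-empty string")
  }
  members <- as.character(members)
  if (anyDuplicated(members)) {
    dups <- unique(members[duplicated(members)])
    warning(sprintf("gene set '%s': removed %d duplicate member(s): %s",
                    name, length(dups), paste(dups, collapse = ", ")),
            call. = FALSE)
    members <- members[!duplicated(members)]
  }
  if (length(members) == 0L) {
    stop_ictair("gene set '", name, "' has no members")
  }
  structure(list(name = name, description = as.character(description)[1L],
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read gene sets from a GMT file
#'
#' Parses the Broad/MSigDB GMT dialect: one set per line, tab-separated
#' fields `name`, `description`, then member gene symbols. Duplicate member
#' symbols within a line are dropped (first kept) with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set] objects in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ictair("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_ictair(sprintf("GMT format error at line %d: expected >= 3 %s",
                          i, "tab-separated fields"))
    }
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)], fields[2L])
  }
  nms <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop_ictair("duplicate gene set names in ", path, ": ",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' Writes canonical GMT: `name TAB description TAB gene TAB gene ...`, one
#' newline-terminated line per set, in input order. `read_gmt()` applied to
#' the result reproduces the input exactly.
#'
#' @param sets A list of [gene_set] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets))
  lines <- vapply(sets, function(s) {
    if (!inherits(s, "gene_set")) stop_ictair("all elements must be gene_set")
    if (length(s$members) == 0L) {
      stop_ictair("gene set '", s$name, "' has no members")
    }
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
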