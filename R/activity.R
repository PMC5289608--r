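#' Build a 0/1 target weight vector aligned to an expression matrix
#'
#' Encodes a regulator's target list against the full gene space of the
#' matrix: weight 1 for genes in the set, 0 for non-targets. Members absent
#' from the matrix are dropped with a warning. Scoring requires at least one
#' target and at least one background (non-target) gene.
#'
#' @param set A [gene_set()].
#' @param x An [expression_matrix()].
#' @return A list of class `weight_vector` with `values` (named 0/1 integer
#'   vector over all matrix genes), `n_targets_effective`, and `dropped`
#'   (member symbols not found in the matrix).
#' @export
make_weight_vector <- function(set, x) {
  stopifnot(inherits(set, "gene_set"), inherits(x, "expression_matrix"))
  genes <- rownames(x)
  hit <- set$members %in% genes
  dropped <- set$members[!hit]
  if (length(dropped)) {
    warning(sprintf("gene set '%s': %d member(s) absent from matrix: %s",
                    set$name, length(dropped),
                    paste(utils::head(dropped, 10L), collapse = ", ")),
            call. = FALSE)
  }
  values <- as.integer(genes %in% set$members)
  names(values) <- genes
  k <- sum(values)
  if (k == 0L) {
    stop_ictair("gene set '", set$name, "' has no members in the matrix")
  }
  if (k == length(genes)) {
    stop_ictair("gene set '", set$name, "' covers every matrix gene; ",
                "the background class is empty")
  }
  structure(list(values = values, n_targets_effective = k, dropped = dropped),
            class = "weight_vector")
}

#' Foreground/background running-sum curves for one sample
#'
#' Sorts the sample's genes by descending relative expression (ties broken by
#' ascending gene index) and accumulates two non-decreasing curves: the
#' foreground `F(k)` over target genes and the background `B(k)` over
#' non-targets, each normalized to end at 1. By default each gene contributes
#' its absolute relative expression `|e|` to its class's mass, so the curves
#' encapsulate expression activity rather than mere rank counts; if a class
#' has zero total mass, equal increments `1/count` are used for it.
#'
#' @param weights A `weight_vector` from [make_weight_vector()], or a plain
#'   0/1 vector aligned to `expression_column`.
#' @param expression_column Numeric vector of relative expression for one
#'   sample, aligned to `weights`.
#' @param weighting `"absolute"` (default) weights increments by `|e|`;
#'   `"uniform"` uses equal steps, for sensitivity checks.
#' @return A list of class `curve_pair` with `foreground`, `background`
#'   (each length `n`), and `order` (the descending-expression permutation).
#' @export
sample_curves <- function(weights, expression_column,
                          weighting = c("absolute", "uniform")) {
  weighting <- match.arg(weighting)
  v <- if (inherits(weights, "weight_vector")) weights$values else weights
  stopifnot(length(v) == length(expression_column),
            all(v %in% c(0L, 1L)))
  e <- as.numeric(expression_column)
  ord <- order(-e, seq_along(e))
  tg <- v[ord] == 1L
  w <- if (weighting == "absolute") abs(e[ord]) else rep(1, length(e))
  fg_w <- ifelse(tg, w, 0)
  bg_w <- ifelse(tg, 0, w)
  tot_fg <- sum(fg_w)
  tot_bg <- sum(bg_w)
  if (tot_fg == 0) fg_w <- ifelse(tg, 1 / sum(tg), 0) else fg_w <- fg_w / tot_fg
  if (tot_bg == 0) bg_w <- ifelse(tg, 0, 1 / sum(!tg)) else bg_w <- bg_w / tot_bg
  structure(list(foreground = cumsum(fg_w), background = cumsum(bg_w),
                 order = ord),
            class = "curve_pair")
}

#' Preliminary activity score from a curve pair
#'
#' The signed maximum-magnitude deviation between the foreground and
#' background curves, analogous to the Kolmogorov-Smirnov D statistic:
#' `D(k) = F(k) - B(k)`, returned at the rank maximising `|D|` (smallest rank
#' on ties). Positive scores indicate that target genes concentrate among
#' the highest relative expression (higher target activity), negative scores
#' the reverse.
#'
#' @param curves A `curve_pair` from [sample_curves()].
#' @return A single numeric score in `[-1, 1]`.
#' @export
preliminary_score <- function(curves) {
  stopifnot(inherits(curves, "curve_pair"))
  d <- curves$foreground - curves$background
  d[which.max(abs(d))]
}

#' Per-sample regulator activity (iRAS) with permutation normalization
#'
#' Computes the preliminary running-sum score of a target gene list for every
#' sample, then normalizes each sample's score by the mean absolute
#' preliminary score of `n_permutations` random gene sets of the same
#' effective size, drawn uniformly without replacement from all matrix genes.
#' One shared collection of permuted sets, generated from `seed`, is reused
#' across all samples so that scores are comparable between samples. The
#' ratio is the individual Regulatory Activity Score (iRAS).
#'
#' @param set A [gene_set()].
#' @param x An [expression_matrix()] with `channel_mode = "pre_normalized"`
#'   (see [normalize_expression()]).
#' @param n_permutations Number of random sets for the null (default 1000).
#' @param seed Integer seed driving the permutation draw.
#' @param weighting Passed to the running-sum kernel; see [sample_curves()].
#' @return An object of class `activity_profile`: list with `regulator`,
#'   `scores` (iRAS per sample), `preliminary`, `null_mean_abs`,
#'   `n_targets_effective`, `n_permutations`, `seed`.
#' @export
compute_iras <- function(set, x, n_permutations = 1000L, seed = 1L,
                         weighting = c("absolute", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(x, "expression_matrix"))
  if (channel_mode(x) != "pre_normalized") {
    stop_ictair("expression matrix must be normalized first; ",
                "call normalize_expression()")
  }
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop_ictair("n_permutations must be a positive integer")
  }
  wv <- make_weight_vector(set, x)
  n <- nrow(x)
  k <- wv$n_targets_effective
  memb <- matrix(0L, nrow = n, ncol = n_permutations + 1L)
  memb[, 1L] <- wv$values
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      memb[sample.int(n, k), p + 1L] <- 1L
    }
  })
  scores <- base_scores_cpp(unclass(x), memb, weighting == "absolute")
  preliminary <- scores[1L, ]
  null_mean_abs <- colMeans(abs(scores[-1L, , drop = FALSE]))
  if (any(null_mean_abs == 0)) {
    bad <- colnames(x)[which(null_mean_abs == 0)[1L]]
    stop_ictair("permutation null is degenerate (all-zero scores) for ",
                "sample '", bad, "'")
  }
  iras <- preliminary / null_mean_abs
  names(iras) <- names(preliminary) <- names(null_mean_abs) <- colnames(x)
  structure(list(regulator = set$name, scores = iras,
                 preliminary = preliminary, null_mean_abs = null_mean_abs,
                 n_targets_effective = k, dropped = wv$dropped,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "<activity_profile> %s: %d samples, %d effective targets, %d perms\n",
    x$regulator, length(x$scores), x$n_targets_effective, x$n_permutations))
  invisible(x)
}

#' Score a collection of gene sets into an activity matrix
#'
#' Applies [compute_iras()] to each set; each set's permutation null is drawn
#' from a sub-seed derived deterministically from `seed` and the set name, so
#' per-set results are independent of collection order and composition. Sets
#' that fail (e.g. no members in the matrix) are skipped with a warning.
#'
#' @inheritParams compute_iras
#' @param sets A list of [gene_set()] objects.
#' @return An `activity_matrix`: numeric matrix (regulators x samples) with
#'   attributes `n_permutations` and `seed`, plus `errors` (named list of
#'   failure messages, possibly empty).
#' @export
score_collection <- function(sets, x, n_permutations = 1000L, seed = 1L,
                             weighting = c("absolute", "uniform")) {
  weighting <- match.arg(weighting)
  scores <- list()
  errors <- list()
  n_targets <- integer(0)
  for (s in sets) {
    prof <- tryCatch(
      compute_iras(s, x, n_permutations,
                   seed = derive_seed(seed, s$name), weighting = weighting),
      error = function(e) e)
    if (inherits(prof, "error")) {
      warning("skipping '", s$name, "': ", conditionMessage(prof),
              call. = FALSE)
      errors[[s$name]] <- conditionMessage(prof)
    } else {
      scores[[s$name]] <- prof$scores
      n_targets[[s$name]] <- prof$n_targets_effective
    }
  }
  m <- do.call(rbind, scores)
  if (is.null(m)) m <- matrix(numeric(0), 0L, ncol(x),
                              dimnames = list(NULL, colnames(x)))
  out <- activity_matrix(m, n_permutations = n_permutations, seed = seed,
                         errors = errors)
  attr(out, "n_targets_effective") <- n_targets
  out
}

#' Construct an activity (iRAS) matrix
#'
#' @param scores Numeric matrix, regulators x samples, with dimnames.
#' @param n_permutations,seed Permutation-null metadata recorded on the
#'   object.
#' @param errors Optional named list of per-regulator scoring failures.
#' @return A matrix of class `activity_matrix`.
#' @export
activity_matrix <- function(scores, n_permutations, seed, errors = list()) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (any(!is.finite(scores))) stop_ictair("activity scores must be finite")
  structure(scores, n_permutations = as.integer(n_permutations),
            seed = as.integer(seed), errors = errors,
            class = c("activity_matrix", class(scores)))
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d regulators x %d samples (%d perms)\n",
              nrow(x), ncol(x), attr(x, "n_permutations")))
  invisible(x)
}

#' Write an activity matrix to TSV
#'
#' Regulators as rows (input order preserved), samples as columns; values at
#' 15 significant digits.
#'
#' @param x An [activity_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_activity <- function(x, path) {
  write_named_matrix(x, path, first_col = "regulator")
}

#' Read an activity matrix written by [write_activity()]
#'
#' @param path Path to the TSV file.
#' @param n_permutations,seed Metadata to record (not stored in the TSV).
#' @return An [activity_matrix()].
#' @export
read_activity <- function(path, n_permutations = NA_integer_,
                          seed = NA_integer_) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  activity_matrix(m, n_permutations, seed)
}
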