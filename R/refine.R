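#' Refinement parameters
#'
#' Bundles the tuning parameters of the iterative refinement loop. The
#' defaults are deliberately permissive: a minimum Spearman correlation of
#' 0.1 drops only targets with essentially no monotone association with the
#' inferred activity, the size floor of 20 keeps lists usable for downstream
#' scoring, and 10 iterations comfortably exceeds the handful typically
#' needed for membership to stabilize.
#'
#' @param min_rho Minimum Spearman correlation in `[0, 1]` a target must
#'   reach to be kept (default 0.1). Targets strictly below are dropped;
#'   equality keeps.
#' @param min_size Minimum allowable target-list length (default 20,
#'   must be >= 2).
#' @param max_iterations Maximum refine cycles (default 10; 0 means return
#'   the input unchanged).
#' @param n_permutations Permutations per activity calculation
#'   (default 1000).
#' @param seed Master seed; all iteration- and set-level randomness derives
#'   from it.
#' @return A list of class `refine_params`.
#' @export
refine_params <- function(min_rho = 0.1, min_size = 20L, max_iterations = 10L,
                          n_permutations = 1000L, seed = 1L) {
  stopifnot(is.numeric(min_rho), length(min_rho) == 1L,
            min_rho >= 0, min_rho <= 1)
  min_size <- as.integer(min_size)
  max_iterations <- as.integer(max_iterations)
  if (is.na(min_size) || min_size < 2L) {
    stop_ictair("min_size must be an integer >= 2")
  }
  if (is.na(max_iterations) || max_iterations < 0L) {
    stop_ictair("max_iterations must be a non-negative integer")
  }
  structure(list(min_rho = min_rho, min_size = min_size,
                 max_iterations = max_iterations,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "refine_params")
}

#' Spearman rank correlation with average-rank ties
#'
#' Ranks both vectors (ties receive average ranks) and returns the
#' product-moment correlation of the rank vectors. On tie-free input this
#' equals the classical closed form `1 - 6 * sum(d^2) / (s * (s^2 - 1))`,
#' where `d` is the per-sample rank difference and `s` the number of
#' samples. If either vector has zero rank variance (constant input) the
#' correlation is undefined and `NA` is returned; the refinement loop treats
#' such targets as failing the threshold, since a constant expression row
#' cannot evidence co-activity.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' One refine cycle: score, correlate, prune
#'
#' Computes the per-sample activity (iRAS) of the current target list, then
#' the Spearman correlation between each listed target's expression row and
#' the activity vector across samples. Targets whose correlation is strictly
#' below `params$min_rho` (or undefined) are dropped.
#'
#' @param set Current [gene_set()].
#' @param x A pre-normalized [expression_matrix()].
#' @param params A [refine_params()].
#' @param seed Seed for this cycle's permutation null (defaults to
#'   `params$seed`).
#' @return A list with `set` (pruned [gene_set()], possibly empty members
#'   represented as a zero-length `kept` — see Details), `rho` (named
#'   per-target correlations, `NA` where undefined), `kept` (logical), and
#'   `profile` (the `activity_profile`).
#' @details The pruned set retains only members present in the matrix; when
#'   every target fails the threshold, `set` is `NULL` and `kept` is all
#'   `FALSE`.
#' @export
refine_once <- function(set, x, params = refine_params(),
                        seed = params$seed) {
  stopifnot(inherits(set, "gene_set"), inherits(params, "refine_params"))
  profile <- compute_iras(set, x, params$n_permutations, seed = seed)
  targets <- setdiff(set$members, profile$dropped)
  rho <- vapply(targets, function(g) spearman_rho(x[g, ], profile$scores),
                numeric(1L))
  kept <- !is.na(rho) & rho >= params$min_rho
  new_set <- if (any(kept)) {
    gene_set(set$name, targets[kept], set$description)
  }
  list(set = new_set, rho = rho, kept = kept, profile = profile)
}

#' Iteratively refine a regulator's target list
#'
#' Repeats [refine_once()] until one of three conditions fires:
#' * `stable` — the pruned membership equals the previous membership;
#' * `floor` — pruning would shrink the list below `params$min_size`; the
#'   last compliant (>= `min_size`) list is returned;
#' * `max_iterations` — the iteration budget is exhausted.
#'
#' Each iteration draws a fresh permutation null from a sub-seed derived
#' deterministically from `params$seed`, the set name, and the iteration
#' number, so whole runs are reproducible from the master seed while no
#' single Monte-Carlo draw is frozen into every cycle.
#'
#' @inheritParams refine_once
#' @return A list of class `refinement_result` with `regulator`,
#'   `final_set`, `initial_size`, `iterations_run`, `termination` (one of
#'   `"stable"`, `"floor"`, `"max_iterations"`), and `trace` — one record
#'   per iteration with `size_before`, `size_after`, `dropped` (gene
#'   symbols), `rho`, and an iRAS summary.
#' @export
ictair <- function(set, x, params = refine_params()) {
  stopifnot(inherits(set, "gene_set"), inherits(params, "refine_params"))
  current <- effective_set(set, x)
  if (length(current$members) < params$min_size) {
    stop_ictair("gene set '", set$name, "' has ",
                length(current$members), " effective target(s), below the ",
                "minimum list length ", params$min_size)
  }
  trace <- list()
  termination <- "max_iterations"
  iterations_run <- 0L
  if (params$max_iterations > 0L) {
    for (iter in seq_len(params$max_iterations)) {
      step <- refine_once(current, x, params,
                          seed = derive_seed(params$seed,
                                             paste0(set$name, "#", iter)))
      iterations_run <- iter
      candidate <- step$set
      cand_members <- if (is.null(candidate)) character(0) else
        candidate$members
      trace[[iter]] <- list(
        iteration = iter,
        size_before = length(current$members),
        size_after = length(cand_members),
        dropped = setdiff(current$members, cand_members),
        rho = step$rho,
        iras_mean = mean(step$profile$scores),
        iras_sd = stats::sd(step$profile$scores))
      if (length(cand_members) < params$min_size) {
        termination <- "floor"
        break
      }
      if (setequal(cand_members, current$members)) {
        current <- candidate
        termination <- "stable"
        break
      }
      current <- candidate
    }
  }
  structure(list(regulator = set$name, final_set = current,
                 initial_size = length(set$members),
                 iterations_run = iterations_run,
                 termination = termination, trace = trace,
                 params = params),
            class = "refinement_result")
}

# Restrict a set to members present in the matrix (quietly; scoring itself
# warns about dropped symbols).
effective_set <- function(set, x) {
  members <- intersect(set$members, rownames(x))
  if (length(members) == 0L) {
    stop_ictair("gene set '", set$name, "' has no members in the matrix")
  }
  suppressWarnings(gene_set(set$name, members, set$description))
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> %s: %d -> %d genes in %d iteration(s) [%s]\n",
              x$regulator, x$initial_size, length(x$final_set$members),
              x$iterations_run, x$termination))
  invisible(x)
}

#' Per-iteration trace as a data frame
#'
#' One row per refine cycle: list size before and after pruning, number of
#' genes dropped, and the termination reason (on the last row).
#'
#' @param result A `refinement_result` from [ictair()].
#' @return A data frame with columns `regulator`, `iteration`,
#'   `size_before`, `size_after`, `n_dropped`, `termination`.
#' @export
trace_table <- function(result) {
  stopifnot(inherits(result, "refinement_result"))
  n <- length(result$trace)
  if (n == 0L) {
    return(data.frame(regulator = character(0), iteration = integer(0),
                      size_before = integer(0), size_after = integer(0),
                      n_dropped = integer(0), termination = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    regulator = result$regulator,
    iteration = vapply(result$trace, `[[`, 0L, "iteration"),
    size_before = vapply(result$trace, `[[`, 0L, "size_before"),
    size_after = vapply(result$trace, `[[`, 0L, "size_after"),
    n_dropped = vapply(result$trace, function(r) length(r$dropped), 0L),
    termination = c(rep("", n - 1L), result$termination),
    stringsAsFactors = FALSE)
}

#' Refine every gene set in a collection
#'
#' Runs [ictair()] independently on each set. Each set's randomness derives
#' from a sub-seed computed from `params$seed` and the set name, so a set's
#' result is identical whether it is refined alone or in a batch. Per-set
#' errors are collected rather than aborting the batch.
#'
#' @param sets A list of [gene_set()] objects.
#' @inheritParams ictair
#' @return A list with `results` (named list of `refinement_result`, input
#'   order, failures omitted) and `errors` (named list of condition
#'   messages).
#' @export
refine_collection <- function(sets, x, params = refine_params()) {
  results <- list()
  errors <- list()
  for (s in sets) {
    sub <- params
    sub$seed <- derive_seed(params$seed, s$name)
    out <- tryCatch(ictair(s, x, sub), error = function(e) e)
    if (inherits(out, "error")) {
      errors[[s$name]] <- conditionMessage(out)
    } else {
      results[[s$name]] <- out
    }
  }
  list(results = results, errors = errors)
}
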