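# Shared fixtures and independent oracles for the suite.

# Small named expression matrix with reproducible standard-normal entries.
random_matrix <- function(n_genes, n_samples, seed,
                          mode = "pre_normalized") {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes,
                 dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                 sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(vals, mode)
}

# Independent brute-force running-sum oracle: recomputes F, B and D at every
# rank by explicit summation, no cumulative trick, no shared code with the
# package kernel.
brute_curve_score <- function(e, targets, weighting = "absolute") {
  ord <- order(-e, seq_along(e))
  is_t <- ord %in% targets
  w <- if (weighting == "absolute") abs(e[ord]) else rep(1, length(e))
  tot_f <- sum(w[is_t])
  tot_b <- sum(w[!is_t])
  d <- numeric(length(e))
  for (k in seq_along(e)) {
    up <- seq_len(k)
    f <- if (tot_f == 0) sum(is_t[up]) / sum(is_t) else
      sum(w[up][is_t[up]]) / tot_f
    b <- if (tot_b == 0) sum(!is_t[up]) / sum(!is_t) else
      sum(w[up][!is_t[up]]) / tot_b
    d[k] <- f - b
  }
  list(d = d, score = d[which.max(abs(d))])
}

# The worked 6-gene instance: expression already sorted descending, targets
# hold the two highest values.
worked_example <- function() {
  list(e = c(3, 2, 1, -1, -2, -3), weights = c(1L, 1L, 0L, 0L, 0L, 0L),
       d_expected = c(0.6, 1, 6 / 7, 5 / 7, 3 / 7, 0))
}

# Tiny planted-regulon scenario for fast refinement tests.
small_scenario <- function(seed = 1, n_contaminants = 10L) {
  generate_scenario(scenario_spec(
    n_background = 150L, n_true_targets = 25L,
    n_contaminants = n_contaminants, n_samples = 80L, seed = seed))
}

expect_file_identical <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
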