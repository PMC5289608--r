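#' Specify a synthetic planted-regulon scenario
#'
#' Describes a generative model with the statistical structure the
#' refinement algorithm assumes: a latent per-sample regulator activity
#' drives the expression of its true targets linearly, a contaminant block
#' of listed-but-false targets and a large background pool are independent
#' noise. Defaults (scenario S1) plant 40 true targets and 40 contaminants
#' — an initial list precision of 0.5 — over a 500-gene background across
#' 200 samples, with per-gene effects between 0.5 and 1.5 on unit-variance
#' activity and unit-variance noise: signal strong enough that genuine
#' targets correlate clearly with inferred activity while contaminants sit
#' at chance level.
#'
#' @param n_background Background (unlisted, unregulated) gene count.
#' @param n_true_targets True target count (listed, activity-driven).
#' @param n_contaminants Contaminant count (listed, not activity-driven).
#' @param n_samples Sample count.
#' @param effect_low,effect_high Range of per-target effect sizes `beta`
#'   (drawn uniformly).
#' @param noise_sd Residual standard deviation of every gene row.
#' @param activity_sd Standard deviation of the latent activity.
#' @param seed Integer seed; the scenario is a pure function of the spec.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_background = 500L, n_true_targets = 40L,
                          n_contaminants = 40L, n_samples = 200L,
                          effect_low = 0.5, effect_high = 1.5,
                          noise_sd = 1, activity_sd = 1, seed = 42L) {
  stopifnot(n_background >= 1L, n_true_targets >= 1L, n_contaminants >= 0L,
            n_samples >= 2L, effect_low <= effect_high, noise_sd > 0,
            activity_sd > 0)
  structure(list(n_background = as.integer(n_background),
                 n_true_targets = as.integer(n_true_targets),
                 n_contaminants = as.integer(n_contaminants),
                 n_samples = as.integer(n_samples),
                 effect_low = effect_low, effect_high = effect_high,
                 noise_sd = noise_sd, activity_sd = activity_sd,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a synthetic expression matrix with a planted regulon
#'
#' Draws latent activity `a_i ~ N(0, activity_sd^2)` per sample; each true
#' target row is `beta_j * a + N(0, noise_sd^2)` with
#' `beta_j ~ U(effect_low, effect_high)`, while contaminant and background
#' rows are pure `N(0, noise_sd^2)` noise independent of the activity. The
#' listed gene set is the union of true targets and contaminants, so its
#' initial precision is `n_true / (n_true + n_contaminants)` by
#' construction. The matrix is already on a relative scale
#' (`pre_normalized`). Fully determined by `spec$seed`.
#'
#' @param spec A [scenario_spec()].
#' @param regulator Name given to the listed gene set.
#' @return A list with `expression` (an [expression_matrix()],
#'   `(n_background + n_true + n_contaminants) x n_samples`), `set` (the
#'   listed [gene_set()]), and `truth` — a list of class `synthetic_truth`
#'   with `true_targets`, `contaminants`, `activity`, `betas`.
#' @export
generate_scenario <- function(spec = scenario_spec(), regulator = "REG1") {
  stopifnot(inherits(spec, "scenario_spec"))
  genes <- c(sprintf("TGT%03d", seq_len(spec$n_true_targets)),
             if (spec$n_contaminants > 0L)
               sprintf("CON%03d", seq_len(spec$n_contaminants)),
             sprintf("BG%04d", seq_len(spec$n_background)))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  n_genes <- length(genes)
  with_seed(spec$seed, {
    activity <- stats::rnorm(spec$n_samples, 0, spec$activity_sd)
    betas <- stats::runif(spec$n_true_targets, spec$effect_low,
                          spec$effect_high)
    vals <- matrix(stats::rnorm(n_genes * spec$n_samples, 0, spec$noise_sd),
                   nrow = n_genes, dimnames = list(genes, samples))
    vals[seq_len(spec$n_true_targets), ] <-
      vals[seq_len(spec$n_true_targets), , drop = FALSE] +
      outer(betas, activity)
  })
  true_targets <- genes[seq_len(spec$n_true_targets)]
  contaminants <- if (spec$n_contaminants > 0L)
    genes[spec$n_true_targets + seq_len(spec$n_contaminants)] else character(0)
  names(betas) <- true_targets
  names(activity) <- samples
  list(
    expression = expression_matrix(vals, "pre_normalized"),
    set = gene_set(regulator, c(true_targets, contaminants),
                   "synthetic planted regulon"),
    truth = structure(list(true_targets = true_targets,
                           contaminants = contaminants,
                           activity = activity, betas = betas),
                      class = "synthetic_truth"))
}

#' Precision, recall and F1 of a refined list against planted truth
#'
#' @param final A [gene_set()] (the refined list) or character vector of
#'   gene symbols.
#' @param truth A `synthetic_truth` from [generate_scenario()].
#' @return A list with `precision` (`NA` for an empty final list), `recall`
#'   and `f1`.
#' @export
recovery_metrics <- function(final, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  members <- if (inherits(final, "gene_set")) final$members
             else as.character(final)
  tp <- length(intersect(members, truth$true_targets))
  precision <- if (length(members) == 0L) NA_real_ else tp / length(members)
  recall <- tp / length(truth$true_targets)
  f1 <- if (is.na(precision) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Write the planted truth of a scenario to TSV
#'
#' One row per listed gene with its role (`true_target` or `contaminant`)
#' and effect size (`beta`, 0 for contaminants).
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- data.frame(
    gene = c(truth$true_targets, truth$contaminants),
    role = c(rep("true_target", length(truth$true_targets)),
             rep("contaminant", length(truth$contaminants))),
    beta = c(unname(truth$betas), rep(0, length(truth$contaminants))),
    stringsAsFactors = FALSE)
  lines <- c("gene\trole\tbeta",
             paste(df$gene, df$role, sprintf("%.15g", df$beta), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
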