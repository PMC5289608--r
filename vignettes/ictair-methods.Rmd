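---
title: "Contextual refinement of regulator target gene lists with ictair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual refinement of regulator target gene lists with ictair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictair)
```

## The problem

Transcription factors and microRNAs act on different target genes in
different tissues and disease states, but curated target gene lists (such
as the MSigDB c3 motif collections) are context-agnostic and often
permissive: a list assembled from sequence motifs or heterologous
experiments carries many genes that the regulator does not actually control
in the context under study. `ictair` addresses this with two coupled ideas:

1. **Activity scoring.** Given a target list and an expression matrix, the
   regulator's activity in each sample is summarized as a single score
   (the *individual Regulatory Activity Score*, iRAS).
2. **Iterative pruning.** A genuine target in a given context should have
   expression that tracks the regulator's inferred activity across samples.
   Listed genes whose expression fails to rank-correlate with the activity
   are removed, the activity re-inferred from the smaller list, and the
   cycle repeated until membership stabilizes.

## The activity score

For one sample, genes are sorted by descending relative expression
$e_{j,i}$ and two non-decreasing curves are accumulated over that ordering:
a foreground curve $F(k)$ over the listed targets (encoded as a 0/1 weight
vector over the whole gene space) and a background curve $B(k)$ over the
non-targets. Each gene contributes its absolute relative expression
$|e_{j,i}|$ to its class's mass, and both curves are normalized to end at
1, so they encapsulate where the *expression activity* of each class
concentrates in the ranking. The preliminary score is the signed maximal
deviation

$$ D^\* = F(k^\*) - B(k^\*), \qquad k^\* = \arg\max_k |F(k) - B(k)|, $$

the analogue of the Kolmogorov–Smirnov D statistic: positive when targets
crowd the top of the ranking (high target activity), negative when they
crowd the bottom. Ranks tie-break by ascending gene index, and the smallest
$k$ wins among equal deviations, so the statistic is deterministic.

Preliminary scores are not comparable across gene sets of different sizes,
so each sample's score is divided by the mean absolute preliminary score of
`n_permutations` random gene sets of the same effective size (default
1000), drawn uniformly from all genes in the matrix. The ratio is the iRAS:
a value near $\pm 1$ means "no stronger than a random set of this size",
values well beyond $\pm 1$ indicate coherent up-/down-activity. One shared
collection of permuted sets, generated from the user's seed, is reused for
all samples so that scores are comparable between samples; drawing fresh
nulls per sample would change nothing statistically and cost a factor of
the sample count.

Two conventions here were genuinely open choices and are worth stating.
First, the maximal *division* of the curves is implemented as their maximal
signed *difference*, i.e. the KS reading — a literal ratio is undefined
wherever the background curve is still zero. Second, increments are
$|e|$-weighted rather than uniform steps, keeping the score sensitive to
expression magnitude and not just rank; a `weighting = "uniform"` mode is
available for sensitivity checks. Degenerate classes whose total $|e|$ mass
is zero fall back to equal increments of $1/\text{count}$.

### Expression normalization

The running sum operates on *relative* expression. Two-channel (ratio)
microarray data is already relative to its internal reference and is used
as-is; one-channel data has each gene row median-centered across samples
(`normalize_expression()`). Missing values are rejected at load time rather
than imputed — imputation would silently change ranks and hence every
score. Gene identifiers are opaque case-sensitive strings; identifier
mapping is a preprocessing concern, not this package's.

## The refinement loop

Each cycle scores the current list, computes the Spearman correlation
$\rho(t_j)$ between each listed target's expression row and the iRAS vector
(average-rank tie handling; the textbook closed form
$1 - 6\sum d_i^2 / (s(s^2-1))$ is the tie-free special case), and keeps the
targets with $\rho(t_j) \ge$ `min_rho`. Dropping is strict (`<` drops,
equality keeps). Undefined correlations — a constant expression row — are
treated as failing and logged: a constant gene cannot evidence co-activity.

The loop stops when

* membership stabilizes (two consecutive cycles with the same set),
* pruning would cross the `min_size` floor — the last compliant list is
  returned, since the floor exists to guarantee a usable list, or
* `max_iterations` refine cycles have run.

Defaults are `min_rho = 0.1`, `min_size = 20`, `max_iterations = 10`,
`n_permutations = 1000`: a deliberately relaxed criterion that removes only
targets with essentially no monotone association while keeping enough genes
for downstream scoring.

Each iteration redraws its permutation null from a sub-seed derived from
the master seed, the set name and the iteration number. Re-using one null
across iterations would freeze a single Monte-Carlo error into every
cycle; per-iteration redraw keeps iterations independent while remaining
fully reproducible. For the same reason `refine_collection()` derives a
per-set sub-seed from the set name, so a regulator's result does not depend
on which other regulators are in the batch or in what order.

## The regulator network

After refinement, regulator-to-regulator structure is read directly off
the lists: if motif A (annotated to regulator symbol $r_A$) carries another
motif's regulator symbol $r_B$ among its targets, a directed edge
$r_A \to r_B$ is drawn; a regulator listing its own symbol yields an
autoregulatory self-loop. Motifs redundant on one regulator are collapsed
to a single node with the union of their edges. Since miRNA family motifs
may encode several regulators (e.g. `TTTGCAC,MIR-19A,MIR-19B`), the
annotation table maps one motif to any number of symbols, one node each;
unclassified motifs carry no symbol and therefore never form nodes.
Restricting to a motif subset (`restrict_to`) limits both who may regulate
and who may be targeted, and always yields a subnetwork of the full run.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` is the package's stand-in for real tumor expression
cohorts. It implements the simplest generative structure consistent with
the method's premise: a latent per-sample activity
$a_i \sim N(0, \sigma_a^2)$, true target rows
$e_j = \beta_j a + N(0, \sigma^2)$ with per-gene effects
$\beta_j \sim U(\beta_{lo}, \beta_{hi})$, and contaminant plus background
rows that are pure noise. The reference scenario (S1) uses 40 true targets
and 40 contaminants over a 500-gene background across 200 samples, with
$\beta \in [0.5, 1.5]$ and unit noise and activity scales — a listed set
whose precision is exactly 0.5 by construction, with signal strong enough
that genuine targets are clearly separable yet weak enough that the
weakest ($\beta = 0.5$, population Spearman roughly 0.43) is not trivially
so. These sizes keep a full ten-scenario refinement sweep within seconds
while leaving the permutation null (200 draws in the validation runs)
meaningfully stochastic.

The generator is deliberately idealized: Gaussian, homoskedastic,
single-regulator, with independent background genes. It does not mimic
microarray heteroskedasticity, probe-level noise, batch effects,
co-expression among non-targets, or multiple overlapping regulons. Passing
the recovery checks therefore demonstrates that the algorithm removes
uncorrelated contaminants and converges under its own assumptions — not
that it is robust to everything real cohorts contain. Repressed targets
($\beta < 0$) are possible in principle but default off: the one-sided
pruning rule $\rho \ge 0.1$ removes anti-correlated genes by design, and
the generator's default mirrors that behavior rather than hiding it.

## Numerical choices

* Descending-expression sort breaks ties by ascending gene index, stably
  and identically in the R reference path and the compiled kernel.
* Among equal-magnitude deviations the smallest rank wins, making the
  preliminary score exactly reproducible.
* The permutation denominator is validated to be strictly positive; an
  all-zero null (a pathological constant sample) is an error naming the
  sample, not a silent `Inf`.
* Negating a tie-free column negates the preliminary score; this identity
  is exact in real arithmetic and holds to ~1e-15 in floating point (the
  reversed accumulation order perturbs the last bits).
* All randomness flows through a single seeded generator
  (Mersenne-Twister), with sub-seeds derived by hashing the master seed
  with the set name/iteration; repeated runs are byte-identical, and the
  caller's RNG state is left untouched.

## Validation problem sizes

The packaged checks run the null calibration with 500 random size-30 sets
against a 600 × 100 standard-normal matrix at 200 permutations, and the
recovery checks on scenario S1 at 200 permutations across 10 seeds. These
sizes were chosen to give stable Monte-Carlo estimates (calibration means
are reproducibly within a few thousandths of their ideals of 0 and 1) at
desk-scale runtimes; production use on cohort-scale matrices with 1000
permutations changes only the constant factor.

## Known limitations

* The pruning rule is one-sided: repressed targets are removed, not
  recovered. Refining against a signed criterion would be a different
  method.
* Refinement is per-regulator; overlapping regulons are neither modeled
  nor deconvolved, and a contaminant correlated with the true activity by
  chance (or through a co-regulated pathway) will survive.
* The permutation null conditions only on set size, not on expression
  level or variance strata of the member genes.
* Survival modeling and any downstream prognostic analysis are out of
  scope; the activity matrix is the hand-off point to standard tools.
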