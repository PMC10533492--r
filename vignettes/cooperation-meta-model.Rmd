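---
title: "Cooperation meta-models for human and machine diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperation meta-models for human and machine diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopdx)
```

## The problem

A multi-class diagnostic task (the running example is otoendoscopy with six
tympanic-membrane classes: Tp, Ar, Myri, Ome, Tumor, No) is attacked by two
very different kinds of classifier. An ensemble of M deep models emits a
softmax probability vector per sample; it is consistent but biased toward
prevalent classes and weak where training data are scarce. A human rater
emits a single class; raters vary widely in overall accuracy but carry
class-specific expertise that machines lack. Because the final decision —
and the liability — stays with the human, the practical question is how to
fuse the two streams so the combination adapts to the *individual* rater,
not to an average physician.

The package's answer has two ingredients:

1. **A rater profile.** On a small probing set with known labels, tally the
   rater's confusion matrix $C_i(T_l, D_d)$ (rows = true class, columns =
   diagnosed class) and column-normalize it:
   $$p_i(T_l \mid D_d) = \frac{C_i(T_l, D_d)}{\sum_k C_i(T_k, D_d)}.$$
   Column $d$ is the distribution of the truth *given that this rater said
   $d$* — the rater's class-specific tendency turned into a calibrated
   probability. A diagnosis expands into a probability vector by reading
   off its column (`expand_response()`).

2. **Weighted fusion.** With $P_M$ the averaged machine vector, $\delta$
   the one-hot human response and $P_H$ the conditional-probability
   expansion, the scalar schemes are
   $$S = 0.5\,P_M + 0.5\,P_H \quad (\text{CavgMH}),$$
   $$S = (1-w^*)\,P_M + w^*\,\delta \quad (\text{PoptMH}),$$
   $$S = (1-w^*)\,P_M + w^*\,P_H \quad (\text{PCoptMH}),$$
   with the decision $\arg\max_c S_c$. CavgMH uses the class-specific
   tendency but ignores overall skill; PoptMH uses overall skill (through
   the fitted $w^*$) but collapses the rater to a delta; PCoptMH uses both.
   A simpler ensemble, `alpha_vote()`, adds $\alpha\,\delta$
   ($0 \le \alpha \le 4$) to the *sum* of the M softmax vectors: $\alpha=0$
   is machines-only, $\alpha=4$ dominates any sum of four sub-unit maxima
   and hence always follows the human. The general form,
   `combine_matrix()`/`fit_weight_matrix()`, gives every classifier its own
   weight per class through an $(M{+}1)\times C$ matrix $W$.

Weights are fitted on the probing set by minimizing cross-entropy between
the weighted score rows and the one-hot truth.

## Numerical choices

* **Cross-entropy.** Score rows are renormalized to sum to 1 before the
  log; for convex combinations of probability vectors this is a no-op, and
  for a free weight matrix it makes the loss scale-invariant (verified by a
  property test). Entries are clipped to `[clip_eps, 1]`, default
  `clip_eps = 1e-9`, purely to keep the logarithm finite.
* **Scalar fit.** The 1-D loss is convex in `w`, so a dense grid (step
  0.01) brackets the optimum and `stats::optimize()` (golden
  section/parabolic) refines it to ~1e-9 in `w`. The procedure is
  deterministic; tests certify it against an exhaustive 1e-3 grid, where
  the refinement is typically ~1e-7 *better* than the best grid point.
  `w` is constrained to `[0, 1]`: the scheme formulas are convex
  combinations, and weights outside the simplex have no interpretation in
  this fusion.
* **Matrix fit.** Projected gradient descent with backtracking line search,
  uniform initialization at `1/(M+1)`, projection onto the nonnegative
  orthant, iteration cap 5,000 and tolerance 1e-10 on the loss change. The
  accepted-loss trace is non-increasing by construction. Nonnegativity is a
  package constraint: negative classifier weights destabilize the argmax
  and have no reading as "trust". With `row_constant = TRUE` the fit is
  restricted to one scalar per classifier, which spans the same family as
  the scalar schemes up to overall scale (used as an internal consistency
  check).
* **Ties.** Every argmax breaks ties toward the lowest class index,
  deterministically; class order is fixed once by the `label_space` and
  enforced everywhere.
* **Zero diagnosis columns.** If a rater never produced diagnosis $d$ on
  the probing set, the column of the conditional matrix is undefined. The
  default (`uniform_fallback`) substitutes the uniform distribution $1/C$
  — an uninformative prior that keeps downstream fusion defined without
  inventing confidence; `laplace` smoothing (pseudocount 0.5) is available,
  and `none` refuses loudly. The fallback columns are recorded in the
  matrix's metadata and surfaced in protocol notes, since with 30 probing
  samples over 6 classes empty columns are a real possibility.

## The evaluation protocol

`assemble_split()` draws the probing set only from the balanced cohort,
stratified by class with largest-remainder apportionment (30 probing
samples over 6 balanced classes is exactly 5 per class; sizes not divisible
by C are resolved by largest remainder, ties toward the lower class index).
The test set is everything else from both cohorts, so 300+300 samples with
100 probing leaves 500 for testing. `probing_protocol()` repeats this for
`folds = 5` independent stratified draws (seeds derived as `seed + fold`):
the draws are independent rather than a partition because the probing pool
(balanced only) and the test pool (both cohorts) are asymmetric — a true
5-fold partition of one set is not defined here. Reported quantities are
per-scheme accuracy, per-class recall (a class absent from a fold's test
truth is reported as missing, never coerced to 0), the gain over the rater
alone, and the gain bin
(decrease, (0,0.05], (0.05,0.1], (0.1,0.2], (0.2,0.3], >0.3).

## What the simulator emulates

The generator exists so the method can be exercised and tested without
clinical data; its defaults encode the study conditions the package
targets.

* **Prevalences.** `balanced` is $1/6$ per class (the 300-sample balanced
  set, 50 per class in quota mode); `imbalanced` uses the tertiary-referral
  case mix 51/20/15/29/18/167 over 300 (shares 17.00, 6.67, 5.00, 9.67,
  6.00, 55.67 percent).
* **Raters.** A rater is a row-stochastic confusion-probability matrix;
  diagnoses are drawn per sample from the row of the true class.
  `calibrate_profile()` scales diagonal against off-diagonal mass
  (preserving off-diagonal proportions) so the expected accuracy under a
  stated prevalence hits a target exactly. The `ent` preset targets 0.7117
  and the `non_ent` preset 0.4563 under balanced prevalence — the two
  physician-group accuracy levels the package is designed around — with
  heterogeneous class profiles (strong on Tumor and Myri, weak on Ome,
  effusions leaking into "normal"), because class-heterogeneity is exactly
  what the conditional-probability machinery is meant to exploit.
  `rater_population()` jitters the base shape log-normally per rater and
  recalibrates to an accuracy drawn from the group's mean and spread
  (0.7117 ± 0.0337, 0.4563 ± 0.0789), producing a plausible physician
  panel.
* **Machines.** Each of M = 4 models draws its softmax vector from a
  Dirichlet whose mean is the (per-model jittered) base confusion row of
  the true class, tilted by `prev^beta` to emulate prevalence bias, with
  total concentration `kappa`. Models are conditionally independent given
  the truth; the paper-like regime of partially redundant deep ensembles is
  approximated by the shared base shape plus small per-model jitter
  (`jitter = 0.06`). The preset base is strong on the four well-trained
  classes and systematically confusable on the two rare ones (Myri, Tumor),
  which is what makes human cooperation valuable at all; with
  `kappa = 5.5` the 4-model average lands near 0.80 argmax accuracy on a
  balanced cohort while per-model softmax maxima average ~0.58 (so the
  per-sample sum of maxima sits near 2.3, inside the 2–3 band typical of
  four-model softmax ensembles). `beta = 0.4` reproduces a mid-80s%
  accuracy on the imbalanced case mix; matching the balanced and imbalanced
  accuracy levels simultaneously over-constrains one exponent, so `beta`
  is an explicit tunable rather than a guarantee.
* **Not emulated.** Image content, per-sample difficulty correlations
  between humans and machines (a rater and the panel err independently
  given the class), rater drift or learning over time, and multi-label
  pathology. Passing tests therefore demonstrate that the meta-model's
  machinery behaves as specified under the stated statistical structure —
  not that the specific accuracy figures transfer to any clinical
  population.

## Problem sizes

The test suite runs the full stack at the study's native scale (300+300
cohorts, probing sizes 30–150, five folds) and uses 50 simulated raters for
the comparative check of PCoptMH over PoptMH over the rater alone (paired
sign tests across raters), 50 replicates for the profile-recovery
contrasts, and 3,000-sample draws for the Bayes-conditional recovery bound
(mean absolute error below 0.05). The whole suite completes in well under a
minute on a single CPU.

## A worked example

```{r example}
space <- otoscopy_labels()
machine <- machine_preset()
raters <- list(resident = rater_preset("ent"))

bal <- simulate_cohort(300, prevalence_spec("balanced"), machine,
                       raters, seed = 7)
imb <- simulate_cohort(300, prevalence_spec("imbalanced"), machine,
                       raters, seed = 8)

rep <- probing_protocol(bal, imb, rater = "resident", eval_total = 100,
                        folds = 5, seed = 30)
rep
```

The report's `folds` element carries fold-level accuracies, gains over the
rater alone and their bins; `recall` the per-class recalls per scheme.

## Known limitations

* The conditional matrix treats the probing confusion counts as the whole
  story: no shrinkage toward a population prior beyond the explicit
  smoothing modes, and no uncertainty on $w^*$.
* The matrix-weight model is provided as a method with its own fitting
  contract; the headline protocol reports the scalar schemes, which are
  the ones a small probing set can support ($(M{+}1)\times C$ free
  parameters on 30 samples overfit, as the shuffled-label test
  illustrates).
* Serial cooperation (machine suggestion shown to the human before they
  answer) is out of scope; the package models parallel, independent
  inputs only.
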