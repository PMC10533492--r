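# coopdx

Human–machine cooperation meta-models for multi-class clinical diagnosis.

## What problem this solves

In image-based diagnosis (the running example is otoendoscopy with six
tympanic-membrane classes: Tp, Ar, Myri, Ome, Tumor, No), deep-learning
ensembles and human physicians fail differently: the machine is consistent
but biased toward prevalent classes and weak where training images are
scarce; raters vary widely in overall accuracy but carry class-specific
expertise. Because the human keeps the final decision, the useful system is
one that fuses both streams *adapted to the individual rater*.

`coopdx` implements that adaptation for statisticians and ML engineers
evaluating human-in-the-loop classifiers:

1. **Profile the rater.** From a small probing sample with known labels,
   build the confusion matrix C(T_l, D_d) (rows = true, columns =
   diagnosed) and column-normalize it into the conditional probability of
   the true class given each diagnosis,

       p(T_l | D_d) = C(T_l, D_d) / Σ_k C(T_k, D_d).

   A single diagnosis then expands into a calibrated probability vector —
   the column for the diagnosed class.

2. **Fuse with the machine panel.** With P_M the averaged machine softmax
   vector, δ the one-hot human response and P_H the conditional expansion:

       S = 0.5 P_M + 0.5 P_H              (CavgMH)
       S = (1 − w*) P_M + w* δ            (PoptMH)
       S = (1 − w*) P_M + w* P_H          (PCoptMH)

   and the decision is argmax_c S_c. The scalar weight w* ∈ [0, 1] is
   fitted on the probing sample by cross-entropy minimization; a full
   (M+1)×C per-classifier-per-class weight matrix is available through
   `fit_weight_matrix()`. A simpler α-vote (`alpha_vote()`,
   0 ≤ α ≤ 4) adds α·δ to the summed machine vectors.

3. **Evaluate the way the study design prescribes.** Stratified probing
   draws from a balanced cohort (30/60/100/150 samples), five repeated
   folds, scheme accuracies, per-class recall, and gains over the rater
   alone — plus a calibrated simulator (prevalence models, Dirichlet
   machine panels with prevalence bias, raters drawn from confusion
   profiles) so everything runs without clinical data.

## Worked example

```r
library(coopdx)

machine <- machine_preset()                       # 4-model ensemble, ~80% balanced accuracy
raters  <- list(resident = rater_preset("ent"))   # specialist-like rater, ~71%

bal <- simulate_cohort(300, prevalence_spec("balanced"),   machine, raters, seed = 7)
imb <- simulate_cohort(300, prevalence_spec("imbalanced"), machine, raters, seed = 8)

probing_protocol(bal, imb, rater = "resident", eval_total = 100,
                 folds = 5, seed = 30)
#> probing protocol: 100 probing samples, 5 folds (seed 30 )
#> mean accuracy by scheme:
#>      HI      AI  CavgMH  PoptMH PCoptMH
#>  0.6952  0.8516  0.8136  0.7628  0.8700
```

Reading the numbers: the rater alone (HI) is at 69.5% on the 500-sample
test sets and the machine ensemble (AI) at 85.2%. PoptMH — which only knows
the rater's *overall* accuracy — lands between them at 76.3%. PCoptMH,
which also knows *which classes* this rater gets right, reaches 87.0%:
better than either party alone, because the fitted weight leans on the
rater exactly where the machine is weak (the rare Myri/Tumor classes) and
on the machine elsewhere. CavgMH (fixed 50:50 averaging of the same
conditional information, no fitting) reaches 81.4%.

The profile itself is inspectable:

```r
prof <- rater_profile(bal$truth[1:100], bal$raters$resident[1:100],
                      otoscopy_labels())
prof
#> rater profile over 6 classes ( 100 evaluation samples )
#> overall accuracy: 0.7000
#> smoothing: uniform_fallback
```

A command-line wrapper with `simulate`, `profile`, `fit`, `evaluate` and
`sweep-alpha` subcommands is installed at `inst/cli/coopdx.R`; file formats
for ratings and probability panels are documented in `?write_ratings` and
`?write_panel`.

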