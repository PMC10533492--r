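#' Class prevalence specification
#'
#' `"balanced"` puts mass `1/C` on every class. `"imbalanced"` uses the
#' tertiary-referral case mix of the default otoendoscopy test set: counts
#' 51, 20, 15, 29, 18, 167 over 300 samples for Tp, Ar, Myri, Ome, Tumor,
#' No (shares 17.00, 6.67, 5.00, 9.67, 6.00, 55.67 percent), and requires
#' the 6-class space.
#'
#' @param kind `"balanced"`, `"imbalanced"`, or `"custom"` (requires
#'   `probs`).
#' @param space A `label_space` (default [otoscopy_labels()]).
#' @param probs Length-C probability vector for `kind = "custom"`.
#' @return A `prevalence_spec`: list with `probs` (sums to 1), `counts`
#'   (reference counts per 300 samples, when defined), `kind`, `space`.
#' @export
prevalence_spec <- function(kind = c("balanced", "imbalanced", "custom"),
                            space = otoscopy_labels(), probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(probs) || length(probs) != space$C || any(probs < 0) ||
        abs(sum(probs) - 1) > 1e-8) {
      stop("custom prevalence needs a length-C probability vector summing to 1")
    }
    counts <- NULL
  } else if (kind == "balanced") {
    probs <- rep(1 / space$C, space$C)
    counts <- if (300 %% space$C == 0) rep(300 %/% space$C, space$C) else NULL
  } else {
    if (space$C != 6L) {
      stop("the imbalanced reference case mix is defined for the 6-class space")
    }
    counts <- c(Tp = 51L, Ar = 20L, Myri = 15L, Ome = 29L,
                Tumor = 18L, No = 167L)
    probs <- as.numeric(counts) / sum(counts)
  }
  probs <- as.numeric(probs)
  names(probs) <- space$names
  structure(list(probs = probs, counts = counts, kind = kind, space = space),
            class = "prevalence_spec")
}

#' Sample true class labels from a prevalence
#'
#' `"quota"` mode apportions `n` across classes by largest remainder (exact
#' class counts, e.g. 50 per class for a balanced 300-sample cohort) and
#' shuffles the order; `"multinomial"` draws i.i.d. from the prevalence.
#'
#' @param n Number of samples.
#' @param prev A `prevalence_spec`.
#' @param seed Integer seed.
#' @param mode `"quota"` (default) or `"multinomial"`.
#' @return Integer label vector of length `n`.
#' @export
sample_truth <- function(n, prev, seed, mode = c("quota", "multinomial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(prev, "prevalence_spec"), n >= 1)
  C <- prev$space$C
  if (mode == "quota") {
    counts <- largest_remainder(n * prev$probs)
    labs <- rep(seq_len(C), counts)
    with_seed(seed, sample(labs))
  } else {
    with_seed(seed, sample.int(C, n, replace = TRUE, prob = prev$probs))
  }
}

# integer apportionment of (possibly fractional) quotas, largest remainder,
# ties resolved toward the lowest class index
largest_remainder <- function(quota) {
  base <- floor(quota)
  rem <- quota - base
  extra <- round(sum(quota)) - sum(base)
  if (extra > 0) {
    ord <- order(-rem, seq_along(quota))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Simulated-rater profile
#'
#' A generating row-stochastic confusion-probability matrix: row `t` is the
#' distribution of diagnoses the rater produces on samples of true class
#' `t`. The expected overall accuracy under a prevalence `pi` is
#' `sum_c pi_c * profile[c, c]`.
#'
#' @param probs C x C row-stochastic matrix.
#' @param space A `label_space`.
#' @param label Free-text description.
#' @return A `rater_sim_profile`.
#' @export
rater_sim_profile <- function(probs, space, label = "custom") {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == space$C, ncol(probs) == space$C,
            all(probs >= 0))
  if (any(abs(rowSums(probs) - 1) > 1e-8)) {
    stop("profile rows must sum to 1")
  }
  dimnames(probs) <- list(true = space$names, diagnosed = space$names)
  structure(list(probs = probs, space = space, label = label),
            class = "rater_sim_profile")
}

#' Calibrate a rater profile to a target overall accuracy
#'
#' Scales every diagonal entry by a common factor and rescales each row's
#' off-diagonal mass proportionally, so that the expected accuracy under
#' `prev` equals `target` exactly while per-class diagonals keep their
#' relative pattern.
#'
#' @param base C x C row-stochastic base shape (relative diagonals matter;
#'   the overall level is recalibrated).
#' @param target Target expected accuracy in `(1/C, 1]`.
#' @param prev A `prevalence_spec`.
#' @param label Description carried into the profile.
#' @return A `rater_sim_profile` with expected accuracy `target` (to 1e-9).
#' @export
calibrate_profile <- function(base, target, prev, label = "calibrated") {
  space <- prev$space
  base <- as.matrix(base)
  stopifnot(nrow(base) == space$C, ncol(base) == space$C)
  if (target <= 1 / space$C || target > 1) {
    stop("target accuracy must lie in (1/C, 1], got ", target)
  }
  base <- base / rowSums(base)
  d <- diag(base)
  s <- target / sum(prev$probs * d)
  new_d <- s * d
  if (any(new_d > 1 + 1e-12)) {
    stop("target ", target, " unreachable: scaling pushes a diagonal above 1")
  }
  new_d <- pmin(new_d, 1)
  out <- base
  for (c in seq_len(space$C)) {
    off <- base[c, -c]
    off_mass <- 1 - d[c]
    if (off_mass <= 0) {
      if (abs(new_d[c] - 1) > 1e-12) {
        stop("row ", c, " has no off-diagonal mass to rescale")
      }
      next
    }
    out[c, -c] <- off * (1 - new_d[c]) / off_mass
    out[c, c] <- new_d[c]
  }
  rater_sim_profile(out, space, label)
}

#' Bayes-implied conditional matrix of a simulated rater
#'
#' The population P(true = l | diagnosed = d) implied by a generating
#' profile and a prevalence:
#' `pi_l * profile[l, d] / sum_k pi_k * profile[k, d]`. This is the matrix
#' that [conditional_from_confusion()] estimates from finite rater data.
#'
#' @param profile A `rater_sim_profile`.
#' @param prev A `prevalence_spec`.
#' @return C x C column-stochastic matrix (columns = diagnosed class).
#' @export
bayes_conditional <- function(profile, prev) {
  joint <- profile$probs * prev$probs # row l scaled by pi_l
  sweep(joint, 2L, colSums(joint), "/")
}

#' Expected accuracy of a simulated-rater profile under a prevalence
#'
#' @param profile A `rater_sim_profile`.
#' @param prev A `prevalence_spec`.
#' @return Scalar expected accuracy.
#' @export
expected_accuracy <- function(profile, prev) {
  sum(prev$probs * diag(profile$probs))
}

# base confusion shapes: plausible otoscopic error structure -- effusions
# are confused with normal ears and retractions, perforations with
# retractions, tumors/myringitis are visually salient. Rows are relative
# shapes; calibrate_profile() sets the overall level.
ent_base_shape <- function() {
  rbind(
    Tp    = c(0.78, 0.10, 0.03, 0.04, 0.01, 0.04),
    Ar    = c(0.08, 0.68, 0.02, 0.10, 0.02, 0.10),
    Myri  = c(0.03, 0.02, 0.82, 0.04, 0.05, 0.04),
    Ome   = c(0.04, 0.10, 0.04, 0.52, 0.03, 0.27),
    Tumor = c(0.02, 0.02, 0.06, 0.03, 0.85, 0.02),
    No    = c(0.02, 0.06, 0.03, 0.12, 0.02, 0.75)
  )
}

nonent_base_shape <- function() {
  rbind(
    Tp    = c(0.55, 0.14, 0.07, 0.09, 0.04, 0.11),
    Ar    = c(0.14, 0.38, 0.06, 0.15, 0.05, 0.22),
    Myri  = c(0.07, 0.05, 0.58, 0.09, 0.12, 0.09),
    Ome   = c(0.08, 0.14, 0.07, 0.28, 0.05, 0.38),
    Tumor = c(0.05, 0.04, 0.13, 0.06, 0.62, 0.10),
    No    = c(0.05, 0.10, 0.05, 0.20, 0.04, 0.56)
  )
}

#' Preset simulated raters
#'
#' `"ent"` mimics a specialist group (overall accuracy 0.7117 under balanced
#' prevalence, strong on Tumor and Myri, weak on Ome); `"non_ent"` mimics a
#' non-specialist group (0.4563). Both are calibrated with
#' [calibrate_profile()] against the balanced 6-class prevalence.
#'
#' @param which `"ent"` or `"non_ent"`.
#' @param target Optional override of the target overall accuracy.
#' @return A `rater_sim_profile`.
#' @export
rater_preset <- function(which = c("ent", "non_ent"), target = NULL) {
  which <- match.arg(which)
  prev <- prevalence_spec("balanced")
  if (which == "ent") {
    calibrate_profile(ent_base_shape(),
                      if (is.null(target)) 0.7117 else target,
                      prev, label = "ENT-like")
  } else {
    calibrate_profile(nonent_base_shape(),
                      if (is.null(target)) 0.4563 else target,
                      prev, label = "non-ENT-like")
  }
}

#' Draw a population of heterogeneous raters around a preset
#'
#' Per rater, jitters the base shape multiplicatively (log-normal, per cell)
#' and recalibrates to an accuracy drawn from a normal around the group
#' mean, truncated to a feasible range. This yields class-heterogeneous
#' raters whose overall accuracies scatter like a physician group's.
#'
#' @param n_raters Number of raters.
#' @param which `"ent"` (mean 0.7117, sd 0.0337) or `"non_ent"`
#'   (mean 0.4563, sd 0.0789).
#' @param seed Integer seed.
#' @param shape_jitter Log-normal sd of the multiplicative cell jitter.
#' @return List of `rater_sim_profile`s.
#' @export
rater_population <- function(n_raters, which = c("ent", "non_ent"), seed,
                             shape_jitter = 0.35) {
  which <- match.arg(which)
  prev <- prevalence_spec("balanced")
  base <- if (which == "ent") ent_base_shape() else nonent_base_shape()
  mu <- if (which == "ent") 0.7117 else 0.4563
  sdv <- if (which == "ent") 0.0337 else 0.0789
  C <- prev$space$C
  with_seed(seed, {
    lapply(seq_len(n_raters), function(i) {
      repeat {
        shp <- base * matrix(exp(stats::rnorm(C * C, 0, shape_jitter)), C, C)
        shp <- shp / rowSums(shp)
        acc <- stats::rnorm(1, mu, sdv)
        acc <- min(max(acc, 1 / C + 0.05), 0.98)
        # recalibration can overflow a diagonal if the jitter flattened it
        ok <- tryCatch({
          p <- calibrate_profile(shp, acc, prev,
                                 label = sprintf("%s rater %d", which, i))
          TRUE
        }, error = function(e) FALSE)
        if (ok) return(p)
      }
    })
  })
}

#' Simulate a rater's diagnoses
#'
#' For each sample, draws the diagnosis from the profile row of the true
#' class.
#'
#' @param truth Integer label vector.
#' @param profile A `rater_sim_profile`.
#' @param seed Integer seed.
#' @return Integer diagnosis vector, same length as `truth`.
#' @export
simulate_rater <- function(truth, profile, seed) {
  stopifnot(inherits(profile, "rater_sim_profile"))
  C <- profile$space$C
  with_seed(seed, {
    vapply(truth, function(t) {
      sample.int(C, 1L, prob = profile$probs[t, ])
    }, integer(1))
  })
}

#' Machine-panel simulation profile
#'
#' Describes an M-model softmax panel: a base row-stochastic
#' confusion-probability shape, a Dirichlet concentration `kappa`
#' controlling how peaked individual softmax draws are, a prevalence-bias
#' exponent `beta` (mean vectors are tilted by `prev^beta`, emulating the
#' over-prediction of common classes learned from imbalanced training
#' data), and a per-model multiplicative jitter of the base shape.
#'
#' @param base C x C row-stochastic matrix (mean classification behaviour).
#' @param kappa Dirichlet concentration, > 0.
#' @param beta Prevalence-bias exponent, >= 0.
#' @param n_models Number of models M.
#' @param jitter Log-normal sd of the per-model shape jitter.
#' @param space A `label_space`.
#' @return A `machine_sim_profile`.
#' @export
machine_sim_profile <- function(base, kappa, beta = 0, n_models = 4L,
                                jitter = 0.05, space = otoscopy_labels()) {
  base <- as.matrix(base)
  stopifnot(nrow(base) == space$C, ncol(base) == space$C, all(base >= 0))
  if (!is.finite(kappa) || kappa <= 0) {
    stop("kappa must be a finite positive concentration, got ", kappa)
  }
  if (beta < 0) stop("beta must be >= 0")
  base <- base / rowSums(base)
  structure(list(base = base, kappa = kappa, beta = beta,
                 n_models = as.integer(n_models), jitter = jitter,
                 space = space),
            class = "machine_sim_profile")
}

# base shape for the deep-ensemble preset. The strong rows have clearly
# dominant diagonals (ensemble recall ~1 after averaging); Myri and Tumor --
# the classes with scarce training data in real otoendoscopy cohorts -- have
# near-tied competitors, so the ensemble errs systematically there. At
# kappa = 5.5 the 4-model average lands ~0.80 argmax accuracy on a balanced
# cohort with per-model softmax maxima averaging ~0.58 (max-sum ~2.3).
machine_base_shape <- function() {
  rbind(
    Tp    = c(0.62, 0.12, 0.04, 0.06, 0.03, 0.13),
    Ar    = c(0.10, 0.55, 0.04, 0.12, 0.04, 0.15),
    Myri  = c(0.16, 0.06, 0.27, 0.08, 0.24, 0.19),
    Ome   = c(0.06, 0.10, 0.05, 0.54, 0.04, 0.21),
    Tumor = c(0.08, 0.05, 0.22, 0.06, 0.29, 0.30),
    No    = c(0.04, 0.07, 0.04, 0.10, 0.03, 0.72)
  )
}

#' Preset machine-panel profile
#'
#' A 4-model ensemble whose balanced-cohort argmax accuracy sits near 0.80
#' and whose per-sample sum of per-model softmax maxima averages about 2.3
#' (kappa = 5.5, jitter = 0.06); it is weak on the rare visually-confusable
#' classes (Myri, Tumor) and strong elsewhere. `beta` defaults to 0.4 so
#' the panel over-predicts prevalent classes on imbalanced cohorts (about
#' 0.86 accuracy on the imbalanced case mix).
#'
#' @param kappa,beta,n_models,jitter Overrides of the preset values.
#' @return A `machine_sim_profile`.
#' @export
machine_preset <- function(kappa = 5.5, beta = 0.4, n_models = 4L,
                           jitter = 0.06) {
  machine_sim_profile(machine_base_shape(), kappa = kappa, beta = beta,
                      n_models = n_models, jitter = jitter)
}

# one Dirichlet draw per row of `alpha` (n x C matrix of concentrations)
rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow(alpha), ncol(alpha))
  # guard: rgamma can return exactly 0 for tiny shapes
  g[g <= 0] <- .Machine$double.xmin
  g / rowSums(g)
}

#' Simulate a machine softmax panel
#'
#' For each sample (true class `t`) and model `m`, the mean vector is the
#' model-jittered base row `t` tilted by `prev^beta` and renormalized; the
#' softmax vector is a Dirichlet draw with that mean and concentration
#' `kappa`. Models are conditionally independent given the truth.
#'
#' @param truth Integer label vector (length N).
#' @param profile A `machine_sim_profile`.
#' @param seed Integer seed.
#' @param prev Optional `prevalence_spec` used for the bias tilt; default
#'   balanced (no tilt when `beta = 0` or prevalence is uniform).
#' @return N x C x M array; every `[n, , m]` slice sums to 1.
#' @export
simulate_machine_panel <- function(truth, profile, seed,
                                   prev = prevalence_spec("balanced",
                                                          profile$space)) {
  stopifnot(inherits(profile, "machine_sim_profile"))
  C <- profile$space$C
  M <- profile$n_models
  N <- length(truth)
  tilt <- prev$probs ^ profile$beta
  with_seed(seed, {
    panel <- array(NA_real_, c(N, C, M),
                   dimnames = list(NULL, profile$space$names,
                                   paste0("M", seq_len(M))))
    for (m in seq_len(M)) {
      jit <- matrix(exp(stats::rnorm(C * C, 0, profile$jitter)), C, C)
      base_m <- profile$base * jit
      base_m <- sweep(base_m, 2L, tilt, "*")
      base_m <- base_m / rowSums(base_m)
      means <- base_m[truth, , drop = FALSE]
      panel[, , m] <- rdirichlet_rows(profile$kappa * means)
    }
    panel
  })
}

#' Simulate a labeled cohort
#'
#' Truth labels, a machine panel, and one or more raters' diagnoses over the
#' same samples: the unit every downstream module consumes.
#'
#' @param n Cohort size.
#' @param prev A `prevalence_spec`.
#' @param machine A `machine_sim_profile`.
#' @param raters Named list of `rater_sim_profile`s (may be empty).
#' @param seed Master seed; per-component seeds are derived from it.
#' @param truth_mode Passed to [sample_truth()].
#' @return A `labeled_cohort`: list with `truth`, `panel`, `raters` (named
#'   list of diagnosis vectors), `space`, `prev`, `seed`.
#' @export
simulate_cohort <- function(n, prev, machine, raters = list(), seed,
                            truth_mode = "quota") {
  stopifnot(inherits(prev, "prevalence_spec"),
            inherits(machine, "machine_sim_profile"))
  truth <- sample_truth(n, prev, seed = seed, mode = truth_mode)
  panel <- simulate_machine_panel(truth, machine, seed = seed + 1L,
                                  prev = prev)
  diag_list <- list()
  if (length(raters)) {
    if (is.null(names(raters)) || any(!nzchar(names(raters)))) {
      names(raters) <- paste0("rater", seq_along(raters))
    }
    diag_list <- lapply(seq_along(raters), function(i) {
      simulate_rater(truth, raters[[i]], seed = seed + 1L + i)
    })
    names(diag_list) <- names(raters)
  }
  structure(list(truth = truth, panel = panel, raters = diag_list,
                 space = prev$space, prev = prev, seed = seed),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("labeled cohort:", length(x$truth), "samples,",
      dim(x$panel)[3], "machine models,",
      length(x$raters), "raters (", x$prev$kind, "prevalence )\n")
  invisible(x)
}
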