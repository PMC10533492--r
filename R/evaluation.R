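#' Draw a probing/test split from a balanced and an imbalanced cohort
#'
#' The probing (evaluation) samples are drawn from the balanced cohort only,
#' stratified by class with largest-remainder apportionment of `eval_total`
#' across the C classes; the test set is everything else from both cohorts,
#' so `|test| = n_bal + n_imb - eval_total` (600 - E for the default
#' 300 + 300 design, e.g. 500 test samples when E = 100).
#'
#' @param balanced_truth Integer labels of the balanced cohort.
#' @param imbalanced_truth Integer labels of the imbalanced cohort.
#' @param eval_total Number of probing samples (0 allowed: machine-only).
#' @param seed Integer seed for the stratified draw.
#' @param space A `label_space`.
#' @return A `split_plan`: list with `eval_idx` (indices into the balanced
#'   cohort), `test_bal_idx`, `test_imb_idx`, `eval_total`, `seed`.
#' @export
assemble_split <- function(balanced_truth, imbalanced_truth, eval_total,
                           seed, space) {
  n_bal <- length(balanced_truth)
  if (eval_total > n_bal) {
    stop("eval_total (", eval_total, ") exceeds the balanced cohort size (",
         n_bal, ")")
  }
  ti <- as_label_index(balanced_truth, space)
  eval_idx <- integer(0)
  if (eval_total > 0) {
    class_n <- tabulate(ti, nbins = space$C)
    quota <- eval_total * class_n / n_bal
    take <- largest_remainder(quota)
    if (any(take > class_n)) {
      stop("stratum smaller than its probing quota; reduce eval_total")
    }
    eval_idx <- with_seed(seed, {
      unlist(lapply(seq_len(space$C), function(c) {
        pool <- which(ti == c)
        if (take[c] == 0L) integer(0)
        else pool[sample.int(length(pool), take[c])]
      }))
    })
    eval_idx <- sort(eval_idx)
  }
  structure(list(eval_idx = eval_idx,
                 test_bal_idx = setdiff(seq_len(n_bal), eval_idx),
                 test_imb_idx = seq_along(imbalanced_truth),
                 eval_total = eval_total, seed = seed),
            class = "split_plan")
}

#' Proportion of correct predictions
#'
#' @param pred,truth Equal-length label vectors.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred (", length(pred), ") and truth (", length(truth),
         ") differ in length")
  }
  if (length(pred) == 0L) stop("empty prediction vector")
  mean(pred == truth)
}

#' Per-class recall
#'
#' `recall[c]` is the number of correctly predicted samples of true class
#' `c` divided by the number of true samples of class `c`. A class absent
#' from `truth` has undefined recall and is reported as `NA`, never 0.
#'
#' @param pred,truth Label vectors.
#' @param space A `label_space`.
#' @return Named numeric length-C vector (NA where undefined).
#' @export
per_class_recall <- function(pred, truth, space) {
  pi <- as_label_index(pred, space)
  ti <- as_label_index(truth, space)
  if (length(pi) != length(ti)) stop("pred and truth differ in length")
  out <- vapply(seq_len(space$C), function(c) {
    n_c <- sum(ti == c)
    if (n_c == 0L) NA_real_ else sum(pi == c & ti == c) / n_c
  }, numeric(1))
  names(out) <- space$names
  out
}

#' Bin an accuracy gain the way the cooperation reports do
#'
#' Gains (scheme accuracy minus the human rater's own accuracy) are binned
#' as: `decrease` (gain <= 0), `(0,0.05]`, `(0.05,0.1]`, `(0.1,0.2]`,
#' `(0.2,0.3]`, `>0.3`; boundaries inclusive on the right.
#'
#' @param gain Finite numeric (vectorized).
#' @return Factor with the six bin labels.
#' @export
gain_bin <- function(gain) {
  if (any(!is.finite(gain))) stop("gain must be finite")
  labs <- c("decrease", "(0,0.05]", "(0.05,0.1]", "(0.1,0.2]",
            "(0.2,0.3]", ">0.3")
  cut(gain, breaks = c(-Inf, 0, 0.05, 0.1, 0.2, 0.3, Inf),
      labels = labs, right = TRUE)
}

#' Sweep the human weight of the delta-vote ensemble
#'
#' For every `alpha` on the grid and every rater, classifies each sample by
#' [alpha_vote()] and averages accuracy (and per-class recall) over the
#' raters of each group. The `alpha = 0` row equals the machine-ensemble
#' accuracy for every group by construction.
#'
#' @param panel N x C x M machine panel.
#' @param raters Named list of diagnosis vectors.
#' @param truth Integer truth labels.
#' @param space A `label_space`.
#' @param grid Alpha grid within `[0, 4]` (default step 0.25).
#' @param groups Optional character vector, one group per rater (default one
#'   group `"all"`).
#' @return Data frame with columns `alpha`, `group`, `accuracy`, and one
#'   `recall_<class>` column per class (group means).
#' @export
alpha_sweep <- function(panel, raters, truth, space,
                        grid = seq(0, 4, by = 0.25),
                        groups = NULL) {
  if (length(grid) == 0L) stop("empty alpha grid")
  if (any(grid < 0 | grid > 4)) stop("alpha grid must lie within [0, 4]")
  if (is.null(groups)) groups <- rep("all", length(raters))
  stopifnot(length(groups) == length(raters))
  N <- length(truth)
  # machine score part is alpha-independent: precompute the summed panel
  msum <- apply(panel, c(1L, 2L), sum)
  rows <- list()
  for (a in grid) {
    per_rater_acc <- numeric(length(raters))
    per_rater_rec <- matrix(NA_real_, length(raters), space$C)
    for (r in seq_along(raters)) {
      d <- as_label_index(raters[[r]], space)
      score <- msum
      score[cbind(seq_len(N), d)] <- score[cbind(seq_len(N), d)] + a
      pred <- max.col(score, ties.method = "first")
      per_rater_acc[r] <- accuracy(pred, truth)
      per_rater_rec[r, ] <- per_class_recall(pred, truth, space)
    }
    for (g in unique(groups)) {
      sel <- groups == g
      rec <- colMeans(per_rater_rec[sel, , drop = FALSE])
      row <- data.frame(alpha = a, group = g,
                        accuracy = mean(per_rater_acc[sel]))
      row[paste0("recall_", space$names)] <- as.list(rec)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# evaluate all five schemes for one rater on given test indices, using a
# profile and weights fitted on the probing samples
evaluate_schemes <- function(truth, pm, diags, cond, w_popt, w_pcopt,
                             space, schemes) {
  N <- length(truth)
  d <- as_label_index(diags, space)
  delta <- delta_matrix(d, space)
  ph <- cond_matrix_for(d, cond)
  preds <- list()
  if ("HI" %in% schemes) preds$HI <- d
  if ("AI" %in% schemes) preds$AI <- max.col(pm, ties.method = "first")
  if ("CavgMH" %in% schemes) {
    preds$CavgMH <- max.col(0.5 * pm + 0.5 * ph, ties.method = "first")
  }
  if ("PoptMH" %in% schemes) {
    preds$PoptMH <- max.col((1 - w_popt) * pm + w_popt * delta,
                            ties.method = "first")
  }
  if ("PCoptMH" %in% schemes) {
    preds$PCoptMH <- max.col((1 - w_pcopt) * pm + w_pcopt * ph,
                             ties.method = "first")
  }
  preds
}

#' Probing protocol: profile, fit, and test a rater over repeated folds
#'
#' The core experimental loop: for each of `folds` repeats, draw a
#' stratified probing set of `eval_total` samples from the balanced cohort
#' (fold seeds derived as `seed + fold`), build the rater's confusion and
#' conditional matrices and fit the scalar weights (PoptMH on the delta
#' response, PCoptMH on the conditional probability) on those probing
#' samples, then score all schemes on the remaining
#' `n_bal + n_imb - eval_total` test samples. Folds are independent
#' stratified draws, not a partition, because probing comes from the
#' balanced cohort only while the test pool spans both cohorts.
#'
#' @param balanced,imbalanced `labeled_cohort`s sharing the machine profile
#'   and the rater.
#' @param rater Name (or index) of the rater in the cohorts' `raters` list.
#' @param eval_total Probing-sample count (e.g. 30, 60, 100, 150).
#' @param folds Number of repeats (default 5).
#' @param seed Base seed; fold `f` uses `seed + f`.
#' @param smoothing,eps Passed to [conditional_from_confusion()].
#' @param schemes Which schemes to report (default all five).
#' @return An `eval_report`: list with `folds` (long data frame: fold,
#'   scheme, accuracy, gain, gain_bin, w), `recall` (fold x scheme x class),
#'   `mean` (per-scheme mean accuracy), `notes` (degenerate-fold records),
#'   `eval_total`, `seed`.
#' @export
probing_protocol <- function(balanced, imbalanced, rater = 1L,
                             eval_total, folds = 5L, seed,
                             smoothing = "uniform_fallback", eps = 0.5,
                             schemes = c("HI", "AI", "CavgMH",
                                         "PoptMH", "PCoptMH")) {
  stopifnot(inherits(balanced, "labeled_cohort"),
            inherits(imbalanced, "labeled_cohort"))
  space <- balanced$space
  diag_bal <- balanced$raters[[rater]]
  diag_imb <- imbalanced$raters[[rater]]
  if (is.null(diag_bal) || is.null(diag_imb)) {
    stop("rater '", rater, "' not present in both cohorts")
  }
  pm_bal <- panel_mean(balanced$panel)
  pm_imb <- panel_mean(imbalanced$panel)

  fold_rows <- list()
  recall_rows <- list()
  notes <- character(0)
  for (f in seq_len(folds)) {
    plan <- assemble_split(balanced$truth, imbalanced$truth, eval_total,
                           seed = seed + f, space = space)
    ev <- plan$eval_idx
    cm <- build_confusion_matrix(balanced$truth[ev], diag_bal[ev], space)
    cond <- conditional_from_confusion(cm, smoothing, eps)
    sm <- attr(cond, "smoothing")
    if (length(sm$fallback_columns)) {
      notes <- c(notes, sprintf(
        "fold %d: uniform fallback for diagnosis column(s) %s",
        f, paste(sm$fallback_columns, collapse = ", ")))
    }
    if (length(unique(balanced$truth[ev])) < space$C) {
      notes <- c(notes, sprintf("fold %d: probing draw misses a class", f))
    }
    y_ev <- balanced$truth[ev]
    d_ev <- as_label_index(diag_bal[ev], space)
    fit_p <- fit_scalar_weight(pm_bal[ev, , drop = FALSE],
                               delta_matrix(d_ev, space), y_ev, "PoptMH")
    fit_pc <- fit_scalar_weight(pm_bal[ev, , drop = FALSE],
                                cond_matrix_for(d_ev, cond), y_ev, "PCoptMH")

    t_truth <- c(balanced$truth[plan$test_bal_idx],
                 imbalanced$truth[plan$test_imb_idx])
    t_pm <- rbind(pm_bal[plan$test_bal_idx, , drop = FALSE],
                  pm_imb[plan$test_imb_idx, , drop = FALSE])
    t_diag <- c(diag_bal[plan$test_bal_idx], diag_imb[plan$test_imb_idx])

    preds <- evaluate_schemes(t_truth, t_pm, t_diag, cond,
                              fit_p$w, fit_pc$w, space, schemes)
    hi_acc <- accuracy(as_label_index(t_diag, space), t_truth)
    for (s in names(preds)) {
      acc <- accuracy(preds[[s]], t_truth)
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = f, scheme = s, accuracy = acc,
        gain = acc - hi_acc,
        gain_bin = as.character(gain_bin(acc - hi_acc)),
        w = switch(s, PoptMH = fit_p$w, PCoptMH = fit_pc$w, NA_real_))
      rec <- per_class_recall(preds[[s]], t_truth, space)
      rr <- data.frame(fold = f, scheme = s)
      rr[paste0("recall_", space$names)] <- as.list(rec)
      recall_rows[[length(recall_rows) + 1L]] <- rr
    }
  }
  fold_df <- do.call(rbind, fold_rows)
  rownames(fold_df) <- NULL
  recall_df <- do.call(rbind, recall_rows)
  rownames(recall_df) <- NULL
  mean_acc <- tapply(fold_df$accuracy, fold_df$scheme, mean)
  structure(list(folds = fold_df, recall = recall_df,
                 mean = mean_acc[schemes[schemes %in% names(mean_acc)]],
                 notes = notes, eval_total = eval_total,
                 folds_n = folds, seed = seed, rater = rater),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("probing protocol:", x$eval_total, "probing samples,",
      x$folds_n, "folds (seed", x$seed, ")\n")
  cat("mean accuracy by scheme:\n")
  print(round(x$mean, 4))
  if (length(x$notes)) cat(length(x$notes), "fold note(s)\n")
  invisible(x)
}
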