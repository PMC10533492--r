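test_that("prevalence specs encode the study case mixes", {
  bal <- prevalence_spec("balanced")
  expect_equal(unname(bal$probs), rep(1 / 6, 6))
  imb <- prevalence_spec("imbalanced")
  expect_equal(unname(imb$counts), c(51L, 20L, 15L, 29L, 18L, 167L))
  expect_equal(sum(imb$counts), 300L)
  expect_equal(sum(imb$probs), 1)
  cust <- prevalence_spec("custom", sp3, probs = c(1, 0, 0))
  expect_equal(unname(cust$probs), c(1, 0, 0))
  expect_error(prevalence_spec("custom", sp3, probs = c(0.5, 0.4)),
               "summing to 1")
})

test_that("truth sampling honours quotas and prevalences", {
  # balanced quota mode: exactly 50 per class
  t1 <- sample_truth(300, prevalence_spec("balanced"), seed = 1)
  expect_equal(tabulate(t1, 6), rep(50L, 6))

  # point-mass prevalence: all labels identical
  pm <- prevalence_spec("custom", sp3, probs = c(0, 1, 0))
  expect_true(all(sample_truth(40, pm, seed = 2) == 2))

  # multinomial mode converges to the prevalence
  t3 <- sample_truth(30000, prevalence_spec("imbalanced"), seed = 0,
                     mode = "multinomial")
  expect_lt(abs(mean(t3 == 6) - 167 / 300), 0.01)

  # determinism
  expect_identical(sample_truth(50, prevalence_spec("balanced"), seed = 3),
                   sample_truth(50, prevalence_spec("balanced"), seed = 3))
})

test_that("simulated raters follow their generating profile", {
  ident <- rater_sim_profile(diag(6), sp6)
  truth <- sample_truth(60, prevalence_spec("balanced"), seed = 4)
  expect_identical(simulate_rater(truth, ident, seed = 5), truth)

  # uniform rows: accuracy ~ 1/C within 3 binomial SEs at n = 5000
  unif <- rater_sim_profile(matrix(1 / 6, 6, 6), sp6)
  t5 <- sample_truth(5000, prevalence_spec("balanced"), seed = 6)
  acc <- mean(simulate_rater(t5, unif, seed = 7) == t5)
  se <- sqrt((1 / 6) * (5 / 6) / 5000)
  expect_lt(abs(acc - 1 / 6), 3 * se)

  # calibrated specialist preset: empirical accuracy near its target
  t10 <- sample_truth(10000, prevalence_spec("balanced"), seed = 8)
  d10 <- simulate_rater(t10, rater_preset("ent"), seed = 9)
  expect_lt(abs(mean(d10 == t10) - 0.71), 0.02)
})

test_that("profile calibration hits the target accuracy exactly", {
  prev <- prevalence_spec("balanced")

  # uniform base at target 0.71: closed form
  p <- calibrate_profile(matrix(1 / 6, 6, 6), 0.71, prev)
  expect_equal(unname(diag(p$probs)), rep(0.71, 6))
  expect_equal(unname(p$probs[1, 2]), 0.29 / 5)

  # identity base at target 1 stays the identity
  pid <- calibrate_profile(diag(6), 1, prev)
  expect_equal(unclass(pid$probs), diag(6), ignore_attr = TRUE)

  # heterogeneous base: expected accuracy exact, diagonals stay unequal
  het <- calibrate_profile(nonent_base_shape(), 0.46, prev)
  expect_equal(expected_accuracy(het, prev), 0.46, tolerance = 1e-9)
  expect_gt(max(diag(het$probs)) - min(diag(het$probs)), 0.05)
  expect_equal(unname(rowSums(het$probs)), rep(1, 6), tolerance = 1e-12)

  expect_error(calibrate_profile(matrix(1 / 6, 6, 6), 0.1, prev), "\\(1/C")
})

test_that("rater presets land their group accuracies", {
  prev <- prevalence_spec("balanced")
  expect_equal(expected_accuracy(rater_preset("ent"), prev), 0.7117,
               tolerance = 1e-9)
  expect_equal(expected_accuracy(rater_preset("non_ent"), prev), 0.4563,
               tolerance = 1e-9)
  # the specialist preset is class-heterogeneous: strong on Tumor/Myri,
  # weak on Ome
  d <- diag(rater_preset("ent")$probs)
  expect_gt(d["Tumor"], d["Ome"])
  expect_gt(d["Myri"], d["Ome"])
})

test_that("machine panels are valid softmax draws", {
  truth <- sample_truth(100, prevalence_spec("balanced"), seed = 10)
  panel <- simulate_machine_panel(truth, machine_preset(), seed = 11)
  expect_equal(dim(panel), c(100L, 6L, 4L))
  sums <- apply(panel, c(1, 3), sum)
  expect_equal(as.numeric(sums), rep(1, 400), tolerance = 1e-9)
  expect_true(all(panel >= 0))
  expect_error(machine_sim_profile(diag(6), kappa = 0), "kappa")
  # determinism from the seed
  expect_identical(panel,
                   simulate_machine_panel(truth, machine_preset(),
                                          seed = 11))
})

test_that("huge concentration with an identity base recovers the truth", {
  truth <- sample_truth(120, prevalence_spec("balanced"), seed = 12)
  prof <- machine_sim_profile(0.99 * diag(6) + 0.01 / 6, kappa = 1e6,
                              beta = 0, n_models = 2, jitter = 0)
  panel <- simulate_machine_panel(truth, prof, seed = 13)
  pm <- panel_mean(panel)
  expect_equal(max.col(pm, ties.method = "first"), truth)
  expect_true(all(pm[cbind(seq_along(truth), truth)] > 0.9))
})

test_that("prevalence bias trades minority recall for majority recall", {
  prev <- prevalence_spec("imbalanced")
  rec_no <- matrix(NA_real_, 10, 2)
  rec_min <- matrix(NA_real_, 10, 2)
  share_no <- matrix(NA_real_, 10, 2)
  for (s in 0:9) {
    truth <- sample_truth(3000, prev, seed = s, mode = "multinomial")
    for (j in 1:2) {
      beta <- c(0, 2)[j]
      panel <- simulate_machine_panel(
        truth, machine_preset(beta = beta), seed = 100 + s, prev = prev)
      pred <- max.col(panel_mean(panel), ties.method = "first")
      rec <- per_class_recall(pred, truth, sp6)
      rec_no[s + 1, j] <- rec["No"]
      rec_min[s + 1, j] <- mean(rec[c("Ar", "Myri", "Ome", "Tumor")],
                                na.rm = TRUE)
      share_no[s + 1, j] <- mean(pred == 6L)
    }
  }
  # paired over seeds: stronger bias never lowers the prevalent class's
  # recall (it saturates at 1 in this regime), strictly inflates how often
  # that class is predicted, and strictly erodes minority-class recall
  expect_gte(mean(rec_no[, 2] - rec_no[, 1]), 0)
  expect_gt(mean(share_no[, 2] - share_no[, 1]), 0)
  expect_lt(mean(rec_min[, 2] - rec_min[, 1]), 0)
})

test_that("empirical confusion converges to the generating profile", {
  prof <- rater_preset("non_ent")
  prev <- prevalence_spec("balanced")
  frob <- function(n, seed) {
    truth <- sample_truth(n, prev, seed = seed)
    d <- simulate_rater(truth, prof, seed = seed + 500)
    cm <- build_confusion_matrix(truth, d, sp6)
    emp <- unclass(cm) / pmax(rowSums(unclass(cm)), 1)
    sqrt(sum((emp - prof$probs)^2))
  }
  e30 <- vapply(1:20, function(s) frob(30, s), numeric(1))
  e3000 <- vapply(1:20, function(s) frob(3000, s), numeric(1))
  expect_lt(mean(e3000), mean(e30))
  expect_lt(mean(e3000), 0.1)
})

test_that("estimated conditionals recover the Bayes-implied matrix", {
  prev <- prevalence_spec("balanced")
  for (which in c("ent", "non_ent")) {
    prof <- rater_preset(which)
    implied <- bayes_conditional(prof, prev)
    truth <- sample_truth(3000, prev, seed = 30)
    d <- simulate_rater(truth, prof, seed = 31)
    cond <- conditional_from_confusion(
      build_confusion_matrix(truth, d, sp6), "uniform_fallback")
    mae <- mean(abs(unclass(cond) - implied))
    expect_lt(mae, 0.05)
  }
})

test_that("cohort simulation is fully determined by the master seed", {
  raters <- list(ent = rater_preset("ent"), gp = rater_preset("non_ent"))
  c1 <- simulate_cohort(90, prevalence_spec("balanced"), machine_preset(),
                        raters, seed = 33)
  c2 <- simulate_cohort(90, prevalence_spec("balanced"), machine_preset(),
                        raters, seed = 33)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_named(c1$raters, c("ent", "gp"))
  expect_length(c1$truth, 90)
})
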