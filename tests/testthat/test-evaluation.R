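test_that("probing/test split accounts for every sample", {
  bal <- sample_truth(300, prevalence_spec("balanced"), seed = 1)
  imb <- sample_truth(300, prevalence_spec("imbalanced"), seed = 2)

  plan <- assemble_split(bal, imb, 100, seed = 3, space = sp6)
  expect_equal(length(plan$eval_idx), 100)
  expect_equal(length(plan$test_bal_idx) + length(plan$test_imb_idx), 500)
  expect_length(intersect(plan$eval_idx, plan$test_bal_idx), 0)

  # E = 0: machine-only baseline uses all 600 samples for testing
  p0 <- assemble_split(bal, imb, 0, seed = 3, space = sp6)
  expect_length(p0$eval_idx, 0)
  expect_equal(length(p0$test_bal_idx) + length(p0$test_imb_idx), 600)

  # E = 30 over 6 equal strata: exactly 5 per class
  p30 <- assemble_split(bal, imb, 30, seed = 4, space = sp6)
  expect_equal(sort(tabulate(bal[p30$eval_idx], 6)), rep(5L, 6))

  # split accounting holds for all probing sizes
  for (E in c(30, 60, 100, 150)) {
    p <- assemble_split(bal, imb, E, seed = 5, space = sp6)
    expect_equal(length(p$eval_idx) + length(p$test_bal_idx) +
                   length(p$test_imb_idx), 600)
  }
  expect_error(assemble_split(bal, imb, 301, seed = 1, space = sp6),
               "exceeds")
})

test_that("accuracy and recall follow their definitions", {
  expect_equal(accuracy(1:5, 1:5), 1.0)
  expect_equal(accuracy(c(2, 1), c(1, 2)), 0.0)
  expect_equal(accuracy(c(1, 2, 3, 4, 4), c(1, 2, 3, 4, 5)), 0.8)
  expect_error(accuracy(1:2, 1:3), "length")

  expect_equal(per_class_recall(1:3, 1:3, sp3),
               c(x = 1, y = 1, z = 1))
  expect_equal(per_class_recall(c(1, 2, 2), c(1, 1, 2), sp3),
               c(x = 0.5, y = 1, z = NA_real_)) # z absent -> missing
})

test_that("accuracy is the prevalence-weighted mean of recalls", {
  withr::with_seed(141, {
    for (i in 1:10) {
      C <- sample(2:6, 1)
      sp <- label_space(letters[1:C])
      truth <- c(1:C, sample.int(C, 80, TRUE)) # every class present
      pred <- sample.int(C, length(truth), TRUE)
      rec <- per_class_recall(pred, truth, sp)
      prev <- tabulate(truth, C) / length(truth)
      expect_equal(sum(prev * rec), accuracy(pred, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("gain bins match the reporting legend", {
  expect_equal(as.character(gain_bin(0.05)), "(0,0.05]")
  expect_equal(as.character(gain_bin(-0.01)), "decrease")
  expect_equal(as.character(gain_bin(0)), "decrease")
  expect_equal(as.character(gain_bin(0.31)), ">0.3")
  expect_equal(as.character(gain_bin(c(0.02, 0.07, 0.15, 0.25))),
               c("(0,0.05]", "(0.05,0.1]", "(0.1,0.2]", "(0.2,0.3]"))
  expect_error(gain_bin(NaN), "finite")
})

test_that("alpha sweep endpoints behave as declared", {
  co <- tiny_cohorts(n = 120)
  bal <- co$bal
  # alpha = 0 equals the machine-ensemble accuracy exactly, for any rater
  ens_acc <- accuracy(max.col(panel_mean(bal$panel) * 4,
                              ties.method = "first"), bal$truth)
  sw <- alpha_sweep(bal$panel, bal$raters, bal$truth, sp6,
                    grid = c(0, 1, 4))
  expect_equal(sw$accuracy[sw$alpha == 0], ens_acc)

  # a perfect rater at alpha = 4 gets everything right
  sw_perfect <- alpha_sweep(bal$panel, list(oracle = bal$truth),
                            bal$truth, sp6, grid = c(4))
  expect_equal(sw_perfect$accuracy, 1.0)
  expect_error(alpha_sweep(bal$panel, bal$raters, bal$truth, sp6,
                           grid = numeric(0)), "empty")
  expect_error(alpha_sweep(bal$panel, bal$raters, bal$truth, sp6,
                           grid = c(0, 5)), "\\[0, 4\\]")
})

test_that("complementary raters give an interior alpha optimum", {
  # raters that beat the machine on some classes only: the sweep curve
  # peaks strictly inside (0, 4)
  machine <- machine_preset()
  raters <- rater_population(20, "ent", seed = 11)
  bal <- simulate_cohort(300, prevalence_spec("balanced"), machine,
                         raters, seed = 11)
  sw <- alpha_sweep(bal$panel, bal$raters, bal$truth, sp6)
  acc <- sw$accuracy
  k <- which.max(acc)
  expect_gt(sw$alpha[k], 0)
  expect_lt(sw$alpha[k], 4)
  expect_gt(acc[k], acc[1])             # better than machines alone
  expect_gt(acc[k], acc[length(acc)])   # better than humans alone
})

test_that("probing protocol is deterministic and reports all schemes", {
  co <- tiny_cohorts(n = 120)
  r1 <- probing_protocol(co$bal, co$imb, rater = "ent", eval_total = 30,
                         folds = 3, seed = 9)
  r2 <- probing_protocol(co$bal, co$imb, rater = "ent", eval_total = 30,
                         folds = 3, seed = 9)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_setequal(unique(r1$folds$scheme),
                  c("HI", "AI", "CavgMH", "PoptMH", "PCoptMH"))
  expect_true(all(r1$folds$accuracy >= 0 & r1$folds$accuracy <= 1))
  # reported means equal the average of the folds
  for (s in names(r1$mean)) {
    expect_equal(unname(r1$mean[s]),
                 mean(r1$folds$accuracy[r1$folds$scheme == s]))
  }
})

test_that("an oracle rater dominates the machine-alone baseline", {
  machine <- machine_preset()
  bal <- simulate_cohort(150, prevalence_spec("balanced"), machine,
                         list(), seed = 17)
  imb <- simulate_cohort(150, prevalence_spec("imbalanced"), machine,
                         list(), seed = 18)
  bal$raters <- list(oracle = bal$truth)
  imb$raters <- list(oracle = imb$truth)
  rep <- probing_protocol(bal, imb, rater = "oracle", eval_total = 60,
                          folds = 3, seed = 19)
  expect_gte(rep$mean["PoptMH"], rep$mean["AI"])
  expect_gte(rep$mean["PCoptMH"], rep$mean["AI"])
  expect_equal(unname(rep$mean["HI"]), 1.0)
})

test_that("scheme subsetting restricts the report columns", {
  co <- tiny_cohorts(n = 120)
  rep <- probing_protocol(co$bal, co$imb, rater = "ent", eval_total = 30,
                          folds = 2, seed = 23,
                          schemes = c("HI", "AI", "PCoptMH"))
  expect_setequal(unique(rep$folds$scheme), c("HI", "AI", "PCoptMH"))
})
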