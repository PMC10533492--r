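# shared tiny fixtures, built in code

sp2 <- label_space(c("a", "b"))
sp3 <- label_space(c("x", "y", "z"))
sp6 <- otoscopy_labels()

# a valid random probability matrix (rows on the simplex)
random_prob_rows <- function(n, C) {
  g <- matrix(stats::rgamma(n * C, 1), n, C)
  g / rowSums(g)
}

# small cohort pair sharing machine preset and raters, for protocol tests
tiny_cohorts <- function(n = 120, raters = list(ent = rater_preset("ent")),
                         seed = 5) {
  machine <- machine_preset()
  list(
    bal = simulate_cohort(n, prevalence_spec("balanced"), machine,
                          raters, seed = seed),
    imb = simulate_cohort(n, prevalence_spec("imbalanced"), machine,
                          raters, seed = seed + 1L)
  )
}
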