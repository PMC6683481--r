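test_that("cross-product OR reproduces reported values and edge cases", {
  expect_equal(round(crossproduct_or(twobytwo(19, 71, 62, 796)), 2), 3.44)
  expect_equal(round(crossproduct_or(twobytwo(6, 56, 13, 845)), 2), 6.96)
  expect_equal(crossproduct_or(twobytwo(10, 90, 10, 90)), 1)
  expect_identical(crossproduct_or(twobytwo(3, 0, 2, 5)), Inf)
  expect_identical(crossproduct_or(twobytwo(0, 5, 2, 5)), 0)
  expect_error(crossproduct_or(twobytwo(0, 0, 0, 0)), "undefined")
  expect_error(twobytwo(-1, 2, 3, 4), "nonnegative")
})

test_that("OR monotonicity: moving a non-carrier case to carrier", {
  for (i in 1:30) {
    a <- i; b <- 40 - i
    or1 <- crossproduct_or(twobytwo(a, b, 25, 75))
    or2 <- crossproduct_or(twobytwo(a + 1, b - 1, 25, 75))
    expect_gte(or2, or1)
  }
})

test_that("Wald CI reproduces the reported interval and the formula", {
  expect_equal(round(unname(wald_ci(twobytwo(19, 71, 62, 796))), 2),
               c(1.95, 6.07))
  # symmetric table: interval log-symmetric about OR 1
  ci <- wald_ci(twobytwo(10, 90, 10, 90))
  expect_lt(ci[["low"]], 1)
  expect_gt(ci[["high"]], 1)
  expect_equal(log(ci[["low"]]) + log(ci[["high"]]), 0, tolerance = 1e-12)
  # independent large-sample formula evaluation
  a <- 18; b <- 72; c <- 58; d <- 800
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expected <- exp(log((a * d) / (b * c)) +
                    c(-1, 1) * qnorm(0.975) * se)
  expect_equal(unname(wald_ci(twobytwo(a, b, c, d))), expected,
               tolerance = 1e-12)
  expect_error(wald_ci(twobytwo(0, 90, 10, 90)), "exact")
})

test_that("Fisher exact p matches the reported sparse row and enumeration", {
  expect_equal(signif(fisher_test(twobytwo(4, 86, 7, 851))$p, 2), 0.015)
  expect_equal(fisher_test(twobytwo(1, 1, 1, 1))$p, 1)
  # brute-force enumeration oracle and the stats::fisher.test cross-check
  set.seed(11)
  for (i in 1:60) {
    t <- twobytwo(sample(0:12, 1), sample(0:25, 1),
                  sample(0:12, 1), sample(0:25, 1))
    if (all(t == 0)) next
    ft <- fisher_test(t)
    expect_equal(ft$p, enum_fisher_p(t[["a"]], t[["b"]], t[["c"]], t[["d"]]),
                 tolerance = 1e-12)
    expect_equal(ft$p,
                 stats::fisher.test(matrix(t, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  # label swap leaves the exact p unchanged, inverts the ORs
  t <- twobytwo(4, 86, 7, 851)
  sw <- twobytwo(7, 851, 4, 86)
  expect_equal(fisher_test(sw)$p, fisher_test(t)$p, tolerance = 1e-12)
  expect_equal(fisher_test(sw)$or_crossproduct,
               1 / fisher_test(t)$or_crossproduct, tolerance = 1e-12)
})

test_that("test selection follows the minimum-cell rule on both cohorts", {
  expect_identical(select_test(twobytwo(4, 86, 7, 851)), "fisher")
  expect_identical(select_test(twobytwo(19, 71, 62, 796)), "logistic")
  # boundary pair: 5 case copies -> Fisher, 6 case copies -> logistic
  expect_identical(select_test(twobytwo(5, 57, 10, 848)), "fisher")
  expect_identical(select_test(twobytwo(6, 56, 13, 845)), "logistic")
})

test_that("logistic dosage model matches the closed 2x2 form", {
  obs <- chrom_expand(19, 71, 62, 796)
  fit <- logistic_assoc(obs$dosage, obs$status)
  expect_equal(fit$or_point, crossproduct_or(twobytwo(19, 71, 62, 796)),
               tolerance = 1e-6)
  expect_equal(c(fit$ci_low, fit$ci_high),
               unname(wald_ci(twobytwo(19, 71, 62, 796))),
               tolerance = 1e-6)
  # label-swap antisymmetry of the estimate
  fit_sw <- logistic_assoc(obs$dosage, 1 - obs$status)
  expect_equal(fit_sw$beta, -fit$beta, tolerance = 1e-6)
  # LRT option agrees with a direct deviance computation
  fit_lrt <- logistic_assoc(obs$dosage, obs$status, p_method = "lrt")
  g1 <- glm(obs$status ~ obs$dosage, family = binomial())
  expect_equal(fit_lrt$p,
               pchisq(g1$null.deviance - g1$deviance, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("logistic model flags degenerate designs", {
  expect_error(logistic_assoc(rep(1, 20), rep(0:1, 10)), "rank deficient")
  expect_error(logistic_assoc(c(rep(1, 10), rep(0, 10)), rep(0:1, 10),
                              covariates = list(c2 = c(rep(2, 10),
                                                       rep(0, 10)))),
               "collinear")
  # complete separation: flagged, p and CI unavailable
  sep <- logistic_assoc(c(rep(1, 10), rep(0, 10)),
                        c(rep(1, 10), rep(0, 10)))
  expect_true(sep$separation)
  expect_true(is.na(sep$p))
})

test_that("planted log-OR is recovered with near-nominal CI coverage", {
  beta <- log(3)
  cover <- 0L
  reps <- 120
  set.seed(101)
  for (i in seq_len(reps)) {
    dosage <- rbinom(900, 2, 0.25)
    status <- rbinom(900, 1, plogis(-1 + beta * dosage))
    fit <- logistic_assoc(dosage, status)
    if (log(fit$ci_low) <= beta && beta <= log(fit$ci_high)) {
      cover <- cover + 1L
    }
  }
  expect_gte(cover / reps, 0.88)
})

test_that("Bonferroni threshold and reported conditional bound agree", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(signif(bonferroni_threshold(60), 2), 8.3e-4)
  expect_equal(bonferroni_threshold(1000), 5e-5)
  expect_error(bonferroni_threshold(0), "positive")
})

test_that("reciprocal two-allele markers give exactly reciprocal ORs", {
  # a gene with exactly two alleles: the markers are complements
  ref <- suppressWarnings(
    reconstruct_reference_tables(reference_allele_freqs("MS")))
  r1 <- ref[ref$marker == "DRA*01:01", ]
  r2 <- ref[ref$marker == "DRA*01:02", ]
  or1 <- crossproduct_or(twobytwo(r1$a, r1$b, r1$c, r1$d))
  or2 <- crossproduct_or(twobytwo(r2$a, r2$b, r2$c, r2$d))
  expect_equal(or1 * or2, 1, tolerance = 1e-12)
  expect_equal(round(or1, 2), 2.00)
  expect_equal(round(or2, 2), 0.50)
})

test_that("the scan chooses tests, sorts by p, and isolates failures", {
  sim <- seed1_cohort()
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  kept <- filter_markers(case_control_frequencies(d, sim$cohort))
  sc <- run_scan(d, sim$cohort, kept)
  expect_identical(nrow(sc), length(kept))
  expect_false(is.unsorted(sc$p, na.rm = TRUE))
  expect_true(any(grepl("^DRB1", sc$marker_id)))
  expect_true(all(sc$test_used[!sc$not_testable] %in%
                    c("logistic", "fisher")))
  expect_equal(attr(sc, "bonferroni"), 0.05 / length(kept))
  # conditioning a marker on itself only poisons that marker
  sc2 <- run_scan(d, sim$cohort, kept,
                  covariate_markers = "DRB1*15:01")
  bad <- sc2[sc2$marker_id == "DRB1*15:01", ]
  expect_true(bad$not_testable)
  expect_gt(sum(!sc2$not_testable), length(kept) - 5)
})
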