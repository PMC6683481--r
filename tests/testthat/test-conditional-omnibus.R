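test_that("conditioning on an uninformative covariate changes nothing", {
  sim <- suppressMessages(simulate_cohort(two_effect_config(seed = 21)))
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  kept <- filter_markers(case_control_frequencies(d, sim$cohort))
  # a marker with constant zero dosage behaves as an all-zero covariate
  zero <- matrix(0, nrow(d$dosage), 1,
                 dimnames = list(rownames(d$dosage), "null*00:00"))
  d0 <- bind_dosage(d, new_dosage(zero, data.frame(
    marker_id = "null*00:00", kind = "allele", gene = "null",
    allele = "null*00:00", position = NA_integer_,
    residue = NA_character_, stringsAsFactors = FALSE)))
  plain <- run_scan(d0, sim$cohort, kept)
  cond <- conditional_scan(d0, sim$cohort, kept,
                           conditioned = "null*00:00")
  plain <- plain[order(plain$marker_id), ]
  cond <- cond[order(cond$marker_id), ]
  same_test <- plain$test_used == "logistic"
  expect_equal(cond$p[same_test], plain$p[same_test], tolerance = 1e-9)
  expect_equal(cond$beta[same_test], plain$beta[same_test],
               tolerance = 1e-9)
})

test_that("conditioning separates two planted independent effects", {
  sim <- suppressMessages(simulate_cohort(two_effect_config(seed = 2)))
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  kept <- filter_markers(case_control_frequencies(d, sim$cohort))
  thr <- bonferroni_threshold(length(kept))
  marginal <- run_scan(d, sim$cohort, kept)
  cond <- conditional_scan(d, sim$cohort, kept,
                           conditioned = "DRB1*15:01")
  # second effect stays significant after conditioning on the first
  expect_lt(cond$p[cond$marker_id == "B*39:01"], thr)
  # the conditioned-on marker itself is flagged
  expect_true(cond$not_testable[cond$marker_id == "DRB1*15:01"])
  # conditioning on an unlinked gene leaves the first effect's p near its
  # marginal value (same order of magnitude)
  cond_b <- conditional_scan(d, sim$cohort, "DRB1*15:01",
                             conditioned = "B*39:01")
  lr <- log10(cond_b$p) - log10(marginal$p[marginal$marker_id ==
                                             "DRB1*15:01"])
  expect_lt(abs(lr), 1.5)
})

test_that("stepwise selection recovers exactly the planted markers", {
  sim <- suppressMessages(simulate_cohort(two_effect_config(seed = 3)))
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  kept <- filter_markers(case_control_frequencies(d, sim$cohort))
  st <- stepwise_select(d, sim$cohort, kept)
  expect_setequal(st$selected, c("DRB1*15:01", "B*39:01"))
  expect_identical(length(st$rounds), length(st$selected) + 1L)
  expect_equal(st$threshold, 0.05 / length(kept))
  # single planted effect -> a trace of exactly that marker
  cfg1 <- synthetic_config(
    genes = list(DRB1 = c("DRB1*15:01" = 0.15, "DRB1*04:05" = 0.25,
                          "DRB1*90:01" = 0.60),
                 B = c("B*39:01" = 0.30, "B*07:02" = 0.30,
                       "B*90:01" = 0.40)),
    n_case = 150, n_control = 600,
    effects = c("DRB1*15:01" = log(3)), seed = 31)
  sim1 <- suppressMessages(simulate_cohort(cfg1))
  d1 <- build_allele_dosage(sim1$genotypes, sim1$cohort)
  st1 <- stepwise_select(d1, sim1$cohort,
                         filter_markers(case_control_frequencies(
                           d1, sim1$cohort)))
  expect_identical(st1$selected, "DRB1*15:01")
})

test_that("perfectly coupled markers: one selected, partner not testable", {
  blk <- data.frame(gene_a = c("DRB1*15:01", "DRB1*90:01"),
                    gene_b = c("DQB1*06:02", "DQB1*90:01"),
                    freq = c(0.2, 0.8), stringsAsFactors = FALSE)
  cfg <- synthetic_config(
    genes = list(DRB1 = c("DRB1*15:01" = 0.2, "DRB1*90:01" = 0.8),
                 DQB1 = c("DQB1*06:02" = 0.2, "DQB1*90:01" = 0.8)),
    n_case = 120, n_control = 480,
    effects = c("DRB1*15:01" = log(3)), hap_blocks = list(blk), seed = 32)
  sim <- suppressMessages(simulate_cohort(cfg))
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  kept <- filter_markers(case_control_frequencies(d, sim$cohort))
  st <- stepwise_select(d, sim$cohort, kept)
  # the two-allele genes are fully coupled, so all four markers carry the
  # same signal: exactly one is selected and every remaining marker is
  # flagged as collinear with it in round 2
  expect_identical(length(st$selected), 1L)
  round2 <- st$rounds[[2]]
  expect_true(all(round2$not_testable))
  expect_true(all(grepl("collinear|covariates", round2$error)))
})

test_that("null cohorts select nothing almost always", {
  reps <- 200
  empty <- 0L
  for (i in seq_len(reps)) {
    cfg <- synthetic_config(
      genes = list(G1 = c("G1*01:01" = 0.3, "G1*02:01" = 0.3,
                          "G1*03:01" = 0.4),
                   G2 = c("G2*01:01" = 0.5, "G2*02:01" = 0.5)),
      n_case = 60, n_control = 120, seed = 4000 + i)
    sim <- suppressMessages(simulate_cohort(cfg))
    d <- build_allele_dosage(sim$genotypes, sim$cohort)
    kept <- filter_markers(case_control_frequencies(d, sim$cohort))
    st <- stepwise_select(d, sim$cohort, kept)
    if (!length(st$selected)) empty <- empty + 1L
  }
  # family-wise selection rate is Bonferroni-bounded at 0.05
  expect_gte(empty / reps, 0.90)
})

test_that("joint fit: single marker and orthogonal designs reduce", {
  sim <- suppressMessages(simulate_cohort(two_effect_config(seed = 33)))
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  jf <- joint_fit(d, sim$cohort, "DRB1*15:01")
  status <- sim$cohort$status == "case"
  la <- logistic_assoc(d$dosage[, "DRB1*15:01"], status)
  expect_equal(jf$beta, la$beta, tolerance = 1e-9)
  expect_equal(jf$p, la$p, tolerance = 1e-9)
  # orthogonal (balanced factorial) dosages: joint betas = marginal betas
  x1 <- rep(c(0, 0, 1, 1), 50)
  x2 <- rep(c(0, 1, 0, 1), 50)
  set.seed(9)
  y <- rbinom(200, 1, plogis(-0.3 + 0.8 * x1 - 0.4 * x2))
  X <- matrix(c(x1, x2), ncol = 2,
              dimnames = list(sprintf("o%03d", 1:200), c("m1", "m2")))
  dd <- new_dosage(X, data.frame(
    marker_id = c("m1", "m2"), kind = "allele", gene = "G",
    allele = c("m1", "m2"), position = NA_integer_,
    residue = NA_character_, stringsAsFactors = FALSE))
  coh <- data.frame(sample_id = rownames(X),
                    status = ifelse(y == 1, "case", "control"),
                    cohort = ifelse(y == 1, "MS", "control"),
                    edss = NA_real_, age_at_onset = NA_real_,
                    stringsAsFactors = FALSE)
  jf2 <- joint_fit(dd, coh, c("m1", "m2"))
  # oracle: orthogonality makes the joint fit separable, so compare with
  # per-marker fits within levels of the other marker collapsed out by glm
  g <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(jf2$beta, unname(coef(g)[c("x1", "x2")]), tolerance = 1e-9)
  expect_error(joint_fit(dd, coh, c("m1", "m1")), "collinear")
})

test_that("omnibus test: biallelic identity, reference invariance, oracle", {
  sim <- seed1_cohort()
  res <- suppressMessages(build_residue_markers(
    demo_alignment_catalog(), sim$genotypes, sim$cohort))
  d <- res$dosage
  status <- as.integer(
    sim$cohort$status[match(rownames(d$dosage),
                            sim$cohort$sample_id)] == "case")

  # biallelic position: omnibus p equals the single residue marker's LRT p
  om <- omnibus_position(d, sim$cohort, "B", 5L)
  expect_identical(om$df, 1L)
  x <- d$dosage[, "B_5_T"]
  cc <- !is.na(x)
  g1 <- glm(status[cc] ~ x[cc], family = binomial())
  expect_equal(om$deviance, g1$null.deviance - g1$deviance,
               tolerance = 1e-9)
  expect_equal(om$p, pchisq(g1$null.deviance - g1$deviance, 1,
                            lower.tail = FALSE), tolerance = 1e-9)

  # 3-residue position: deviance is reference-invariant and equals the
  # binomial log-likelihood difference oracle
  ids <- c("DQB1_9_F", "DQB1_9_L", "DQB1_9_Y")
  om9 <- omnibus_position(d, sim$cohort, "DQB1", 9L)
  expect_identical(om9$n_residues, 3L)
  expect_identical(om9$df, 2L)
  X <- d$dosage[, ids]
  cc <- complete.cases(X)
  for (drop_id in ids) {
    keep <- setdiff(ids, drop_id)
    gf <- glm(status[cc] ~ X[cc, keep[1]] + X[cc, keep[2]],
              family = binomial())
    g0 <- glm(status[cc] ~ 1, family = binomial())
    dev <- 2 * (binom_ll(status[cc], fitted(gf)) -
                  binom_ll(status[cc], fitted(g0)))
    expect_equal(om9$deviance, dev, tolerance = 1e-9)
  }

  # covariates spanning the position's own residues: deviance 0, p 1
  om0 <- omnibus_position(d, sim$cohort, "DQB1", 9L,
                          covariate_markers = c("DQB1_9_F", "DQB1_9_L"))
  expect_equal(om0$deviance, 0, tolerance = 1e-9)
  expect_equal(om0$p, 1)

  # monomorphic position errors
  expect_error(omnibus_position(d, sim$cohort, "DQB1", 2L), "monomorphic")

  # nested conditioning never lowers the null log-likelihood
  om_s <- omnibus_position(d, sim$cohort, "DQB1", 9L,
                           covariate_markers = "B_5_T")
  om_s2 <- omnibus_position(d, sim$cohort, "DQB1", 9L,
                            covariate_markers = c("B_5_T", "DRB1_4_Q"))
  expect_lte(om_s2$deviance, om_s$deviance + 1e-6)
})

test_that("LD r2: identities, independence, and coupled-block targets", {
  sim <- seed1_cohort()
  d <- build_allele_dosage(sim$genotypes, sim$cohort)
  expect_equal(ld_r2(d, sim$cohort, "DRB1*15:01", "DRB1*15:01")$r2, 1)
  # biallelic gene: an allele and its complement are perfectly correlated
  expect_equal(ld_r2(d, sim$cohort, "DRA*01:01", "DRA*01:02")$r2, 1,
               tolerance = 1e-12)
  # independent planted markers at n = 2000: near-zero r2
  cfg <- synthetic_config(
    genes = list(G1 = c("G1*01:01" = 0.3, "G1*90:01" = 0.7),
                 G2 = c("G2*01:01" = 0.3, "G2*90:01" = 0.7)),
    n_case = 200, n_control = 1800, seed = 4)
  sim2 <- suppressMessages(simulate_cohort(cfg))
  d2 <- build_allele_dosage(sim2$genotypes, sim2$cohort)
  expect_lt(ld_r2(d2, sim2$cohort, "G1*01:01", "G2*01:01", "all")$r2, 0.01)
  # zero-variance marker
  mono <- synthetic_config(
    genes = list(G1 = c("G1*01:01" = 1), G2 = c("G2*01:01" = 0.5,
                                                "G2*90:01" = 0.5)),
    n_case = 20, n_control = 20, seed = 5)
  sim3 <- suppressMessages(simulate_cohort(mono))
  d3 <- build_allele_dosage(sim3$genotypes, sim3$cohort)
  expect_error(ld_r2(d3, sim3$cohort, "G1*01:01", "G2*01:01", "all"),
               "zero dosage variance")
})

test_that("a residue tagging two risk alleles outranks either allele", {
  # reciprocal conditioning: Phe-like residue carried by two effect
  # alleles stays significant given one allele; the allele given the
  # residue does not beat it
  cfg <- synthetic_config(
    genes = list(DQB1 = c("DQB1*06:02" = 0.10, "DQB1*03:02" = 0.10,
                          "DQB1*05:01" = 0.50, "DQB1*03:01" = 0.30)),
    n_case = 200, n_control = 800,
    effects = c("DQB1*06:02" = log(3), "DQB1*03:02" = log(3)), seed = 6)
  sim <- suppressMessages(simulate_cohort(cfg))
  da <- build_allele_dosage(sim$genotypes, sim$cohort)
  res <- suppressMessages(build_residue_markers(
    demo_alignment_catalog()["DQB1"], sim$genotypes, sim$cohort))
  d <- bind_dosage(da, res$dosage)
  p_res_given_allele <- conditional_scan(
    d, sim$cohort, "DQB1_9_F", conditioned = "DQB1*06:02")$p
  p_allele_given_res <- conditional_scan(
    d, sim$cohort, "DQB1*06:02", conditioned = "DQB1_9_F")$p
  expect_lt(p_res_given_allele, 0.01)
  expect_lt(p_res_given_allele, p_allele_given_res)
})
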