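# Shared fixtures built in code.

# study-scale seed-1 synthetic MS cohort, simulated once per test run
seed1_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(simulate_cohort(ms_like_config(seed = 1)))
    }
    cache
  }
})

# tiny hand-written genotype/cohort pair: 3 samples, 2 genes
tiny_tables <- function() {
  g <- data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    gene = rep(c("DRB1", "B"), 3),
    allele1 = c("DRB1*15:01", "B*39:01", "DRB1*15:01", "B*07:02",
                "DRB1*04:05", NA),
    allele2 = c("DRB1*15:01", "B*07:02", "DRB1*04:05", "B*07:02",
                "DRB1*09:01", "B*39:01"),
    stringsAsFactors = FALSE)
  ph <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    status = c("case", "case", "control"),
    cohort = c("MS", "MS", "control"),
    edss = c(3, 5, NA), age_at_onset = c(30, 41, NA),
    stringsAsFactors = FALSE)
  list(genotypes = g, cohort = ph)
}

# expand a 2x2 allele-count table into chromosome-level observations
chrom_expand <- function(a, b, c, d) {
  list(dosage = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
       status = c(rep(1, a + b), rep(0, c + d)))
}

# dosage object + cohort with an exact carrier split among 45 cases
clinical_fixture <- function(n_carrier = 18, n_case = 45, seed = 42) {
  g <- data.frame(
    sample_id = sprintf("c%02d", seq_len(n_case)),
    gene = "DRB1",
    allele1 = c(rep("DRB1*15:01", n_carrier),
                rep("DRB1*90:01", n_case - n_carrier)),
    allele2 = "DRB1*90:01",
    stringsAsFactors = FALSE)
  set.seed(seed)
  ph <- data.frame(
    sample_id = g$sample_id, status = "case", cohort = "MS",
    edss = round(pmin(pmax(rnorm(n_case, 3.1, 1.8), 0), 10), 1),
    age_at_onset = round(rnorm(n_case, 34, 11), 1),
    stringsAsFactors = FALSE)
  list(dosage = build_allele_dosage(g, ph), cohort = ph)
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins via the hypergeometric probability written out with lchoose
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# binomial log-likelihood of a fitted logistic model
binom_ll <- function(y, fitted) sum(stats::dbinom(y, 1, fitted, log = TRUE))

# two-gene cohort with independent planted effects
two_effect_config <- function(seed, n_case = 150, n_control = 600,
                              beta = log(3)) {
  synthetic_config(
    genes = list(
      DRB1 = c("DRB1*15:01" = 0.15, "DRB1*04:05" = 0.25,
               "DRB1*90:01" = 0.60),
      B = c("B*39:01" = 0.15, "B*07:02" = 0.35, "B*90:01" = 0.50)),
    n_case = n_case, n_control = n_control,
    effects = c("DRB1*15:01" = beta, "B*39:01" = beta),
    seed = seed)
}
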