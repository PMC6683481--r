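#' Synthetic case-control HLA cohorts
#'
#' Generates unphased diploid HLA genotypes under Hardy-Weinberg pairing of
#' haplotypes with configurable per-gene allele frequencies, optional
#' explicit two-gene haplotype coupling (to induce a target LD r-squared),
#' and case/control status drawn from an additive logistic liability,
#' `logit P(case) = beta0 + sum(beta * dosage)`. Case-control
#' ascertainment uses rejection sampling until the requested group sizes
#' are filled, under which the dosage logistic odds ratio remains
#' consistent. One master seed drives everything; per-(gene, batch)
#' substreams are derived from it so adding a gene leaves other genes'
#' draws unchanged.
#'
#' @name synthetic-cohort
NULL

# deterministic 31-bit substream seed from the master seed and a label
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483563
  as.integer((seed %% 2147483563) * 31 + h) %% 2147483563L
}

#' Build a synthetic cohort configuration
#'
#' @param genes named list: gene -> named numeric vector of allele
#'   frequencies summing to 1 (names are full `GENE*NN:NN` alleles).
#' @param n_case,n_control requested group sizes.
#' @param effects named numeric vector of planted log-odds ratios per
#'   allele dosage unit; names must be configured alleles.
#' @param beta0 logistic intercept; default calibrated so the marginal
#'   case probability is about `target_case_rate`.
#' @param target_case_rate marginal case probability used to calibrate the
#'   default intercept (default 0.1, mimicking case-control sampling from
#'   a population where disease is uncommon).
#' @param hap_blocks optional list of data frames with columns
#'   `gene_a`, `gene_b` (allele names) and `freq`, giving an explicit joint
#'   haplotype distribution for a pair of genes (see
#'   [couple_haplotypes()]); listed genes are drawn jointly.
#' @param clinical list controlling case clinical values:
#'   `edss_base`, `edss_sd`, `onset_base`, `onset_sd`, and optional named
#'   shift vectors `edss_shifts` / `onset_shifts` added per carried copy of
#'   the named allele.
#' @param cohort_label cohort name given to cases (default `"MS"`).
#' @param seed master seed (integer).
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(genes, n_case, n_control,
                             effects = numeric(), beta0 = NULL,
                             target_case_rate = 0.1, hap_blocks = NULL,
                             clinical = NULL, cohort_label = "MS",
                             seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1)
  for (gene in names(genes)) {
    f <- genes[[gene]]
    if (abs(sum(f) - 1) > 1e-9) {
      stop("allele frequencies for ", gene, " must sum to 1", call. = FALSE)
    }
    if (any(f < 0 | f > 1)) {
      stop("frequencies must lie in [0, 1]", call. = FALSE)
    }
    if (!all(allele_gene(names(f)) == gene)) {
      stop("allele names for ", gene, " must carry that gene prefix",
           call. = FALSE)
    }
  }
  all_alleles <- unlist(lapply(genes, names), use.names = FALSE)
  if (length(effects) && !all(names(effects) %in% all_alleles)) {
    stop("effect allele(s) not configured: ",
         paste(setdiff(names(effects), all_alleles), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(hap_blocks)) {
    for (blk in hap_blocks) {
      stopifnot(all(c("gene_a", "gene_b", "freq") %in% names(blk)))
      if (abs(sum(blk$freq) - 1) > 1e-9) {
        stop("haplotype block frequencies must sum to 1", call. = FALSE)
      }
    }
  }
  clin_default <- list(edss_base = 3.1, edss_sd = 1.8, onset_base = 34.3,
                       onset_sd = 11, edss_shifts = numeric(),
                       onset_shifts = numeric())
  clinical <- utils::modifyList(clin_default, clinical %||% list())
  if (is.null(beta0)) {
    mean_eta <- if (length(effects)) {
      freq <- vapply(names(effects), function(a) {
        genes[[allele_gene(a)]][[a]]
      }, 0)
      sum(effects * 2 * freq)
    } else 0
    beta0 <- stats::qlogis(target_case_rate) - mean_eta
  }
  structure(list(genes = genes, n_case = as.integer(n_case),
                 n_control = as.integer(n_control), effects = effects,
                 beta0 = beta0, hap_blocks = hap_blocks,
                 clinical = clinical, cohort_label = cohort_label,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Joint two-gene haplotype table inducing a target r-squared
#'
#' Couples one focal allele per gene at haplotype-level correlation
#' `sqrt(r2)` and leaves all other allele combinations at independence
#' proportions. Under random (Hardy-Weinberg) pairing the dosage
#' correlation between the two focal alleles converges to the haplotype
#' correlation, so the realized dosage r-squared matches `r2`.
#'
#' @param freq_a,freq_b named allele frequency vectors of the two genes.
#' @param focal_a,focal_b the coupled allele in each gene.
#' @param r2 target r-squared in `[0, 1]`.
#' @return data frame with `gene_a`, `gene_b`, `freq` covering all allele
#'   pairs (zero-frequency rows dropped).
#' @export
couple_haplotypes <- function(freq_a, freq_b, focal_a, focal_b, r2) {
  stopifnot(focal_a %in% names(freq_a), focal_b %in% names(freq_b),
            r2 >= 0, r2 <= 1)
  pA <- freq_a[[focal_a]]
  pB <- freq_b[[focal_b]]
  pAB <- pA * pB + sqrt(r2 * pA * (1 - pA) * pB * (1 - pB))
  if (pAB > min(pA, pB) + 1e-12) {
    stop("target r2 unattainable at these focal frequencies", call. = FALSE)
  }
  pAB <- min(pAB, pA, pB)
  others_a <- setdiff(names(freq_a), focal_a)
  others_b <- setdiff(names(freq_b), focal_b)
  wa <- freq_a[others_a] / max(1 - pA, 1e-12)
  wb <- freq_b[others_b] / max(1 - pB, 1e-12)
  grid <- expand.grid(gene_a = names(freq_a), gene_b = names(freq_b),
                      stringsAsFactors = FALSE)
  grid$freq <- apply(grid, 1, function(row) {
    a_focal <- row[["gene_a"]] == focal_a
    b_focal <- row[["gene_b"]] == focal_b
    if (a_focal && b_focal) pAB
    else if (a_focal) (pA - pAB) * wb[[row[["gene_b"]]]]
    else if (b_focal) (pB - pAB) * wa[[row[["gene_a"]]]]
    else (1 - pA - pB + pAB) * wa[[row[["gene_a"]]]] * wb[[row[["gene_b"]]]]
  })
  grid <- grid[grid$freq > 0, ]
  grid$freq <- grid$freq / sum(grid$freq)
  rownames(grid) <- NULL
  grid
}

#' Sample haplotypes for a batch of individuals
#'
#' Two independent haplotypes per individual; within a haplotype, genes are
#' independent unless covered by a haplotype block, which is drawn jointly.
#' Each (gene, batch) pair uses its own RNG substream.
#'
#' @param config a `synthetic_config`.
#' @param n number of individuals.
#' @param batch batch index used in substream derivation.
#' @return list of two data frames (`hap1`, `hap2`), each n x genes of
#'   allele names.
#' @export
sample_haplotypes <- function(config, n, batch = 1L) {
  genes <- names(config$genes)
  block_genes <- character()
  draws <- list()
  for (bi in seq_along(config$hap_blocks %||% list())) {
    blk <- config$hap_blocks[[bi]]
    ga <- allele_gene(blk$gene_a[1])
    gb <- allele_gene(blk$gene_b[1])
    block_genes <- c(block_genes, ga, gb)
    lab <- paste0("block:", ga, ":", gb, ":", batch)
    idx <- local_rng(substream_seed(config$seed, lab), {
      sample.int(nrow(blk), 2 * n, replace = TRUE, prob = blk$freq)
    })
    draws[[ga]] <- matrix(blk$gene_a[idx], n, 2)
    draws[[gb]] <- matrix(blk$gene_b[idx], n, 2)
  }
  for (gene in setdiff(genes, block_genes)) {
    f <- config$genes[[gene]]
    idx <- local_rng(substream_seed(config$seed,
                                    paste0("gene:", gene, ":", batch)), {
      sample.int(length(f), 2 * n, replace = TRUE, prob = f)
    })
    draws[[gene]] <- matrix(names(f)[idx], n, 2)
  }
  hap1 <- as.data.frame(lapply(draws[genes], function(m) m[, 1]),
                        optional = TRUE, stringsAsFactors = FALSE)
  hap2 <- as.data.frame(lapply(draws[genes], function(m) m[, 2]),
                        optional = TRUE, stringsAsFactors = FALSE)
  names(hap1) <- names(hap2) <- genes
  list(hap1 = hap1, hap2 = hap2)
}

# run code under a local RNG state without disturbing the caller's stream
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a case-control cohort
#'
#' Draws batches of individuals, assigns case status from the additive
#' logistic liability, and keeps rejection-sampling until the configured
#' numbers of cases and controls are reached (bounded attempt budget).
#' Case clinical values (EDSS, age at onset) come from the configured
#' carrier-shift normal model; EDSS is clamped to `[0, 10]`.
#'
#' @param config a `synthetic_config`.
#' @param max_batches attempt budget (batches of
#'   `max(2000, 2 * (n_case + n_control))` individuals).
#' @return list with `genotypes` (genotype table covering every configured
#'   gene) and `cohort` (cohort table; cases first).
#' @export
simulate_cohort <- function(config, max_batches = 60L) {
  genes <- names(config$genes)
  n_need <- c(case = config$n_case, control = config$n_control)
  batch_n <- max(2000L, 2L * (config$n_case + config$n_control))
  kept_h1 <- list(); kept_h2 <- list(); kept_status <- list()
  got <- c(case = 0L, control = 0L)
  for (b in seq_len(max_batches)) {
    haps <- sample_haplotypes(config, batch_n, batch = b)
    eta <- rep(config$beta0, batch_n)
    for (al in names(config$effects)) {
      gene <- allele_gene(al)
      dosage <- (haps$hap1[[gene]] == al) + (haps$hap2[[gene]] == al)
      eta <- eta + config$effects[[al]] * dosage
    }
    u <- local_rng(substream_seed(config$seed, paste0("status:", b)),
                   stats::runif(batch_n))
    is_case <- u < stats::plogis(eta)
    for (grp in c("case", "control")) {
      want <- n_need[[grp]] - got[[grp]]
      if (want <= 0) next
      rows <- which(if (grp == "case") is_case else !is_case)
      rows <- utils::head(rows, want)
      if (!length(rows)) next
      kept_h1[[length(kept_h1) + 1L]] <- haps$hap1[rows, , drop = FALSE]
      kept_h2[[length(kept_h2) + 1L]] <- haps$hap2[rows, , drop = FALSE]
      kept_status[[length(kept_status) + 1L]] <- rep(grp, length(rows))
      got[[grp]] <- got[[grp]] + length(rows)
    }
    if (all(got >= n_need)) break
  }
  if (!all(got >= n_need)) {
    stop("could not reach requested case/control counts within the ",
         "attempt budget; check beta0/effects", call. = FALSE)
  }
  h1 <- do.call(rbind, kept_h1)
  h2 <- do.call(rbind, kept_h2)
  status <- unlist(kept_status)
  ord <- order(factor(status, levels = c("case", "control")))
  h1 <- h1[ord, , drop = FALSE]; h2 <- h2[ord, , drop = FALSE]
  status <- status[ord]
  n <- length(status)
  ids <- sprintf("S%05d", seq_len(n))
  genotypes <- data.frame(
    sample_id = rep(ids, each = length(genes)),
    gene = rep(genes, n),
    allele1 = as.vector(t(as.matrix(h1))),
    allele2 = as.vector(t(as.matrix(h2))),
    stringsAsFactors = FALSE)
  cohort <- data.frame(sample_id = ids, status = status,
                       cohort = ifelse(status == "case",
                                       config$cohort_label, "control"),
                       edss = NA_real_, age_at_onset = NA_real_,
                       stringsAsFactors = FALSE)
  ci <- which(status == "case")
  if (length(ci)) {
    cl <- config$clinical
    shift_sum <- function(shifts) {
      s <- rep(0, length(ci))
      for (al in names(shifts)) {
        gene <- allele_gene(al)
        s <- s + shifts[[al]] *
          ((h1[[gene]][ci] == al) + (h2[[gene]][ci] == al))
      }
      s
    }
    vals <- local_rng(substream_seed(config$seed, "clinical"), {
      list(edss = cl$edss_base + shift_sum(cl$edss_shifts) +
             stats::rnorm(length(ci), 0, cl$edss_sd),
           onset = cl$onset_base + shift_sum(cl$onset_shifts) +
             stats::rnorm(length(ci), 0, cl$onset_sd))
    })
    cohort$edss[ci] <- round(pmin(pmax(vals$edss, 0), 10), 1)
    cohort$age_at_onset[ci] <- round(pmax(vals$onset, 1), 1)
  }
  list(genotypes = validate_genotypes(genotypes),
       cohort = validate_cohort(cohort))
}
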