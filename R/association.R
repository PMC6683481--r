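#' Single-marker case-control association tests
#'
#' The scan fits an additive-dosage logistic model per marker (status on
#' intercept + dosage, optionally + covariate dosages) when the marker's
#' 2x2 allele-count table is dense, and falls back to Fisher's exact test
#' when any cell of that table is 5 or fewer. Significance is judged by
#' Bonferroni correction over the markers assessed in the scan.
#'
#' @name association
NULL

#' A 2x2 allele-count table
#'
#' @param a case chromosomes carrying the allele.
#' @param b case chromosomes not carrying it.
#' @param c control chromosomes carrying the allele.
#' @param d control chromosomes not carrying it.
#' @return named integer-ish vector of class `twobytwo`.
#' @export
twobytwo <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) {
    stop("2x2 cells must be nonnegative integers", call. = FALSE)
  }
  structure(v, class = "twobytwo")
}

#' Cross-product (sample) odds ratio
#'
#' `(a * d) / (b * c)`. A zero `b` or `c` with a nonzero numerator returns
#' `Inf`; a zero numerator returns 0; the all-zero table is an error.
#'
#' @param t a [twobytwo()].
#' @return the sample odds ratio.
#' @export
crossproduct_or <- function(t) {
  if (all(t == 0)) stop("odds ratio undefined for the all-zero table",
                        call. = FALSE)
  num <- t[["a"]] * t[["d"]]
  den <- t[["b"]] * t[["c"]]
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / den
}

#' Large-sample (Wald) confidence interval for the odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile for the requested level. Requires all four
#' cells positive; sparse tables should use the exact CI from
#' [fisher_test()].
#'
#' @param t a [twobytwo()].
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
wald_ci <- function(t, level = 0.95) {
  if (any(t == 0)) {
    stop("wald_ci requires all cells > 0; use the exact CI from fisher_test",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- log(crossproduct_or(t))
  se <- sqrt(sum(1 / t))
  c(low = exp(lo - z * se), high = exp(lo + z * se))
}

# Two-sided exact p: sum hypergeometric probabilities not exceeding the
# observed table's, with the conventional 1e-7 relative tolerance for ties.
fisher_p_twosided <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities less than
#' or equal to that of the observed table (the standard convention). When
#' `or = TRUE` the conditional maximum-likelihood odds ratio and exact CI
#' (from [stats::fisher.test()]) and the sample cross-product odds ratio
#' are also returned.
#'
#' @param t a [twobytwo()].
#' @param or also compute the conditional-MLE OR and exact CI (slower).
#' @param level confidence level for the exact CI.
#' @return list with `p`, and if `or`: `or_cmle`, `ci_low`, `ci_high`,
#'   `or_crossproduct`.
#' @export
fisher_test <- function(t, or = TRUE, level = 0.95) {
  p <- fisher_p_twosided(t[["a"]], t[["b"]], t[["c"]], t[["d"]])
  out <- list(p = p)
  if (or) {
    ft <- stats::fisher.test(matrix(t, 2, 2, byrow = TRUE),
                             conf.level = level)
    out$or_cmle <- unname(ft$estimate)
    out$ci_low <- ft$conf.int[1]
    out$ci_high <- ft$conf.int[2]
    out$or_crossproduct <- if (all(t == 0)) NaN else
      suppressWarnings(tryCatch(crossproduct_or(t), error = function(e) NaN))
  }
  out
}

#' Choose the per-marker test
#'
#' Fisher's exact test when the smallest cell of the 2x2 allele-count table
#' is 5 or fewer; the additive logistic model otherwise. This minimum-cell
#' rule reproduces the sparse-row/dense-row split used for the reference
#' cohorts.
#'
#' @param t a [twobytwo()].
#' @return `"fisher"` or `"logistic"`.
#' @export
select_test <- function(t) {
  if (min(t) <= 5) "fisher" else "logistic"
}

#' Bonferroni-adjusted significance threshold
#' @param m number of variants assessed in the scan.
#' @return `0.05 / m`.
#' @export
bonferroni_threshold <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("m must be a positive count", call. = FALSE)
  }
  0.05 / m
}

#' Additive-dosage logistic association
#'
#' Maximum-likelihood logistic regression of case status on an intercept,
#' the marker dosage, and optional covariate dosages. Reports the dosage
#' coefficient (log-odds per copy), its Wald standard error, two-sided
#' Wald p (likelihood-ratio p optionally), the odds ratio `exp(beta)` and
#' its Wald 95% CI. Complete-case over the marker and covariates.
#'
#' @param dosage numeric dosage vector.
#' @param status logical or 0/1 case indicator, same length.
#' @param covariates optional numeric matrix / data frame / list of
#'   covariate dosage vectors.
#' @param p_method `"wald"` (default) or `"lrt"` for the dosage p-value.
#' @return list with `beta`, `se`, `p`, `or_point`, `ci_low`, `ci_high`,
#'   `n`, `converged`, `separation` (TRUE flags an unreliable fit whose
#'   p/CI are set `NA`).
#' @export
logistic_assoc <- function(dosage, status, covariates = NULL,
                           p_method = c("wald", "lrt")) {
  p_method <- match.arg(p_method)
  status <- as.integer(as.logical(status))
  X <- cbind(dosage = dosage)
  if (!is.null(covariates)) {
    cov <- as.matrix(as.data.frame(covariates))
    if (is.null(colnames(cov)) || any(colnames(cov) == "")) {
      colnames(cov) <- paste0("cov", seq_len(ncol(cov)))
    }
    X <- cbind(X, cov)
  }
  cc <- stats::complete.cases(X) & !is.na(status)
  X <- X[cc, , drop = FALSE]
  y <- status[cc]
  if (length(unique(y)) < 2) {
    stop("need at least one case and one control with observed dosage",
         call. = FALSE)
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(D, y, family = stats::binomial()))
  beta <- fit$coefficients[["dosage"]]
  cov_mat <- tryCatch(chol2inv(chol(crossprod(D * sqrt(fit$weights)))),
                      error = function(e) NULL)
  se <- if (is.null(cov_mat)) NA_real_ else
    sqrt(cov_mat[which(colnames(D) == "dosage"),
                 which(colnames(D) == "dosage")])
  separation <- !fit$converged || is.na(se) || abs(beta) > 15 || se > 100
  if (separation) {
    p <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else if (p_method == "wald") {
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    D0 <- D[, colnames(D) != "dosage", drop = FALSE]
    fit0 <- suppressWarnings(stats::glm.fit(D0, y,
                                            family = stats::binomial()))
    dev <- fit0$deviance - fit$deviance
    p <- stats::pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(beta = unname(beta), se = unname(se), p = p,
       or_point = exp(unname(beta)), ci_low = ci[1], ci_high = ci[2],
       n = length(y), converged = fit$converged, separation = separation)
}

#' Per-marker 2x2 table from a dosage matrix
#' @param d an `hla_dosage`.
#' @param cohort cohort table.
#' @param marker marker id.
#' @return a [twobytwo()] of allele-count (chromosome) cells.
#' @export
marker_table <- function(d, cohort, marker) {
  x <- d$dosage[, marker]
  status <- cohort$status[match(rownames(d$dosage), cohort$sample_id)]
  ok <- !is.na(x)
  a <- sum(x[ok & status == "case"])
  ca_den <- 2 * sum(ok & status == "case")
  c_ <- sum(x[ok & status == "control"])
  co_den <- 2 * sum(ok & status == "control")
  twobytwo(a, ca_den - a, c_, co_den - c_)
}

#' Single-marker association scan
#'
#' For each marker, chooses the test by [select_test()] on its allele-count
#' 2x2 table, runs the additive logistic model or Fisher's exact test, and
#' flags Bonferroni significance at `0.05 / m` with `m` the number of
#' markers in the scan. With covariates every marker is fit by
#' covariate-adjusted logistic regression (Fisher admits no covariates);
#' sparse markers keep a `sparse` reliability flag.
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table.
#' @param markers marker ids to scan (typically from [filter_markers()]).
#' @param covariate_markers marker ids used as covariate dosages.
#' @param test `"auto"` (select per marker), `"logistic"`, or `"fisher"`.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data frame sorted by p: one row per marker with `marker_id`,
#'   `test_used`, `beta`, `se`, `or_point`, `ci_low`, `ci_high`, `p`,
#'   `or_crossproduct`, `sparse`, `not_testable`, `error`,
#'   `significant_bonferroni`; attribute `bonferroni` holds the threshold.
#' @export
run_scan <- function(d, cohort, markers = d$markers$marker_id,
                     covariate_markers = character(),
                     test = c("auto", "logistic", "fisher"), alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(all(markers %in% colnames(d$dosage)),
            all(covariate_markers %in% colnames(d$dosage)))
  status <- cohort$status[match(rownames(d$dosage), cohort$sample_id)]
  y <- status == "case"
  covs <- if (length(covariate_markers)) {
    cv <- d$dosage[, covariate_markers, drop = FALSE]
    # a conditioned marker with constant dosage carries no information
    keep_cv <- apply(cv, 2, function(x) stats::var(x, na.rm = TRUE) > 0)
    if (any(!keep_cv)) cv <- cv[, keep_cv, drop = FALSE]
    if (ncol(cv)) cv else NULL
  } else NULL
  rows <- lapply(markers, function(mk) {
    out <- data.frame(marker_id = mk, test_used = NA_character_,
                      beta = NA_real_, se = NA_real_, or_point = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      or_crossproduct = NA_real_, sparse = FALSE,
                      not_testable = FALSE, error = NA_character_,
                      stringsAsFactors = FALSE)
    tab <- marker_table(d, cohort, mk)
    out$or_crossproduct <- suppressWarnings(
      tryCatch(crossproduct_or(tab), error = function(e) NaN))
    choice <- if (test == "auto") select_test(tab) else test
    out$sparse <- min(tab) <= 5
    tryCatch({
      if (!is.null(covs) || choice == "logistic") {
        if (mk %in% covariate_markers) {
          out$not_testable <- TRUE
          out$error <- "marker is one of the conditioning covariates"
          return(out)
        }
        if (!is.null(covs) &&
            projection_r2(d$dosage[, mk], covs) > 0.99) {
          out$not_testable <- TRUE
          out$error <- "collinear with conditioned markers (r2 > 0.99)"
          return(out)
        }
        fit <- logistic_assoc(d$dosage[, mk], y, covariates = covs)
        out$test_used <- "logistic"
        out[c("beta", "se", "p", "or_point", "ci_low", "ci_high")] <-
          fit[c("beta", "se", "p", "or_point", "ci_low", "ci_high")]
      } else {
        ft <- fisher_test(tab)
        out$test_used <- "fisher"
        out$p <- ft$p
        out$or_point <- ft$or_cmle
        out$ci_low <- ft$ci_low
        out$ci_high <- ft$ci_high
      }
      out
    }, error = function(e) {
      out$not_testable <- TRUE
      out$error <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  thr <- bonferroni_threshold(length(markers)) * (alpha / 0.05)
  res$significant_bonferroni <- !is.na(res$p) & res$p < thr
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  attr(res, "bonferroni") <- thr
  attr(res, "n_markers") <- length(markers)
  res
}

# R-squared of a marker dosage on the span of covariate dosages
# (intercept included), over complete cases.
projection_r2 <- function(x, covs) {
  cc <- stats::complete.cases(covs) & !is.na(x)
  x <- x[cc]
  if (stats::var(x) == 0) return(1)
  fit <- stats::lm.fit(cbind(1, as.matrix(covs)[cc, , drop = FALSE]), x)
  1 - sum(fit$residuals^2) / sum((x - mean(x))^2)
}
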