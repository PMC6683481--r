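#' Conditional, stepwise, and joint association analysis
#'
#' Conditional scans re-test each marker with previously selected markers'
#' dosages as covariates; stepwise selection iterates this, adding the
#' minimum-p marker while it stays under the Bonferroni threshold fixed at
#' the initial marker count. Because Fisher's exact test admits no
#' covariates, sparse markers are also fit by covariate-adjusted logistic
#' regression inside conditional rounds and carry a reliability flag.
#'
#' @name conditional
NULL

#' Conditional association scan
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table.
#' @param markers marker ids to test.
#' @param conditioned marker ids used as covariates.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data frame as [run_scan()]; markers collinear with the
#'   conditioned span (r-squared > 0.99) are flagged `not_testable`.
#' @export
conditional_scan <- function(d, cohort, markers = d$markers$marker_id,
                             conditioned = character(), alpha = 0.05) {
  run_scan(d, cohort, markers, covariate_markers = conditioned,
           alpha = alpha)
}

#' Stepwise forward selection of independent markers
#'
#' Round 1 is the unconditional scan; the minimum-p marker is selected if
#' its p-value is below `0.05 / m` with `m` the initial marker count, and
#' subsequent rounds condition on everything selected so far. Stops at the
#' first round where no marker passes. Ties break by smallest p, then
#' largest absolute beta, then lexicographic marker id.
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table.
#' @param markers marker ids entering the scan.
#' @param threshold selection threshold; default `0.05 / length(markers)`,
#'   fixed across rounds.
#' @return list of class `stepwise_trace`: `selected` (marker ids in
#'   selection order), `threshold`, and `rounds` (list of per-round scan
#'   data frames with the selected marker in `attr(, "selected")`).
#' @export
stepwise_select <- function(d, cohort, markers = d$markers$marker_id,
                            threshold = NULL) {
  stopifnot(length(markers) >= 1)
  if (is.null(threshold)) threshold <- bonferroni_threshold(length(markers))
  selected <- character()
  rounds <- list()
  repeat {
    res <- conditional_scan(d, cohort, setdiff(markers, selected),
                            conditioned = selected)
    cand <- res[!res$not_testable & !is.na(res$p) & res$p < threshold, ,
                drop = FALSE]
    if (nrow(cand)) {
      ord <- order(cand$p, -abs(cand$beta), cand$marker_id)
      pick <- cand$marker_id[ord[1]]
    } else {
      pick <- NA_character_
    }
    attr(res, "selected") <- pick
    rounds[[length(rounds) + 1L]] <- res
    if (is.na(pick)) break
    selected <- c(selected, pick)
    if (length(selected) == length(markers)) break
  }
  structure(list(selected = selected, threshold = threshold,
                 rounds = rounds), class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("<stepwise_trace> %d round(s), threshold %.3g\n",
              length(x$rounds), x$threshold))
  if (length(x$selected)) {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("selected: (none)\n")
  }
  invisible(x)
}

#' Joint multivariate logistic fit
#'
#' One logistic model with all requested marker dosages; each marker's
#' coefficient is its effect conditional on the others.
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table.
#' @param markers marker ids entering the joint model.
#' @return data frame with one row per marker: `beta`, `se`, `or_point`,
#'   `ci_low`, `ci_high`, `p` (two-sided Wald).
#' @export
joint_fit <- function(d, cohort, markers) {
  stopifnot(length(markers) >= 1, all(markers %in% colnames(d$dosage)))
  X <- d$dosage[, markers, drop = FALSE]
  status <- cohort$status[match(rownames(d$dosage), cohort$sample_id)]
  cc <- stats::complete.cases(X) & !is.na(status)
  X <- X[cc, , drop = FALSE]
  y <- as.integer(status[cc] == "case")
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dep <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    # name a minimal collinear subset: each dependent column plus the
    # independent columns with nonzero weight in its representation
    subsets <- vapply(dep, function(cn) {
      basis <- D[, setdiff(colnames(D), dep), drop = FALSE]
      w <- stats::lm.fit(basis, D[, cn])$coefficients
      involved <- names(w)[!is.na(w) & abs(w) > 1e-8]
      paste(c(cn, setdiff(involved, "(Intercept)")), collapse = " + ")
    }, "")
    stop("collinear marker set; minimal dependent subset(s): ",
         paste(subsets, collapse = "; "), call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(D, y, family = stats::binomial()))
  V <- chol2inv(chol(crossprod(D * sqrt(fit$weights))))
  idx <- match(markers, colnames(D))
  beta <- fit$coefficients[idx]
  se <- sqrt(diag(V))[idx]
  z <- beta / se
  data.frame(marker_id = markers, beta = unname(beta), se = unname(se),
             or_point = exp(unname(beta)),
             ci_low = exp(unname(beta - stats::qnorm(0.975) * se)),
             ci_high = exp(unname(beta + stats::qnorm(0.975) * se)),
             p = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}
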