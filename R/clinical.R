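#' Carrier-status association with clinical measures
#'
#' Cases are split into carriers (dosage >= 1) and non-carriers of a marker
#' and compared on a clinical measure (EDSS, age at onset) by the classic
#' pooled-variance two-sample t-test. Controls carry no clinical measures
#' and never enter these tests.
#'
#' @name clinical
NULL

#' Carrier status of a marker
#' @param d an `hla_dosage`.
#' @param marker marker id.
#' @return named logical vector: `TRUE` for dosage >= 1, `NA` when the
#'   dosage is missing.
#' @export
carrier_status <- function(d, marker) {
  stopifnot(marker %in% colnames(d$dosage))
  x <- d$dosage[, marker]
  out <- x >= 1
  names(out) <- rownames(d$dosage)
  out
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic equal-variance t with `n1 + n2 - 2` degrees of freedom and a
#' two-sided p. `welch = TRUE` switches to the unequal-variance form.
#' Identical constant groups return `t = 0, p = 1` rather than `NaN`.
#'
#' @param x,y numeric value vectors (NAs dropped); each needs >= 2 values.
#' @param welch use the Welch (unequal-variance) test instead.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
students_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observed values", call. = FALSE)
  }
  pooled_sd <- sqrt(((length(x) - 1) * stats::var(x) +
                       (length(y) - 1) * stats::var(y)) /
                      (length(x) + length(y) - 2))
  if (pooled_sd == 0 && mean(x) == mean(y)) {
    res <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                p.value = 1)
  } else {
    res <- stats::t.test(x, y, var.equal = !welch)
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_x = mean(x), mean_y = mean(y),
       n_x = length(x), n_y = length(y))
}

#' Carrier-status tests of clinical measures across markers
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table (only cases with an observed measure enter).
#' @param markers marker ids to test.
#' @param measures clinical columns to test (default EDSS and age at
#'   onset).
#' @param welch use the Welch test instead of pooled-variance Student's t.
#' @return data frame with one row per marker x measure: `n_pos`, `n_neg`,
#'   `mean_pos`, `mean_neg`, `t_stat`, `p`.
#' @export
clinical_scan <- function(d, cohort, markers,
                          measures = c("edss", "age_at_onset"),
                          welch = FALSE) {
  stopifnot(all(measures %in% names(cohort)))
  cases <- cohort[cohort$status == "case", ]
  rows <- list()
  for (mk in markers) {
    carrier <- carrier_status(d, mk)[cases$sample_id]
    for (ms in measures) {
      val <- cases[[ms]]
      ok <- !is.na(carrier) & !is.na(val)
      res <- tryCatch(
        students_t(val[ok & carrier], val[ok & !carrier], welch = welch),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = mk, measure = ms,
        n_pos = sum(ok & carrier), n_neg = sum(ok & !carrier),
        mean_pos = if (is.null(res)) NA_real_ else res$mean_x,
        mean_neg = if (is.null(res)) NA_real_ else res$mean_y,
        t_stat = if (is.null(res)) NA_real_ else res$t,
        p = if (is.null(res)) NA_real_ else res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
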