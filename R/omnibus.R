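#' Per-position omnibus likelihood-ratio test
#'
#' Tests whether any residue at an amino-acid position carries case-control
#' signal: the full logistic model has an intercept, any conditioning
#' covariates, and n - 1 residue dosage terms (the reference residue, the
#' most frequent in controls, is dropped); the null drops the residue
#' terms. The deviance, twice the log-likelihood difference, is referred to
#' a chi-squared distribution with n - 1 degrees of freedom.
#'
#' @param d an `hla_dosage` containing the position's residue markers.
#' @param cohort cohort table.
#' @param gene gene name.
#' @param position signed nonzero position.
#' @param covariate_markers marker ids used as covariates in both models.
#' @return list with `gene`, `position`, `n_residues`, `reference_residue`,
#'   `deviance`, `df`, `p`, `separation`.
#' @export
omnibus_position <- function(d, cohort, gene, position,
                             covariate_markers = character()) {
  sel <- d$markers$kind == "residue" & d$markers$gene == gene &
    d$markers$position == position
  ids <- d$markers$marker_id[sel]
  if (length(ids) < 2) {
    stop("position ", gene, ":", position,
         " is monomorphic (fewer than 2 residue markers)", call. = FALSE)
  }
  status <- cohort$status[match(rownames(d$dosage), cohort$sample_id)]
  X <- d$dosage[, ids, drop = FALSE]
  covs <- if (length(covariate_markers)) {
    d$dosage[, covariate_markers, drop = FALSE]
  } else NULL
  cc <- stats::complete.cases(X) & !is.na(status)
  if (!is.null(covs)) cc <- cc & stats::complete.cases(covs)
  X <- X[cc, , drop = FALSE]
  y <- as.integer(status[cc] == "case")
  ctrl_counts <- colSums(X[y == 0, , drop = FALSE])
  # reference residue: most frequent in controls; ties alphabetical.
  residues <- d$markers$residue[sel]
  ord <- order(-ctrl_counts, residues)
  ref_id <- ids[ord[1]]
  keep <- setdiff(ids, ref_id)
  D0 <- matrix(1, nrow(X), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covs)) D0 <- cbind(D0, as.matrix(covs)[cc, , drop = FALSE])
  D1 <- cbind(D0, X[, keep, drop = FALSE])
  # degenerate residue terms (constant or inside the null span) reduce df
  qr1 <- qr(D1)
  if (qr1$rank < ncol(D1)) {
    drop_cols <- colnames(D1)[qr1$pivot[(qr1$rank + 1):ncol(D1)]]
    keep <- setdiff(keep, drop_cols)
    D1 <- cbind(D0, X[, keep, drop = FALSE])
  }
  df <- ncol(D1) - ncol(D0)
  if (df < 1) {
    return(list(gene = gene, position = position,
                n_residues = length(ids), reference_residue =
                  d$markers$residue[d$markers$marker_id == ref_id],
                deviance = 0, df = 0L, p = 1, separation = FALSE))
  }
  fit0 <- suppressWarnings(stats::glm.fit(D0, y,
                                          family = stats::binomial()))
  fit1 <- suppressWarnings(stats::glm.fit(D1, y,
                                          family = stats::binomial()))
  deviance <- max(fit0$deviance - fit1$deviance, 0)
  separation <- !fit1$converged || any(abs(fit1$coefficients) > 15,
                                       na.rm = TRUE)
  list(gene = gene, position = position, n_residues = length(ids),
       reference_residue = d$markers$residue[d$markers$marker_id == ref_id],
       deviance = deviance, df = as.integer(df),
       p = stats::pchisq(deviance, df = df, lower.tail = FALSE),
       separation = separation)
}

#' Omnibus scan over all polymorphic positions in a dosage object
#'
#' @inheritParams omnibus_position
#' @param markers optional subset of residue marker ids defining which
#'   positions are scanned (e.g. after [filter_markers()]).
#' @return data frame with one row per (gene, position).
#' @export
omnibus_scan <- function(d, cohort, markers = NULL,
                         covariate_markers = character()) {
  def <- d$markers[d$markers$kind == "residue", ]
  if (!is.null(markers)) def <- def[def$marker_id %in% markers, ]
  keys <- unique(def[, c("gene", "position")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    om <- tryCatch(
      omnibus_position(d, cohort, keys$gene[i], keys$position[i],
                       covariate_markers),
      error = function(e) NULL)
    if (is.null(om)) return(NULL)
    as.data.frame(om[c("gene", "position", "n_residues", "deviance", "df",
                       "p", "separation")])
  })
  out <- do.call(rbind, rows)
  out[order(out$p), ]
}

#' Linkage-disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of the two dosage vectors over complete
#' cases in the requested group.
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table.
#' @param marker_a,marker_b marker ids.
#' @param group `"control"` (the usual reporting group), `"case"`, or
#'   `"all"`.
#' @return list with `marker_a`, `marker_b`, `group`, `r2`, `n`.
#' @export
ld_r2 <- function(d, cohort, marker_a, marker_b,
                  group = c("control", "case", "all")) {
  group <- match.arg(group)
  status <- cohort$status[match(rownames(d$dosage), cohort$sample_id)]
  keep <- if (group == "all") rep(TRUE, length(status)) else status == group
  x <- d$dosage[keep, marker_a]
  y <- d$dosage[keep, marker_b]
  cc <- !is.na(x) & !is.na(y)
  if (sum(cc) < 2) stop("fewer than 2 complete observations", call. = FALSE)
  if (stats::var(x[cc]) == 0 || stats::var(y[cc]) == 0) {
    stop("LD undefined: a marker has zero dosage variance in group ",
         group, call. = FALSE)
  }
  list(marker_a = marker_a, marker_b = marker_b, group = group,
       r2 = stats::cor(x[cc], y[cc])^2, n = sum(cc))
}
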