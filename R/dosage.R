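#' Additive dosage matrices and marker frequency tables
#'
#' Markers are either alleles (one column per distinct four-digit allele) or
#' residues (one column per gene/position/residue combination). Dosages are
#' additive copy counts in {0, 1, 2}; a sample with any unobserved allele at
#' a gene is missing (`NA`) for all of that gene's markers.
#'
#' @name dosage
NULL

new_dosage <- function(mat, markers) {
  stopifnot(ncol(mat) == nrow(markers),
            identical(colnames(mat), markers$marker_id))
  structure(list(dosage = mat, markers = markers), class = "hla_dosage")
}

#' @export
print.hla_dosage <- function(x, ...) {
  cat(sprintf("<hla_dosage> %d samples x %d markers (%d allele, %d residue)\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(x$markers$kind == "allele"),
              sum(x$markers$kind == "residue")))
  invisible(x)
}

#' Combine dosage objects column-wise
#' @param ... `hla_dosage` objects over identical sample sets.
#' @return a single `hla_dosage`.
#' @export
bind_dosage <- function(...) {
  parts <- list(...)
  ids <- rownames(parts[[1]]$dosage)
  for (p in parts) stopifnot(identical(rownames(p$dosage), ids))
  new_dosage(do.call(cbind, lapply(parts, `[[`, "dosage")),
             do.call(rbind, lapply(parts, `[[`, "markers")))
}

#' Build the allele dosage matrix
#'
#' One marker per distinct allele observed in the genotype table. A
#' homozygote scores 2, a heterozygous carrier 1, a non-carrier with both
#' alleles observed 0; any missing allele at a gene makes the sample missing
#' for all that gene's markers. Samples absent from the cohort table are an
#' error; genes with no record for a sample are missing for that sample.
#'
#' @param g genotype table (see [read_genotypes()]).
#' @param cohort cohort table (see [read_cohort()]); defines row order.
#' @return an `hla_dosage`: list with `dosage` (samples x markers matrix)
#'   and `markers` (marker definition data frame).
#' @export
build_allele_dosage <- function(g, cohort) {
  missing_samples <- setdiff(unique(g$sample_id), cohort$sample_id)
  if (length(missing_samples)) {
    stop("genotyped sample(s) absent from cohort: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  samples <- cohort$sample_id[cohort$sample_id %in% g$sample_id]
  alleles <- sort(unique(stats::na.omit(c(g$allele1, g$allele2))))
  markers <- data.frame(marker_id = alleles, kind = "allele",
                        gene = allele_gene(alleles), allele = alleles,
                        position = NA_integer_, residue = NA_character_,
                        stringsAsFactors = FALSE)
  mat <- matrix(NA_real_, length(samples), length(alleles),
                dimnames = list(samples, alleles))
  genes <- unique(g$gene)
  for (gene in genes) {
    cols <- markers$marker_id[markers$gene == gene]
    sub <- g[g$gene == gene, ]
    full <- sub[!is.na(sub$allele1) & !is.na(sub$allele2), ]
    if (!nrow(full)) next
    mat[full$sample_id, cols] <- 0
    for (col in c("allele1", "allele2")) {
      idx <- cbind(match(full$sample_id, samples),
                   match(full[[col]], alleles))
      mat[idx] <- mat[idx] + 1
    }
  }
  new_dosage(mat, markers)
}

#' Marker frequencies by group
#'
#' Counts are summed dosages over the group; denominators are observed
#' chromosomes, i.e. twice the number of group samples with a non-missing
#' dosage at the marker, so typing failures do not deflate frequencies.
#'
#' @param d an `hla_dosage`.
#' @param cohort cohort table covering the dosage rows.
#' @param group `"case"`, `"control"`, or `"all"`.
#' @return data frame with marker definitions plus `count`, `denominator`,
#'   `freq` for the requested group.
#' @export
allele_frequencies <- function(d, cohort, group = c("all", "case", "control")) {
  group <- match.arg(group)
  status <- cohort$status[match(rownames(d$dosage), cohort$sample_id)]
  keep <- if (group == "all") rep(TRUE, length(status)) else status == group
  if (!any(keep)) stop("empty group: ", group, call. = FALSE)
  sub <- d$dosage[keep, , drop = FALSE]
  count <- colSums(sub, na.rm = TRUE)
  denom <- 2 * colSums(!is.na(sub))
  out <- d$markers
  out$count <- as.integer(count)
  out$denominator <- as.integer(denom)
  out$freq <- ifelse(denom > 0, count / denom, NA_real_)
  out
}

#' Case and control frequencies side by side
#' @inheritParams allele_frequencies
#' @return data frame with `case_count`, `case_denominator`, `case_freq`,
#'   and the control analogues.
#' @export
case_control_frequencies <- function(d, cohort) {
  ca <- allele_frequencies(d, cohort, "case")
  co <- allele_frequencies(d, cohort, "control")
  out <- d$markers
  out$case_count <- ca$count
  out$case_denominator <- ca$denominator
  out$case_freq <- ca$freq
  out$control_count <- co$count
  out$control_denominator <- co$denominator
  out$control_freq <- co$freq
  out
}

#' Frequency and monomorphism marker filters
#'
#' Keeps markers with frequency above `min_freq` in both cases and controls.
#' Residue markers are additionally dropped when their position is
#' monomorphic (a single residue carried) within cases or within controls.
#'
#' @param freqs output of [case_control_frequencies()].
#' @param min_freq frequency threshold applied to both groups
#'   (default 0.001, i.e. 0.1%).
#' @return character vector of surviving `marker_id`s.
#' @export
filter_markers <- function(freqs, min_freq = 0.001) {
  keep <- !is.na(freqs$case_freq) & !is.na(freqs$control_freq) &
    freqs$case_freq > min_freq & freqs$control_freq > min_freq
  res <- freqs$kind == "residue"
  if (any(res)) {
    pos_key <- paste(freqs$gene, freqs$position)
    for (key in unique(pos_key[res])) {
      at <- res & pos_key == key
      mono <- sum(freqs$case_count[at] > 0) < 2 ||
        sum(freqs$control_count[at] > 0) < 2
      if (mono) keep[at] <- FALSE
    }
  }
  freqs$marker_id[keep]
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Reconstruct allele copy counts from a printed frequency
#'
#' Inverts a frequency reported to three decimals over `n_individuals`
#' diploid subjects: the denominator is `2 * n_individuals` chromosomes and
#' the count is the frequency times the denominator rounded to the nearest
#' integer (ties rounding half up). The reconstruction is checked by
#' re-rounding `count / denominator` to three decimals; disagreement with
#' the input sets `consistent = FALSE`, with a warning.
#'
#' @param freq reported frequency in `[0, 1]` (vectorized).
#' @param n_individuals number of diploid individuals in the group.
#' @return data frame with `count`, `denominator`, `consistent`.
#' @export
reconstruct_counts <- function(freq, n_individuals) {
  stopifnot(all(freq >= 0 & freq <= 1), n_individuals >= 1)
  denominator <- as.integer(2 * n_individuals)
  count <- as.integer(round_half_up(freq * denominator))
  consistent <- round_half_up(count / denominator, 3) == round_half_up(freq, 3)
  if (!all(consistent)) {
    warning("reconstructed count(s) do not re-round to the printed frequency",
            call. = FALSE)
  }
  data.frame(count = count, denominator = rep(denominator, length(count)),
             consistent = consistent)
}
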