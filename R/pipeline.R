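#' End-to-end fine-mapping pipeline
#'
#' Orchestrates the full analysis on genotype/phenotype files: marker
#' construction and filtering, the single-marker scan, stepwise conditional
#' selection, the joint multivariate model, per-position omnibus tests
#' (when an alignment is supplied), LD between the top two markers, and
#' carrier-status clinical tests. Writes TSV reports plus a run log and
#' returns the result objects.
#'
#' @param genotypes genotype table or path to a genotype TSV.
#' @param cohort cohort table or path to a phenotype TSV.
#' @param alignment optional alignment catalog (list of
#'   `protein_alignment`) or path to an alignment file; enables residue
#'   markers and omnibus tests.
#' @param out_dir output directory for reports (created); `NULL` skips
#'   writing.
#' @param marker_class `"allele"`, `"residue"`, or `"both"`.
#' @param min_freq marker frequency filter (both groups), default 0.001.
#' @param alpha family-wise error rate.
#' @param test `"auto"`, `"logistic"`, or `"fisher"`.
#' @param conditioned marker ids conditioned on in an extra conditional
#'   scan (optional).
#' @param clinical_markers marker ids for carrier-status clinical tests;
#'   default: the stepwise-selected markers.
#' @return list with `frequencies`, `kept_markers`, `scan`, `stepwise`,
#'   `joint`, `conditional`, `omnibus`, `ld_top_pair`, `clinical`, `log`.
#' @export
run_pipeline <- function(genotypes, cohort, alignment = NULL,
                         out_dir = NULL,
                         marker_class = c("allele", "residue", "both"),
                         min_freq = 0.001, alpha = 0.05,
                         test = c("auto", "logistic", "fisher"),
                         conditioned = character(),
                         clinical_markers = NULL) {
  marker_class <- match.arg(marker_class)
  test <- match.arg(test)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(alignment)) alignment <- read_protein_alignment(alignment)
  log_lines <- c(sprintf("hlafinemap %s | %d samples (%d case / %d control)",
                         as.character(utils::packageVersion("hlafinemap")),
                         nrow(cohort), sum(cohort$status == "case"),
                         sum(cohort$status == "control")))
  d_all <- build_allele_dosage(genotypes, cohort)
  if (marker_class %in% c("residue", "both")) {
    if (is.null(alignment)) {
      stop("residue markers need an alignment catalog", call. = FALSE)
    }
    res <- suppressMessages(
      build_residue_markers(alignment, genotypes, cohort))
    d <- if (marker_class == "both") bind_dosage(d_all, res$dosage) else
      res$dosage
  } else {
    d <- d_all
  }
  freqs <- case_control_frequencies(d, cohort)
  kept <- filter_markers(freqs, min_freq = min_freq)
  log_lines <- c(log_lines,
                 sprintf("markers: %d built, %d pass filters (min_freq %g)",
                         nrow(freqs), length(kept), min_freq))
  out <- list(frequencies = freqs, kept_markers = kept)
  if (length(kept)) {
    out$scan <- run_scan(d, cohort, kept, test = test, alpha = alpha)
    log_lines <- c(log_lines,
                   sprintf("bonferroni threshold: %.4g (m = %d)",
                           attr(out$scan, "bonferroni"), length(kept)))
    out$stepwise <- stepwise_select(d, cohort, kept)
    if (length(out$stepwise$selected) >= 1) {
      out$joint <- joint_fit(d, cohort, out$stepwise$selected)
    }
    if (length(conditioned)) {
      out$conditional <- conditional_scan(d, cohort, kept,
                                          conditioned = conditioned,
                                          alpha = alpha)
    }
    if (marker_class %in% c("residue", "both")) {
      out$omnibus <- omnibus_scan(d, cohort,
                                  markers = intersect(kept,
                                                      d$markers$marker_id[
                                                        d$markers$kind ==
                                                          "residue"]))
    }
    top <- out$scan$marker_id[!out$scan$not_testable][1:2]
    if (length(top) == 2 && !anyNA(top)) {
      out$ld_top_pair <- tryCatch(
        ld_r2(d, cohort, top[1], top[2], group = "control"),
        error = function(e) NULL)
    }
    cm <- clinical_markers %||% out$stepwise$selected
    if (length(cm) && any(!is.na(cohort$edss[cohort$status == "case"]))) {
      out$clinical <- clinical_scan(d, cohort, cm)
    }
  } else {
    log_lines <- c(log_lines, "no markers assessed")
  }
  out$log <- log_lines
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) {
      if (!is.null(x)) {
        utils::write.table(x, file.path(out_dir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "NA")
      }
    }
    wt(freqs, "frequencies.tsv")
    wt(out$scan, "scan.tsv")
    wt(out$joint, "joint_fit.tsv")
    wt(out$conditional, "conditional_scan.tsv")
    wt(out$omnibus, "omnibus.tsv")
    wt(out$clinical, "clinical.tsv")
    if (!is.null(out$stepwise)) {
      trace <- do.call(rbind, lapply(seq_along(out$stepwise$rounds),
                                     function(i) {
        r <- out$stepwise$rounds[[i]]
        r$round <- i
        r$selected <- r$marker_id %in% attr(r, "selected")
        r
      }))
      wt(trace, "stepwise_trace.tsv")
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}
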