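#' Genotype and phenotype tables
#'
#' A genotype table holds unphased four-digit HLA allele pairs, one row per
#' (sample, gene). A cohort table holds case/control status and the clinical
#' measures used downstream. Both are plain data frames validated on read.
#'
#' @name genotype-tables
NULL

ALLELE_PATTERN <- "^[A-Z][A-Z0-9]*\\*[0-9]{2,}:[0-9]{2,}(:[0-9]{2,})*[A-Z]?$"

#' Normalize a four-digit HLA allele name
#'
#' Uppercases the gene, validates the `GENE*NN:NN` shape, and truncates
#' higher-resolution names (6/8-digit fields, expression suffixes) to
#' two-field resolution with a message.
#'
#' @param allele character vector of allele names; `NA` passes through.
#' @param quiet suppress the truncation message.
#' @return character vector of normalized two-field allele names.
#' @export
normalize_allele <- function(allele, quiet = FALSE) {
  out <- as.character(allele)
  idx <- !is.na(out)
  out[idx] <- toupper(trimws(out[idx]))
  bad <- idx & !grepl(ALLELE_PATTERN, out)
  if (any(bad)) {
    stop("malformed allele name(s): ", paste(unique(out[bad]), collapse = ", "),
         " (expected GENE*NN:NN)", call. = FALSE)
  }
  long <- idx & grepl("^[^:]+:[0-9]+[:A-Z]", out)
  if (any(long)) {
    trunc <- sub("^([A-Z][A-Z0-9]*\\*[0-9]+:[0-9]+).*$", "\\1", out[long])
    if (!quiet) {
      message("truncated ", sum(long),
              " allele name(s) to 4-digit resolution")
    }
    out[long] <- trunc
  }
  out
}

#' Gene component of an allele name
#' @param allele character vector of `GENE*NN:NN` names.
#' @return character vector of gene names.
#' @export
allele_gene <- function(allele) {
  sub("\\*.*$", "", allele)
}

#' Read a genotype TSV
#'
#' File dialect: tab-separated with header
#' `sample_id  gene  allele1  allele2`; a missing allele is written `NA`.
#' Allele names are normalized to four-digit resolution; duplicate
#' (sample, gene) rows are an error.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `sample_id`, `gene`, `allele1`, `allele2`.
#' @export
read_genotypes <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  need <- c("sample_id", "gene", "allele1", "allele2")
  if (!all(need %in% names(g))) {
    stop("genotype file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g <- g[, need]
  validate_genotypes(g, path = path)
}

#' Validate a genotype table
#'
#' @param g data frame with `sample_id`, `gene`, `allele1`, `allele2`.
#' @param path optional source path used in error messages.
#' @return the validated (normalized) table, invisibly classed as given.
#' @export
validate_genotypes <- function(g, path = NULL) {
  src <- if (is.null(path)) "" else paste0(" in ", path)
  g$gene <- toupper(trimws(g$gene))
  for (col in c("allele1", "allele2")) {
    ok <- is.na(g[[col]]) | grepl(ALLELE_PATTERN, toupper(trimws(g[[col]])))
    if (!all(ok)) {
      stop("malformed allele name", src, " at line(s) ",
           paste(which(!ok) + 1L, collapse = ", "), ": ",
           paste(unique(g[[col]][!ok]), collapse = ", "), call. = FALSE)
    }
    g[[col]] <- normalize_allele(g[[col]], quiet = TRUE)
    mism <- !is.na(g[[col]]) & allele_gene(g[[col]]) != g$gene
    if (any(mism)) {
      stop("allele gene prefix disagrees with gene column", src,
           " at line(s) ", paste(which(mism) + 1L, collapse = ", "),
           call. = FALSE)
    }
  }
  key <- paste(g$sample_id, g$gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (sample, gene) record(s)", src, ": ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }
  rownames(g) <- NULL
  g
}

#' Write a genotype TSV
#' @param g genotype table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  utils::write.table(g[, c("sample_id", "gene", "allele1", "allele2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a phenotype TSV
#'
#' Dialect: tab-separated, header
#' `sample_id  status  cohort  edss  age_at_onset`; `status` is `case` or
#' `control`; missing numerics are `NA`. Controls carry cohort `control`.
#'
#' @param path path to the TSV file.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("sample_id", "status", "cohort", "edss", "age_at_onset")
  if (!all(need %in% names(ph))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(ph[, need])
}

#' Validate a cohort table
#' @param ph data frame with sample_id, status, cohort, edss, age_at_onset.
#' @return the validated table.
#' @export
validate_cohort <- function(ph) {
  if (anyDuplicated(ph$sample_id)) {
    stop("duplicate sample_id in cohort table", call. = FALSE)
  }
  if (!all(ph$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'", call. = FALSE)
  }
  if (!all((ph$status == "control") == (ph$cohort == "control"))) {
    stop("status 'control' must coincide with cohort 'control'",
         call. = FALSE)
  }
  ph$edss <- as.numeric(ph$edss)
  ph$age_at_onset <- as.numeric(ph$age_at_onset)
  if (any(ph$edss < 0, na.rm = TRUE)) {
    stop("edss must be nonnegative", call. = FALSE)
  }
  rownames(ph) <- NULL
  ph
}

#' Write a phenotype TSV
#' @param ph cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ph, path) {
  utils::write.table(ph[, c("sample_id", "status", "cohort", "edss",
                            "age_at_onset")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
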