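#' Bundled miniature fixtures
#'
#' A small in-code protein-alignment catalog (DQB1/DRB1/B) and a
#' study-scale synthetic cohort configuration whose control allele
#' frequencies follow the reference frequency tables
#' ([reference_allele_freqs()]), with planted effects on the four
#' MS-associated alleles and DRB1*15:01/DQB1*06:02 haplotype coupling at
#' r-squared 0.94. The alignment is synthetic: residues and spans are
#' invented for testing, not copied from any database release.
#'
#' @name fixtures
NULL

# assemble a protein_alignment from a reference string and variant specs
build_alignment <- function(gene, start, ref_name, ref_seq, variants,
                            extra = NULL) {
  seqs <- c(stats::setNames(ref_seq, ref_name),
            vapply(names(variants), function(al) {
              s <- strsplit(ref_seq, "")[[1]]
              for (v in variants[[al]]) s[v$col] <- v$res
              paste(s, collapse = "")
            }, ""))
  if (!is.null(extra)) seqs <- c(seqs, extra)
  new_alignment(gene, start, ref_name, seqs)
}

#' Miniature synthetic alignment catalog for DQB1, DRB1, and B
#'
#' DQB1 spans positions -18..12 (leader residues negative, no position 0)
#' with a gap column and one unknown residue; planted polymorphisms sit at
#' positions -18, -5, 7, and 9 (three residues at 9). DRB1 and B span
#' mature positions 1..10 with two polymorphic positions each.
#'
#' @return named list of `protein_alignment` objects.
#' @export
demo_alignment_catalog <- function() {
  # DQB1: 18 leader + gap column (col 19) + 12 mature columns
  ref_dqb1 <- paste0("MSWKKALRIPGGLRVATV", ".", "AYDSPQGRYHEL")
  v <- function(col, res) list(col = col, res = res)
  dqb1 <- build_alignment(
    "DQB1", start = -18L, ref_name = "DQB1*05:01", ref_seq = ref_dqb1,
    variants = list(
      "DQB1*06:02" = list(v(1, "V"), v(14, "L"), v(28, "F")),
      "DQB1*06:01" = list(v(1, "V"), v(14, "L")),
      "DQB1*03:02" = list(v(1, "*"), v(28, "F")),
      "DQB1*03:01" = list(v(26, "R")),
      "DQB1*03:03" = list(v(26, "R")),
      "DQB1*04:01" = list(v(28, "L")),
      "DQB1*90:01" = list(v(22, "E"))))
  drb1 <- build_alignment(
    "DRB1", start = 1L, ref_name = "DRB1*01:01", ref_seq = "GDTRPRFLWQ",
    variants = list(
      "DRB1*15:01" = list(v(4, "Q")),
      "DRB1*15:02" = list(v(4, "Q")),
      "DRB1*04:05" = list(v(6, "E")),
      "DRB1*09:01" = list(v(9, "K")),
      "DRB1*14:06" = list(v(9, "K")),
      "DRB1*90:01" = list(v(2, "N"))))
  b <- build_alignment(
    "B", start = 1L, ref_name = "B*07:02", ref_seq = "GSHSMRYFYT",
    variants = list(
      "B*15:01" = list(v(5, "T")),
      "B*39:01" = list(v(5, "T")),
      "B*52:01" = list(v(8, "S")),
      "B*90:01" = list(v(10, "A"))))
  list(DQB1 = dqb1, DRB1 = drb1, B = b)
}

#' Study-scale synthetic MS cohort configuration
#'
#' 45 cases vs 429 controls over the 16 sequenced HLA genes. Control
#' allele frequencies follow the reference tables where available (filler
#' `GENE*90:01` alleles absorb the remaining mass; unlisted genes get
#' generic distributions). Planted log-odds effects sit on DRB1*15:01,
#' DRB1*04:05, B*39:01, and B*15:01 at the log of their reported marginal
#' odds ratios, and DRB1*15:01 is coupled to DQB1*06:02 on a haplotype
#' block targeting r-squared 0.94.
#'
#' @param seed master seed.
#' @param n_case,n_control group sizes (defaults 45 / 429).
#' @return a `synthetic_config`.
#' @export
ms_like_config <- function(seed = 1L, n_case = 45L, n_control = 429L) {
  pad <- function(x, filler) c(x, stats::setNames(1 - sum(x), filler))
  genes <- list(
    A = c("A*24:02" = 0.36, "A*02:01" = 0.20, "A*26:03" = 0.02,
          "A*90:01" = 0.42),
    B = pad(c("B*15:01" = 0.078, "B*39:01" = 0.043, "B*52:01" = 0.127,
              "B*07:02" = 0.059), "B*90:01"),
    C = pad(c("C*07:02" = 0.145, "C*12:02" = 0.127), "C*90:01"),
    E = c("E*01:01" = 0.60, "E*01:03" = 0.40),
    F = c("F*01:01" = 0.95, "F*01:03" = 0.05),
    G = c("G*01:01" = 0.70, "G*01:04" = 0.30),
    DMA = c("DMA*01:01" = 0.80, "DMA*01:02" = 0.20),
    DMB = pad(c("DMB*01:07" = 0.008, "DMB*01:01" = 0.70), "DMB*90:01"),
    DOA = c("DOA*01:01" = 0.997, "DOA*90:01" = 0.003),
    DOB = c("DOB*01:01" = 0.75, "DOB*01:02" = 0.25),
    DPA1 = c("DPA1*01:03" = 0.45, "DPA1*02:02" = 0.40, "DPA1*90:01" = 0.15),
    DPB1 = pad(c("DPB1*05:01" = 0.356), "DPB1*90:01"),
    DQA1 = pad(c("DQA1*01:02" = 0.156, "DQA1*03:03" = 0.141,
                 "DQA1*01:01" = 0.058, "DQA1*03:02" = 0.147,
                 "DQA1*05:03" = 0.015), "DQA1*90:01"),
    DQB1 = pad(c("DQB1*03:01" = 0.104, "DQB1*04:01" = 0.100,
                 "DQB1*06:02" = 0.068, "DQB1*03:03" = 0.149),
               "DQB1*90:01"),
    DRA = c("DRA*01:01" = 0.579, "DRA*01:02" = 0.421),
    DRB1 = pad(c("DRB1*04:05" = 0.120, "DRB1*15:01" = 0.072,
                 "DRB1*15:02" = 0.120, "DRB1*01:01" = 0.058,
                 "DRB1*09:01" = 0.135, "DRB1*14:06" = 0.012),
               "DRB1*90:01"))
  block <- couple_haplotypes(genes$DRB1, genes$DQB1,
                             "DRB1*15:01", "DQB1*06:02", r2 = 0.94)
  synthetic_config(
    genes, n_case = n_case, n_control = n_control,
    effects = c("DRB1*15:01" = log(3.44), "DRB1*04:05" = log(2.23),
                "B*39:01" = log(3.09), "B*15:01" = log(2.95)),
    hap_blocks = list(block), cohort_label = "MS", seed = seed)
}

#' Write the seed-numbered fixture files
#'
#' Simulates the study-scale MS cohort and writes `genotypes.tsv`,
#' `phenotypes.tsv`, and `alignment.txt` (the miniature catalog) into
#' `outdir`. Rerunning with the same seed reproduces the files byte for
#' byte.
#'
#' @param outdir writable output directory (created if absent).
#' @param seed master seed for the cohort.
#' @return named character vector of the written paths, invisibly.
#' @export
make_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(ms_like_config(seed = seed))
  paths <- c(genotypes = file.path(outdir, "genotypes.tsv"),
             phenotypes = file.path(outdir, "phenotypes.tsv"),
             alignment = file.path(outdir, "alignment.txt"))
  write_genotypes(sim$genotypes, paths[["genotypes"]])
  write_cohort(sim$cohort, paths[["phenotypes"]])
  write_protein_alignment(demo_alignment_catalog(), paths[["alignment"]])
  invisible(paths)
}
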