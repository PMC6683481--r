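#!/usr/bin/env Rscript
# Amino-acid level analysis of the synthetic MS cohort: translate alleles
# to residue markers through the bundled alignment catalog, scan residues,
# run the per-position omnibus likelihood-ratio tests, and probe whether
# the Phe-like residue at DQB1 position 9 carries signal beyond the
# DRB1*15:01 allele (reciprocal conditioning). Run 02_simulate_cohort.R
# first.

library(hlafinemap)

g <- read_genotypes("results/synthetic_cohort/genotypes.tsv")
ph <- read_cohort("results/synthetic_cohort/phenotypes.tsv")
al <- read_protein_alignment("results/synthetic_cohort/alignment.txt")

res <- suppressMessages(run_pipeline(
  g, ph, alignment = al, out_dir = "results/residue_scan",
  marker_class = "residue"))
cat(sprintf("residue markers assessed: %d across %d positions\n",
            length(res$kept_markers), nrow(res$omnibus)))
cat("omnibus per-position tests (sorted by p):\n")
print(head(res$omnibus, 6), digits = 3)

# reciprocal conditioning between the tagging residue and the allele
da <- build_allele_dosage(g, ph)
dr <- suppressMessages(build_residue_markers(al, g, ph))$dosage
d <- bind_dosage(da, dr)
p1 <- conditional_scan(d, ph, "DQB1_9_F", conditioned = "DRB1*15:01")
p2 <- conditional_scan(d, ph, "DRB1*15:01", conditioned = "DQB1_9_F")
cat(sprintf("p(DQB1 Phe9 | DRB1*15:01) = %s; p(DRB1*15:01 | DQB1 Phe9) = %s\n",
            format(p1$p, digits = 3), format(p2$p, digits = 3)))
if (p1$not_testable || p2$not_testable) {
  cat("note: in this replicate the residue and allele are collinear",
      "(r2 > 0.99), so the conditional fits are flagged not-testable\n")
}
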