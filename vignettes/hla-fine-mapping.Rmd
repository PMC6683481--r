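---
title: "Fine-mapping HLA risk at allele and amino-acid resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping HLA risk at allele and amino-acid resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafinemap)
```

## The problem

The MHC region carries the strongest common-variant risk for most
autoimmune diseases, but its dense linkage disequilibrium (LD) makes it
hard to say *which* HLA allele — or which amino-acid residue of which HLA
protein — drives a signal. Fine-mapping therefore proceeds in layers:
test every four-digit allele, translate alleles into per-position residue
markers and test those, and then use conditional models to ask which
signals survive adjustment for the others. This package implements that
workflow for small case-control cohorts genotyped at four-digit
resolution across classical and non-classical HLA genes, with a synthetic
cohort generator standing in for subject-level data that cannot be
shared.

## Model and procedure

Every marker is scored as an additive dosage $g \in \{0,1,2\}$: for an
allele, the number of copies carried; for a residue, the number of the
sample's alleles carrying that residue at the position. The primary test
is the logistic dosage model

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta g
  \;(+\,\gamma^\top z \text{ for conditioning covariates } z),$$

reported as OR $= e^\beta$ with Wald standard error, two-sided Wald $p$
(a likelihood-ratio $p$ is available via `p_method = "lrt"`; the
reference analyses do not say which was used, and at these counts the two
agree closely), and Wald 95% CI. When the marker's 2×2 allele-count table
has any cell $\le 5$, the scan falls back to Fisher's exact test:
two-sided $p$ by hypergeometric summation, conditional-MLE OR and exact
CI. The minimum-cell rule is a design decision: the reference study's
stated rule ("more than five cases") does not reproduce its own
sparse-row flags (one flagged row has 88 case copies but a cell of 2),
while the minimum-cell rule reproduces the Fisher/logistic assignment of
all 29 published rows, so it is adopted.

Markers enter a scan only if their frequency exceeds 0.1% in both cases
and controls; residue markers are additionally dropped when their
position carries a single residue within either group (monomorphic).
Significance is Bonferroni-corrected at $0.05/m$ over the $m$ markers
assessed in the scan, with alleles and residues corrected separately
because they are scanned separately.

**Stepwise conditional analysis** starts from the unconditional scan,
selects the minimum-$p$ marker while $p < 0.05/m$ (with $m$ fixed at the
initial marker count — the reference study's quoted conditional bound
$8.3\times10^{-4}$ equals $0.05/60$, suggesting a fixed denominator), and
repeats with all selected markers as covariates. Sparse markers are still
fit by covariate-adjusted logistic regression inside conditional rounds —
Fisher's test admits no covariates — and carry a reliability flag. A
tested marker whose dosage lies in the span of the conditioned dosages
($R^2 > 0.99$ against the fitted projection) is flagged not-testable
rather than refit; ties in selection break by smallest $p$, then largest
$|\beta|$, then marker id.

**Omnibus position tests.** For a position with $n$ observed residues the
full model adds $n-1$ residue dosage terms (the reference residue — most
frequent in controls, ties alphabetical — is dropped; the choice does not
affect the deviance, which the tests verify to $10^{-9}$). Twice the
log-likelihood difference against the covariates-only null is referred to
$\chi^2_{n-1}$. For biallelic positions this reduces exactly to the
single residue marker's likelihood-ratio test.

**LD** is reported as the squared Pearson correlation of dosages over
complete cases of a stated group (controls, by convention).

**Clinical tests** compare carriers (dosage $\ge 1$) with non-carriers
among cases on EDSS and age at onset using the classical pooled-variance
Student's t ($df = n_1+n_2-2$); "Student's t" is read as the
equal-variance test per the classical name, with Welch behind a flag.
Controls carry no clinical measures and never enter.

## Residue translation

Four-digit alleles map to residues through a per-gene protein alignment
catalog in a small explicit dialect (header
`#gene=... start=... ref=...`, then one aligned string per allele; `-`
means identical-to-reference, `*` unknown, `.` gap). Positions use
mature-protein numbering: leader-peptide residues are negative and no
position 0 exists, so a span starting at −18 runs −18…−1, 1, 2, ….
Indel columns are excluded from the marker space (substitutions only),
and an unknown residue makes the dosage missing — not zero — so unknowns
cannot deflate carrier counts. The bundled catalog
(`demo_alignment_catalog()`) is synthetic: spans, residues and variant
placements are invented for testing and do not reproduce any database
release.

## Reconstructing the published tables

The reported cohort statistics are reproduced from the printed
three-decimal frequencies: with $n$ diploid subjects, the denominator is
$2n$ chromosomes and the count is the frequency times the denominator
rounded to the nearest integer, ties half-up. Re-rounding the
reconstructed count must give back the printed frequency; this
round-trip closes for 57 of the 58 printed frequencies, the exception
being one control frequency (DPB1\*05:01, 0.356) that no integer count
over 858 chromosomes yields — most plausibly a smaller typed denominator
in the source — and the reconstruction flags it rather than guessing.
Reproduction of the printed ORs uses the allele-count cross-product
$(ad)/(bc)$, since genotype-level homozygote/heterozygote splits are not
published; on chromosome-expanded data the logistic MLE equals this
cross-product exactly, which the tests assert to $10^{-6}$.

## The synthetic cohort generator

`simulate_cohort()` draws two haplotypes per individual (random mating /
Hardy–Weinberg pairing; the reference study gives no population-structure
information), genes independent within a haplotype unless covered by an
explicit two-gene haplotype table (`couple_haplotypes()` builds one that
induces a target dosage $r^2$), assigns case status from
$\operatorname{logit} P = \beta_0 + \sum_a \beta_a g_a$, and
rejection-samples until the configured group sizes are filled — the
case-control ascertainment under which the dosage OR remains consistent.
By default $\beta_0$ is calibrated for a ${\sim}10\%$ marginal case rate.
One master seed drives everything; per-(gene, batch) substreams mean
adding a gene does not perturb other genes' draws, and identical seeds
give byte-identical output files.

The study-scale configuration (`ms_like_config()`) is fixed once: 45
cases vs 429 controls over 16 genes; control allele frequencies follow
the published control columns where available, with filler `*90:01`
alleles absorbing the remaining per-gene mass and generic two/three-allele
distributions for unlisted genes; planted effects sit on DRB1\*15:01,
DRB1\*04:05, B\*39:01 and B\*15:01 at the log of their reported marginal
ORs; and DRB1\*15:01 is coupled to DQB1\*06:02 at target $r^2 = 0.94$.
At these focal frequencies (0.072/0.068) the coupling sits essentially at
the attainable boundary, so small control samples often realize
$r^2 \approx 1$; the acceptance checks therefore assert strong LD rather
than a two-decimal match. What the generator does **not** emulate:
genome-wide LD beyond one coupled pair, population structure,
genotyping error, and typing dropout — so passing tests validate the
statistical machinery, not robustness to those real-data features.

## Numerical choices and degenerate inputs

- Exact p-values sum hypergeometric probabilities $\le$ the observed
  table's with the conventional $10^{-7}$ relative tie tolerance; this is
  validated against brute-force enumeration over all tables with margins
  $\le 50$ (1.76 million tables).
- A 2×2 with a zero cell: the cross-product OR returns signed
  zero/infinity, the Wald CI refuses and points to the exact CI.
- Complete separation or non-convergence in a logistic fit flags the
  result and withholds $p$/CI instead of reporting a wild estimate.
- Conditioning on a constant (e.g. all-zero) dosage is a no-op: such
  covariates are dropped as uninformative rather than crashing the fit
  as rank-deficient.
- Identical constant groups in the t-test give $t = 0, p = 1$.
- Missingness is per (sample, gene): any unobserved allele at a gene
  makes the sample missing for all that gene's markers, and analyses are
  complete-case per marker; denominators count observed chromosomes so
  typing failures do not deflate frequencies. The source analyses do not
  state a missingness rule; this is the minimal well-defined one.

## Problem sizes used in validation

The simulation-based checks use sizes chosen to make their operating
characteristics sharp but cheap: type-I error over 300 null markers at
250/250; CI coverage of a planted $\log(3.44)$ effect over 300
replicates at the case-control ratio 450/4290 (tenfold the study scale,
where coverage lands at ~94–95%); stepwise recovery of two independent
$\log 3$ effects at 150/600; and 200 null replicates for the
empty-selection rate. The fixture cohort itself stays at the study's own
45/429.

## Known limitations

- Fisher-row ORs: published sparse rows appear to mix conventions (one
  row matches the cross-product OR, another the conditional MLE), so both
  are always reported and neither is asserted as "the" published value.
- Individual-level quantities of the reference study (conditional ORs,
  the amino-acid scan p-values, $r^2 = 0.94$, clinical p-values) cannot
  be recomputed without the unavailable genotypes; they are covered by
  property-based checks on synthetic cohorts with the matching structure.
- No covariate adjustment for sex or age, no HWE testing, no phasing or
  imputation — none were used in the reference analyses.
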