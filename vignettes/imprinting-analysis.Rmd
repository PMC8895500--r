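---
title: "Quantifying genomic imprinting: P-scores, ICR methylation and colony bisulfite analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic imprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
library(dplyr)
```

## The biological setting

Imprinted genes are expressed from only one parental allele, under the
control of imprinting control regions (ICRs) that carry germline-derived,
parent-of-origin DNA methylation. The KRAB zinc-finger protein ZFP57
maintains this methylation after fertilisation; it acts both through
protein deposited in the oocyte (the *maternal* contribution, M) and
through the embryo's own gene copy (the *zygotic* contribution, Z). A
cross of homozygous-mutant 129 females to heterozygous DBA males yields
three informative embryo genotypes — M⁺Z⁺ (maternal protein present),
M⁻Z⁺ (maternal protein absent, zygotic gene intact) and M⁻Z⁻ (both
absent) — in both sexes, and the hybrid 129×DBA background provides the
exonic SNPs needed to assign sequencing reads to a parental allele. The
M⁺Z⁻ genotype cannot arise from this cross, and the package's genotype
enumeration deliberately excludes it.

`imprintr` implements the quantitative machinery such a study runs on top
of aligned, allele-split sequencing data: allelic-expression statistics,
expression-level comparison, ICR methylation quantification from
read-level bisulfite calls, and clone analysis of bacterial-colony
bisulfite sequencing — plus a seeded generator that simulates all of
these data types with known truth, so that every stage is testable
without any sequencing run.

## The P-score and switch selection

For a gene with `M` maternal-allele and `P` paternal-allele reads, the
P-score is the centred paternal fraction

$$\mathrm{Pscore} = \frac{P}{M+P} - 0.5,$$

so 0.5 means exclusively paternal expression, −0.5 exclusively maternal,
and 0 balanced biallelic expression. Genes enter the analysis only when
their pooled allelic count across the analysis set exceeds 10 reads
(strict inequality, all-or-none per gene). An *allelic expression switch*
— a monoallelic gene becoming (partially) biallelic when imprinting
maintenance fails — is detected per sex by

1. an omnibus Kruskal–Wallis rank test of per-sample P-scores across the
   three genotypes (mid-ranks, tie-corrected; an all-constant input is
   defined as H = 0), and
2. the absolute difference of group-mean P-scores, ΔP, for a named
   genotype pair;

a gene is *selected* when ΔP ≥ 0.1 and the omnibus p < 0.05. Group means
(not medians) define ΔP: the selection rule compares one summary P-score
per group, and the mean is the simplest summary consistent with the
per-sample heatmaps. An exact two-sided binomial test of `P` against a
null proportion of 0.5 is provided as the single-sample analogue. No
multiple-testing correction is applied by default (a Benjamini–Hochberg
option exists); the selection rule is already a conjunction of an effect
size and a significance gate.

Group-mean P-scores are classified into the verbal vocabulary
(biallelic, slightly/preferential/fully maternal or paternal) by
symmetric cutoffs at 0.1, 0.25 and 0.4. These cutoffs are a package
convention — the vocabulary has no published numeric boundaries — and are
arguments that are echoed into every report.

```{r pscore-demo}
counts <- tibble::tibble(
  gene = "Snrpn", sample = c("F1", "F2"),
  maternal_count = c(0, 3), paternal_count = c(120, 97)
)
compute_pscore(counts)
```

## Expression levels in TPM

Expression comparison uses transcripts per million,
$\mathrm{TPM}_g = 10^6 \,(c_g/\ell_g) / \sum_h (c_h/\ell_h)$, computed per
sample from raw counts $c$ and transcript-union lengths $\ell$; TPM sums
to $10^6$ per sample whenever any count is non-zero. Genes are
quantifiable when pooled counts exceed 10 and TPM exceeds 1.0 in at least
one embryo (both strict). The fold change between two groups is
`log2(mean TPM ratio)` with no pseudocount (the ratio is taken on raw
TPM); the significance test is a Welch t-test on `log2(TPM + 1)`. A gene
is called differential when |log2FC| strictly exceeds the gate (0.5 for
genotype contrasts; 0.3 for the female-versus-male control contrast) and
p < 0.05. The shortlisting test is deliberately a plain two-group test on
transformed TPM rather than a negative-binomial count model: the
package's validation is parameter recovery on synthetic data with known
effects, and the simple test keeps the criterion transparent. Group
comparison across the three genotypes uses one-way ANOVA with Fisher's
LSD — all pairwise t-statistics on the pooled error mean square with
N − k degrees of freedom, flagged as unprotected when the omnibus F-test
is not itself significant — and female-versus-male comparisons within a
genotype use the two-tailed pooled-variance Student t-test.

## ICR methylation from read-level calls

Each bisulfite call records one read's methylation state at one CpG
(forward-strand C coordinate, 0-based). The quantification rules are:

* duplicate reads collapse on the key (sample, alignment start, end,
  strand) — the standard bisulfite convention; a read-id-only key is
  available;
* a CpG site qualifies for total methylation when covered by **at least
  3 unique reads**; its level is methylated calls / total calls.
  Sub-threshold sites are *excluded*, which is distinct from a level of
  zero, and are reported as excluded;
* the ICR percentage is the **unweighted** mean of qualifying site levels
  × 100 (sites are not weighted by coverage); an ICR with no qualifying
  site yields an explicit no-data value, never a silent 0;
* allele-split quantification keeps only reads tagged maternal or
  paternal and relaxes the site rule to ≥ 1 read, reflecting the sparsity
  of SNP-informative bisulfite reads.

Read-to-allele assignment is bisulfite-aware: an observed T is compatible
with a reference C (conversion), and an observed A with a reference G
(the reverse-strand image), so such observations are uninformative when
they are compatible with both alleles; a read is assigned only when all
its informative SNP observations agree, and conflicting mixtures are
flagged rather than guessed. Per-site levels export as 4-column bedGraph
on a 0–1 scale for genome-browser display.

```{r wgbs-demo}
preset <- scenario_preset("rasgrf1_sex_dimorphic")
samples <- simulate_cross(preset$design)
calls <- simulate_wgbs_calls(preset$icrs[[1]], samples, seed = 1)
sites <- site_methylation(calls, min_reads = 3)
icr_methylation(sites, preset$icrs[[1]]$icr) |>
  inner_join(samples, by = "sample") |>
  group_by(genotype, sex) |>
  summarise(mean_pct = mean(pct), .groups = "drop")
```

## Colony bisulfite sequencing

Bacterial-colony sequencing of a bisulfite PCR product yields one read
per clone. Against the amplicon reference, a retained C at a CpG is read
as methylated and a T as unmethylated; retained **non-CpG** cytosines —
conversion failures — form a clone's fingerprint. Clones are *unique*
only if they differ in CpG pattern **or** fingerprint; indistinguishable
clones collapse into one unique clone with a multiplicity count, so PCR
and cloning duplicates are not double-counted. The clone-set percentage
is methylated CpG states over all CpG states of the **unique** clones,
unweighted by multiplicity (a weighted variant is available but off by
default). Clone QC follows common practice for this assay: non-CpG
conversion rate ≥ 0.95 and ≥ 90% identity outside cytosine positions,
both configurable; failing clones are kept as flagged records. Alignment
is positional at amplicon scale (equal length with mismatch tolerance),
which is adequate for clone reads of a fixed PCR product;
reverse-orientation clones are out of scope because the bisulfite PCR
primers fix the strand. Genotype comparisons of per-embryo percentages
use the two-tailed pooled t-test with 0.05/0.01/0.001 significance
stars.

## What the generator emulates — and what it does not

The synthetic module is first-class, tested code. Its models:

* **Allelic counts.** Totals are negative-binomial (mean, overdispersion;
  0 gives the Poisson limit); a binomial thinning models the fraction of
  reads overlapping an informative exonic SNP; the per-sample paternal
  fraction θ\* is Beta(θc, (1−θ)c) around the group truth θ — the
  standard overdispersed model for allele-specific counts — and assigned
  reads split Binomial(θ\*). θ maps onto the P-score as θ − 0.5, so
  simulated truths translate directly into expected ΔP.
* **Bisulfite calls.** Per sample and CpG, Poisson-many molecules; each
  derives from one parental allele (50:50), shows its allele tag with the
  SNP-informative probability, and is methylated with the allele's true
  per-molecule probability. An unmethylated molecule still reads
  methylated at the conversion-failure rate (default 0.005, a config
  knob). Each simulated molecule observes a single CpG; real reads span
  several CpGs and correlate neighbouring sites, which the generator does
  not reproduce.
* **Colony reads.** Molecules methylate CpGs independently at the true
  level; conversion rewrites unconverted-due cytosines to T and fails at
  the same rate everywhere; after the first read, each output read is an
  exact PCR copy of a random earlier read with the duplication
  probability.

All randomness flows from one master seed through deterministic
per-stage child seeds, so identical configurations are byte-identical.
Not emulated: read sequences and alignment artifacts, mapping bias,
chromosome-scale genomes, strand chemistry beyond the C/T rewrite, or
correlated methylation along a molecule. Passing recovery tests
therefore demonstrates that the statistics recover truth *under these
models*, not that the models capture every property of real embryo data.

## Preset study conditions

Two presets encode the qualitative patterns the pipeline is designed to
detect, at desk-scale sizes chosen once as realistic conditions:

* `snrpn_partial_MZ` — 20 paternally expressed genes whose θ falls
  0.98 → 0.75 → 0.50 across M⁺Z⁺ → M⁻Z⁺ → M⁻Z⁻ (partial switch without
  maternal protein, full biallelic switch in the double mutant), plus 180
  null biallelic genes; 6/3/4 female embryos per genotype; mean
  expression 300 reads, dispersion 0.1, SNP-informative fraction 0.7,
  beta-binomial concentration 50.
* `rasgrf1_sex_dimorphic` — a paternally methylated ICR whose
  methylated-allele level stays 0.90 in control genotypes but falls to
  0.50 in female and 0.10 in male M⁻Z⁻ embryos; 3 embryos per
  genotype×sex, 20 CpGs, depth 40, SNP-informative fraction 0.6,
  background level 0.03 on the unmethylated allele.
* `rasgrf1_colony` — a 256-bp synthetic amplicon (16 CpGs, 32 non-CpG
  cytosines, the CpG density of a typical ICR bisulfite product) at
  per-group true methylation 0.9/0.5/0.1, 30 colonies per embryo, 10%
  PCR duplication.

Preset numbers are illustrative study conditions, not measured
quantities. Under them, the test suite verifies: switch selection at
ΔP ≥ 0.1, p < 0.05 recovers ≥ 90% of true switches with ≤ 5% false
selection over 200 replicates; allelic ICR estimates land within ±5
percentage points of truth with the male-versus-female M⁻Z⁻ t-test
significant in ≥ 95% of 100 seeds; and the colony pipeline estimates
within ±7 points of the simulated level.

## Numerical conventions and degenerate inputs

* All thresholds are strict inequalities (`> 10` reads, `> 1.0` TPM,
  `|log2FC| > gate`), matching their "more than" definitions; the ΔP and
  p gates are `≥ 0.1` and `< 0.05`.
* Kruskal–Wallis on an all-constant vector returns H = 0, p = 1 (the tie
  correction would otherwise be 0/0).
* A pooled t-test with zero pooled variance returns p = 1 for equal
  means and p = 0 (flagged "degenerate") otherwise; the all-constant
  ANOVA returns F = 0, p = 1.
* A sample with no counts gets TPM 0 with a warning; a zero-denominator
  fold change is an error, not an Inf silently propagated.
* Intervals are 0-based half-open throughout (BED/bedGraph compatible);
  1-based inclusive ICR spans are converted on read. Amplicon and clone
  indices are reported 1-based, following R conventions.
* Genes missing a genotype group, alleles with no tagged reads, and
  undersized comparison groups raise named errors instead of returning
  partial numbers.

## Known limitations

The differential-expression test is a two-group test on transformed TPM,
not a count-model fit; with very few replicates it is conservative. The
unique-clone methylation estimator deliberately discards multiplicity
and therefore under-weights common patterns when distinct molecules
coincide — a property of the assay's own formula, visible in the
simulator at extreme methylation levels with short amplicons. Allelic
methylation requires SNP-informative reads and inherits their sparsity;
ICRs without SNPs have no allelic estimate, only a total one.
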