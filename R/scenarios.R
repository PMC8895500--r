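# Scenario constructors: declarative descriptions of what the simulator emulates.

#' Define the embryo cohort of a maternal-zygotic cross
#'
#' Describes how many embryos of each genotype and sex enter a simulated study,
#' mirroring a timed mating between homozygous mutant 129 females and
#' heterozygous DBA males. Only `M+Z+`, `M-Z+` and `M-Z-` genotypes can arise.
#'
#' @param n_embryos Data frame with columns `genotype`, `sex`, `n` giving the
#'   number of embryos per group (groups with `n = 0` may be omitted).
#' @param maternal_strain,paternal_strain Strain labels for the two alleles.
#' @return An object of class `cross_design`.
#' @export
#' @examples
#' cross_design(data.frame(
#'   genotype = c("M+Z+", "M-Z-"), sex = c("F", "M"), n = c(2, 3)
#' ))
cross_design <- function(n_embryos, maternal_strain = "129",
                         paternal_strain = "DBA") {
  check_columns(n_embryos, c("genotype", "sex", "n"), "n_embryos")
  check_genotype(n_embryos$genotype)
  check_sex(n_embryos$sex)
  if (any(n_embryos$n < 0) || any(n_embryos$n != round(n_embryos$n))) {
    abort("embryo counts must be non-negative integers")
  }
  if (sum(n_embryos$n) < 1) abort("a cross design needs at least one embryo")
  structure(
    list(
      n_embryos = as_tibble(n_embryos[, c("genotype", "sex", "n")]),
      maternal_strain = maternal_strain,
      paternal_strain = paternal_strain
    ),
    class = "cross_design"
  )
}

#' Define the allelic-count generative model for one gene
#'
#' Total counts per sample are negative-binomial (`mean_expression`,
#' overdispersion `dispersion`; 0 gives the Poisson limit). A binomial thinning
#' with `snp_informative_fraction` models reads that overlap an exonic SNP and
#' can be assigned to an allele. The per-sample paternal fraction is
#' beta-distributed around the group truth `theta` with concentration
#' `allelic_concentration` (infinite concentration = no biological scatter),
#' and assigned reads split binomially. `theta` maps onto the P-score as
#' `theta = pscore + 0.5`: 1 is paternal-only, 0.5 biallelic, 0 maternal-only.
#'
#' @param gene_id Gene identifier.
#' @param gene_length Transcript-union length in bases (used for TPM).
#' @param mean_expression Expected total read count per sample.
#' @param dispersion Negative-binomial overdispersion (>= 0).
#' @param snp_informative_fraction Fraction of reads assignable to an allele.
#' @param paternal_fraction Either a single `theta` in `[0, 1]` for all groups
#'   or a data frame `(genotype, sex, theta)`.
#' @param allelic_concentration Beta concentration for per-sample `theta`
#'   scatter (`Inf` for none).
#' @return An object of class `gene_scenario`.
#' @export
gene_scenario <- function(gene_id, gene_length, mean_expression,
                          dispersion = 0.1, snp_informative_fraction = 0.7,
                          paternal_fraction = 0.5,
                          allelic_concentration = 50) {
  stopifnot(gene_length > 0, mean_expression > 0, dispersion >= 0,
            allelic_concentration > 0)
  check_fraction(snp_informative_fraction, "snp_informative_fraction")
  theta <- normalise_group_param(paternal_fraction, "theta", "paternal_fraction")
  check_fraction(theta$theta, "paternal_fraction")
  structure(
    list(gene_id = gene_id, gene_length = gene_length,
         mean_expression = mean_expression, dispersion = dispersion,
         snp_informative_fraction = snp_informative_fraction,
         paternal_fraction = theta,
         allelic_concentration = allelic_concentration),
    class = "gene_scenario"
  )
}

#' Define an imprinting control region
#'
#' @param name ICR name (e.g. `"Snrpn"`).
#' @param chrom Chromosome.
#' @param start,end 0-based half-open interval.
#' @param germline_origin `"maternal"` or `"paternal"`: the parental allele
#'   carrying the germline methylation imprint.
#' @return One-row tibble of class `icr_region`.
#' @export
icr_region <- function(name, chrom, start, end,
                       germline_origin = c("maternal", "paternal")) {
  germline_origin <- match.arg(germline_origin)
  if (start >= end) abort("ICR interval must satisfy start < end")
  structure(
    tibble(name = name, chrom = chrom, start = as.integer(start),
           end = as.integer(end), germline_origin = germline_origin),
    class = c("icr_region", "tbl_df", "tbl", "data.frame")
  )
}

#' Define the bisulfite-call generative model for one ICR
#'
#' Each simulated molecule observes one CpG: its underlying parental allele is
#' drawn 50:50, its allele tag is revealed with probability
#' `snp_informative_fraction` (otherwise `unassigned`), and its methylation
#' state is Bernoulli at the allele's true level. The germline-methylated
#' allele (per `icr$germline_origin`) carries `methylated_allele_level`; the
#' other allele the background `unmethylated_allele_level`. An unmethylated
#' molecule still reads methylated with probability `conversion_failure_rate`.
#'
#' @param icr An [icr_region()].
#' @param cpg_positions Strictly increasing 0-based CpG coordinates inside the
#'   ICR interval.
#' @param methylated_allele_level,unmethylated_allele_level Per-molecule
#'   methylation probability on each allele: a single number or a data frame
#'   `(genotype, sex, level)`.
#' @param read_depth Mean reads per CpG (Poisson).
#' @param conversion_failure_rate Probability an unmethylated C escapes
#'   conversion and reads as methylated.
#' @param snp_informative_fraction Fraction of reads carrying an allele tag.
#' @return An object of class `icr_scenario`.
#' @export
icr_scenario <- function(icr, cpg_positions, methylated_allele_level,
                         unmethylated_allele_level = 0.03, read_depth = 30,
                         conversion_failure_rate = 0.005,
                         snp_informative_fraction = 0.6) {
  stopifnot(inherits(icr, "icr_region"), read_depth > 0)
  if (length(cpg_positions) == 0) abort("cpg_positions must be non-empty")
  if (any(diff(cpg_positions) <= 0)) {
    abort("cpg_positions must be strictly increasing")
  }
  if (any(cpg_positions < icr$start) || any(cpg_positions >= icr$end)) {
    abort("cpg_positions must lie inside the ICR interval")
  }
  check_fraction(conversion_failure_rate, "conversion_failure_rate")
  check_fraction(snp_informative_fraction, "snp_informative_fraction")
  meth <- normalise_group_param(methylated_allele_level, "level",
                                "methylated_allele_level")
  unmeth <- normalise_group_param(unmethylated_allele_level, "level",
                                  "unmethylated_allele_level")
  check_fraction(meth$level, "methylated_allele_level")
  check_fraction(unmeth$level, "unmethylated_allele_level")
  structure(
    list(icr = icr, cpg_positions = as.integer(cpg_positions),
         methylated_allele_level = meth, unmethylated_allele_level = unmeth,
         read_depth = read_depth,
         conversion_failure_rate = conversion_failure_rate,
         snp_informative_fraction = snp_informative_fraction),
    class = "icr_scenario"
  )
}

#' Define the colony bisulfite-sequencing generative model for one amplicon
#'
#' Each molecule methylates every CpG independently with probability
#' `true_methylation`; bisulfite conversion rewrites unmethylated C to T,
#' retains methylated C, and fails (retains C) with probability
#' `conversion_failure_rate` at any cytosine due for conversion. A fraction
#' `pcr_duplication_rate` of output reads are exact copies of earlier
#' molecules, for the deduplication stage to collapse.
#'
#' @param name Amplicon name.
#' @param sequence Reference (unconverted) amplicon DNA sequence.
#' @param true_methylation Per-molecule CpG methylation probability.
#' @param conversion_failure_rate Probability a convertible C is retained.
#' @param n_colonies Number of sequenced colonies (output reads).
#' @param pcr_duplication_rate Fraction of reads that are PCR copies.
#' @return An object of class `amplicon_scenario`; CpG and non-CpG cytosine
#'   positions (1-based) are derived from the sequence.
#' @export
amplicon_scenario <- function(name, sequence, true_methylation,
                              conversion_failure_rate = 0.005,
                              n_colonies = 30, pcr_duplication_rate = 0.1) {
  if (n_colonies < 1) abort("n_colonies must be at least 1")
  check_fraction(true_methylation, "true_methylation")
  check_fraction(conversion_failure_rate, "conversion_failure_rate")
  check_fraction(pcr_duplication_rate, "pcr_duplication_rate",
                 allow_one = FALSE)
  ref <- amplicon_reference(name, sequence)
  structure(
    list(reference = ref, true_methylation = true_methylation,
         conversion_failure_rate = conversion_failure_rate,
         n_colonies = as.integer(n_colonies),
         pcr_duplication_rate = pcr_duplication_rate),
    class = "amplicon_scenario"
  )
}

#' Bundled scenario presets
#'
#' Ready-made scenarios named after the qualitative patterns they emulate.
#' Preset parameter values are illustrative study conditions, not measured
#' quantities:
#' \describe{
#'   \item{`"snrpn_partial_MZ"`}{Allelic switch scan: 20 paternally expressed
#'     genes whose paternal fraction falls 0.98 (M+Z+) to 0.75 (M-Z+, partial
#'     switch) to 0.50 (M-Z-, full biallelic switch), plus 180 null biallelic
#'     genes; cohort of 6/3/4 female embryos per genotype.}
#'   \item{`"rasgrf1_sex_dimorphic"`}{A paternally methylated ICR whose
#'     methylated-allele level stays 0.90 in controls but drops to 0.50 in
#'     female M-Z- and 0.10 in male M-Z- embryos; 3 embryos per genotype and
#'     sex.}
#'   \item{`"rasgrf1_colony"`}{A 120-bp synthetic amplicon in the same
#'     sex-dimorphic pattern for the colony pipeline (per-group
#'     `true_methylation` 0.9 / 0.5 / 0.1).}
#' }
#'
#' @param name Preset name.
#' @return A list with elements among `design`, `genes`, `icrs`, `amplicons`.
#' @export
#' @examples
#' preset <- scenario_preset("rasgrf1_sex_dimorphic")
#' names(preset)
scenario_preset <- function(name = c("snrpn_partial_MZ",
                                     "rasgrf1_sex_dimorphic",
                                     "rasgrf1_colony")) {
  name <- match.arg(name)
  switch(name,
    snrpn_partial_MZ = {
      design <- cross_design(tidyr::expand_grid(
        genotype = GENOTYPES, sex = "F"
      ) |> mutate(n = c(6L, 3L, 4L)))
      switch_theta <- tibble(
        genotype = rep(GENOTYPES, each = 2), sex = rep(SEXES, 3),
        theta = rep(c(0.98, 0.75, 0.50), each = 2)
      )
      switch_genes <- lapply(sprintf("switch%02d", 1:20), function(g) {
        gene_scenario(g, gene_length = 2000, mean_expression = 300,
                      dispersion = 0.1, snp_informative_fraction = 0.7,
                      paternal_fraction = switch_theta,
                      allelic_concentration = 50)
      })
      null_genes <- lapply(sprintf("null%03d", 1:180), function(g) {
        gene_scenario(g, gene_length = 2000, mean_expression = 300,
                      dispersion = 0.1, snp_informative_fraction = 0.7,
                      paternal_fraction = 0.5, allelic_concentration = 50)
      })
      list(design = design, genes = c(switch_genes, null_genes))
    },
    rasgrf1_sex_dimorphic = {
      design <- cross_design(tidyr::expand_grid(
        genotype = GENOTYPES, sex = SEXES
      ) |> mutate(n = 3L))
      icr <- icr_region("Rasgrf1", "chr9", 89774439L, 89774883L,
                        germline_origin = "paternal")
      levels <- tibble(
        genotype = rep(GENOTYPES, each = 2), sex = rep(SEXES, 3),
        level = c(0.90, 0.90, 0.90, 0.90, 0.50, 0.10)
      )
      scen <- icr_scenario(
        icr, cpg_positions = seq(89774450L, by = 22L, length.out = 20),
        methylated_allele_level = levels, unmethylated_allele_level = 0.03,
        read_depth = 40, conversion_failure_rate = 0.005,
        snp_informative_fraction = 0.6
      )
      list(design = design, icrs = list(scen))
    },
    rasgrf1_colony = {
      # 256-bp synthetic amplicon: 16 CpGs and 32 non-CpG cytosines, the
      # CpG density of a typical ICR bisulfite PCR product
      base <- strrep("TTACGGATCATTCAGT", 16)
      list(amplicons = list(
        high = amplicon_scenario("RasAmp", base, true_methylation = 0.9),
        partial = amplicon_scenario("RasAmp", base, true_methylation = 0.5),
        low = amplicon_scenario("RasAmp", base, true_methylation = 0.1)
      ))
    }
  )
}
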