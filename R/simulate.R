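# Seeded generators for allelic counts, read-level CpG calls and colony reads.

#' Enumerate the embryos of a cross design
#'
#' Produces the sample metadata table. Naming is deterministic: within each
#' sex, embryos are numbered consecutively across genotypes in the fixed order
#' `M+Z+`, `M-Z+`, `M-Z-` (F1..Fn, M1..Mn), mirroring the conventional
#' labelling of hybrid embryo cohorts.
#'
#' @param design A [cross_design()].
#' @return Tibble with columns `sample`, `genotype`, `sex`.
#' @export
#' @examples
#' simulate_cross(cross_design(
#'   data.frame(genotype = c("M+Z+", "M-Z-"), sex = c("F", "M"), n = c(2, 3))
#' ))
simulate_cross <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  tab <- design$n_embryos |>
    mutate(genotype = factor(.data$genotype, levels = GENOTYPES),
           sex = factor(.data$sex, levels = SEXES)) |>
    arrange(.data$sex, .data$genotype) |>
    filter(.data$n > 0)
  samples <- tab |>
    tidyr::uncount(.data$n) |>
    group_by(.data$sex) |>
    mutate(sample = paste0(as.character(.data$sex), row_number())) |>
    ungroup() |>
    mutate(genotype = as.character(.data$genotype),
           sex = as.character(.data$sex)) |>
    select("sample", "genotype", "sex")
  samples
}

#' Simulate allele-resolved RNA-seq counts
#'
#' Draws, per gene and sample: a negative-binomial total count, a binomial
#' number of SNP-informative (allele-assignable) reads, a beta-distributed
#' per-sample paternal fraction around the group truth, and a binomial split
#' of assignable reads into paternal and maternal. See [gene_scenario()] for
#' the model.
#'
#' @param scenarios A [gene_scenario()] or list of them.
#' @param samples Sample metadata from [simulate_cross()].
#' @param seed Integer seed.
#' @return Tibble `gene`, `sample`, `maternal_count`, `paternal_count`,
#'   `total_count` (`total_count` includes unassignable reads).
#' @export
simulate_allelic_counts <- function(scenarios, samples, seed) {
  if (inherits(scenarios, "gene_scenario")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, TRUE, "gene_scenario")))
  check_columns(samples, c("sample", "genotype", "sex"), "samples")
  withr::with_seed(derive_seed(seed, "allelic_counts"), {
    purrr::map_dfr(scenarios, simulate_gene_counts, samples = samples)
  })
}

simulate_gene_counts <- function(scn, samples) {
  n <- nrow(samples)
  theta <- lookup_group_param(samples, scn$paternal_fraction, "theta",
                              paste0("gene ", scn$gene_id))
  total <- if (scn$dispersion == 0) {
    rpois(n, scn$mean_expression)
  } else {
    rnbinom(n, size = 1 / scn$dispersion, mu = scn$mean_expression)
  }
  assignable <- rbinom(n, total, scn$snp_informative_fraction)
  theta_i <- draw_theta(theta, scn$allelic_concentration)
  paternal <- rbinom(n, assignable, theta_i)
  tibble(
    gene = scn$gene_id, sample = samples$sample,
    maternal_count = assignable - paternal, paternal_count = paternal,
    total_count = total
  )
}

# Beta(theta * c, (1 - theta) * c); degenerate at theta in {0, 1} or c = Inf.
draw_theta <- function(theta, concentration) {
  out <- theta
  live <- theta > 0 & theta < 1 & is.finite(concentration)
  if (any(live)) {
    out[live] <- rbeta(sum(live), theta[live] * concentration,
                       (1 - theta[live]) * concentration)
  }
  out
}

#' Simulate read-level bisulfite CpG calls over an ICR
#'
#' Per sample and CpG site, a Poisson number of molecules is observed. Each
#' molecule derives from one parental allele (50:50), carries an allele tag
#' only when it overlaps an informative SNP, and is methylated with the
#' allele's true per-molecule probability; unmethylated molecules still read
#' methylated at the conversion-failure rate. One molecule observes one CpG.
#'
#' @param scenario An [icr_scenario()].
#' @param samples Sample metadata from [simulate_cross()].
#' @param seed Integer seed.
#' @return Tibble `sample`, `chrom`, `pos`, `read_id`, `allele`, `state` with
#'   `allele` in maternal/paternal/unassigned and `state` in
#'   methylated/unmethylated.
#' @export
simulate_wgbs_calls <- function(scenario, samples, seed) {
  stopifnot(inherits(scenario, "icr_scenario"))
  check_columns(samples, c("sample", "genotype", "sex"), "samples")
  icr <- scenario$icr
  meth_level <- lookup_group_param(samples, scenario$methylated_allele_level,
                                   "level", paste0("ICR ", icr$name))
  unmeth_level <- lookup_group_param(samples, scenario$unmethylated_allele_level,
                                     "level", paste0("ICR ", icr$name))
  meth_allele <- icr$germline_origin
  withr::with_seed(derive_seed(seed, paste0("wgbs_", icr$name)), {
    purrr::map_dfr(seq_len(nrow(samples)), function(i) {
      n_reads <- rpois(length(scenario$cpg_positions), scenario$read_depth)
      pos <- rep(scenario$cpg_positions, n_reads)
      m <- length(pos)
      if (m == 0) {
        return(tibble(sample = character(), chrom = character(),
                      pos = integer(), read_id = character(),
                      allele = character(), state = character()))
      }
      true_allele <- ifelse(runif(m) < 0.5, "maternal", "paternal")
      tag <- ifelse(runif(m) < scenario$snp_informative_fraction,
                    true_allele, "unassigned")
      level <- ifelse(true_allele == meth_allele, meth_level[i],
                      unmeth_level[i])
      methylated <- runif(m) < level
      # conversion failure: a truly unmethylated molecule reads methylated
      methylated <- methylated |
        (runif(m) < scenario$conversion_failure_rate)
      tibble(
        sample = samples$sample[i], chrom = icr$chrom, pos = pos,
        read_id = sprintf("%s_%s_%d_r%d", samples$sample[i], icr$name, pos,
                          stats::ave(pos, pos, FUN = seq_along)),
        allele = tag,
        state = ifelse(methylated, "methylated", "unmethylated")
      )
    })
  })
}

#' Simulate bacterial-colony bisulfite reads for one amplicon
#'
#' Each new molecule methylates its CpGs independently at `true_methylation`;
#' conversion rewrites unmethylated cytosines to T, retains methylated CpG
#' cytosines, and fails (retains C) at the conversion-failure rate. After the
#' first read, each subsequent read is an exact PCR copy of a uniformly chosen
#' earlier read with probability `pcr_duplication_rate`.
#'
#' @param scenario An [amplicon_scenario()].
#' @param seed Integer seed.
#' @param embryo Optional embryo label folded into read ids.
#' @return Tibble `read_id`, `sequence`, `is_duplicate`.
#' @export
simulate_colony_reads <- function(scenario, seed, embryo = "E1") {
  stopifnot(inherits(scenario, "amplicon_scenario"))
  ref <- scenario$reference
  withr::with_seed(derive_seed(seed, paste0("colony_", ref$name, "_", embryo)), {
    reads <- character(scenario$n_colonies)
    dup <- logical(scenario$n_colonies)
    for (i in seq_len(scenario$n_colonies)) {
      if (i > 1 && runif(1) < scenario$pcr_duplication_rate) {
        reads[i] <- reads[sample.int(i - 1, 1)]
        dup[i] <- TRUE
      } else {
        reads[i] <- convert_molecule(ref, scenario$true_methylation,
                                     scenario$conversion_failure_rate)
      }
    }
    tibble(
      read_id = sprintf("%s_%s_c%02d", embryo, ref$name,
                        seq_len(scenario$n_colonies)),
      sequence = reads, is_duplicate = dup
    )
  })
}

convert_molecule <- function(ref, true_methylation, failure_rate) {
  chars <- strsplit(ref$sequence, "")[[1]]
  methylated <- runif(length(ref$cpg_indices)) < true_methylation
  # cytosines due for conversion: all non-CpG Cs plus unmethylated CpG Cs
  convertible <- c(ref$non_cpg_c_indices, ref$cpg_indices[!methylated])
  converts <- runif(length(convertible)) >= failure_rate
  chars[convertible[converts]] <- "T"
  paste(chars, collapse = "")
}

#' Write simulated reads to a FASTA file
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  check_columns(reads, c("read_id", "sequence"), "reads")
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file into a reads tibble
#'
#' @param path FASTA path.
#' @return Tibble `read_id`, `sequence`.
#' @export
read_reads_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(read_id = names(seqs), sequence = unname(as.character(seqs)))
}
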