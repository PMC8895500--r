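# Shared in-code fixtures.

fixture_samples <- function(n_per_group = 2, sexes = c("F", "M")) {
  simulate_cross(cross_design(
    tidyr::expand_grid(genotype = GENOTYPES, sex = sexes) |>
      dplyr::mutate(n = n_per_group)
  ))
}

# A minimal call table: one sample, one chromosome, explicit states per site.
fixture_calls <- function(states_by_pos, sample = "F1", chrom = "chr1") {
  purrr::imap_dfr(states_by_pos, function(states, pos) {
    tibble::tibble(
      sample = sample, chrom = chrom, pos = as.integer(pos),
      read_id = paste0(sample, "_", pos, "_", seq_along(states)),
      allele = "unassigned", state = states
    )
  })
}

fixture_icr <- function(name = "TestICR", chrom = "chr1", start = 0L,
                        end = 1000L, origin = "maternal") {
  icr_region(name, chrom, start, end, germline_origin = origin)
}

# Random clone tibble for dedup/percentage properties.
fixture_random_clones <- function(n, n_cpg = 8, n_fingerprint_pool = 3) {
  tibble::tibble(
    clone_id = sprintf("c%03d", seq_len(n)),
    pattern = vapply(seq_len(n), function(i) {
      paste(sample(c("0", "1"), n_cpg, replace = TRUE), collapse = "")
    }, character(1)),
    fingerprint = sample(c("", "3", "3;7"), n, replace = TRUE)[
      seq_len(n)],
    qc_pass = TRUE, multiplicity = 1L
  )
}
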