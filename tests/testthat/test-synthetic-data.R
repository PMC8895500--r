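# Generators: cross enumeration, allelic counts, WGBS calls, colony reads.

test_that("simulate_cross enumerates embryos with deterministic names", {
  d <- cross_design(data.frame(genotype = c("M+Z+", "M-Z-"),
                               sex = c("F", "M"), n = c(2, 3)))
  s <- simulate_cross(d)
  expect_equal(nrow(s), 5)
  expect_equal(s$sample, c("F1", "F2", "M1", "M2", "M3"))
  expect_equal(s$genotype, c("M+Z+", "M+Z+", "M-Z-", "M-Z-", "M-Z-"))
  # numbering continues across genotypes within a sex, in genotype order
  full <- simulate_cross(cross_design(data.frame(
    genotype = c("M-Z-", "M+Z+", "M-Z+"), sex = "F", n = c(1, 2, 1)
  )))
  expect_equal(full$sample, paste0("F", 1:4))
  expect_equal(full$genotype, c("M+Z+", "M+Z+", "M-Z+", "M-Z-"))
  # enumeration is purely deterministic
  expect_identical(simulate_cross(d), simulate_cross(d))
})

test_that("cross designs reject impossible genotypes and empty cohorts", {
  expect_error(cross_design(data.frame(genotype = "M+Z-", sex = "F", n = 1)),
               "Invalid genotype")
  expect_error(cross_design(data.frame(genotype = "M+Z+", sex = "F", n = 0)),
               "at least one embryo")
  expect_error(cross_design(data.frame(genotype = "M+Z+", sex = "X", n = 1)),
               "Invalid sex")
})

test_that("allelic counts respect model boundaries", {
  samples <- fixture_samples(2)
  # paternal-only, fully informative, no scatter: maternal must be zero
  pat_only <- gene_scenario("pat", 1000, 100, dispersion = 0.1,
                            snp_informative_fraction = 1,
                            paternal_fraction = 1,
                            allelic_concentration = Inf)
  cc <- simulate_allelic_counts(pat_only, samples, seed = 11)
  expect_true(all(cc$maternal_count == 0))
  expect_true(all(cc$paternal_count == cc$total_count))
  # conservation: assigned reads never exceed simulated totals
  mixed <- gene_scenario("mix", 1000, 100, snp_informative_fraction = 0.5,
                         paternal_fraction = 0.3)
  cm <- simulate_allelic_counts(mixed, samples, seed = 11)
  expect_true(all(cm$maternal_count + cm$paternal_count <= cm$total_count))
})

test_that("zero dispersion gives Poisson-like counts", {
  samples <- simulate_cross(cross_design(
    data.frame(genotype = "M+Z+", sex = "F", n = 2000)
  ))
  scn <- gene_scenario("g", 1000, 50, dispersion = 0,
                       snp_informative_fraction = 1, paternal_fraction = 0.5)
  cc <- simulate_allelic_counts(scn, samples, seed = 5)
  idx <- var(cc$total_count) / mean(cc$total_count)
  expect_gt(idx, 0.85) # Poisson dispersion index ~ 1
  expect_lt(idx, 1.15)
  expect_gt(mean(cc$total_count), 45)
  expect_lt(mean(cc$total_count), 55)
})

test_that("pooled paternal fraction recovers theta across its range", {
  samples <- simulate_cross(cross_design(
    data.frame(genotype = "M+Z+", sex = "F", n = 500)
  ))
  for (theta in c(0.05, 0.5, 0.95)) {
    scn <- gene_scenario("g", 1000, 200, paternal_fraction = theta,
                         allelic_concentration = 50)
    cc <- simulate_allelic_counts(scn, samples, seed = 42)
    observed <- sum(cc$paternal_count) /
      sum(cc$paternal_count + cc$maternal_count)
    expect_lt(abs(observed - theta), 0.02)
  }
})

test_that("allelic count simulation is reproducible and validates groups", {
  samples <- fixture_samples(2)
  scn <- gene_scenario("g", 1000, 100)
  expect_identical(simulate_allelic_counts(scn, samples, seed = 9),
                   simulate_allelic_counts(scn, samples, seed = 9))
  partial <- gene_scenario(
    "gap", 1000, 100,
    paternal_fraction = data.frame(genotype = "M+Z+", sex = "F", theta = 0.9)
  )
  expect_error(simulate_allelic_counts(partial, samples, seed = 1),
               "gene gap.*no `theta` entry")
})

test_that("wgbs calls honour the noiseless and saturated limits", {
  samples <- simulate_cross(cross_design(
    data.frame(genotype = "M+Z+", sex = "F", n = 1)
  ))
  icr <- fixture_icr(origin = "maternal")
  clean <- icr_scenario(icr, cpg_positions = seq(10L, 100L, by = 10L),
                        methylated_allele_level = 1,
                        unmethylated_allele_level = 0, read_depth = 20,
                        conversion_failure_rate = 0,
                        snp_informative_fraction = 1)
  calls <- simulate_wgbs_calls(clean, samples, seed = 2)
  expect_true(all(calls$allele %in% c("maternal", "paternal")))
  expect_true(all(calls$state[calls$allele == "maternal"] == "methylated"))
  expect_true(all(calls$state[calls$allele == "paternal"] == "unmethylated"))
  # total conversion failure: every call reads methylated
  saturated <- icr_scenario(icr, cpg_positions = c(10L, 20L),
                            methylated_allele_level = 0,
                            unmethylated_allele_level = 0,
                            conversion_failure_rate = 1)
  calls2 <- simulate_wgbs_calls(saturated, samples, seed = 2)
  expect_true(all(calls2$state == "methylated"))
})

test_that("total ICR estimate matches the allelic mixture mean", {
  samples <- simulate_cross(cross_design(
    data.frame(genotype = "M+Z+", sex = "F", n = 1)
  ))
  icr <- fixture_icr()
  scn <- icr_scenario(icr, cpg_positions = seq(10L, 200L, by = 10L),
                      methylated_allele_level = 0.95,
                      unmethylated_allele_level = 0.05, read_depth = 30,
                      conversion_failure_rate = 0)
  # both alleles contribute equally, so the expectation is (0.95 + 0.05) / 2
  for (seed in 1:10) {
    calls <- simulate_wgbs_calls(scn, samples, seed = seed)
    sites <- site_methylation(calls, min_reads = 3)
    pct <- icr_methylation(sites, icr)$pct
    expect_lt(abs(pct / 100 - 0.50), 0.05)
  }
})

test_that("icr scenarios validate their CpG grid", {
  icr <- fixture_icr()
  expect_error(icr_scenario(icr, cpg_positions = integer(),
                            methylated_allele_level = 1), "non-empty")
  expect_error(icr_scenario(icr, cpg_positions = c(10L, 10L),
                            methylated_allele_level = 1),
               "strictly increasing")
  expect_error(icr_scenario(icr, cpg_positions = c(10L, 5000L),
                            methylated_allele_level = 1),
               "inside the ICR")
})

test_that("colony reads follow the conversion chemistry", {
  scn_un <- amplicon_scenario("amp", "ACGTCCGATCGA", true_methylation = 0,
                              conversion_failure_rate = 0, n_colonies = 10,
                              pcr_duplication_rate = 0)
  reads <- simulate_colony_reads(scn_un, seed = 1)
  c_pos <- sort(c(scn_un$reference$cpg_indices,
                  scn_un$reference$non_cpg_c_indices))
  for (s in reads$sequence) {
    expect_true(all(strsplit(s, "")[[1]][c_pos] == "T"))
  }
  scn_me <- amplicon_scenario("amp", "ACGTCCGATCGA", true_methylation = 1,
                              conversion_failure_rate = 0, n_colonies = 10,
                              pcr_duplication_rate = 0)
  reads2 <- simulate_colony_reads(scn_me, seed = 1)
  for (s in reads2$sequence) {
    expect_true(all(strsplit(s, "")[[1]][scn_me$reference$cpg_indices] == "C"))
  }
  expect_error(amplicon_scenario("amp", "ACGT", true_methylation = 0.5,
                                 n_colonies = 0), "n_colonies")
})

test_that("pcr duplication produces the expected share of copies", {
  scn <- amplicon_scenario("amp", "ACGTCCGATCGA", true_methylation = 0.5,
                           n_colonies = 20, pcr_duplication_rate = 0.5)
  dups <- vapply(1:50, function(seed) {
    sum(simulate_colony_reads(scn, seed = seed)$is_duplicate)
  }, numeric(1))
  # 19 eligible reads at rate 0.5: expectation 9.5
  expect_lt(abs(mean(dups) - 9.5), 1.5)
  expect_identical(simulate_colony_reads(scn, seed = 3),
                   simulate_colony_reads(scn, seed = 3))
})
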