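# ICR methylation quantification from read-level calls.

test_that("reads are assigned to alleles by their SNP observations", {
  snps <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                         maternal_base = c("A", "G", "C"),
                         paternal_base = c("T", "A", "T"))
  obs <- tibble::tibble(
    read_id = c("r_mat", "r_mat", "r_pat", "r_pat", "r_mix", "r_mix",
                "r_none"),
    chrom = "chr1",
    pos = c(100L, 200L, 100L, 200L, 100L, 200L, 999L),
    base = c("A", "G", "T", "A", "T", "G", "A")
  )
  expect_warning(calls <- assign_alleles(obs, snps), "ignored")
  lookup <- setNames(calls$allele, calls$read_id)
  expect_equal(lookup[["r_mat"]], "maternal")
  expect_equal(lookup[["r_pat"]], "paternal")
  expect_equal(lookup[["r_mix"]], "conflicting")
  expect_equal(lookup[["r_none"]], "unassigned")
  expect_equal(attr(calls, "ignored_observations"), 1L)
})

test_that("allele assignment is bisulfite-aware at C/T and G/A SNPs", {
  # maternal C vs paternal T: an observed T is compatible with both
  # (converted C or true T), hence uninformative
  snps <- tibble::tibble(chrom = "chr1", pos = 10L,
                         maternal_base = "C", paternal_base = "T")
  obs_t <- tibble::tibble(read_id = "r1", chrom = "chr1", pos = 10L,
                          base = "T")
  expect_equal(assign_alleles(obs_t, snps)$allele, "unassigned")
  # an observed C can only be the (possibly methylated) maternal C
  obs_c <- tibble::tibble(read_id = "r2", chrom = "chr1", pos = 10L,
                          base = "C")
  expect_equal(assign_alleles(obs_c, snps)$allele, "maternal")
  # reverse-strand image: G reference, observed A is ambiguous
  snps_g <- tibble::tibble(chrom = "chr1", pos = 10L,
                           maternal_base = "G", paternal_base = "A")
  obs_a <- tibble::tibble(read_id = "r3", chrom = "chr1", pos = 10L,
                          base = "A")
  expect_equal(assign_alleles(obs_a, snps_g)$allele, "unassigned")
  # without bisulfite-awareness the same observation is decisive
  expect_equal(assign_alleles(obs_a, snps_g, bisulfite = FALSE)$allele,
               "paternal")
})

test_that("read deduplication keys on sample, span and strand", {
  calls <- tibble::tibble(
    sample = "F1", chrom = "chr1", pos = 10L,
    read_id = c("a", "b", "c"),
    start = c(0L, 0L, 0L), end = c(100L, 100L, 100L),
    strand = c("+", "+", "-"),
    state = "methylated"
  )
  dd <- deduplicate_reads(calls)
  expect_equal(nrow(dd), 2) # duplicate span on + collapses; - survives
  expect_setequal(dd$strand, c("+", "-"))
  sizes <- attr(dd, "duplicate_groups")
  expect_equal(sort(sizes$n_reads), c(1, 2))
  expect_equal(nrow(deduplicate_reads(calls[0, ])), 0)
  expect_error(deduplicate_reads(dplyr::select(calls, -start)), "start")
  # read-id key keeps everything with distinct ids
  expect_equal(nrow(deduplicate_reads(calls, key = "read_id")), 3)
})

test_that("site levels follow the coverage rule and the counting formula", {
  calls <- fixture_calls(list(
    `100` = c("methylated", "methylated", "methylated", "unmethylated"),
    `200` = c("methylated", "unmethylated"),
    `300` = c("methylated", "methylated", "methylated")
  ))
  sites <- site_methylation(calls, min_reads = 3)
  s100 <- sites[sites$pos == 100, ]
  expect_equal(s100$level, 0.75)
  expect_true(s100$qualifies)
  s200 <- sites[sites$pos == 200, ]
  expect_false(s200$qualifies) # 2 reads < 3: excluded, not zero
  expect_equal(s200$level, 0.5) # level still reported for inspection
  expect_equal(sites$level[sites$pos == 300], 1.0)
})

test_that("ICR percentage averages qualifying sites unweighted", {
  calls <- fixture_calls(list(
    `100` = rep("methylated", 4),                      # level 1.0, n = 4
    `200` = rep(c("methylated", "unmethylated"), 4)    # level 0.5, n = 8
  ))
  sites <- site_methylation(calls)
  out <- icr_methylation(sites, fixture_icr())
  expect_equal(out$pct, 75) # unweighted mean of 1.0 and 0.5, not 6/12
  expect_equal(out$n_sites, 2L)
  single <- site_methylation(fixture_calls(list(
    `100` = c("methylated", "methylated", "unmethylated", "unmethylated",
              "unmethylated")
  )))
  expect_equal(icr_methylation(single, fixture_icr())$pct, 40)
})

test_that("an ICR with no qualifying site is no-data, never zero", {
  thin <- site_methylation(fixture_calls(list(`100` = "methylated")),
                           min_reads = 3)
  out <- icr_methylation(thin, fixture_icr())
  expect_true(is.na(out$pct))
  expect_equal(out$n_sites, 0L)
})

test_that("site and ICR levels match a naive recount on random instances", {
  withr::with_seed(301, {
    for (i in 1:40) {
      n <- sample(5:60, 1)
      calls <- tibble::tibble(
        sample = sample(c("F1", "M1"), n, replace = TRUE),
        chrom = "chr1",
        pos = sample(c(100L, 150L, 220L, 310L), n, replace = TRUE),
        read_id = paste0("r", seq_len(n)),
        allele = "unassigned",
        state = sample(c("methylated", "unmethylated"), n, replace = TRUE)
      )
      sites <- site_methylation(calls, min_reads = 3)
      want_sites <- oracle_site_levels(calls)
      got <- dplyr::arrange(sites, sample, pos)
      want <- dplyr::arrange(tibble::as_tibble(want_sites), sample, pos)
      expect_identical(got$n_reads, as.integer(want$n_reads))
      expect_identical(got$level, want$level)
      pct <- icr_methylation(sites, fixture_icr(start = 0L, end = 400L))
      for (s in unique(calls$sample)) {
        expect_identical(pct$pct[pct$sample == s],
                         oracle_icr_pct(calls[calls$sample == s, ], 0, 400))
      }
    }
  })
})

test_that("adding calls moves a site level monotonically", {
  base <- fixture_calls(list(`100` = c("methylated", "unmethylated",
                                       "methylated")))
  lvl <- function(calls) site_methylation(calls)$level
  before <- lvl(base)
  plus_m <- dplyr::bind_rows(base, dplyr::mutate(base[1, ], read_id = "new",
                                                 state = "methylated"))
  plus_u <- dplyr::bind_rows(base, dplyr::mutate(base[1, ], read_id = "new",
                                                 state = "unmethylated"))
  expect_gte(lvl(plus_m), before)
  expect_lte(lvl(plus_u), before)
})

test_that("allelic ICR methylation recovers each allele's level", {
  samples <- simulate_cross(cross_design(
    data.frame(genotype = "M+Z+", sex = "F", n = 2)
  ))
  icr <- fixture_icr(origin = "maternal")
  scn <- icr_scenario(icr, cpg_positions = seq(10L, 400L, by = 10L),
                      methylated_allele_level = 0.9,
                      unmethylated_allele_level = 0.1, read_depth = 40,
                      conversion_failure_rate = 0,
                      snp_informative_fraction = 0.7)
  calls <- simulate_wgbs_calls(scn, samples, seed = 6)
  mat <- allelic_icr_methylation(calls, icr, "maternal")
  pat <- allelic_icr_methylation(calls, icr, "paternal")
  expect_true(all(abs(mat$pct - 90) < 5))
  expect_true(all(abs(pat$pct - 10) < 5))
  # total lies between the allelic levels
  tot <- icr_methylation(site_methylation(calls), icr)
  for (s in samples$sample) {
    expect_gte(tot$pct[tot$sample == s], pat$pct[pat$sample == s])
    expect_lte(tot$pct[tot$sample == s], mat$pct[mat$sample == s])
  }
})

test_that("an allele with no tagged reads reports no-data", {
  calls <- fixture_calls(list(`100` = rep("methylated", 5)))
  out <- allelic_icr_methylation(calls, fixture_icr(), "paternal")
  expect_true(is.na(out$pct))
  expect_equal(out$n_sites, 0L)
  # fully maternal-tagged calls across sites give 100%
  mat_calls <- dplyr::mutate(calls, allele = "maternal")
  out_m <- allelic_icr_methylation(mat_calls, fixture_icr(), "maternal")
  expect_equal(out_m$pct, 100)
})

test_that("group comparisons produce the study's statistics and stars", {
  samples <- fixture_samples(3)
  icr <- fixture_icr()
  scn <- icr_scenario(
    icr, cpg_positions = seq(10L, 400L, by = 20L),
    methylated_allele_level = tibble::tibble(
      genotype = rep(GENOTYPES, each = 2), sex = rep(c("F", "M"), 3),
      level = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.1)
    ),
    unmethylated_allele_level = 0.05, read_depth = 40
  )
  calls <- simulate_wgbs_calls(scn, samples, seed = 10)
  pct <- icr_methylation(site_methylation(calls), icr)
  sex_cmp <- compare_icr_groups(pct, samples, "sex_within_genotype")
  mzz <- sex_cmp[sex_cmp$genotype == "M-Z-", ]
  expect_lt(mzz$p_value, 0.05)
  expect_gt(mzz$mean_female, mzz$mean_male)
  geno_cmp <- compare_icr_groups(pct, samples, "genotype_within_sex")
  male_pair <- geno_cmp[geno_cmp$sex == "M" & geno_cmp$group_b == "M-Z-" &
                          geno_cmp$group_a == "M+Z+", ]
  expect_lt(male_pair$p_value, 0.05)
  expect_true(male_pair$stars %in% c("*", "**", "***"))
  expect_equal(star_label(0.004), "**")
  expect_equal(star_label(0.03), "*")
  expect_equal(star_label(0.2), "ns")
})

test_that("identical groups compare as indistinguishable", {
  pct <- tibble::tibble(
    sample = paste0(rep(c("F", "M"), each = 2), 1:2),
    icr = "X", pct = c(50, 60, 50, 60)
  )
  samples <- tibble::tibble(sample = pct$sample, genotype = "M+Z+",
                            sex = rep(c("F", "M"), each = 2))
  cmp <- compare_icr_groups(pct, samples, "sex_within_genotype")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$stars, "ns")
})

test_that("bedGraph export follows the fixed 0-1 track format", {
  sites <- tibble::tibble(sample = "F1", chrom = "chr9", pos = 89774500L,
                          n_reads = 4L, n_methylated = 3L, level = 0.75,
                          qualifies = TRUE)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  export_methylation_track(sites, "F1", path)
  expect_identical(readLines(path), "chr9\t89774500\t89774501\t0.75")
  # empty site set: header-only file
  export_methylation_track(sites[0, ], "F1", path, track_name = "F1")
  expect_identical(readLines(path), "track type=bedGraph name=\"F1\"")
  # emitted values are clipped into [0, 1]
  many <- tibble::tibble(sample = "F1", chrom = "chr1",
                         pos = seq(10L, 100L, 10L), n_reads = 5L,
                         n_methylated = 1L,
                         level = seq(-0.2, 1.3, length.out = 10),
                         qualifies = TRUE)
  export_methylation_track(many, "F1", path)
  vals <- as.numeric(vapply(strsplit(readLines(path), "\t"), `[[`, "", 4))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("ICR BED files round-trip with coordinate conventions", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr9\t89774439\t89774883\tRasgrf1\tpaternal",
               "chr7\t67148026\t67150181\tSnrpn\tmaternal"), path)
  icrs <- read_icr_bed(path)
  expect_equal(icrs$name, c("Rasgrf1", "Snrpn"))
  expect_equal(icrs$start[1], 89774439L)
  one <- read_icr_bed(path, one_based = TRUE)
  expect_equal(one$start[1], 89774438L)
  writeLines("chr1\t10\t20\tX\tboth", path)
  expect_error(read_icr_bed(path), "germline_origin")
})
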