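# ICR methylation quantification from read-level bisulfite CpG calls.

#' Read ICR definitions from a BED-like file
#'
#' Expects a tab-separated file with columns chrom, start, end, name,
#' germline_origin (maternal/paternal). Coordinates are 0-based half-open as
#' in BED; pass `one_based = TRUE` for 1-based inclusive spans, which are
#' converted on read.
#'
#' @param path File path.
#' @param one_based Input coordinates are 1-based inclusive.
#' @return Tibble `name`, `chrom`, `start`, `end`, `germline_origin`.
#' @export
read_icr_bed <- function(path, one_based = FALSE) {
  icrs <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "germline_origin"),
    col_types = "ciicc", comment = "#", progress = FALSE
  )
  if (one_based) icrs$start <- icrs$start - 1L
  bad <- setdiff(unique(icrs$germline_origin), c("maternal", "paternal"))
  if (length(bad) > 0) {
    abort(paste0("invalid germline_origin value(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(icrs$start >= icrs$end)) abort("ICR intervals must have start < end")
  select(icrs, "name", "chrom", "start", "end", "germline_origin")
}

#' Assign reads to a parental allele from SNP base observations
#'
#' Implements the hybrid-cross read-assignment contract: a read whose
#' informative SNP observations all match the maternal (129) base is
#' `maternal`, all-paternal (DBA) is `paternal`, a mixture is `conflicting`,
#' and a read with no informative observation is `unassigned`. Matching is
#' bisulfite-aware: an observed T is compatible with a reference C, and an
#' observed A with a reference G (the reverse-strand image of C-to-T
#' conversion), so such observations cannot distinguish the alleles and are
#' treated as uninformative when both alleles are compatible.
#'
#' @param observations Tibble `read_id`, `chrom`, `pos`, `base`: the base each
#'   read shows at each SNP position it overlaps.
#' @param snps Tibble `chrom`, `pos`, `maternal_base`, `paternal_base` with
#'   distinct bases per SNP.
#' @param bisulfite Apply bisulfite-aware matching (default `TRUE`).
#' @return Tibble `read_id`, `allele`; the number of observations at non-SNP
#'   positions is reported in the `ignored_observations` attribute.
#' @export
assign_alleles <- function(observations, snps, bisulfite = TRUE) {
  check_columns(observations, c("read_id", "chrom", "pos", "base"),
                "observations")
  check_columns(snps, c("chrom", "pos", "maternal_base", "paternal_base"),
                "snps")
  if (any(snps$maternal_base == snps$paternal_base)) {
    abort("SNP table contains entries with identical parental bases")
  }
  obs <- inner_join(as_tibble(observations), as_tibble(snps),
                    by = c("chrom", "pos"))
  n_ignored <- nrow(observations) - nrow(obs)
  if (n_ignored > 0) {
    warn(paste0(n_ignored,
                " observation(s) at non-SNP positions were ignored"))
  }
  compat <- function(observed, reference) {
    same <- observed == reference
    if (!bisulfite) return(same)
    same | (reference == "C" & observed == "T") |
      (reference == "G" & observed == "A")
  }
  obs <- obs |>
    mutate(
      m_ok = compat(.data$base, .data$maternal_base),
      p_ok = compat(.data$base, .data$paternal_base),
      informative = xor(.data$m_ok, .data$p_ok)
    )
  calls <- obs |>
    group_by(.data$read_id) |>
    summarise(
      n_m = sum(.data$informative & .data$m_ok),
      n_p = sum(.data$informative & .data$p_ok)
    ) |>
    mutate(allele = dplyr::case_when(
      .data$n_m > 0 & .data$n_p > 0 ~ "conflicting",
      .data$n_m > 0 ~ "maternal",
      .data$n_p > 0 ~ "paternal",
      TRUE ~ "unassigned"
    )) |>
    select("read_id", "allele")
  # reads with zero observations on any SNP are unassigned too
  all_reads <- distinct(as_tibble(observations), .data$read_id)
  out <- left_join(all_reads, calls, by = "read_id") |>
    mutate(allele = dplyr::coalesce(.data$allele, "unassigned"))
  attr(out, "ignored_observations") <- n_ignored
  out
}

#' Collapse duplicate reads by alignment coordinates
#'
#' Keeps one representative per (sample, start, end, strand) group — the
#' standard bisulfite deduplication key — or per (sample, read_id) with
#' `key = "read_id"`. Group sizes are reported in the `duplicate_groups`
#' attribute.
#'
#' @param calls Call-level tibble carrying `sample`, `start`, `end`, `strand`
#'   (for the coordinate key) in addition to its call columns.
#' @param key `"coordinates"` (default) or `"read_id"`.
#' @return Deduplicated tibble.
#' @export
deduplicate_reads <- function(calls, key = c("coordinates", "read_id")) {
  key <- match.arg(key)
  cols <- if (key == "coordinates") c("sample", "start", "end", "strand")
          else c("sample", "read_id")
  check_columns(calls, cols, "calls")
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) return(calls)
  grouped <- calls |>
    group_by(dplyr::across(dplyr::all_of(cols)))
  sizes <- grouped |>
    summarise(n_reads = dplyr::n_distinct(.data$read_id), .groups = "drop")
  first_read <- grouped |>
    summarise(read_id = dplyr::first(.data$read_id), .groups = "drop")
  out <- semi_join(calls, first_read,
                   by = c(cols, if (!"read_id" %in% cols) "read_id"))
  attr(out, "duplicate_groups") <- sizes
  out
}

#' Per-CpG methylation level with a coverage rule
#'
#' For each sample and CpG site, the methylation level is the number of
#' methylated calls divided by the total calls. Sites covered by fewer than
#' `min_reads` unique reads are marked not qualifying (`qualifies = FALSE`,
#' level still reported) — exclusion is distinct from a level of zero.
#'
#' @param calls Deduplicated call tibble (`sample`, `chrom`, `pos`,
#'   `read_id`, `state`).
#' @param min_reads Minimum unique-read coverage per site (default 3).
#' @return Tibble `sample`, `chrom`, `pos`, `n_reads`, `n_methylated`,
#'   `level`, `qualifies`.
#' @export
site_methylation <- function(calls, min_reads = 3) {
  check_columns(calls, c("sample", "chrom", "pos", "read_id", "state"),
                "calls")
  bad <- setdiff(unique(calls$state), c("methylated", "unmethylated"))
  if (length(bad) > 0) {
    abort(paste0("invalid methylation state(s): ", paste(bad, collapse = ", ")))
  }
  as_tibble(calls) |>
    group_by(.data$sample, .data$chrom, .data$pos) |>
    summarise(
      n_reads = dplyr::n(),
      n_methylated = sum(.data$state == "methylated"),
      .groups = "drop"
    ) |>
    mutate(level = .data$n_methylated / .data$n_reads,
           qualifies = .data$n_reads >= min_reads)
}

#' ICR methylation percentage per sample
#'
#' Averages the qualifying per-site levels inside each ICR interval,
#' unweighted by coverage, and scales to percent. A sample with no qualifying
#' site in an ICR yields `NA` with `n_sites = 0` — an explicit no-data
#' marker, never a silent zero.
#'
#' @param sites Output of [site_methylation()].
#' @param icrs ICR tibble (`name`, `chrom`, `start`, `end`) from
#'   [read_icr_bed()] or [icr_region()].
#' @return Tibble `sample`, `icr`, `n_sites`, `pct` (0-100 or `NA`).
#' @export
icr_methylation <- function(sites, icrs) {
  check_columns(sites, c("sample", "chrom", "pos", "level", "qualifies"),
                "sites")
  check_columns(icrs, c("name", "chrom", "start", "end"), "icrs")
  sites <- as_tibble(sites)
  purrr::map_dfr(seq_len(nrow(icrs)), function(i) {
    icr <- icrs[i, ]
    inside <- sites |>
      filter(.data$chrom == icr$chrom, .data$pos >= icr$start,
             .data$pos < icr$end, .data$qualifies)
    per_sample <- inside |>
      group_by(.data$sample) |>
      summarise(n_sites = dplyr::n(), pct = 100 * mean(.data$level),
                .groups = "drop")
    all_samples <- distinct(sites, .data$sample)
    left_join(all_samples, per_sample, by = "sample") |>
      mutate(icr = icr$name,
             n_sites = dplyr::coalesce(.data$n_sites, 0L)) |>
      select("sample", "icr", "n_sites", "pct")
  })
}

#' Allele-split ICR methylation
#'
#' Restricts the calls to reads tagged with one parental allele and
#' quantifies ICR methylation with the relaxed coverage rule used for allelic
#' measurements (at least one unique read per CpG by default).
#'
#' @param calls Call tibble with an `allele` column.
#' @param icrs ICR tibble.
#' @param allele `"maternal"` or `"paternal"`.
#' @param min_reads Minimum unique-read coverage per site (default 1).
#' @return As [icr_methylation()], with an `allele` column.
#' @export
allelic_icr_methylation <- function(calls, icrs, allele, min_reads = 1) {
  check_columns(calls, c("sample", "chrom", "pos", "read_id", "state",
                         "allele"), "calls")
  if (!allele %in% c("maternal", "paternal")) {
    abort("allele must be \"maternal\" or \"paternal\"")
  }
  tagged <- filter(as_tibble(calls), .data$allele == .env$allele)
  all_samples <- distinct(as_tibble(calls), .data$sample)
  if (nrow(tagged) == 0) {
    return(tidyr::expand_grid(all_samples, icr = icrs$name) |>
             mutate(n_sites = 0L, pct = NA_real_, allele = .env$allele))
  }
  sites <- site_methylation(tagged, min_reads = min_reads)
  # keep samples that lost all tagged reads visible as no-data
  out <- icr_methylation(sites, icrs)
  tidyr::expand_grid(all_samples, icr = icrs$name) |>
    left_join(out, by = c("sample", "icr")) |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           allele = .env$allele)
}

#' Compare per-embryo ICR methylation between groups
#'
#' Two designs mirror the study's statistics: `"genotype_within_sex"` runs a
#' one-way ANOVA with Fisher-LSD pairwise comparisons across the genotypes of
#' each sex, and `"sex_within_genotype"` runs a two-tailed pooled t-test of
#' females versus males within each genotype. Significance stars follow the
#' 0.05 / 0.01 / 0.001 convention.
#'
#' @param icr_pct Per-embryo percentages (`sample`, `icr`, `pct`) from
#'   [icr_methylation()].
#' @param samples Sample metadata.
#' @param design Comparison design.
#' @param alpha Protection level for the LSD omnibus gate.
#' @return Tidy statistics tibble, one row per comparison.
#' @export
compare_icr_groups <- function(icr_pct, samples,
                               design = c("genotype_within_sex",
                                          "sex_within_genotype"),
                               alpha = 0.05) {
  design <- match.arg(design)
  check_columns(icr_pct, c("sample", "icr", "pct"), "icr_pct")
  check_columns(samples, c("sample", "genotype", "sex"), "samples")
  dat <- inner_join(as_tibble(icr_pct), as_tibble(samples), by = "sample") |>
    filter(!is.na(.data$pct))
  if (design == "genotype_within_sex") {
    dat |>
      group_by(.data$icr, .data$sex) |>
      dplyr::group_modify(function(d, key) {
        sizes <- table(d$genotype)
        if (length(sizes) < 3 || any(sizes < 2)) {
          abort(paste0("ICR ", key$icr, " sex ", key$sex,
                       ": each genotype group needs >= 2 embryos"))
        }
        fit <- anova_fisher_lsd(d, .data$pct, .data$genotype, alpha = alpha)
        mutate(tidy(fit), omnibus_p = glance(fit)$p_value)
      }) |>
      ungroup()
  } else {
    dat |>
      group_by(.data$icr, .data$genotype) |>
      dplyr::group_modify(function(d, key) {
        f <- d$pct[d$sex == "F"]; m <- d$pct[d$sex == "M"]
        if (length(f) < 2 || length(m) < 2) {
          abort(paste0("ICR ", key$icr, " genotype ", key$genotype,
                       ": each sex group needs >= 2 embryos"))
        }
        two_tailed_ttest(f, m) |>
          rename(mean_female = "mean_a", mean_male = "mean_b")
      }) |>
      ungroup()
  }
}

#' Export per-site methylation levels as bedGraph text
#'
#' Writes one `chrom start start+1 level` line per qualifying CpG site of one
#' sample, sorted by coordinate, values in `[0, 1]` — the 0-1 methylation
#' track convention of genome-browser methylation plots.
#'
#' @param sites Output of [site_methylation()].
#' @param sample Sample to export.
#' @param path Output file path.
#' @param track_name Optional track header name; `NULL` for no header.
#' @return `path`, invisibly.
#' @export
export_methylation_track <- function(sites, sample, path,
                                     track_name = NULL) {
  check_columns(sites, c("sample", "chrom", "pos", "level", "qualifies"),
                "sites")
  sub <- as_tibble(sites) |>
    filter(.data$sample == .env$sample, .data$qualifies) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(level = pmin(pmax(.data$level, 0), 1))
  lines <- sprintf("%s\t%d\t%d\t%s", sub$chrom, sub$pos, sub$pos + 1L,
                   format(sub$level, trim = TRUE, scientific = FALSE))
  if (!is.null(track_name)) {
    lines <- c(sprintf("track type=bedGraph name=\"%s\"", track_name), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Heatmap-style plot of per-site methylation across samples
#'
#' @param sites Output of [site_methylation()].
#' @param qualifying_only Drop sites below the coverage rule.
#' @return A ggplot object.
#' @export
plot_methylation_profile <- function(sites, qualifying_only = TRUE) {
  check_columns(sites, c("sample", "chrom", "pos", "level", "qualifies"),
                "sites")
  df <- as_tibble(sites)
  if (qualifying_only) df <- filter(df, .data$qualifies)
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$sample,
                                   fill = .data$level)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "methylation") +
    ggplot2::labs(x = "CpG position", y = NULL) +
    ggplot2::theme_minimal()
}
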