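# End-to-end orchestration: scenario config -> simulation -> analyses -> report.

#' Default run configuration
#'
#' Assembles the bundled presets into a complete demo run: the allelic-switch
#' scan preset, the sex-dimorphic ICR preset and the colony amplicon preset,
#' with the study's threshold defaults (delta P-score 0.1, alpha 0.05,
#' |log2FC| 0.5, pooled-count filter 10, TPM filter 1.0, 3-read CpG coverage
#' rule).
#'
#' @param seed Master seed.
#' @param out Output directory.
#' @return A run-config list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, out = tempfile("imprintr_run_")) {
  sw <- scenario_preset("snrpn_partial_MZ")
  me <- scenario_preset("rasgrf1_sex_dimorphic")
  co <- scenario_preset("rasgrf1_colony")
  # one cohort covering both sexes so every analysis stage has its groups
  design <- cross_design(
    tidyr::expand_grid(genotype = GENOTYPES, sex = SEXES) |>
      mutate(n = 3L)
  )
  list(
    seed = as.integer(seed), out = out,
    stages = c("simulate", "pscore", "expression", "methylation", "colony"),
    thresholds = list(delta_pscore = 0.1, alpha = 0.05, fc = 0.5,
                      fc_sex = 0.3, min_counts = 10, min_tpm = 1.0,
                      min_site_reads = 3),
    design = design,
    genes = sw$genes[c(1:8, 21:40)],   # 8 switching + 20 null genes
    icrs = me$icrs,
    amplicons = co$amplicons,
    pscore_sex = "F", pscore_pair = c("M+Z+", "M-Z-"),
    expression_contrast = "F:M-Z- vs F:M+Z+",
    colony_groups = list(high = "M-Z+", low = "M-Z-"), colony_sex = "M"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file mirrors [default_run_config()]: top-level `seed`, `out`,
#' `stages`, `thresholds`, plus declarative `design` (rows of
#' genotype/sex/n), `genes`, `icrs` and `amplicons` sections whose entries are
#' passed to [gene_scenario()], [icr_scenario()] / [icr_region()] and
#' [amplicon_scenario()]. Omitted sections fall back to the bundled presets.
#'
#' @param path YAML file path.
#' @return A run-config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = raw$seed %||% 1L,
                            out = raw$out %||% tempfile("imprintr_run_"))
  for (k in c("stages", "pscore_sex", "pscore_pair", "expression_contrast",
              "colony_sex")) {
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  }
  if (!is.null(raw$thresholds)) {
    cfg$thresholds <- modifyList(cfg$thresholds, raw$thresholds)
  }
  if (!is.null(raw$design)) {
    cfg$design <- cross_design(dplyr::bind_rows(raw$design))
  }
  if (!is.null(raw$genes)) {
    cfg$genes <- lapply(raw$genes, function(g) {
      if (!is.null(g$paternal_fraction) && is.list(g$paternal_fraction)) {
        g$paternal_fraction <- dplyr::bind_rows(g$paternal_fraction)
      }
      do.call(gene_scenario, g)
    })
  }
  if (!is.null(raw$icrs)) {
    cfg$icrs <- lapply(raw$icrs, function(s) {
      s$icr <- do.call(icr_region, s$icr)
      for (k in c("methylated_allele_level", "unmethylated_allele_level")) {
        if (is.list(s[[k]])) s[[k]] <- dplyr::bind_rows(s[[k]])
      }
      s$cpg_positions <- as.integer(unlist(s$cpg_positions))
      do.call(icr_scenario, s)
    })
  }
  if (!is.null(raw$amplicons)) {
    cfg$amplicons <- lapply(raw$amplicons, function(a) {
      do.call(amplicon_scenario, a)
    })
  }
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (!is.numeric(th$alpha) || th$alpha <= 0 || th$alpha >= 1) {
    abort("config error: alpha must lie strictly between 0 and 1")
  }
  for (k in c("delta_pscore", "fc", "fc_sex", "min_counts", "min_tpm",
              "min_site_reads")) {
    if (!is.numeric(th[[k]]) || th[[k]] <= 0) {
      abort(paste0("config error: threshold `", k, "` must be positive"))
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("config error: seed must be a single integer")
  }
  bad <- setdiff(cfg$stages, c("simulate", "pscore", "expression",
                               "methylation", "colony"))
  if (length(bad) > 0) {
    abort(paste0("config error: unknown stage(s) ", paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

write_tsv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages — simulate the cohort, allelic-switch scan,
#' TPM differential expression, ICR methylation (total, allelic, group
#' comparisons, bedGraph tracks) and colony clone analysis — writing fixed-
#' format TSV outputs, a manifest recording seed and thresholds, and a
#' human-readable summary. All randomness derives from the config seed, so a
#' rerun with the same config is byte-identical.
#'
#' @param config A run-config list ([default_run_config()]) or a YAML path
#'   ([read_run_config()]).
#' @return Invisibly, a list of stage outputs plus `out` (directory) and
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(default_run_config(seed = 7))
#' list.files(res$out)
#' }
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  outputs <- list(out = config$out)
  files <- character()

  samples <- simulate_cross(config$design)
  if ("simulate" %in% config$stages) {
    files["samples"] <- write_tsv_out(samples, config$out, "samples.tsv")
  }
  outputs$samples <- samples

  if (any(c("simulate", "pscore", "expression") %in% config$stages)) {
    counts <- simulate_allelic_counts(config$genes, samples, config$seed)
    outputs$counts <- counts
    if ("simulate" %in% config$stages) {
      files["counts"] <- write_tsv_out(counts, config$out, "counts.tsv")
    }
  }

  if ("pscore" %in% config$stages) {
    scores <- counts |>
      filter_expressed_allelic(min_total = th$min_counts) |>
      compute_pscore()
    scan <- select_switched_genes(
      scores, samples, sex = config$pscore_sex, pair = config$pscore_pair,
      delta_threshold = th$delta_pscore, alpha = th$alpha
    )
    outputs$switch_scan <- scan
    files["switch_results"] <-
      write_tsv_out(tidy(scan), config$out, "switch_results.tsv")
    files["pscore_matrix"] <- write_tsv_out(
      as_tibble(scan$matrix, rownames = "gene"), config$out,
      "pscore_matrix.tsv"
    )
  }

  if ("expression" %in% config$stages) {
    lengths <- tibble(
      gene = vapply(config$genes, `[[`, character(1), "gene_id"),
      length_bp = vapply(config$genes, `[[`, numeric(1), "gene_length")
    )
    expr <- counts |>
      select("gene", "sample", count = "total_count") |>
      compute_tpm(lengths) |>
      filter_quantifiable(min_reads = th$min_counts, min_tpm = th$min_tpm)
    diff <- differential_genes(expr, samples, config$expression_contrast,
                               fc_threshold = th$fc, alpha = th$alpha)
    outputs$expression <- expr
    outputs$differential <- diff
    files["expression"] <- write_tsv_out(expr, config$out, "expression.tsv")
    files["differential"] <-
      write_tsv_out(tidy(diff), config$out, "differential.tsv")
  }

  if ("methylation" %in% config$stages) {
    icr_tab <- dplyr::bind_rows(lapply(config$icrs, function(s) s$icr))
    calls <- purrr::map_dfr(config$icrs, simulate_wgbs_calls,
                            samples = samples, seed = config$seed)
    sites <- site_methylation(calls, min_reads = th$min_site_reads)
    icr_pct <- icr_methylation(sites, icr_tab)
    allelic <- dplyr::bind_rows(
      allelic_icr_methylation(calls, icr_tab, "maternal"),
      allelic_icr_methylation(calls, icr_tab, "paternal")
    )
    comparisons <- compare_icr_groups(icr_pct, samples,
                                      design = "sex_within_genotype")
    outputs$methylation <- list(calls = calls, sites = sites,
                                icr_pct = icr_pct, allelic = allelic,
                                comparisons = comparisons)
    files["methylation_calls"] <-
      write_tsv_out(calls, config$out, "methylation_calls.tsv")
    files["icr_methylation"] <-
      write_tsv_out(icr_pct, config$out, "icr_methylation.tsv")
    files["allelic_icr_methylation"] <-
      write_tsv_out(allelic, config$out, "allelic_icr_methylation.tsv")
    files["icr_comparisons"] <-
      write_tsv_out(comparisons, config$out, "icr_comparisons.tsv")
    for (s in unique(sites$sample)) {
      export_methylation_track(
        sites, s, file.path(config$out, paste0("methylation_", s, ".bedGraph"))
      )
    }
  }

  if ("colony" %in% config$stages) {
    grp_samples <- samples |>
      filter(.data$sex == config$colony_sex,
             .data$genotype %in% unlist(config$colony_groups))
    scen_for <- function(genotype) {
      if (genotype == config$colony_groups$low) config$amplicons$low
      else config$amplicons$high
    }
    per_embryo <- purrr::map_dfr(seq_len(nrow(grp_samples)), function(i) {
      s <- grp_samples[i, ]
      scen <- scen_for(s$genotype)
      reads <- simulate_colony_reads(scen, config$seed, embryo = s$sample)
      clones <- call_clones(reads, scen$reference)
      uniq <- deduplicate_clones(clones)
      tibble(sample = s$sample, genotype = s$genotype, sex = s$sex,
             n_clones = sum(clones$qc_pass), n_unique = nrow(uniq),
             pct = clone_set_methylation(uniq))
    })
    comp <- compare_clone_methylation(
      per_embryo$pct[per_embryo$genotype == config$colony_groups$high],
      per_embryo$pct[per_embryo$genotype == config$colony_groups$low]
    )
    outputs$colony <- list(per_embryo = per_embryo, comparison = comp)
    files["colony_pct"] <-
      write_tsv_out(per_embryo, config$out, "colony_pct.tsv")
    files["colony_comparison"] <-
      write_tsv_out(comp, config$out, "colony_comparison.tsv")
  }

  manifest <- list(
    package = "imprintr",
    version = as.character(utils::packageVersion("imprintr")),
    seed = config$seed, stages = config$stages, thresholds = th,
    outputs = as.list(files)
  )
  yaml::write_yaml(manifest, file.path(config$out, "manifest.yaml"))
  outputs$manifest <- manifest
  writeLines(summarize_run(outputs), file.path(config$out, "summary.txt"))
  invisible(outputs)
}

#' Summarise pipeline outputs as readable text
#'
#' Stable, deterministic ordering: ICRs sorted by name with group means and
#' comparison stars, the selected switched genes with their allelic states,
#' and the significant differential genes.
#'
#' @param outputs The list returned by [run_pipeline()].
#' @return Character vector of report lines.
#' @export
summarize_run <- function(outputs) {
  lines <- c("imprintr run summary", "====================")
  if (!is.null(outputs$methylation)) {
    icr_groups <- outputs$methylation$icr_pct |>
      inner_join(outputs$samples, by = "sample") |>
      group_by(.data$icr, .data$genotype, .data$sex) |>
      summarise(mean_pct = mean(.data$pct, na.rm = TRUE), .groups = "drop") |>
      arrange(.data$icr, .data$sex,
              factor(.data$genotype, levels = GENOTYPES))
    lines <- c(lines, "", "ICR methylation (group means, %):",
               sprintf("  %-10s %-5s %-4s %6.1f", icr_groups$icr,
                       icr_groups$genotype, icr_groups$sex,
                       icr_groups$mean_pct))
    comp <- outputs$methylation$comparisons |> arrange(.data$icr)
    lines <- c(lines, "ICR sex comparisons (F vs M, within genotype):",
               sprintf("  %-10s %-5s p = %.3g %s", comp$icr, comp$genotype,
                       comp$p_value, comp$stars))
  }
  if (!is.null(outputs$switch_scan)) {
    res <- tidy(outputs$switch_scan) |> filter(.data$selected) |>
      arrange(.data$gene)
    lines <- c(lines, "", sprintf(
      "Switched genes (%s; delta >= %.2g, p < %.2g):",
      outputs$switch_scan$params$sex,
      outputs$switch_scan$params$delta_threshold,
      outputs$switch_scan$params$alpha
    ))
    lines <- c(lines, if (nrow(res) == 0) "  none selected" else
      sprintf("  %-10s dP = %.3f p = %.3g  %s -> %s", res$gene,
              res$delta_pscore, res$p_value, res$state_ctrl, res$state_mzz))
  }
  if (!is.null(outputs$differential)) {
    res <- tidy(outputs$differential) |> filter(.data$significant) |>
      arrange(.data$gene)
    lines <- c(lines, "", sprintf("Differential genes (%s):",
                                  outputs$differential$params$contrast))
    lines <- c(lines, if (nrow(res) == 0) "  none selected" else
      sprintf("  %-10s log2FC = %+.2f p = %.3g", res$gene, res$log2fc,
              res$p_value))
  }
  if (!is.null(outputs$colony)) {
    pe <- outputs$colony$per_embryo |> arrange(.data$sample)
    lines <- c(lines, "", "Colony bisulfite methylation (per embryo, %):",
               sprintf("  %-6s %-5s %5.1f (%d unique / %d clones)",
                       pe$sample, pe$genotype, pe$pct, pe$n_unique,
                       pe$n_clones),
               sprintf("  group comparison: p = %.3g %s",
                       outputs$colony$comparison$p_value,
                       outputs$colony$comparison$stars))
  }
  lines
}
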