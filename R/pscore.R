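# P-score allelic-expression statistics and switch selection.

#' Filter genes by pooled allelic read count
#'
#' Restricts the analysis to genes with strictly more than `min_total` reads
#' summed over maternal and paternal alleles across the whole analysis set.
#' Retention is all-or-none per gene: either every row of a gene is kept or
#' none is.
#'
#' @param counts Tibble with `gene`, `sample`, `maternal_count`,
#'   `paternal_count`.
#' @param min_total Pooled-count threshold (strict `>`); default 10.
#' @return The filtered tibble.
#' @export
#' @examples
#' counts <- data.frame(gene = "g1", sample = c("F1", "F2"),
#'                      maternal_count = c(3, 2), paternal_count = c(4, 1))
#' filter_expressed_allelic(counts)   # 3+2+4+1 = 10, not > 10: dropped
filter_expressed_allelic <- function(counts, min_total = 10) {
  check_columns(counts, c("gene", "sample", "maternal_count",
                          "paternal_count"), "counts")
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) {
    warn("empty allelic count table; nothing to filter")
    return(counts)
  }
  keep <- counts |>
    group_by(.data$gene) |>
    summarise(total = sum(.data$maternal_count + .data$paternal_count)) |>
    filter(.data$total > min_total)
  semi_join(counts, keep, by = "gene")
}

#' Compute the P-score from allelic counts
#'
#' The P-score measures the paternal share of a gene's transcripts, centred at
#' zero: `P/(M + P) - 0.5`, where `P` and `M` are paternal- and
#' maternal-allele read counts. It is 0.5 for paternal-only expression, -0.5
#' for maternal-only, and 0 for balanced biallelic expression.
#'
#' @param counts Tibble with `gene`, `sample`, `maternal_count`,
#'   `paternal_count`; rows with `M + P = 0` are an error (filter first with
#'   [filter_expressed_allelic()]).
#' @return The input with a `pscore` column appended.
#' @export
#' @examples
#' compute_pscore(data.frame(gene = "Snrpn", sample = "F1",
#'                           maternal_count = 0, paternal_count = 120))
compute_pscore <- function(counts) {
  check_columns(counts, c("gene", "sample", "maternal_count",
                          "paternal_count"), "counts")
  counts <- as_tibble(counts)
  tot <- counts$maternal_count + counts$paternal_count
  if (any(tot == 0)) {
    bad <- counts[tot == 0, ]
    abort(paste0(
      "P-score undefined for records with zero total allelic counts (e.g. ",
      bad$gene[1], "/", bad$sample[1],
      "); apply filter_expressed_allelic() first."
    ))
  }
  mutate(counts, pscore = .data$paternal_count / tot - 0.5)
}

#' Absolute difference of group-mean P-scores
#'
#' @param scores_a,scores_b Numeric P-score vectors for the two groups.
#' @return Non-negative scalar `|mean(a) - mean(b)|`.
#' @export
#' @examples
#' delta_pscore(c(0.40, 0.45, 0.50), c(0.00, 0.05, -0.05))
delta_pscore <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    abort("both P-score groups must be non-empty")
  }
  abs(mean(scores_a) - mean(scores_b))
}

#' Kruskal-Wallis rank test across genotype groups
#'
#' Mid-rank/tie-corrected Kruskal-Wallis H with a chi-square p-value on
#' `k - 1` degrees of freedom. All-constant input (tie correction degenerate)
#' returns `H = 0`, `p = 1` by convention.
#'
#' @param values Numeric vector of P-scores (or any responses).
#' @param groups Grouping vector of the same length, at least two levels.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(c("a", "b", "c"), each = 3))
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort("kruskal_wallis needs at least two non-empty groups")
  }
  if (any(tabulate(droplevels(groups)) == 0)) {
    abort("kruskal_wallis: empty group")
  }
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = nlevels(droplevels(groups)) - 1L,
                  p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Exact binomial test of allelic balance
#'
#' Two-sided exact binomial test of the paternal read count against a null
#' proportion of 0.5 — the single-sample analogue of the P-score comparison.
#'
#' @param maternal_count,paternal_count Non-negative read counts with a
#'   positive sum; vectorised.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' binomial_allelic_test(0, 10)
binomial_allelic_test <- function(maternal_count, paternal_count) {
  tot <- maternal_count + paternal_count
  if (any(tot == 0)) abort("binomial test undefined for zero total counts")
  purrr::map2_dbl(paternal_count, tot,
                  ~ binom.test(.x, .y, p = 0.5)$p.value)
}

#' Classify the allelic state of a gene in one group
#'
#' Maps a group-mean P-score onto the verbal allelic-state vocabulary using
#' symmetric cutoffs: `|mean| < 0.1` biallelic, `[0.1, 0.25)` slightly,
#' `[0.25, 0.4)` preferential, `>= 0.4` monoallelic; the sign distinguishes
#' maternal (negative) from paternal (positive). Cutoffs are overridable and
#' recorded in downstream reports.
#'
#' @param scores Numeric P-scores of one gene in one group (non-empty).
#' @param cutoffs Increasing length-3 numeric: biallelic/slight, slight/
#'   preferential, preferential/monoallelic boundaries.
#' @return A single state label.
#' @export
#' @examples
#' classify_allelic_state(c(0.47, 0.49))
classify_allelic_state <- function(scores, cutoffs = c(0.1, 0.25, 0.4)) {
  if (length(scores) == 0) abort("cannot classify an empty score group")
  stopifnot(length(cutoffs) == 3, !is.unsorted(cutoffs))
  s <- mean(scores)
  grade <- findInterval(abs(s), cutoffs)
  side <- if (s >= 0) "paternal" else "maternal"
  c("biallelic", paste0("slightly_", side), paste0("preferential_", side),
    side)[grade + 1L]
}

#' Scan for allelic expression switches within one sex
#'
#' For every gene, runs the omnibus Kruskal-Wallis test of P-scores across the
#' three genotypes within the chosen sex, computes the absolute group-mean
#' P-score difference for the named genotype pair, and selects genes with
#' `delta >= delta_threshold` and omnibus `p < alpha`. Also classifies the
#' allelic state of each genotype group and assembles heatmap-ready matrices.
#'
#' @param pscores P-score table from [compute_pscore()].
#' @param samples Sample metadata (`sample`, `genotype`, `sex`).
#' @param sex `"F"` or `"M"`.
#' @param pair Length-2 genotype vector for the pairwise delta,
#'   e.g. `c("M+Z+", "M-Z-")`.
#' @param delta_threshold Minimum group-mean P-score difference (default 0.1).
#' @param alpha Omnibus significance level (default 0.05).
#' @param state_cutoffs Passed to [classify_allelic_state()].
#' @param adjust Optional p-value adjustment method (default `"none"`; the
#'   selection rule applies no multiple-testing correction, `"BH"` available).
#' @return A `switch_scan` object: `results` tibble (gene, delta_pscore,
#'   statistic, p_value, selected, per-genotype states), `matrix` of
#'   per-sample P-scores for selected genes (columns ordered M+Z+, M-Z+,
#'   M-Z-), `diff_matrix` of deviations from the reference (first `pair`)
#'   group mean, and the parameters used. Use [tidy()], [glance()],
#'   [autoplot()].
#' @export
select_switched_genes <- function(pscores, samples, sex, pair,
                                  delta_threshold = 0.1, alpha = 0.05,
                                  state_cutoffs = c(0.1, 0.25, 0.4),
                                  adjust = "none") {
  check_columns(pscores, c("gene", "sample", "pscore"), "pscores")
  check_columns(samples, c("sample", "genotype", "sex"), "samples")
  check_sex(sex)
  check_genotype(pair)
  stopifnot(length(pair) == 2, length(sex) == 1)
  dat <- inner_join(as_tibble(pscores), as_tibble(samples), by = "sample") |>
    filter(.data$sex == .env$sex)
  present <- unique(dat$genotype)
  missing_geno <- setdiff(GENOTYPES, present)
  if (length(missing_geno) > 0) {
    abort(paste0("sex ", sex, " subset lacks genotype group(s): ",
                 paste(missing_geno, collapse = ", ")))
  }
  results <- dat |>
    group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      gene_missing <- setdiff(GENOTYPES, unique(d$genotype))
      if (length(gene_missing) > 0) {
        abort(paste0("gene ", key$gene, " has no P-scores in genotype ",
                     paste(gene_missing, collapse = ", ")))
      }
      kw <- kruskal_wallis(d$pscore, d$genotype)
      a <- d$pscore[d$genotype == pair[1]]
      b <- d$pscore[d$genotype == pair[2]]
      states <- vapply(GENOTYPES, function(g) {
        classify_allelic_state(d$pscore[d$genotype == g], state_cutoffs)
      }, character(1))
      tibble(
        delta_pscore = delta_pscore(a, b), statistic = kw$statistic,
        p_value = kw$p_value,
        state_ctrl = states[1], state_mz = states[2], state_mzz = states[3]
      )
    }) |>
    ungroup() |>
    mutate(
      p_adjusted = stats::p.adjust(.data$p_value, method = adjust),
      selected = .data$delta_pscore >= delta_threshold &
        .data$p_adjusted < alpha,
      comparison = paste0(sex, ":", pair[1], " vs ", sex, ":", pair[2])
    )
  ord_samples <- dat |>
    distinct(.data$sample, .data$genotype) |>
    arrange(factor(.data$genotype, levels = GENOTYPES), .data$sample)
  sel_genes <- results$gene[results$selected]
  mat <- pscore_matrix(dat, sel_genes, ord_samples$sample)
  ref_mean <- dat |>
    filter(.data$genotype == pair[1]) |>
    group_by(.data$gene) |>
    summarise(ref = mean(.data$pscore))
  diff_mat <- mat - ref_mean$ref[match(rownames(mat), ref_mean$gene)]
  structure(
    list(results = results, matrix = mat, diff_matrix = diff_mat,
         samples = ord_samples,
         params = list(sex = sex, pair = pair,
                       delta_threshold = delta_threshold, alpha = alpha,
                       state_cutoffs = state_cutoffs, adjust = adjust)),
    class = "switch_scan"
  )
}

pscore_matrix <- function(dat, genes, sample_order) {
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_order),
                dimnames = list(genes, sample_order))
  sub <- dat[dat$gene %in% genes, ]
  mat[cbind(match(sub$gene, genes), match(sub$sample, sample_order))] <-
    sub$pscore
  mat
}

#' @export
print.switch_scan <- function(x, ...) {
  cat("Allelic switch scan (", x$params$sex, "; ",
      x$params$pair[1], " vs ", x$params$pair[2], ")\n", sep = "")
  cat("  ", nrow(x$results), " genes tested, ", sum(x$results$selected),
      " selected at delta >= ", x$params$delta_threshold, ", p < ",
      x$params$alpha, "\n", sep = "")
  invisible(x)
}

#' @rdname select_switched_genes
#' @param x,object A `switch_scan` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.switch_scan <- function(x, ...) x$results

#' @rdname select_switched_genes
#' @exportS3Method generics::glance
glance.switch_scan <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results), n_selected = sum(x$results$selected),
    sex = x$params$sex,
    comparison = paste(x$params$pair, collapse = " vs "),
    delta_threshold = x$params$delta_threshold, alpha = x$params$alpha
  )
}

#' @rdname select_switched_genes
#' @param intensity_difference Plot deviations from the reference-group mean
#'   instead of raw per-sample P-scores.
#' @exportS3Method ggplot2::autoplot
autoplot.switch_scan <- function(object, intensity_difference = FALSE, ...) {
  mat <- if (intensity_difference) object$diff_matrix else object$matrix
  if (nrow(mat) == 0) abort("no selected genes to plot")
  df <- as_tibble(mat, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "pscore") |>
    mutate(sample = factor(.data$sample, levels = colnames(mat)),
           gene = factor(.data$gene, levels = rev(rownames(mat))))
  lim <- if (intensity_difference) c(-1, 1) else c(-0.5, 0.5)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$gene,
                                   fill = .data$pscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = lim,
                                  name = if (intensity_difference)
                                    "P-score\ndifference" else "P-score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
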