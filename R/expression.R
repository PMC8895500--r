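# TPM quantification, fold change and the group statistics.

#' Compute transcripts-per-million (TPM)
#'
#' Length-normalises counts within each sample:
#' `tpm_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`, so TPM
#' sums to one million per sample. A sample with no counts at all gets TPM 0
#' everywhere, with a warning.
#'
#' @param counts Tibble `gene`, `sample`, `count` (non-negative).
#' @param lengths Tibble `gene`, `length_bp` (> 0) covering every gene.
#' @return Tibble `gene`, `sample`, `count`, `length_bp`, `tpm`.
#' @export
#' @examples
#' compute_tpm(
#'   data.frame(gene = c("a", "b"), sample = "s1", count = c(100, 200)),
#'   data.frame(gene = c("a", "b"), length_bp = c(1000, 2000))
#' )
compute_tpm <- function(counts, lengths) {
  check_columns(counts, c("gene", "sample", "count"), "counts")
  check_columns(lengths, c("gene", "length_bp"), "lengths")
  if (any(counts$count < 0)) abort("counts must be non-negative")
  if (any(lengths$length_bp <= 0)) abort("gene lengths must be positive")
  missing <- setdiff(unique(counts$gene), lengths$gene)
  if (length(missing) > 0) {
    abort(paste0("no length for gene(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(counts) |>
    left_join(as_tibble(lengths), by = "gene") |>
    group_by(.data$sample) |>
    mutate(
      rate = .data$count / .data$length_bp,
      tpm = if (sum(.data$rate) == 0) 0 else
        .data$rate / sum(.data$rate) * 1e6
    ) |>
    ungroup() |>
    select(-"rate")
  dead <- out |>
    group_by(.data$sample) |>
    summarise(all_zero = all(.data$count == 0)) |>
    filter(.data$all_zero)
  if (nrow(dead) > 0) {
    warn(paste0("sample(s) with no counts, TPM set to 0: ",
                paste(dead$sample, collapse = ", ")))
  }
  out
}

#' Filter genes to the quantifiable set
#'
#' Keeps genes with strictly more than `min_reads` raw counts pooled across
#' samples and TPM strictly above `min_tpm` in at least one sample.
#'
#' @param expression Output of [compute_tpm()].
#' @param min_reads Pooled raw-count threshold (strict `>`); default 10.
#' @param min_tpm Per-sample TPM threshold (strict `>`); default 1.0.
#' @return The filtered expression tibble.
#' @export
filter_quantifiable <- function(expression, min_reads = 10, min_tpm = 1.0) {
  check_columns(expression, c("gene", "sample", "count", "tpm"), "expression")
  if (nrow(expression) == 0) return(as_tibble(expression))
  keep <- as_tibble(expression) |>
    group_by(.data$gene) |>
    summarise(pooled = sum(.data$count), max_tpm = max(.data$tpm)) |>
    filter(.data$pooled > min_reads, .data$max_tpm > min_tpm)
  semi_join(as_tibble(expression), keep, by = "gene")
}

#' Log2 fold change of group-mean TPM
#'
#' `log2((mean(a) + pseudocount) / (mean(b) + pseudocount))`. The default
#' pseudocount of 0 computes fold change on raw TPM ratios.
#'
#' @param group_a,group_b Numeric TPM vectors (non-empty).
#' @param pseudocount Non-negative stabiliser added to both means.
#' @return Scalar log2 fold change.
#' @export
#' @examples
#' log2_fold_change(c(210, 190), c(110, 90))
log2_fold_change <- function(group_a, group_b, pseudocount = 0) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  stopifnot(pseudocount >= 0)
  denom <- mean(group_b) + pseudocount
  if (denom == 0) {
    abort("log2 fold change undefined: mean(group_b) + pseudocount is zero")
  }
  log2((mean(group_a) + pseudocount) / denom)
}

#' Parse a contrast string into two sample groups
#'
#' Contrasts are written `"F:M-Z- vs F:M+Z+"` (genotype contrast within a
#' sex) or `"F:M+Z+ vs M:M+Z+"` (sex contrast within a genotype).
#'
#' @param contrast Contrast string.
#' @param samples Sample metadata.
#' @return List with `label`, `samples_a`, `samples_b`.
#' @export
parse_contrast <- function(contrast, samples) {
  check_columns(samples, c("sample", "genotype", "sex"), "samples")
  sides <- strsplit(contrast, "\\s+vs\\s+")[[1]]
  if (length(sides) != 2) {
    abort("contrast must be of the form \"SEX:GENOTYPE vs SEX:GENOTYPE\"")
  }
  pick <- function(side) {
    parts <- strsplit(side, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste0("malformed contrast side: ", side))
    check_sex(parts[1]); check_genotype(parts[2])
    samples$sample[samples$sex == parts[1] & samples$genotype == parts[2]]
  }
  list(label = contrast, samples_a = pick(sides[1]), samples_b = pick(sides[2]))
}

#' Differential expression of imprinted genes between two groups
#'
#' Per gene, computes the log2 fold change of group-mean TPM and a Welch
#' t-test on `log2(TPM + 1)`, and flags genes significant when
#' `|log2FC| > fc_threshold` (strict) and `p < alpha`. The fold-change gate is
#' 0.5 for genotype contrasts and 0.3 for the female-versus-male control
#' comparison in the source design; set `fc_threshold` accordingly.
#'
#' @param expression Output of [compute_tpm()] (optionally pre-filtered with
#'   [filter_quantifiable()]).
#' @param samples Sample metadata.
#' @param contrast Contrast string, see [parse_contrast()].
#' @param fc_threshold Absolute log2FC threshold (strict `>`).
#' @param alpha Significance level.
#' @param adjust P-value adjustment method (default `"none"`).
#' @return A `differential_scan` object with a `results` tibble (`gene`,
#'   `log2fc`, `p_value`, `significant`, `comparison`) and a per-sample
#'   `matrix` of `log2(TPM + 1)` for significant genes. Use [tidy()],
#'   [glance()], [autoplot()].
#' @export
differential_genes <- function(expression, samples, contrast,
                               fc_threshold = 0.5, alpha = 0.05,
                               adjust = "none") {
  check_columns(expression, c("gene", "sample", "tpm"), "expression")
  grp <- parse_contrast(contrast, samples)
  if (length(grp$samples_a) < 2 || length(grp$samples_b) < 2) {
    abort("each contrast group needs at least two samples")
  }
  expr <- as_tibble(expression)
  results <- expr |>
    filter(.data$sample %in% c(grp$samples_a, grp$samples_b)) |>
    group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      a <- d$tpm[d$sample %in% grp$samples_a]
      b <- d$tpm[d$sample %in% grp$samples_b]
      if (length(a) < 2 || length(b) < 2) {
        abort(paste0("gene ", key$gene, " lacks replicates in one group"))
      }
      la <- log2(a + 1); lb <- log2(b + 1)
      p <- if (stats::sd(c(la - mean(la), lb - mean(lb))) == 0) {
        if (mean(la) == mean(lb)) 1 else 0
      } else {
        t.test(la, lb)$p.value
      }
      tibble(log2fc = log2_fold_change(a, b), p_value = p)
    }) |>
    ungroup() |>
    mutate(
      p_adjusted = stats::p.adjust(.data$p_value, method = adjust),
      significant = abs(.data$log2fc) > fc_threshold &
        .data$p_adjusted < alpha,
      comparison = grp$label
    )
  ord <- c(grp$samples_a, grp$samples_b)
  sig <- results$gene[results$significant]
  sub <- expr |> filter(.data$gene %in% sig, .data$sample %in% ord)
  mat <- matrix(NA_real_, length(sig), length(ord),
                dimnames = list(sig, ord))
  mat[cbind(match(sub$gene, sig), match(sub$sample, ord))] <-
    log2(sub$tpm + 1)
  structure(
    list(results = results, matrix = mat,
         params = list(contrast = grp$label, fc_threshold = fc_threshold,
                       alpha = alpha, adjust = adjust)),
    class = "differential_scan"
  )
}

#' @export
print.differential_scan <- function(x, ...) {
  cat("Differential expression scan (", x$params$contrast, ")\n", sep = "")
  cat("  ", nrow(x$results), " genes tested, ", sum(x$results$significant),
      " significant at |log2FC| > ", x$params$fc_threshold, ", p < ",
      x$params$alpha, "\n", sep = "")
  invisible(x)
}

#' @rdname differential_genes
#' @param x,object A `differential_scan` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.differential_scan <- function(x, ...) x$results

#' @rdname differential_genes
#' @exportS3Method generics::glance
glance.differential_scan <- function(x, ...) {
  tibble(n_genes = nrow(x$results),
         n_significant = sum(x$results$significant),
         comparison = x$params$contrast,
         fc_threshold = x$params$fc_threshold, alpha = x$params$alpha)
}

#' @rdname differential_genes
#' @exportS3Method ggplot2::autoplot
autoplot.differential_scan <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$fc_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (TPM)", y = "-log10 p",
                  title = object$params$contrast) +
    ggplot2::theme_minimal()
}

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Fits a one-way ANOVA across at least three groups and reports all pairwise
#' least-significant-difference t-tests using the pooled error mean square on
#' `N - k` degrees of freedom. Pairwise p-values are reported for every pair
#' and flagged `protected = FALSE` when the omnibus F-test is not significant
#' at `alpha` (unprotected LSD inflates the family error rate).
#'
#' @param data Data frame with a response and a grouping column.
#' @param value,group Column names (tidy-eval) of response and group.
#' @param alpha Protection level for the omnibus gate.
#' @return A `fisher_lsd` object: `omnibus` (F, df, p) and `pairwise`
#'   (group means, t, df, p, stars, protected). Use [tidy()]/[glance()].
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 9, 10, 11),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' anova_fisher_lsd(d, y, g)
anova_fisher_lsd <- function(data, value, group, alpha = 0.05) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  y <- dplyr::pull(data, !!value)
  g <- as.factor(dplyr::pull(data, !!group))
  g <- droplevels(g)
  sizes <- table(g)
  if (length(sizes) < 3) {
    abort("anova_fisher_lsd needs at least three groups; use two_tailed_ttest() for two")
  }
  if (any(sizes < 2)) abort("every group needs at least two values")
  if (length(unique(y)) == 1) {
    # all-constant response: no variance to partition
    pairs <- utils::combn(levels(g), 2)
    pairwise <- tibble(
      group_a = pairs[1, ], group_b = pairs[2, ], mean_a = y[1], mean_b = y[1],
      statistic = 0, df = length(y) - length(sizes), p_value = 1,
      stars = "ns", protected = FALSE
    )
    return(structure(
      list(omnibus = tibble(statistic = 0, df1 = length(sizes) - 1L,
                            df2 = length(y) - length(sizes), p_value = 1),
           pairwise = pairwise, alpha = alpha),
      class = "fisher_lsd"
    ))
  }
  an <- stats::anova(stats::lm(y ~ g))
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  omnibus <- tibble(statistic = an["g", "F value"],
                    df1 = an["g", "Df"], df2 = df_err,
                    p_value = an["g", "Pr(>F)"])
  means <- tapply(y, g, mean)
  pairs <- utils::combn(levels(g), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(mse * (1 / sizes[[a]] + 1 / sizes[[b]]))
    tstat <- if (se == 0) {
      if (means[[a]] == means[[b]]) 0 else Inf * sign(means[[a]] - means[[b]])
    } else {
      (means[[a]] - means[[b]]) / se
    }
    p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df_err)
    tibble(group_a = a, group_b = b, mean_a = means[[a]], mean_b = means[[b]],
           statistic = tstat, df = df_err, p_value = p)
  }) |>
    mutate(stars = star_label(.data$p_value),
           protected = omnibus$p_value < alpha)
  structure(list(omnibus = omnibus, pairwise = pairwise, alpha = alpha),
            class = "fisher_lsd")
}

#' @export
print.fisher_lsd <- function(x, ...) {
  cat("One-way ANOVA: F(", x$omnibus$df1, ", ", x$omnibus$df2, ") = ",
      signif(x$omnibus$statistic, 4), ", p = ",
      signif(x$omnibus$p_value, 3), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @rdname anova_fisher_lsd
#' @param x A `fisher_lsd` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fisher_lsd <- function(x, ...) x$pairwise

#' @rdname anova_fisher_lsd
#' @exportS3Method generics::glance
glance.fisher_lsd <- function(x, ...) x$omnibus

#' Two-tailed pooled-variance Student t-test
#'
#' Classic two-sided Student t-test with pooled variance, as used for
#' female-versus-male comparisons within a genotype. Degenerate inputs with
#' zero pooled variance return `p = 1` when the means are equal and `p = 0`
#' (flagged `"degenerate"`) when they differ.
#'
#' @param group_a,group_b Numeric vectors, each with at least two values.
#' @return One-row tibble `mean_a`, `mean_b`, `statistic`, `df`, `p_value`,
#'   `stars`, `note`.
#' @export
#' @examples
#' two_tailed_ttest(c(90, 88, 92), c(10, 12, 9))
two_tailed_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least two values")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
    (n1 + n2 - 2)
  if (pooled == 0) {
    equal <- mean(group_a) == mean(group_b)
    return(tibble(
      mean_a = mean(group_a), mean_b = mean(group_b),
      statistic = if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b)),
      df = n1 + n2 - 2, p_value = if (equal) 1 else 0,
      stars = star_label(if (equal) 1 else 0), note = "degenerate"
    ))
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  tibble(mean_a = mean(group_a), mean_b = mean(group_b),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, stars = star_label(tt$p.value),
         note = NA_character_)
}
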