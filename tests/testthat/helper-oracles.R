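# Independent brute-force oracles. These re-derive each statistic from first
# principles (explicit ranking, sums of squares, tail enumeration) and are the
# reference the package implementations are checked against.

# Kruskal-Wallis H by explicit mid-ranking with tie correction, chi-square p.
oracle_kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  r <- rank(values) # mid-ranks
  n <- length(values)
  group_levels <- levels(droplevels(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(group_levels, function(g) {
      ri <- r[groups == g]
      length(ri) * (mean(ri) - (n + 1) / 2)^2
    }, numeric(1)))
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  k <- length(group_levels)
  list(statistic = h, p_value = pchisq(h, k - 1, lower.tail = FALSE))
}

# One-way ANOVA + Fisher LSD from textbook sums of squares.
oracle_anova_lsd <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  k <- nlevels(groups)
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  msb <- ss_between / df1
  mse <- ss_within / df2
  f <- msb / mse
  pairs <- utils::combn(levels(groups), 2)
  pairwise <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    t_stat <- (means[[a]] - means[[b]]) /
      sqrt(mse * (1 / sizes[[a]] + 1 / sizes[[b]]))
    list(group_a = a, group_b = b, statistic = t_stat,
         p_value = 2 * pt(-abs(t_stat), df2))
  })
  list(statistic = f, df1 = df1, df2 = df2,
       p_value = pf(f, df1, df2, lower.tail = FALSE), pairwise = pairwise,
       mse = mse)
}

# Exact two-sided binomial p by enumerating all outcomes at least as extreme
# (probability at most that of the observed outcome), null p = 0.5.
oracle_binomial_two_sided <- function(successes, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[successes + 1] * (1 + 1e-7)])
}

# Pooled-variance two-sided Student t from the direct formula.
oracle_pooled_ttest <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t_stat, p_value = 2 * pt(-abs(t_stat), n1 + n2 - 2))
}

# Naive per-site and per-region methylation recount over raw calls.
oracle_site_levels <- function(calls) {
  key <- paste(calls$sample, calls$chrom, calls$pos, sep = "\r")
  out <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    d <- calls[idx, ]
    data.frame(sample = d$sample[1], chrom = d$chrom[1], pos = d$pos[1],
               n_reads = nrow(d),
               level = mean(d$state == "methylated"))
  })
  do.call(rbind, unname(out))
}

oracle_icr_pct <- function(calls, start, end, min_reads = 3) {
  sites <- oracle_site_levels(calls)
  sites <- sites[sites$pos >= start & sites$pos < end &
                   sites$n_reads >= min_reads, ]
  if (nrow(sites) == 0) return(NA_real_)
  100 * mean(sites$level)
}

# Naive double loop over unique-clone CpG states.
oracle_clone_set_pct <- function(patterns) {
  meth <- 0
  total <- 0
  for (p in patterns) {
    for (ch in strsplit(p, "")[[1]]) {
      meth <- meth + (ch == "1")
      total <- total + 1
    }
  }
  100 * meth / total
}
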