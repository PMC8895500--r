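# shared internal helpers

#' Derive a deterministic child seed for a pipeline stage
#'
#' All stochastic stages draw from a child seed derived from one master seed and
#' the stage name, so stages can be rerun independently yet reproducibly.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "allelic_counts")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 2654435) %% 2147483629 + 1)
}

#' Significance star labels
#'
#' Maps p-values onto the conventional star annotation used in group-comparison
#' figures: `***` below 0.001, `**` below 0.01, `*` below 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
#' @examples
#' star_label(c(0.0004, 0.004, 0.03, 0.4))
star_label <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

check_genotype <- function(genotype) {
  bad <- setdiff(unique(genotype), GENOTYPES)
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid genotype(s): ", paste(bad, collapse = ", "),
      ". The cross can only produce ", paste(GENOTYPES, collapse = ", "), "."
    ))
  }
  invisible(genotype)
}

check_sex <- function(sex) {
  bad <- setdiff(unique(sex), SEXES)
  if (length(bad) > 0) {
    abort(paste0("Invalid sex value(s): ", paste(bad, collapse = ", "),
                 ". Must be one of ", paste(SEXES, collapse = ", "), "."))
  }
  invisible(sex)
}

check_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) abort(paste0(what, " must be a data frame"))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_fraction <- function(x, name, allow_one = TRUE) {
  ok <- is.numeric(x) && all(x >= 0) && all(if (allow_one) x <= 1 else x < 1)
  if (!ok) abort(paste0("`", name, "` must lie in [0, 1",
                        if (allow_one) "]" else ")"))
  invisible(x)
}

# Normalise a per-(genotype, sex) parameter given either as a single number
# (applies to every group) or a data frame (genotype, sex, <value_col>).
normalise_group_param <- function(x, value_col, name) {
  if (is.numeric(x) && length(x) == 1L) {
    grid <- tidyr::expand_grid(genotype = GENOTYPES, sex = SEXES)
    grid[[value_col]] <- x
    return(grid)
  }
  check_columns(x, c("genotype", "sex", value_col), name)
  check_genotype(x$genotype)
  check_sex(x$sex)
  as_tibble(x[, c("genotype", "sex", value_col)])
}

# Look up a group-level parameter for each sample; errors name the gap.
lookup_group_param <- function(samples, param, value_col, context) {
  merged <- left_join(samples, param, by = c("genotype", "sex"))
  miss <- is.na(merged[[value_col]])
  if (any(miss)) {
    grp <- unique(paste0(merged$genotype[miss], "/", merged$sex[miss]))
    abort(paste0(context, ": no `", value_col, "` entry for group(s) ",
                 paste(grp, collapse = ", ")))
  }
  merged[[value_col]]
}
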