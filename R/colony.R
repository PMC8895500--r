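# Bacterial-colony bisulfite sequencing: clone calling, fingerprint
# deduplication and clone-set methylation.

#' Build an amplicon reference from its unconverted sequence
#'
#' Locates the CpG cytosines (a `C` immediately followed by `G`) and all other
#' cytosines of the reference. The non-CpG cytosines should read as T after
#' complete bisulfite conversion; where they are retained they form the
#' unconverted-C fingerprint used to tell clones apart.
#'
#' @param name Amplicon name.
#' @param sequence Unconverted reference DNA sequence (A/C/G/T).
#' @return An `amplicon_reference` object with 1-based `cpg_indices` and
#'   `non_cpg_c_indices`.
#' @export
#' @examples
#' ref <- amplicon_reference("amp", "ACGTCCGATC")
#' ref$cpg_indices
amplicon_reference <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    abort("amplicon sequence must contain only A/C/G/T")
  }
  chars <- strsplit(sequence, "")[[1]]
  c_pos <- which(chars == "C")
  is_cpg <- c_pos < length(chars) & chars[pmin(c_pos + 1L, length(chars))] == "G"
  cpg <- c_pos[is_cpg]
  if (length(cpg) == 0) abort("amplicon contains no CpG site")
  structure(
    list(name = name, sequence = sequence, cpg_indices = cpg,
         non_cpg_c_indices = c_pos[!is_cpg]),
    class = "amplicon_reference"
  )
}

#' Call clones from colony reads against an amplicon reference
#'
#' Positional comparison at amplicon scale (reads must match the reference
#' length). At each CpG cytosine, `C` is read as methylated and `T` as
#' unmethylated; retained non-CpG cytosines form the clone's unconverted-C
#' fingerprint, and the conversion rate is the fraction of non-CpG cytosines
#' that converted. Clones failing quality control — identity outside cytosine
#' positions below `min_identity`, conversion rate below `min_conversion`, or
#' an unreadable (non-C/T) base at a CpG — are flagged `qc_pass = FALSE` with
#' a reason, never silently dropped; length-mismatched reads are rejected the
#' same way.
#'
#' @param reads Tibble `read_id`, `sequence` (see [read_reads_fasta()]).
#' @param reference An [amplicon_reference()].
#' @param min_identity Minimum identity outside cytosine positions.
#' @param min_conversion Minimum non-CpG conversion rate.
#' @return Tibble, one row per read: `clone_id`, `pattern` (string of 0/1 per
#'   CpG in amplicon order), `fingerprint` (semicolon-joined retained non-CpG
#'   C positions, 1-based), `n_methylated`, `n_cpg`, `conversion_rate`,
#'   `identity`, `qc_pass`, `qc_reason`, `multiplicity` (1).
#' @export
call_clones <- function(reads, reference, min_identity = 0.9,
                        min_conversion = 0.95) {
  check_columns(reads, c("read_id", "sequence"), "reads")
  stopifnot(inherits(reference, "amplicon_reference"))
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  ref_len <- length(ref_chars)
  non_c <- setdiff(seq_len(ref_len),
                   c(reference$cpg_indices, reference$non_cpg_c_indices))
  purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    seq_i <- toupper(reads$sequence[i])
    chars <- strsplit(seq_i, "")[[1]]
    if (length(chars) != ref_len) {
      return(tibble(
        clone_id = reads$read_id[i], pattern = NA_character_,
        fingerprint = NA_character_, n_methylated = NA_integer_,
        n_cpg = length(reference$cpg_indices),
        conversion_rate = NA_real_, identity = NA_real_,
        qc_pass = FALSE, qc_reason = "length_mismatch", multiplicity = 1L
      ))
    }
    identity <- if (length(non_c) == 0) 1 else
      mean(chars[non_c] == ref_chars[non_c])
    cpg_base <- chars[reference$cpg_indices]
    pattern_bits <- dplyr::case_when(
      cpg_base == "C" ~ 1L, cpg_base == "T" ~ 0L, TRUE ~ NA_integer_
    )
    ncc <- reference$non_cpg_c_indices
    retained <- ncc[chars[ncc] == "C"]
    conversion_rate <- if (length(ncc) == 0) 1 else
      sum(chars[ncc] == "T") / length(ncc)
    reason <- if (identity < min_identity) "low_identity"
      else if (conversion_rate < min_conversion) "poor_conversion"
      else if (anyNA(pattern_bits)) "ambiguous_cpg"
      else NA_character_
    tibble(
      clone_id = reads$read_id[i],
      pattern = paste(ifelse(is.na(pattern_bits), "N", pattern_bits),
                      collapse = ""),
      fingerprint = paste(retained, collapse = ";"),
      n_methylated = sum(pattern_bits, na.rm = TRUE),
      n_cpg = length(reference$cpg_indices),
      conversion_rate = conversion_rate, identity = identity,
      qc_pass = is.na(reason), qc_reason = reason, multiplicity = 1L
    )
  })
}

#' Collapse clones indistinguishable by CpG pattern and fingerprint
#'
#' Clones sharing both the CpG methylation pattern and the unconverted-C
#' fingerprint cannot be told apart and are counted as one unique clone whose
#' multiplicity is the group size. Clones with the same CpG pattern but
#' different fingerprints remain separate. Only QC-passing clones enter the
#' unique set; the sum of multiplicities equals the number of QC-passing
#' input clones.
#'
#' @param clones Output of [call_clones()] (or a compatible tibble with
#'   `pattern`, `fingerprint`, `qc_pass`, `multiplicity`).
#' @return Tibble of unique clones: `clone_id` (representative), `pattern`,
#'   `fingerprint`, `n_methylated`, `n_cpg`, `multiplicity`, `member_ids`
#'   (list column).
#' @export
deduplicate_clones <- function(clones) {
  check_columns(clones, c("clone_id", "pattern", "fingerprint", "qc_pass",
                          "multiplicity"), "clones")
  clones <- as_tibble(clones)
  if ("n_cpg" %in% names(clones) &&
      dplyr::n_distinct(clones$n_cpg[clones$qc_pass]) > 1) {
    abort("clones come from amplicons with different CpG counts; deduplicate per amplicon")
  }
  passing <- filter(clones, .data$qc_pass)
  if (nrow(passing) == 0) {
    return(passing[, c("clone_id", "pattern", "fingerprint", "qc_pass",
                       "multiplicity")])
  }
  passing |>
    group_by(.data$pattern, .data$fingerprint) |>
    summarise(
      member_ids = list(.data$clone_id),
      clone_id = dplyr::first(.data$clone_id),
      multiplicity = sum(.data$multiplicity),
      .groups = "drop"
    ) |>
    mutate(
      n_methylated = vapply(strsplit(.data$pattern, ""),
                            function(b) sum(b == "1"), integer(1)),
      n_cpg = nchar(.data$pattern),
      qc_pass = TRUE
    ) |>
    select("clone_id", "pattern", "fingerprint", "n_methylated", "n_cpg",
           "multiplicity", "qc_pass", "member_ids") |>
    arrange(dplyr::desc(.data$multiplicity), .data$pattern)
}

#' Methylation percentage of a unique-clone set
#'
#' `100 x` methylated CpG states over all CpG states of the unique clones.
#' Each unique clone contributes once regardless of its multiplicity, per the
#' unique-clone formulation; set `weight_by_multiplicity = TRUE` for the
#' duplication-weighted variant.
#'
#' @param unique_clones Output of [deduplicate_clones()].
#' @param weight_by_multiplicity Weight clones by multiplicity (default off).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' clones <- data.frame(clone_id = c("a", "b"), pattern = c("1111100000", "1111111111"),
#'                      fingerprint = "", qc_pass = TRUE, multiplicity = 1)
#' clone_set_methylation(deduplicate_clones(clones))
clone_set_methylation <- function(unique_clones,
                                  weight_by_multiplicity = FALSE) {
  check_columns(unique_clones, c("pattern", "multiplicity"), "unique_clones")
  if (nrow(unique_clones) == 0) {
    abort("cannot compute methylation of an empty clone set")
  }
  bits <- strsplit(unique_clones$pattern, "")
  w <- if (weight_by_multiplicity) unique_clones$multiplicity
       else rep(1L, nrow(unique_clones))
  meth <- sum(purrr::map2_dbl(bits, w, ~ .y * sum(.x == "1")))
  total <- sum(purrr::map2_dbl(bits, w, ~ .y * length(.x)))
  100 * meth / total
}

#' Compare per-embryo clone-set methylation between two groups
#'
#' Two-tailed pooled Student t-test on per-embryo methylation percentages
#' with the conventional significance stars.
#'
#' @param pct_a,pct_b Numeric vectors of per-embryo percentages (>= 2 each).
#' @return One-row tibble from [two_tailed_ttest()].
#' @export
#' @examples
#' compare_clone_methylation(c(90, 88, 92), c(10, 12, 9))
compare_clone_methylation <- function(pct_a, pct_b) {
  two_tailed_ttest(pct_a, pct_b)
}

#' Render unique clones as a lollipop-style 0/1 matrix
#'
#' One row per unique clone prefixed by its multiplicity; one column per CpG
#' site in amplicon order, `1` methylated (filled circle), `0` unmethylated
#' (open circle). [parse_lollipop_matrix()] inverts the rendering.
#'
#' @param unique_clones Output of [deduplicate_clones()].
#' @return Tibble `multiplicity`, `cpg_1` ... `cpg_k`.
#' @export
render_lollipop_matrix <- function(unique_clones) {
  check_columns(unique_clones, c("pattern", "multiplicity"), "unique_clones")
  if (nrow(unique_clones) == 0) abort("no unique clones to render")
  bits <- strsplit(unique_clones$pattern, "")
  k <- length(bits[[1]])
  mat <- do.call(rbind, lapply(bits, as.integer))
  colnames(mat) <- paste0("cpg_", seq_len(k))
  dplyr::bind_cols(tibble(multiplicity = unique_clones$multiplicity),
                   as_tibble(mat))
}

#' @rdname render_lollipop_matrix
#' @param matrix A tibble produced by [render_lollipop_matrix()].
#' @export
parse_lollipop_matrix <- function(matrix) {
  check_columns(matrix, "multiplicity", "matrix")
  cpg_cols <- grep("^cpg_", names(matrix), value = TRUE)
  if (length(cpg_cols) == 0) abort("no cpg_* columns to parse")
  patterns <- apply(as.data.frame(matrix)[, cpg_cols, drop = FALSE], 1,
                    paste, collapse = "")
  tibble(pattern = unname(patterns),
         multiplicity = as.integer(matrix$multiplicity))
}

#' Lollipop plot of a unique-clone set
#'
#' @param unique_clones Output of [deduplicate_clones()].
#' @return A ggplot object: filled points are methylated CpGs.
#' @export
plot_lollipop <- function(unique_clones) {
  mat <- render_lollipop_matrix(unique_clones)
  df <- mat |>
    mutate(clone = paste0(.data$multiplicity, "x clone ", row_number())) |>
    tidyr::pivot_longer(dplyr::starts_with("cpg_"), names_to = "site",
                        values_to = "methylated") |>
    mutate(site = as.integer(sub("cpg_", "", .data$site)),
           clone = factor(.data$clone, levels = rev(unique(.data$clone))))
  ggplot2::ggplot(df, ggplot2::aes(.data$site, .data$clone)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$clone), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(fill = factor(.data$methylated)),
                        shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               name = NULL,
                               labels = c(`0` = "unmethylated",
                                          `1` = "methylated")) +
    ggplot2::labs(x = "CpG site", y = NULL) +
    ggplot2::theme_minimal()
}
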