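# Resistance-assay statistics (mutation frequencies, medians, rank-sum
# comparisons) and marker-gene clone mutation classification.

#' Per-culture mutation frequencies
#'
#' The mutation frequency of a culture is the ratio of resistant colonies
#' to viable cells plated from the same culture (this is the frequency
#' estimator, deliberately not a Luria-Delbruck mutation-rate estimate).
#'
#' @param counts Tibble with columns `group`, `colonies`, `viable_cells`
#'   and optionally `culture` and `dilution_factor` (default 1);
#'   `viable_cells` is the viable count represented on the selective plate
#'   before dilution correction.
#' @return Tibble with one row per culture and an added `frequency` column
#'   (`colonies / (viable_cells * dilution_factor)`).
#' @seealso [summarize_frequencies()], [compare_frequencies()]
#' @export
mutation_frequency <- function(counts) {
  check_columns(counts, c("group", "colonies", "viable_cells"), "`counts`")
  counts <- tibble::as_tibble(counts)
  if (!"dilution_factor" %in% names(counts)) counts$dilution_factor <- 1
  if (any(counts$viable_cells <= 0) || any(counts$dilution_factor <= 0)) {
    abort("`viable_cells` and `dilution_factor` must be positive.",
          class = "deamscan_invalid_culture")
  }
  if (any(counts$colonies < 0) || any(counts$colonies != round(counts$colonies))) {
    abort("`colonies` must be non-negative integers.",
          class = "deamscan_invalid_argument")
  }
  dplyr::mutate(counts, frequency = .data$colonies /
                  (.data$viable_cells * .data$dilution_factor))
}

#' Group medians of mutation frequencies
#'
#' @param freqs A [mutation_frequency()] result.
#' @return Tibble with `group`, `median_frequency`, `n_cultures`.
#' @export
summarize_frequencies <- function(freqs) {
  check_columns(freqs, c("group", "frequency"), "`freqs`")
  dplyr::summarise(dplyr::group_by(freqs, .data$group),
                   median_frequency = median(.data$frequency),
                   n_cultures = dplyr::n(), .groups = "drop")
}

#' Compare mutation frequencies between two groups
#'
#' Two-tailed Wilcoxon rank-sum test for unpaired per-culture frequencies:
#' exact enumeration when both groups have at most 10 cultures and no tied
#' values, otherwise the normal approximation with tie-corrected variance
#' and continuity correction. Also reports the ratio of group medians.
#'
#' @param freqs A [mutation_frequency()] result (or any tibble with
#'   `group` and `frequency`).
#' @param a,b Group labels: the comparison is `a` versus `b`, with the
#'   fold-change `median(a) / median(b)`.
#' @return One-row tibble: sample sizes, `statistic` (rank-sum W),
#'   `p_value`, `method`, group medians, `fold_of_medians` (`NA` with
#'   `fold_flag = "zero_denominator_median"` when `median(b)` is 0).
#' @export
compare_frequencies <- function(freqs, a, b) {
  check_columns(freqs, c("group", "frequency"), "`freqs`")
  x <- freqs$frequency[freqs$group == a]
  y <- freqs$frequency[freqs$group == b]
  if (length(x) < 3L || length(y) < 3L) {
    abort("each group needs at least 3 cultures.",
          class = "deamscan_invalid_design")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= 10L && length(y) <= 10L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  p_value <- wt$p.value
  if (!is.finite(p_value)) p_value <- 1  # complete ties: no evidence at all
  med_a <- median(x)
  med_b <- median(y)
  tibble::tibble(
    group_a = a, group_b = b, n_a = length(x), n_b = length(y),
    statistic = unname(wt$statistic),
    p_value = min(p_value, 1),
    method = if (use_exact) "exact" else "normal_approximation",
    median_a = med_a, median_b = med_b,
    fold_of_medians = if (med_b > 0) med_a / med_b else NA_real_,
    fold_flag = if (med_b > 0) NA_character_ else "zero_denominator_median"
  )
}

#' Classify the substitution carried by a sequenced clone
#'
#' Compares a clone sequence to its reference (ungapped, equal lengths),
#' expecting the single substitution typical of one resistant colony per
#' culture. The call is annotated with collapsed pair notation, the
#' collapsed trinucleotide context, and - when a reading frame is supplied -
#' a codon label in the marker-gene style `"S512 (tct)"` (wild-type residue
#' letter, residue number, lower-case wild-type codon).
#'
#' @param clone_seq,ref_seq Equal-length DNA strings.
#' @param frame_offset Number of bases before the first complete codon
#'   (0-based; `NULL` skips codon labelling).
#' @param residue_offset Added to the in-fragment residue number so a toy
#'   fragment can carry gene-level numbering (default 0).
#' @param gene Optional gene label carried into the output.
#' @param structure Optional tibble (`position`, `site_class` in
#'   loop/stem/linear) annotating each position's secondary-structure
#'   class; unannotated positions report `"unknown"`.
#' @param strict Error on clones with more than one substitution (default
#'   `TRUE`); otherwise all substitutions are returned.
#' @return Tibble with zero rows for an identical clone, else one row per
#'   substitution: `gene`, `position`, `ref_base`, `obs_base`,
#'   `pair_notation`, `triplet_context`, `codon_label`, `structure_site`.
#' @export
classify_clone_mutation <- function(clone_seq, ref_seq, frame_offset = NULL,
                                    residue_offset = 0, gene = NA_character_,
                                    structure = NULL, strict = TRUE) {
  if (nchar(clone_seq) != nchar(ref_seq)) {
    abort("clone and reference sequences must have equal length.",
          class = "deamscan_malformed_input")
  }
  L <- nchar(ref_seq)
  cs <- stringi::stri_sub(toupper(clone_seq), 1:L, 1:L)
  rs <- stringi::stri_sub(toupper(ref_seq), 1:L, 1:L)
  pos <- which(cs != rs)
  empty <- tibble::tibble(gene = character(), position = integer(),
                          ref_base = character(), obs_base = character(),
                          pair_notation = character(),
                          triplet_context = character(),
                          codon_label = character(),
                          structure_site = character())
  if (!length(pos)) return(empty)
  if (length(pos) > 1L && strict) {
    abort(sprintf("clone carries %d substitutions; expected one (set strict = FALSE to keep all).",
                  length(pos)),
          class = "deamscan_multi_hit")
  }
  ctx <- ifelse(pos > 1L & pos < L,
                paste0(rs[pmax(pos - 1L, 1L)], rs[pos], rs[pmin(pos + 1L, L)]),
                NA_character_)
  codon_label <- rep(NA_character_, length(pos))
  if (!is.null(frame_offset)) {
    ci <- (pos - frame_offset - 1L) %/% 3L        # 0-based codon index
    cstart <- frame_offset + 3L * ci + 1L
    ok <- cstart >= 1L & cstart + 2L <= L & ci >= 0L
    wt_codon <- ifelse(ok, substr(toupper(ref_seq), cstart, cstart + 2L),
                       NA_character_)
    aa <- ifelse(is.na(wt_codon), NA_character_,
                 unname(Biostrings::GENETIC_CODE[wt_codon]))
    codon_label <- ifelse(is.na(aa), NA_character_,
                          sprintf("%s%d (%s)", aa, ci + 1L + residue_offset,
                                  tolower(wt_codon)))
  }
  site <- rep("unknown", length(pos))
  if (!is.null(structure)) {
    check_columns(structure, c("position", "site_class"), "`structure`")
    idx <- match(pos, structure$position)
    site[!is.na(idx)] <- structure$site_class[idx[!is.na(idx)]]
  }
  tibble::tibble(
    gene = gene, position = pos, ref_base = rs[pos], obs_base = cs[pos],
    pair_notation = collapse_type(rs[pos], cs[pos]),
    triplet_context = ifelse(is.na(ctx), NA_character_,
                             collapse_context(ctx)),
    codon_label = codon_label, structure_site = site
  )
}

#' Fraction of deamination-type mutations at hairpin-loop sites
#'
#' Restricts clone calls to the two deamination classes (C:G>T:A and
#' A:T>G:C) and reports the fraction located at loop-annotated positions.
#'
#' @param calls A [classify_clone_mutation()]-style tibble (columns
#'   `position`, `pair_notation`).
#' @param structure Tibble (`position`, `site_class` in loop/stem/linear)
#'   covering every deamination call position.
#' @return One-row tibble: `n_deamination`, `n_loop`, `fraction` (`NA` with
#'   `flag = "no_deamination_calls"` when the restricted set is empty).
#' @export
structure_site_fraction <- function(calls, structure) {
  check_columns(calls, c("position", "pair_notation"), "`calls`")
  check_columns(structure, c("position", "site_class"), "`structure`")
  deam <- calls[calls$pair_notation %in% c("C:G>T:A", "A:T>G:C"), ]
  if (!nrow(deam)) {
    return(tibble::tibble(n_deamination = 0L, n_loop = 0L,
                          fraction = NA_real_,
                          flag = "no_deamination_calls"))
  }
  idx <- match(deam$position, structure$position)
  if (anyNA(idx)) {
    abort("some deamination call positions lack a structure annotation.",
          class = "deamscan_missing_annotation")
  }
  cls <- structure$site_class[idx]
  tibble::tibble(n_deamination = nrow(deam),
                 n_loop = sum(cls == "loop"),
                 fraction = mean(cls == "loop"),
                 flag = NA_character_)
}
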