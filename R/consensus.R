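# Rolling-circle consensus calling: quality filtering, tandem-period
# detection and per-bin plurality voting, turning each tandem read into one
# error-corrected consensus fragment.

#' Quality-control and consensus-calling parameters
#'
#' @param min_mean_quality Reads with mean Phred below this are dropped
#'   (default 20).
#' @param quality_mask_threshold Individual bases below this Phred are
#'   masked: excluded from voting without dropping the read (default 20).
#' @param min_copies Minimum unmasked observations per consensus position;
#'   thinner positions are called N (default 2, must be >= 2).
#' @param max_period_mismatch Maximum self-offset mismatch fraction for a
#'   period to be accepted (default 0.1).
#' @param period_range Allowed tandem period (= circularised fragment
#'   length) range, default 90-120 bp.
#' @param min_overlap Minimum self-overlap used to score a period
#'   (default 25 bp).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_mean_quality = 20, quality_mask_threshold = 20,
                      min_copies = 2L, max_period_mismatch = 0.1,
                      period_range = c(90L, 120L), min_overlap = 25L) {
  check_scalar_number(min_mean_quality, "min_mean_quality", min = 0)
  check_scalar_number(quality_mask_threshold, "quality_mask_threshold", min = 0)
  check_scalar_number(min_copies, "min_copies", min = 2)
  check_scalar_number(max_period_mismatch, "max_period_mismatch", min = 0, max = 1)
  check_scalar_number(min_overlap, "min_overlap", min = 1)
  if (length(period_range) != 2L || period_range[1] > period_range[2] ||
      period_range[1] < 1) {
    abort("`period_range` must be an increasing pair of positive lengths.",
          class = "deamscan_invalid_argument")
  }
  structure(list(min_mean_quality = min_mean_quality,
                 quality_mask_threshold = as.integer(quality_mask_threshold),
                 min_copies = as.integer(min_copies),
                 max_period_mismatch = max_period_mismatch,
                 period_range = as.integer(period_range),
                 min_overlap = as.integer(min_overlap)),
            class = "qc_params")
}

#' Quality-filter reads
#'
#' Applies the read-level rule (mean Phred below `min_mean_quality` drops
#' the read) and counts per-base maskable positions (Phred below
#' `quality_mask_threshold`); masked bases stay in the read but are excluded
#' from consensus voting downstream.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`
#'   (Phred+33).
#' @param params A [qc_params()] object.
#' @return The input with added columns `mean_quality`, `n_masked`,
#'   `status` (`"kept"`/`"dropped"`) and `reason` (`NA` or
#'   `"low_mean_quality"`).
#' @export
qc_filter <- function(reads, params = qc_params()) {
  check_columns(reads, c("read_id", "sequence", "quality"), "`reads`")
  if (nrow(reads) &&
      any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("sequence and quality strings differ in length.",
          class = "deamscan_malformed_input")
  }
  dplyr::mutate(tibble::as_tibble(reads),
    mean_quality = cpp_mean_qual(.data$quality),
    n_masked = cpp_count_below(.data$quality, params$quality_mask_threshold),
    status = ifelse(.data$mean_quality < params$min_mean_quality,
                    "dropped", "kept"),
    reason = ifelse(.data$status == "dropped", "low_mean_quality",
                    NA_character_)
  )
}

#' Detect the tandem-repeat period of reads
#'
#' Scores every candidate period `p` in `period_range` by the mismatch
#' fraction between the read and itself shifted by `p`, and returns the
#' minimising period provided the fraction is at most
#' `max_period_mismatch` and the compared overlap is at least
#' `min_overlap`. Ties break toward the smaller period. `NA` means the read
#' has no credible tandem structure (abstention, not an error).
#'
#' @param sequence Character vector of read sequences.
#' @param params A [qc_params()] object.
#' @return Integer vector of periods (`NA` = abstain).
#' @export
detect_period <- function(sequence, params = qc_params()) {
  cpp_detect_period(sequence, params$period_range[1], params$period_range[2],
                    params$max_period_mismatch, params$min_overlap)
}

#' Fold tandem reads into consensus fragments
#'
#' Read positions are binned by position modulo the period; within each bin
#' the unmasked observations vote and the plurality base is called. Ties
#' resolve by the higher total Phred, then abstain as N; bins with fewer
#' than `min_copies` observations are N. Trailing partial repeat copies
#' vote like any other observation.
#'
#' @param sequence,quality Character vectors (equal lengths per element).
#' @param period Integer vector of tandem periods (`NA` skips the read).
#' @param params A [qc_params()] object.
#' @return Tibble with columns `consensus`, `support` (Phred+33-encoded
#'   per-base observation count, capped at 40), `copies_used`, `n_masked`,
#'   `n_called`, `n_tied`.
#' @export
fold_consensus <- function(sequence, quality, period, params = qc_params()) {
  if (any(nchar(sequence) != nchar(quality))) {
    abort("sequence and quality strings differ in length.",
          class = "deamscan_malformed_input")
  }
  bad <- !is.na(period) & period >= nchar(sequence)
  if (any(bad)) {
    abort("`period` must be smaller than the read length.",
          class = "deamscan_invalid_argument")
  }
  res <- cpp_fold_consensus(sequence, quality, as.integer(period),
                            params$quality_mask_threshold, params$min_copies)
  tibble::as_tibble(res)
}

#' Call consensus fragments for a batch of reads
#'
#' Runs [qc_filter()], [detect_period()] and [fold_consensus()] over a read
#' table and reports per-read status plus batch summary counts. The
#' consensus never consults any reference sequence. Deterministic for a
#' fixed input.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`, e.g.
#'   from [sim_rc_reads()] or [read_fastq()].
#' @param params A [qc_params()] object.
#' @return List with `consensus` (tibble: `read_id`, `sequence` (consensus),
#'   `support`, `period`, `copies_used`, `n_masked`, `status`) and `report`
#'   (one-row tibble of batch counts and `mean_copies_used`).
#' @export
call_consensus <- function(reads, params = qc_params()) {
  qc <- qc_filter(reads, params)
  n <- nrow(qc)
  period <- rep(NA_integer_, n)
  kept <- qc$status == "kept"
  period[kept] <- detect_period(qc$sequence[kept], params)
  folded <- kept & !is.na(period)
  out <- tibble::tibble(
    read_id = qc$read_id,
    sequence = NA_character_,
    support = NA_character_,
    period = period,
    copies_used = NA_integer_,
    n_masked = NA_integer_,
    status = dplyr::case_when(!kept ~ "low_mean_quality",
                              is.na(period) ~ "no_period",
                              TRUE ~ "ok")
  )
  if (any(folded)) {
    f <- cpp_fold_consensus(qc$sequence[folded], qc$quality[folded],
                            period[folded], params$quality_mask_threshold,
                            params$min_copies)
    out$sequence[folded] <- f$consensus
    out$support[folded] <- f$support
    out$copies_used[folded] <- f$copies_used
    out$n_masked[folded] <- f$n_masked
  }
  report <- tibble::tibble(
    n_reads = n,
    n_dropped_quality = sum(!kept),
    n_no_period = sum(kept & is.na(period)),
    n_folded = sum(folded),
    mean_copies_used = if (any(folded)) mean(out$copies_used[folded]) else 0
  )
  list(consensus = out, report = report)
}
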