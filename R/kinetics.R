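# Deamination kinetics: gel-lane fractions, single-exponential fits for the
# apparent rate constant k_app, fold-ratios, and oligonucleotide substrate
# annotation with cleavage read-out fragment sizes.

#' Fraction deaminated from gel band intensities
#'
#' The deaminated fraction of a lane is `cleaved / (cleaved + uncleaved)`,
#' the densitometry ratio behind every time-course point.
#'
#' @param lanes Tibble with columns `cleaved` and `uncleaved` (non-negative
#'   intensities; any other columns, e.g. `substrate_id`, `replicate`,
#'   `time_min`, pass through).
#' @return The input with an added `fraction` column.
#' @export
#' @examples
#' fraction_deaminated(tibble::tibble(time_min = 30, cleaved = 1, uncleaved = 3))
fraction_deaminated <- function(lanes) {
  check_columns(lanes, c("cleaved", "uncleaved"), "`lanes`")
  if (any(lanes$cleaved < 0 | lanes$uncleaved < 0)) {
    abort("intensities must be non-negative.",
          class = "deamscan_invalid_argument")
  }
  if (any(lanes$cleaved + lanes$uncleaved == 0)) {
    abort("a lane has zero total intensity; the fraction is undefined.",
          class = "deamscan_undefined_lane")
  }
  dplyr::mutate(tibble::as_tibble(lanes),
                fraction = .data$cleaved / (.data$cleaved + .data$uncleaved))
}

# fit one replicate time course; returns list(k, plateau, rms, flag)
.fit_one_exponential <- function(time_min, fraction, fix_plateau, replicate) {
  if (all(fraction == 0)) {
    return(list(k = 0, plateau = if (is.null(fix_plateau)) NA_real_ else fix_plateau,
                rms = 0, flag = "no_signal"))
  }
  p0 <- min(max(max(fraction), 0.05), 1)
  nz <- which(fraction > 0 & time_min > 0)
  nz <- nz[order(time_min[nz])][seq_len(min(2L, length(nz)))]
  k0 <- if (length(nz)) {
    mean(-log(pmax(1 - fraction[nz] / max(p0, fraction[nz] + 1e-9), 1e-9)) /
           time_min[nz])
  } else 1e-3
  k0 <- max(k0, 1e-9)
  d <- data.frame(t = time_min, f = fraction)
  fit <- tryCatch({
    if (is.null(fix_plateau)) {
      minpack.lm::nlsLM(f ~ P * (1 - exp(-k * t)), data = d,
                        start = list(P = p0, k = k0),
                        lower = c(P = 1e-9, k = 0), upper = c(P = 1, k = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(f ~ P0 * (1 - exp(-k * t)),
                        data = cbind(d, P0 = fix_plateau),
                        start = list(k = k0), lower = c(k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(sprintf("exponential fit failed for replicate %s: %s",
                  replicate, conditionMessage(e)),
          class = "deamscan_fit_failure")
  })
  cf <- coef(fit)
  list(k = unname(cf[["k"]]),
       plateau = if (is.null(fix_plateau)) unname(cf[["P"]]) else fix_plateau,
       rms = sqrt(mean(stats::residuals(fit)^2)), flag = NA_character_)
}

#' Fit single-exponential deamination kinetics
#'
#' Fits `F(t) = P * (1 - exp(-k * t))` to each replicate time course by
#' nonlinear least squares (Levenberg-Marquardt) and reports the apparent
#' rate constant as the replicate mean with its standard error across
#' replicates, matching the mean +/- SEM convention for independent
#' experiments. The plateau `P` is fitted within `(0, 1]` unless
#' `fix_plateau` pins it.
#'
#' @param timecourses Tibble with columns `replicate`, `time_min`,
#'   `fraction` (optionally `substrate_id`, which must be single-valued),
#'   e.g. from [sim_timecourse()] or [fraction_deaminated()].
#' @param fix_plateau Optional fixed plateau in `(0, 1]`; `NULL` (default)
#'   fits it.
#' @return Object of class `kinetic_fit` with `k_app` (per minute), `k_sem`
#'   (0 for a single replicate), `plateau`, `n_replicates`, `residual_rms`,
#'   per-replicate results in `$replicates`, and a `flag` (`"no_signal"`
#'   when every fraction is zero).
#' @seealso [tidy.kinetic_fit()], [glance.kinetic_fit()],
#'   [autoplot.kinetic_fit()], [fit_kapp_table()]
#' @export
fit_kapp <- function(timecourses, fix_plateau = NULL) {
  check_columns(timecourses, c("replicate", "time_min", "fraction"),
                "`timecourses`")
  substrate_id <- if ("substrate_id" %in% names(timecourses)) {
    u <- unique(timecourses$substrate_id)
    if (length(u) > 1L) {
      abort("`fit_kapp()` expects a single substrate; see `fit_kapp_table()`.",
            class = "deamscan_invalid_argument")
    }
    u
  } else NA_character_
  if (length(unique(timecourses$time_min)) < 3L) {
    abort("need at least 3 distinct time points.",
          class = "deamscan_invalid_argument")
  }
  if (any(timecourses$fraction < 0 | timecourses$fraction > 1)) {
    abort("fractions must lie in [0, 1].", class = "deamscan_invalid_argument")
  }
  if (!is.null(fix_plateau)) {
    check_scalar_number(fix_plateau, "fix_plateau", min = 1e-12, max = 1)
  }
  reps <- split(timecourses, timecourses$replicate)
  fits <- lapply(names(reps), function(rn) {
    d <- reps[[rn]]
    c(list(replicate = rn),
      .fit_one_exponential(d$time_min, d$fraction, fix_plateau, rn))
  })
  rep_tb <- tibble::tibble(
    replicate = vapply(fits, `[[`, "", "replicate"),
    k = vapply(fits, `[[`, 0, "k"),
    plateau = vapply(fits, `[[`, 0, "plateau"),
    residual_rms = vapply(fits, `[[`, 0, "rms"),
    flag = vapply(fits, `[[`, "", "flag")
  )
  n <- nrow(rep_tb)
  structure(list(
    substrate_id = substrate_id,
    k_app = mean(rep_tb$k),
    k_sem = if (n > 1L) sd(rep_tb$k) / sqrt(n) else 0,
    plateau = mean(rep_tb$plateau),
    n_replicates = n,
    residual_rms = sqrt(mean(rep_tb$residual_rms^2)),
    plateau_mode = if (is.null(fix_plateau)) "fitted"
                   else sprintf("fixed at %g", fix_plateau),
    flag = if (all(rep_tb$flag == "no_signal", na.rm = FALSE) &&
               !anyNA(rep_tb$flag)) "no_signal" else NA_character_,
    replicates = rep_tb,
    data = tibble::as_tibble(timecourses)
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit>%s k_app = %.3g +/- %.2g min^-1 (n = %d, plateau %s = %.3g)\n",
    if (is.na(x$substrate_id)) "" else paste0(" ", x$substrate_id),
    x$k_app, x$k_sem, x$n_replicates, x$plateau_mode, x$plateau))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A [fit_kapp()] result.
#' @param ... Unused.
#' @return One row per parameter with `estimate` and `std.error`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_app", "plateau"),
    estimate = c(x$k_app, x$plateau),
    std.error = c(x$k_sem,
                  if (x$n_replicates > 1L)
                    sd(x$replicates$plateau) / sqrt(x$n_replicates) else 0)
  )
}

#' One-row summary of a kinetic fit
#'
#' @param x A [fit_kapp()] result.
#' @param ... Unused.
#' @return One-row tibble: `substrate_id`, `k_app`, `k_sem`, `plateau`,
#'   `plateau_mode`, `n_replicates`, `residual_rms`, `flag`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(substrate_id = x$substrate_id, k_app = x$k_app,
                 k_sem = x$k_sem, plateau = x$plateau,
                 plateau_mode = x$plateau_mode,
                 n_replicates = x$n_replicates,
                 residual_rms = x$residual_rms, flag = x$flag)
}

#' Fit kinetics for every substrate in a table
#'
#' @param timecourses Tibble with a `substrate_id` column plus the columns
#'   required by [fit_kapp()].
#' @param fix_plateau Optional fixed plateau passed to every fit.
#' @return Tibble with one [glance.kinetic_fit()] row per substrate.
#' @export
fit_kapp_table <- function(timecourses, fix_plateau = NULL) {
  check_columns(timecourses, "substrate_id", "`timecourses`")
  timecourses |>
    dplyr::group_split(.data$substrate_id) |>
    purrr::map(~ glance(fit_kapp(.x, fix_plateau = fix_plateau))) |>
    dplyr::bind_rows()
}

#' Fold-ratio of two apparent rate constants
#'
#' @param numerator,denominator [fit_kapp()] results or bare rate constants
#'   (per minute).
#' @param rounding `"nearest_fold"` (nearest integer, for statements like
#'   "sixfold") or `"one_decimal"` (e.g. 5.3-fold).
#' @return The rounded fold value.
#' @export
#' @examples
#' fold_ratio(0.00206, 0.00032, "nearest_fold")
fold_ratio <- function(numerator, denominator,
                       rounding = c("nearest_fold", "one_decimal")) {
  rounding <- match.arg(rounding)
  k_of <- function(x) if (inherits(x, "kinetic_fit")) x$k_app else
    check_scalar_number(x, "rate", min = 0)
  num <- k_of(numerator)
  den <- k_of(denominator)
  if (den <= 0) {
    abort("denominator rate constant must be positive.",
          class = "deamscan_undefined_ratio")
  }
  switch(rounding,
         nearest_fold = round(num / den),
         one_decimal = round(num / den, 1))
}

# substrate annotation --------------------------------------------------------

.wc_pair <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate a designed oligonucleotide substrate
#'
#' Searches exhaustively for the longest contiguous Watson-Crick stem under
#' a single-hairpin model: a run of pairs `(i, j), (i+1, j-1), ...` leaving
#' a loop of at least `min_loop` unpaired bases between the innermost pair.
#' The molecule is classified `hairpin` when the stem reaches `min_stem`
#' and the unpaired tails outside the stem are shorter than `max_tail`,
#' `mixed` when a qualifying hairpin carries a long single-stranded tail,
#' and `linear` otherwise. Ties in stem length prefer the 5'-most, then
#' outermost register. No wobble pairs and no multi-loop structures are
#' considered; the in-scope substrates are designed single hairpins or
#' linear oligos.
#'
#' @param sequence DNA string (length >= 8).
#' @param min_stem Minimum stem length to call a hairpin (default 4).
#' @param min_loop Minimum loop length (default 3).
#' @param max_tail Unpaired-tail length at or beyond which a hairpin-bearing
#'   molecule is classified `mixed` (default 8).
#' @param target_index Optional 1-based position of the editable base; when
#'   absent, a base occurring exactly once in the sequence is used if one
#'   exists.
#' @return Object of class `substrate_annotation`: `sequence`,
#'   `stem_pairs` (tibble `i`, `j`), `loop` (inclusive 1-based interval or
#'   `NULL`), `structure_class`, `target_index`.
#' @export
#' @examples
#' annotate_substrate("GTCTGCTTAGTTTGCAGA", target_index = 9)
annotate_substrate <- function(sequence, min_stem = 4L, min_loop = 3L,
                               max_tail = 8L, target_index = NULL) {
  L <- nchar(sequence)
  if (L < 8L) {
    abort("`sequence` must be at least 8 bases.",
          class = "deamscan_invalid_argument")
  }
  s <- strsplit(toupper(sequence), "")[[1]]
  best <- list(len = 0L, i = NA_integer_, j = NA_integer_)
  for (i in seq_len(L - 1L)) {
    if (L < i + min_loop + 1L) break
    for (j in L:(i + min_loop + 1L)) {
      len <- 0L
      while (i + len <= L && j - len >= 1L &&
             (j - len) - (i + len) - 1L >= min_loop &&
             !is.na(.wc_pair[s[i + len]]) &&
             .wc_pair[s[i + len]] == s[j - len]) {
        len <- len + 1L
      }
      if (len > best$len) best <- list(len = len, i = i, j = j)
    }
  }
  if (!is.null(target_index)) {
    check_scalar_number(target_index, "target_index", min = 1, max = L)
    target_index <- as.integer(target_index)
  } else {
    tab <- table(s)
    uniq <- names(tab)[tab == 1L]
    target_index <- if (length(uniq) == 1L) which(s == uniq) else NA_integer_
  }
  if (best$len >= 1L) {
    stem_pairs <- tibble::tibble(i = best$i + 0:(best$len - 1L),
                                 j = best$j - 0:(best$len - 1L))
    loop <- c(best$i + best$len, best$j - best$len)
    tails <- c(best$i - 1L, L - best$j)
  } else {
    stem_pairs <- tibble::tibble(i = integer(), j = integer())
    loop <- NULL
    tails <- c(L, L)
  }
  structure_class <- if (best$len >= min_stem) {
    if (max(tails) >= max_tail) "mixed" else "hairpin"
  } else "linear"
  structure(list(sequence = toupper(sequence), stem_pairs = stem_pairs,
                 loop = loop, stem_length = best$len,
                 structure_class = structure_class,
                 target_index = target_index),
            class = "substrate_annotation")
}

#' @export
print.substrate_annotation <- function(x, ...) {
  cat(sprintf("<substrate_annotation> %s (%d nt): %s", x$sequence,
              nchar(x$sequence), x$structure_class))
  if (!is.null(x$loop)) {
    cat(sprintf(", stem %d bp, loop %d-%d", x$stem_length,
                x$loop[1], x$loop[2]))
  }
  if (!is.na(x$target_index)) cat(sprintf(", target at %d", x$target_index))
  cat("\n")
  invisible(x)
}

#' Position of the n-th loop base of a hairpin substrate
#'
#' @param annotation An [annotate_substrate()] result with a loop.
#' @param n Which loop base (1 = 5'-most).
#' @return 1-based sequence position.
#' @export
loop_base_position <- function(annotation, n) {
  stopifnot(inherits(annotation, "substrate_annotation"))
  if (is.null(annotation$loop)) {
    abort("substrate has no loop.", class = "deamscan_invalid_argument")
  }
  pos <- annotation$loop[1] + as.integer(n) - 1L
  if (pos > annotation$loop[2]) {
    abort("loop is shorter than `n`.", class = "deamscan_invalid_argument")
  }
  pos
}

#' Predict the labelled 5' cleavage fragment length
#'
#' For the A-editing read-out, endonuclease V cuts the second
#' phosphodiester bond 3' of the deoxyinosine, leaving a 5' fragment of
#' `target_index + 1` nt. For the C-editing read-out, uracil-DNA
#' glycosylase plus alkali cleaves the strand at the abasic target
#' position, leaving `target_index - 1` nt.
#'
#' @param annotation An [annotate_substrate()] result with a target.
#' @param chemistry `"endoV"` or `"udg_naoh"`.
#' @return 5' fragment length in nt.
#' @export
#' @examples
#' hp <- annotate_substrate("GTCTGCTTAGTTTGCAGA", target_index = 9)
#' predict_cleavage_fragment(hp, "endoV")
predict_cleavage_fragment <- function(annotation,
                                      chemistry = c("endoV", "udg_naoh")) {
  stopifnot(inherits(annotation, "substrate_annotation"))
  chemistry <- match.arg(chemistry)
  t <- annotation$target_index
  if (is.na(t)) {
    abort("substrate has no target_index.", class = "deamscan_invalid_argument")
  }
  L <- nchar(annotation$sequence)
  len <- switch(chemistry, endoV = t + 1L, udg_naoh = t - 1L)
  if (len <= 0L || len >= L) {
    abort(sprintf("%s cleavage of a target at position %d of %d nt leaves no valid labelled fragment.",
                  chemistry, t, L),
          class = "deamscan_edge_case")
  }
  len
}
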