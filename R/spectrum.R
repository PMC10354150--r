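# Placement of consensus fragments on the reference, per-site tallying, and
# the collapsed mutation spectrum / trinucleotide-context rates with group
# comparisons.

#' Place consensus fragments on the reference
#'
#' Exact k-mer seeding on both strands followed by ungapped extension. Only
#' a unique best placement is accepted: fragments matching several sites
#' equally well abstain as `"ambiguous"`, fragments exceeding
#' `max_mismatch_frac` mismatches (over non-N bases) abstain as
#' `"too_many_mismatches"`. Minus-strand observations are
#' reverse-complemented onto the top strand before mismatches are reported.
#' Circular references wrap.
#'
#' @param consensus Tibble with columns `read_id` and `sequence` (consensus
#'   fragments, possibly containing N), e.g. from [call_consensus()].
#' @param ref A [ref_genome].
#' @param max_mismatch_frac Maximum mismatch fraction (default 0.05).
#' @param seed_kmer Exact-match seed length (default 21).
#' @return List with `placements` (tibble: `read_id`, `ref_start` 1-based,
#'   `strand`, `n_mismatch`, `status`) and `mismatches` (tibble: `read_id`,
#'   `ref_pos`, `ref_base`, `obs_base`, top-strand).
#' @export
place_consensus <- function(consensus, ref, max_mismatch_frac = 0.05,
                            seed_kmer = 21L) {
  check_columns(consensus, c("read_id", "sequence"), "`consensus`")
  stopifnot(inherits(ref, "ref_genome"))
  res <- cpp_place(consensus$sequence, ref$sequence, ref$circular,
                   max_mismatch_frac, as.integer(seed_kmer))
  placements <- tibble::tibble(
    read_id = consensus$read_id,
    sequence = consensus$sequence,
    ref_start = res$ref_start,
    strand = res$strand,
    aligned = res$aligned,
    n_mismatch = res$n_mismatch,
    status = res$status
  )
  mismatches <- tibble::tibble(
    read_id = consensus$read_id[res$mismatch_cons],
    ref_pos = res$mismatch_pos,
    ref_base = res$mismatch_ref,
    obs_base = res$mismatch_obs
  )
  list(placements = placements, mismatches = mismatches)
}

#' Tally per-site coverage and base observations
#'
#' Every non-N base of every placed fragment contributes one top-strand
#' observation at its reference site; N bases count toward neither coverage
#' nor mutations. At every site the base counts sum exactly to the
#' coverage.
#'
#' @param placed Result of [place_consensus()].
#' @param ref A [ref_genome].
#' @return Object of class `site_tally`: list with `coverage` (integer
#'   vector), `counts` (4 x L matrix, rows A/C/G/T) and `ref`.
#' @export
tally_sites <- function(placed, ref) {
  stopifnot(inherits(ref, "ref_genome"))
  pl <- placed$placements
  ok <- !is.na(pl$status) & pl$status == "placed"
  res <- cpp_tally(pl$aligned[ok], pl$ref_start[ok], nchar(ref$sequence))
  rownames(res$counts) <- DNA_BASES
  structure(list(coverage = res$coverage, counts = res$counts, ref = ref),
            class = "site_tally")
}

#' @export
print.site_tally <- function(x, ...) {
  cat(sprintf("<site_tally> %d sites, total coverage %s, mean depth %.2f\n",
              length(x$coverage), format(sum(x$coverage), big.mark = ","),
              mean(x$coverage)))
  invisible(x)
}

#' @export
as_tibble.site_tally <- function(x, ...) {
  tibble::tibble(
    pos = seq_along(x$coverage),
    ref_base = stringi::stri_sub(x$ref$sequence, seq_along(x$coverage),
                                 seq_along(x$coverage)),
    coverage = x$coverage,
    A = x$counts["A", ], C = x$counts["C", ],
    G = x$counts["G", ], T = x$counts["T", ]
  )
}

# long table of non-reference observations: pos, ref, obs, count, context
.mismatch_table <- function(tally) {
  seq <- tally$ref$sequence
  L <- nchar(seq)
  bases <- stringi::stri_sub(seq, 1:L, 1:L)
  ref_idx <- match(bases, DNA_BASES)
  out <- vector("list", 4L)
  for (b in 1:4) {
    cnt <- tally$counts[b, ]
    hit <- which(cnt > 0L & ref_idx != b)
    if (length(hit)) {
      out[[b]] <- tibble::tibble(pos = hit, ref = bases[hit],
                                 obs = DNA_BASES[b], count = cnt[hit])
    }
  }
  tb <- dplyr::bind_rows(out)
  if (!nrow(tb)) {
    return(tibble::tibble(pos = integer(), ref = character(),
                          obs = character(), count = integer(),
                          context = character()))
  }
  if (tally$ref$circular) {
    ext <- paste0(stringi::stri_sub(seq, L, L), seq,
                  stringi::stri_sub(seq, 1, 1))
    tb$context <- stringi::stri_sub(ext, tb$pos, tb$pos + 2L)
  } else {
    tb$context <- NA_character_
    inner <- tb$pos > 1L & tb$pos < L
    tb$context[inner] <- stringi::stri_sub(seq, tb$pos[inner] - 1L,
                                           tb$pos[inner] + 1L)
  }
  dplyr::arrange(tb, .data$pos)
}

#' Extract per-site variant calls from a tally
#'
#' One row per (site, observed non-reference base) with its collapsed
#' substitution type and collapsed trinucleotide context.
#'
#' @param tally A [tally_sites()] result.
#' @return Tibble with columns `pos`, `ref`, `obs`, `count`, `context`
#'   (top-strand triplet), `type` (collapsed), `context_collapsed`.
#' @export
call_variants <- function(tally) {
  stopifnot(inherits(tally, "site_tally"))
  tb <- .mismatch_table(tally)
  tb$type <- if (nrow(tb)) collapse_type(tb$ref, tb$obs) else character()
  tb$context_collapsed <- ifelse(is.na(tb$context), NA_character_,
                                 collapse_context(tb$context))
  tb
}

#' Collapsed six-type mutation spectrum
#'
#' For each collapsed substitution class, the numerator is the number of
#' qualifying non-reference observations on either strand representation
#' and the denominator is the coverage-weighted number of site-observations
#' of the focal base pair (C+G sites for C:G-focal classes, A+T sites
#' otherwise); the frequency is their ratio, reported as 0 (with a zero
#' denominator flag) rather than NaN when nothing was observed.
#'
#' @param tally A [tally_sites()] result.
#' @return Tibble with columns `type`, `n_mut`, `n_sites`, `frequency`.
#' @export
mutation_spectrum <- function(tally) {
  stopifnot(inherits(tally, "site_tally"))
  seq <- tally$ref$sequence
  L <- nchar(seq)
  bases <- stringi::stri_sub(seq, 1:L, 1:L)
  cg_obs <- sum(tally$coverage[bases %in% c("C", "G")])
  at_obs <- sum(tally$coverage[bases %in% c("A", "T")])
  denom <- ifelse(substr(deam_types, 1, 1) %in% c("C", "G"), cg_obs, at_obs)
  tb <- .mismatch_table(tally)
  num <- if (nrow(tb)) {
    tapply(tb$count, factor(collapse_type(tb$ref, tb$obs), levels = deam_types),
           sum, default = 0L)
  } else {
    setNames(rep(0L, 6L), deam_types)
  }
  tibble::tibble(
    type = deam_types,
    n_mut = as.integer(num),
    n_sites = as.numeric(denom),
    frequency = ifelse(denom > 0, as.numeric(num) / denom, 0)
  )
}

#' Trinucleotide-context mutation rates (16 collapsed contexts)
#'
#' For the two deamination classes (C:G>T:A and A:T>G:C), each qualifying
#' mutation is assigned to the collapsed context of its top-strand triplet
#' (a G>A at 5'CGA3' collapses to 5'TCG3'). By default the denominator is
#' the total coverage-weighted C+G (or A+T) site-observations, identical
#' across the 16 rows; `denominator = "per-context"` divides instead by the
#' site-observations of each collapsed context. Sites lacking a 5' or 3'
#' flank on a linear reference are excluded from context tables only.
#'
#' @param tally A [tally_sites()] result.
#' @param denominator `"total"` (default) or `"per-context"`.
#' @return Tibble with columns `type`, `context`, `n_mut`, `n_sites`,
#'   `rate`, 32 rows (16 contexts x 2 classes).
#' @export
context_spectrum <- function(tally, denominator = c("total", "per-context")) {
  stopifnot(inherits(tally, "site_tally"))
  denominator <- match.arg(denominator)
  seq <- tally$ref$sequence
  L <- nchar(seq)
  bases <- stringi::stri_sub(seq, 1:L, 1:L)
  if (tally$ref$circular) {
    ext <- paste0(stringi::stri_sub(seq, L, L), seq, stringi::stri_sub(seq, 1, 1))
    ctx <- stringi::stri_sub(ext, 1:L, 1:L + 2L)
  } else {
    ctx <- rep(NA_character_, L)
    if (L >= 3) ctx[2:(L - 1)] <- stringi::stri_sub(seq, 1:(L - 2), 3:L)
  }
  ctx_collapsed <- ifelse(is.na(ctx), NA_character_, collapse_context(ctx))
  tb <- .mismatch_table(tally)
  if (nrow(tb)) {
    tb$type <- collapse_type(tb$ref, tb$obs)
    tb <- tb[tb$type %in% c("C:G>T:A", "A:T>G:C") & !is.na(tb$context), ]
    tb$context_collapsed <- collapse_context(tb$context)
  }
  out <- lapply(c("C:G>T:A" = "C", "A:T>G:C" = "A"), function(focal) {
    contexts <- .all_contexts(focal)
    pair <- if (focal == "C") c("C", "G") else c("A", "T")
    type <- if (focal == "C") "C:G>T:A" else "A:T>G:C"
    sub <- if (nrow(tb)) tb[tb$type == type, ] else tb
    num <- if (nrow(sub)) {
      tapply(sub$count, factor(sub$context_collapsed, levels = contexts),
             sum, default = 0L)
    } else setNames(rep(0L, 16L), contexts)
    focal_sites <- bases %in% pair & !is.na(ctx_collapsed)
    if (denominator == "total") {
      den <- rep(sum(tally$coverage[focal_sites]), 16L)
    } else {
      den <- tapply(tally$coverage[focal_sites],
                    factor(ctx_collapsed[focal_sites], levels = contexts),
                    sum, default = 0L)
      den <- as.numeric(den)
    }
    tibble::tibble(type = type, context = contexts, n_mut = as.integer(num),
                   n_sites = as.numeric(den),
                   rate = ifelse(den > 0, as.integer(num) / den, 0))
  })
  dplyr::bind_rows(out)
}

#' Compare per-replicate mutation rates between groups
#'
#' One-way ANOVA with Tukey's HSD post-test per substitution type (the
#' standard multi-group comparison for per-culture spectra), plus a
#' label-permutation p-value for the ANOVA F statistic as an internal
#' cross-check.
#'
#' @param spectra Tibble with one row per (replicate, type): columns
#'   `group`, `type`, and the rate column named by `value`.
#' @param value Name of the rate column (default `"frequency"`).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional seed for the permutation draw.
#' @return List with `anova` (per type: `f_statistic`, `p_anova`,
#'   `p_permutation`) and `tukey` (per type and group pair: `diff`,
#'   `p_adj`).
#' @export
compare_spectra <- function(spectra, value = "frequency", n_perm = 10000L,
                            seed = NULL) {
  check_columns(spectra, c("group", "type", value), "`spectra`")
  counts <- dplyr::count(spectra, .data$type, .data$group)
  if (dplyr::n_distinct(counts$group) < 2L || any(counts$n < 2L)) {
    abort("need >= 2 groups with >= 2 replicates each.",
          class = "deamscan_invalid_design")
  }
  types <- unique(spectra$type)
  with_seed(seed, {
    res <- lapply(types, function(tp) {
      d <- spectra[spectra$type == tp, ]
      y <- d[[value]]
      g <- factor(d$group)
      fit <- aov(y ~ g)
      an <- summary(fit)[[1]]
      f_obs <- an$`F value`[1]
      p_an <- an$`Pr(>F)`[1]
      f_perm <- vapply(seq_len(n_perm), function(i) {
        gp <- sample(g)
        m <- tapply(y, gp, mean)
        nn <- tapply(y, gp, length)
        ssb <- sum(nn * (m - mean(y))^2)
        ssw <- sum((y - m[gp])^2)
        (ssb / (nlevels(g) - 1)) / (ssw / (length(y) - nlevels(g)))
      }, 0)
      p_perm <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
      tk <- TukeyHSD(fit)$g
      list(
        anova = tibble::tibble(type = tp, f_statistic = f_obs,
                               p_anova = p_an, p_permutation = p_perm),
        tukey = tibble::tibble(type = tp, pair = rownames(tk),
                               diff = tk[, "diff"], p_adj = tk[, "p adj"])
      )
    })
    list(anova = dplyr::bind_rows(lapply(res, `[[`, "anova")),
         tukey = dplyr::bind_rows(lapply(res, `[[`, "tukey")))
  })
}
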