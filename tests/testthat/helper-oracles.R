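# Independent brute-force oracles used to validate the fast implementations.

# plurality vote over bins (position mod period) with quality-sum tie-break,
# then N; bins with fewer than min_copies unmasked observations give N
vote_oracle <- function(read, qual, period, qmask = 20, min_copies = 2) {
  bases <- strsplit(read, "")[[1]]
  phred <- utf8ToInt(qual) - 33L
  out <- character(period)
  for (j in seq_len(period)) {
    idx <- seq(j, length(bases), by = period)
    keep <- idx[phred[idx] >= qmask & bases[idx] %in% c("A", "C", "G", "T")]
    if (length(keep) < min_copies) {
      out[j] <- "N"
      next
    }
    obs <- bases[keep]
    cnt <- table(factor(obs, levels = c("A", "C", "G", "T")))
    qs <- tapply(phred[keep], factor(obs, levels = c("A", "C", "G", "T")),
                 sum, default = 0L)
    best <- which(cnt == max(cnt))
    if (length(best) > 1L) best <- best[qs[best] == max(qs[best])]
    out[j] <- if (length(best) == 1L) names(cnt)[best] else "N"
  }
  paste(out, collapse = "")
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
ranksum_exact_oracle <- function(x, y) {
  m <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(m)])
  combos <- utils::combn(m + length(y), m)
  w_all <- apply(combos, 2, function(i) sum(ranks[i]))
  ew <- m * (m + length(y) + 1) / 2
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# maximal single-hairpin stem length by enumeration of every register
stem_oracle <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  pair <- c(A = "T", C = "G", G = "C", T = "A")
  L <- length(s)
  best <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j <= i) next
      len <- 0L
      while (i + len <= L && j - len >= 1 &&
             (j - len) - (i + len) - 1 >= min_loop &&
             !is.na(pair[s[i + len]]) && pair[s[i + len]] == s[j - len]) {
        len <- len + 1L
      }
      best <- max(best, len)
    }
  }
  best
}

# single-exponential fraction at time t
exp_fraction <- function(k, t, plateau = 1) plateau * (1 - exp(-k * t))

# random DNA string
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# build a site_tally object directly (for arithmetic checks on known counts)
make_tally <- function(ref, coverage, counts) {
  structure(list(coverage = coverage, counts = counts, ref = ref),
            class = "site_tally")
}

# reconstruct the fragment of a simulated read from the generator truth
truth_fragment <- function(pool, truth_row) {
  mol <- pool$molecules[truth_row$molecule_id]
  len <- truth_row$fragment_len
  src <- paste0(mol, substr(mol, 1, len))
  substr(src, truth_row$fragment_start, truth_row$fragment_start + len - 1)
}

# the consensus implied by the generator truth: fragment rotated by phase
truth_consensus <- function(pool, truth_row) {
  frag <- truth_fragment(pool, truth_row)
  if (truth_row$strand == "-") frag <- deamscan::revcomp(frag)
  p <- truth_row$phase
  paste0(substr(frag, p + 1, nchar(frag)), substr(frag, 1, p))
}
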