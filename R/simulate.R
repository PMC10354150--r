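# Synthetic-data generators: reference genomes, motif-biased mutagenesis,
# rolling-circle tandem reads, deamination time courses and fluctuation-assay
# colony counts. Every generator returns its ground truth so downstream
# recovery can be tested.

#' Construct a reference genome object
#'
#' @param sequence Single DNA string over A/C/G/T (length >= 3).
#' @param id Sequence identifier.
#' @param circular Is the molecule circular (bacterial chromosome-like)?
#' @return An object of class `ref_genome`: a list with elements `id`,
#'   `sequence` and `circular`.
#' @export
ref_genome <- function(sequence, id = "ref", circular = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 3L) {
    abort("`sequence` must be a single DNA string of length >= 3.",
          class = "deamscan_invalid_argument")
  }
  if (stringi::stri_detect_regex(sequence, "[^ACGT]")) {
    abort("`sequence` may only contain A, C, G, T.",
          class = "deamscan_invalid_argument")
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %s bp, %s\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Simulate a random reference genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`, emulating a bacterial chromosome of
#' known base composition.
#'
#' @param length Genome length in bp (>= 3).
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @param circular Simulate a circular molecule (default `TRUE`).
#' @param id Sequence identifier.
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @return A [ref_genome] object.
#' @export
#' @examples
#' sim_reference(1000, gc_fraction = 0.5, seed = 1)
sim_reference <- function(length, gc_fraction = 0.5, circular = TRUE,
                          id = "synthetic_ref", seed = NULL) {
  check_scalar_number(length, "length", min = 3)
  check_scalar_number(gc_fraction, "gc_fraction", min = 0, max = 1)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = probs),
          collapse = "")
  })
  ref_genome(seq, id = id, circular = circular)
}

# mutation models -------------------------------------------------------------

# normalise a directed substitution "X>Y" so the reference base is C or A;
# optionally reverse-complements an attached context the same way
.canon_sub <- function(sub, context = NULL) {
  ref <- substr(sub, 1, 1)
  obs <- substr(sub, 3, 3)
  ok <- ref %in% DNA_BASES & obs %in% DNA_BASES & ref != obs &
    nchar(sub) == 3 & substr(sub, 2, 2) == ">"
  if (!all(ok)) {
    abort("substitutions must be written as e.g. \"C>T\".",
          class = "deamscan_invalid_argument")
  }
  flip <- ref %in% c("G", "T")
  comp <- function(b) chartr("ACGT", "TGCA", b)
  sub[flip] <- paste0(comp(ref[flip]), ">", comp(obs[flip]))
  if (is.null(context)) return(sub)
  context[flip] <- revcomp(context[flip])
  list(sub = sub, context = context)
}

#' Specify a strand-symmetric mutation model
#'
#' Per-site, per-molecule substitution probabilities. The effective rate of a
#' directed change at a site is `base_rates[sub] * m(context, sub)`, where
#' `m` is the listed context multiplier or `default_multiplier` for contexts
#' not listed. The model is always strand symmetric: a rate defined for C>T
#' at 5'TCG3' applies equally to the reverse-complement event (G>A within
#' 5'CGA3' on the top strand).
#'
#' @param base_rates Named numeric vector of per-site probabilities; names
#'   are directed substitutions such as `"C>T"` (either strand's spelling is
#'   accepted and canonicalised to a C or A reference base).
#' @param context_multipliers Named numeric vector keyed `"TCG:C>T"` style
#'   (triplet context, colon, substitution), or a data frame with columns
#'   `context`, `sub`, `multiplier`. Non-negative.
#' @param default_multiplier Multiplier applied to every (context, sub)
#'   combination not listed (default 1).
#' @return A `mutation_model` object.
#' @seealso [motif_mutation_model()] for pure target-motif models.
#' @export
mutation_model <- function(base_rates = numeric(), context_multipliers = NULL,
                           default_multiplier = 1) {
  if (length(base_rates)) {
    if (is.null(names(base_rates)) || any(!is.finite(base_rates)) ||
        any(base_rates < 0 | base_rates > 1)) {
      abort("`base_rates` must be a named vector of probabilities in [0, 1].",
            class = "deamscan_invalid_argument")
    }
    names(base_rates) <- .canon_sub(names(base_rates))
    if (anyDuplicated(names(base_rates))) {
      abort("`base_rates` lists the same substitution class twice.",
            class = "deamscan_invalid_argument")
    }
  }
  mult <- tibble::tibble(context = character(), sub = character(),
                         multiplier = numeric())
  if (!is.null(context_multipliers)) {
    if (is.data.frame(context_multipliers)) {
      check_columns(context_multipliers, c("context", "sub", "multiplier"),
                    "`context_multipliers`")
      mult <- tibble::as_tibble(context_multipliers[c("context", "sub", "multiplier")])
    } else {
      key <- stringi::stri_split_fixed(names(context_multipliers), ":", n = 2)
      mult <- tibble::tibble(
        context = vapply(key, `[`, "", 1),
        sub = vapply(key, `[`, "", 2),
        multiplier = unname(context_multipliers)
      )
    }
    if (any(nchar(mult$context) != 3) || any(mult$multiplier < 0)) {
      abort("context multipliers need 3-base contexts and factors >= 0.",
            class = "deamscan_invalid_argument")
    }
    canon <- .canon_sub(mult$sub, mult$context)
    mult$sub <- canon$sub
    mult$context <- canon$context
    if (any(substr(mult$context, 2, 2) != substr(mult$sub, 1, 1))) {
      abort("each context's focal base must equal the substitution's reference base.",
            class = "deamscan_invalid_argument")
    }
  }
  structure(list(base_rates = base_rates, context_multipliers = mult,
                 default_multiplier = default_multiplier,
                 strand_symmetric = TRUE),
            class = "mutation_model")
}

#' Target-motif mutation model
#'
#' Convenience wrapper for a deaminase-style model in which mutations occur
#' only at listed motifs, e.g. C>T within 5'TCG3' and A>G within 5'GAA3'.
#'
#' @param rates Named numeric vector keyed `"TCG:C>T"` style; values are
#'   per-site, per-molecule probabilities at that motif (both strands).
#' @return A `mutation_model` with zero rate outside the listed motifs.
#' @export
#' @examples
#' motif_mutation_model(c("TCG:C>T" = 1e-4, "GAA:A>G" = 5e-5))
motif_mutation_model <- function(rates) {
  key <- stringi::stri_split_fixed(names(rates), ":", n = 2)
  ctx <- vapply(key, `[`, "", 1)
  sub <- vapply(key, `[`, "", 2)
  canon <- .canon_sub(sub, ctx)
  base <- tapply(unname(rates), canon$sub, max)
  mult <- tibble::tibble(context = canon$context, sub = canon$sub,
                         multiplier = unname(rates) / base[canon$sub])
  mutation_model(base_rates = setNames(as.numeric(base), names(base)),
                 context_multipliers = mult, default_multiplier = 0)
}

# per-site directed rates implied by a model on a given reference:
# tibble(pos, ref, alt, rate) with rate > 0
.site_rates <- function(ref, model) {
  seq <- ref$sequence
  L <- nchar(seq)
  bases <- stringi::stri_sub(seq, 1:L, 1:L)
  if (ref$circular) {
    ext <- paste0(stringi::stri_sub(seq, L, L), seq, stringi::stri_sub(seq, 1, 1))
    ctx <- stringi::stri_sub(ext, 1:L, (1:L) + 2L)
  } else {
    ctx <- rep(NA_character_, L)
    if (L >= 3) ctx[2:(L - 1)] <- stringi::stri_sub(seq, 1:(L - 2), 3:L)
  }
  mm <- model$context_multipliers
  out <- vector("list", 2L * length(model$base_rates))
  k <- 0L
  for (sub in names(model$base_rates)) {
    rate0 <- model$base_rates[[sub]]
    if (rate0 == 0) next
    rb <- substr(sub, 1, 1)          # C or A
    ob <- substr(sub, 3, 3)
    cb <- chartr("ACGT", "TGCA", rb) # complementary reference base
    co <- chartr("ACGT", "TGCA", ob)
    subm <- mm[mm$sub == sub, ]
    lookup <- function(contexts) {
      m <- rep(model$default_multiplier, length(contexts))
      if (nrow(subm)) {
        idx <- match(contexts, subm$context)
        m[!is.na(idx)] <- subm$multiplier[idx[!is.na(idx)]]
      }
      m[is.na(contexts)] <- model$default_multiplier
      m
    }
    # top-strand occurrences of the canonical reference base
    i_top <- which(bases == rb)
    if (length(i_top)) {
      r <- rate0 * lookup(ctx[i_top])
      keep <- r > 0
      k <- k + 1L
      out[[k]] <- tibble::tibble(pos = i_top[keep], ref = rb, alt = ob,
                                 rate = r[keep])
    }
    # bottom-strand occurrences: top-strand base is the complement and the
    # bottom-strand context is the reverse complement of the top triplet
    i_bot <- which(bases == cb)
    if (length(i_bot)) {
      r <- rate0 * lookup(revcomp(ctx[i_bot]))
      keep <- r > 0
      k <- k + 1L
      out[[k]] <- tibble::tibble(pos = i_bot[keep], ref = cb, alt = co,
                                 rate = r[keep])
    }
  }
  rates <- dplyr::bind_rows(out[seq_len(k)])
  if (nrow(rates) && any(rates$rate > 1)) {
    abort("effective per-site rate exceeds 1; lower the base rate or multipliers.",
          class = "deamscan_invalid_model")
  }
  if (nrow(rates)) {
    tot <- tapply(rates$rate, rates$pos, sum)
    if (any(tot > 1)) {
      abort("summed per-site rates exceed 1 at some sites.",
            class = "deamscan_invalid_model")
    }
  }
  rates
}

#' Generate a pool of independently mutated genome copies
#'
#' Each molecule is an independent copy of the reference in which every
#' eligible (site, substitution) is hit with its model probability. Strand
#' symmetry is enforced; all events are recorded in top-strand coordinates.
#'
#' @param ref A [ref_genome].
#' @param model A [mutation_model] or [motif_mutation_model()] result.
#' @param n_molecules Number of genome copies (>= 1).
#' @param seed Optional integer seed.
#' @return A list of class `molecule_pool` with elements `molecules`
#'   (character vector), `truth` (tibble: `molecule_id`, `pos`, `ref`,
#'   `alt`; 1-based top-strand positions) and `ref`.
#' @export
inject_mutations <- function(ref, model, n_molecules, seed = NULL) {
  stopifnot(inherits(ref, "ref_genome"), inherits(model, "mutation_model"))
  check_scalar_number(n_molecules, "n_molecules", min = 1)
  n_molecules <- as.integer(n_molecules)
  rates <- .site_rates(ref, model)
  truth <- with_seed(seed, {
    if (!nrow(rates)) {
      tibble::tibble(molecule_id = integer(), pos = integer(),
                     ref = character(), alt = character())
    } else {
      hits <- rbinom(nrow(rates), n_molecules, rates$rate)
      idx <- rep.int(seq_len(nrow(rates)), hits)
      mol <- unlist(lapply(which(hits > 0), function(i) {
        sample.int(n_molecules, hits[i])
      }), use.names = FALSE)
      tb <- tibble::tibble(molecule_id = as.integer(mol),
                           pos = rates$pos[idx],
                           ref = rates$ref[idx], alt = rates$alt[idx])
      # a molecule can be drawn for two different changes at one site;
      # keep the first
      tb[!duplicated(tb[c("molecule_id", "pos")]), ]
    }
  })
  truth <- dplyr::arrange(truth, .data$molecule_id, .data$pos)
  molecules <- rep(ref$sequence, n_molecules)
  for (i in seq_len(nrow(truth))) {
    stringi::stri_sub(molecules[truth$molecule_id[i]],
                      truth$pos[i], truth$pos[i]) <- truth$alt[i]
  }
  structure(list(molecules = molecules, truth = truth, ref = ref),
            class = "molecule_pool")
}

# substitute `k[i]` random positions of string i with a random different base
.add_base_noise <- function(seqs, k) {
  width <- stringi::stri_length(seqs)
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 4, byrow = TRUE,
                dimnames = list(DNA_BASES, NULL))
  for (round in seq_len(max(k, 0L))) {
    sel <- which(k >= round)
    if (!length(sel)) break
    p <- 1L + as.integer(floor(runif(length(sel)) * width[sel]))
    cur <- stringi::stri_sub(seqs[sel], p, p)
    new <- alt[cbind(match(cur, DNA_BASES),
                     sample.int(3L, length(sel), replace = TRUE))]
    stringi::stri_sub(seqs[sel], p, p) <- new
  }
  seqs
}

# set `k[i]` random positions of quality string i to the low-quality symbol
.add_low_quality <- function(quals, k, low_char) {
  width <- stringi::stri_length(quals)
  for (round in seq_len(max(k, 0L))) {
    sel <- which(k >= round)
    if (!length(sel)) break
    p <- 1L + as.integer(floor(runif(length(sel)) * width[sel]))
    stringi::stri_sub(quals[sel], p, p) <- low_char
  }
  quals
}

#' Simulate rolling-circle tandem-repeat reads
#'
#' Random fragments (uniform length within `frag_len_range`) are drawn from
#' random molecules, circularised, and read as tandem concatemers starting at
#' a uniform random phase, emulating rolling-circle amplification of
#' size-selected fragments. Per-base substitution errors are i.i.d. at
#' `error_rate`; base qualities follow a two-state model (high quality, with
#' a `low_q_prob` chance per base of a sub-threshold quality).
#'
#' @param pool A `molecule_pool` from [inject_mutations()], or a character
#'   vector of molecule sequences (then `circular` applies).
#' @param n_reads Number of reads (merged mode) or fragments (paired mode).
#' @param read_len Read length in bp; merged mode emits one read of
#'   `read_len` (default 300, approximately the insert size), paired mode two
#'   mates of `read_len` each from a `2 * read_len` insert.
#' @param frag_len_range Circularised fragment length range (default 90-120).
#' @param mode `"merged"` (default) or `"paired"`.
#' @param error_rate Per-base substitution error probability in `[0, 0.5)`.
#' @param low_q_prob Per-base probability of a low-quality (masked
#'   downstream) base.
#' @param q_high,q_low Phred scores of the two quality states.
#' @param circular Used only when `pool` is a bare character vector.
#' @param seed Optional integer seed.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`)
#'   and `truth` (tibble: `read_id`, `molecule_id`, `fragment_start`,
#'   `fragment_len`, `phase`, `strand`). `phase` is the 0-based offset such
#'   that `read[i]` equals position `((phase + i - 1) %% fragment_len) + 1`
#'   of the fragment (of its reverse complement for `strand == "-"`).
#' @export
sim_rc_reads <- function(pool, n_reads, read_len = 300L,
                         frag_len_range = c(90L, 120L),
                         mode = c("merged", "paired"),
                         error_rate = 0, low_q_prob = 0,
                         q_high = 36L, q_low = 11L,
                         circular = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(pool, "molecule_pool")) {
    molecules <- pool$molecules
    circular <- pool$ref$circular
  } else {
    molecules <- pool
  }
  check_scalar_number(n_reads, "n_reads", min = 1)
  check_scalar_number(error_rate, "error_rate", min = 0, max = 0.5 - 1e-12)
  fmin <- as.integer(frag_len_range[1]); fmax <- as.integer(frag_len_range[2])
  if (fmin < 30L || fmax < fmin || read_len < fmin) {
    abort("need 30 <= frag_len_range[1] <= frag_len_range[2] and read_len >= min fragment length.",
          class = "deamscan_invalid_argument")
  }
  n_reads <- as.integer(n_reads)
  L <- nchar(molecules[1])
  insert <- if (mode == "merged") as.integer(read_len) else 2L * as.integer(read_len)

  with_seed(seed, {
    mol_idx <- sample.int(length(molecules), n_reads, replace = TRUE)
    frag_len <- if (fmax > fmin) {
      fmin + as.integer(floor(runif(n_reads) * (fmax - fmin + 1L)))
    } else rep(fmin, n_reads)
    if (circular) {
      start <- 1L + as.integer(floor(runif(n_reads) * L))
      src <- paste0(molecules, stringi::stri_sub(molecules, 1L, fmax - 1L))
    } else {
      start <- 1L + as.integer(floor(runif(n_reads) * (L - frag_len + 1L)))
      src <- molecules
    }
    frag <- stringi::stri_sub(src[mol_idx], start, start + frag_len - 1L)
    phase <- as.integer(floor(runif(n_reads) * frag_len))
    nrep <- as.integer(ceiling((phase + insert) / frag_len))
    ins_seq <- stringi::stri_sub(stringi::stri_dup(frag, nrep),
                                 phase + 1L, phase + insert)
    if (error_rate > 0) {
      ins_seq <- .add_base_noise(ins_seq, rbinom(n_reads, insert, error_rate))
    }
    if (mode == "merged") {
      seqs <- ins_seq
      ids <- sprintf("read%07d", seq_len(n_reads))
      truth <- tibble::tibble(read_id = ids, molecule_id = mol_idx,
                              fragment_start = start, fragment_len = frag_len,
                              phase = phase, strand = "+")
    } else {
      mate1 <- stringi::stri_sub(ins_seq, 1L, read_len)
      mate2 <- revcomp(stringi::stri_sub(ins_seq, insert - read_len + 1L, insert))
      base_id <- sprintf("read%07d", seq_len(n_reads))
      seqs <- c(rbind(mate1, mate2))
      ids <- c(rbind(paste0(base_id, "/1"), paste0(base_id, "/2")))
      phase2 <- (frag_len - 1L - ((phase + insert - 1L) %% frag_len)) %% frag_len
      truth <- tibble::tibble(
        read_id = ids,
        molecule_id = rep(mol_idx, each = 2L),
        fragment_start = rep(start, each = 2L),
        fragment_len = rep(frag_len, each = 2L),
        phase = c(rbind(phase, phase2)),
        strand = rep(c("+", "-"), times = n_reads)
      )
    }
    out_len <- if (mode == "merged") insert else as.integer(read_len)
    quals <- rep(strrep(int_to_phred(q_high), out_len), length(seqs))
    if (low_q_prob > 0) {
      quals <- .add_low_quality(quals,
                                rbinom(length(seqs), out_len, low_q_prob),
                                int_to_phred(q_low))
    }
    list(reads = tibble::tibble(read_id = ids, sequence = seqs, quality = quals),
         truth = truth)
  })
}

#' Simulate deamination time courses
#'
#' Fractions follow a rise-to-plateau single exponential,
#' `F(t) = plateau * (1 - exp(-k_true * t))`, plus Gaussian noise, clamped to
#' `[0, 1]`.
#'
#' @param k_true True apparent rate constant (per minute, >= 0).
#' @param times Sampling times in minutes (non-negative).
#' @param plateau Reaction end point in `(0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_replicates Number of replicate courses.
#' @param substrate_id Label carried through to the output.
#' @param seed Optional integer seed.
#' @return Tibble with columns `substrate_id`, `replicate`, `time_min`,
#'   `fraction`.
#' @export
#' @examples
#' sim_timecourse(0.008, times = c(0, 15, 30, 60, 120), noise_sd = 0)
sim_timecourse <- function(k_true, times, plateau = 1, noise_sd = 0,
                           n_replicates = 1L, substrate_id = "substrate",
                           seed = NULL) {
  check_scalar_number(k_true, "k_true", min = 0)
  check_scalar_number(plateau, "plateau", min = 1e-12, max = 1)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  if (any(times < 0)) {
    abort("`times` must be non-negative minutes.",
          class = "deamscan_invalid_argument")
  }
  with_seed(seed, {
    tidyr::crossing(replicate = seq_len(n_replicates), time_min = sort(times)) |>
      dplyr::mutate(
        substrate_id = substrate_id,
        fraction = pmin(pmax(
          plateau * (1 - exp(-k_true * .data$time_min)) +
            rnorm(dplyr::n(), 0, noise_sd), 0), 1),
        .before = 1
      ) |>
      dplyr::select("substrate_id", "replicate", "time_min", "fraction")
  })
}

#' Simulate a resistance fluctuation assay
#'
#' Per-culture resistant colony counts are Poisson with mean
#' `freq * viable_cells`, the regime in which the colony-count / viable-cell
#' ratio estimates the mutation frequency.
#'
#' @param n_cultures Number of independent cultures.
#' @param viable_cells Viable cells plated per culture (> 0).
#' @param freq True per-cell mutant frequency in `[0, 1]`.
#' @param group Group label.
#' @param dilution_factor Plating dilution factor (> 0).
#' @param seed Optional integer seed.
#' @return Tibble with columns `group`, `culture`, `colonies`,
#'   `viable_cells`, `dilution_factor`.
#' @export
sim_fluctuation_assay <- function(n_cultures, viable_cells, freq,
                                  group = "group", dilution_factor = 1,
                                  seed = NULL) {
  check_scalar_number(n_cultures, "n_cultures", min = 1)
  check_scalar_number(viable_cells, "viable_cells", min = 1e-300)
  check_scalar_number(freq, "freq", min = 0, max = 1)
  if (!is.finite(freq * viable_cells)) {
    abort("`freq * viable_cells` must be finite.",
          class = "deamscan_invalid_argument")
  }
  with_seed(seed, tibble::tibble(
    group = group,
    culture = seq_len(as.integer(n_cultures)),
    colonies = rpois(as.integer(n_cultures), freq * viable_cells),
    viable_cells = viable_cells,
    dilution_factor = dilution_factor
  ))
}
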