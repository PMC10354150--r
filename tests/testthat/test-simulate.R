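# Generators: composition, ground-truth bookkeeping, and the statistical
# structure the downstream analyses assume.

test_that("reference simulation honours length and base composition", {
  ref <- sim_reference(10000, gc_fraction = 0.5, seed = 1)
  expect_s3_class(ref, "ref_genome")
  expect_equal(nchar(ref$sequence), 10000)
  expect_false(stringi::stri_detect_regex(ref$sequence, "[^ACGT]"))

  gc_only <- sim_reference(500, gc_fraction = 1, seed = 2)
  expect_false(stringi::stri_detect_regex(gc_only$sequence, "[AT]"))

  # observed GC within 3 binomial sigma of the target:
  # sd = sqrt(0.5 * 0.5 / 1e5) = 0.00158, so 3 sigma < 0.005
  big <- sim_reference(1e5, gc_fraction = 0.5, seed = 7)
  gc <- mean(strsplit(big$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.005)

  expect_error(sim_reference(2), class = "deamscan_invalid_argument")
  # identical seeds reproduce identical sequences
  expect_identical(sim_reference(1000, seed = 5)$sequence,
                   sim_reference(1000, seed = 5)$sequence)
})

test_that("mutation injection follows the motif model and records truth", {
  ref <- sim_reference(20000, gc_fraction = 0.5, seed = 3)

  # null model: no mutations, molecules identical to the reference
  null_pool <- inject_mutations(ref, mutation_model(), 5, seed = 1)
  expect_equal(nrow(null_pool$truth), 0)
  expect_true(all(null_pool$molecules == ref$sequence))

  # motif-only model: every event is a C>T at TCG or a G>A at CGA and the
  # total count is within 3 sigma of Binomial(K * n, r)
  r <- 2e-3
  pool <- inject_mutations(ref, motif_mutation_model(c("TCG:C>T" = r)),
                           100, seed = 4)
  g2 <- paste0(ref$sequence, substr(ref$sequence, 1, 2))
  K <- sum(stringi::stri_count_fixed(g2, "TCG"),
           stringi::stri_count_fixed(g2, "CGA"))
  expected <- K * 100 * r
  expect_lt(abs(nrow(pool$truth) - expected), 3 * sqrt(expected) + 1)
  expect_true(all(paste0(pool$truth$ref, ">", pool$truth$alt) %in%
                    c("C>T", "G>A")))
  # truth matches reference base and actual molecule content
  ref_at <- stringi::stri_sub(ref$sequence, pool$truth$pos, pool$truth$pos)
  expect_identical(ref_at, pool$truth$ref)
  mol_at <- stringi::stri_sub(pool$molecules[pool$truth$molecule_id],
                              pool$truth$pos, pool$truth$pos)
  expect_identical(mol_at, pool$truth$alt)
})

test_that("a forced motif hit mutates every molecule", {
  # a single 5'TCG3' in poly-A: the C is mutated in every molecule (the
  # overlapping 5'CGA3' also carries the strand-symmetric G>A event)
  ref <- ref_genome(paste0(strrep("A", 20), "TCG", strrep("A", 20)),
                    circular = FALSE)
  pool <- inject_mutations(ref, motif_mutation_model(c("TCG:C>T" = 1)),
                           8, seed = 1)
  expect_true(all(stringi::stri_sub(pool$molecules, 22, 22) == "T"))
  expect_true(all(pool$truth$pos %in% c(22L, 23L)))

  # with a 3' G the motif has no overlapping reverse-complement partner,
  # so the C>T at position 22 is the only possible event
  ref2 <- ref_genome(paste0(strrep("A", 20), "TCGG", strrep("A", 20)),
                     circular = FALSE)
  pool2 <- inject_mutations(ref2, motif_mutation_model(c("TCG:C>T" = 1)),
                            8, seed = 2)
  expect_equal(nrow(pool2$truth), 8)
  expect_true(all(pool2$truth$pos == 22L & pool2$truth$alt == "T"))
})

test_that("injection is strand symmetric after context collapsing", {
  ref <- sim_reference(30000, gc_fraction = 0.45, seed = 9)
  model <- motif_mutation_model(c("TCG:C>T" = 5e-3, "GAA:A>G" = 3e-3))
  rc_ref <- ref_genome(revcomp(ref$sequence), circular = TRUE)
  spectrum_of <- function(truth, genome) {
    L <- nchar(genome$sequence)
    ext <- paste0(stringi::stri_sub(genome$sequence, L, L), genome$sequence,
                  stringi::stri_sub(genome$sequence, 1, 1))
    ctx <- stringi::stri_sub(ext, truth$pos, truth$pos + 2)
    sort(table(paste(collapse_type(truth$ref, truth$alt),
                     collapse_context(ctx))))
  }
  p1 <- inject_mutations(ref, model, 60, seed = 10)
  p2 <- inject_mutations(rc_ref, model, 60, seed = 10)
  # same seed + reverse-complemented genome: identical collapsed spectrum
  expect_identical(spectrum_of(p1$truth, ref), spectrum_of(p2$truth, rc_ref))
})

test_that("excessive per-site rates are rejected", {
  ref <- sim_reference(1000, seed = 1)
  model <- mutation_model(base_rates = c("C>T" = 0.5),
                          context_multipliers = c("TCG:C>T" = 3))
  expect_error(inject_mutations(ref, model, 2, seed = 1),
               class = "deamscan_invalid_model")
})

test_that("rolling-circle reads are tandem copies of their fragment", {
  ref <- sim_reference(5000, seed = 21)
  pool <- inject_mutations(ref, mutation_model(), 3, seed = 1)
  rr <- sim_rc_reads(pool, 200, read_len = 300, seed = 22)
  expect_equal(nrow(rr$reads), 200)
  expect_equal(nchar(rr$reads$sequence[1]), 300)
  # tandem invariant r[i] == r[i + p] and agreement with the recorded
  # fragment/phase for every noiseless read
  for (i in seq_len(20)) {
    s <- rr$reads$sequence[i]
    p <- rr$truth$fragment_len[i]
    expect_identical(substr(s, 1, 300 - p), substr(s, p + 1, 300))
    cyc <- truth_consensus(pool, rr$truth[i, ])
    expect_identical(s, substr(strrep(cyc, 4), 1, 300))
  }
})

test_that("fragment/read length arithmetic gives the expected copy number", {
  # fragment 120 read into 150 bases: one full copy plus a 30-base partial
  ref <- sim_reference(2000, seed = 30)
  rr <- sim_rc_reads(inject_mutations(ref, mutation_model(), 1, seed = 1),
                     50, read_len = 150, frag_len_range = c(120, 120),
                     seed = 31)
  s <- rr$reads$sequence[1]
  expect_equal(nchar(s), 150)
  expect_identical(substr(s, 121, 150), substr(s, 1, 30))
})

test_that("read errors occur at the configured rate", {
  ref <- sim_reference(4000, seed = 41)
  pool <- inject_mutations(ref, mutation_model(), 2, seed = 1)
  rr <- sim_rc_reads(pool, 400, read_len = 300, error_rate = 0.01, seed = 42)
  mism <- 0L
  for (i in seq_len(400)) {
    expected <- substr(strrep(truth_consensus(pool, rr$truth[i, ]), 4), 1, 300)
    mism <- mism + sum(utf8ToInt(rr$reads$sequence[i]) != utf8ToInt(expected))
  }
  n_bases <- 400 * 300
  # substitution draws can repeat a position, losing a fraction ~ e of
  # events, and a third of re-draws restore the original base; allow the
  # binomial 3 sigma on top of that small deficit
  expect_lt(abs(mism / n_bases - 0.01), 3 * sqrt(0.01 * 0.99 / n_bases) + 2e-4)
})

test_that("read simulation is deterministic and paired mode folds cleanly", {
  ref <- sim_reference(3000, seed = 51)
  pool <- inject_mutations(ref, mutation_model(), 2, seed = 1)
  a <- sim_rc_reads(pool, 50, seed = 52, low_q_prob = 0.05)
  b <- sim_rc_reads(pool, 50, seed = 52, low_q_prob = 0.05)
  expect_identical(a, b)

  pe <- sim_rc_reads(pool, 30, read_len = 150, mode = "paired", seed = 53)
  expect_equal(nrow(pe$reads), 60)
  # both mates obey the tandem invariant against the recorded phase/strand
  for (i in seq_len(12)) {
    cyc <- truth_consensus(pool, pe$truth[i, ])
    expect_identical(pe$reads$sequence[i], substr(strrep(cyc, 4), 1, 150))
  }
})

test_that("invalid read-simulation arguments error", {
  ref <- sim_reference(1000, seed = 1)
  pool <- inject_mutations(ref, mutation_model(), 1, seed = 1)
  expect_error(sim_rc_reads(pool, 10, read_len = 80),
               class = "deamscan_invalid_argument")
  expect_error(sim_rc_reads(pool, 10, error_rate = 0.6),
               class = "deamscan_invalid_argument")
})

test_that("time courses follow the exponential closed form", {
  # at t = 0 the fraction is 0; with k = 0 it stays 0
  tc0 <- sim_timecourse(0.01, times = c(0, 10, 20), noise_sd = 0)
  expect_equal(tc0$fraction[tc0$time_min == 0], 0)
  flat <- sim_timecourse(0, times = c(0, 30, 60), noise_sd = 0)
  expect_true(all(flat$fraction == 0))
  # at the half-life ln(2)/k the noiseless fraction is exactly 1/2
  k <- 0.008
  th <- log(2) / k
  tc <- sim_timecourse(k, times = c(0, th, 2 * th), plateau = 1, noise_sd = 0)
  expect_equal(tc$fraction[tc$time_min == th], 0.5, tolerance = 1e-12)
  expect_error(sim_timecourse(0.01, times = c(-1, 5)),
               class = "deamscan_invalid_argument")
})

test_that("fluctuation assay counts are Poisson with the right mean", {
  zero <- sim_fluctuation_assay(20, 1e8, 0, seed = 1)
  expect_true(all(zero$colonies == 0))
  x <- sim_fluctuation_assay(1000, 1e8, 4e-8, seed = 2)
  # mean within 3 sigma of Poisson(4): sd of the mean = 2/sqrt(1000)
  expect_lt(abs(mean(x$colonies) - 4), 3 * 2 / sqrt(1000))
  # doubling viable cells doubles counts but not the frequency estimate
  y <- sim_fluctuation_assay(1000, 2e8, 4e-8, seed = 3)
  fx <- median(mutation_frequency(x)$frequency)
  fy <- median(mutation_frequency(y)$frequency)
  expect_lt(abs(fy / fx - 1), 0.25)
})
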