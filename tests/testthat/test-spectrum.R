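# Placement, tallying, spectrum arithmetic and group comparisons.

test_that("exact unique substrings place with zero mismatches", {
  set.seed(201)
  ref <- ref_genome(random_dna(3000), circular = FALSE)
  cons <- tibble::tibble(read_id = "c1",
                         sequence = substr(ref$sequence, 501, 600))
  pl <- place_consensus(cons, ref)
  expect_equal(pl$placements$status, "placed")
  expect_equal(pl$placements$ref_start, 501L)
  expect_equal(pl$placements$strand, "+")
  expect_equal(pl$placements$n_mismatch, 0L)
  expect_equal(nrow(pl$mismatches), 0)
})

test_that("a substituted base is reported as exactly one mismatch", {
  set.seed(202)
  ref <- ref_genome(random_dna(3000), circular = FALSE)
  s <- substr(ref$sequence, 1001, 1100)
  target <- 37
  orig <- substr(s, target, target)
  alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(s, target, target) <- alt
  pl <- place_consensus(tibble::tibble(read_id = "c1", sequence = s), ref)
  expect_equal(pl$placements$status, "placed")
  expect_equal(pl$mismatches$ref_pos, 1000L + target)
  expect_equal(pl$mismatches$ref_base, orig)
  expect_equal(pl$mismatches$obs_base, alt)
})

test_that("repeated reference content abstains as ambiguous", {
  set.seed(203)
  unit <- random_dna(120)
  filler1 <- random_dna(400)
  filler2 <- random_dna(400)
  ref <- ref_genome(paste0(filler1, unit, filler2, unit, random_dna(200)),
                    circular = FALSE)
  pl <- place_consensus(tibble::tibble(read_id = "c1",
                                       sequence = substr(unit, 11, 110)), ref)
  expect_equal(pl$placements$status, "ambiguous")
})

test_that("rotated and reverse-complemented fragments place correctly", {
  set.seed(204)
  ref <- ref_genome(random_dna(5000), circular = TRUE)
  frag <- substr(ref$sequence, 2001, 2100)
  rot <- paste0(substr(frag, 41, 100), substr(frag, 1, 40))
  pl <- place_consensus(tibble::tibble(read_id = "r", sequence = rot), ref)
  expect_equal(pl$placements$status, "placed")
  expect_equal(pl$placements$ref_start, 2001L)
  expect_equal(pl$placements$aligned, frag)

  pl2 <- place_consensus(tibble::tibble(read_id = "rc", sequence = revcomp(rot)),
                         ref)
  expect_equal(pl2$placements$status, "placed")
  expect_equal(pl2$placements$ref_start, 2001L)
  expect_equal(pl2$placements$strand, "-")
  expect_equal(pl2$placements$aligned, frag)

  # a fragment spanning the circular origin still places
  wrap <- paste0(substr(ref$sequence, 4951, 5000), substr(ref$sequence, 1, 50))
  pl3 <- place_consensus(tibble::tibble(read_id = "w", sequence = wrap), ref)
  expect_equal(pl3$placements$status, "placed")
  expect_equal(pl3$placements$ref_start, 4951L)
})

test_that("tallies conserve observations and respect N bases", {
  set.seed(205)
  ref <- ref_genome(random_dna(1000), circular = FALSE)
  empty <- tally_sites(place_consensus(
    tibble::tibble(read_id = character(), sequence = character()), ref), ref)
  expect_true(all(empty$coverage == 0))

  s <- substr(ref$sequence, 101, 200)
  substr(s, 50, 50) <- setdiff(c("A","C","G","T"), substr(s, 50, 50))[1]
  s2 <- substr(ref$sequence, 151, 250)
  pl <- place_consensus(tibble::tibble(read_id = c("a", "b"),
                                       sequence = c(s, s2)), ref)
  tl <- tally_sites(pl, ref)
  expect_equal(sum(tl$coverage), 200)
  expect_equal(colSums(tl$counts), tl$coverage,
               ignore_attr = TRUE)
  # overlap covered twice, one non-reference observation in total
  expect_true(all(tl$coverage[151:200] == 2))
  v <- call_variants(tl)
  expect_equal(nrow(v), 1)
  expect_equal(sum(v$count), 1)

  # an N base drops out of both coverage and mutation counts
  sN <- substr(ref$sequence, 301, 400)
  substr(sN, 10, 10) <- "N"
  plN <- place_consensus(tibble::tibble(read_id = "n", sequence = sN), ref)
  tlN <- tally_sites(plN, ref)
  expect_equal(tlN$coverage[310], 0)
  expect_equal(sum(tlN$coverage), 99)
})

test_that("spectrum frequencies follow the stated ratio formula", {
  # 2 C>T and 1 G>A over 300 coverage-weighted C+G site-observations: 0.01
  ref <- ref_genome(paste(rep(c("C", "G", "A"), 200), collapse = ""),
                    circular = FALSE)
  L <- nchar(ref$sequence)
  coverage <- integer(L)
  counts <- matrix(0L, 4, L, dimnames = list(c("A","C","G","T"), NULL))
  bases <- strsplit(ref$sequence, "")[[1]]
  cg <- which(bases %in% c("C", "G"))[1:300]
  coverage[cg] <- 1L
  counts[cbind(match(bases[cg], c("A","C","G","T")), cg)] <- 1L
  # convert two covered C sites to C>T and one covered G site to G>A
  c_sites <- cg[bases[cg] == "C"][1:2]
  g_site <- cg[bases[cg] == "G"][1]
  counts["C", c_sites] <- 0L; counts["T", c_sites] <- 1L
  counts["G", g_site] <- 0L; counts["A", g_site] <- 1L
  tl <- make_tally(ref, coverage, counts)
  sp <- mutation_spectrum(tl)
  expect_equal(sp$frequency[sp$type == "C:G>T:A"], 0.01)
  expect_equal(sp$n_sites[sp$type == "C:G>T:A"], 300)
  expect_true(all(sp$frequency[sp$type != "C:G>T:A"] == 0))

  # no coverage at all: frequencies are 0, not NaN
  sp0 <- mutation_spectrum(make_tally(ref, integer(L),
                                      matrix(0L, 4, L,
                                             dimnames = list(c("A","C","G","T"), NULL))))
  expect_true(all(sp0$frequency == 0))
})

test_that("context assignment collapses onto the canonical strand", {
  # a G>A observation inside a top-strand 5'CGA3' counts as TCG
  ref <- ref_genome(paste0("AAAAAAAAAACGAAAAAAAAAA", strrep("T", 10)),
                    circular = FALSE)
  L <- nchar(ref$sequence)
  coverage <- rep(1L, L)
  bases <- strsplit(ref$sequence, "")[[1]]
  counts <- matrix(0L, 4, L, dimnames = list(c("A","C","G","T"), NULL))
  counts[cbind(match(bases, c("A","C","G","T")), seq_len(L))] <- 1L
  counts["G", 12] <- 0L
  counts["A", 12] <- 1L
  tl <- make_tally(ref, coverage, counts)
  cs <- context_spectrum(tl)
  hit <- cs[cs$n_mut > 0, ]
  expect_equal(hit$type, "C:G>T:A")
  expect_equal(hit$context, "TCG")
  expect_equal(hit$n_mut, 1L)
  # default denominator: identical across all 16 rows of a class
  expect_equal(length(unique(cs$n_sites[cs$type == "C:G>T:A"])), 1L)
  # per-context denominators sum to (at most) the class total
  pc <- context_spectrum(tl, denominator = "per-context")
  expect_lte(sum(pc$n_sites[pc$type == "C:G>T:A"]),
             unique(cs$n_sites[cs$type == "C:G>T:A"]))
})

test_that("context numerators partition the type numerator", {
  ref <- sim_reference(20000, seed = 211)
  pool <- inject_mutations(
    ref, motif_mutation_model(c("TCG:C>T" = 2e-3, "GAA:A>G" = 1e-3)),
    40, seed = 212)
  rr <- sim_rc_reads(pool, 3000, seed = 213)
  cc <- call_consensus(rr$reads)
  tl <- tally_sites(place_consensus(cc$consensus, ref), ref)
  sp <- mutation_spectrum(tl)
  cs <- context_spectrum(tl)
  for (tp in c("C:G>T:A", "A:T>G:C")) {
    expect_equal(sum(cs$n_mut[cs$type == tp]), sp$n_mut[sp$type == tp])
  }
  # motif-only injection: the target contexts dominate
  top_c <- cs$context[cs$type == "C:G>T:A"][which.max(cs$n_mut[cs$type == "C:G>T:A"])]
  expect_equal(top_c, "TCG")
})

test_that("the full spectrum is invariant under reverse complementation", {
  ref <- sim_reference(8000, seed = 221)
  pool <- inject_mutations(ref, motif_mutation_model(c("TCG:C>T" = 2e-3)),
                           20, seed = 222)
  rr <- sim_rc_reads(pool, 1500, seed = 223)
  run <- function(reads, genome) {
    cc <- call_consensus(reads)
    tl <- tally_sites(place_consensus(cc$consensus, genome), genome)
    list(spectrum = mutation_spectrum(tl)[c("type", "n_mut", "n_sites")],
         contexts = context_spectrum(tl)[c("type", "context", "n_mut")])
  }
  fwd <- run(rr$reads, ref)
  rc_reads <- rr$reads
  rc_reads$sequence <- revcomp(rc_reads$sequence)
  rc_reads$quality <- stringi::stri_reverse(rc_reads$quality)
  rev <- run(rc_reads, ref_genome(revcomp(ref$sequence), circular = TRUE))
  expect_identical(fwd$spectrum, rev$spectrum)
  expect_identical(fwd$contexts, rev$contexts)
})

test_that("group comparison flags shifted groups and matches the permutation check", {
  make_spectra <- function(means, sds, n = 3, seed) {
    withr::with_seed(seed, {
      dplyr::bind_rows(lapply(names(means), function(g) {
        tibble::tibble(group = g, replicate = seq_len(n), type = "C:G>T:A",
                       frequency = rnorm(n, means[[g]], sds[[g]]))
      }))
    })
  }
  # identical values everywhere: nothing significant
  flat <- tidyr::crossing(group = c("a", "b", "c"), replicate = 1:3) |>
    dplyr::mutate(type = "C:G>T:A", frequency = 1e-5)
  res_flat <- compare_spectra(flat, n_perm = 200, seed = 1)
  expect_true(all(is.na(res_flat$tukey$p_adj) | res_flat$tukey$p_adj > 0.05))

  # one group shifted by 10 within-group SDs: Tukey flags its pairs
  shifted <- make_spectra(list(a = 1e-5, b = 1e-5, c = 1.0e-5 + 10 * 1e-6),
                          list(a = 1e-6, b = 1e-6, c = 1e-6), seed = 2)
  res <- compare_spectra(shifted, n_perm = 2000, seed = 3)
  tk <- res$tukey
  expect_true(all(tk$p_adj[grepl("c", tk$pair)] < 0.05))
  # ANOVA p and permutation p agree within Monte-Carlo error
  expect_lt(abs(res$anova$p_anova - res$anova$p_permutation),
            3 * sqrt(0.05 * 0.95 / 2000) + 0.01)

  expect_error(compare_spectra(flat[flat$replicate == 1, ]),
               class = "deamscan_invalid_design")
})
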