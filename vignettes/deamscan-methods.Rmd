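---
title: "Methods: rare-mutation detection, deamination kinetics and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-mutation detection, deamination kinetics and assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamscan)
```

deamscan characterises the DNA-editing activity of a deaminase — an enzyme
that converts cytosine to uracil (read as C>T after replication) or adenine
to inosine (read as A>G) — from three complementary experiments: genome-wide
rare-mutation detection by rolling-circle consensus sequencing, in vitro
deamination kinetics on designed oligonucleotide substrates, and
resistance-based mutagenesis assays. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions behind the
implementation.

## Rolling-circle consensus sequencing

### Why tandem reads

A deaminase acting on a bacterial genome leaves rare substitutions —
roughly one event per 10^4–10^6 site-observations. Standard short-read
sequencing cannot see them: its per-base error (~10^-2 to 10^-3 after
quality filtering) swamps the signal. Rolling-circle (CirSeq-style) library
preparation solves this physically: genomic DNA is fragmented, size-selected
to 90–120 bp, denatured, circularised, and rolling-circle amplified so that
each sequencing read contains several tandem copies of one template
molecule. Because sequencer errors are independent across copies while a
true mutation is present in every copy, a per-read plurality vote suppresses
the error rate roughly quadratically: with three copies and per-base error
$e$, a wrong consensus call requires at least two coincident errors, so the
miscall probability is bounded by $3e^2(1-e) + e^3$ — about $3\times10^{-4}$
at $e = 0.01$, and the realised rate is lower still because two errors must
also agree on the same wrong base.

### The consensus caller

`call_consensus()` runs three stages, none of which ever consults the
reference genome (no reference leakage into the error correction):

1. **Quality filtering** (`qc_filter()`). Reads whose mean Phred score falls
   below `min_mean_quality` (default 20) are dropped; individual bases below
   `quality_mask_threshold` (default 20) are masked — kept in the read but
   excluded from voting. Both knobs exist because a read-level Q20 rule can
   be applied either way; the defaults apply both.
2. **Period detection** (`detect_period()`). The tandem period (= the
   circularised fragment length) is the offset $p$ in `period_range`
   (default 90–120) minimising the self-mismatch fraction between the read
   and itself shifted by $p$. A period is accepted only if that fraction is
   at most `max_period_mismatch` (default 0.1) and the compared overlap is
   at least `min_overlap` (default 25 bp); otherwise the read abstains. For
   an i.i.d. random sequence the expected self-mismatch is ~0.75, so false
   periods are effectively impossible; at 1% read error the true offset
   scores ~$2e(1-e) \approx 0.02$, far below the threshold. Ties break
   toward the smaller period.
3. **Folding** (`fold_consensus()`). Read positions are binned by position
   modulo the period; unmasked observations vote per bin. The consensus base
   is the plurality; ties resolve by the higher summed Phred, then abstain
   as N. Bins with fewer than `min_copies` (default 2) observations give N.
   Trailing partial copies vote like full copies — with 300 b reads and
   90–120 bp fragments, a partial third copy is the norm, and discarding it
   would waste a third of the information.

The defaults `min_copies = 2` and plurality-with-quality-tie-break are
declared design choices: abstention (N) is the conservative default for a
2-copy disagreement, and the quality-sum tie-break uses information the
sequencer already provides. The consensus "quality" channel encodes the
per-base observation count (capped at 40) rather than a Phred probability,
because downstream tallying weights by support, not by error probability.

### Placement of circular fragments

A consensus fragment derives from a circularised molecule read out from a
random phase of the rolling circle, so it is a *rotation* of a contiguous
genome segment, not a substring. `place_consensus()` therefore seeds with
exact 21-mers sampled around the circular consensus on both strands, and for
every seed chooses the length-$L$ reference window that minimises mismatches
under the circular mapping fixed by the seed. Only a unique best placement
is accepted; fragments matching several distinct sites equally well abstain
as ambiguous, and fragments whose best placement exceeds
`max_mismatch_frac` (default 0.05) abstain rather than contaminate the
tally. One subtlety: when the bases flanking the true fragment happen to
equal the bases at its ends, windows shifted by the coincidence length are
genuinely indistinguishable from the data; these realise the same circular
alignment and are treated as one placement (preferring an unrotated window
when one ties), not as ambiguity. Placement is ungapped by design — the
tally counts substitutions only, and an indel-bearing fragment fails the
mismatch threshold and is counted as unplaced rather than silently dropped.

### Spectrum and context rates

`tally_sites()` accumulates per-site coverage and base counts, mapping
minus-strand placements onto the top strand; N bases count toward neither
coverage nor mutations, so base counts sum exactly to coverage at every
site. `mutation_spectrum()` reports the six collapsed substitution classes
(e.g. C:G>T:A pools C>T with G>A): the numerator is the number of
qualifying non-reference observations, the denominator the coverage-weighted
number of site-observations of the focal base pair (C+G sites for C:G-focal
classes, A+T otherwise), and the frequency their ratio. Rates are therefore
*per site-observation* (coverage-weighted), which is the quantity the
sequencing experiment actually measures; a per-site alternative would
require choosing a coverage cutoff.

`context_spectrum()` assigns each deamination-class mutation to the
collapsed trinucleotide context of its top-strand triplet — a context and
its reverse complement are one (5'TGT3' ≡ 5'ACA3'; a G>A inside 5'CGA3'
collapses to 5'TCG3'), giving 16 contexts per class. By default the
denominator is the *total* C+G (or A+T) coverage, identical across the 16
rows, matching the frequency-distribution convention for such tables;
`denominator = "per-context"` divides by each context's own coverage
instead, which is the statistically conventional rate and is exposed
because the two disagree whenever context composition is uneven. Sites
lacking a flank on a linear reference are excluded from context tables
only, never from the six-type table.

`compare_spectra()` performs the standard multi-group comparison for
per-culture spectra — one-way ANOVA with Tukey's HSD per substitution type —
and additionally reports a seeded label-permutation p-value for the F
statistic as an internal cross-check; with the tiny group sizes typical of
such designs (n = 3 cultures), agreement between the two is evidence the
normality assumption is not driving the call. Tukey's HSD is the only
multiplicity adjustment applied; no additional FDR layer is added on top.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with ground-truth
sidecars, under the conditions the analyses assume:

- `sim_reference()` draws i.i.d. bases at a chosen GC fraction (default
  0.5, circular). Real bacterial genomes have skews, repeats and coding
  structure that i.i.d. sequence lacks; passing tests on synthetic genomes
  therefore demonstrates the pipeline's statistical behaviour, not its
  robustness to genomic repeat families (true repeats abstain as ambiguous
  placements, which the tests exercise synthetically).
- `inject_mutations()` applies a strand-symmetric `mutation_model()`:
  per-substitution base rates times per-(context, substitution)
  multipliers. `motif_mutation_model()` builds the deaminase-style case —
  e.g. C>T only within 5'TCG3' at a fixed per-site, per-molecule
  probability, automatically mirrored to G>A within top-strand 5'CGA3'.
  Molecules are mutated independently (no lineage or jackpot structure);
  jackpots appear only in the fluctuation-assay generator, which is the
  arm where they matter.
- `sim_rc_reads()` emits merged reads (default 300 b, the insert size of a
  PE150 library with ~300 bp inserts, giving ≥2.5 copies of a 90–120 bp
  fragment) or independent 150 b mates. Errors are substitution-only and
  i.i.d. — the analysis tallies substitutions only, and indel errors would
  be absorbed by the placement mismatch threshold. Qualities follow a
  two-state model (Q36 / Q11 at probability `low_q_prob`) so the
  quality-masking rule is exercisable. Coordinates in all truth sidecars
  are 1-based inclusive.
- `sim_timecourse()` and `sim_fluctuation_assay()` generate the kinetics
  and assay inputs described below.

Sequencing depth per culture and the callable genome fraction are not
dictated by the experimental design being emulated; they are free
parameters of the generator, and the test suite sizes them for the
statistical bound being checked (stated per test below).

## Deamination kinetics

The gel read-out quantifies, per time point, cleaved and uncleaved band
intensities; `fraction_deaminated()` computes cleaved / (cleaved +
uncleaved). `fit_kapp()` fits the rise-to-plateau single exponential

$$F(t) = P\,(1 - e^{-k_{\mathrm{app}} t})$$

per replicate by Levenberg–Marquardt nonlinear least squares, with the
initial rate taken from the earliest nonzero points. The apparent
first-order rate constant $k_{app}$ (min⁻¹) is reported as the replicate
mean, and its SEM is computed *across replicate fits* — matching the
mean ± SEM over independent experiments convention — rather than from the
covariance matrix of a pooled fit. If the analysed reaction instead follows
substrate decay $e^{-kt}$, the fitted $k_{app}$ is identical, so the choice
of parameterisation does not affect the rate constant.

The plateau $P$ is *fitted* within (0, 1] by default, because incomplete
cleavage and incomplete substrate folding routinely cap real reactions
below 1; `fix_plateau = 1` pins it for comparability. The two modes are
reported in the output metadata. A caveat that drove the validation design:
when a slow reaction (e.g. $k = 3\times10^{-4}$ min⁻¹) is sampled only over
its initial quasi-linear phase, $k$ and $P$ enter the model essentially as
the product $kP$ and are jointly unidentifiable — no fitting algorithm can
beat that. The kinetics-recovery tests therefore use sampling grids scaled
to ~2/k (capped at 25 h) and the fixed-plateau mode; under those conditions
the median relative error over 200 noisy courses (Gaussian sd 0.02) is
~2%, comfortably inside the 10% bound asserted. Flat all-zero courses
return $k_{app} = 0$ with a `no_signal` flag instead of a fit.

`fold_ratio()` compares substrates; the rounding mode is explicit
(`nearest_fold` vs `one_decimal`) because published comparisons mix integer
("sixfold") and one-decimal ("5.3-fold") statements, and silently choosing
one would misreproduce the other.

## Substrate annotation and cleavage read-out

`annotate_substrate()` models the designed oligos: an exhaustive search
over single-hairpin registers finds the longest contiguous Watson–Crick
stem (no G·T wobble, no multi-loop structures — every in-scope substrate is
a designed single hairpin or a linear oligo) with a loop of at least
`min_loop = 3` nt. A molecule is classified `hairpin` when the stem reaches
`min_stem = 4` bp, `mixed` when a qualifying hairpin carries a
single-stranded tail of `max_tail = 8` nt or more (the hairpin-plus-linear
composite substrates), and `linear` otherwise. Ties in stem length prefer
the 5'-most, then outermost register — a deterministic, documented rule for
a case real designed substrates avoid.

The two enzymatic read-outs give different labelled 5'-fragment lengths
from the same target: endonuclease V cleaves the second phosphodiester
bond 3' of deoxyinosine (A-editing; fragment = target + 1 nt), while
uracil-DNA glycosylase plus alkali breaks the strand at the abasic site
itself (C-editing; fragment = target − 1 nt); the two always differ by
exactly 2 nt, which `predict_cleavage_fragment()` enforces and the tests
assert. Targets too close to an end to leave a fragment inside (0, L) raise
an edge-case error rather than a clamped number.

## Resistance-assay statistics

`mutation_frequency()` computes, per culture, resistant colonies divided by
viable cells (with a plating dilution correction) — the mutation
*frequency* estimator, deliberately not a Luria–Delbrück mutation-*rate*
estimator: the emulated experiments report frequencies and medians, and an
m-estimator would answer a different question. Group summaries use medians
because per-culture counts are jackpot-skewed. `compare_frequencies()`
applies the two-tailed Wilcoxon rank-sum test: exact enumeration whenever
both groups have ≤10 cultures and the values are tie-free, otherwise the
normal approximation with mid-ranks, tie-corrected variance and continuity
correction; with completely tied data the test carries no evidence and
p = 1 is reported. The exact branch is validated against an exhaustive
enumeration oracle for all group sizes up to 8.

`classify_clone_mutation()` identifies the single substitution of a
sequenced resistant clone against its marker-gene reference (strictly one
by default — one colony per culture carries one causal mutation; a
multi-hit clone errors unless `strict = FALSE`), and annotates collapsed
pair notation, collapsed triplet context, and — when a reading frame and
residue offset are supplied — a codon label in the marker-gene style
"S512 (tct)": wild-type residue letter, gene-level residue number,
lower-case wild-type codon. `structure_site_fraction()` then reports the
fraction of deamination-class calls (C:G>T:A and A:T>G:C only) at
loop-annotated positions; structure classes arrive as an input table
because gene-scale secondary-structure prediction is out of scope here.

## Numerical and validation choices

- **Determinism.** Every generator takes an optional seed and restores the
  RNG state afterwards; identical seeds give byte-identical outputs. The
  analysis stages are deterministic by construction.
- **Problem sizes.** The end-to-end recovery check uses a 100 kb genome,
  1000 molecules, motif C>T at 1×10⁻⁴ per site per molecule, and 1.55
  million 300 b reads — sized so that ≥500 mutation observations are
  expected, at which point the Poisson sampling error of the rate estimate
  (~4.5%) sits well inside the 20% bound being asserted. That run executes
  with the sequencing-error channel off, isolating coordinate bookkeeping,
  strand collapsing and denominator accounting: at 1% read error the
  residual consensus miscall floor (~10⁻⁴–10⁻⁵ per site-observation at 2–3
  copies) would exceed the injected signal (~6×10⁻⁶ per C:G
  site-observation) and the comparison would measure the error floor, not
  the pipeline. Sequencing noise is instead exercised by two dedicated
  checks: the consensus miscall bound at 1% error and three copies over
  ≥10⁵ bases, and the false-positive floor (no injection, 1% error,
  `min_copies = 3`, rate < 3×10⁻⁴ per site-observation).
- **Oracles.** The consensus vote, the rank-sum p-value and the hairpin
  register search are each validated against independent brute-force
  enumerations (all ≤12-base two-letter reads at periods ≤4; all group
  sizes ≤8; all registers of ≤14-mers). The exponential fit is validated by
  closed-form round trips.
- **Hot paths.** Period detection, consensus voting, placement and
  tallying are implemented in C++ (Rcpp), as per-base loops over millions
  of reads; everything else is vectorised R.

## Known limitations

- The i.i.d. reference has no repeat families, GC skew or coding
  constraint; placement ambiguity on real genomes will be higher.
- No PCR-duplicate, GC-bias or indel modelling in the read simulator; no
  adapter trimming (reads are generated adapter-free), no paired-mate
  co-folding, and no base-quality recalibration.
- The hairpin model is single-stem Watson–Crick only; thermodynamic
  folding and wobble pairs are out of scope.
- Mutation frequencies are not converted to Luria–Delbrück rates.
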