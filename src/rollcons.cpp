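#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Per-read tandem-repeat period detection: the period p in [pmin, pmax]
// minimising the self-offset mismatch fraction between read[0..L-p) and
// read[p..L), accepted only if the fraction is <= max_mm and the compared
// overlap is >= min_overlap. Ties break toward the smaller p. NA = abstain.
// [[Rcpp::export]]
IntegerVector cpp_detect_period(CharacterVector reads, int pmin, int pmax,
                                double max_mm, int min_overlap) {
  int n = reads.size();
  IntegerVector out(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) continue;
    const char *s = CHAR(reads[r]);
    int L = LENGTH(reads[r]);
    int best_p = NA_INTEGER;
    double best_frac = R_PosInf;
    for (int p = pmin; p <= pmax; ++p) {
      int overlap = L - p;
      if (overlap < min_overlap) break;
      double cut = std::min(max_mm, best_frac);
      int limit = (int)std::floor(cut * overlap); // allowable mismatches
      int mm = 0;
      for (int i = 0; i < overlap; ++i) {
        if (s[i] != s[i + p]) {
          if (++mm > limit) break;
        }
      }
      double frac = (double)mm / overlap;
      if (frac <= max_mm && frac < best_frac) {
        best_frac = frac;
        best_p = p;
      }
    }
    out[r] = best_p;
  }
  return out;
}

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// Fold each tandem read into a per-period consensus by per-bin plurality
// vote over unmasked observations. Ties resolve by higher total Phred, then
// N; bins with fewer than min_copies observations give N. Returns the
// consensus string, a support string (Phred+33-encoded observation count,
// capped at 40), and bookkeeping counts.
// [[Rcpp::export]]
List cpp_fold_consensus(CharacterVector reads, CharacterVector quals,
                        IntegerVector periods, int qmask, int min_copies) {
  int n = reads.size();
  CharacterVector cons(n, NA_STRING), support(n, NA_STRING);
  IntegerVector copies(n, NA_INTEGER), n_masked(n, 0), n_called(n, 0),
      n_ambig(n, 0);
  std::string cbuf, sbuf;
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING || periods[r] == NA_INTEGER) continue;
    const char *s = CHAR(reads[r]);
    const char *q = CHAR(quals[r]);
    int L = LENGTH(reads[r]);
    int p = periods[r];
    if (p <= 0 || p >= L) continue;
    cbuf.assign(p, 'N');
    sbuf.assign(p, '!');
    int masked = 0, called = 0, ambig = 0;
    for (int j = 0; j < p; ++j) {
      int cnt[4] = {0, 0, 0, 0};
      int qsum[4] = {0, 0, 0, 0};
      int total = 0;
      for (int i = j; i < L; i += p) {
        int phred = q[i] - 33;
        int b = base_index(s[i]);
        if (phred < qmask || b < 0) {
          ++masked;
          continue;
        }
        ++cnt[b];
        qsum[b] += phred;
        ++total;
      }
      sbuf[j] = (char)(33 + std::min(total, 40));
      if (total < min_copies) continue;
      int best = 0;
      for (int b = 1; b < 4; ++b) {
        if (cnt[b] > cnt[best] ||
            (cnt[b] == cnt[best] && qsum[b] > qsum[best]))
          best = b;
      }
      bool tie = false;
      for (int b = 0; b < 4; ++b) {
        if (b != best && cnt[b] == cnt[best] && qsum[b] == qsum[best])
          tie = true;
      }
      if (tie) {
        ++ambig;
        continue;
      }
      cbuf[j] = "ACGT"[best];
      ++called;
    }
    cons[r] = cbuf;
    support[r] = sbuf;
    copies[r] = (L + p - 1) / p; // full plus trailing partial copies
    n_masked[r] = masked;
    n_called[r] = called;
    n_ambig[r] = ambig;
  }
  return List::create(_["consensus"] = cons, _["support"] = support,
                      _["copies_used"] = copies, _["n_masked"] = n_masked,
                      _["n_called"] = n_called, _["n_tied"] = n_ambig);
}

// [[Rcpp::export]]
NumericVector cpp_mean_qual(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n, NA_REAL);
  for (int r = 0; r < n; ++r) {
    if (quals[r] == NA_STRING) continue;
    const char *q = CHAR(quals[r]);
    int L = LENGTH(quals[r]);
    if (L == 0) continue;
    long sum = 0;
    for (int i = 0; i < L; ++i) sum += q[i] - 33;
    out[r] = (double)sum / L;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_count_below(CharacterVector quals, int threshold) {
  int n = quals.size();
  IntegerVector out(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    if (quals[r] == NA_STRING) continue;
    const char *q = CHAR(quals[r]);
    int L = LENGTH(quals[r]);
    int k = 0;
    for (int i = 0; i < L; ++i)
      if (q[i] - 33 < threshold) ++k;
    out[r] = k;
  }
  return out;
}

struct Candidate {
  int start;     // 0-based window start on the reference (may wrap if circular)
  int rotation;  // consensus index aligned to the window start
  bool minus;    // alignment uses the reverse-complemented consensus
  int mm;        // mismatches over non-N bases
};

// A consensus fragment derives from a circularised molecule read out at an
// arbitrary phase, so it is a rotation of a contiguous reference segment.
// Each exact k-mer seed (consensus offset o -> reference position p) fixes
// the circular mapping cons[(o + q - p) mod clen] <-> ref[q]; the aligned
// window of length clen containing the seed is chosen to minimise
// mismatches.
static void score_seed(const std::string &q, const std::string &ref,
                       bool circular, int o, int p, int k, bool minus,
                       std::vector<Candidate> &out) {
  int clen = q.size();
  int L = ref.size();
  int lo = p + k - clen;     // leftmost window start keeping the seed inside
  int hi = p;                // rightmost window start
  if (!circular) {
    lo = std::max(lo, 0);
    hi = std::min(hi, L - clen);
    if (lo > hi) return;
  }
  // match indicator over candidate reference positions [lo, hi + clen)
  int span = hi + clen - lo;
  std::vector<int> mism(span + 1, 0);  // prefix sums of non-N mismatches
  std::vector<int> nns(span + 1, 0);   // prefix sums of N positions
  for (int t = 0; t < span; ++t) {
    int qpos = lo + t;
    int ci = ((o + qpos - p) % clen + clen) % clen;
    char c = q[ci];
    char rb = circular ? ref[((qpos % L) + L) % L] : ref[qpos];
    mism[t + 1] = mism[t] + (c != 'N' && c != rb ? 1 : 0);
    nns[t + 1] = nns[t] + (c == 'N' ? 1 : 0);
  }
  int best_s = lo, best_mm = INT_MAX;
  bool best_unrotated = false;
  for (int s = lo; s <= hi; ++s) {
    int t0 = s - lo;
    int mm = mism[t0 + clen] - mism[t0];
    // equal-scoring windows are indistinguishable; prefer an unrotated
    // alignment when one ties, else the leftmost window
    bool unrot = ((o + s - p) % clen + clen) % clen == 0;
    if (mm < best_mm || (mm == best_mm && unrot && !best_unrotated)) {
      best_mm = mm;
      best_s = s;
      best_unrotated = unrot;
    }
  }
  int s_norm = circular ? ((best_s % L) + L) % L : best_s;
  int rot = ((o + best_s - p) % clen + clen) % clen;
  out.push_back({s_norm, rot, minus, best_mm});
}

static void collect_seeds(const std::string &seq, int k,
                          const std::unordered_map<uint64_t, std::vector<int>> &index,
                          std::vector<std::pair<int, int>> &hits) {
  int L = seq.size();
  // sample the consensus circularly so a seed exists whatever the rotation
  for (int o = 0; o + k <= 2 * L - 1; o += k) {
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base_index(seq[(o + i) % L]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    auto it = index.find(key);
    if (it == index.end()) continue;
    for (int pos : it->second) hits.push_back({o % L, pos});
  }
}

// Place consensus fragments on the reference by exact k-mer seeding on both
// strands followed by rotation-aware ungapped scoring. The unique best
// placement (fewest mismatches over non-N bases, at most max_mm_frac of
// them) is reported with the rotated top-strand sequence; equal-best
// placements at distinct sites abstain as ambiguous. Coordinates are
// 1-based top-strand; circular references wrap.
// [[Rcpp::export]]
List cpp_place(CharacterVector cons, std::string ref, bool circular,
               double max_mm_frac, int k) {
  int L = ref.size();
  int n = cons.size();
  std::string ext = ref;
  if (circular && L > k) ext += ref.substr(0, k - 1); // junction k-mers

  std::unordered_map<uint64_t, std::vector<int>> index;
  if (L >= k) {
    index.reserve(L * 2);
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < (int)ext.size(); ++i) {
      int b = base_index(ext[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        int pos = i - k + 1;
        if (pos < L) index[key].push_back(pos);
      }
    }
  }

  IntegerVector ref_start(n, NA_INTEGER), n_mm(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING), status(n), aligned(n, NA_STRING);
  std::vector<int> mm_cons, mm_pos;
  std::vector<char> mm_ref, mm_obs;
  std::vector<std::pair<int, int>> hits;
  std::vector<Candidate> cand;
  std::string wbuf;

  for (int r = 0; r < n; ++r) {
    if (cons[r] == NA_STRING) { status[r] = "no_consensus"; continue; }
    std::string fwd = CHAR(cons[r]);
    int clen = fwd.size();
    int n_informative = 0;
    for (char c : fwd) if (c != 'N') ++n_informative;
    if (n_informative < k || clen > L) {
      status[r] = "too_short";
      continue;
    }
    std::string rev(clen, 'N');
    for (int i = 0; i < clen; ++i) {
      char c = fwd[clen - 1 - i];
      rev[i] = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C'
               : (c == 'T') ? 'A' : 'N';
    }
    hits.clear();
    cand.clear();
    collect_seeds(fwd, k, index, hits);
    size_t n_fwd = hits.size();
    collect_seeds(rev, k, index, hits);
    if (hits.empty()) { status[r] = "no_seed"; continue; }
    for (size_t h = 0; h < hits.size(); ++h) {
      bool minus = h >= n_fwd;
      score_seed(minus ? rev : fwd, ref, circular, hits[h].first,
                 hits[h].second, k, minus, cand);
    }
    if (cand.empty()) { status[r] = "no_seed"; continue; }
    // deduplicate identical placements, keep distinct ones for ambiguity
    std::sort(cand.begin(), cand.end(), [](const Candidate &a, const Candidate &b) {
      if (a.mm != b.mm) return a.mm < b.mm;
      if (a.start != b.start) return a.start < b.start;
      if (a.minus != b.minus) return a.minus < b.minus;
      return a.rotation < b.rotation;
    });
    cand.erase(std::unique(cand.begin(), cand.end(),
                           [](const Candidate &a, const Candidate &b) {
                             return a.start == b.start && a.minus == b.minus &&
                                    a.rotation == b.rotation;
                           }),
               cand.end());
    int limit = (int)std::floor(max_mm_frac * n_informative);
    if (cand[0].mm > limit) { status[r] = "too_many_mismatches"; continue; }
    // equal-best candidates that realise the same circular mapping in a
    // shifted window (possible when bases flanking the fragment coincide)
    // are one placement, not an ambiguity
    bool ambiguous = false;
    int anchor0 = ((cand[0].rotation - cand[0].start) % clen + clen) % clen;
    for (size_t ci = 1; ci < cand.size() && cand[ci].mm == cand[0].mm; ++ci) {
      int anchor = ((cand[ci].rotation - cand[ci].start) % clen + clen) % clen;
      int d = cand[ci].start - cand[0].start;
      if (circular) d = ((d % L) + L) % L;
      int dist = circular ? std::min(d, L - d) : std::abs(d);
      if (cand[ci].minus != cand[0].minus || anchor != anchor0 ||
          dist >= clen) {
        ambiguous = true;
        break;
      }
    }
    if (ambiguous) {
      status[r] = "ambiguous";
      continue;
    }
    const Candidate &b = cand[0];
    const std::string &q = b.minus ? rev : fwd;
    ref_start[r] = b.start + 1;
    strand[r] = b.minus ? "-" : "+";
    n_mm[r] = b.mm;
    status[r] = "placed";
    wbuf.assign(clen, 'N');
    for (int w = 0; w < clen; ++w) {
      char c = q[(b.rotation + w) % clen];
      wbuf[w] = c;
      if (c == 'N') continue;
      int rp = circular ? (b.start + w) % L : b.start + w;
      if (c != ref[rp]) {
        mm_cons.push_back(r + 1);
        mm_pos.push_back(rp + 1);
        mm_ref.push_back(ref[rp]);
        mm_obs.push_back(c);
      }
    }
    aligned[r] = wbuf;
  }
  int m = mm_cons.size();
  CharacterVector mr(m), mo(m);
  for (int i = 0; i < m; ++i) {
    mr[i] = std::string(1, mm_ref[i]);
    mo[i] = std::string(1, mm_obs[i]);
  }
  return List::create(
      _["ref_start"] = ref_start, _["strand"] = strand, _["n_mismatch"] = n_mm,
      _["status"] = status, _["aligned"] = aligned,
      _["mismatch_cons"] = IntegerVector(mm_cons.begin(), mm_cons.end()),
      _["mismatch_pos"] = IntegerVector(mm_pos.begin(), mm_pos.end()),
      _["mismatch_ref"] = mr, _["mismatch_obs"] = mo);
}

// Accumulate per-site coverage and base counts from placed consensus
// fragments already expressed on the top strand. N bases contribute
// nothing. Positions wrap modulo the reference length.
// [[Rcpp::export]]
List cpp_tally(CharacterVector top_seqs, IntegerVector starts, int ref_len) {
  IntegerVector coverage(ref_len, 0);
  IntegerMatrix counts(4, ref_len);
  int n = top_seqs.size();
  for (int r = 0; r < n; ++r) {
    if (top_seqs[r] == NA_STRING || starts[r] == NA_INTEGER) continue;
    const char *s = CHAR(top_seqs[r]);
    int L = LENGTH(top_seqs[r]);
    int s0 = starts[r] - 1;
    for (int i = 0; i < L; ++i) {
      int b = base_index(s[i]);
      if (b < 0) continue;
      int pos = (s0 + i) % ref_len;
      ++coverage[pos];
      ++counts(b, pos);
    }
  }
  return List::create(_["coverage"] = coverage, _["counts"] = counts);
}
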