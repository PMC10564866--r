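#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Affine-gap Smith-Waterman. A gap of length k costs gap_open + k * gap_ext
// (both supplied as positive numbers). Traceback prefers diagonal, then a gap
// in the query, then a gap in the subject; the endpoint is the first maximal
// cell in row-major scan order, which makes results deterministic.
// [[Rcpp::export]]
List cpp_align_local(std::string query, std::string subject,
                     int match = 1, int mismatch = -2,
                     int gap_open = 5, int gap_ext = 2) {
  const int n = query.size(), m = subject.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // H: best score ending at (i,j); E: gap in subject (consume query);
  // F: gap in query (consume subject). Stored row-major, (n+1) x (m+1).
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, INT_MIN / 4),
      F((n + 1) * W, INT_MIN / 4);
  // trace: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  std::vector<unsigned char> tr((n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qi = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int e = std::max(H[(i - 1) * W + j] - gap_open - gap_ext,
                             E[(i - 1) * W + j] - gap_ext);
      const int f = std::max(H[idx - 1] - gap_open - gap_ext,
                             F[idx - 1] - gap_ext);
      const int s = (qi == subject[j - 1] && qi != 'N') ? match : mismatch;
      const int d = H[(i - 1) * W + (j - 1)] + s;
      int h = d; unsigned char t = 1;
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[idx] = h; E[idx] = e; F[idx] = f; tr[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER,
                        _["subject_start"] = NA_INTEGER,
                        _["subject_end"] = NA_INTEGER,
                        _["query_aln"] = "", _["subject_aln"] = "");
  std::string qa, sa;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && tr[i * W + j] != 0 && H[i * W + j] > 0) {
    const unsigned char t = tr[i * W + j];
    if (t == 1) { qa += query[i - 1]; sa += subject[j - 1]; --i; --j; }
    else if (t == 2) {
      // walk the whole gap run using E recurrence
      while (i > 0 && E[i * W + j] == E[(i - 1) * W + j] - gap_ext &&
             E[i * W + j] > H[(i - 1) * W + j] - gap_open - gap_ext) {
        qa += query[i - 1]; sa += '-'; --i;
      }
      qa += query[i - 1]; sa += '-'; --i;
    } else {
      while (j > 0 && F[i * W + j] == F[i * W + j - 1] - gap_ext &&
             F[i * W + j] > H[i * W + j - 1] - gap_open - gap_ext) {
        qa += '-'; sa += subject[j - 1]; --j;
      }
      qa += '-'; sa += subject[j - 1]; --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best, _["query_start"] = i + 1,
                      _["query_end"] = bi, _["subject_start"] = j + 1,
                      _["subject_end"] = bj, _["query_aln"] = qa,
                      _["subject_aln"] = sa);
}

// Score-only affine Smith-Waterman (same scheme and result as
// cpp_align_local's score), two-row rolling arrays; used to rank candidate
// germline segments before the single full-traceback alignment.
// [[Rcpp::export]]
int cpp_sw_score(std::string query, std::string subject,
                 int match = 1, int mismatch = -2,
                 int gap_open = 5, int gap_ext = 2) {
  const int n = query.size(), m = subject.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int NEG = INT_MIN / 4;
  std::vector<int> Hp(m + 1, 0), Hc(m + 1, 0), Ep(m + 1, NEG), Ec(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const char qi = query[i - 1];
    Hc[0] = 0; Ec[0] = NEG;
    int f = NEG;
    for (int j = 1; j <= m; ++j) {
      const int e = std::max(Hp[j] - gap_open - gap_ext, Ep[j] - gap_ext);
      f = std::max(Hc[j - 1] - gap_open - gap_ext, f - gap_ext);
      const int s = (qi == subject[j - 1] && qi != 'N') ? match : mismatch;
      int h = Hp[j - 1] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hc[j] = h; Ec[j] = e;
      if (h > best) best = h;
    }
    Hp.swap(Hc); Ep.swap(Ec);
  }
  return best;
}

// Needleman-Wunsch with linear gaps (match +1, mismatch -1, gap -2),
// diagonal-preferring traceback. Returns matches and alignment length,
// the two numbers the 99% dereplication identity is defined from.
// [[Rcpp::export]]
IntegerVector cpp_identity(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<int> S((n + 1) * W);
  for (int j = 0; j <= m; ++j) S[j] = -2 * j;
  for (int i = 1; i <= n; ++i) {
    S[i * W] = -2 * i;
    for (int j = 1; j <= m; ++j) {
      const int d = S[(i - 1) * W + j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
      const int u = S[(i - 1) * W + j] - 2;
      const int l = S[i * W + j - 1] - 2;
      S[i * W + j] = std::max(d, std::max(u, l));
    }
  }
  int i = n, j = m, matches = 0, len = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i * W + j] == S[(i - 1) * W + j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && S[i * W + j] == S[(i - 1) * W + j] - 2) {
      --i;
    } else {
      --j;
    }
    ++len;
  }
  return IntegerVector::create(_["matches"] = matches, _["aln_length"] = len);
}

// Banded variant of the decision "global-alignment identity >= threshold".
// Any alignment reaching identity t has at most (1-t)*(l1+l2) gap columns,
// so a band of that width around the diagonal contains every path that could
// qualify; outside-band paths cannot reach the threshold.
// [[Rcpp::export]]
bool cpp_identity_at_least(std::string a, std::string b, double threshold) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return false;
  const int maxlen = std::max(n, m);
  if ((double)std::min(n, m) / maxlen < threshold) return false;
  int band = (int)std::ceil((1.0 - threshold) * (n + m)) + std::abs(n - m) + 2;
  if (band > m) band = m;
  const int W = 2 * band + 1;
  const int NEG = INT_MIN / 4;
  // S in score space (match +1, mismatch -1, gap -2); track max matches
  // attainable at equal score to resolve the identity of the traced path is
  // unnecessary: we bound identity via best matches over any in-band path.
  // M[k] = max matches over paths to (i, j) with j - i = k - band.
  std::vector<int> M(W, NEG), Mn(W, NEG);
  M[band] = 0;
  for (int i = 0; i <= n; ++i) {
    if (i > 0) {
      std::fill(Mn.begin(), Mn.end(), NEG);
      for (int k = 0; k < W; ++k) {
        const int j = i + k - band;
        if (j < 0 || j > m) continue;
        int bestm = NEG;
        if (j > 0 && M[k] != NEG) {  // diag from (i-1, j-1): same k, prev row
          const int add = (a[i - 1] == b[j - 1]) ? 1 : 0;
          bestm = M[k] + add;
        }
        if (k + 1 < W && M[k + 1] != NEG && M[k + 1] > bestm)
          bestm = M[k + 1];  // up from (i-1, j): gap in b
        if (k > 0 && Mn[k - 1] != NEG && Mn[k - 1] > bestm)
          bestm = Mn[k - 1];  // left from (i, j-1): gap in a
        Mn[k] = bestm;
      }
      M.swap(Mn);
      // early abort: even with all remaining positions matching we cannot
      // reach threshold * max(n, m) matches
      int rowbest = NEG;
      for (int k = 0; k < W; ++k) if (M[k] > rowbest) rowbest = M[k];
      if (rowbest == NEG) return false;
      if (rowbest + (n - i) < threshold * maxlen - 1e-9) return false;
    } else {
      // row 0: leading gaps in a
      for (int k = band + 1; k < W; ++k) if (k - band <= m) M[k] = 0;
    }
  }
  const int k_end = m - n + band;
  if (k_end < 0 || k_end >= W || M[k_end] == NEG) return false;
  // identity = matches / aln_length with aln_length >= max(n, m); we use the
  // optimistic aln_length = max(n, m), an upper bound on identity, and then
  // confirm borderline accepts with the exact DP.
  if ((double)M[k_end] / maxlen < threshold) return false;
  IntegerVector ex = cpp_identity(a, b);
  return (double)ex[0] / ex[1] >= threshold;
}

// Hamming distance; -1 when lengths differ.
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) return -1;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// All unordered pairs at Hamming distance exactly 1 within a set of
// equal-length sequences. Early exit after the second mismatch.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming1_pairs(std::vector<std::string> seqs) {
  const int n = seqs.size();
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    const std::string &a = seqs[i];
    for (int j = i + 1; j < n; ++j) {
      const std::string &b = seqs[j];
      if (a.size() != b.size()) continue;
      int d = 0;
      for (size_t k = 0; k < a.size(); ++k) {
        if (a[k] != b[k] && ++d > 1) break;
      }
      if (d == 1) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t r = 0; r < ii.size(); ++r) { out(r, 0) = ii[r]; out(r, 1) = jj[r]; }
  return out;
}

// Overlap scan for paired-end merging: r2 must already be reverse
// complemented. Tries every overlap length ov in [min_overlap, min(l1, l2)],
// comparing the r1 suffix with the r2 prefix; keeps the ov maximizing matches
// subject to mismatch rate <= max_mm_rate (ties -> longer overlap).
// [[Rcpp::export]]
List cpp_find_overlap(std::string r1, std::string r2, int min_overlap,
                      double max_mm_rate) {
  const int l1 = r1.size(), l2 = r2.size();
  const int maxov = std::min(l1, l2);
  int best_ov = -1, best_matches = -1, best_mm = -1;
  for (int ov = min_overlap; ov <= maxov; ++ov) {
    int mm = 0;
    const int off = l1 - ov;
    for (int k = 0; k < ov; ++k) if (r1[off + k] != r2[k]) ++mm;
    if ((double)mm / ov > max_mm_rate) continue;
    const int matches = ov - mm;
    if (matches > best_matches || (matches == best_matches && ov > best_ov)) {
      best_matches = matches; best_ov = ov; best_mm = mm;
    }
  }
  return List::create(_["overlap"] = best_ov, _["matches"] = best_matches,
                      _["mismatches"] = best_mm);
}

// Shared k-mer counts between each query and each subject (2-bit encoded,
// k <= 15; positions containing non-ACGT are skipped). One hash map over
// all subjects keyed by k-mer with a subject bitmask, so screening a large
// query batch against a small germline set is a single pass per query.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_counts(std::vector<std::string> queries,
                              std::vector<std::string> subjects,
                              int k = 12) {
  const int ns = subjects.size();
  if (ns > 32) stop("at most 32 subjects supported");
  auto code_of = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  std::unordered_map<uint32_t, uint32_t> index;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  for (int s = 0; s < ns; ++s) {
    const std::string &sub = subjects[s];
    uint32_t kmer = 0; int run = 0;
    for (size_t i = 0; i < sub.size(); ++i) {
      const int c = code_of(sub[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | c) & mask;
      if (++run >= k) index[kmer] |= (1u << s);
    }
  }
  IntegerMatrix out(queries.size(), ns);
  for (size_t q = 0; q < queries.size(); ++q) {
    const std::string &qs = queries[q];
    uint32_t kmer = 0; int run = 0;
    for (size_t i = 0; i < qs.size(); ++i) {
      const int c = code_of(qs[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | c) & mask;
      if (++run >= k) {
        auto it = index.find(kmer);
        if (it != index.end()) {
          uint32_t bits = it->second;
          while (bits) {
            out(q, __builtin_ctz(bits)) += 1;
            bits &= bits - 1;
          }
        }
      }
    }
  }
  return out;
}

// 32-bit FNV-1a hash, hex encoded; used for deterministic family ids and
// output manifests.
// [[Rcpp::export]]
CharacterVector cpp_fnv1a(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    uint32_t h = 2166136261u;
    for (const char *p = s; *p; ++p) { h ^= (unsigned char)*p; h *= 16777619u; }
    char buf[9];
    snprintf(buf, sizeof(buf), "%08x", h);
    out[i] = buf;
  }
  return out;
}
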