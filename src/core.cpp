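#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit sets over (A, C, G, T).
// Inosine ('I') pairs promiscuously and is treated as N.
static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': case 'I': case 'i': return 15;
    default: return 0;
  }
}

static inline void check_alphabet(const std::string& s, const char* what) {
  for (size_t i = 0; i < s.size(); ++i) {
    if (iupac_bits(s[i]) == 0) {
      stop("invalid IUPAC character '%s' in %s",
           std::string(1, s[i]).c_str(), what);
    }
  }
}

// [[Rcpp::export]]
bool cpp_iupac_match(std::string a, std::string b) {
  if (a.size() != 1 || b.size() != 1)
    stop("iupacMatch expects single characters");
  int ba = iupac_bits(a[0]), bb = iupac_bits(b[0]);
  if (ba == 0) stop("invalid IUPAC character '%s'", a.c_str());
  if (bb == 0) stop("invalid IUPAC character '%s'", b.c_str());
  return (ba & bb) != 0;
}

// [[Rcpp::export]]
int cpp_count_mismatches(std::string primer, std::string window) {
  if (primer.size() != window.size())
    stop("primer and window lengths differ (%d vs %d)",
         (int)primer.size(), (int)window.size());
  check_alphabet(primer, "primer");
  check_alphabet(window, "window");
  int mm = 0;
  for (size_t i = 0; i < primer.size(); ++i)
    if ((iupac_bits(primer[i]) & iupac_bits(window[i])) == 0) ++mm;
  return mm;
}

// All windows of width |primer| in tmpl with <= max_mm IUPAC mismatches.
// Returns 0-based starts and mismatch counts, sorted by start.
// [[Rcpp::export]]
List cpp_find_sites(std::string primer, std::string tmpl, int max_mm) {
  check_alphabet(primer, "primer");
  check_alphabet(tmpl, "template");
  const int m = primer.size(), n = tmpl.size();
  std::vector<int> starts, mms, pbits(m);
  for (int i = 0; i < m; ++i) pbits[i] = iupac_bits(primer[i]);
  if (m > 0 && n >= m) {
    std::vector<int> tbits(n);
    for (int i = 0; i < n; ++i) tbits[i] = iupac_bits(tmpl[i]);
    for (int s = 0; s + m <= n; ++s) {
      int mm = 0;
      for (int i = 0; i < m; ++i) {
        if ((pbits[i] & tbits[s + i]) == 0 && ++mm > max_mm) break;
      }
      if (mm <= max_mm) { starts.push_back(s); mms.push_back(mm); }
    }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}

// i.i.d. substitution errors at rate eps (uses R's RNG).
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double eps) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  if (eps <= 0) return clone(seqs);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int len = s.size();
    // number of error positions ~ Binomial(len, eps)
    int k = (int)R::rbinom((double)len, eps);
    for (int e = 0; e < k; ++e) {
      int pos = (int)(R::unif_rand() * len);
      if (pos >= len) pos = len - 1;
      char cur = s[pos];
      char nb = cur;
      while (nb == cur) nb = BASES[(int)(R::unif_rand() * 4) % 4];
      s[pos] = nb;
    }
    out[i] = s;
  }
  return out;
}

// Merge mate pairs. r2 and q2 must already be reverse-complemented /
// reversed so both mates are on the same strand. The best overlap is the
// LONGEST o >= min_overlap whose mismatch fraction is <= max_mm_frac;
// discordant overlap bases take the higher-quality call. Reads merging
// to a mean Phred < min_mean_phred are rejected.
// status: 0 = merged, 1 = no admissible overlap, 2 = low mean quality.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2, CharacterVector q2,
                     int min_overlap, double max_mm_frac,
                     double min_mean_phred) {
  const R_xlen_t n = r1.size();
  if (q1.size() != n || r2.size() != n || q2.size() != n)
    stop("mate vectors must have equal length");
  CharacterVector seq(n), qual(n);
  IntegerVector status(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]), qa = as<std::string>(q1[i]);
    std::string b = as<std::string>(r2[i]), qb = as<std::string>(q2[i]);
    const int la = a.size(), lb = b.size();
    int best_o = -1;
    const int omax = std::min(la, lb);
    for (int o = omax; o >= min_overlap; --o) {
      const int allowed = (int)(max_mm_frac * o);
      int mm = 0;
      bool ok = true;
      const char* pa = a.c_str() + (la - o);
      const char* pb = b.c_str();
      for (int j = 0; j < o; ++j) {
        if (pa[j] != pb[j] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { best_o = o; break; }
    }
    if (best_o < 0) {
      seq[i] = NA_STRING; qual[i] = NA_STRING; status[i] = 1;
      continue;
    }
    const int o = best_o;
    std::string ms = a.substr(0, la - o);
    std::string mq = qa.substr(0, la - o);
    for (int j = 0; j < o; ++j) {
      const char ca = a[la - o + j], cb = b[j];
      const char qca = qa[la - o + j], qcb = qb[j];
      if (ca == cb) {
        ms.push_back(ca);
        mq.push_back(qca >= qcb ? qca : qcb);
      } else if (qca >= qcb) {
        ms.push_back(ca); mq.push_back(qca);
      } else {
        ms.push_back(cb); mq.push_back(qcb);
      }
    }
    ms += b.substr(o);
    mq += qb.substr(o);
    double qsum = 0;
    for (size_t j = 0; j < mq.size(); ++j) qsum += (double)(mq[j] - 33);
    if (mq.size() > 0 && qsum / mq.size() < min_mean_phred) {
      seq[i] = NA_STRING; qual[i] = NA_STRING; status[i] = 2;
      continue;
    }
    seq[i] = ms; qual[i] = mq; status[i] = 0;
  }
  return List::create(_["seq"] = seq, _["qual"] = qual,
                      _["status"] = status);
}

// Locate both primers at the read ends (IUPAC-aware, <= max_mm each),
// strip them, and apply the ambiguity and length filters.
// rev_rc is the reverse primer already reverse-complemented.
// status: 0 ok, 1 ambiguous base, 2 forward primer missing,
//         3 reverse primer missing, 4 too short after trimming.
// [[Rcpp::export]]
List cpp_trim_primers(CharacterVector seqs, std::string fwd,
                      std::string rev_rc, int max_mm, int min_len) {
  check_alphabet(fwd, "forward primer");
  check_alphabet(rev_rc, "reverse primer");
  const int lf = fwd.size(), lr = rev_rc.size();
  std::vector<int> fb(lf), rb(lr);
  for (int i = 0; i < lf; ++i) fb[i] = iupac_bits(fwd[i]);
  for (int i = 0; i < lr; ++i) rb[i] = iupac_bits(rev_rc[i]);
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  IntegerVector status(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int ls = s.size();
    bool amb = false;
    for (int j = 0; j < ls; ++j) {
      char c = s[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { amb = true; break; }
    }
    if (amb) { out[i] = NA_STRING; status[i] = 1; continue; }
    if (ls < lf + lr) { out[i] = NA_STRING; status[i] = 2; continue; }
    int mm = 0;
    for (int j = 0; j < lf; ++j)
      if ((fb[j] & iupac_bits(s[j])) == 0) ++mm;
    if (mm > max_mm) { out[i] = NA_STRING; status[i] = 2; continue; }
    mm = 0;
    for (int j = 0; j < lr; ++j)
      if ((rb[j] & iupac_bits(s[ls - lr + j])) == 0) ++mm;
    if (mm > max_mm) { out[i] = NA_STRING; status[i] = 3; continue; }
    const int tl = ls - lf - lr;
    if (tl < min_len) { out[i] = NA_STRING; status[i] = 4; continue; }
    out[i] = s.substr(lf, tl);
    status[i] = 0;
  }
  return List::create(_["seq"] = out, _["status"] = status);
}

// Global alignment with unit substitution and gap costs; among
// minimum-cost alignments, the one with most matches. With m matches and
// d edit operations the alignment has m + d columns, so
// identity = m / (m + d).
static void nw_edit(const std::string& a, const std::string& b,
                    int& edits, int& matches) {
  const int la = a.size(), lb = b.size();
  std::vector<int> D(lb + 1), M(lb + 1), Dp(lb + 1), Mp(lb + 1);
  for (int j = 0; j <= lb; ++j) { Dp[j] = j; Mp[j] = 0; }
  for (int i = 1; i <= la; ++i) {
    D[0] = i; M[0] = 0;
    for (int j = 1; j <= lb; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      int dd = Dp[j - 1] + (eq ? 0 : 1);
      int dm = Mp[j - 1] + (eq ? 1 : 0);
      int du = Dp[j] + 1, mu = Mp[j];
      int dl = D[j - 1] + 1, ml = M[j - 1];
      if (du < dd || (du == dd && mu > dm)) { dd = du; dm = mu; }
      if (dl < dd || (dl == dd && ml > dm)) { dd = dl; dm = ml; }
      D[j] = dd; M[j] = dm;
    }
    std::swap(D, Dp); std::swap(M, Mp);
  }
  edits = Dp[lb]; matches = Mp[lb];
}

// [[Rcpp::export]]
NumericVector cpp_align_identity(std::string a, std::string b) {
  int d, m;
  nw_edit(a, b, d, m);
  const double cols = m + d;
  return NumericVector::create(
      _["identity"] = cols > 0 ? m / cols : 1.0,
      _["edits"] = d, _["columns"] = cols);
}

// Banded check: is identity(a, b) >= thr? Uses a Hamming lower bound for
// equal lengths, a length-ratio upper bound, then banded edit DP.
static bool identity_at_least(const std::string& a, const std::string& b,
                              double thr) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) return la == lb;
  const int lmin = std::min(la, lb), lmax = std::max(la, lb);
  // identity <= matches/(matches+edits) <= lmin/(lmin + (lmax-lmin))
  if ((double)lmin / lmax < thr) return false;
  if (la == lb) {
    int h = 0;
    for (int i = 0; i < la; ++i) if (a[i] != b[i]) ++h;
    if ((double)(la - h) / la >= thr) return true;  // gapless witness
  }
  // identity m/(m+d) >= thr with m <= lmin  =>  d <= lmin*(1-thr)/thr
  const int dmax = (int)(lmin * (1.0 - thr) / thr) + 1;
  const int band = dmax + (lmax - lmin) + 1;
  const int INF = 1 << 28;
  std::vector<int> D(lb + 1, INF), M(lb + 1, 0), Dp(lb + 1, INF),
      Mp(lb + 1, 0);
  for (int j = 0; j <= std::min(lb, band); ++j) { Dp[j] = j; Mp[j] = 0; }
  for (int i = 1; i <= la; ++i) {
    const int jlo = std::max(1, i - band), jhi = std::min(lb, i + band);
    std::fill(D.begin(), D.end(), INF);
    if (i - band <= 0) { D[0] = i; M[0] = 0; }
    bool alive = false;
    for (int j = jlo; j <= jhi; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      int dd = INF, dm = 0;
      if (Dp[j - 1] < INF) { dd = Dp[j - 1] + (eq ? 0 : 1);
                             dm = Mp[j - 1] + (eq ? 1 : 0); }
      if (Dp[j] < INF) {
        int du = Dp[j] + 1;
        if (du < dd || (du == dd && Mp[j] > dm)) { dd = du; dm = Mp[j]; }
      }
      if (D[j - 1] < INF) {
        int dl = D[j - 1] + 1;
        if (dl < dd || (dl == dd && M[j - 1] > dm)) { dd = dl; dm = M[j - 1]; }
      }
      D[j] = dd; M[j] = dm;
      if (dd <= dmax) alive = true;
    }
    if (!alive) return false;
    std::swap(D, Dp); std::swap(M, Mp);
  }
  if (Dp[lb] >= INF) return false;
  const double cols = Mp[lb] + Dp[lb];
  return cols > 0 && Mp[lb] / cols >= thr;
}

// Greedy centroid clustering of abundance-sorted unique sequences:
// each sequence joins the FIRST (earliest-opened) centroid with global
// identity >= thr, else opens a new centroid. Returns the 1-based index
// (into `seqs`) of each sequence's centroid.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double thr) {
  const R_xlen_t n = seqs.size();
  IntegerVector out(n);
  std::vector<std::string> cent;
  std::vector<int> cent_idx;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int hit = -1;
    for (size_t c = 0; c < cent.size(); ++c) {
      if (identity_at_least(s, cent[c], thr)) { hit = (int)c; break; }
    }
    if (hit < 0) {
      cent.push_back(s);
      cent_idx.push_back((int)i + 1);
      hit = (int)cent.size() - 1;
    }
    out[i] = cent_idx[hit];
  }
  return out;
}

// Hamming distance between equal-length strings (test/QC helper).
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int h = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++h;
  return h;
}
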