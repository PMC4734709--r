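// Low-level string kernels for barcode lookup, anchored primer matching and
// paired-read overlap merging. All inputs are plain upper-case DNA strings;
// validation happens on the R side.
#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static int levenshtein(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static int hamming(const std::string& a, const std::string& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) d += (a[i] != b[i]);
  return d;
}

// [[Rcpp::export(name = ".cpp_levenshtein")]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = levenshtein(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// Nearest-barcode lookup. Hamming distance when lengths are equal,
// Levenshtein otherwise. Returns, per observed sequence, the 1-based index
// of the unique barcode at minimal distance <= max_dist (0 when no barcode
// qualifies or the minimum is tied) and that minimal distance (-1 when the
// table is empty).
// [[Rcpp::export(name = ".cpp_bc_match")]]
IntegerMatrix cpp_bc_match(CharacterVector observed, CharacterVector barcodes,
                           int max_dist) {
  const int n = observed.size(), m = barcodes.size();
  std::vector<std::string> bcs(m);
  for (int j = 0; j < m; ++j) bcs[j] = as<std::string>(barcodes[j]);
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::string obs = as<std::string>(observed[i]);
    int best = INT_MAX, best_j = 0, n_best = 0;
    for (int j = 0; j < m; ++j) {
      int d = (bcs[j].size() == obs.size()) ? hamming(obs, bcs[j])
                                            : levenshtein(obs, bcs[j]);
      if (d < best) { best = d; best_j = j + 1; n_best = 1; }
      else if (d == best) ++n_best;
    }
    if (m == 0) { out(i, 0) = 0; out(i, 1) = -1; continue; }
    out(i, 1) = best;
    out(i, 0) = (best <= max_dist && n_best == 1) ? best_j : 0;
  }
  return out;
}

// Anchored ("firm end") primer match of one primer against one read prefix.
// The primer's 3'-terminal `firm` bases must match the read exactly and
// contiguously; Levenshtein edits (incl. indels) are allowed 5' of the firm
// block, so the number of read bases consumed may differ from the primer
// length by up to max_dist. Returns {dist, consumed}, dist = -1 if no
// admissible placement.
static void firm_end_one(const std::string& read, const std::string& primer,
                         int firm, int max_dist, int* dist, int* consumed) {
  *dist = -1; *consumed = 0;
  const int P = primer.size(), R = read.size();
  if (R < P || P < firm) return;  // reads shorter than the primer never match
  const int h = P - firm;         // fuzzy head length
  const std::string head = primer.substr(0, h);
  const std::string firm_block = primer.substr(h, firm);
  int best = INT_MAX, best_m = -1;
  const int lo = std::max(0, h - max_dist);
  const int hi = h + max_dist;
  for (int m = lo; m <= hi; ++m) {
    if (m + firm > R) break;
    if (read.compare(m, firm, firm_block) != 0) continue;
    int d = levenshtein(head, read.substr(0, m));
    if (d > max_dist) continue;
    bool better = d < best;
    if (d == best && best_m >= 0) {
      int cur_off = std::abs(m - h), best_off = std::abs(best_m - h);
      better = cur_off < best_off || (cur_off == best_off && m > best_m);
    }
    if (better) { best = d; best_m = m; }
  }
  if (best_m >= 0) { *dist = best; *consumed = best_m + firm; }
}

// Vectorised firm-end match of each read prefix against a primer panel.
// Returns per read: 1-based index of the unique best primer within max_dist
// (0 = none or tied), its distance (-1 = none), and bases consumed.
// [[Rcpp::export(name = ".cpp_primer_match")]]
IntegerMatrix cpp_primer_match(CharacterVector reads, CharacterVector primers,
                               int firm, int max_dist) {
  const int n = reads.size(), m = primers.size();
  std::vector<std::string> prs(m);
  for (int j = 0; j < m; ++j) prs[j] = as<std::string>(primers[j]);
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int best = INT_MAX, best_j = 0, best_cons = 0, n_best = 0;
    for (int j = 0; j < m; ++j) {
      int d, cons;
      firm_end_one(rd, prs[j], firm, max_dist, &d, &cons);
      if (d < 0) continue;
      if (d < best) { best = d; best_j = j + 1; best_cons = cons; n_best = 1; }
      else if (d == best) ++n_best;
    }
    if (n_best == 1) { out(i, 0) = best_j; out(i, 1) = best; out(i, 2) = best_cons; }
    else { out(i, 0) = 0; out(i, 1) = (n_best > 0 ? best : -1); out(i, 2) = 0; }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_reverse_strings")]]
CharacterVector cpp_reverse_strings(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}

// Overlap-merge of mate pairs (read 2 already reverse-complemented, its
// quality already reversed). Scans every overlap length >= min_overlap,
// picks the one minimising the mismatch fraction (ties -> longest overlap);
// merges when that fraction <= max_mismatch, otherwise concatenates.
// Disagreements within a merged overlap resolve toward the higher-quality
// base (tie -> read-1 base); the kept quality is the max of the two.
// [[Rcpp::export(name = ".cpp_merge_pairs")]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2rc,
                     CharacterVector q1, CharacterVector q2rc,
                     int min_overlap, double max_mismatch) {
  const int n = r1.size();
  CharacterVector seq(n), qual(n);
  LogicalVector joined(n);
  IntegerVector junction(n), overlap_len(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]), b = as<std::string>(r2rc[i]);
    std::string qa = as<std::string>(q1[i]), qb = as<std::string>(q2rc[i]);
    const int la = a.size(), lb = b.size();
    const int max_o = std::min(la, lb);
    int best_o = -1;
    double best_frac = 2.0;
    for (int o = min_overlap; o <= max_o; ++o) {
      int mm = 0;
      const int off = la - o;
      for (int p = 0; p < o; ++p) mm += (a[off + p] != b[p]);
      double frac = (double)mm / o;
      if (frac < best_frac || (frac == best_frac && o > best_o)) {
        best_frac = frac; best_o = o;
      }
    }
    if (best_o >= min_overlap && best_frac <= max_mismatch) {
      const int off = la - best_o;
      std::string s = a.substr(0, off);
      std::string q = qa.substr(0, off);
      for (int p = 0; p < best_o; ++p) {
        char ba = a[off + p], bb = b[p];
        char ca = qa[off + p], cb = qb[p];
        if (ba == bb) { s += ba; }
        else { s += (cb > ca) ? bb : ba; }  // tie -> read-1 base
        q += std::max(ca, cb);
      }
      s += b.substr(best_o);
      q += qb.substr(best_o);
      seq[i] = s; qual[i] = q; joined[i] = true;
      junction[i] = NA_INTEGER; overlap_len[i] = best_o;
    } else {
      seq[i] = a + b; qual[i] = qa + qb; joined[i] = false;
      junction[i] = la; overlap_len[i] = 0;
    }
  }
  return List::create(_["sequence"] = seq, _["qual"] = qual,
                      _["joined"] = joined, _["junction"] = junction,
                      _["overlap"] = overlap_len);
}
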