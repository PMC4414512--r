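#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Glocal (read-global, reference-local) affine-gap alignment.
// The read must be aligned end to end; reference bases before the first and
// after the last consumed base are free. Internal gap of length k costs
// gap_open + k * gap_extend. CIGAR operations are relative to the read:
// I consumes read only, D consumes reference only.

namespace {

const int NEG_INF = INT_MIN / 4;

inline int subst_score(char a, char b, int match, int mismatch) {
  return (a == b) ? match : -mismatch;
}

// score-only DP, rolling rows
int glocal_score_one(const std::string& read, const std::string& ref,
                     int match, int mismatch, int gopen, int gext) {
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, NEG_INF);
  std::vector<int> Icol(n + 1, NEG_INF);
  for (int i = 1; i <= m; ++i) {
    int D = NEG_INF;
    Icol[0] = std::max(Hprev[0] - gopen - gext, Icol[0] - gext);
    Hcur[0] = Icol[0];
    for (int j = 1; j <= n; ++j) {
      D = std::max(Hcur[j - 1] - gopen - gext, D - gext);
      Icol[j] = std::max(Hprev[j] - gopen - gext, Icol[j] - gext);
      int diag = Hprev[j - 1] + subst_score(read[i - 1], ref[j - 1], match, mismatch);
      int h = diag;
      if (Icol[j] > h) h = Icol[j];
      if (D > h) h = D;
      Hcur[j] = h;
    }
    std::swap(Hprev, Hcur);
  }
  int best = NEG_INF;
  for (int j = 0; j <= n; ++j) best = std::max(best, Hprev[j]);
  return best;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".glocal_score_matrix")]]
IntegerMatrix glocal_score_matrix(CharacterVector reads, CharacterVector refs,
                                  int match, int mismatch, int gap_open,
                                  int gap_extend) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> rf(nf);
  for (int k = 0; k < nf; ++k) rf[k] = as<std::string>(refs[k]);
  IntegerMatrix out(nr, nf);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    for (int k = 0; k < nf; ++k)
      out(i, k) = glocal_score_one(rd, rf[k], match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// Full DP with traceback. Tie order when several moves reach the optimum:
// diagonal > up (insertion, consumes read) > left (deletion, consumes ref).
// End column ties resolve to the smallest j (fewest reference bases).
// [[Rcpp::export(name = ".glocal_traceback")]]
List glocal_traceback(std::string read, std::string ref, int match,
                      int mismatch, int gopen, int gext) {
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<std::vector<int> > H(m + 1, std::vector<int>(n + 1, NEG_INF));
  std::vector<std::vector<int> > I(m + 1, std::vector<int>(n + 1, NEG_INF));
  std::vector<std::vector<int> > D(m + 1, std::vector<int>(n + 1, NEG_INF));
  for (int j = 0; j <= n; ++j) H[0][j] = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      I[i][j] = std::max(H[i - 1][j] - gopen - gext, I[i - 1][j] - gext);
      if (j > 0) {
        D[i][j] = std::max(H[i][j - 1] - gopen - gext, D[i][j - 1] - gext);
        int diag = H[i - 1][j - 1] +
                   subst_score(read[i - 1], ref[j - 1], match, mismatch);
        H[i][j] = std::max(diag, std::max(I[i][j], D[i][j]));
      } else {
        H[i][j] = I[i][j];
      }
    }
  }
  int jend = 0, best = NEG_INF;
  for (int j = 0; j <= n; ++j)
    if (H[m][j] > best) { best = H[m][j]; jend = j; }

  // traceback with a state machine over (H, I, D)
  std::string ops;  // reversed op per consumed unit: M/X/I/D
  int i = m, j = jend, n_mm = 0, n_ins = 0, n_del = 0;
  char state = 'H';
  while (i > 0) {
    if (state == 'H') {
      int diag = (j > 0) ? H[i - 1][j - 1] + subst_score(read[i - 1], ref[j - 1],
                                                         match, mismatch)
                         : NEG_INF;
      if (j > 0 && H[i][j] == diag) {
        if (read[i - 1] != ref[j - 1]) { ops.push_back('X'); ++n_mm; }
        else ops.push_back('M');
        --i; --j;
      } else if (H[i][j] == I[i][j]) {
        state = 'I';
      } else {
        state = 'D';
      }
    } else if (state == 'I') {
      ops.push_back('I'); ++n_ins;
      if (I[i][j] == H[i - 1][j] - gopen - gext) state = 'H';
      --i;
    } else { // D
      ops.push_back('D'); ++n_del;
      if (D[i][j] == H[i][j - 1] - gopen - gext) state = 'H';
      --j;
    }
  }
  // leading gap in a D state that opened exactly at i==0 cannot occur: D needs i>0 context
  int ref_start = j;

  // compress reversed ops into a CIGAR (M covers both match and mismatch)
  std::string cigar;
  int run = 0; char cur = 0;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    char op = ops[k];
    if (op == 'X') op = 'M';
    if (op == cur) { ++run; }
    else {
      if (run > 0) cigar += std::to_string(run) + cur;
      cur = op; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + cur;

  return List::create(_["score"] = best, _["cigar"] = cigar,
                      _["n_mismatch"] = n_mm, _["n_ins"] = n_ins,
                      _["n_del"] = n_del, _["ref_start"] = ref_start,
                      _["aligned_ref_bases"] = jend - ref_start);
}

// Map each read (and its reverse complement) against all references at
// once: best score over the 2 * n_ref candidates, with traceback of the
// winner only. Candidates are scanned in descending order of a score upper
// bound, and a candidate is abandoned once a row-level bound proves its
// score cannot reach max(second, best - prune_margin): such a candidate can
// change neither the assignment nor the MAPQ (the MAPQ formula saturates at
// margins >= prune_margin). The reported second_best is therefore exact
// whenever it lies within prune_margin of the best score and NA otherwise.
// Exact ties keep the first candidate in (forward regions, then reverse)
// order; ties more than prune_margin below the best may resolve to bounds,
// which is irrelevant to both outputs.
// [[Rcpp::export(name = ".glocal_map")]]
List glocal_map(CharacterVector reads, CharacterVector reads_rc,
                CharacterVector refs, int match, int mismatch, int gap_open,
                int gap_extend, int prune_margin) {
  const int nr = reads.size(), nf = refs.size(), nc = 2 * nf;
  std::vector<std::string> rf(nf);
  for (int k = 0; k < nf; ++k) rf[k] = as<std::string>(refs[k]);
  IntegerVector o_idx(nr), o_best(nr), o_second(nr);
  std::vector<int> ub(nc), ord(nc);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::string rc = as<std::string>(reads_rc[i]);
    const int m = (int)rd.size();
    // rank candidates so the likely winner is scanned first: presence of a
    // few 12-mer probes of the query, then the score upper bound. Ordering
    // is a heuristic only; the bounds below are exact regardless of order.
    std::vector<int> probe_hits(nc, 0);
    const int kmer = 12;
    if (m >= kmer) {
      int pos[4] = {0, m / 3, (2 * m) / 3, m - kmer};
      for (int k = 0; k < nc; ++k) {
        const std::string& q = (k < nf) ? rd : rc;
        const std::string& s = rf[k % nf];
        for (int t = 0; t < 4; ++t)
          if (s.find(q.substr(pos[t], kmer)) != std::string::npos)
            ++probe_hits[k];
      }
    }
    for (int k = 0; k < nc; ++k) {
      int n = (int)rf[k % nf].size();
      ub[k] = (m <= n) ? m * match
                       : n * match - (gap_open + (m - n) * gap_extend);
      ord[k] = k;
    }
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (probe_hits[a] != probe_hits[b]) return probe_hits[a] > probe_hits[b];
      return ub[a] > ub[b];
    });
    int best = NEG_INF, second = NEG_INF, best_k = -1;
    for (int kk = 0; kk < nc; ++kk) {
      int k = ord[kk];
      int thr = std::max(second,
                         best == NEG_INF ? NEG_INF : best - prune_margin);
      if (ub[k] < thr) continue;  // cannot affect assignment or MAPQ
      const std::string& q = (k < nf) ? rd : rc;
      const std::string& s = rf[k % nf];
      int sc;
      if (m <= (int)s.size() && s.find(q) != std::string::npos) {
        sc = m * match;  // exact substring, no DP needed
      } else {
        // DP with row-level abandon against the pruning threshold
        const int n = (int)s.size();
        std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, NEG_INF);
        std::vector<int> Icol(n + 1, NEG_INF);
        sc = NEG_INF;
        bool abandoned = false;
        for (int r = 1; r <= m; ++r) {
          int D = NEG_INF, rowmax = NEG_INF;
          Icol[0] = std::max(Hprev[0] - gap_open - gap_extend,
                             Icol[0] - gap_extend);
          Hcur[0] = Icol[0];
          for (int j = 1; j <= n; ++j) {
            D = std::max(Hcur[j - 1] - gap_open - gap_extend,
                         D - gap_extend);
            Icol[j] = std::max(Hprev[j] - gap_open - gap_extend,
                               Icol[j] - gap_extend);
            int h = Hprev[j - 1] +
                    subst_score(q[r - 1], s[j - 1], match, mismatch);
            if (Icol[j] > h) h = Icol[j];
            if (D > h) h = D;
            Hcur[j] = h;
            if (h > rowmax) rowmax = h;
          }
          if (rowmax + (m - r) * match < thr) { abandoned = true; break; }
          std::swap(Hprev, Hcur);
        }
        if (abandoned) continue;
        for (int j = 0; j <= n; ++j) sc = std::max(sc, Hprev[j]);
      }
      if (sc > best) {
        second = best; best = sc; best_k = k;
      } else if (best_k >= 0 && k < best_k && sc == best) {
        // earlier candidate in canonical order wins exact ties
        second = best; best_k = k;
      } else if (sc > second) {
        second = sc;
      }
    }
    o_idx[i] = best_k + 1;  // 1-based; column-major over (refs, strands)
    o_best[i] = best;
    o_second[i] = (second < best - prune_margin) ? NA_INTEGER : second;
  }
  // traceback of each winner
  CharacterVector o_cigar(nr);
  IntegerVector o_mm(nr), o_ins(nr), o_del(nr), o_arb(nr), o_rs(nr);
  for (int i = 0; i < nr; ++i) {
    int k = o_idx[i] - 1;
    std::string q = (k < nf) ? as<std::string>(reads[i])
                             : as<std::string>(reads_rc[i]);
    List tb = glocal_traceback(q, rf[k % nf], match, mismatch, gap_open,
                               gap_extend);
    o_cigar[i] = as<std::string>(tb["cigar"]);
    o_mm[i] = as<int>(tb["n_mismatch"]);
    o_ins[i] = as<int>(tb["n_ins"]);
    o_del[i] = as<int>(tb["n_del"]);
    o_arb[i] = as<int>(tb["aligned_ref_bases"]);
    o_rs[i] = as<int>(tb["ref_start"]);
  }
  return List::create(_["best_idx"] = o_idx, _["score"] = o_best,
                      _["second_best"] = o_second, _["cigar"] = o_cigar,
                      _["n_mismatch"] = o_mm, _["n_ins"] = o_ins,
                      _["n_del"] = o_del, _["aligned_ref_bases"] = o_arb,
                      _["ref_start"] = o_rs);
}

namespace {
// 4-bit IUPAC masks; 0 for non-DNA letters
int iupac_mask(char c) {
  switch (toupper(c)) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}
} // namespace

// IUPAC-aware mismatch count between a fixed pattern and the prefix (or
// suffix) of each sequence; two letters match when their base sets intersect.
// Sequences shorter than the pattern get NA.
// [[Rcpp::export(name = ".pattern_mismatch")]]
IntegerVector pattern_mismatch(CharacterVector seqs, std::string pattern,
                               bool from_end) {
  const int p = (int)pattern.size();
  std::vector<int> pm(p);
  for (int k = 0; k < p; ++k) pm[k] = iupac_mask(pattern[k]);
  IntegerVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < p) { out[i] = NA_INTEGER; continue; }
    int off = from_end ? (int)s.size() - p : 0, mm = 0;
    for (int k = 0; k < p; ++k)
      if ((pm[k] & iupac_mask(s[off + k])) == 0) ++mm;
    out[i] = mm;
  }
  return out;
}
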