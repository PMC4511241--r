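#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment (Gotoh), returning the single
// best-scoring alignment with traceback statistics. Gap of length L costs
// gap_open + L * gap_ext. 'N' never matches anything (masking character).
//
// Returned coordinates are 1-based inclusive; score 0 means no positive
// local alignment exists.

// [[Rcpp::export(name = ".sw_local_align")]]
List sw_local_align(std::string query, std::string subject,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int n = query.size();
  const int m = subject.size();
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, R_NegInf),
      F((n + 1) * W, R_NegInf);
  // traceback codes for H: 0 stop, 1 diag, 2 left-gap (E), 3 up-gap (F)
  std::vector<unsigned char> tbH((n + 1) * W, 0), tbE((n + 1) * W, 0),
      tbF((n + 1) * W, 0);  // tbE/tbF: 1 = extend, 0 = open from H

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char sc = subject[j - 1];
      const double sub =
          (qc == sc && qc != 'N' && qc != 'X') ? match : mismatch;
      const int idx = i * W + j;
      // gap in query (consume subject): move left
      double e_open = H[idx - 1] - gap_open - gap_ext;
      double e_ext = E[idx - 1] - gap_ext;
      if (e_ext > e_open) { E[idx] = e_ext; tbE[idx] = 1; }
      else { E[idx] = e_open; tbE[idx] = 0; }
      // gap in subject (consume query): move up
      double f_open = H[idx - W] - gap_open - gap_ext;
      double f_ext = F[idx - W] - gap_ext;
      if (f_ext > f_open) { F[idx] = f_ext; tbF[idx] = 1; }
      else { F[idx] = f_open; tbF[idx] = 0; }
      double diag = H[idx - W - 1] + sub;
      double h = 0.0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["aln_len"] = 0,
                        _["n_match"] = 0, _["max_match_run"] = 0);
  }

  // traceback from the best cell
  int i = bi, j = bj;
  int aln_len = 0, n_match = 0, run = 0, max_run = 0;
  int state = 0;  // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++aln_len;
        const char qc = query[i - 1], sc = subject[j - 1];
        if (qc == sc && qc != 'N' && qc != 'X') {
          ++n_match; ++run; if (run > max_run) max_run = run;
        } else run = 0;
        --i; --j;
      } else state = t;
    } else if (state == 2) {
      ++aln_len; run = 0;
      if (tbE[idx] == 0) state = 0;
      --j;
    } else {
      ++aln_len; run = 0;
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj,
                      _["aln_len"] = aln_len, _["n_match"] = n_match,
                      _["max_match_run"] = max_run);
}
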