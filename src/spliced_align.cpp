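// est2genome-style local spliced alignment by dynamic programming.
//
// States per cell (est position i, target position j): best local score of
// an alignment ending at (i,j). Moves: diagonal match/mismatch, per-base
// linear gaps on either sequence, and an intron -- a target-only jump of
// length within [min_intron, max_intron] charged a flat penalty:
// spliced_intron_open when the intron starts GT and ends AG, intron_open
// otherwise. Bounded-length intron maxima are maintained with two
// monotonic deques per row (all donors / GT donors). Traceback stores one
// byte per cell; intron start positions are recovered by rescanning the
// window against the stored score matrix.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(std::string est, std::string target,
                       int match, int mismatch, int gap,
                       int intron_open, int spliced_intron_open,
                       int min_intron, int max_intron,
                       double max_cells = 1.5e8) {
  const int m = (int)est.size(), n = (int)target.size();
  if (m < 1 || n < 1) stop("sequences must be non-empty");
  if ((double)(m + 1) * (double)(n + 1) > max_cells)
    stop("sequence too long for exhaustive spliced DP (%.0f cells > %.0f); "
         "use map_est with seeded windows", (double)(m + 1) * (n + 1), max_cells);

  const int W = n + 1;
  // buffers persist across calls (single-threaded R): avoids paying
  // page-fault + zero-fill costs on every window
  static std::vector<int> H;
  static std::vector<unsigned char> TB;
  const size_t need = (size_t)(m + 1) * W;
  if (H.size() < need) { H.resize(need); TB.resize(need); }
  std::memset(H.data(), 0, (size_t)W * sizeof(int));  // row 0
  for (int i = 1; i <= m; ++i) H[(size_t)i * W] = 0;  // column 0
  // TB codes: 0 stop, 1 diag, 2 up (est gap), 3 left (target gap), 4 intron

  // donor[j'] true when target[j'..j'+1] (0-based) == "GT", i.e. an intron
  // starting at target position j'+1 (1-based) is a GT donor
  std::vector<char> donorGT(n + 1, 0);
  for (int jp = 0; jp + 1 < n; ++jp)
    donorGT[jp] = (target[jp] == 'G' && target[jp + 1] == 'T');

  int best = 0, bi = -1, bj = -1;

  // monotonic queues as preallocated index arrays, reset per row
  static std::vector<int> qAll, qGT;
  if ((int)qAll.size() < n + 2) { qAll.resize(n + 2); qGT.resize(n + 2); }
  for (int i = 1; i <= m; ++i) {
    int* Hi = &H[(size_t)i * W];
    int* Hp = &H[(size_t)(i - 1) * W];
    unsigned char* Ti = &TB[(size_t)i * W];
    int aHead = 0, aTail = 0, gHead = 0, gTail = 0;  // [head, tail)
    const char ei = est[i - 1];
    for (int j = 1; j <= n; ++j) {
      // admit candidate j' = j - min_intron (computed earlier this row);
      // a source scoring at most the penalty can never produce a
      // positive resume score, so it is skipped -- this keeps the
      // monotonic queues nearly empty on noise
      int enter = j - min_intron;
      if (enter >= 0) {
        int v = Hi[enter];
        if (v > intron_open) {
          while (aTail > aHead && Hi[qAll[aTail - 1]] <= v) --aTail;
          qAll[aTail++] = enter;
        }
        if (v > spliced_intron_open && donorGT[enter]) {
          while (gTail > gHead && Hi[qGT[gTail - 1]] <= v) --gTail;
          qGT[gTail++] = enter;
        }
      }
      int lo = j - max_intron;
      while (aTail > aHead && qAll[aHead] < lo) ++aHead;
      while (gTail > gHead && qGT[gHead] < lo) ++gHead;

      const char tj = target[j - 1];
      const bool diag_match = (ei != 'N' && ei == tj);
      const int diag = Hp[j - 1] + (diag_match ? match : mismatch);
      const int up = Hp[j] - gap;
      const int left = Hi[j - 1] - gap;
      // tie order: matching diagonal > intron > mismatching diagonal >
      // gaps; among equally scoring optima this reports the alignment
      // with the most matched bases instead of letting an intron
      // boundary slide into mismatching sequence
      int cur = 0; unsigned char tb = 0;
      if (diag_match && diag > 0) { cur = diag; tb = 1; }
      if (aTail > aHead) {
        int cand = Hi[qAll[aHead]] - intron_open;
        if (cand > cur) { cur = cand; tb = 4; }
      }
      if (gTail > gHead && j >= 2 && target[j - 2] == 'A' && tj == 'G') {
        int cand = Hi[qGT[gHead]] - spliced_intron_open;
        if (cand > cur) { cur = cand; tb = 4; }
      }
      if (!diag_match && diag > cur) { cur = diag; tb = 1; }
      if (up > cur) { cur = up; tb = 2; }
      if (left > cur) { cur = left; tb = 3; }
      Hi[j] = cur; Ti[j] = tb;
      if (cur > best) { best = cur; bi = i; bj = j; }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["blocks"] = IntegerMatrix(0, 2),
                        _["est_start"] = NA_INTEGER, _["est_end"] = NA_INTEGER,
                        _["n_match"] = 0, _["n_aligned"] = 0);
  }

  // traceback
  int i = bi, j = bj;
  int est_end = bi, est_start = bi;
  int n_match = 0, n_aligned = 0;
  std::vector<std::pair<int, int> > blocks;  // filled back-to-front
  int block_end = -1, block_start = -1;

  auto close_block = [&]() {
    if (block_end >= 0) blocks.push_back(std::make_pair(block_start, block_end));
    block_end = block_start = -1;
  };

  while (i > 0 && j > 0 && H[(size_t)i * W + j] > 0) {
    unsigned char tb = TB[(size_t)i * W + j];
    if (tb == 0) break;
    if (tb == 1) {
      if (block_end < 0) block_end = j;
      block_start = j - 1;
      if (est[i - 1] != 'N' && est[i - 1] == target[j - 1]) ++n_match;
      ++n_aligned; est_start = i - 1;
      --i; --j;
    } else if (tb == 2) {
      ++n_aligned; est_start = i - 1;
      --i;
    } else if (tb == 3) {
      if (block_end < 0) block_end = j;
      block_start = j - 1;
      --j;
    } else {  // intron: find start j' with H[i][j'] - penalty == H[i][j]
      int val = H[(size_t)i * W + j];
      int lo = j - max_intron; if (lo < 0) lo = 0;
      int hi = j - min_intron;
      int jp_found = -1;
      bool acceptorAG = (j >= 2 && target[j - 2] == 'A' && target[j - 1] == 'G');
      if (acceptorAG) {
        for (int jp = lo; jp <= hi; ++jp)
          if (donorGT[jp] && H[(size_t)i * W + jp] - spliced_intron_open == val) {
            jp_found = jp; break;
          }
      }
      if (jp_found < 0) {
        for (int jp = lo; jp <= hi; ++jp)
          if (H[(size_t)i * W + jp] - intron_open == val) { jp_found = jp; break; }
      }
      if (jp_found < 0) stop("internal error: intron traceback failed");
      close_block();
      j = jp_found;
    }
  }
  close_block();

  IntegerMatrix bm((int)blocks.size(), 2);
  for (int b = 0; b < (int)blocks.size(); ++b) {
    // reverse order; emit ascending, 0-based half-open
    bm(b, 0) = blocks[blocks.size() - 1 - b].first;
    bm(b, 1) = blocks[blocks.size() - 1 - b].second;
  }

  return List::create(_["score"] = best, _["blocks"] = bm,
                      _["est_start"] = est_start, _["est_end"] = est_end,
                      _["n_match"] = n_match, _["n_aligned"] = n_aligned);
}
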