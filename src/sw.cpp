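#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) of a read against a reference
// window. Gap of length L costs gap_open + (L-1)*gap_extend. Returns the
// best-scoring local alignment with a traceback CIGAR; unaligned read ends
// are reported as soft clips (S). Ties are broken toward the smallest
// reference end position, then the smallest read end position, so results
// are deterministic. When band_lo <= band_hi, the DP is restricted to the
// diagonal band j - i in [band_lo, band_hi] (j = ref column, i = read row);
// callers set the band from the seed diagonals so only alignments whose
// gaps stay inside the band are found.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string ref,
                  int match = 1, int mismatch = 1,
                  int gap_open = 2, int gap_extend = 1,
                  int band_lo = 1, int band_hi = 0) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  const bool banded = band_lo <= band_hi;
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0);

  const int NEG = -1000000;
  // H, E (gap in read, consumes ref => D), F (gap in ref, consumes read => I)
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);
  std::vector<int> F((m + 1) * (n + 1), NEG);
  // traceback: 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  // for E/F: 1 = opened from H, 0 = extended
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    int j_from = 1, j_to = n;
    if (banded) {
      j_from = std::max(1, i + band_lo);
      j_to = std::min(n, i + band_hi);
    }
    for (int j = j_from; j <= j_to; ++j) {
      const int idx = i * (n + 1) + j;
      const int left = i * (n + 1) + (j - 1);
      const int up = (i - 1) * (n + 1) + j;
      const int diag = (i - 1) * (n + 1) + (j - 1);

      int e_open = H[left] - gap_open;
      int e_ext = E[left] - gap_extend;
      E[idx] = e_open >= e_ext ? e_open : e_ext;
      tbE[idx] = e_open >= e_ext ? 1 : 0;

      int f_open = H[up] - gap_open;
      int f_ext = F[up] - gap_extend;
      F[idx] = f_open >= f_ext ? f_open : f_ext;
      tbF[idx] = f_open >= f_ext ? 1 : 0;

      int s = (rc == ref[j - 1]) ? match : -mismatch;
      int h = H[diag] + s;
      unsigned char tb = 1;
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      if (h <= 0) { h = 0; tb = 0; }
      H[idx] = h;
      tbH[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback from (bi, bj)
  std::vector<std::pair<char,int> > ops; // reversed
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    const int idx = i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
        else ops.push_back(std::make_pair('M', 1));
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: deletion from read (consumes ref)
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back(std::make_pair('D', 1));
      unsigned char tb = tbE[idx];
      --j;
      if (tb == 1) state = 0;
    } else { // F: insertion to read (consumes read)
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
      unsigned char tb = tbF[idx];
      --i;
      if (tb == 1) state = 0;
    }
  }
  const int read_start = i;      // 0-based, clipped prefix length
  const int ref_start = j;       // 0-based position in ref
  std::string cigar;
  if (read_start > 0)
    cigar += std::to_string(read_start) + "S";
  for (int k = (int) ops.size() - 1; k >= 0; --k)
    cigar += std::to_string(ops[k].second) + std::string(1, ops[k].first);
  if (bi < m)
    cigar += std::to_string(m - bi) + "S";

  return List::create(
    _["score"] = best,
    _["ref_start"] = ref_start,
    _["read_start"] = read_start,
    _["read_end"] = bi,
    _["ref_end"] = bj,
    _["cigar"] = cigar);
}
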