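#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with an asymmetric, bisulfite-aware
// substitution rule: a reference C aligned to a read T scores as a full match
// (the "converted" column class). Linear gap penalty. Ties are resolved
// deterministically: maximize score, then minimize the number of gap columns,
// then prefer diagonal over a gap in the read over a gap in the reference
// during traceback (pushes gaps leftward in the reference).
//
// conv_ref / conv_read select which substitution is treated as converted:
// 'C'/'T' for the amplicon's C strand, 'G'/'A' for the opposite strand.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string ref, std::string read, int match, int converted,
                  int mismatch, int gap, char conv_ref, char conv_read) {
  const int n = ref.size(), m = read.size();
  // score and gap-count matrices, row-major (n+1) x (m+1)
  std::vector<int> S((n + 1) * (m + 1));
  std::vector<int> G((n + 1) * (m + 1));
  std::vector<unsigned char> M((n + 1) * (m + 1)); // 1=diag 2=up(ref) 3=left(read)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  S[at(0, 0)] = 0; G[at(0, 0)] = 0; M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    S[at(i, 0)] = i * gap; G[at(i, 0)] = i; M[at(i, 0)] = 2;
  }
  for (int j = 1; j <= m; ++j) {
    S[at(0, j)] = j * gap; G[at(0, j)] = j; M[at(0, j)] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    const char a = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char b = read[j - 1];
      int sub;
      if (a == b && a != 'N') sub = match;
      else if (a == conv_ref && b == conv_read) sub = converted;
      else sub = mismatch;
      int sd = S[at(i - 1, j - 1)] + sub, gd = G[at(i - 1, j - 1)];
      int su = S[at(i - 1, j)] + gap,     gu = G[at(i - 1, j)] + 1;
      int sl = S[at(i, j - 1)] + gap,     gl = G[at(i, j - 1)] + 1;
      // preference order diag, up, left under (score desc, gaps asc)
      int bs = sd, bg = gd; unsigned char bm = 1;
      if (su > bs || (su == bs && gu < bg)) { bs = su; bg = gu; bm = 2; }
      if (sl > bs || (sl == bs && gl < bg)) { bs = sl; bg = gl; bm = 3; }
      S[at(i, j)] = bs; G[at(i, j)] = bg; M[at(i, j)] = bm;
    }
  }

  std::string ra, da, ops;
  ra.reserve(n + m); da.reserve(n + m); ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char mv = M[at(i, j)];
    if (mv == 1) {
      char a = ref[i - 1], b = read[j - 1];
      ra.push_back(a); da.push_back(b);
      if (a == b && a != 'N') ops.push_back('M');
      else if (a == conv_ref && b == conv_read) ops.push_back('C');
      else ops.push_back('X');
      --i; --j;
    } else if (mv == 2) {
      ra.push_back(ref[i - 1]); da.push_back('-'); ops.push_back('G');
      --i;
    } else {
      ra.push_back('-'); da.push_back(read[j - 1]); ops.push_back('G');
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(da.begin(), da.end());
  std::reverse(ops.begin(), ops.end());

  return List::create(_["ref_aln"] = ra, _["read_aln"] = da,
                      _["ops"] = ops, _["score"] = S[at(n, m)],
                      _["n_gap"] = G[at(n, m)]);
}
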