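#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Induced rooted topology of one-tip-per-group subsets.
//
// depth[i,j] holds the topological depth (edges from the root) of the MRCA
// of tips i and j in the full gene tree. For a binary rooted tree the
// induced topology of any tip subset is obtained by repeatedly merging the
// pair of clusters with the deepest MRCA; after a merge the MRCA depth of
// the new cluster with any other is the shallower (minimum) of its parts.
// Clusters are printed in a canonical nested-parenthesis form with the two
// children of every node ordered by their smallest member label (byte
// order), which must match the R-side catalog canonicalization exactly.
//
// combos: n x k matrix of 1-based tip indices, one column per group slot.
// labels: the group label of each slot.
// [[Rcpp::export]]
CharacterVector induce_topologies(IntegerMatrix depth, IntegerMatrix combos,
                                  CharacterVector labels) {
  const int nc = combos.nrow();
  const int k = combos.ncol();
  std::vector<std::string> labs(k);
  for (int g = 0; g < k; ++g) labs[g] = as<std::string>(labels[g]);
  CharacterVector out(nc);
  std::vector<int> tip(k);
  std::vector<std::string> name(k), mn(k);
  std::vector<std::vector<int> > d(k, std::vector<int>(k, 0));
  std::vector<bool> alive(k);

  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < k; ++i) {
      tip[i] = combos(c, i) - 1;
      name[i] = labs[i];
      mn[i] = labs[i];
      alive[i] = true;
    }
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        d[i][j] = d[j][i] = depth(tip[i], tip[j]);
    int nalive = k;
    int last = 0;
    while (nalive > 1) {
      int bi = -1, bj = -1, bd = -1;
      for (int i = 0; i < k; ++i) {
        if (!alive[i]) continue;
        for (int j = i + 1; j < k; ++j) {
          if (!alive[j]) continue;
          if (d[i][j] > bd) { bd = d[i][j]; bi = i; bj = j; }
        }
      }
      const bool a_first = mn[bi] < mn[bj];
      name[bi] = "(" + (a_first ? name[bi] : name[bj]) + "," +
                 (a_first ? name[bj] : name[bi]) + ")";
      if (mn[bj] < mn[bi]) mn[bi] = mn[bj];
      alive[bj] = false;
      --nalive;
      for (int j = 0; j < k; ++j) {
        if (!alive[j] || j == bi) continue;
        const int dv = std::min(d[bi][j], d[bj][j]);
        d[bi][j] = d[j][bi] = dv;
      }
      last = bi;
    }
    out[c] = name[last];
  }
  return out;
}
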