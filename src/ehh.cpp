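#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity decay along one direction from a core SNP,
// by incremental partition refinement: haplotypes start in one group and are
// split as each successive SNP is appended to the shared segment.
//
// H        0/1 haplotype-by-SNP matrix (1 = derived allele)
// carriers 0-based row indices of the haplotypes carrying the core allele
// core     0-based column index of the core SNP
// step     +1 (rightwards) or -1 (leftwards)
// floor_   stop once EHH drops below this value (0 = run to the panel edge)
//
// Returns ehh values at core+step, core+2*step, ... (stopping after the first
// value below the floor, or at zero, or at the edge) and whether the floor
// was reached before the edge.
// [[Rcpp::export(name = ".ehh_decay_cpp")]]
List ehh_decay_cpp(const IntegerMatrix& H, const IntegerVector& carriers,
                   int core, int step, double floor_) {
  const int nc = carriers.size();
  const int M = H.ncol();
  if (nc < 2) stop("fewer than 2 carriers");
  const double denom = 0.5 * (double)nc * (nc - 1);

  std::vector<int> group(nc, 0);
  int ngroups = 1;
  std::vector<double> out;
  out.reserve(64);
  bool reached = false;

  for (int j = core + step; j >= 0 && j < M; j += step) {
    // refine: new key = 2*group + allele, compacted to 0..ngroups'-1
    std::vector<int> relabel(2 * ngroups, -1);
    std::vector<int> size;
    int next_id = 0;
    for (int i = 0; i < nc; ++i) {
      int a = H(carriers[i], j);
      if (a == NA_INTEGER) stop("missing allele in phased panel");
      int key = 2 * group[i] + (a != 0 ? 1 : 0);
      if (relabel[key] < 0) {
        relabel[key] = next_id++;
        size.push_back(0);
      }
      group[i] = relabel[key];
      size[group[i]] += 1;
    }
    ngroups = next_id;
    double num = 0.0;
    for (int g = 0; g < ngroups; ++g)
      num += 0.5 * (double)size[g] * (size[g] - 1);
    double e = num / denom;
    out.push_back(e);
    if (e < floor_ || e == 0.0) {
      reached = true;
      break;
    }
  }
  return List::create(_["ehh"] = NumericVector(out.begin(), out.end()),
                      _["reached_floor"] = reached);
}
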