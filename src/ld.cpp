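#include <Rcpp.h>
using namespace Rcpp;

// Pearson r^2 between two dosage rows over jointly non-missing individuals.
// Returns NA_REAL when fewer than min_shared individuals are shared or when
// either vector is monomorphic among the shared individuals.
static double pair_r2(const double* a, const double* b, int n, int min_shared) {
  int m = 0;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (int k = 0; k < n; ++k) {
    double x = a[k], y = b[k];
    if (ISNAN(x) || ISNAN(y)) continue;
    ++m;
    sa += x; sb += y; saa += x * x; sbb += y * y; sab += x * y;
  }
  if (m < min_shared) return NA_REAL;
  double va = saa - sa * sa / m;
  double vb = sbb - sb * sb / m;
  if (va <= 1e-12 || vb <= 1e-12) return NA_REAL;
  double cov = sab - sa * sb / m;
  double r2 = (cov * cov) / (va * vb);
  return r2 > 1.0 ? 1.0 : r2;
}

// All same-chromosome pairs within max_dist bp. `dos` is SNP x individual
// with NA for missing; pos/chrom are per-SNP. 1-based indices in the output.
// [[Rcpp::export(name = ".ld_pairs_band_cpp")]]
DataFrame ld_pairs_band_cpp(NumericMatrix dos, IntegerVector pos,
                            IntegerVector chrom, double max_dist,
                            int min_shared) {
  int S = dos.nrow(), N = dos.ncol();
  std::vector<int> ii, jj, dd;
  std::vector<double> rr;
  std::vector<double> buf_i(N), buf_j(N);
  for (int i = 0; i < S; ++i) {
    for (int k = 0; k < N; ++k) buf_i[k] = dos(i, k);
    for (int j = i + 1; j < S; ++j) {
      if (chrom[j] != chrom[i]) break;
      double d = (double)pos[j] - (double)pos[i];
      if (d > max_dist) break;
      for (int k = 0; k < N; ++k) buf_j[k] = dos(j, k);
      double r2 = pair_r2(buf_i.data(), buf_j.data(), N, min_shared);
      if (ISNAN(r2)) continue;
      ii.push_back(i + 1);
      jj.push_back(j + 1);
      dd.push_back((int)d);
      rr.push_back(r2);
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd,
                           _["r2"] = rr);
}

// Tight-linkage link counts for boundary refinement. For each focal SNP
// (1-based rows in `focal`), counts partners within max_dist whose r^2
// exceeds `thr`, split into downstream (larger position) and upstream
// (smaller position) partners. All SNPs are assumed to sit on one
// chromosome with increasing positions.
// [[Rcpp::export(name = ".link_counts_cpp")]]
DataFrame link_counts_cpp(NumericMatrix dos, IntegerVector pos,
                          IntegerVector focal, double max_dist, double thr,
                          int min_shared) {
  int S = dos.nrow(), N = dos.ncol(), F = focal.size();
  IntegerVector down(F), up(F);
  std::vector<double> a(N), b(N);
  for (int t = 0; t < F; ++t) {
    int i = focal[t] - 1;
    for (int k = 0; k < N; ++k) a[k] = dos(i, k);
    for (int j = i + 1; j < S; ++j) {
      if ((double)pos[j] - (double)pos[i] > max_dist) break;
      for (int k = 0; k < N; ++k) b[k] = dos(j, k);
      double r2 = pair_r2(a.data(), b.data(), N, min_shared);
      if (!ISNAN(r2) && r2 > thr) ++down[t];
    }
    for (int j = i - 1; j >= 0; --j) {
      if ((double)pos[i] - (double)pos[j] > max_dist) break;
      for (int k = 0; k < N; ++k) b[k] = dos(j, k);
      double r2 = pair_r2(a.data(), b.data(), N, min_shared);
      if (!ISNAN(r2) && r2 > thr) ++up[t];
    }
  }
  return DataFrame::create(_["site"] = focal, _["down"] = down,
                           _["up"] = up);
}

// r^2 for explicit (1-based) row-index pairs; NA where skipped.
// [[Rcpp::export(name = ".r2_for_pairs_cpp")]]
NumericVector r2_for_pairs_cpp(NumericMatrix dos, IntegerVector ii,
                               IntegerVector jj, int min_shared) {
  int n = ii.size(), N = dos.ncol();
  NumericVector out(n);
  std::vector<double> a(N), b(N);
  for (int t = 0; t < n; ++t) {
    int i = ii[t] - 1, j = jj[t] - 1;
    for (int k = 0; k < N; ++k) { a[k] = dos(i, k); b[k] = dos(j, k); }
    out[t] = pair_r2(a.data(), b.data(), N, min_shared);
  }
  return out;
}
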