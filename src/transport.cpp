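// Straight-line continuous-slowing-down (CSDA) electron transport on a
// voxel grid.
//
// Each history: an emission voxel is drawn proportional to its
// time-integrated activity, the emission point uniformly inside that
// voxel, the direction isotropically, and the energy from the tabulated
// beta spectrum (inverse CDF). The electron then travels on a straight
// line; its residual water-equivalent range decreases by rho * ds per
// geometric step ds (range scales as 1/density), and the energy released
// over each step -- the difference of the range-energy table evaluated at
// the old and new residual range -- is deposited in the voxel the step
// started in. Energy carried outside the grid is tallied as escaped, so
// deposited + escaped = emitted holds to rounding.
//
// Uses R's RNG stream (set.seed-reproducible).

#include <Rcpp.h>
using namespace Rcpp;

// linear interpolation on a sorted grid
static inline double lininterp(const std::vector<double> &x,
                               const std::vector<double> &y, double xv) {
  if (xv <= x.front()) return y.front();
  if (xv >= x.back()) return y.back();
  size_t hi = std::upper_bound(x.begin(), x.end(), xv) - x.begin();
  size_t lo = hi - 1;
  double w = (xv - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + w * (y[hi] - y[lo]);
}

// [[Rcpp::export(name = ".transportCsda")]]
List transportCsda(NumericVector tiaWeights, IntegerVector dims,
                   NumericVector spacing, NumericVector cdfP,
                   NumericVector cdfE, NumericVector rangeE,
                   NumericVector rangeR, NumericVector density,
                   NumericVector tallyW, double stepMm, double nHistories,
                   int nBatches) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (tiaWeights.size() != nvox || density.size() != nvox)
    stop("TIA / density size mismatch with dims");

  // cumulative emission probabilities
  std::vector<double> cum(nvox);
  double tot = 0.0;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double w = tiaWeights[v];
    if (w < 0) stop("negative TIA weight");
    tot += w;
    cum[v] = tot;
  }
  if (tot <= 0) stop("all-zero TIA: nothing to simulate");
  for (R_xlen_t v = 0; v < nvox; ++v) cum[v] /= tot;

  std::vector<double> cp(cdfP.begin(), cdfP.end()),
      ce(cdfE.begin(), cdfE.end()), re(rangeE.begin(), rangeE.end()),
      rr(rangeR.begin(), rangeR.end());

  NumericVector edep(nvox);          // total deposited keV
  NumericVector batchSum(nvox);      // sum over batches of batch deposits
  NumericVector batchSumSq(nvox);    // sum of squares of batch deposits
  std::vector<double> bdep(nvox);
  const bool haveTally = tallyW.size() == nvox;
  NumericVector tallyBatch(nBatches);   // weighted deposit per batch, keV
  NumericVector histBatch(nBatches);

  double emitted = 0.0, escaped = 0.0;
  const double ex = spacing[0] * nx, ey = spacing[1] * ny,
               ez = spacing[2] * nz;  // grid extent, origin at 0

  R_xlen_t histTotal = (R_xlen_t)nHistories;
  R_xlen_t perBatch = histTotal / nBatches;

  RNGScope scope;
  for (int b = 0; b < nBatches; ++b) {
    std::fill(bdep.begin(), bdep.end(), 0.0);
    R_xlen_t nb = (b == nBatches - 1) ? histTotal - perBatch * (nBatches - 1)
                                      : perBatch;
    for (R_xlen_t h = 0; h < nb; ++h) {
      // emission voxel
      double u = unif_rand();
      R_xlen_t v = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (v >= nvox) v = nvox - 1;
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int j = (int)((v - (R_xlen_t)k * nx * ny) / nx);
      int i = (int)(v - (R_xlen_t)k * nx * ny - (R_xlen_t)j * nx);
      // uniform position inside the voxel (grid corner at 0)
      double px = (i + unif_rand()) * spacing[0];
      double py = (j + unif_rand()) * spacing[1];
      double pz = (k + unif_rand()) * spacing[2];
      // isotropic direction
      double cz = 2.0 * unif_rand() - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      double phi = 2.0 * M_PI * unif_rand();
      double dx = st * std::cos(phi), dy = st * std::sin(phi), dz = cz;
      // energy and residual water-equivalent range
      double E = lininterp(cp, ce, unif_rand());
      emitted += E;
      double r = lininterp(re, rr, E);

      while (E > 0.0) {
        // current voxel
        int ci = (int)std::floor(px / spacing[0]);
        int cj = (int)std::floor(py / spacing[1]);
        int ck = (int)std::floor(pz / spacing[2]);
        if (ci < 0 || ci >= nx || cj < 0 || cj >= ny || ck < 0 || ck >= nz) {
          escaped += E;
          break;
        }
        R_xlen_t cv = (R_xlen_t)ck * nx * ny + (R_xlen_t)cj * nx + ci;
        double rho = density[cv];
        double dsw = stepMm * rho;    // water-equivalent path of one step
        if (dsw >= r) {
          // track ends inside this voxel
          bdep[cv] += E;
          E = 0.0;
          break;
        }
        r -= dsw;
        double Enew = lininterp(rr, re, r);
        if (Enew > E) Enew = E;
        bdep[cv] += E - Enew;
        E = Enew;
        px += dx * stepMm; py += dy * stepMm; pz += dz * stepMm;
        if (px < 0 || px >= ex || py < 0 || py >= ey || pz < 0 || pz >= ez) {
          escaped += E;
          break;
        }
      }
    }
    for (R_xlen_t v = 0; v < nvox; ++v) {
      edep[v] += bdep[v];
      batchSum[v] += bdep[v];
      batchSumSq[v] += bdep[v] * bdep[v];
    }
    histBatch[b] = (double)nb;
    if (haveTally) {
      double tb = 0.0;
      for (R_xlen_t v = 0; v < nvox; ++v) tb += bdep[v] * tallyW[v];
      tallyBatch[b] = tb;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["edep"] = edep, _["batchSum"] = batchSum,
                      _["batchSumSq"] = batchSumSq, _["emitted"] = emitted,
                      _["escaped"] = escaped, _["nBatches"] = nBatches,
                      _["histBatch"] = histBatch,
                      _["tallyBatch"] = tallyBatch);
}
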