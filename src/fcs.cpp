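// Monte Carlo lattice diffusion, photon-trace generation and the multi-tau
// correlator. Hot loops only; all orchestration stays in R.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// splitmix64: fast, well-mixed 64-bit generator used for the per-molecule
// streams (one independently seeded stream per molecule, so adding
// molecules never reshuffles existing trajectories).
static inline uint64_t sm64_next(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t molecule_seed(uint64_t master, int mol) {
  uint64_t s = master;
  uint64_t a = sm64_next(s);
  s = a ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(mol + 1));
  return sm64_next(s);
}

// One lattice hop decision per axis from 21-bit slices of a single draw:
// move -1 with probability p, +1 with probability p (21-bit threshold
// quantization, relative error < 1e-5 for the p used here).
static inline int hop(uint32_t r, uint32_t thr) {
  if (r < thr) return -1;
  if (r < 2 * thr) return +1;
  return 0;
}

// Fused trajectory + expected-photon-rate accumulation.
// mde: flattened n_cells^3 array (x fastest), normalized to peak 1.
// Returns expected counts per bin (length n_bins); Poisson drawing happens
// in R with R's RNG.
// [[Rcpp::export(name = ".fcs_expected_trace")]]
NumericVector fcs_expected_trace(int n_mol, int n_cells, double p,
                                 int n_steps, int steps_per_bin,
                                 NumericVector mde, double peak_rate,
                                 double dt, double master_seed) {
  if (p > 0.25) stop("hop probability p = D*dt/cell^2 exceeds 0.25");
  if (mde.size() != (R_xlen_t)n_cells * n_cells * n_cells)
    stop("MDE array does not match the lattice");
  int n_bins = n_steps / steps_per_bin;
  NumericVector expected(n_bins);
  double *exp_ptr = REAL(expected);
  const double *m = REAL(mde);
  uint32_t thr = (uint32_t)(p * 2097152.0); // p * 2^21
  uint64_t master = (uint64_t)master_seed;
  for (int i = 0; i < n_mol; ++i) {
    uint64_t s = molecule_seed(master, i);
    // uniform initial position from one draw
    uint64_t r0 = sm64_next(s);
    int x = (int)(r0 % n_cells);
    int y = (int)((r0 >> 16) % n_cells);
    int z = (int)((r0 >> 32) % n_cells);
    for (int t = 0; t < n_bins * steps_per_bin; ++t) {
      uint64_t r = sm64_next(s);
      x += hop((uint32_t)(r & 0x1FFFFF), thr);
      y += hop((uint32_t)((r >> 21) & 0x1FFFFF), thr);
      z += hop((uint32_t)((r >> 42) & 0x1FFFFF), thr);
      if (x < 0) x += n_cells; else if (x >= n_cells) x -= n_cells;
      if (y < 0) y += n_cells; else if (y >= n_cells) y -= n_cells;
      if (z < 0) z += n_cells; else if (z >= n_cells) z -= n_cells;
      double v = m[(size_t)(z * n_cells + y) * n_cells + x];
      if (v > 0.0) exp_ptr[t / steps_per_bin] += peak_rate * v * dt;
    }
  }
  return expected;
}

// Explicit trajectories (same RNG streams as the fused path) for
// analysis-scale runs; returns an n_steps+1 x n_mol x 3 array of lattice
// indices (0-based).
// [[Rcpp::export(name = ".fcs_trajectories")]]
IntegerVector fcs_trajectories(int n_mol, int n_cells, double p, int n_steps,
                               double master_seed) {
  if (p > 0.25) stop("hop probability p = D*dt/cell^2 exceeds 0.25");
  if ((double)n_mol * (n_steps + 1) * 3 > 2e8)
    stop("trajectory array too large; use the fused photon-trace path");
  IntegerVector out(Dimension(n_steps + 1, n_mol, 3));
  int *o = INTEGER(out);
  uint32_t thr = (uint32_t)(p * 2097152.0);
  uint64_t master = (uint64_t)master_seed;
  size_t plane = (size_t)(n_steps + 1) * n_mol;
  for (int i = 0; i < n_mol; ++i) {
    uint64_t s = molecule_seed(master, i);
    uint64_t r0 = sm64_next(s);
    int x = (int)(r0 % n_cells);
    int y = (int)((r0 >> 16) % n_cells);
    int z = (int)((r0 >> 32) % n_cells);
    o[(size_t)i * (n_steps + 1)] = x;
    o[plane + (size_t)i * (n_steps + 1)] = y;
    o[2 * plane + (size_t)i * (n_steps + 1)] = z;
    for (int t = 1; t <= n_steps; ++t) {
      uint64_t r = sm64_next(s);
      x += hop((uint32_t)(r & 0x1FFFFF), thr);
      y += hop((uint32_t)((r >> 21) & 0x1FFFFF), thr);
      z += hop((uint32_t)((r >> 42) & 0x1FFFFF), thr);
      if (x < 0) x += n_cells; else if (x >= n_cells) x -= n_cells;
      if (y < 0) y += n_cells; else if (y >= n_cells) y -= n_cells;
      if (z < 0) z += n_cells; else if (z >= n_cells) z -= n_cells;
      o[(size_t)i * (n_steps + 1) + t] = x;
      o[plane + (size_t)i * (n_steps + 1) + t] = y;
      o[2 * plane + (size_t)i * (n_steps + 1) + t] = z;
    }
  }
  return out;
}

// Multi-tau autocorrelation with symmetric normalization and block-averaged
// standard errors. m linear channels per stage; from stage 1 on the series
// is rebinned by 2 and lags m/2+1..m (in rebinned units) are evaluated.
// G(l) = mean(I_t I_{t+l}) / (mean_left * mean_right) - 1.
// [[Rcpp::export(name = ".multitau_cpp")]]
List multitau_cpp(NumericVector counts, int m, int n_stages, int n_blocks) {
  R_xlen_t n = counts.size();
  if (n < 2 * m) stop("trace shorter than one correlator stage");
  std::vector<double> series(counts.begin(), counts.end());
  std::vector<double> lags, G, SE;
  double bin = 1.0; // lag unit in original bins
  for (int stage = 0; stage < n_stages; ++stage) {
    R_xlen_t len = (R_xlen_t)series.size();
    if (len < 2 * m) break;
    int l_lo = (stage == 0) ? 1 : m / 2 + 1;
    for (int l = l_lo; l <= m; ++l) {
      R_xlen_t M = len - l;
      if (M < n_blocks) break;
      // per-block sums for the block-averaged error
      std::vector<double> bs(n_blocks, 0.0), bl(n_blocks, 0.0),
          br(n_blocks, 0.0);
      std::vector<R_xlen_t> bn(n_blocks, 0);
      double s = 0.0, sl = 0.0, sr = 0.0;
      for (R_xlen_t t = 0; t < M; ++t) {
        int b = (int)((t * (R_xlen_t)n_blocks) / M);
        double prod = series[t] * series[t + l];
        s += prod; sl += series[t]; sr += series[t + l];
        bs[b] += prod; bl[b] += series[t]; br[b] += series[t + l];
        bn[b]++;
      }
      double ml = sl / M, mr = sr / M;
      if (ml <= 0.0 || mr <= 0.0)
        stop("undefined normalization: trace mean is zero");
      double g = (s / M) / (ml * mr) - 1.0;
      // block estimates
      double bsum = 0.0, bsq = 0.0; int bcnt = 0;
      for (int b = 0; b < n_blocks; ++b) {
        if (bn[b] < 2) continue;
        double mlb = bl[b] / bn[b], mrb = br[b] / bn[b];
        if (mlb <= 0.0 || mrb <= 0.0) continue;
        double gb = (bs[b] / bn[b]) / (mlb * mrb) - 1.0;
        bsum += gb; bsq += gb * gb; bcnt++;
      }
      double se = NA_REAL;
      if (bcnt >= 2) {
        double mb = bsum / bcnt;
        double var = (bsq - bcnt * mb * mb) / (bcnt - 1);
        se = sqrt(var > 0 ? var / bcnt : 0.0);
      }
      lags.push_back(l * bin);
      G.push_back(g);
      SE.push_back(se);
    }
    // rebin by 2 for the next stage
    R_xlen_t half = len / 2;
    for (R_xlen_t t = 0; t < half; ++t)
      series[t] = 0.5 * (series[2 * t] + series[2 * t + 1]);
    series.resize(half);
    bin *= 2.0;
  }
  return List::create(_["lag_bins"] = wrap(lags), _["G"] = wrap(G),
                      _["se"] = wrap(SE));
}
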