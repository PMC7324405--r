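#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Boltzmann-sum kernel for the implicit-ligand-sampling landscape.
//
// coords: (M*N) x 3 stacked frame coordinates (frame-major blocks of N).
// sigc1/epsc1, sigc2/epsc2: per-atom LJ parameters already combined with
// ligand site 1 / site 2 (combination rule applied on the R side).
// For each voxel: C insertion draws, position uniform in the voxel cube,
// orientation uniform on the sphere (normalized Gaussian 3-vector); each
// draw is evaluated in every frame; per-draw interaction energies are
// clamped at `clamp` kJ/mol before exponentiation. Returns the per-voxel
// sum of exp(-beta * dE) over all M*C (draw, frame) pairs. Uses R's RNG,
// so results are reproducible under set.seed(); draw order is voxel-major,
// then draw, with 3 uniforms followed by 3 normals per draw.
// [[Rcpp::export]]
NumericVector ils_sum_cpp(NumericMatrix coords, int n_frames, int n_atoms,
                          NumericVector sigc1, NumericVector epsc1,
                          NumericVector sigc2, NumericVector epsc2,
                          double half_bond,
                          NumericVector origin, NumericVector spacing,
                          IntegerVector shape,
                          int n_insert, double beta,
                          double cutoff2, double clamp) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *cx = &coords(0, 0), *cy = &coords(0, 1), *cz = &coords(0, 2);

  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++v) {
        const double vx = origin[0] + i * spacing[0];
        const double vy = origin[1] + j * spacing[1];
        const double vz = origin[2] + k * spacing[2];
        double s = 0.0;
        for (int c = 0; c < n_insert; ++c) {
          for (int m = 0; m < n_frames; ++m) {
            // fresh insertion draw for every (draw, configuration) pair
            const double px = vx + (unif_rand() - 0.5) * spacing[0];
            const double py = vy + (unif_rand() - 0.5) * spacing[1];
            const double pz = vz + (unif_rand() - 0.5) * spacing[2];
            double ox = norm_rand(), oy = norm_rand(), oz = norm_rand();
            double nrm = std::sqrt(ox * ox + oy * oy + oz * oz);
            if (nrm < 1e-12) { ox = 0.0; oy = 0.0; oz = 1.0; nrm = 1.0; }
            const double hx = half_bond * ox / nrm;
            const double hy = half_bond * oy / nrm;
            const double hz = half_bond * oz / nrm;
            const double s1x = px + hx, s1y = py + hy, s1z = pz + hz;
            const double s2x = px - hx, s2y = py - hy, s2z = pz - hz;
            const R_xlen_t off = (R_xlen_t)m * n_atoms;
            double e = 0.0;
            for (int a = 0; a < n_atoms; ++a) {
              const double ax = cx[off + a], ay = cy[off + a], az = cz[off + a];
              double dx = s1x - ax, dy = s1y - ay, dz = s1z - az;
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 <= cutoff2) {
                if (r2 < 1e-12) { e = clamp; break; }
                double sr2 = sigc1[a] * sigc1[a] / r2;
                double sr6 = sr2 * sr2 * sr2;
                e += 4.0 * epsc1[a] * (sr6 * sr6 - sr6);
              }
              dx = s2x - ax; dy = s2y - ay; dz = s2z - az;
              r2 = dx * dx + dy * dy + dz * dz;
              if (r2 <= cutoff2) {
                if (r2 < 1e-12) { e = clamp; break; }
                double sr2 = sigc2[a] * sigc2[a] / r2;
                double sr6 = sr2 * sr2 * sr2;
                e += 4.0 * epsc2[a] * (sr6 * sr6 - sr6);
              }
              if (e >= clamp) { e = clamp; break; }
            }
            if (e > clamp) e = clamp;
            s += std::exp(-beta * e);
          }
        }
        out[v] = s;
      }
    }
  }
  return out;
}

// Metropolis random walks on voxel centers with 26-neighbor proposals.
// Proposals off-grid or into masked voxels are rejected (walker stays).
// Returns an (n_steps * n_ligands) x 3 matrix of 0-based voxel indices,
// ligand-major. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix metropolis_walk_cpp(NumericVector values, LogicalVector mask,
                                  IntegerVector shape, IntegerMatrix start,
                                  int n_steps, double beta) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int n_lig = start.nrow();
  IntegerMatrix out((R_xlen_t)n_steps * n_lig, 3);
  // the 26 neighbour offsets
  int offs[26][3]; int no = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) { offs[no][0] = dx; offs[no][1] = dy; offs[no][2] = dz; ++no; }
  for (int l = 0; l < n_lig; ++l) {
    int ci = start(l, 0), cj = start(l, 1), ck = start(l, 2);
    R_xlen_t cur = ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck);
    if (ci < 0 || ci >= nx || cj < 0 || cj >= ny || ck < 0 || ck >= nz || mask[cur])
      stop("walk start voxel out of grid or masked");
    double ecur = values[cur];
    for (int t = 0; t < n_steps; ++t) {
      int p = (int)std::floor(unif_rand() * 26.0);
      if (p > 25) p = 25;
      const int ni = ci + offs[p][0], nj = cj + offs[p][1], nk = ck + offs[p][2];
      if (ni >= 0 && ni < nx && nj >= 0 && nj < ny && nk >= 0 && nk < nz) {
        const R_xlen_t nxt = ni + (R_xlen_t)nx * (nj + (R_xlen_t)ny * nk);
        if (!mask[nxt]) {
          const double de = values[nxt] - ecur;
          if (de <= 0.0 || unif_rand() < std::exp(-beta * de)) {
            ci = ni; cj = nj; ck = nk; ecur = values[nxt];
          }
        }
      }
      const R_xlen_t row = (R_xlen_t)l * n_steps + t;
      out(row, 0) = ci; out(row, 1) = cj; out(row, 2) = ck;
    }
  }
  return out;
}

// Long-run trajectory-counting estimate of the reactive flux of a Markov
// chain: simulate n_steps transitions from the source state and count
// completions of source -> target reactive excursions per step, in
// n_batches equal batches (for batch-means standard errors). Independent
// of the transition-path-theory linear algebra. Uses R's RNG.
// [[Rcpp::export]]
NumericVector count_reactive_cpp(NumericMatrix T, int source,
                                 IntegerVector targets,
                                 double n_steps, int n_batches) {
  const int n = T.nrow();
  std::vector<bool> is_target(n, false);
  for (int t = 0; t < targets.size(); ++t) is_target[targets[t]] = true;
  // cumulative rows for inverse-CDF sampling
  std::vector<double> cum((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) { acc += T(i, j); cum[(size_t)i * n + j] = acc; }
    cum[(size_t)i * n + n - 1] = 1.0;
  }
  NumericVector counts(n_batches);
  const double per_batch = n_steps / n_batches;
  int state = source;
  bool from_source = true;  // visited source more recently than targets
  for (int b = 0; b < n_batches; ++b) {
    double cnt = 0.0;
    for (double s = 0; s < per_batch; ++s) {
      const double u = unif_rand();
      const double *row = &cum[(size_t)state * n];
      int nxt = (int)(std::lower_bound(row, row + n, u) - row);
      if (nxt >= n) nxt = n - 1;
      if (from_source && is_target[nxt] && !is_target[state]) cnt += 1.0;
      if (nxt == source) from_source = true;
      else if (is_target[nxt]) from_source = false;
      state = nxt;
    }
    counts[b] = cnt;
  }
  return counts;
}
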