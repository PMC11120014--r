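#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-voxel Haralick texture maps from sliding-window gray-level
// co-occurrence matrices. For every voxel a window^3 neighbourhood
// (edge-replicated at borders) is scanned once per spatial offset;
// co-occurrence pairs (v, v+offset) with both ends inside the window are
// accumulated symmetrically and normalised, the eight Haralick statistics
// are evaluated, and finally averaged across offsets.
//
// Feature order (alphabetical, fixed):
//   1 ClusterProminence  2 ClusterShade  3 Correlation  4 Energy
//   5 Entropy  6 HaralickCorrelation  7 Inertia  8 InverseDifferenceMoment
//
// HaralickCorrelation follows the ITK texture-feature convention: the
// centering/scaling statistics are the mean and population variance of the
// *values* of the marginal distribution p_x over the G bins (not the moments
// of the gray-level index), which distinguishes it from Correlation for
// symmetric GLCMs. Degenerate denominators return 0.

static const double EPS_VAR = 1e-12;

// [[Rcpp::export]]
List texture_maps_cpp(IntegerVector q, int G, int window, IntegerMatrix offsets) {
  IntegerVector qd = q.attr("dim");
  const int X = qd[0], Y = qd[1], Z = qd[2];
  const int h = window / 2;
  const int n_off = offsets.nrow();

  // replicate-padded copy
  const int Xp = X + 2 * h, Yp = Y + 2 * h, Zp = Z + 2 * h;
  std::vector<int> qp(R_xlen_t(Xp) * Yp * Zp);
  const int *qv = INTEGER(q);
  for (int k = 0; k < Zp; ++k) {
    int zk = std::min(std::max(k - h, 0), Z - 1);
    for (int j = 0; j < Yp; ++j) {
      int yj = std::min(std::max(j - h, 0), Y - 1);
      for (int i = 0; i < Xp; ++i) {
        int xi = std::min(std::max(i - h, 0), X - 1);
        qp[i + R_xlen_t(Xp) * (j + R_xlen_t(Yp) * k)] =
          qv[xi + R_xlen_t(X) * (yj + R_xlen_t(Y) * zk)];
      }
    }
  }

  const int nf = 8;
  List out(nf);
  std::vector<double *> maps(nf);
  for (int f = 0; f < nf; ++f) {
    NumericVector m(R_xlen_t(X) * Y * Z);
    m.attr("dim") = qd;
    out[f] = m;
    maps[f] = REAL(m);
  }

  std::vector<double> pbuf(R_xlen_t(G) * G, 0.0);
  std::vector<double> rowbuf(G, 0.0);
  std::vector<int> cells, rows;
  cells.reserve(256); rows.reserve(64);

  const double inv_g = 1.0 / G;

  R_xlen_t vidx = 0;
  for (int zc = 0; zc < Z; ++zc)
    for (int yc = 0; yc < Y; ++yc)
      for (int xc = 0; xc < X; ++xc, ++vidx) {
        double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
        int n_valid = 0;
        for (int o = 0; o < n_off; ++o) {
          const int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
          double total = 0.0;
          cells.clear(); rows.clear();
          // window spans [c, c+window) in padded coordinates
          for (int wz = 0; wz < window; ++wz) {
            const int z2 = wz + dz;
            if (z2 < 0 || z2 >= window) continue;
            for (int wy = 0; wy < window; ++wy) {
              const int y2 = wy + dy;
              if (y2 < 0 || y2 >= window) continue;
              for (int wx = 0; wx < window; ++wx) {
                const int x2 = wx + dx;
                if (x2 < 0 || x2 >= window) continue;
                const int a = qp[(xc + wx) + R_xlen_t(Xp) * ((yc + wy) + R_xlen_t(Yp) * (zc + wz))];
                const int b = qp[(xc + x2) + R_xlen_t(Xp) * ((yc + y2) + R_xlen_t(Yp) * (zc + z2))];
                const int c1 = a + G * b, c2 = b + G * a;
                if (pbuf[c1] == 0.0) { cells.push_back(c1); if (c1 != c2) cells.push_back(c2); }
                pbuf[c1] += 1.0;
                pbuf[c2] += 1.0;
                total += 2.0;
              }
            }
          }
          if (total == 0.0) continue;
          ++n_valid;
          // marginal p_x
          double energy = 0, entropy = 0, inertia = 0, idm = 0, sij = 0;
          for (size_t t = 0; t < cells.size(); ++t) {
            const int c = cells[t];
            const double p = pbuf[c] / total;
            const int i = c % G, j = c / G;
            energy += p * p;
            if (p > 0) entropy -= p * std::log2(p);
            const double d = i - j;
            inertia += d * d * p;
            idm += p / (1.0 + d * d);
            sij += double(i) * j * p;
            if (rowbuf[i] == 0.0) rows.push_back(i);
            rowbuf[i] += p;
          }
          double mu = 0;
          for (size_t t = 0; t < rows.size(); ++t) mu += rows[t] * rowbuf[rows[t]];
          double sig2 = 0, sum_p2 = 0;
          for (size_t t = 0; t < rows.size(); ++t) {
            const double pr = rowbuf[rows[t]];
            const double dr = rows[t] - mu;
            sig2 += dr * dr * pr;
            sum_p2 += pr * pr;
          }
          double shade = 0, prom = 0;
          for (size_t t = 0; t < cells.size(); ++t) {
            const int c = cells[t];
            const double p = pbuf[c] / total;
            const int i = c % G, j = c / G;
            const double s = (i - mu) + (j - mu);
            const double s3 = s * s * s;
            shade += s3 * p;
            prom += s3 * s * p;
          }
          const double corr = (sig2 > EPS_VAR) ? (sij - mu * mu) / sig2 : 0.0;
          const double mds = (sum_p2 - inv_g) * inv_g;  // Var_k of p_x values
          const double hc = (mds > EPS_VAR * inv_g) ? (sij - inv_g * inv_g) / mds : 0.0;

          acc[0] += prom; acc[1] += shade; acc[2] += corr; acc[3] += energy;
          acc[4] += entropy; acc[5] += hc; acc[6] += inertia; acc[7] += idm;

          // reset buffers
          for (size_t t = 0; t < cells.size(); ++t) pbuf[cells[t]] = 0.0;
          for (size_t t = 0; t < rows.size(); ++t) rowbuf[rows[t]] = 0.0;
        }
        if (n_valid > 0)
          for (int f = 0; f < nf; ++f) maps[f][vidx] = acc[f] / n_valid;
      }

  out.names() = CharacterVector::create(
    "ClusterProminence", "ClusterShade", "Correlation", "Energy",
    "Entropy", "HaralickCorrelation", "Inertia", "InverseDifferenceMoment");
  return out;
}
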