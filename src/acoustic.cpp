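// Homogeneous lossless-medium acoustics: spherical-spreading forward
// projection of initial pressure to point detectors, and 3D delay-and-sum.
// All geometry in meters, time in seconds.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// pos: 3 x m voxel coordinates, val: m source amplitudes, epos: 3 x n element
// coordinates. Bins 1/(4*pi*d)-weighted arrivals at t = d/c with linear
// splitting between samples, then takes the central-difference time
// derivative. Returns n x n_samples.
// [[Rcpp::export]]
arma::mat cpp_forward_project(const arma::mat& pos, const arma::vec& val,
                              const arma::mat& epos, double c, double fs,
                              double t0, int n_samples) {
  const int m = pos.n_cols, n = epos.n_cols;
  arma::mat S(n, n_samples, arma::fill::zeros);
  const double fourpi = 4.0 * M_PI;
  for (int e = 0; e < n; ++e) {
    const double ex = epos(0, e), ey = epos(1, e), ez = epos(2, e);
    arma::rowvec acc(n_samples, arma::fill::zeros);
    for (int v = 0; v < m; ++v) {
      const double dx = pos(0, v) - ex, dy = pos(1, v) - ey, dz = pos(2, v) - ez;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d <= 0) continue;
      const double ti = (d / c - t0) * fs;
      const int i0 = (int)std::floor(ti);
      if (i0 < 0 || i0 + 1 >= n_samples)
        stop("arrival time outside the record: need at least %d samples", i0 + 2);
      const double fr = ti - i0;
      const double w = val[v] / (fourpi * d);
      acc[i0] += w * (1.0 - fr);
      acc[i0 + 1] += w * fr;
    }
    S.row(e) = acc;
  }
  // time derivative with the backprojection sign convention (-dp/dt),
  // discretized as a forward difference so the positive extremum of the
  // bipolar transient falls exactly at t = d/c (delay-and-sum then peaks
  // at the source location)
  arma::mat D(n, n_samples);
  for (int e = 0; e < n; ++e) {
    for (int t = 0; t < n_samples - 1; ++t)
      D(e, t) = (S(e, t) - S(e, t + 1)) * fs;
    D(e, n_samples - 1) = S(e, n_samples - 1) * fs;
  }
  return D;
}

// St: n_t x n_elem (time down the columns), epos: 3 x n_elem.
// Unweighted delay-and-sum with linear interpolation between samples.
// [[Rcpp::export]]
arma::vec cpp_das(const arma::mat& St, const arma::mat& epos,
                  const arma::vec& origin, double pitch, IntegerVector dims,
                  double c, double fs, double t0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_t = St.n_rows, ne = St.n_cols;
  arma::vec out((long)nx * ny * nz, arma::fill::zeros);
  for (int z = 0; z < nz; ++z) {
    const double pz = origin[2] + z * pitch;
    for (int y = 0; y < ny; ++y) {
      const double py = origin[1] + y * pitch;
      for (int x = 0; x < nx; ++x) {
        const double px = origin[0] + x * pitch;
        double s = 0;
        for (int e = 0; e < ne; ++e) {
          const double dx = px - epos(0, e), dy = py - epos(1, e), dz = pz - epos(2, e);
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          const double ti = (d / c - t0) * fs;
          const int i0 = (int)std::floor(ti);
          if (i0 < 0 || i0 + 1 >= n_t)
            stop("voxel-element delay outside the record: need at least %d samples", i0 + 2);
          const double fr = ti - i0;
          const double* col = St.colptr(e);
          s += col[i0] * (1.0 - fr) + col[i0 + 1] * fr;
        }
        out[x + (long)nx * (y + (long)ny * z)] = s;
      }
    }
  }
  return out;
}
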