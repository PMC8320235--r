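#include <Rcpp.h>
using namespace Rcpp;

// 3x3 matrix helpers, row-major double[9]
static inline void mat_mult(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] + A[3 * i + 2] * B[6 + j];
}

static inline void rot_x(double phi, double* R) {
  double c = std::cos(phi), s = std::sin(phi);
  R[0] = 1; R[1] = 0; R[2] = 0;
  R[3] = 0; R[4] = c; R[5] = -s;
  R[6] = 0; R[7] = s; R[8] = c;
}

static inline void rot_y(double theta, double* R) {
  double c = std::cos(theta), s = std::sin(theta);
  R[0] = c; R[1] = 0; R[2] = s;
  R[3] = 0; R[4] = 1; R[5] = 0;
  R[6] = -s; R[7] = 0; R[8] = c;
}

// Evaluate kinked-chain conformations from pre-drawn uniforms.
//
// U: n x (3*nseg) uniforms in [0,1): per segment (length, phi, theta).
// Segment i direction is the z-axis of frame M_i = M_{i-1} Rx(phi_i) Ry(theta_i);
// M_0 maps the local z-axis onto the outward radial direction at the epitope
// (0, y0, z0) and keeps x along the microtubule axis.
// Steric predicate: every vertex k >= 1 satisfies y_k^2 + z_k^2 > y0^2 + z0^2
// (microtubule impenetrable at the epitope radius), and every pair of points
// sampled at arc_res spacing on non-sequential segments is farther apart
// than d_min.
// [[Rcpp::export]]
List chain_eval_cpp(NumericMatrix U, List lenValues, IntegerVector lenType,
                    NumericVector phiLo, NumericVector phiHi,
                    NumericVector thetaLo, NumericVector thetaHi,
                    double y0, double z0, double dMin, double arcRes,
                    bool checkWall, bool checkClash, bool keepVertices) {
  const int n = U.nrow();
  const int nseg = lenType.size();
  if (U.ncol() != 3 * nseg) stop("uniform matrix must have 3 columns per segment");

  NumericMatrix endpoints(n, 3);
  LogicalVector accepted(n);
  NumericMatrix vertices;
  if (keepVertices) vertices = NumericMatrix(n, 3 * (nseg + 1));
  NumericMatrix angles(n, 2 * nseg);   // phi_1..phi_n, theta_1..theta_n
  NumericVector lengths(n * nseg);

  const double re2 = y0 * y0 + z0 * z0;
  const double re = std::sqrt(re2);

  // epitope frame: columns are local x (MT axis), y, z (outward radial)
  double M0[9] = {1, 0, 0,
                  0, z0 / re, y0 / re,
                  0, -y0 / re, z0 / re};
  if (re == 0) stop("epitope cannot sit on the microtubule axis");

  std::vector<double> Lw(nseg), vx(nseg + 1), vy(nseg + 1), vz(nseg + 1);
  std::vector<double> dx(nseg), dy(nseg), dz(nseg);
  // cache finite length sets
  std::vector<NumericVector> lv(nseg);
  for (int s = 0; s < nseg; ++s) lv[s] = as<NumericVector>(lenValues[s]);

  for (int i = 0; i < n; ++i) {
    double M[9], Mr[9], T1[9], T2[9];
    std::copy(M0, M0 + 9, M);
    vx[0] = 0.0; vy[0] = y0; vz[0] = z0;
    bool ok = true;

    for (int s = 0; s < nseg; ++s) {
      double ul = U(i, 3 * s), up = U(i, 3 * s + 1), ut = U(i, 3 * s + 2);
      double L;
      if (lenType[s] == 0) {              // finite set
        int m = lv[s].size();
        int idx = (int)(ul * m); if (idx >= m) idx = m - 1;
        L = lv[s][idx];
      } else {                            // continuous range
        L = lv[s][0] + ul * (lv[s][1] - lv[s][0]);
      }
      double phi = phiLo[s] + up * (phiHi[s] - phiLo[s]);
      double theta = thetaLo[s] + ut * (thetaHi[s] - thetaLo[s]);
      angles(i, s) = phi; angles(i, nseg + s) = theta;
      lengths[(size_t)i * nseg + s] = L;
      Lw[s] = L;

      rot_x(phi, T1); rot_y(theta, T2);
      mat_mult(T1, T2, Mr);      // Rx * Ry
      mat_mult(M, Mr, T1);       // M * Rx * Ry
      std::copy(T1, T1 + 9, M);
      dx[s] = M[2]; dy[s] = M[5]; dz[s] = M[8];   // third column = direction
      vx[s + 1] = vx[s] + L * dx[s];
      vy[s + 1] = vy[s] + L * dy[s];
      vz[s + 1] = vz[s] + L * dz[s];
      if (checkWall && (vy[s + 1] * vy[s + 1] + vz[s + 1] * vz[s + 1] <= re2)) ok = false;
    }

    if (ok && checkClash && dMin > 0 && nseg >= 3) {
      const double d2min = dMin * dMin;
      for (int a = 0; a < nseg - 2 && ok; ++a) {
        int na = std::max(2, (int)std::ceil(Lw[a] / arcRes) + 1);
        for (int b = a + 2; b < nseg && ok; ++b) {
          int nb = std::max(2, (int)std::ceil(Lw[b] / arcRes) + 1);
          for (int p = 0; p < na && ok; ++p) {
            double ta = Lw[a] * p / (na - 1);
            double ax = vx[a] + ta * dx[a], ay = vy[a] + ta * dy[a], az = vz[a] + ta * dz[a];
            for (int q = 0; q < nb; ++q) {
              double tb = Lw[b] * q / (nb - 1);
              double ddx = ax - (vx[b] + tb * dx[b]);
              double ddy = ay - (vy[b] + tb * dy[b]);
              double ddz = az - (vz[b] + tb * dz[b]);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= d2min) { ok = false; break; }
            }
          }
        }
      }
    }

    accepted[i] = ok;
    endpoints(i, 0) = vx[nseg]; endpoints(i, 1) = vy[nseg]; endpoints(i, 2) = vz[nseg];
    if (keepVertices)
      for (int k = 0; k <= nseg; ++k) {
        vertices(i, 3 * k) = vx[k];
        vertices(i, 3 * k + 1) = vy[k];
        vertices(i, 3 * k + 2) = vz[k];
      }
  }

  List out = List::create(_["endpoints"] = endpoints,
                          _["accepted"] = accepted,
                          _["angles"] = angles,
                          _["lengths"] = lengths);
  if (keepVertices) out["vertices"] = vertices;
  return out;
}
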