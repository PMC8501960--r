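// Rigid base-pair-step kernel: mid-step-frame (CEHS/3DNA-style) transforms,
// chain reconstruction, and the penalized elastic objective used by the
// loop optimizer.  All angles in RADIANS, lengths in Angstrom here; the R
// layer converts from the user-facing degree convention.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat rot_z(double a) {
  mat R(3, 3, fill::eye);
  double c = std::cos(a), s = std::sin(a);
  R(0, 0) = c; R(0, 1) = -s; R(1, 0) = s; R(1, 1) = c;
  return R;
}

static mat rot_y(double a) {
  mat R(3, 3, fill::eye);
  double c = std::cos(a), s = std::sin(a);
  R(0, 0) = c; R(0, 2) = s; R(2, 0) = -s; R(2, 2) = c;
  return R;
}

// 4x4 homogeneous transform from frame i to frame i+1.
// p = (tilt, roll, twist, shift, slide, rise); rotation
// Rz(w/2 - phi) Ry(Gamma) Rz(w/2 + phi) with Gamma = sqrt(tilt^2 + roll^2),
// phi = atan2(tilt, roll); translation expressed in the mid-step frame
// Rz(w/2 - phi) Ry(Gamma/2) Rz(phi).
static mat44 step_mat(const double* p) {
  double tilt = p[0], roll = p[1], twist = p[2];
  double gam = std::sqrt(tilt * tilt + roll * roll);
  double phi = (gam < 1e-14) ? 0.0 : std::atan2(tilt, roll);
  double a = 0.5 * twist - phi, b = 0.5 * twist + phi;
  mat Q = rot_z(a) * rot_y(gam) * rot_z(b);
  mat Mid = rot_z(a) * rot_y(0.5 * gam) * rot_z(phi);
  vec d = { p[3], p[4], p[5] };
  vec t = Mid * d;
  mat44 M(fill::eye);
  M.submat(0, 0, 2, 2) = Q;
  M(0, 3) = t(0); M(1, 3) = t(1); M(2, 3) = t(2);
  return M;
}

// [[Rcpp::export]]
arma::mat cpp_step_matrix(const arma::vec& p) {
  mat44 M = step_mat(p.memptr());
  return mat(M);
}

// [[Rcpp::export]]
arma::cube cpp_chain_frames(const arma::mat& first, const arma::mat& steps) {
  const uword n = steps.n_rows;
  cube out(4, 4, n + 1);
  mat44 T(fill::eye);
  T = first;
  out.slice(0) = T;
  for (uword k = 0; k < n; ++k) {
    double p[6];
    for (int j = 0; j < 6; ++j) p[j] = steps(k, j);
    T = T * step_mat(p);
    out.slice(k + 1) = T;
  }
  return out;
}

// Inverse of step_mat for a pair of frames (ZYZ Euler decomposition of
// R1^T R2 plus mid-frame transport of the origin difference).
// [[Rcpp::export]]
arma::mat cpp_extract_steps(const arma::cube& frames) {
  const uword n = frames.n_slices - 1;
  mat out(n, 6);
  for (uword k = 0; k < n; ++k) {
    mat R1 = frames.slice(k).submat(0, 0, 2, 2);
    mat R2 = frames.slice(k + 1).submat(0, 0, 2, 2);
    vec o1 = frames.slice(k).submat(0, 3, 2, 3);
    vec o2 = frames.slice(k + 1).submat(0, 3, 2, 3);
    mat Q = R1.t() * R2;
    double cg = std::max(-1.0, std::min(1.0, Q(2, 2)));
    double gam = std::acos(cg);
    double a, b;
    if (gam < 1e-9) {            // pure twist: Q ~ Rz(a + b)
      double w = std::atan2(Q(1, 0), Q(0, 0));
      a = 0.5 * w; b = 0.5 * w; gam = 0.0;
    } else {
      a = std::atan2(Q(1, 2), Q(0, 2));
      b = std::atan2(Q(2, 1), -Q(2, 0));
    }
    double twist = a + b, phi = 0.5 * (b - a);
    // canonical branch: |twist| <= pi (the (twist - 2pi, phi + pi)
    // representation encodes the same rotation)
    if (twist > M_PI) { twist -= 2.0 * M_PI; phi += M_PI; }
    else if (twist <= -M_PI) { twist += 2.0 * M_PI; phi += M_PI; }
    double tilt = gam * std::sin(phi), roll = gam * std::cos(phi);
    mat Mid = R1 * rot_z(0.5 * twist - phi) * rot_y(0.5 * gam) * rot_z(phi);
    vec d = Mid.t() * (o2 - o1);
    out(k, 0) = tilt; out(k, 1) = roll; out(k, 2) = twist;
    out(k, 3) = d(0); out(k, 4) = d(1); out(k, 5) = d(2);
  }
  return out;
}

// Penalized objective for loop optimization.
//   par      : packed free-step parameters (length 6 * n_free, radians/Angstrom)
//   steps0   : full (N-1) x 6 step matrix; frozen rows used as-is
//   free_idx : 0-based indices of free steps (rows of steps0 replaced by par)
//   first    : fixed first frame (4x4)
//   target   : target last frame (4x4)
//   rest     : rest-state step (usually c(0,0,twist0,0,0,rise0))
//   kdof     : 6 quadratic constants (kBT per rad^2 / per A^2)
//   kpos,krot: penalty stiffness on end-origin distance^2 and Frobenius
//              orientation mismatch
// Returns objective value, elastic part, end residuals, and the gradient.
// [[Rcpp::export]]
Rcpp::List cpp_loop_objective(const arma::vec& par,
                              const arma::mat& steps0,
                              const arma::uvec& free_idx,
                              const arma::mat& first,
                              const arma::mat& target,
                              const arma::vec& rest,
                              const arma::vec& kdof,
                              double kpos, double krot,
                              bool want_grad) {
  const uword nstep = steps0.n_rows;
  const uword nfree = free_idx.n_elem;
  mat steps = steps0;
  for (uword i = 0; i < nfree; ++i)
    for (int j = 0; j < 6; ++j)
      steps(free_idx(i), j) = par(6 * i + j);

  // elastic energy over free steps
  double elastic = 0.0;
  for (uword i = 0; i < nfree; ++i) {
    const uword k = free_idx(i);
    for (int j = 0; j < 6; ++j) {
      double d = steps(k, j) - rest(j);
      elastic += 0.5 * kdof(j) * d * d;
    }
  }

  // chain transforms, prefix and suffix products
  std::vector<mat44> M(nstep), P(nstep + 1), S(nstep + 1);
  for (uword k = 0; k < nstep; ++k) {
    double p[6];
    for (int j = 0; j < 6; ++j) p[j] = steps(k, j);
    M[k] = step_mat(p);
  }
  P[0] = mat44(first);
  for (uword k = 0; k < nstep; ++k) P[k + 1] = P[k] * M[k];
  S[nstep].eye();
  for (uword k = nstep; k-- > 0;) S[k] = M[k] * S[k + 1];

  mat44 Tend = P[nstep];
  mat44 Tgt(target);
  vec3 dro;
  for (int i = 0; i < 3; ++i) dro(i) = Tend(i, 3) - Tgt(i, 3);
  mat33 dR;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      dR(i, j) = Tend(i, j) - Tgt(i, j);
  double pos2 = dot(dro, dro);
  double rot2 = accu(dR % dR);
  double value = elastic + 0.5 * kpos * pos2 + 0.5 * krot * rot2;

  vec grad;
  if (want_grad) {
    grad.zeros(6 * nfree);
    const double h = 1e-6;
    for (uword i = 0; i < nfree; ++i) {
      const uword k = free_idx(i);
      double p[6];
      for (int j = 0; j < 6; ++j) p[j] = steps(k, j);
      for (int j = 0; j < 6; ++j) {
        // elastic part, analytic
        double g = kdof(j) * (p[j] - rest(j));
        // end-frame part via dM/dp (central difference on the 4x4 step)
        double save = p[j];
        p[j] = save + h; mat44 Mp = step_mat(p);
        p[j] = save - h; mat44 Mm = step_mat(p);
        p[j] = save;
        mat44 dM = (Mp - Mm) / (2.0 * h);
        mat44 dT = P[k] * dM * S[k + 1];
        for (int r = 0; r < 3; ++r) {
          g += kpos * dro(r) * dT(r, 3);
          for (int c = 0; c < 3; ++c) g += krot * dR(r, c) * dT(r, c);
        }
        grad(6 * i + j) = g;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("value") = value,
    Rcpp::Named("elastic") = elastic,
    Rcpp::Named("pos_residual") = std::sqrt(pos2),
    Rcpp::Named("rot_frobenius") = std::sqrt(rot2),
    Rcpp::Named("gradient") = grad);
}
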