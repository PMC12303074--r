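// k-space pseudo-spectral time-domain core for 2D acoustics.
//
// First-order split-field formulation (particle velocity ux/uy, acoustic
// density splits rx/ry, pressure p = c^2 (rx + ry), homogeneous ambient
// density rho0 = 1).  Spatial derivatives are spectral with the k-space
// correction factor sinc(c_ref * k * dt / 2) folded into the derivative
// multipliers, which makes the scheme (including the staggered velocity
// initialisation) exact for homogeneous media.  The PML is applied as
// exp(-alpha dt / 2) factors on each side of every update (split-field).
//
// ks_backward_cpp implements the exact transpose of ks_forward_cpp as a
// linear map from the initial pressure to the sensor traces, plus the exact
// reverse-mode accumulation of the sensitivity of <v, f(p0, c)> with respect
// to the sound speed c.  Spectral derivative operators are real
// skew-symmetric (Nyquist rows zeroed on even grids), so the transposed
// recursion reuses them with flipped signs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat spec_d(const cx_mat& ik, const cx_mat& F) {
  return real(ifft2(cx_mat(ik % F)));
}

// conj(W(-k)): spectrum of the imaginary part separator
static cx_mat creflect(const cx_mat& W) {
  const uword n1 = W.n_rows, n2 = W.n_cols;
  cx_mat out(n1, n2);
  for (uword j = 0; j < n2; ++j) {
    const uword jr = (j == 0) ? 0 : n2 - j;
    for (uword i = 0; i < n1; ++i) {
      const uword ir = (i == 0) ? 0 : n1 - i;
      out(i, j) = std::conj(W(ir, jr));
    }
  }
  return out;
}

// Given real fields a, b, compute Dx a and Dy b with two transforms:
// W = fft2(a + i b) splits into the spectra of a and b via conjugate
// reflection, and the two real derivative fields share one inverse
// transform (Dx a = Re, Dy b = Im).
static void dual_deriv(const mat& a, const mat& b,
                       const cx_mat& ikx, const cx_mat& iky,
                       mat& dxa, mat& dyb) {
  cx_mat W = fft2(cx_mat(a, b));
  cx_mat R = creflect(W);
  cx_mat Af = 0.5 * (W + R);
  cx_mat Bf = cx_double(0, -0.5) * (W - R);
  cx_mat D = ifft2(cx_mat(ikx % Af + cx_double(0, 1) * (iky % Bf)));
  dxa = real(D);
  dyb = imag(D);
}

// [[Rcpp::export]]
Rcpp::List ks_forward_cpp(const arma::mat& p0,
                          const arma::mat& c2,
                          const arma::cx_mat& ikx,
                          const arma::cx_mat& iky,
                          const arma::mat& sx,
                          const arma::mat& sy,
                          const arma::uvec& sensor_idx,
                          const int nt,
                          const double dt,
                          const bool record_rho,
                          const bool record_p,
                          const arma::mat& u0x,
                          const arma::mat& u0y,
                          const bool use_u0) {
  const uword n1 = p0.n_rows, n2 = p0.n_cols;
  const uword M = sensor_idx.n_elem;

  mat rx = p0 / (2.0 * c2);
  mat ry = rx;
  mat ux(n1, n2, fill::zeros), uy(n1, n2, fill::zeros);
  if (use_u0) { ux = u0x; uy = u0y; }

  mat y(M, nt, fill::zeros);
  mat rho_hist, p_hist;
  if (record_rho) rho_hist.set_size(n1 * n2, nt);
  if (record_p)   p_hist.set_size(n1 * n2, nt);

  {
    vec p0v = vectorise(p0);
    y.col(0) = p0v.elem(sensor_idx);
    if (record_rho) rho_hist.col(0) = vectorise(rx + ry);
    if (record_p)   p_hist.col(0) = p0v;
  }

  for (int s = 1; s < nt; ++s) {
    const double dtn = (s == 1 && !use_u0) ? dt / 2.0 : dt;

    mat p = c2 % (rx + ry);
    mat dpx, dpy;
    dual_deriv(p, p, ikx, iky, dpx, dpy);
    ux = sx % (sx % ux - dtn * dpx);
    uy = sy % (sy % uy - dtn * dpy);

    mat dux, duy;
    dual_deriv(ux, uy, ikx, iky, dux, duy);
    rx = sx % (sx % rx - dt * dux);
    ry = sy % (sy % ry - dt * duy);

    mat pn = c2 % (rx + ry);
    vec pv = vectorise(pn);
    y.col(s) = pv.elem(sensor_idx);
    if (record_rho) rho_hist.col(s) = vectorise(rx + ry);
    if (record_p)   p_hist.col(s) = pv;

    if (s % 50 == 0 && !pn.is_finite())
      Rcpp::stop("numerical blow-up: non-finite pressure at time step %d", s);
  }

  if (!y.is_finite())
    Rcpp::stop("numerical blow-up: non-finite sensor data");

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("y") = y,
    Rcpp::Named("ux") = ux, Rcpp::Named("uy") = uy,
    Rcpp::Named("rx") = rx, Rcpp::Named("ry") = ry);
  if (record_rho) out["rho_hist"] = rho_hist;
  if (record_p)   out["p_hist"] = p_hist;
  return out;
}

// Transpose of the forward map (and exact c-sensitivity).  Given sensor-space
// v (M x nt), returns gp0 = (d/dp0) <v, f(p0, c)> = F^T v and, when a forward
// density history is supplied, gc = (d/dc) <v, f(p0, c)>.
// [[Rcpp::export]]
Rcpp::List ks_backward_cpp(const arma::mat& v,
                           const arma::mat& c,
                           const arma::mat& c2,
                           const arma::cx_mat& ikx,
                           const arma::cx_mat& iky,
                           const arma::mat& sx,
                           const arma::mat& sy,
                           const arma::uvec& sensor_idx,
                           const double dt,
                           const arma::mat& rho_hist,
                           const bool want_gc,
                           const bool record_q) {
  const uword n1 = c2.n_rows, n2 = c2.n_cols;
  const int nt = v.n_cols;
  const uword M = sensor_idx.n_elem;
  if (v.n_rows != M) Rcpp::stop("adjoint source has %d rows, expected %d", v.n_rows, M);
  if (want_gc && (rho_hist.n_cols != (uword)nt || rho_hist.n_rows != n1 * n2))
    Rcpp::stop("forward density history missing or mismatched; rerun the forward solve with record_full");

  mat ax(n1, n2, fill::zeros), ay(n1, n2, fill::zeros);
  mat bx(n1, n2, fill::zeros), by(n1, n2, fill::zeros);
  mat gc;
  if (want_gc) gc.zeros(n1, n2);
  mat q_hist;
  if (record_q) q_hist.zeros(n1 * n2, nt);

  for (int s = nt - 1; s >= 1; --s) {
    // output transpose: y_s = E (c^2 (rx + ry))
    mat EtV(n1, n2, fill::zeros);
    vec vs = v.col(s);
    for (uword m = 0; m < M; ++m) EtV(sensor_idx(m)) += vs(m);
    if (want_gc) {
      mat rho_s = reshape(rho_hist.col(s), n1, n2);
      gc += 2.0 * (c % rho_s % EtV);
    }
    bx += c2 % EtV;
    by += c2 % EtV;

    // density update transpose: r' = sx^2 r - dt sx Dx u
    mat dbx, dby;
    dual_deriv(sx % bx, sy % by, ikx, iky, dbx, dby);
    ax += dt * dbx;   // Dx^T = -Dx
    ay += dt * dby;
    bx = sx % sx % bx;
    by = sy % sy % by;

    // velocity update transpose: u' = sx^2 u - dtn sx Dx (c^2 (rx + ry))
    const double dtn = (s == 1) ? dt / 2.0 : dt;
    mat dax, day;
    dual_deriv(sx % ax, sy % ay, ikx, iky, dax, day);
    mat phat = dtn * (dax + day);
    if (record_q) q_hist.col(s) = vectorise(phat);
    if (want_gc) {
      mat rho_pre = reshape(rho_hist.col(s - 1), n1, n2);
      gc += 2.0 * (c % rho_pre % phat);
    }
    bx += c2 % phat;
    by += c2 % phat;
    ax = sx % sx % ax;
    ay = sy % sy % ay;
  }

  // initial conditions transpose: rx0 = ry0 = p0 / (2 c^2), y_0 = E p0
  mat gp0 = (bx + by) / (2.0 * c2);
  vec v0 = v.col(0);
  for (uword m = 0; m < M; ++m) gp0(sensor_idx(m)) += v0(m);
  if (want_gc) {
    mat p0 = c2 % reshape(rho_hist.col(0), n1, n2);
    gc -= (bx + by) % p0 / (c % c % c);
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("gp0") = gp0);
  if (want_gc) out["gc"] = gc;
  if (record_q) out["q_hist"] = q_hist;
  return out;
}
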