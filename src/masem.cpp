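// Compiled kernels for the stage-1 TSSEM multigroup likelihood and the
// stage-2 ML / WLS discrepancy functions, with analytic gradients.
// Variable order everywhere: (Y1, Y2, X1, X2); correlation-vector order:
// (2,1), (3,1), (4,1), (3,2), (4,2), (4,3)  [0-based: see PAIR_I/PAIR_J].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const uword PAIR_I[6] = {1, 2, 3, 2, 3, 3};
static const uword PAIR_J[6] = {0, 0, 0, 1, 1, 2};

static const double BIG = 1e10;

// Build a 4x4 correlation matrix from the 6-vector.
static mat corr_from_vec(const vec& rho) {
  mat R(4, 4, fill::eye);
  for (uword m = 0; m < 6; ++m) {
    R(PAIR_I[m], PAIR_J[m]) = rho(m);
    R(PAIR_J[m], PAIR_I[m]) = rho(m);
  }
  return R;
}

// ---------------------------------------------------------------------
// TSSEM stage 1: F(par) = sum_g (n_g/N) [ log|Sigma_g| - log|S_g|
//                                         + tr(S_g Sigma_g^-1) - p ]
// with Sigma_g = D_g R D_g, par = (rho_6, log d_{g,a}).
// ---------------------------------------------------------------------

// Returns list(value, gradient); value = BIG (gradient 0) when R is
// not positive definite at the trial point.
// [[Rcpp::export]]
Rcpp::List cpp_tssem_objgrad(const arma::vec& par, const arma::cube& S,
                             const arma::vec& n) {
  const uword k = S.n_slices, p = 4;
  const double N = accu(n);
  vec rho = par.subvec(0, 5);
  mat R = corr_from_vec(rho);

  mat cR;
  if (!chol(cR, R) || max(abs(rho)) >= 1.0) {
    return Rcpp::List::create(Rcpp::Named("value") = BIG,
                              Rcpp::Named("gradient") = zeros<vec>(par.n_elem));
  }
  double logdetR = 2.0 * accu(log(cR.diag()));
  mat Rinv = inv_sympd(R);

  double F = 0.0;
  mat Hrho(4, 4, fill::zeros);          // dF/dR (full matrix form)
  vec grad(par.n_elem, fill::zeros);

  for (uword g = 0; g < k; ++g) {
    vec logd = par.subvec(6 + 4 * g, 9 + 4 * g);
    vec d = exp(logd);
    const mat& Sg = S.slice(g);
    double logdetS;
    double sign;
    log_det(logdetS, sign, Sg);
    if (sign <= 0) Rcpp::stop("study %d: correlation matrix not positive definite", g + 1);

    // Sigma^-1 = D^-1 R^-1 D^-1 ; tr(S Sigma^-1) = tr((D^-1 S D^-1) R^-1)
    mat Dinv = diagmat(1.0 / d);
    mat Sigmainv = Dinv * Rinv * Dinv;
    double logdetSigma = logdetR + 2.0 * accu(logd);
    double tr_term = accu(Sg % Sigmainv);  // both symmetric
    double w = n(g) / N;
    F += w * (logdetSigma - logdetS + tr_term - (double)p);

    // G = w (Sigma^-1 - Sigma^-1 S Sigma^-1)
    mat G = w * (Sigmainv - Sigmainv * Sg * Sigmainv);
    mat D = diagmat(d);
    Hrho += D * G * D;
    // d/d log d_a : 2 d_a (G D R)_aa
    mat GDR = G * D * R;
    for (uword a = 0; a < p; ++a)
      grad(6 + 4 * g + a) = 2.0 * d(a) * GDR(a, a);
  }
  for (uword m = 0; m < 6; ++m)
    grad(m) = 2.0 * Hrho(PAIR_I[m], PAIR_J[m]);

  return Rcpp::List::create(Rcpp::Named("value") = F,
                            Rcpp::Named("gradient") = grad);
}

// Expected (Fisher) information of the multigroup likelihood at 'par',
// profiled to the 6 common correlations: inverts
//   I_rr - sum_g I_rd_g I_dd_g^-1 I_dr_g
// and returns the 6x6 asymptotic covariance of the pooled correlations.
// [[Rcpp::export]]
arma::mat cpp_tssem_acov(const arma::vec& par, const arma::vec& n) {
  const uword k = n.n_elem, p = 4;
  vec rho = par.subvec(0, 5);
  mat R = corr_from_vec(rho);
  mat Rinv = inv_sympd(R);

  mat Irr(6, 6, fill::zeros);
  mat Schur(6, 6, fill::zeros);

  for (uword g = 0; g < k; ++g) {
    vec d = exp(par.subvec(6 + 4 * g, 9 + 4 * g));
    mat D = diagmat(d);
    mat Dinv = diagmat(1.0 / d);
    mat Sigmainv = Dinv * Rinv * Dinv;

    // T_m = Sigma^-1 dSigma/dtheta_m for the 10 parameters touching
    // this group: 6 shared correlations then 4 own scale factors d_a.
    std::vector<mat> T(10);
    for (uword m = 0; m < 6; ++m) {
      mat dS(p, p, fill::zeros);
      dS(PAIR_I[m], PAIR_J[m]) = d(PAIR_I[m]) * d(PAIR_J[m]);
      dS(PAIR_J[m], PAIR_I[m]) = dS(PAIR_I[m], PAIR_J[m]);
      T[m] = Sigmainv * dS;
    }
    mat RD = R * D;
    for (uword a = 0; a < p; ++a) {
      mat dS(p, p, fill::zeros);
      dS.row(a) = RD.row(a);        // E_a R D
      dS.col(a) += RD.row(a).t();   // + D R E_a
      T[6 + a] = Sigmainv * dS;
    }

    mat info(10, 10, fill::zeros);
    for (uword i = 0; i < 10; ++i)
      for (uword j = i; j < 10; ++j) {
        info(i, j) = 0.5 * n(g) * accu(T[i] % T[j].t());
        info(j, i) = info(i, j);
      }
    Irr += info.submat(0, 0, 5, 5);
    mat C = info.submat(0, 6, 5, 9);
    mat A = info.submat(6, 6, 9, 9);
    Schur += C * solve(A, C.t());
  }
  return inv_sympd(symmatu(Irr - Schur));
}

// ---------------------------------------------------------------------
// Stage 2 shared machinery: the implied covariance of the 4-variable
// recursive path model and its parameter derivatives.
// theta9 = (g11, g12, g21, b21, phi11, phi22, phi12, psi11, psi22)
// ---------------------------------------------------------------------

static void build_model(const vec& th, mat& Sigma, cube& dSigma) {
  mat Gamma = { {th(0), th(1)}, {th(2), 0.0} };
  double b21 = th(3);
  mat Phi = { {th(4), th(6)}, {th(6), th(5)} };
  mat Psi = { {th(7), 0.0}, {0.0, th(8)} };
  mat A = { {1.0, 0.0}, {b21, 1.0} };     // (I - B)^-1 for strictly lower B

  mat GP = Gamma * Phi;
  mat M = GP * Gamma.t() + Psi;
  mat Syy = A * M * A.t();
  mat Syx = A * GP;

  Sigma.set_size(4, 4);
  Sigma.submat(0, 0, 1, 1) = Syy;
  Sigma.submat(0, 2, 1, 3) = Syx;
  Sigma.submat(2, 0, 3, 1) = Syx.t();
  Sigma.submat(2, 2, 3, 3) = Phi;
  Sigma = symmatu(Sigma);

  dSigma.set_size(4, 4, 9);
  dSigma.zeros();
  auto put = [&](uword q, const mat& dSyy, const mat& dSyx, const mat& dSxx) {
    mat dS(4, 4, fill::zeros);
    dS.submat(0, 0, 1, 1) = dSyy;
    dS.submat(0, 2, 1, 3) = dSyx;
    dS.submat(2, 0, 3, 1) = dSyx.t();
    dS.submat(2, 2, 3, 3) = dSxx;
    dSigma.slice(q) = 0.5 * (dS + dS.t());
  };

  mat Z22(2, 2, fill::zeros);
  // gamma elements (1,1), (1,2), (2,1)
  const uword gi[3] = {0, 0, 1}, gj[3] = {0, 1, 0};
  for (uword q = 0; q < 3; ++q) {
    mat E(2, 2, fill::zeros);
    E(gi[q], gj[q]) = 1.0;
    mat EP = E * Phi;
    mat dSyy = A * (EP * Gamma.t() + GP * E.t()) * A.t();
    put(q, dSyy, A * EP, Z22);
  }
  // beta21: dA = A E21 A
  {
    mat E(2, 2, fill::zeros);
    E(1, 0) = 1.0;
    mat dA = A * E * A;
    mat dSyy = dA * M * A.t() + A * M * dA.t();
    put(3, dSyy, dA * GP, Z22);
  }
  // phi11, phi22, phi12 (symmetric elementary matrices)
  const uword pi_[3] = {0, 1, 0}, pj_[3] = {0, 1, 1};
  for (uword q = 0; q < 3; ++q) {
    mat E(2, 2, fill::zeros);
    E(pi_[q], pj_[q]) = 1.0;
    E(pj_[q], pi_[q]) = 1.0;
    mat dSyy = A * Gamma * E * Gamma.t() * A.t();
    put(4 + q, dSyy, A * Gamma * E, E);
  }
  // psi11, psi22
  for (uword q = 0; q < 2; ++q) {
    mat E(2, 2, fill::zeros);
    E(q, q) = 1.0;
    put(7 + q, A * E * A.t(), Z22, Z22);
  }
}

// ML discrepancy F = log|Sigma| - log|S| + tr(S Sigma^-1) - 4 and its
// gradient over the 9 free parameters.
// [[Rcpp::export]]
Rcpp::List cpp_ml_objgrad(const arma::vec& theta, const arma::mat& S) {
  mat Sigma;
  cube dSigma;
  build_model(theta, Sigma, dSigma);

  mat cS;
  if (!chol(cS, Sigma)) {
    return Rcpp::List::create(Rcpp::Named("value") = BIG,
                              Rcpp::Named("gradient") = zeros<vec>(9));
  }
  double logdetSigma = 2.0 * accu(log(cS.diag()));
  double logdetS;
  double sign;
  log_det(logdetS, sign, S);
  if (sign <= 0) Rcpp::stop("sample matrix not positive definite");
  mat Sigmainv = inv_sympd(Sigma);
  double F = logdetSigma - logdetS + accu(S % Sigmainv) - 4.0;

  mat W = Sigmainv - Sigmainv * S * Sigmainv;
  vec grad(9);
  for (uword q = 0; q < 9; ++q) grad(q) = accu(W % dSigma.slice(q));
  return Rcpp::List::create(Rcpp::Named("value") = F,
                            Rcpp::Named("gradient") = grad);
}

// Implied correlation vector rho(theta5) of the standardized model
// (phi11 = phi22 = 1, psi solved for unit variances) and its 6x5
// Jacobian.  ok = false flags an inadmissible theta (psi <= 0).
// [[Rcpp::export]]
Rcpp::List cpp_rho_jac(const arma::vec& theta5) {
  double g11 = theta5(0), g12 = theta5(1), g21 = theta5(2),
         b21 = theta5(3), p12 = theta5(4);
  double psi1 = 1.0 - (g11 * g11 + 2.0 * g11 * g12 * p12 + g12 * g12);
  double u1 = g11 * b21 + g21, u2 = g12 * b21;
  double psi2 = 1.0 - (u1 * u1 + 2.0 * u1 * u2 * p12 + u2 * u2)
                - b21 * b21 * psi1;
  if (psi1 <= 0.0 || psi2 <= 0.0) {
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  }
  // dpsi/dtheta (2x5)
  double v1 = u1 + p12 * u2, v2 = p12 * u1 + u2;
  rowvec dpsi1 = { -2.0 * (g11 + g12 * p12), -2.0 * (g12 + g11 * p12),
                   0.0, 0.0, -2.0 * g11 * g12 };
  rowvec dpsi2 = { -2.0 * v1 * b21 - b21 * b21 * dpsi1(0),
                   -2.0 * v2 * b21 - b21 * b21 * dpsi1(1),
                   -2.0 * v1,
                   -2.0 * (v1 * g11 + v2 * g12) - 2.0 * b21 * psi1,
                   -2.0 * u1 * u2 - b21 * b21 * dpsi1(4) };

  vec th9 = { g11, g12, g21, b21, 1.0, 1.0, p12, psi1, psi2 };
  mat Sigma;
  cube dSigma;
  build_model(th9, Sigma, dSigma);

  vec rho(6);
  mat J(6, 5);
  for (uword m = 0; m < 6; ++m) {
    rho(m) = Sigma(PAIR_I[m], PAIR_J[m]);
    for (uword q = 0; q < 5; ++q) {
      uword q9 = (q < 4) ? q : 6;  // map theta5 index into theta9 slot
      double val = dSigma(PAIR_I[m], PAIR_J[m], q9)
                 + dSigma(PAIR_I[m], PAIR_J[m], 7) * dpsi1(q)
                 + dSigma(PAIR_I[m], PAIR_J[m], 8) * dpsi2(q);
      J(m, q) = val;
    }
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("rho") = rho,
                            Rcpp::Named("J") = J,
                            Rcpp::Named("psi") = vec({psi1, psi2}),
                            Rcpp::Named("dpsi") = join_vert(dpsi1, dpsi2));
}

// WLS discrepancy F = (r - rho(theta))' W (r - rho(theta)) with analytic
// gradient -2 J' W e; BIG outside the admissible region.
// [[Rcpp::export]]
Rcpp::List cpp_wls_objgrad(const arma::vec& theta5, const arma::vec& r,
                           const arma::mat& W) {
  Rcpp::List rj = cpp_rho_jac(theta5);
  if (!Rcpp::as<bool>(rj["ok"])) {
    return Rcpp::List::create(Rcpp::Named("value") = BIG,
                              Rcpp::Named("gradient") = zeros<vec>(5));
  }
  vec rho = rj["rho"];
  mat J = rj["J"];
  vec e = r - rho;
  vec We = W * e;
  double F = dot(e, We);
  vec grad = -2.0 * J.t() * We;
  return Rcpp::List::create(Rcpp::Named("value") = F,
                            Rcpp::Named("gradient") = grad);
}
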