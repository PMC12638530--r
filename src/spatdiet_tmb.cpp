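// Spatiotemporal GLMM with SPDE Matern GMRFs, Poisson-link delta-gamma /
// Tweedie / Gaussian observation families, breakpoint (hockey-stick)
// covariate effects, AR(1) or random-walk time-varying coefficients,
// month random intercepts and spatially varying coefficients.
// One or two linear predictors (component 2 is used by the delta family).
#define TMB_LIB_INIT R_init_spatdiet
#include <TMB.hpp>

template <class Type>
Eigen::SparseMatrix<Type> Q_spde(const Eigen::SparseMatrix<Type>& M0,
                                 const Eigen::SparseMatrix<Type>& M1,
                                 const Eigen::SparseMatrix<Type>& M2,
                                 Type kappa, Type tau) {
  Type k2 = kappa * kappa;
  return pow(tau, Type(2)) * (k2 * k2 * M0 + Type(2) * k2 * M1 + M2);
}

template <class Type>
Type hockey(Type x, Type b0, Type b1) {
  return b0 * CppAD::CondExpLt(x, b1, x, b1);
}

template <class Type>
Type objective_function<Type>::operator()() {
  using namespace density;

  DATA_VECTOR(y);
  DATA_INTEGER(family);  // 0 gaussian, 1 tweedie, 2 poisson-link delta-gamma
  DATA_MATRIX(X1);
  DATA_MATRIX(X2);
  DATA_MATRIX(Xbp1);
  DATA_MATRIX(Xbp2);
  DATA_MATRIX(Xtvc1);
  DATA_MATRIX(Xtvc2);
  DATA_IVECTOR(tvc_code1);  // 0 = AR1 (stationary), 1 = RW
  DATA_IVECTOR(tvc_code2);
  DATA_MATRIX(Xsvc1);
  DATA_MATRIX(Xsvc2);
  DATA_IVECTOR(year_idx);   // 0-based, into 0..n_year-1
  DATA_IVECTOR(month_idx);  // 0-based, into 0..11
  DATA_INTEGER(n_year);
  DATA_SPARSE_MATRIX(A);    // obs x mesh projector
  DATA_SPARSE_MATRIX(M0);   // lumped mass
  DATA_SPARSE_MATRIX(M1);   // stiffness
  DATA_SPARSE_MATRIX(M2);   // G C^-1 G
  DATA_INTEGER(include_omega1);
  DATA_INTEGER(include_omega2);
  DATA_INTEGER(include_epsilon1);
  DATA_INTEGER(include_epsilon2);
  DATA_INTEGER(include_month1);
  DATA_INTEGER(include_month2);

  PARAMETER_VECTOR(beta1);
  PARAMETER_VECTOR(beta2);
  PARAMETER_VECTOR(bp_b0_1);
  PARAMETER_VECTOR(bp_b1_1);
  PARAMETER_VECTOR(bp_b0_2);
  PARAMETER_VECTOR(bp_b1_2);
  PARAMETER_MATRIX(gamma1);  // n_tvc x n_year
  PARAMETER_MATRIX(gamma2);
  PARAMETER_VECTOR(tvc_log_sigma1);
  PARAMETER_VECTOR(tvc_rho_raw1);
  PARAMETER_VECTOR(tvc_log_sigma2);
  PARAMETER_VECTOR(tvc_rho_raw2);
  PARAMETER_VECTOR(alpha1);  // month random intercepts
  PARAMETER_VECTOR(alpha2);
  PARAMETER(log_sigma_alpha1);
  PARAMETER(log_sigma_alpha2);
  PARAMETER_VECTOR(omega1);
  PARAMETER_VECTOR(omega2);
  PARAMETER_MATRIX(epsilon1);  // n_mesh x n_year
  PARAMETER_MATRIX(epsilon2);
  PARAMETER_MATRIX(zeta1);  // n_mesh x n_svc
  PARAMETER_MATRIX(zeta2);
  PARAMETER(log_kappa1);  // shared decorrelation scale within component
  PARAMETER(log_kappa2);
  PARAMETER(log_tau_omega1);
  PARAMETER(log_tau_omega2);
  PARAMETER(log_tau_epsilon1);
  PARAMETER(log_tau_epsilon2);
  PARAMETER_VECTOR(log_tau_zeta1);
  PARAMETER_VECTOR(log_tau_zeta2);
  PARAMETER(log_phi);     // gaussian SD / tweedie dispersion / gamma shape
  PARAMETER(power_raw);   // tweedie power = 1 + invlogit(power_raw)

  int n = y.size();
  Type nll = 0;

  // ---------- linear predictor, component 1 ----------
  vector<Type> eta1 = X1 * beta1;
  for (int k = 0; k < Xbp1.cols(); k++)
    for (int i = 0; i < n; i++)
      eta1(i) += hockey(Type(Xbp1(i, k)), bp_b0_1(k), bp_b1_1(k));
  for (int g = 0; g < gamma1.rows(); g++) {
    Type sg = exp(tvc_log_sigma1(g));
    if (tvc_code1(g) == 0) {
      Type rho = Type(2) / (Type(1) + exp(-tvc_rho_raw1(g))) - Type(1);
      nll -= dnorm(gamma1(g, 0), Type(0), sg, true);
      for (int t = 1; t < n_year; t++)
        nll -= dnorm(gamma1(g, t), rho * gamma1(g, t - 1),
                     sg * sqrt(Type(1) - rho * rho), true);
    } else {
      nll -= dnorm(gamma1(g, 0), Type(0), sg, true);
      for (int t = 1; t < n_year; t++)
        nll -= dnorm(gamma1(g, t), gamma1(g, t - 1), sg, true);
    }
    for (int i = 0; i < n; i++)
      eta1(i) += Xtvc1(i, g) * gamma1(g, year_idx(i));
  }
  if (include_month1) {
    Type sa = exp(log_sigma_alpha1);
    for (int m = 0; m < alpha1.size(); m++)
      nll -= dnorm(alpha1(m), Type(0), sa, true);
    for (int i = 0; i < n; i++) eta1(i) += alpha1(month_idx(i));
  }
  Type kappa1 = exp(log_kappa1);
  if (include_omega1) {
    nll += GMRF(Q_spde(M0, M1, M2, kappa1, exp(log_tau_omega1)))(omega1);
    vector<Type> Ao = (A * omega1.matrix()).array();
    eta1 += Ao;
  }
  if (include_epsilon1) {
    GMRF_t<Type> gmrf_e(Q_spde(M0, M1, M2, kappa1, exp(log_tau_epsilon1)));
    matrix<Type> Aeps = A * epsilon1;
    for (int t = 0; t < n_year; t++) {
      vector<Type> et = epsilon1.col(t);
      nll += gmrf_e(et);
    }
    for (int i = 0; i < n; i++) eta1(i) += Aeps(i, year_idx(i));
  }
  for (int k = 0; k < zeta1.cols(); k++) {
    nll += GMRF(Q_spde(M0, M1, M2, kappa1, exp(log_tau_zeta1(k))))(
        vector<Type>(zeta1.col(k)));
    vector<Type> Az = (A * zeta1.col(k)).array();
    for (int i = 0; i < n; i++) eta1(i) += Xsvc1(i, k) * Az(i);
  }

  // ---------- linear predictor, component 2 (delta models) ----------
  vector<Type> eta2(n);
  eta2.setZero();
  if (X2.cols() > 0) eta2 += vector<Type>(X2 * beta2);
  for (int k = 0; k < Xbp2.cols(); k++)
    for (int i = 0; i < n; i++)
      eta2(i) += hockey(Type(Xbp2(i, k)), bp_b0_2(k), bp_b1_2(k));
  for (int g = 0; g < gamma2.rows(); g++) {
    Type sg = exp(tvc_log_sigma2(g));
    if (tvc_code2(g) == 0) {
      Type rho = Type(2) / (Type(1) + exp(-tvc_rho_raw2(g))) - Type(1);
      nll -= dnorm(gamma2(g, 0), Type(0), sg, true);
      for (int t = 1; t < n_year; t++)
        nll -= dnorm(gamma2(g, t), rho * gamma2(g, t - 1),
                     sg * sqrt(Type(1) - rho * rho), true);
    } else {
      nll -= dnorm(gamma2(g, 0), Type(0), sg, true);
      for (int t = 1; t < n_year; t++)
        nll -= dnorm(gamma2(g, t), gamma2(g, t - 1), sg, true);
    }
    for (int i = 0; i < n; i++)
      eta2(i) += Xtvc2(i, g) * gamma2(g, year_idx(i));
  }
  if (include_month2) {
    Type sa = exp(log_sigma_alpha2);
    for (int m = 0; m < alpha2.size(); m++)
      nll -= dnorm(alpha2(m), Type(0), sa, true);
    for (int i = 0; i < n; i++) eta2(i) += alpha2(month_idx(i));
  }
  Type kappa2 = exp(log_kappa2);
  if (include_omega2) {
    nll += GMRF(Q_spde(M0, M1, M2, kappa2, exp(log_tau_omega2)))(omega2);
    vector<Type> Ao = (A * omega2.matrix()).array();
    eta2 += Ao;
  }
  if (include_epsilon2) {
    GMRF_t<Type> gmrf_e(Q_spde(M0, M1, M2, kappa2, exp(log_tau_epsilon2)));
    matrix<Type> Aeps = A * epsilon2;
    for (int t = 0; t < n_year; t++) {
      vector<Type> et = epsilon2.col(t);
      nll += gmrf_e(et);
    }
    for (int i = 0; i < n; i++) eta2(i) += Aeps(i, year_idx(i));
  }
  for (int k = 0; k < zeta2.cols(); k++) {
    nll += GMRF(Q_spde(M0, M1, M2, kappa2, exp(log_tau_zeta2(k))))(
        vector<Type>(zeta2.col(k)));
    vector<Type> Az = (A * zeta2.col(k)).array();
    for (int i = 0; i < n; i++) eta2(i) += Xsvc2(i, k) * Az(i);
  }

  // ---------- observation likelihood ----------
  Type phi = exp(log_phi);
  vector<Type> mu(n);
  if (family == 0) {
    mu = eta1;
    for (int i = 0; i < n; i++) nll -= dnorm(y(i), eta1(i), phi, true);
  } else if (family == 1) {
    Type power = Type(1) + invlogit(power_raw);
    for (int i = 0; i < n; i++) {
      mu(i) = exp(eta1(i));
      nll -= dtweedie(y(i), mu(i), phi, power, true);
    }
  } else {
    // Poisson link: n = exp(eta1) group density, w = exp(eta2) mass per
    // group; p = 1 - exp(-n), positive-part mean r = n w / p.
    for (int i = 0; i < n; i++) {
      Type nd = exp(eta1(i));
      mu(i) = exp(eta1(i) + eta2(i));  // p * r
      if (y(i) > Type(0)) {
        Type logp = logspace_sub(Type(0), -nd);
        Type r = nd * exp(eta2(i)) / (Type(1) - exp(-nd));
        nll -= logp + dgamma(y(i), phi, r / phi, true);
      } else {
        nll -= -nd;  // log(1 - p) = -n exactly
      }
    }
  }

  REPORT(eta1);
  REPORT(eta2);
  REPORT(mu);
  return nll;
}
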