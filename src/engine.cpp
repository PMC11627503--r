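#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigm(double a) { return 1.0 / (1.0 + std::exp(-a)); }

// Attribute-layer outputs for one trial.
// u: length n_u vector of (already normalized, gain-scaled) attribute inputs.
// attr_mu, attr_sigma: n_u x n_x threshold/slope matrices.
// Returns the flattened n_u*n_x vector in attribute-major order
// (index = (i-1)*n_x + j, matching C's row order on the R side).
static vec attribute_outputs(const rowvec& u, const mat& attr_mu,
                             const mat& attr_sigma) {
  const uword n_u = attr_mu.n_rows, n_x = attr_mu.n_cols;
  vec x(n_u * n_x);
  for (uword i = 0; i < n_u; ++i)
    for (uword j = 0; j < n_x; ++j)
      x(i * n_x + j) = sigm((u(i) - attr_mu(i, j)) / attr_sigma(i, j));
  return x;
}

// Run the two-layer value-synthesis network over a trial series, with the
// anti-Hebbian infomax plasticity recursion
//   dC_t = alpha*(1-beta)*dC_{t-1} + alpha*beta*(1-2z)/sigma_z * x
// applied after each trial's forward pass (alpha = 0 or beta = 0 => static).
// U: n_t x n_u matrix of normalized inputs. C: (n_u*n_x) x n_z.
// [[Rcpp::export]]
Rcpp::List ann_run_cpp(const arma::mat& attr_mu, const arma::mat& attr_sigma,
                       const arma::vec& int_mu, const arma::vec& int_sigma,
                       const arma::mat& C0, const arma::vec& w, double bias,
                       const arma::mat& U, double alpha, double beta,
                       bool keep_activity) {
  const uword n_t = U.n_rows, n_z = C0.n_cols, n_in = C0.n_rows;
  mat C = C0;
  mat dC(n_in, n_z, fill::zeros);
  vec V(n_t);
  vec delta_norm(n_t, fill::zeros);
  mat Z, Vin, X;
  if (keep_activity) {
    Z.set_size(n_z, n_t);
    Vin.set_size(n_z, n_t);
    X.set_size(n_in, n_t);
  }
  const bool plastic = (alpha > 0.0) && (beta > 0.0);
  const double a1 = alpha * (1.0 - beta), a2 = alpha * beta;
  vec z(n_z), v(n_z);
  for (uword t = 0; t < n_t; ++t) {
    vec x = attribute_outputs(U.row(t), attr_mu, attr_sigma);
    v = C.t() * x;
    for (uword k = 0; k < n_z; ++k)
      z(k) = sigm((v(k) - int_mu(k)) / int_sigma(k));
    V(t) = dot(w, z);
    if (keep_activity) {
      Z.col(t) = z;
      Vin.col(t) = v;
      X.col(t) = x;
    }
    if (plastic) {
      vec g_col = (1.0 - 2.0 * z) / int_sigma;  // per-unit factor
      dC = a1 * dC + a2 * (x * g_col.t());
      C += dC;
      delta_norm(t) = accu(abs(dC)) / (double)(n_in * n_z);
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("V") = V, Rcpp::Named("C") = C,
      Rcpp::Named("delta_norm") = delta_norm,
      Rcpp::Named("p") = 1.0 / (1.0 + exp(-(bias + V))));
  if (keep_activity) {
    out["Z"] = Z;
    out["v"] = Vin;
    out["X"] = X;
  }
  return out;
}

// Negative log-likelihood of a 0/1 choice series under the sequential model,
// skipping missing responses (coded as any value < 0). Much cheaper than
// ann_run_cpp inside an optimizer: no trajectory is stored.
// [[Rcpp::export]]
double ann_nll_cpp(const arma::mat& attr_mu, const arma::mat& attr_sigma,
                   const arma::vec& int_mu, const arma::vec& int_sigma,
                   const arma::mat& C0, const arma::vec& w, double bias,
                   const arma::mat& U, double alpha, double beta,
                   const arma::vec& choice) {
  const uword n_t = U.n_rows, n_z = C0.n_cols, n_in = C0.n_rows;
  mat C = C0;
  mat dC(n_in, n_z, fill::zeros);
  const bool plastic = (alpha > 0.0) && (beta > 0.0);
  const double a1 = alpha * (1.0 - beta), a2 = alpha * beta;
  double nll = 0.0;
  vec z(n_z), v(n_z);
  for (uword t = 0; t < n_t; ++t) {
    vec x = attribute_outputs(U.row(t), attr_mu, attr_sigma);
    v = C.t() * x;
    for (uword k = 0; k < n_z; ++k)
      z(k) = sigm((v(k) - int_mu(k)) / int_sigma(k));
    double eta = bias + dot(w, z);
    if (choice(t) >= 0.0) {
      // log(1+exp(.)) in a numerically safe form
      double lse = eta > 0 ? eta + std::log1p(std::exp(-eta))
                           : std::log1p(std::exp(eta));
      nll += lse - choice(t) * eta;
    }
    if (plastic) {
      vec g_col = (1.0 - 2.0 * z) / int_sigma;
      dC = a1 * dC + a2 * (x * g_col.t());
      C += dC;
    }
  }
  return nll;
}
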