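// Generative weight-transformation network: two ReLU hidden layers with
// dropout and a double-softmax head, trained by analytic backpropagation of
// the kernel MMD objective plus balance/dispersion regularizers.
//
// All stochastic inputs (parameter initialisation, Dirichlet draws, dropout
// masks, batch indices) are generated on the R side with R's RNG and passed
// in, so the C++ layer is a deterministic function of its arguments; single
// precision is used for the dense algebra (GEMM-bound).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

struct QrerNet {
  int N, N1, N0, H;
  fmat A1, A2, C1, C0;     // layer weights
  frowvec b1, b2, c1, c0;  // biases
  // Adam state for theta (shared step counter)
  fmat mA1, vA1, mA2, vA2, mC1, vC1, mC0, vC0;
  frowvec mb1, vb1, mb2, vb2, mc1, vc1, mc0, vc0;
  long t_adam;
  double lr, beta1, beta2, eps;
  // kernel bandwidth, optimized on the log scale by gradient ascent
  double log_gamma, mg, vg, lr_gamma;
  long t_gamma;
};

static fmat as_f(Rcpp::NumericMatrix m) {
  mat d(m.begin(), m.nrow(), m.ncol(), false, true);
  return conv_to<fmat>::from(d);
}

static Rcpp::NumericMatrix as_r(const fmat& m) {
  mat d = conv_to<mat>::from(m);
  return Rcpp::wrap(d);
}

// [[Rcpp::export]]
SEXP net_create(int N1, int N0, Rcpp::List params,
                double lr, double lr_gamma, double log_gamma_init) {
  QrerNet* net = new QrerNet();
  net->N1 = N1; net->N0 = N0; net->N = N1 + N0;
  net->A1 = as_f(params["A1"]);
  net->A2 = as_f(params["A2"]);
  net->C1 = as_f(params["C1"]);
  net->C0 = as_f(params["C0"]);
  net->b1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["b1"]));
  net->b2 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["b2"]));
  net->c1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["c1"]));
  net->c0 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["c0"]));
  net->H = net->A1.n_cols;
  net->lr = lr; net->beta1 = 0.9; net->beta2 = 0.999; net->eps = 1e-8;
  net->lr_gamma = lr_gamma;
  net->log_gamma = log_gamma_init;
  net->mg = 0.0; net->vg = 0.0; net->t_gamma = 0;
  net->t_adam = 0;
  net->mA1.zeros(size(net->A1)); net->vA1.zeros(size(net->A1));
  net->mA2.zeros(size(net->A2)); net->vA2.zeros(size(net->A2));
  net->mC1.zeros(size(net->C1)); net->vC1.zeros(size(net->C1));
  net->mC0.zeros(size(net->C0)); net->vC0.zeros(size(net->C0));
  net->mb1.zeros(size(net->b1)); net->vb1.zeros(size(net->b1));
  net->mb2.zeros(size(net->b2)); net->vb2.zeros(size(net->b2));
  net->mc1.zeros(size(net->c1)); net->vc1.zeros(size(net->c1));
  net->mc0.zeros(size(net->c0)); net->vc0.zeros(size(net->c0));
  Rcpp::XPtr<QrerNet> ptr(net, true);
  return ptr;
}

static void softmax_rows(fmat& Z) {
  fvec mx = max(Z, 1);
  Z.each_col() -= mx;
  Z = exp(Z);
  fvec s = sum(Z, 1);
  Z.each_col() /= s;
}

struct Forward {
  fmat Z1, H1d, Z2, H2d, S1, S0;
};

// M1, M2: dropout masks (already scaled by 1/keep), or empty for inference
static void forward_pass(const QrerNet& net, const fmat& W,
                         const fmat& M1, const fmat& M2, Forward& f) {
  f.Z1 = W * net.A1;
  f.Z1.each_row() += net.b1;
  f.H1d = clamp(f.Z1, 0.0f, fdatum::inf);
  if (M1.n_elem > 0) f.H1d %= M1;
  f.Z2 = f.H1d * net.A2;
  f.Z2.each_row() += net.b2;
  f.H2d = clamp(f.Z2, 0.0f, fdatum::inf);
  if (M2.n_elem > 0) f.H2d %= M2;
  f.S1 = f.H2d * net.C1;
  f.S1.each_row() += net.c1;
  softmax_rows(f.S1);
  f.S0 = f.H2d * net.C0;
  f.S0.each_row() += net.c0;
  softmax_rows(f.S0);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix net_forward(SEXP ptr_, Rcpp::NumericMatrix W,
                                Rcpp::Nullable<Rcpp::NumericMatrix> M1_ = R_NilValue,
                                Rcpp::Nullable<Rcpp::NumericMatrix> M2_ = R_NilValue) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  fmat Wf = as_f(W);
  fmat M1, M2;
  if (M1_.isNotNull()) M1 = as_f(Rcpp::NumericMatrix(M1_));
  if (M2_.isNotNull()) M2 = as_f(Rcpp::NumericMatrix(M2_));
  Forward f;
  forward_pass(*ptr, Wf, M1, M2, f);
  return as_r(join_rows(f.S1, f.S0));
}

static void adam_update(fmat& p, fmat& m, fmat& v, const fmat& g,
                        double lr, double b1c, double b2c,
                        double beta1, double beta2, double eps) {
  m = (float)beta1 * m + (float)(1.0 - beta1) * g;
  v = (float)beta2 * v + (float)(1.0 - beta2) * square(g);
  p -= (float)lr * (m / (float)b1c) / (sqrt(v / (float)b2c) + (float)eps);
}

static void adam_update_row(frowvec& p, frowvec& m, frowvec& v, const frowvec& g,
                            double lr, double b1c, double b2c,
                            double beta1, double beta2, double eps) {
  m = (float)beta1 * m + (float)(1.0 - beta1) * g;
  v = (float)beta2 * v + (float)(1.0 - beta2) * square(g);
  p -= (float)lr * (m / (float)b1c) / (sqrt(v / (float)b2c) + (float)eps);
}

// Backpropagate from head gradients (w.r.t. the softmax outputs) and apply
// one Adam step on all network parameters.
static void backward_and_step(QrerNet& net, const fmat& W, const fmat& M1,
                              const fmat& M2, const Forward& f,
                              const fmat& G1, const fmat& G0) {
  // softmax Jacobian, rowwise: dZ = S % (G - rowsum(G % S))
  fvec r1 = sum(G1 % f.S1, 1);
  fmat dZh1 = G1;
  dZh1.each_col() -= r1;
  dZh1 %= f.S1;
  fvec r0 = sum(G0 % f.S0, 1);
  fmat dZh0 = G0;
  dZh0.each_col() -= r0;
  dZh0 %= f.S0;

  fmat gC1 = f.H2d.t() * dZh1;
  frowvec gc1 = sum(dZh1, 0);
  fmat gC0 = f.H2d.t() * dZh0;
  frowvec gc0 = sum(dZh0, 0);

  fmat dH2d = dZh1 * net.C1.t() + dZh0 * net.C0.t();
  if (M2.n_elem > 0) dH2d %= M2;
  fmat dZ2 = dH2d % conv_to<fmat>::from(f.Z2 > 0.0f);
  fmat gA2 = f.H1d.t() * dZ2;
  frowvec gb2 = sum(dZ2, 0);

  fmat dH1d = dZ2 * net.A2.t();
  if (M1.n_elem > 0) dH1d %= M1;
  fmat dZ1 = dH1d % conv_to<fmat>::from(f.Z1 > 0.0f);
  fmat gA1 = W.t() * dZ1;
  frowvec gb1 = sum(dZ1, 0);

  net.t_adam += 1;
  double b1c = 1.0 - std::pow(net.beta1, (double)net.t_adam);
  double b2c = 1.0 - std::pow(net.beta2, (double)net.t_adam);
  adam_update(net.A1, net.mA1, net.vA1, gA1, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update(net.A2, net.mA2, net.vA2, gA2, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update(net.C1, net.mC1, net.vC1, gC1, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update(net.C0, net.mC0, net.vC0, gC0, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update_row(net.b1, net.mb1, net.vb1, gb1, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update_row(net.b2, net.mb2, net.vb2, gb2, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update_row(net.c1, net.mc1, net.vc1, gc1, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
  adam_update_row(net.c0, net.mc0, net.vc0, gc0, net.lr, b1c, b2c, net.beta1, net.beta2, net.eps);
}

// One identity-initialization step: MSE between log input and log output
// weights, averaged over the batch.
// [[Rcpp::export]]
double net_init_step(SEXP ptr_, Rcpp::NumericMatrix W,
                     Rcpp::NumericMatrix M1_, Rcpp::NumericMatrix M2_) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  QrerNet& net = *ptr;
  fmat Wf = as_f(W);
  fmat M1 = as_f(M1_), M2 = as_f(M2_);
  Forward f;
  forward_pass(net, Wf, M1, M2, f);
  int B = Wf.n_rows;
  const float floor_w = 1e-12f;

  fmat W1in = Wf.cols(0, net.N1 - 1);
  fmat W0in = Wf.cols(net.N1, net.N - 1);
  fmat S1 = clamp(f.S1, floor_w, fdatum::inf);
  fmat S0 = clamp(f.S0, floor_w, fdatum::inf);
  fmat D1 = log(S1) - log(clamp(W1in, floor_w, fdatum::inf));
  fmat D0 = log(S0) - log(clamp(W0in, floor_w, fdatum::inf));
  double loss = ((double)accu(square(D1)) + (double)accu(square(D0))) / B;

  fmat G1 = (2.0f / B) * (D1 / S1);
  fmat G0 = (2.0f / B) * (D0 / S0);
  backward_and_step(net, Wf, M1, M2, f, G1, G0);
  return loss;
}

// accumulate in double: the MMD value is a small difference of three large
// kernel sums, which float accumulation cannot resolve reliably
static double accu_d(const fmat& A) {
  double s = 0.0;
  for (uword i = 0; i < A.n_elem; ++i) s += (double)A[i];
  return s;
}

static fmat pdist2(const fmat& A, const fmat& Bm) {
  fvec an = sum(square(A), 1), bn = sum(square(Bm), 1);
  fmat D = -2.0f * A * Bm.t();
  D.each_col() += an;
  D.each_row() += bn.t();
  return clamp(D, 0.0f, fdatum::inf);
}

// One full training step: forward with dropout, MMD + lambda1*R1 + lambda2*R2,
// Adam step on theta, then one Adam ascent step on log(gamma) using the
// pairwise distances of the same batch.
// [[Rcpp::export]]
Rcpp::NumericVector net_train_step(SEXP ptr_, Rcpp::NumericMatrix W,
                                   Rcpp::NumericMatrix M1_, Rcpp::NumericMatrix M2_,
                                   Rcpp::NumericMatrix deltaT_,
                                   Rcpp::NumericMatrix X1_, Rcpp::NumericMatrix X0_,
                                   Rcpp::NumericVector xbar_,
                                   double lambda1, double lambda2,
                                   bool update_gamma = true) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  QrerNet& net = *ptr;
  fmat Wf = as_f(W);
  fmat M1 = as_f(M1_), M2 = as_f(M2_);
  fmat dT = as_f(deltaT_);
  fmat X1 = as_f(X1_), X0 = as_f(X0_);
  frowvec xbar = conv_to<frowvec>::from(Rcpp::as<rowvec>(xbar_));
  int B = Wf.n_rows;
  float gamma = (float)std::exp(net.log_gamma);

  Forward f;
  forward_pass(net, Wf, M1, M2, f);

  // weighted covariate mean differences, one row per batch element
  fmat Dlt = f.S1 * X1 - f.S0 * X0;

  fmat D2ww = pdist2(Dlt, Dlt);
  fmat D2tt = pdist2(dT, dT);
  fmat D2wt = pdist2(Dlt, dT);
  fmat Kww = exp(-gamma * D2ww);
  fmat Ktt = exp(-gamma * D2tt);
  fmat Kwt = exp(-gamma * D2wt);
  double B2 = (double)B * (double)B;
  double V = (accu_d(Kww) + accu_d(Ktt) - 2.0 * accu_d(Kwt)) / B2;
  double Lmmd = std::sqrt(std::max(V, 0.0));

  // d L_MMD / d Dlt
  fmat Gdlt(B, Dlt.n_cols, fill::zeros);
  if (Lmmd > 1e-12) {
    fvec sw = sum(Kww, 1), uw = sum(Kwt, 1);
    fmat t1 = Dlt;
    t1.each_col() %= sw;
    t1 -= Kww * Dlt;                             // sum_j Kww_aj (d_a - d_j)
    fmat t2 = Dlt;
    t2.each_col() %= uw;
    t2 -= Kwt * dT;                              // sum_j Kwt_aj (d_a - t_j)
    fmat gradV = (-4.0f * gamma / (float)B2) * t1 + (4.0f * gamma / (float)B2) * t2;
    Gdlt = gradV / (float)(2.0 * Lmmd);
  }

  // R1: squared deviation of each weighted arm mean from the pooled mean
  fmat Mt1 = f.S1 * X1;
  Mt1.each_row() -= xbar;
  fmat Mt0 = f.S0 * X0;
  Mt0.each_row() -= xbar;
  double r1val = ((double)accu(square(Mt1)) + (double)accu(square(Mt0))) / B;

  // R2: squared deviation of the weights from uniform
  fmat U1 = f.S1 - 1.0f / net.N1;
  fmat U0 = f.S0 - 1.0f / net.N0;
  double r2val = ((double)accu(square(U1)) + (double)accu(square(U0))) / B;

  fmat G1 = Gdlt * X1.t()
    + (float)(2.0 * lambda1 / B) * (Mt1 * X1.t())
    + (float)(2.0 * lambda2 / B) * U1;
  fmat G0 = -Gdlt * X0.t()
    + (float)(2.0 * lambda1 / B) * (Mt0 * X0.t())
    + (float)(2.0 * lambda2 / B) * U0;

  backward_and_step(net, Wf, M1, M2, f, G1, G0);

  // gradient-ascent step on log(gamma), holding theta's batch fixed
  if (update_gamma && Lmmd > 1e-12) {
    double dVdg = (-accu_d(D2ww % Kww) - accu_d(D2tt % Ktt)
                   + 2.0 * accu_d(D2wt % Kwt)) / B2;
    double g = std::exp(net.log_gamma) * dVdg / (2.0 * Lmmd);  // d L / d log gamma
    if (std::isfinite(g)) {
      net.t_gamma += 1;
      net.mg = net.beta1 * net.mg + (1.0 - net.beta1) * g;
      net.vg = net.beta2 * net.vg + (1.0 - net.beta2) * g * g;
      double mh = net.mg / (1.0 - std::pow(net.beta1, (double)net.t_gamma));
      double vh = net.vg / (1.0 - std::pow(net.beta2, (double)net.t_gamma));
      net.log_gamma += net.lr_gamma * mh / (std::sqrt(vh) + net.eps);
    }
  }

  return Rcpp::NumericVector::create(Lmmd, r1val, r2val, std::exp(net.log_gamma));
}

// [[Rcpp::export]]
Rcpp::List net_get_params(SEXP ptr_) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  return Rcpp::List::create(
    Rcpp::Named("A1") = as_r(ptr->A1), Rcpp::Named("b1") = Rcpp::wrap(conv_to<rowvec>::from(ptr->b1)),
    Rcpp::Named("A2") = as_r(ptr->A2), Rcpp::Named("b2") = Rcpp::wrap(conv_to<rowvec>::from(ptr->b2)),
    Rcpp::Named("C1") = as_r(ptr->C1), Rcpp::Named("c1") = Rcpp::wrap(conv_to<rowvec>::from(ptr->c1)),
    Rcpp::Named("C0") = as_r(ptr->C0), Rcpp::Named("c0") = Rcpp::wrap(conv_to<rowvec>::from(ptr->c0)));
}

// [[Rcpp::export]]
void net_set_params(SEXP ptr_, Rcpp::List params) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  ptr->A1 = as_f(params["A1"]);
  ptr->A2 = as_f(params["A2"]);
  ptr->C1 = as_f(params["C1"]);
  ptr->C0 = as_f(params["C0"]);
  ptr->b1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["b1"]));
  ptr->b2 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["b2"]));
  ptr->c1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["c1"]));
  ptr->c0 = conv_to<frowvec>::from(Rcpp::as<rowvec>(params["c0"]));
}

// [[Rcpp::export]]
double net_get_log_gamma(SEXP ptr_) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  return ptr->log_gamma;
}

// [[Rcpp::export]]
void net_set_log_gamma(SEXP ptr_, double lg) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  ptr->log_gamma = lg;
}

// Fresh optimizer state between the initialization and training phases
// (the two phases minimize different objectives).
// [[Rcpp::export]]
void net_reset_adam(SEXP ptr_) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  ptr->t_adam = 0;
  ptr->mA1.zeros(); ptr->vA1.zeros(); ptr->mA2.zeros(); ptr->vA2.zeros();
  ptr->mC1.zeros(); ptr->vC1.zeros(); ptr->mC0.zeros(); ptr->vC0.zeros();
  ptr->mb1.zeros(); ptr->vb1.zeros(); ptr->mb2.zeros(); ptr->vb2.zeros();
  ptr->mc1.zeros(); ptr->vc1.zeros(); ptr->mc0.zeros(); ptr->vc0.zeros();
  ptr->t_gamma = 0; ptr->mg = 0.0; ptr->vg = 0.0;
}

// [[Rcpp::export]]
int net_param_count(SEXP ptr_) {
  Rcpp::XPtr<QrerNet> ptr(ptr_);
  return ptr->A1.n_elem + ptr->b1.n_elem + ptr->A2.n_elem + ptr->b2.n_elem +
    ptr->C1.n_elem + ptr->c1.n_elem + ptr->C0.n_elem + ptr->c0.n_elem;
}
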