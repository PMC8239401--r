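#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::umat;
using arma::vec;

// Unrolls a length-preserving ("same", stride 1) 1-d convolution into a
// matrix product: X is (l x C), cols becomes (l x k*C) with column block
// j holding X shifted by (j - pad) rows and zero outside the sequence.
// Filter sizes are odd so the zero padding is symmetric.
static void im2col(const mat& X, int k, mat& cols) {
  const int l = X.n_rows, C = X.n_cols, pad = (k - 1) / 2;
  cols.zeros(l, k * C);
  for (int j = 0; j < k; ++j) {
    const int shift = j - pad;  // input row = output row + shift
    const int out_lo = std::max(0, -shift);
    const int out_hi = std::min(l - 1, l - 1 - shift);
    if (out_lo > out_hi) continue;
    cols.submat(out_lo, j * C, out_hi, j * C + C - 1) =
        X.rows(out_lo + shift, out_hi + shift);
  }
}

// Adjoint of im2col: scatter-adds column-block gradients back onto rows.
static void col2im(const mat& dcols, int k, mat& dX) {
  const int l = dX.n_rows, C = dX.n_cols, pad = (k - 1) / 2;
  dX.zeros();
  for (int j = 0; j < k; ++j) {
    const int shift = j - pad;
    const int out_lo = std::max(0, -shift);
    const int out_hi = std::min(l - 1, l - 1 - shift);
    if (out_lo > out_hi) continue;
    dX.rows(out_lo + shift, out_hi + shift) +=
        dcols.submat(out_lo, j * C, out_hi, j * C + C - 1);
  }
}

// Max pooling with stride equal to the window; first maximum wins on ties.
static void maxpool(const mat& A, int p, mat& P, umat& idx) {
  const int lo = A.n_rows / p, F = A.n_cols;
  P.set_size(lo, F);
  idx.set_size(lo, F);
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < lo; ++t) {
      int best = t * p;
      double bv = A(best, f);
      for (int i = t * p + 1; i < (t + 1) * p; ++i) {
        if (A(i, f) > bv) {
          bv = A(i, f);
          best = i;
        }
      }
      P(t, f) = bv;
      idx(t, f) = best;
    }
  }
}

// Inverted-dropout mask drawn from R's RNG stream (deterministic under
// set.seed); kept values are scaled by 1/(1-p) so inference needs no scaling.
static void fill_mask(cube& m, double p) {
  const double scale = 1.0 / (1.0 - p);
  for (arma::uword i = 0; i < m.n_elem; ++i)
    m(i) = (R::unif_rand() >= p) ? scale : 0.0;
}

// One combined forward/backward pass over a batch.
//
// X:       input cube, l x 4 x B (one-hot, or any real values for probing).
// W:       list with W1 (k1*4 x F1), b1, W2 (k2*F1 x F2), b2,
//          Wh (flat x H), bh, Wo (H x 1), bo.
// labels:  if non-null, computes the mean binary cross-entropy and the
//          parameter gradients (training mode; dropout active if dropout_p>0).
// input_grad: if true, returns d(pre-sigmoid score)/d(input) per sample
//          (saliency mode; dropout always off).
// [[Rcpp::export]]
List cnn_core(const arma::cube& X, const List& W, int k1, int p1, int k2,
              int p2, Nullable<NumericVector> labels, double dropout_p,
              bool input_grad) {
  const int l = X.n_rows, B = X.n_slices;
  const mat W1 = W["W1"];
  const rowvec b1 = as<rowvec>(W["b1"]);
  const mat W2 = W["W2"];
  const rowvec b2 = as<rowvec>(W["b2"]);
  const mat Wh = W["Wh"];
  const rowvec bh = as<rowvec>(W["bh"]);
  const mat Wo = W["Wo"];
  const double bo = as<double>(W["bo"]);
  const int F1 = W1.n_cols, F2 = W2.n_cols, H = Wh.n_cols;
  const int l1 = l / p1, l2 = l1 / p2, flat = l2 * F2;

  const bool training = labels.isNotNull();
  const bool dropout = training && dropout_p > 0.0;
  const bool backward = training || input_grad;

  // Combined ReLU x dropout masks (0 where the unit is off, 1/(1-p) or 1
  // where it passes); multiplying the pre-activation by the mask gives the
  // layer output, multiplying the upstream gradient gives the downstream one.
  cube cols1(l, k1 * 4, B), A1d(l, F1, B), M1(l, F1, B);
  cube P1(l1, F1, B), cols2(l1, k2 * F1, B), A2d(l1, F2, B), M2(l1, F2, B);
  cube P2(l2, F2, B);
  arma::ucube idx1(l1, F1, B), idx2(l2, F2, B);
  mat Flat(B, flat);

  cube dm1, dm2;
  mat dm3;
  if (dropout) {
    dm1.set_size(l, F1, B);
    dm2.set_size(l1, F2, B);
    dm3.set_size(B, H);
    fill_mask(dm1, dropout_p);
    fill_mask(dm2, dropout_p);
    for (arma::uword i = 0; i < dm3.n_elem; ++i)
      dm3(i) = (R::unif_rand() >= dropout_p) ? 1.0 / (1.0 - dropout_p) : 0.0;
  }

  for (int b = 0; b < B; ++b) {
    mat c1;
    im2col(X.slice(b), k1, c1);
    cols1.slice(b) = c1;
    mat a1 = c1 * W1;
    a1.each_row() += b1;
    mat m1 = arma::conv_to<mat>::from(a1 > 0);
    if (dropout) m1 %= dm1.slice(b);
    M1.slice(b) = m1;
    mat a1d = a1 % m1;
    A1d.slice(b) = a1d;
    mat p1m;
    umat i1;
    maxpool(a1d, p1, p1m, i1);
    P1.slice(b) = p1m;
    idx1.slice(b) = i1;

    mat c2;
    im2col(p1m, k2, c2);
    cols2.slice(b) = c2;
    mat a2 = c2 * W2;
    a2.each_row() += b2;
    mat m2 = arma::conv_to<mat>::from(a2 > 0);
    if (dropout) m2 %= dm2.slice(b);
    M2.slice(b) = m2;
    mat a2d = a2 % m2;
    A2d.slice(b) = a2d;
    mat p2m;
    umat i2;
    maxpool(a2d, p2, p2m, i2);
    P2.slice(b) = p2m;
    idx2.slice(b) = i2;
    Flat.row(b) = arma::vectorise(p2m).t();
  }

  mat Hpre = Flat * Wh;
  Hpre.each_row() += bh;
  mat Mh = arma::conv_to<mat>::from(Hpre > 0);
  if (dropout) Mh %= dm3;
  mat Hd = Hpre % Mh;
  vec score = Hd * Wo + bo;
  vec prob = 1.0 / (1.0 + arma::exp(-score));

  List out = List::create(Named("prob") = prob, Named("score") = score);
  if (!backward) return out;

  vec dO(B);
  if (training) {
    vec y = as<vec>(labels);
    vec pc = arma::clamp(prob, 1e-12, 1.0 - 1e-12);
    double loss =
        -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
    out["loss"] = loss;
    dO = (prob - y) / static_cast<double>(B);
  } else {
    dO.ones();  // d(score_b)/d(score_b): per-sample input gradients
  }

  mat dHd = dO * Wo.t();
  mat dHpre = dHd % Mh;
  mat dFlat = dHpre * Wh.t();

  mat gW1(arma::size(W1), arma::fill::zeros);
  rowvec gb1(F1, arma::fill::zeros);
  mat gW2(arma::size(W2), arma::fill::zeros);
  rowvec gb2(F2, arma::fill::zeros);
  cube dX;
  if (input_grad) dX.set_size(l, 4, B);

  for (int b = 0; b < B; ++b) {
    mat dP2 = arma::reshape(dFlat.row(b).t(), l2, F2);
    mat dA2d(l1, F2, arma::fill::zeros);
    const umat& i2 = idx2.slice(b);
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < l2; ++t) dA2d(i2(t, f), f) += dP2(t, f);
    mat dA2 = dA2d % M2.slice(b);
    gW2 += cols2.slice(b).t() * dA2;
    gb2 += arma::sum(dA2, 0);
    mat dcols2 = dA2 * W2.t();
    mat dP1(l1, F1);
    col2im(dcols2, k2, dP1);

    mat dA1d(l, F1, arma::fill::zeros);
    const umat& i1 = idx1.slice(b);
    for (int f = 0; f < F1; ++f)
      for (int t = 0; t < l1; ++t) dA1d(i1(t, f), f) += dP1(t, f);
    mat dA1 = dA1d % M1.slice(b);
    gW1 += cols1.slice(b).t() * dA1;
    gb1 += arma::sum(dA1, 0);
    if (input_grad) {
      mat dc1 = dA1 * W1.t();
      mat dx(l, 4);
      col2im(dc1, k1, dx);
      dX.slice(b) = dx;
    }
  }

  if (training) {
    out["grads"] = List::create(
        Named("W1") = gW1, Named("b1") = gb1.t(), Named("W2") = gW2,
        Named("b2") = gb2.t(), Named("Wh") = Flat.t() * dHpre,
        Named("bh") = arma::sum(dHpre, 0).t(), Named("Wo") = Hd.t() * dO,
        Named("bo") = arma::accu(dO));
  }
  if (input_grad) out["input_grad"] = dX;
  return out;
}
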