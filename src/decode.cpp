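// Per-timepoint shrinkage-LDA decoding: the hot loop of the pipeline.
// Data enter as a trials x channels x times cube; all randomness (fold
// assignment, balancing subsamples, label permutations) is drawn in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// z-score columns of train by train mean/sd; apply the same transform to
// test. Zero-variance columns get sd 1 (feature contributes nothing after
// centring).
static void zscore_pair(mat& train, mat& test) {
  rowvec mu = mean(train, 0);
  rowvec sdv = stddev(train, 0, 0); // normalisation by n-1
  sdv.elem(find(sdv < 1e-300)).fill(1.0);
  train.each_row() -= mu;
  train.each_row() /= sdv;
  test.each_row() -= mu;
  test.each_row() /= sdv;
}

// Ledoit-Wolf shrinkage intensity toward the scaled-identity target,
// computed from class-centred rows X (n x p) with S = X'X / n.
static double lw_lambda(const mat& Xc, const mat& S) {
  const double n = (double)Xc.n_rows;
  const double p = (double)Xc.n_cols;
  const double m = trace(S) / p;
  mat D = S; D.diag() -= m;
  const double d2 = accu(square(D));
  if (d2 <= 0.0) return 0.0;
  vec row_norms2 = sum(square(Xc), 1);
  double sum4 = accu(square(row_norms2));
  double b2bar = sum4 / (n * n) - accu(square(S)) / n;
  double b2 = std::min(std::max(b2bar, 0.0), d2);
  return b2 / d2;
}

// Fit two-class LDA with shrinkage on z-scored train (rows = samples),
// returning the discriminant (w, b). y1 marks class 1 (the target).
// lambda < 0 requests the analytic Ledoit-Wolf estimate.
static void lda_wb(const mat& X, const uvec& is1, double lambda,
                   vec& w, double& b) {
  uvec i1 = find(is1 == 1);
  uvec i0 = find(is1 == 0);
  rowvec mu1 = mean(X.rows(i1), 0);
  rowvec mu0 = mean(X.rows(i0), 0);
  mat Xc = X;
  for (uword j = 0; j < i1.n_elem; ++j) Xc.row(i1(j)) -= mu1;
  for (uword j = 0; j < i0.n_elem; ++j) Xc.row(i0(j)) -= mu0;
  mat S = (Xc.t() * Xc) / (double)X.n_rows; // pooled MLE covariance
  double lam = lambda < 0 ? lw_lambda(Xc, S) : lambda;
  double m = trace(S) / (double)X.n_cols;
  mat Sh = (1.0 - lam) * S;
  Sh.diag() += lam * m;
  vec d = (mu1 - mu0).t();
  bool ok = solve(w, Sh, d, solve_opts::no_approx);
  if (!ok) {
    w = pinv(Sh) * d;
  }
  b = -dot(w, 0.5 * (mu1 + mu0).t());
}

// Cross-validated decoding accuracy per timepoint.
// X: trials x channels x times; y1: 1 = target class; fold: 1..k fold id
// per trial, 0 = unused trial. Returns accuracy (mean over folds) per
// timepoint. Ties at the discriminant (score == 0) go to class 0.
//
// Implementation note: z-scoring + class means + pooled covariance are
// fused into one pass over the training rows (cross-product matrix with
// rank-1 class corrections), and the discriminant is folded back into raw
// feature space for test scoring, avoiding per-fold matrix copies. This is
// algebraically identical to z-score-then-fit.
static arma::vec decode_cv_core(const arma::cube& X, const arma::uvec& y1,
                                const arma::ivec& fold, double lambda) {
  const uword n_times = X.n_slices;
  const uword n = X.n_rows;
  const uword p = X.n_cols;
  const int k = fold.max();
  vec acc(n_times, fill::zeros);
  std::vector<uvec> tr1(k), tr0(k), te_sets(k);
  for (int f = 1; f <= k; ++f) {
    tr1[f - 1] = find(fold > 0 && fold != f && y1 == 1);
    tr0[f - 1] = find(fold > 0 && fold != f && y1 == 0);
    te_sets[f - 1] = find(fold == f);
  }
  mat M(p, p), C(p, p), Sh(p, p);
  vec sum1(p), sum0(p), mu1(p), mu0(p), mu(p), sdv(p), dmu(p), w(p), weff(p);
  for (uword t = 0; t < n_times; ++t) {
    const mat St(const_cast<double*>(X.slice_memptr(t)), n, p, false, true);
    double fold_acc_sum = 0.0;
    for (int f = 0; f < k; ++f) {
      const uvec& i1 = tr1[f];
      const uvec& i0 = tr0[f];
      const uvec& te = te_sets[f];
      const double m1 = (double)i1.n_elem, m0 = (double)i0.n_elem;
      const double m = m1 + m0;
      // single pass: per-class sums and pooled raw cross-products
      // (raw-pointer accumulation of the upper triangle; no temporaries)
      sum1.zeros(); sum0.zeros(); M.zeros();
      const double* Sm = St.memptr();
      std::vector<double> xb(p);
      for (int cls = 0; cls < 2; ++cls) {
        const uvec& rows = cls ? i0 : i1;
        vec& sums = cls ? sum0 : sum1;
        for (uword r = 0; r < rows.n_elem; ++r) {
          const uword row = rows(r);
          for (uword j = 0; j < p; ++j) xb[j] = Sm[row + j * n];
          for (uword j = 0; j < p; ++j) {
            sums(j) += xb[j];
            double* Mc = M.colptr(j);
            const double xj = xb[j];
            for (uword l = j; l < p; ++l) Mc[l] += xj * xb[l];
          }
        }
      }
      for (uword j = 0; j < p; ++j)
        for (uword l = j + 1; l < p; ++l) M(j, l) = M(l, j);
      mu1 = sum1 / m1; mu0 = sum0 / m0;
      mu = (sum1 + sum0) / m;
      // training sd per feature (n-1 denominator), zero-variance -> 1
      for (uword j = 0; j < p; ++j) {
        double v = (M(j, j) - m * mu(j) * mu(j)) / (m - 1.0);
        sdv(j) = v > 1e-300 ? std::sqrt(v) : 1.0;
      }
      // pooled class-centred covariance in z-space, MLE (divide by m)
      C = M;
      C -= m1 * (mu1 * mu1.t());
      C -= m0 * (mu0 * mu0.t());
      for (uword j = 0; j < p; ++j)
        for (uword l = 0; l < p; ++l)
          C(j, l) /= m * sdv(j) * sdv(l);
      double lam = lambda;
      if (lambda < 0) {
        // Ledoit-Wolf on the z-space class-centred rows
        const double mbar = trace(C) / (double)p;
        double d2 = accu(square(C)) - 2.0 * mbar * trace(C) +
          (double)p * mbar * mbar;
        if (d2 <= 0.0) {
          lam = 0.0;
        } else {
          double sum4 = 0.0;
          for (int cls = 0; cls < 2; ++cls) {
            const uvec& rows = cls ? i0 : i1;
            const vec& muc = cls ? mu0 : mu1;
            for (uword r = 0; r < rows.n_elem; ++r) {
              const uword row = rows(r);
              double s = 0.0;
              for (uword j = 0; j < p; ++j) {
                const double z = (Sm[row + j * n] - muc(j)) / sdv(j);
                s += z * z;
              }
              sum4 += s * s;
            }
          }
          double b2bar = sum4 / (m * m) - accu(square(C)) / m;
          double b2 = std::min(std::max(b2bar, 0.0), d2);
          lam = b2 / d2;
        }
      }
      const double mbar2 = trace(C) / (double)p;
      Sh = (1.0 - lam) * C;
      Sh.diag() += lam * mbar2;
      dmu = (mu1 - mu0) / sdv; // z-space mean difference
      if (!solve(w, Sh, dmu, solve_opts::likely_sympd + solve_opts::no_approx)) {
        w = pinv(Sh) * dmu;
      }
      // z-space bias: class means in z-space are (mu_c - mu)/sd
      double b = -0.5 * dot(w, (mu1 + mu0 - 2.0 * mu) / sdv);
      // fold back to raw features: score = weff . x + beff
      weff = w / sdv;
      const double beff = b - dot(weff, mu);
      uword correct = 0;
      for (uword r = 0; r < te.n_elem; ++r) {
        const uword row = te(r);
        double score = beff;
        for (uword j = 0; j < p; ++j) score += Sm[row + j * n] * weff(j);
        const uword pred = score > 0 ? 1u : 0u;
        if (pred == y1(row)) ++correct;
      }
      fold_acc_sum += (double)correct / (double)te.n_elem;
    }
    acc(t) = fold_acc_sum / (double)k;
  }
  return acc;
}

// [[Rcpp::export]]
arma::vec decode_cv_cpp(const arma::cube& X, const arma::uvec& y1,
                        const arma::ivec& fold, double lambda) {
  return decode_cv_core(X, y1, fold, lambda);
}

// Batched variant for permutation nulls: each column of Y1 / FOLD is one
// label permutation with its fold assignment. Returns [n_perm x n_times].
// [[Rcpp::export]]
arma::mat decode_cv_batch_cpp(const arma::cube& X, const arma::umat& Y1,
                              const arma::imat& FOLD, double lambda) {
  const uword n_perm = Y1.n_cols;
  mat out(n_perm, X.n_slices);
  for (uword i = 0; i < n_perm; ++i) {
    out.row(i) = decode_cv_core(X, Y1.col(i), FOLD.col(i), lambda).t();
  }
  return out;
}

// Cross-classification / temporal generalization.
// Xtrain: balanced train-pair trials (y1 = target indicator); Xtest:
// test-condition trials. For each train time t a classifier is fit on all
// train trials (z-scored at t). If tg is false, only the matched test time
// is scored (vector over time); if true, every test time is scored, with
// the test features standardised by the *training* statistics computed at
// the test timepoint (only the classifier crosses time, not the scaler).
// The score is the fraction of test trials classified as the target.
// [[Rcpp::export]]
arma::mat cross_decode_cpp(const arma::cube& Xtrain, const arma::uvec& y1,
                           const arma::cube& Xtest, double lambda,
                           bool tg) {
  const uword n_times = Xtrain.n_slices;
  const uword p = Xtrain.n_cols;

  // per-timepoint training stats and standardised test slices
  mat mus(n_times, p), sds(n_times, p);
  std::vector<mat> test_z(n_times);
  for (uword t = 0; t < n_times; ++t) {
    rowvec mu = mean(Xtrain.slice(t), 0);
    rowvec sdv = stddev(Xtrain.slice(t), 0, 0);
    sdv.elem(find(sdv < 1e-300)).fill(1.0);
    mus.row(t) = mu;
    sds.row(t) = sdv;
    mat Z = Xtest.slice(t);
    Z.each_row() -= mu;
    Z.each_row() /= sdv;
    test_z[t] = Z;
  }

  mat out(n_times, tg ? n_times : 1);
  for (uword t = 0; t < n_times; ++t) {
    mat Xtr = Xtrain.slice(t);
    Xtr.each_row() -= mus.row(t);
    Xtr.each_row() /= sds.row(t);
    vec w; double b;
    lda_wb(Xtr, y1, lambda, w, b);
    if (tg) {
      for (uword u = 0; u < n_times; ++u) {
        vec score = test_z[u] * w + b;
        out(t, u) = (double)accu(score > 0) / (double)score.n_elem;
      }
    } else {
      vec score = test_z[t] * w + b;
      out(t, 0) = (double)accu(score > 0) / (double)score.n_elem;
    }
  }
  return out;
}

// Plain fit on one feature matrix, exposed for the R-level lda_shrink().
// Returns w, b and the shrinkage intensity actually used.
// [[Rcpp::export]]
Rcpp::List lda_fit_cpp(const arma::mat& X, const arma::uvec& y1,
                       double lambda) {
  uvec i1 = find(y1 == 1);
  uvec i0 = find(y1 == 0);
  rowvec mu1 = mean(X.rows(i1), 0);
  rowvec mu0 = mean(X.rows(i0), 0);
  mat Xc = X;
  for (uword j = 0; j < i1.n_elem; ++j) Xc.row(i1(j)) -= mu1;
  for (uword j = 0; j < i0.n_elem; ++j) Xc.row(i0(j)) -= mu0;
  mat S = (Xc.t() * Xc) / (double)X.n_rows;
  double lam = lambda < 0 ? lw_lambda(Xc, S) : lambda;
  double m = trace(S) / (double)X.n_cols;
  mat Sh = (1.0 - lam) * S;
  Sh.diag() += lam * m;
  vec d = (mu1 - mu0).t();
  vec w;
  bool ok = solve(w, Sh, d, solve_opts::no_approx);
  if (!ok) w = pinv(Sh) * d;
  double b = -dot(w, 0.5 * (mu1 + mu0).t());
  return Rcpp::List::create(
    Rcpp::Named("w") = w, Rcpp::Named("b") = b,
    Rcpp::Named("lambda") = lam,
    Rcpp::Named("mu1") = mu1.t(), Rcpp::Named("mu0") = mu0.t(),
    Rcpp::Named("cov") = S, Rcpp::Named("cov_shrunk") = Sh);
}
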