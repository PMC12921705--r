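#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;

// Batched per-dimension Gaussian KDE over stacked node embeddings.
// Hn: N x D node values; grp: 1-based graph index per row; ngv: nodes per
// graph; LO/SPAN/BW/DEGEN: per-graph per-dimension grid and bandwidth.
// Returns U (ng x G*D, the density images), plus the moment sums
// A = sum_i z phi and B2 = sum_i z^2 phi needed for the backward chains
// through the grid endpoints and the bandwidth.
// [[Rcpp::export(name = ".kde_batch_u_cpp")]]
List kde_batch_u_cpp(NumericMatrix Hn, IntegerVector grp, NumericVector ngv,
                     NumericMatrix LO, NumericMatrix SPAN, NumericMatrix BW,
                     LogicalMatrix DEGEN, int G) {
  int N = Hn.nrow(), D = Hn.ncol(), ng = LO.nrow();
  NumericMatrix U(ng, G * D), A(ng, G * D), B2(ng, G * D);
  for (int i = 0; i < N; ++i) {
    int g = grp[i] - 1;
    for (int j = 0; j < D; ++j) {
      if (DEGEN(g, j)) continue;
      double b = BW(g, j), lo = LO(g, j), span = SPAN(g, j), v = Hn(i, j);
      for (int t = 0; t < G; ++t) {
        double gt = lo + span * t / (G - 1.0);
        double z = (gt - v) / b;
        double phi = INV_SQRT_2PI * std::exp(-0.5 * z * z);
        U(g, j * G + t) += phi;
        A(g, j * G + t) += z * phi;
        B2(g, j * G + t) += z * z * phi;
      }
    }
  }
  for (int g = 0; g < ng; ++g) {
    for (int j = 0; j < D; ++j) {
      double s = 1.0 / (ngv[g] * BW(g, j));
      for (int t = 0; t < G; ++t) {
        int c = j * G + t;
        if (DEGEN(g, j)) {
          U(g, c) = (t == 0) ? 1.0 : 0.0;
          A(g, c) = 0.0;
          B2(g, c) = 0.0;
        } else {
          U(g, c) *= s;
        }
      }
    }
  }
  return List::create(_["U"] = U, _["A"] = A, _["B2"] = B2);
}

// direct part of the KDE backward pass: dH(i, j) = sum_t z phi dU / (n b^2)
// [[Rcpp::export(name = ".kde_batch_dh_cpp")]]
NumericMatrix kde_batch_dh_cpp(NumericMatrix Hn, IntegerVector grp,
                               NumericVector ngv, NumericMatrix LO,
                               NumericMatrix SPAN, NumericMatrix BW,
                               LogicalMatrix DEGEN, int G, NumericMatrix dU) {
  int N = Hn.nrow(), D = Hn.ncol();
  NumericMatrix dH(N, D);
  for (int i = 0; i < N; ++i) {
    int g = grp[i] - 1;
    for (int j = 0; j < D; ++j) {
      if (DEGEN(g, j)) continue;
      double b = BW(g, j), lo = LO(g, j), span = SPAN(g, j), v = Hn(i, j);
      double inv = 1.0 / (ngv[g] * b * b);
      double acc = 0.0;
      for (int t = 0; t < G; ++t) {
        double gt = lo + span * t / (G - 1.0);
        double z = (gt - v) / b;
        double phi = INV_SQRT_2PI * std::exp(-0.5 * z * z);
        acc += z * phi * dU(g, j * G + t) * inv;
      }
      dH(i, j) = acc;
    }
  }
  return dH;
}
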