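#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs chain for the many-to-many mixed stock model.
//
// Latent-source augmentation: each mixture individual with haplotype h is
// assigned to rookery r with probability proportional to theta(m,r) *
// pi(r,h); rookery haplotype frequencies pi_r and mixture contribution
// vectors theta_m are then redrawn from their Dirichlet full conditionals.
// Uses R's RNG throughout, so determinism is governed by set.seed() on the
// R side.
//
// X:     R x H baseline haplotype counts
// Y:     M x H mixture haplotype counts
// alpha: M x R Dirichlet prior for theta
// beta:  symmetric Dirichlet prior mass per haplotype for pi
// Returns a numeric vector with dim (n_iter, M, R) of theta draws.
// [[Rcpp::export]]
NumericVector msa_gibbs_chain(IntegerMatrix X, IntegerMatrix Y,
                              NumericMatrix alpha, double beta,
                              int n_iter) {
  const int R = X.nrow(), H = X.ncol(), M = Y.nrow();
  NumericVector out(Dimension(n_iter, M, R));
  std::vector<double> pi(R * H), theta(M * R);
  std::vector<double> A(R * H);      // assignment counts by (r, h)
  std::vector<double> Nmr(M * R);    // assignment counts by (m, r)
  std::vector<double> prob(R);

  RNGScope scope;

  // init: theta from its prior, pi from Dirichlet(beta + X)
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    for (int r = 0; r < R; ++r) {
      double g = R::rgamma(alpha(m, r), 1.0);
      theta[m * R + r] = g;
      s += g;
    }
    for (int r = 0; r < R; ++r)
      theta[m * R + r] = (s > 0.0) ? theta[m * R + r] / s : 1.0 / R;
  }
  for (int r = 0; r < R; ++r) {
    double s = 0.0;
    for (int h = 0; h < H; ++h) {
      double g = R::rgamma(beta + X(r, h), 1.0);
      pi[r * H + h] = g;
      s += g;
    }
    for (int h = 0; h < H; ++h)
      pi[r * H + h] = (s > 0.0) ? pi[r * H + h] / s : 1.0 / H;
  }

  for (int it = 0; it < n_iter; ++it) {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(Nmr.begin(), Nmr.end(), 0.0);

    // z-step: multinomial split of each (mixture, haplotype) count
    for (int m = 0; m < M; ++m) {
      for (int h = 0; h < H; ++h) {
        int y = Y(m, h);
        if (y == 0) continue;
        double s = 0.0;
        for (int r = 0; r < R; ++r) {
          prob[r] = theta[m * R + r] * pi[r * H + h];
          s += prob[r];
        }
        if (s <= 0.0) {
          // haplotype unseen in every baseline draw: fall back to theta
          for (int r = 0; r < R; ++r) prob[r] = theta[m * R + r];
          s = 1.0;
        }
        // sequential conditional binomials
        int remaining = y;
        double rest = s;
        for (int r = 0; r < R - 1 && remaining > 0; ++r) {
          double p = prob[r] / rest;
          if (p > 1.0) p = 1.0;
          int k = (int) R::rbinom((double) remaining, p);
          A[r * H + h] += k;
          Nmr[m * R + r] += k;
          remaining -= k;
          rest -= prob[r];
          if (rest <= 0.0) rest = 1e-300;
        }
        if (remaining > 0) {
          A[(R - 1) * H + h] += remaining;
          Nmr[m * R + (R - 1)] += remaining;
        }
      }
    }

    // pi-step
    for (int r = 0; r < R; ++r) {
      double s = 0.0;
      for (int h = 0; h < H; ++h) {
        double g = R::rgamma(beta + X(r, h) + A[r * H + h], 1.0);
        pi[r * H + h] = g;
        s += g;
      }
      for (int h = 0; h < H; ++h)
        pi[r * H + h] = (s > 0.0) ? pi[r * H + h] / s : 1.0 / H;
    }

    // theta-step
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int r = 0; r < R; ++r) {
        double g = R::rgamma(alpha(m, r) + Nmr[m * R + r], 1.0);
        theta[m * R + r] = g;
        s += g;
      }
      for (int r = 0; r < R; ++r)
        theta[m * R + r] = (s > 0.0) ? theta[m * R + r] / s : 1.0 / R;
      for (int r = 0; r < R; ++r)
        out[it + (size_t) n_iter * m + (size_t) n_iter * M * r] =
          theta[m * R + r];
    }
  }
  return out;
}
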