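#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Batched MCMC engine: the per-voxel chain is scalar (propose, accept/reject,
// adapt), while the K per-gradient signal evaluations and the residual
// reduction are tight array loops -- the compiled analogue of distributing
// the K likelihood terms across a thread block. Every floating-point
// operation is written in the same order as the plain-R serial engine
// (run_chain_serial) so both engines produce the same chain from the same
// pre-generated random stream; src/Makevars disables FP contraction to keep
// the operation streams identical.

// signal prediction into s[]; layout of v: S0, d, then (f, theta, phi) per stick
// accumulated as e_iso + sum_j f_j (e_j - e_iso), exactly S0 at b = 0;
// e_iso[] is caller-provided scratch of length K
static void predict_signal_c(const double *v, int L, const double *bvals,
                             const double *bv1, const double *bv2,
                             const double *bv3, int K, double *s,
                             double *e_iso) {
  const double S0 = v[0], d = v[1];
  for (int i = 0; i < K; ++i) {
    e_iso[i] = std::exp(-(bvals[i] * d));
    s[i] = e_iso[i];
  }
  for (int j = 1; j <= L; ++j) {
    const double f = v[3 * j - 1], th = v[3 * j], ph = v[3 * j + 1];
    const double st = std::sin(th);
    const double x1 = st * std::cos(ph), x2 = st * std::sin(ph),
                 x3 = std::cos(th);
    for (int i = 0; i < K; ++i) {
      const double dt = bv1[i] * x1 + bv2[i] * x2 + bv3[i] * x3;
      s[i] = s[i] + f * (std::exp(-(bvals[i] * d) * (dt * dt)) - e_iso[i]);
    }
  }
  for (int i = 0; i < K; ++i) s[i] = S0 * s[i];
}

// marginalised Gaussian log-likelihood; long-double accumulator matches R's
// sum() reduction
static double loglik_c(const double *v, int L, const double *data,
                       const double *bvals, const double *bv1,
                       const double *bv2, const double *bv3, int K,
                       double *scratch, double *scratch2) {
  predict_signal_c(v, L, bvals, bv1, bv2, bv3, K, scratch, scratch2);
  long double acc = 0.0L;
  for (int i = 0; i < K; ++i) {
    const double r = data[i] - scratch[i];
    const double r2 = r * r;
    acc += r2;
  }
  double ss = (double)acc;
  if (ss < 1e-12) ss = 1e-12;
  return -((double)K / 2.0) * std::log(ss);
}

static double log_prior_c(const double *v, int L) {
  if (v[0] < 0.0 || v[1] < 0.0) return R_NegInf;
  double fsum = 0.0, lp = 0.0;
  for (int j = 1; j <= L; ++j) {
    const double f = v[3 * j - 1];
    if (f < 0.0 || f > 1.0) return R_NegInf;
    fsum += f;
    const double s = std::fabs(std::sin(v[3 * j]));
    if (s <= 0.0) return R_NegInf;
    lp += std::log(s);
  }
  if (fsum > 1.0) return R_NegInf;
  return lp;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericVector data, NumericVector bvals,
                   NumericMatrix bvecs, NumericVector init, int L,
                   int burnin, int njumps, int sampleevery,
                   NumericVector proposal_sds, bool adapt,
                   NumericMatrix normals, NumericMatrix uniforms) {
  const int R = 3 * L + 2;
  const int K = data.size();
  const int niter = burnin + njumps;
  if (init.size() != R) stop("'init' must have 3L + 2 entries");
  if (bvals.size() != K || bvecs.nrow() != K)
    stop("scheme and data dimensions do not match");
  if (normals.nrow() < niter || normals.ncol() != R ||
      uniforms.nrow() < niter || uniforms.ncol() != R)
    stop("random stream buffers do not cover the requested iterations");

  std::vector<double> bv1(K), bv2(K), bv3(K);
  for (int i = 0; i < K; ++i) {
    bv1[i] = bvecs(i, 0); bv2[i] = bvecs(i, 1); bv3[i] = bvecs(i, 2);
  }
  std::vector<double> cur(init.begin(), init.end()), prop(R), sds(R),
      scratch(K), scratch2(K);
  for (int p = 0; p < R; ++p) sds[p] = proposal_sds[p];

  double lp = log_prior_c(cur.data(), L);
  if (!std::isfinite(lp)) stop("starting point lies outside the prior support");
  double ll = loglik_c(cur.data(), L, REAL(data), REAL(bvals), bv1.data(),
                       bv2.data(), bv3.data(), K, scratch.data(),
                       scratch2.data());

  const int nsamp = njumps / sampleevery;
  NumericMatrix samples(nsamp, R);
  IntegerVector acc_total(R);
  std::vector<int> acc_win(R, 0);
  const double *nrm = REAL(normals), *unf = REAL(uniforms);
  const int nr = normals.nrow();
  int k = 0;

  for (int it = 1; it <= niter; ++it) {
    for (int p = 0; p < R; ++p) {
      for (int q = 0; q < R; ++q) prop[q] = cur[q];
      prop[p] = cur[p] + sds[p] * nrm[(it - 1) + p * nr];
      const double lpp = log_prior_c(prop.data(), L);
      double delta, llp = 0.0;
      if (std::isfinite(lpp)) {
        llp = loglik_c(prop.data(), L, REAL(data), REAL(bvals), bv1.data(),
                       bv2.data(), bv3.data(), K, scratch.data(),
                       scratch2.data());
        delta = (lpp + llp) - (lp + ll);
      } else {
        delta = R_NegInf;
      }
      if (std::log(unf[(it - 1) + p * nr]) < delta) {
        for (int q = 0; q < R; ++q) cur[q] = prop[q];
        lp = lpp; ll = llp;
        acc_total[p] += 1;
        acc_win[p] += 1;
      }
    }
    if (adapt && it <= burnin && it % 40 == 0) {
      for (int p = 0; p < R; ++p) {
        double fac = acc_win[p] / 20.0;
        if (fac < 0.5) fac = 0.5;
        if (fac > 2.0) fac = 2.0;
        sds[p] = sds[p] * fac;
        acc_win[p] = 0;
      }
    }
    if (it > burnin && (it - burnin) % sampleevery == 0) {
      for (int p = 0; p < R; ++p) samples(k, p) = cur[p];
      ++k;
    }
  }

  NumericVector final_state(cur.begin(), cur.end());
  NumericVector sds_out(sds.begin(), sds.end());
  IntegerVector n_updates(R, niter);
  return List::create(_["samples"] = samples, _["accept"] = acc_total,
                      _["n_updates"] = n_updates,
                      _["final_state"] = final_state,
                      _["proposal_sds"] = sds_out);
}
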