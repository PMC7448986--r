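// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
using namespace Rcpp;

// Site-model likelihood kernel for pairwise codon alignments under the
// GY94 model with uniform codon frequencies. The symmetric rate matrix of
// each (kappa, omega) class is eigendecomposed once and cached across
// calls; only exp(lambda * t) changes along an optimization trajectory in
// t, so gradient evaluations touch the expensive path rarely.

namespace {
struct Eig { arma::vec eval; arma::mat evec; double mean_rate; };
std::map<std::pair<long long, long long>, Eig> cache;

long long keyof(double x) {
  return (long long)std::llround(x * 1e9);
}

const Eig &get_eig(double kappa, double omega, const arma::mat &TS,
                   const arma::mat &NS, const arma::mat &ALLOWED) {
  auto key = std::make_pair(keyof(kappa), keyof(omega));
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  const int n = TS.n_rows;
  arma::mat Q = ALLOWED % arma::exp(TS * std::log(kappa)) %
                arma::exp(NS * std::log(omega)) / (double)n;
  arma::vec rs = arma::sum(Q, 1);
  Q.diag() = -rs;
  Eig e;
  arma::eig_sym(e.eval, e.evec, Q);
  e.mean_rate = arma::mean(rs);
  return cache.emplace(key, std::move(e)).first->second;
}
} // namespace

// [[Rcpp::export(name = ".cpp_codon_lnL")]]
double cpp_codon_lnL(NumericVector omegas, NumericVector weights,
                     double kappa, double t, IntegerVector pat_x,
                     IntegerVector pat_y, NumericVector pat_n,
                     arma::mat TS, arma::mat NS, arma::mat ALLOWED) {
  if (cache.size() > 4000) cache.clear(); // safe: no live references yet
  const int n = TS.n_rows, K = omegas.size(), npat = pat_x.size();
  double mu = 0;
  std::vector<const Eig *> eigs(K);
  for (int k = 0; k < K; ++k) {
    eigs[k] = &get_eig(kappa, omegas[k], TS, NS, ALLOWED);
    mu += weights[k] * eigs[k]->mean_rate;
  }
  if (mu <= 0) return -1e300;
  arma::vec lik(npat, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const Eig &e = *eigs[k];
    arma::vec ex = arma::exp(e.eval * (t / mu));
    // P = V diag(ex) V' ; only the rows present in patterns are needed
    arma::mat Vex = e.evec.each_row() % ex.t();
    for (int p = 0; p < npat; ++p) {
      double pij = arma::dot(Vex.row(pat_x[p] - 1),
                             e.evec.row(pat_y[p] - 1));
      if (pij < 0) pij = 0;
      lik[p] += weights[k] * pij / (double)n;
    }
  }
  double lnL = 0;
  for (int p = 0; p < npat; ++p)
    lnL += pat_n[p] * std::log(std::max(lik[p], 1e-300));
  return lnL;
}

// per-site per-class likelihoods at fixed parameters (NEB/BEB support);
// mu_fixed < 0 means "compute from this class set"
// [[Rcpp::export(name = ".cpp_codon_site_liks")]]
NumericMatrix cpp_codon_site_liks(NumericVector omegas,
                                  NumericVector weights, double kappa,
                                  double t, IntegerVector site_x,
                                  IntegerVector site_y, double mu_fixed,
                                  arma::mat TS, arma::mat NS,
                                  arma::mat ALLOWED) {
  if (cache.size() > 4000) cache.clear(); // safe: no live references yet
  const int n = TS.n_rows, K = omegas.size(), ns = site_x.size();
  double mu = mu_fixed;
  std::vector<const Eig *> eigs(K);
  for (int k = 0; k < K; ++k)
    eigs[k] = &get_eig(kappa, omegas[k], TS, NS, ALLOWED);
  if (mu <= 0) {
    mu = 0;
    for (int k = 0; k < K; ++k) mu += weights[k] * eigs[k]->mean_rate;
  }
  NumericMatrix L(ns, K);
  for (int k = 0; k < K; ++k) {
    const Eig &e = *eigs[k];
    arma::vec ex = arma::exp(e.eval * (t / mu));
    arma::mat Vex = e.evec.each_row() % ex.t();
    for (int s = 0; s < ns; ++s) {
      double pij = arma::dot(Vex.row(site_x[s] - 1),
                             e.evec.row(site_y[s] - 1));
      if (pij < 0) pij = 0;
      L(s, k) = pij / (double)n;
    }
  }
  return L;
}
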