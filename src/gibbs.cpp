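// Collapsed Gibbs sweeps for the multi-stream Dirichlet multinomial
// mixture. One R-visible entry point, cppGibbsFit, evaluating exactly the
// same collapsed conditional as the R reference gibbsConditional():
// log(tau_k\m + alpha_k) plus, per stream, rising-factorial log ratios
// computed as lgamma differences. Categorical draws consume R's RNG
// (unif_rand) so runs are reproducible from set.seed() on the R side and
// resumable from a stored RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List cppGibbsFit(List segWords,        // per stream: list of IntegerVector (0-based distinct word ids)
                 List segCounts,       // per stream: list of IntegerVector (matching counts)
                 IntegerVector Vs,     // per stream vocabulary sizes
                 int K,
                 NumericVector alpha,  // length K
                 List betaList,        // per stream: K x V NumericMatrix
                 IntegerVector zInit,  // 0-based, length M
                 int iterations,
                 bool recordHistory,
                 bool verbose) {
  const int L = segWords.size();
  List firstStream = segWords[0];
  const int M = firstStream.size();

  std::vector<std::vector<std::vector<int>>> words(L), cnts(L);
  std::vector<std::vector<double>> beta(L);       // column-major K x V
  std::vector<double> betaRowTot;                 // per stream*K
  betaRowTot.assign((size_t)L * K, 0.0);
  for (int s = 0; s < L; ++s) {
    List ws = segWords[s], cs = segCounts[s];
    words[s].resize(M);
    cnts[s].resize(M);
    for (int m = 0; m < M; ++m) {
      IntegerVector w = ws[m], c = cs[m];
      words[s][m].assign(w.begin(), w.end());
      cnts[s][m].assign(c.begin(), c.end());
    }
    NumericMatrix B = betaList[s];
    beta[s].assign(B.begin(), B.end());
    for (int k = 0; k < K; ++k) {
      double tot = 0.0;
      for (int v = 0; v < Vs[s]; ++v) tot += B(k, v);
      betaRowTot[(size_t)s * K + k] = tot;
    }
  }

  std::vector<double> tau(K, 0.0);
  std::vector<std::vector<double>> omega(L);      // column-major K x V
  std::vector<std::vector<double>> omegaTot(L);   // per stream, length K
  for (int s = 0; s < L; ++s) {
    omega[s].assign((size_t)K * Vs[s], 0.0);
    omegaTot[s].assign(K, 0.0);
  }
  std::vector<int> z(zInit.begin(), zInit.end());
  for (int m = 0; m < M; ++m) {
    tau[z[m]] += 1.0;
    for (int s = 0; s < L; ++s) {
      const std::vector<int>& w = words[s][m];
      const std::vector<int>& c = cnts[s][m];
      for (size_t j = 0; j < w.size(); ++j) {
        omega[s][(size_t)w[j] * K + z[m]] += c[j];
        omegaTot[s][z[m]] += c[j];
      }
    }
  }

  std::vector<double> logw(K), prob(K);
  NumericVector logJoint(iterations), nonEmpty(iterations);
  IntegerMatrix history(recordHistory ? iterations : 0, recordHistory ? M : 0);

  for (int iter = 0; iter < iterations; ++iter) {
    for (int m = 0; m < M; ++m) {
      const int kOld = z[m];
      tau[kOld] -= 1.0;
      for (int s = 0; s < L; ++s) {
        const std::vector<int>& w = words[s][m];
        const std::vector<int>& c = cnts[s][m];
        double nm = 0.0;
        for (size_t j = 0; j < w.size(); ++j) {
          omega[s][(size_t)w[j] * K + kOld] -= c[j];
          nm += c[j];
        }
        omegaTot[s][kOld] -= nm;
      }

      for (int k = 0; k < K; ++k) logw[k] = std::log(tau[k] + alpha[k]);
      for (int s = 0; s < L; ++s) {
        const std::vector<int>& w = words[s][m];
        const std::vector<int>& c = cnts[s][m];
        if (w.empty()) continue;
        double nm = 0.0;
        for (size_t j = 0; j < w.size(); ++j) {
          const double* om = &omega[s][(size_t)w[j] * K];
          const double* Bc = &beta[s][(size_t)w[j] * K];
          const double cj = c[j];
          nm += cj;
          for (int k = 0; k < K; ++k) {
            const double a = om[k] + Bc[k];
            logw[k] += R::lgammafn(a + cj) - R::lgammafn(a);
          }
        }
        for (int k = 0; k < K; ++k) {
          const double b = omegaTot[s][k] + betaRowTot[(size_t)s * K + k];
          logw[k] -= R::lgammafn(b + nm) - R::lgammafn(b);
        }
      }

      double mx = logw[0];
      for (int k = 1; k < K; ++k) if (logw[k] > mx) mx = logw[k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { prob[k] = std::exp(logw[k] - mx); tot += prob[k]; }
      const double u = unif_rand() * tot;
      double acc = 0.0;
      int kNew = K - 1;
      for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { kNew = k; break; } }

      z[m] = kNew;
      tau[kNew] += 1.0;
      for (int s = 0; s < L; ++s) {
        const std::vector<int>& w = words[s][m];
        const std::vector<int>& c = cnts[s][m];
        double nm = 0.0;
        for (size_t j = 0; j < w.size(); ++j) {
          omega[s][(size_t)w[j] * K + kNew] += c[j];
          nm += c[j];
        }
        omegaTot[s][kNew] += nm;
      }
    }

    // collapsed log joint after the sweep (for convergence inspection)
    double alphaTot = 0.0, lj = 0.0;
    for (int k = 0; k < K; ++k) alphaTot += alpha[k];
    for (int k = 0; k < K; ++k)
      lj += R::lgammafn(tau[k] + alpha[k]) - R::lgammafn(alpha[k]);
    lj += R::lgammafn(alphaTot) - R::lgammafn(alphaTot + M);
    for (int s = 0; s < L; ++s) {
      for (int k = 0; k < K; ++k) {
        double bt = betaRowTot[(size_t)s * K + k];
        lj += R::lgammafn(bt) - R::lgammafn(bt + omegaTot[s][k]);
        for (int v = 0; v < Vs[s]; ++v) {
          const double om = omega[s][(size_t)v * K + k];
          if (om > 0.0) {
            const double b = beta[s][(size_t)v * K + k];
            lj += R::lgammafn(om + b) - R::lgammafn(b);
          }
        }
      }
    }
    logJoint[iter] = lj;
    int ne = 0;
    for (int k = 0; k < K; ++k) if (tau[k] > 0.0) ++ne;
    nonEmpty[iter] = ne;
    if (recordHistory)
      for (int m = 0; m < M; ++m) history(iter, m) = z[m];
    if (verbose)
      Rcpp::Rcerr << "sweep " << (iter + 1) << ": log joint " << lj
                  << ", non-empty clusters " << ne << "\n";
    Rcpp::checkUserInterrupt();
  }

  List omegaOut(L);
  for (int s = 0; s < L; ++s) {
    NumericMatrix om(K, Vs[s]);
    std::copy(omega[s].begin(), omega[s].end(), om.begin());
    omegaOut[s] = om;
  }
  return List::create(
    Named("z") = IntegerVector(z.begin(), z.end()),
    Named("tau") = NumericVector(tau.begin(), tau.end()),
    Named("omega") = omegaOut,
    Named("logJoint") = logJoint,
    Named("nonEmpty") = nonEmpty,
    Named("history") = history);
}
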