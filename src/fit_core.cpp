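// Coordinate-descent core for the penalized constrained bilinear
// least-squares fit. Mirrors the model documented in R/estimation.R:
// objective = sum_obs (y - mu)^2 + sum_j lambda[j] sum_{i,k} omega0 u v,
// u, v >= 0, hard zeros where mask is set. Updates are exact non-negative
// soft-thresholding steps, so the objective is non-increasing.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cd_fit")]]
List cd_fit(NumericMatrix y0, LogicalMatrix M, NumericVector Z,
            NumericVector lambda, NumericVector omega0, LogicalMatrix mask,
            NumericMatrix u_in, NumericMatrix v_in,
            double tol, int max_iter, double ridge) {
  IntegerVector zdim = Z.attr("dim"); // J, K, I, T
  const int J = zdim[0], K = zdim[1], I = zdim[2], T = zdim[3];
  NumericMatrix u = clone(u_in), v = clone(v_in);

  // strides for Z[j,k,i,t] = Z[j + J*(k + K*(i + I*t))]
  auto zat = [&](int j, int k, int i, int t) {
    return Z[j + J * (k + (size_t)K * (i + (size_t)I * t))];
  };
  // omega0[j,i,k]
  auto oat = [&](int j, int i, int k) {
    return omega0[j + J * (i + (size_t)I * k)];
  };

  // initial fitted mean and masked residual
  NumericMatrix R(I, T);
  for (int i = 0; i < I; ++i)
    for (int t = 0; t < T; ++t) {
      if (!M(i, t)) { R(i, t) = 0.0; continue; }
      double mu = 0.0;
      for (int j = 0; j < J; ++j) {
        if (u(j, i) == 0.0) continue;
        double c = 0.0;
        for (int k = 0; k < K; ++k) c += v(j, k) * zat(j, k, i, t);
        mu += u(j, i) * c;
      }
      R(i, t) = y0(i, t) - mu;
    }

  auto objective = [&]() {
    double rss = 0.0, pen = 0.0;
    for (int i = 0; i < I; ++i)
      for (int t = 0; t < T; ++t)
        if (M(i, t)) rss += R(i, t) * R(i, t);
    for (int j = 0; j < J; ++j) {
      if (lambda[j] != 0.0) {
        double pj = 0.0;
        for (int i = 0; i < I; ++i) {
          if (u(j, i) == 0.0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += oat(j, i, k) * v(j, k);
          pj += u(j, i) * s;
        }
        pen += lambda[j] * pj;
      }
      if (ridge > 0.0) {
        for (int i = 0; i < I; ++i) pen += ridge * u(j, i) * u(j, i);
        for (int k = 0; k < K; ++k) pen += ridge * v(j, k) * v(j, k);
      }
    }
    return rss + pen;
  };

  double Q = objective();
  std::vector<double> trace;
  trace.push_back(Q);
  bool converged = false;
  std::vector<double> cvec(T);

  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (int j = 0; j < J; ++j) {
      // (a) u[j, ] update: separable across regions
      for (int i = 0; i < I; ++i) {
        if (mask(j, i)) continue;
        double den = 0.0, num = 0.0;
        for (int t = 0; t < T; ++t) {
          if (!M(i, t)) { cvec[t] = 0.0; continue; }
          double c = 0.0;
          for (int k = 0; k < K; ++k) c += v(j, k) * zat(j, k, i, t);
          cvec[t] = c;
          den += c * c;
          num += (R(i, t) + u(j, i) * c) * c;
        }
        double unew = 0.0;
        if (den > 0.0) {
          double pen = 0.0;
          if (lambda[j] > 0.0)
            for (int k = 0; k < K; ++k) pen += oat(j, i, k) * v(j, k);
          unew = (num - lambda[j] * pen / 2.0) / (den + ridge);
          if (unew < 0.0) unew = 0.0;
        }
        double diff = unew - u(j, i);
        if (diff != 0.0) {
          for (int t = 0; t < T; ++t)
            if (M(i, t)) R(i, t) -= diff * cvec[t];
          u(j, i) = unew;
        }
      }
      // (b) v[j, ] update: inner coordinate sweeps (overlapping bases);
      // cache d_k = u[j,] * Z[j,k,,] * M, constant within the sweeps
      std::vector<double> dcache((size_t)K * I * T);
      std::vector<double> dden(K, 0.0);
      for (int k = 0; k < K; ++k) {
        double den = 0.0;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < I; ++i) {
            double d = (M(i, t) && u(j, i) != 0.0)
              ? u(j, i) * zat(j, k, i, t) : 0.0;
            dcache[k + (size_t)K * (i + (size_t)I * t)] = d;
            den += d * d;
          }
        dden[k] = den;
      }
      for (int sweep = 0; sweep < 10; ++sweep) {
        double delta = 0.0;
        for (int k = 0; k < K; ++k) {
          double den = dden[k];
          double vnew = 0.0;
          if (den > 0.0) {
            double num = 0.0;
            for (int t = 0; t < T; ++t)
              for (int i = 0; i < I; ++i) {
                double d = dcache[k + (size_t)K * (i + (size_t)I * t)];
                if (d != 0.0) num += (R(i, t) + v(j, k) * d) * d;
              }
            double pen = 0.0;
            if (lambda[j] > 0.0)
              for (int i = 0; i < I; ++i) pen += oat(j, i, k) * u(j, i);
            vnew = (num - lambda[j] * pen / 2.0) / (den + ridge);
            if (vnew < 0.0) vnew = 0.0;
          }
          double diff = vnew - v(j, k);
          if (diff != 0.0) {
            for (int t = 0; t < T; ++t)
              for (int i = 0; i < I; ++i) {
                double d = dcache[k + (size_t)K * (i + (size_t)I * t)];
                if (d != 0.0) R(i, t) -= diff * d;
              }
            v(j, k) = vnew;
            double step = std::fabs(diff) * std::sqrt(den);
            if (step > delta) delta = step;
          }
        }
        if (delta < 1e-12) break;
      }
      // rescaling (cu, v/c): fit and L1 penalty unchanged; with ridge the
      // optimal c minimises c^2*ridge*sum(u^2) + ridge*sum(v^2)/c^2
      double su = 0.0, sv = 0.0, su2 = 0.0, sv2 = 0.0;
      for (int i = 0; i < I; ++i) { su += u(j, i); su2 += u(j, i) * u(j, i); }
      for (int k = 0; k < K; ++k) { sv += v(j, k); sv2 += v(j, k) * v(j, k); }
      if (su > 0.0 && sv > 0.0) {
        double cc = (ridge > 0.0) ? std::pow(sv2 / su2, 0.25)
                                  : std::sqrt(sv / su);
        for (int i = 0; i < I; ++i) u(j, i) *= cc;
        for (int k = 0; k < K; ++k) v(j, k) /= cc;
      }
    }
    double Qnew = objective();
    if (Qnew > Q + 1e-8 * (1.0 + std::fabs(Q)))
      stop("internal error: objective increased during block update");
    trace.push_back(Qnew);
    if (Q - Qnew < tol * (1.0 + std::fabs(Q))) {
      Q = Qnew;
      converged = true;
      break;
    }
    Q = Qnew;
  }

  return List::create(
    _["u"] = u, _["v"] = v, _["objective"] = Q,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["iterations"] = (int)trace.size() - 1,
    _["R"] = R);
}
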