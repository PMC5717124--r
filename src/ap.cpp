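#include <Rcpp.h>
using namespace Rcpp;

// Affinity propagation message passing (responsibility/availability updates
// with damping). S is the full similarity matrix with the preference already
// placed on the diagonal. Stops when the exemplar set is unchanged for
// conv_iter consecutive sweeps, or after max_iter sweeps.
//
// Returns the exemplar indices (1-based), the per-point assignment
// (1-based index into the input set), the sweep count, and whether the
// exemplar set was stable at exit.
// [[Rcpp::export]]
List ap_message_passing(NumericMatrix S, double damping, int max_iter,
                        int conv_iter) {
  const int n = S.nrow();
  if (S.ncol() != n) stop("similarity matrix must be square");
  NumericMatrix R(n, n), A(n, n);
  std::vector<char> is_ex(n, 0), was_ex(n, 1);  // force initial "change"
  int stable = 0, it = 0;

  for (it = 0; it < max_iter; ++it) {
    // responsibilities: r(i,k) = s(i,k) - max_{k'!=k} [a(i,k') + s(i,k')]
    for (int i = 0; i < n; ++i) {
      double max1 = R_NegInf, max2 = R_NegInf;
      int k1 = -1;
      for (int k = 0; k < n; ++k) {
        double v = A(i, k) + S(i, k);
        if (v > max1) { max2 = max1; max1 = v; k1 = k; }
        else if (v > max2) { max2 = v; }
      }
      for (int k = 0; k < n; ++k) {
        double rnew = S(i, k) - (k == k1 ? max2 : max1);
        R(i, k) = damping * R(i, k) + (1.0 - damping) * rnew;
      }
    }
    // availabilities: a(i,k) = min(0, r(k,k) + sum_{i'!=i,k} max(0, r(i',k)))
    //                 a(k,k) = sum_{i'!=k} max(0, r(i',k))
    for (int k = 0; k < n; ++k) {
      double possum = 0.0;
      for (int i = 0; i < n; ++i)
        if (i != k) possum += std::max(0.0, R(i, k));
      for (int i = 0; i < n; ++i) {
        double anew;
        if (i == k) {
          anew = possum;
        } else {
          anew = R(k, k) + possum - std::max(0.0, R(i, k));
          if (anew > 0.0) anew = 0.0;
        }
        A(i, k) = damping * A(i, k) + (1.0 - damping) * anew;
      }
    }
    // exemplar set: points with a(k,k) + r(k,k) > 0
    bool changed = false;
    int ne = 0;
    for (int k = 0; k < n; ++k) {
      char e = (A(k, k) + R(k, k) > 0.0) ? 1 : 0;
      if (e != was_ex[k]) changed = true;
      is_ex[k] = e;
      ne += e;
    }
    was_ex = is_ex;
    // a stable but empty exemplar set is not convergence
    stable = (changed || ne == 0) ? 0 : stable + 1;
    if (stable >= conv_iter) { ++it; break; }
  }

  std::vector<int> exemplars;
  for (int k = 0; k < n; ++k)
    if (is_ex[k]) exemplars.push_back(k);

  IntegerVector assignment(n, NA_INTEGER);
  if (!exemplars.empty()) {
    for (int i = 0; i < n; ++i) {
      if (is_ex[i]) { assignment[i] = i + 1; continue; }
      double best = R_NegInf;
      int bestk = exemplars[0];
      for (size_t j = 0; j < exemplars.size(); ++j) {
        int k = exemplars[j];
        if (S(i, k) > best) { best = S(i, k); bestk = k; }
      }
      assignment[i] = bestk + 1;
    }
  }
  IntegerVector ex(exemplars.size());
  for (size_t j = 0; j < exemplars.size(); ++j) ex[j] = exemplars[j] + 1;

  return List::create(_["exemplars"] = ex,
                      _["assignment"] = assignment,
                      _["iterations"] = it,
                      _["converged"] = stable >= conv_iter);
}
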