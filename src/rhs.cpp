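#include <Rcpp.h>
using namespace Rcpp;

// Stack-machine evaluation of all node derivatives.
//
// xext: state vector followed by current signal values.
// Hill terms are precomputed per "term" (one regulatory input): h[e] =
// 1 / (1 + (theta/x)^mu) with x clipped at 0 (solvers may probe tiny
// negative values).
//
// Each node's production tree is a postfix program over opcodes
//   1 PUSH_H term      2 PUSH_INH term (1-h)   3 PUSH_CONST1
//   4 COOP (min)       5 SYN (capped sum)      6 COMP (max(0, a-b))
// Degradation: d0, plus di * min(1, sum of the node's miRNA hill terms)
// for genes with miRNA regulators.

// [[Rcpp::export]]
NumericVector rhs_eval_cpp(NumericVector xext,
                           IntegerVector hsrc, NumericVector htheta,
                           NumericVector hmu,
                           IntegerVector ops, IntegerVector args,
                           IntegerVector prog_ptr,
                           IntegerVector mir_ptr, IntegerVector mir_idx,
                           NumericVector p, NumericVector d0,
                           NumericVector di, int n_state) {
  const int nh = hsrc.size();
  std::vector<double> h(nh);
  for (int e = 0; e < nh; e++) {
    double x = xext[hsrc[e]];
    if (x <= 0.0) { h[e] = 0.0; continue; }
    h[e] = 1.0 / (1.0 + std::pow(htheta[e] / x, hmu[e]));
  }
  NumericVector dx(n_state);
  std::vector<double> stack(ops.size() + 1);
  for (int i = 0; i < n_state; i++) {
    int sp = 0;
    for (int k = prog_ptr[i]; k < prog_ptr[i + 1]; k++) {
      switch (ops[k]) {
      case 1: stack[sp++] = h[args[k]]; break;
      case 2: stack[sp++] = 1.0 - h[args[k]]; break;
      case 3: stack[sp++] = 1.0; break;
      case 4: { double b = stack[--sp]; double a = stack[--sp];
                stack[sp++] = a < b ? a : b; } break;
      case 5: { double b = stack[--sp]; double a = stack[--sp];
                double s = a + b; stack[sp++] = s > 1.0 ? 1.0 : s; } break;
      case 6: { double b = stack[--sp]; double a = stack[--sp];
                double d = a - b; stack[sp++] = d > 0.0 ? d : 0.0; } break;
      }
    }
    double prod = (sp > 0) ? stack[0] : 1.0;
    double deg = d0[i];
    int m0 = mir_ptr[i], m1 = mir_ptr[i + 1];
    if (m1 > m0) {
      double s = 0.0;
      for (int k = m0; k < m1; k++) s += h[mir_idx[k]];
      if (s > 1.0) s = 1.0;
      deg += di[i] * s;
    }
    double xi = xext[i];
    dx[i] = p[i] * prod - deg * xi;
  }
  return dx;
}
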