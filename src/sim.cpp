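#include <Rcpp.h>
using namespace Rcpp;

// Synchronous minute-resolution simulation of a delayed Boolean network.
//
// Per edge j->i the gate keeps an accumulator tau and emits a bit g:
//   h = 1 iff the source has been on continuously for >= theta minutes
//       (measured on states up to t-1);
//   r >= 1 (sustained):  h=1 -> g=1, tau grows by r-1 per minute
//                        (bounded mode: clamped at r-1);
//                        h=0 -> g=1 while tau>0, tau decays by 1, else g=0.
//   r <= -1 (delayed):   h=1 -> tau grows by 1, g=1 once tau >= |r|
//                        (tau then held at |r|); h=0 -> g=0, tau resets.
// Node states are then the gate tree evaluated on the g bits (negated
// terms contribute !g), OR'd with any exogenous stimulus, with knocked-out
// nodes clamped to 0.
//
// rpn: one integer vector per node, reverse-Polish over gate bits:
//   k >= 1 push gate k-1; 0 NOT; -1 AND; -2 OR (binary). Empty = constant 0.

// [[Rcpp::export(name = ".sim_core")]]
IntegerMatrix sim_core(int n_nodes, int horizon,
                       IntegerVector e_src, IntegerVector e_theta,
                       IntegerVector e_r, IntegerVector e_neg,
                       List rpn, IntegerMatrix stim,
                       IntegerVector knockout, IntegerVector init,
                       bool bounded) {
  const int n_edges = e_src.size();
  IntegerMatrix states(horizon + 1, n_nodes);
  std::vector<int> x(n_nodes), run(n_nodes), newx(n_nodes);
  std::vector<long long> tau(n_edges, 0);
  std::vector<int> gate(n_edges, 0), gbit(n_edges, 0);
  std::vector<int> stack(64);

  // pre-extract rpn programs
  std::vector<std::vector<int>> prog(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    IntegerVector p = rpn[i];
    prog[i] = std::vector<int>(p.begin(), p.end());
  }

  for (int i = 0; i < n_nodes; ++i) {
    int v = init[i] || stim(i, 0);
    if (knockout[i]) v = 0;
    x[i] = v;
    run[i] = v;  // no pre-simulation history: a node on at t=0 has run 1
    states(0, i) = v;
  }

  for (int t = 1; t <= horizon; ++t) {
    // 1. every edge gate from minute-(t-1) source states
    for (int e = 0; e < n_edges; ++e) {
      const int h = run[e_src[e]] >= e_theta[e];
      const int r = e_r[e];
      int g;
      if (r >= 1) {
        if (h) {
          tau[e] += r - 1;
          if (bounded && tau[e] > r - 1) tau[e] = r - 1;
          g = 1;
        } else if (tau[e] > 0) {
          --tau[e];
          g = 1;
        } else {
          g = 0;
        }
      } else {
        if (h) {
          if (tau[e] < -r) ++tau[e];
          g = (tau[e] >= -r) ? 1 : 0;
        } else {
          tau[e] = 0;
          g = 0;
        }
      }
      gate[e] = g;
      gbit[e] = e_neg[e] ? !g : g;
    }
    // 2. every node rule on the gate bits
    for (int i = 0; i < n_nodes; ++i) {
      const std::vector<int>& p = prog[i];
      int v;
      if (p.empty()) {
        v = 0;
      } else {
        int sp = 0;
        if (stack.size() < p.size() + 1) stack.resize(p.size() + 1);
        for (size_t k = 0; k < p.size(); ++k) {
          const int op = p[k];
          if (op >= 1) {
            stack[sp++] = gbit[op - 1];
          } else if (op == 0) {
            stack[sp - 1] = !stack[sp - 1];
          } else {
            const int b = stack[--sp];
            const int a = stack[sp - 1];
            stack[sp - 1] = (op == -1) ? (a && b) : (a || b);
          }
        }
        v = stack[0];
      }
      if (stim(i, t)) v = 1;
      if (knockout[i]) v = 0;
      newx[i] = v;
    }
    for (int i = 0; i < n_nodes; ++i) {
      x[i] = newx[i];
      run[i] = x[i] ? run[i] + 1 : 0;
      states(t, i) = x[i];
    }
  }
  return states;
}
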