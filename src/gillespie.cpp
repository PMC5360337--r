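#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the bound chain.  States are 0-based bound
// states; transitions are drawn from the full off-diagonal rate matrix plus
// the per-state unbinding rate.  Uses R's RNG, so results are reproducible
// under set.seed().

static inline int next_state(const NumericMatrix &rot,
                             const NumericVector &unbind,
                             int s, double total, bool &unbound) {
  double u = unif_rand() * total;
  double acc = unbind[s];
  if (u < acc) { unbound = true; return -1; }
  int m = unbind.size();
  for (int j = 0; j < m; ++j) {
    acc += rot(s, j);
    if (u < acc) { unbound = false; return j; }
  }
  unbound = false;
  return m - 1;  // guard against rounding at the very top of the scan
}

// [[Rcpp::export(name = ".gillespie_batch")]]
List gillespie_batch(NumericMatrix rot, NumericVector unbind, int start,
                     double t_max, int n_rep, bool stop_at_parallel) {
  int m = unbind.size();
  if (rot.nrow() != m || rot.ncol() != m)
    stop("rate matrix dimensions do not match unbinding vector");
  std::vector<double> tot(m);
  for (int i = 0; i < m; ++i) {
    double s = unbind[i];
    for (int j = 0; j < m; ++j) s += rot(i, j);
    if (s <= 0) stop("zero total exit rate in state %d", i + 1);
    tot[i] = s;
  }
  IntegerVector terminal(n_rep);  // 0 UNBOUND, 1 REACHED_PARALLEL, 2 CENSORED
  NumericVector tend(n_rep);
  IntegerVector nev(n_rep);
  IntegerVector fstate(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    int s = start, code = 2, ne = 0;
    double t = 0.0;
    if (stop_at_parallel && s == 0) {
      code = 1;
    } else {
      for (;;) {
        t += exp_rand() / tot[s];
        if (t > t_max) { t = t_max; code = 2; break; }
        ++ne;
        bool unbound;
        int nxt = next_state(rot, unbind, s, tot[s], unbound);
        if (unbound) { code = 0; break; }
        s = nxt;
        if (stop_at_parallel && s == 0) { code = 1; break; }
      }
    }
    terminal[r] = code;
    tend[r] = t;
    nev[r] = ne;
    fstate[r] = s + 1;
  }
  return List::create(_["terminal"] = terminal, _["time"] = tend,
                      _["n_events"] = nev, _["state"] = fstate);
}

// [[Rcpp::export(name = ".gillespie_path")]]
List gillespie_path(NumericMatrix rot, NumericVector unbind, int start,
                    double t_max, bool stop_at_parallel, double max_events) {
  int m = unbind.size();
  std::vector<double> tot(m);
  for (int i = 0; i < m; ++i) {
    double s = unbind[i];
    for (int j = 0; j < m; ++j) s += rot(i, j);
    if (s <= 0) stop("zero total exit rate in state %d", i + 1);
    tot[i] = s;
  }
  std::vector<double> times;
  std::vector<int> states;
  times.push_back(0.0);
  states.push_back(start + 1);
  int s = start, code = 2;
  double t = 0.0;
  if (stop_at_parallel && s == 0) {
    code = 1;
  } else {
    for (;;) {
      if ((double)times.size() > max_events)
        stop("trajectory exceeded max_events; raise the cap or lower t_max");
      t += exp_rand() / tot[s];
      if (t > t_max) { t = t_max; code = 2; break; }
      bool unbound;
      int nxt = next_state(rot, unbind, s, tot[s], unbound);
      if (unbound) {
        code = 0;
        times.push_back(t);
        states.push_back(0);  // 0 encodes UNBOUND
        break;
      }
      s = nxt;
      times.push_back(t);
      states.push_back(s + 1);
      if (stop_at_parallel && s == 0) { code = 1; break; }
    }
  }
  return List::create(_["time"] = wrap(times), _["state"] = wrap(states),
                      _["terminal"] = code, _["t_end"] = t);
}
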