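// Exact stochastic simulation of the age-structured birth-death-
// mutation-competition process by thinning.
//
// Every living individual is bounded by the constant rate
//   b_i = i_b + i_d + c * (N - 1),
// which dominates its true birth rate (i_b on [0, x_b)) plus its true
// death rate (i_d past max(x_d, 0), plus c * (N - 1)). Proposed event
// times are drawn from the aggregate bound N * b_i, a candidate is
// picked uniformly, and the proposal is accepted as a birth or a death
// with probability (true rate) / b_i evaluated at the proposed time --
// exact for the piecewise-constant age-dependent rates, with no time-
// discretization bias at the x_b / x_d crossings. The bound is refreshed
// whenever N changes.
//
// Randomness comes from R's RNG stream, so set.seed() in R makes runs
// bit-identical.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_bd_cpp(NumericVector xb0, NumericVector xd0, NumericVector btime0,
                IntegerVector lineage0,
                double ib, double id, double comp,
                double p, double sigma,
                bool lansing_on, double magnitude,
                double max_events, double time_horizon,
                bool record_events, double max_proposals,
                NumericVector sample_times) {
  const int n0 = xb0.size();
  std::vector<double> xb(xb0.begin(), xb0.end());
  std::vector<double> xd(xd0.begin(), xd0.end());
  std::vector<double> bt(btime0.begin(), btime0.end());
  std::vector<int> lin(lineage0.begin(), lineage0.end());
  std::vector<int> id_of(n0);
  for (int i = 0; i < n0; ++i) id_of[i] = i + 1;
  int next_id = n0 + 1;

  const int64_t budget = R_finite(max_events)
    ? (int64_t)(max_events + 0.5) : INT64_MAX;
  const int64_t prop_cap = R_finite(max_proposals)
    ? (int64_t)(max_proposals + 0.5) : INT64_MAX;

  std::vector<double> ev_t, ev_xb, ev_xd;
  std::vector<int> ev_kind, ev_id, ev_parent, ev_lin;
  if (record_events) {
    size_t guess = budget < 4000000 ? (size_t)budget : (size_t)4000000;
    ev_t.reserve(guess); ev_xb.reserve(guess); ev_xd.reserve(guess);
    ev_kind.reserve(guess); ev_id.reserve(guess);
    ev_parent.reserve(guess); ev_lin.reserve(guess);
  }

  double births_by_lin[2] = {0, 0}, deaths_by_lin[2] = {0, 0};
  double t = 0.0;
  int64_t events = 0, proposals = 0;
  std::string term = "";

  // optional time-series sampling of the living population
  const int ns = sample_times.size();
  int si = 0;
  NumericVector samp_gap(ns, NA_REAL), samp_xb(ns, NA_REAL),
    samp_xd(ns, NA_REAL);
  IntegerVector samp_n0(ns, 0), samp_n1(ns, 0);
  auto take_samples_until = [&](double tnow) {
    while (si < ns && sample_times[si] <= tnow) {
      const int N = (int)xb.size();
      int n1 = 0;
      double sg = 0, sb = 0, sd = 0;
      for (int i = 0; i < N; ++i) {
        sg += xb[i] - xd[i]; sb += xb[i]; sd += xd[i];
        n1 += (lin[i] == 1);
      }
      samp_n0[si] = N - n1; samp_n1[si] = n1;
      if (N > 0) {
        samp_gap[si] = sg / N; samp_xb[si] = sb / N; samp_xd[si] = sd / N;
      }
      ++si;
    }
  };

  while (true) {
    const int N = (int)xb.size();
    if (N == 0) { take_samples_until(time_horizon); term = "extinction"; break; }
    if (events >= budget) { term = "event_budget"; break; }
    const double bi = ib + id + comp * (N - 1);
    const double B = (double)N * bi;
    if (B <= 0.0) {
      if (R_finite(time_horizon)) {
        t = time_horizon; take_samples_until(t); term = "time_horizon";
      } else term = "stalled";
      break;
    }
    const double dt = R::exp_rand() / B;
    if (t + dt >= time_horizon) {
      t = time_horizon; take_samples_until(t);
      term = "time_horizon"; break;
    }
    t += dt;
    take_samples_until(t);
    if (++proposals > prop_cap) { term = "proposal_limit"; break; }

    int k = (int)(unif_rand() * N);
    if (k == N) k = N - 1;
    const double a = t - bt[k];
    const double rb = (xb[k] > 0.0 && a < xb[k]) ? ib : 0.0;
    const double rd = (a >= std::max(xd[k], 0.0) ? id : 0.0)
      + comp * (N - 1);
    const double u = unif_rand() * bi;

    if (u < rb) {
      // birth: copy, mutate each gene independently, then Lansing rule
      double cxb = xb[k], cxd = xd[k];
      if (p > 0.0 && sigma > 0.0) {
        if (unif_rand() < p) cxb += norm_rand() * sigma;
        if (unif_rand() < p) cxd += norm_rand() * sigma;
      } else if (p > 0.0) {
        // degenerate kernel: draws consumed identically for stream parity
        if (unif_rand() < p) { }
        if (unif_rand() < p) { }
      }
      if (lansing_on && lin[k] == 1 && magnitude > 0.0 &&
          xd[k] < xb[k] && a > xd[k]) {
        cxd = (1.0 - magnitude) * cxd;
      }
      xb.push_back(cxb); xd.push_back(cxd); bt.push_back(t);
      lin.push_back(lin[k]); id_of.push_back(next_id);
      births_by_lin[lin[k]] += 1.0;
      if (record_events) {
        ev_t.push_back(t); ev_kind.push_back(1); ev_id.push_back(next_id);
        ev_parent.push_back(id_of[k]); ev_xb.push_back(cxb);
        ev_xd.push_back(cxd); ev_lin.push_back(lin[k]);
      }
      ++next_id;
      ++events;
    } else if (u < rb + rd) {
      deaths_by_lin[lin[k]] += 1.0;
      if (record_events) {
        ev_t.push_back(t); ev_kind.push_back(2); ev_id.push_back(id_of[k]);
        ev_parent.push_back(NA_INTEGER); ev_xb.push_back(xb[k]);
        ev_xd.push_back(xd[k]); ev_lin.push_back(lin[k]);
      }
      const int last = N - 1;
      xb[k] = xb[last]; xd[k] = xd[last]; bt[k] = bt[last];
      lin[k] = lin[last]; id_of[k] = id_of[last];
      xb.pop_back(); xd.pop_back(); bt.pop_back();
      lin.pop_back(); id_of.pop_back();
      ++events;
    }
    // else: thinning rejection, clock advanced only
  }

  const int nf = (int)xb.size();
  IntegerVector f_id(nf), f_lin(nf);
  NumericVector f_xb(nf), f_xd(nf), f_bt(nf);
  for (int i = 0; i < nf; ++i) {
    f_id[i] = id_of[i]; f_xb[i] = xb[i]; f_xd[i] = xd[i];
    f_bt[i] = bt[i]; f_lin[i] = lin[i];
  }

  List ev = R_NilValue;
  if (record_events) {
    ev = List::create(
      _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
      _["id"] = IntegerVector(ev_id.begin(), ev_id.end()),
      _["parent_id"] = IntegerVector(ev_parent.begin(), ev_parent.end()),
      _["x_b"] = NumericVector(ev_xb.begin(), ev_xb.end()),
      _["x_d"] = NumericVector(ev_xd.begin(), ev_xd.end()),
      _["lineage"] = IntegerVector(ev_lin.begin(), ev_lin.end()));
  }

  return List::create(
    _["events"] = ev,
    _["final_id"] = f_id, _["final_x_b"] = f_xb, _["final_x_d"] = f_xd,
    _["final_birth_time"] = f_bt, _["final_lineage"] = f_lin,
    _["time_end"] = t,
    _["n_events"] = (double)events,
    _["n_proposals"] = (double)proposals,
    _["termination"] = term,
    _["births_by_lineage"] = NumericVector::create(
        births_by_lin[0], births_by_lin[1]),
    _["deaths_by_lineage"] = NumericVector::create(
        deaths_by_lin[0], deaths_by_lin[1]),
    _["samples"] = List::create(
        _["time"] = sample_times, _["mean_gap"] = samp_gap,
        _["mean_x_b"] = samp_xb, _["mean_x_d"] = samp_xd,
        _["n_non_lansing"] = samp_n0, _["n_lansing"] = samp_n1));
}
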