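#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Agent-based mitogen-competition simulation on a periodic 1D tubule.
//
// The concentration field is advanced with explicit diffusion at the
// stability-limited stride dt_field; agents are updated every dt_agent
// (an integer multiple of dt_field): Gaussian motility step, then
// Bernoulli thinning of duplication / loss events at the local
// concentration.  All randomness comes from R's RNG so set.seed() in R
// makes runs reproducible.
//
// [[Rcpp::export]]
List abm_run_cpp(NumericVector field0, NumericVector positions0,
                 NumericVector production, NumericVector bead_production,
                 double bead_on, double bead_off,
                 double L, double h, double Dc, double Da,
                 double dt_field, int n_sub, int n_agent_steps,
                 double k, double kprime, double c0, double lam, double beta,
                 int record_every, IntegerVector checkpoint_steps) {
  const int m = field0.size();
  std::vector<double> c(field0.begin(), field0.end());
  std::vector<double> cnew(m);
  std::vector<double> pos(positions0.begin(), positions0.end());
  std::vector<int> cellcount(m);

  const double dt_agent = dt_field * n_sub;
  const double lap = Dc * dt_field / (h * h);
  const double sd_step = std::sqrt(2.0 * Da * dt_agent);

  long births = 0, deaths = 0, clip_events = 0;
  double mass_err_max = 0.0;
  bool extinct = false;
  double t = 0.0;

  std::vector<double> rec_t, rec_n, rec_meanc;
  List checkpoints(checkpoint_steps.size());
  int next_cp = 0;

  RNGScope scope;

  for (int step = 0; step < n_agent_steps; ++step) {
    // agent occupancy, frozen over the field substeps
    std::fill(cellcount.begin(), cellcount.end(), 0);
    for (size_t a = 0; a < pos.size(); ++a) {
      int i = (int)(pos[a] / h);
      if (i < 0) i = 0; if (i >= m) i = m - 1;
      cellcount[i]++;
    }

    for (int sub = 0; sub < n_sub; ++sub) {
      const bool bead_active = (t >= bead_on && t < bead_off);
      double total_before = 0.0, prod_tot = 0.0, decay_tot = 0.0,
             cons_tot = 0.0, clip_added = 0.0;
      for (int i = 0; i < m; ++i) total_before += c[i];
      for (int i = 0; i < m; ++i) {
        const int il = (i == 0) ? m - 1 : i - 1;
        const int ir = (i == m - 1) ? 0 : i + 1;
        double prod = production[i] + (bead_active ? bead_production[i] : 0.0);
        double decay = k * c[i];
        double cons = (c[i] / c0) * kprime * (cellcount[i] / h);
        double v = c[i] + lap * (c[il] - 2.0 * c[i] + c[ir]) +
                   dt_field * (prod - decay - cons);
        prod_tot += prod; decay_tot += decay; cons_tot += cons;
        if (v < 0.0) { clip_added += -v; v = 0.0; clip_events++; }
        cnew[i] = v;
      }
      double total_after = 0.0;
      for (int i = 0; i < m; ++i) total_after += cnew[i];
      double expected = dt_field * (prod_tot - decay_tot - cons_tot) + clip_added;
      double scale = std::max(total_after, 1.0);
      double err = std::fabs((total_after - total_before) - expected) / scale;
      if (err > mass_err_max) mass_err_max = err;
      c.swap(cnew);
      t += dt_field;
    }

    // motility: symmetric Gaussian step, periodic wrap (no chemotaxis)
    for (size_t a = 0; a < pos.size(); ++a) {
      double p = pos[a] + norm_rand() * sd_step;
      p -= L * std::floor(p / L);   // periodic wrap (p in [0, L))
      if (p >= L) p = 0.0;          // guard against floor rounding
      pos[a] = p;
    }

    // fate events by Bernoulli thinning at the local concentration
    std::vector<double> daughters;
    size_t write = 0;
    for (size_t a = 0; a < pos.size(); ++a) {
      int i = (int)(pos[a] / h);
      if (i < 0) i = 0; if (i >= m) i = m - 1;
      const double r = lam * (c[i] - c0) / c0;
      double pdup = (beta + 0.5 * r) * dt_agent;
      double ploss = (beta - 0.5 * r) * dt_agent;
      if (pdup < 0) pdup = 0;
      if (ploss < 0) ploss = 0;
      const double u = unif_rand();
      if (u < pdup) {
        daughters.push_back(pos[a]);
        births++;
        pos[write++] = pos[a];
      } else if (u < pdup + ploss) {
        deaths++;            // differentiation exit or death: leaves the pool
      } else {
        pos[write++] = pos[a];
      }
    }
    pos.resize(write);
    pos.insert(pos.end(), daughters.begin(), daughters.end());

    if (record_every > 0 && (step + 1) % record_every == 0) {
      double csum = 0.0;
      for (int i = 0; i < m; ++i) csum += c[i];
      rec_t.push_back(t);
      rec_n.push_back((double)pos.size());
      rec_meanc.push_back(csum / m);
    }
    while (next_cp < checkpoint_steps.size() &&
           step + 1 == checkpoint_steps[next_cp]) {
      checkpoints[next_cp] = NumericVector(pos.begin(), pos.end());
      next_cp++;
    }

    if (pos.empty()) { extinct = true; break; }
  }
  // unreached checkpoints (extinction) -> empty vectors
  for (int j = next_cp; j < checkpoint_steps.size(); ++j) {
    checkpoints[j] = NumericVector(0);
  }

  return List::create(
    _["time"] = rec_t, _["n"] = rec_n, _["mean_c"] = rec_meanc,
    _["checkpoints"] = checkpoints,
    _["final_field"] = NumericVector(c.begin(), c.end()),
    _["final_positions"] = NumericVector(pos.begin(), pos.end()),
    _["births"] = (double)births, _["deaths"] = (double)deaths,
    _["clip_events"] = (double)clip_events,
    _["mass_err_max"] = mass_err_max,
    _["extinct"] = extinct, _["t_end"] = t);
}
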