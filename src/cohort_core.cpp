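#include <Rcpp.h>
using namespace Rcpp;

// Weekly-cycle six-state cohort trace.
// States: 0 event-free, 1 locoregional recurrence (one-cycle tunnel),
// 2 locoregional remission, 3 metastatic progression-free,
// 4 metastatic disease progression, 5 death (absorbing).
// Membership is evaluated at cycle start (no half-cycle correction);
// one-time entry costs (salvage surgery, systemic therapy) are charged on
// the inflow mass at the arrival cycle's discount factor.
// [[Rcpp::export]]
List cohort_core(NumericVector p_ef_lr, NumericVector p_ef_met,
                 NumericVector p_ef_death, NumericVector p_lr_death,
                 double p_rem_met, NumericVector p_rem_death,
                 double p_met_prog, NumericVector p_met_death,
                 NumericVector p_prog_death, NumericVector disc,
                 NumericVector neo_stream, NumericVector surg_stream,
                 NumericVector adj_stream, NumericVector qaly_penalty_stream,
                 double mgmt_ef, double mgmt_lr, double mgmt_rem,
                 double mgmt_mpf, double mgmt_prog, NumericVector util,
                 double salvage_cost, double systemic_cost,
                 double cure_fraction, bool keep_trace) {
  const int H = p_ef_lr.size();
  if (disc.size() != H + 1) stop("`disc` must have length H + 1");

  double ef = 1.0, lr = 0.0, rem = 0.0, mpf = 0.0, mpr = 0.0, dead = 0.0;
  double cured = cure_fraction;
  double c_neo = 0, c_surg = 0, c_adj = 0, c_before = 0, c_after = 0;
  double qaly = 0, ly_disc = 0, ly_undisc = 0, met_entrants = 0;
  int clamped = 0;

  NumericMatrix occ;
  if (keep_trace) occ = NumericMatrix(H, 6);

  for (int k = 0; k < H; ++k) {
    double total = ef + lr + rem + mpf + mpr + dead;
    if (std::fabs(total - 1.0) > 1e-9) stop("occupancy not conserved at cycle %d", k);
    if (keep_trace) {
      occ(k, 0) = ef; occ(k, 1) = lr; occ(k, 2) = rem;
      occ(k, 3) = mpf; occ(k, 4) = mpr; occ(k, 5) = dead;
    }
    const double d = disc[k];
    const double at_risk = std::max(0.0, ef - cured);

    // accruals at cycle start
    c_before += at_risk * mgmt_ef * d;
    c_after += (lr * mgmt_lr + rem * mgmt_rem + mpf * mgmt_mpf +
                mpr * mgmt_prog) * d;
    c_neo += ef * neo_stream[k] * d;
    c_surg += ef * surg_stream[k] * d;
    c_adj += ef * adj_stream[k] * d;
    const double alive = ef + lr + rem + mpf + mpr;
    qaly += (ef * util[0] + lr * util[1] + rem * util[2] + mpf * util[3] +
             mpr * util[4]) / 52.0 * d;
    qaly -= ef * qaly_penalty_stream[k] * d;
    ly_disc += alive / 52.0 * d;
    ly_undisc += alive / 52.0;

    // transitions
    double f_lr = p_ef_lr[k], f_met = p_ef_met[k], f_d = p_ef_death[k];
    double out_ef = f_lr + f_met + f_d;
    if (out_ef > 1.0) { // defensive: rescale a pathological cycle
      f_lr /= out_ef; f_met /= out_ef; f_d /= out_ef; ++clamped;
    }
    const double ef_lr_in = ef * f_lr;
    const double ef_met_in = ef * f_met;
    const double ef_dead = ef * f_d;
    const double lr_dead = lr * p_lr_death[k];
    const double lr_rem_in = lr - lr_dead;
    const double rem_met_in = rem * p_rem_met;
    const double rem_dead = rem * p_rem_death[k];
    const double mpf_prog_in = mpf * p_met_prog;
    const double mpf_dead = mpf * p_met_death[k];
    const double mpr_dead = mpr * p_prog_death[k];

    ef -= ef_lr_in + ef_met_in + ef_dead;
    const double rem_new = rem - rem_met_in - rem_dead + lr_rem_in;
    lr = ef_lr_in;
    rem = rem_new;
    mpf += ef_met_in + rem_met_in - mpf_prog_in - mpf_dead;
    mpr += mpf_prog_in - mpr_dead;
    dead += ef_dead + lr_dead + rem_dead + mpf_dead + mpr_dead;

    // one-time costs on state entry, discounted at arrival
    const double d_arrival = disc[k + 1];
    c_after += ef_lr_in * salvage_cost * d_arrival;
    c_after += (ef_met_in + rem_met_in) * systemic_cost * d_arrival;
    met_entrants += ef_met_in + rem_met_in;

    cured *= (1.0 - p_ef_death[k]);
  }

  List out = List::create(
    _["cost"] = NumericVector::create(
      _["neoadjuvant"] = c_neo, _["surgery"] = c_surg, _["adjuvant"] = c_adj,
      _["before_recurrence"] = c_before, _["after_recurrence"] = c_after),
    _["qaly"] = qaly, _["ly_disc"] = ly_disc, _["ly_undisc"] = ly_undisc,
    _["met_entrants"] = met_entrants, _["clamped_cycles"] = clamped);
  if (keep_trace) out["occupancy"] = occ;
  return out;
}
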