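#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (direct method) of the three-step chain
//   R + L <-> RL* <-> RL <-> C
// in molecule counts. Reaction indices:
//   0: R + L -> RL*   propensity d+ * nR * nL / volNA
//   1: RL* -> R + L   d- * nRL*
//   2: RL* -> RL      e+ * nRL*
//   3: RL  -> RL*     e- * nRL
//   4: RL  -> C       k+ * nRL
//   5: C   -> RL      k- * nC
// volNA = N_A * (reaction volume or contact area): converts the
// concentration-based bimolecular constant d+ to a count propensity,
// consistent with the deterministic term d+ [R][L].
// Uses R's RNG so set.seed() governs reproducibility.

static inline void propensities(const double *rates, double inv_volNA,
                                const long *n, double *a) {
  a[0] = rates[0] * inv_volNA * (double)n[0] * (double)n[1];
  a[1] = rates[1] * (double)n[2];
  a[2] = rates[2] * (double)n[2];
  a[3] = rates[3] * (double)n[3];
  a[4] = rates[4] * (double)n[3];
  a[5] = rates[5] * (double)n[4];
}

static inline void apply_reaction(int j, long *n) {
  switch (j) {
  case 0: n[0]--; n[1]--; n[2]++; break;
  case 1: n[0]++; n[1]++; n[2]--; break;
  case 2: n[2]--; n[3]++; break;
  case 3: n[2]++; n[3]--; break;
  case 4: n[3]--; n[4]++; break;
  case 5: n[3]++; n[4]--; break;
  }
}

// [[Rcpp::export]]
List cpp_gillespie(NumericVector rates, double volNA, IntegerVector init,
                   double t_max, NumericVector record_times,
                   bool record_events, int max_events) {
  if (rates.size() != 6) stop("rates must have length 6");
  if (init.size() != 5) stop("init must have length 5");
  double r[6];
  for (int i = 0; i < 6; ++i) r[i] = rates[i];
  double inv_volNA = (volNA > 0.0) ? 1.0 / volNA : 0.0;
  long n[5];
  for (int i = 0; i < 5; ++i) n[i] = init[i];

  int n_rec = record_times.size();
  IntegerMatrix rec(n_rec, 5);
  int rec_i = 0;

  std::vector<double> ev_t;
  std::vector<int> ev_type;

  RNGScope scope;
  double t = 0.0;
  double a[6];
  long n_events = 0;

  while (true) {
    propensities(r, inv_volNA, n, a);
    double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    double t_next;
    if (a0 <= 0.0) {
      t_next = R_PosInf;
    } else {
      double u = unif_rand();
      if (u <= 0.0) u = DBL_MIN;
      t_next = t - std::log(u) / a0;
    }
    double t_stop = (t_next < t_max) ? t_next : t_max;
    while (rec_i < n_rec && record_times[rec_i] <= t_stop) {
      for (int s = 0; s < 5; ++s) rec(rec_i, s) = (int)n[s];
      rec_i++;
    }
    if (t_next >= t_max || !R_FINITE(t_next)) break;
    // pick reaction
    double u2 = unif_rand() * a0;
    int j = 0;
    double cum = a[0];
    while (j < 5 && u2 > cum) { cum += a[++j]; }
    apply_reaction(j, n);
    t = t_next;
    n_events++;
    if (record_events) {
      ev_t.push_back(t);
      ev_type.push_back(j + 1); // 1-based reaction index for R
    }
    if (max_events > 0 && n_events >= max_events)
      stop("event budget exceeded (%ld events before t_max)", n_events);
  }
  // fill any recording times at/after t_max with the final state
  while (rec_i < n_rec) {
    for (int s = 0; s < 5; ++s) rec(rec_i, s) = (int)n[s];
    rec_i++;
  }

  IntegerVector fin(5);
  for (int s = 0; s < 5; ++s) fin[s] = (int)n[s];
  List out = List::create(
      _["final"] = fin, _["n_events"] = (double)n_events,
      _["states"] = rec,
      _["event_times"] = record_events ? wrap(ev_t) : R_NilValue,
      _["event_types"] = record_events ? wrap(ev_type) : R_NilValue);
  return out;
}

// Repeated short-contact cycles for the adhesion frequency assay: each cycle
// starts from free receptors/ligands in the contact area, runs to t_contact,
// and scores adhesion as >= 1 bound complex C at contact end.
// [[Rcpp::export]]
IntegerVector cpp_af_cycles(NumericVector rates, double volNA, int nR, int nL,
                            NumericVector t_contact, int n_cycles) {
  if (rates.size() != 6) stop("rates must have length 6");
  double r[6];
  for (int i = 0; i < 6; ++i) r[i] = rates[i];
  double inv_volNA = (volNA > 0.0) ? 1.0 / volNA : 0.0;
  int n_pts = t_contact.size();
  IntegerVector adhered(n_pts);
  RNGScope scope;
  double a[6];
  for (int p = 0; p < n_pts; ++p) {
    double tc = t_contact[p];
    int hits = 0;
    for (int c = 0; c < n_cycles; ++c) {
      long n[5] = {nR, nL, 0, 0, 0};
      double t = 0.0;
      while (true) {
        propensities(r, inv_volNA, n, a);
        double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
        if (a0 <= 0.0) break;
        double u = unif_rand();
        if (u <= 0.0) u = DBL_MIN;
        t -= std::log(u) / a0;
        if (t >= tc) break;
        double u2 = unif_rand() * a0;
        int j = 0;
        double cum = a[0];
        while (j < 5 && u2 > cum) { cum += a[++j]; }
        apply_reaction(j, n);
      }
      if (n[4] >= 1) hits++;
    }
    adhered[p] = hits;
  }
  return adhered;
}
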