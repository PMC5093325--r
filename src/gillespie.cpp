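#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Gillespie simulation of a two-ended filament.
//
// Ends are the two axial faces of the filament: O (mapped to terminus B,
// outward = +x) and N (mapped to terminus A, outward = -x). Per uncapped
// end the elementary events and propensities (per minute) are
//   attach: k_on * c / layer   (adds one layer of `layer` um outward)
//   detach: k_off / layer      (removes one layer; only if length > 0)
//   cap:    cap_rate           (irreversibly silences the end)
// Open mode holds c constant; closed mode moves c by -/+ gamma per
// attach/detach so that c + gamma * (net layers added) == c0 exactly.
// Uses R's RNG (unif_rand/exp_rand) so set.seed() governs the trace.
// [[Rcpp::export]]
List gillespie_core(double kOnO, double kOffO, double capO,
                    double kOnN, double kOffN, double capN,
                    double layer, double L0, bool open_mode,
                    double c0, double gamma, double tmax) {
  if (layer <= 0) stop("layer_um must be > 0");
  if (!open_mode && gamma <= 0) stop("gamma must be > 0 in closed mode");
  if (c0 < 0) stop("c0 must be >= 0");
  if (tmax <= 0) stop("t_max must be > 0");

  // snap initial length to a whole number of layers so dissolution reaches
  // exactly zero and closed-mode book-keeping is exact
  long layers = (long)(L0 / layer + 0.5);
  double posA = -0.5 * (double)layers * layer;
  double posB = 0.5 * (double)layers * layer;
  double c = c0;
  double t = 0.0;
  bool cappedO = false, cappedN = false;

  std::vector<double> ev_t, ev_posA, ev_posB, ev_c;
  std::vector<int> ev_end, ev_type; // end: 1 = O, 2 = N; type: 1 attach, 2 detach, 3 cap
  size_t guess = 1024;
  ev_t.reserve(guess);

  int status = 0; // 0 running -> becomes 1 t_max, 2 dissolved, 3 both_capped
  RNGScope rngScope;

  for (;;) {
    bool haveLen = layers > 0;
    double cEff = c;
    if (!open_mode && c < gamma) cEff = 0.0; // cannot deplete below zero
    double aAttO = cappedO ? 0.0 : kOnO * cEff / layer;
    double aDetO = (cappedO || !haveLen) ? 0.0 : kOffO / layer;
    double aCapO = cappedO ? 0.0 : capO;
    double aAttN = cappedN ? 0.0 : kOnN * cEff / layer;
    double aDetN = (cappedN || !haveLen) ? 0.0 : kOffN / layer;
    double aCapN = cappedN ? 0.0 : capN;
    double aTot = aAttO + aDetO + aCapO + aAttN + aDetN + aCapN;

    if (cappedO && cappedN) { status = 3; break; }
    if (aTot <= 0.0) { status = 1; t = tmax; break; } // absorbing: wait out the clock

    double dt = exp_rand() / aTot;
    if (t + dt > tmax) { status = 1; t = tmax; break; }
    t += dt;

    double u = unif_rand() * aTot;
    int end, type;
    if (u < aAttO) { end = 1; type = 1; }
    else if (u < aAttO + aDetO) { end = 1; type = 2; }
    else if (u < aAttO + aDetO + aCapO) { end = 1; type = 3; }
    else if (u < aAttO + aDetO + aCapO + aAttN) { end = 2; type = 1; }
    else if (u < aAttO + aDetO + aCapO + aAttN + aDetN) { end = 2; type = 2; }
    else { end = 2; type = 3; }

    if (type == 1) { // attach: outward
      if (end == 1) posB += layer; else posA -= layer;
      layers += 1;
      if (!open_mode) c -= gamma;
    } else if (type == 2) { // detach: inward
      if (end == 1) posB -= layer; else posA += layer;
      layers -= 1;
      if (!open_mode) c += gamma;
    } else { // cap
      if (end == 1) cappedO = true; else cappedN = true;
    }

    ev_t.push_back(t);
    ev_end.push_back(end);
    ev_type.push_back(type);
    ev_posA.push_back(posA);
    ev_posB.push_back(posB);
    ev_c.push_back(c);

    if (layers == 0) { status = 2; break; } // full dissolution ends the trace
    if (ev_t.size() % 65536 == 0) checkUserInterrupt();
  }

  return List::create(
    _["time_min"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["end"] = IntegerVector(ev_end.begin(), ev_end.end()),
    _["type"] = IntegerVector(ev_type.begin(), ev_type.end()),
    _["pos_A_um"] = NumericVector(ev_posA.begin(), ev_posA.end()),
    _["pos_B_um"] = NumericVector(ev_posB.begin(), ev_posB.end()),
    _["conc_mM"] = NumericVector(ev_c.begin(), ev_c.end()),
    _["status"] = status,
    _["t_end"] = t,
    _["init_pos_A"] = -0.5 * ( (double)((long)(L0 / layer + 0.5)) ) * layer,
    _["init_pos_B"] = 0.5 * ( (double)((long)(L0 / layer + 0.5)) ) * layer
  );
}
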