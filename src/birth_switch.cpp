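#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact (Gillespie, direct method) simulation of the birth-switch process:
// low-state cells divide at gL and rise at r; high-state cells divide at gH
// and fall at f. Counts are recorded on a fixed grid; optionally, at each
// record time the population is diluted back to `dilutionTarget` cells by
// binomial subsampling (the every-12-h resuspension protocol), with the
// cumulative log dilution factor retained so that
//   log N_true(t) = log(nL(t) + nH(t)) + logDilution(t).
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List birth_switch_gillespie(double gL, double gH, double r, double f,
                            double n0L, double n0H,
                            double duration, double recordInterval,
                            double dilutionTarget) {
  const int nRec = (int)std::floor(duration / recordInterval + 1e-9) + 1;
  NumericVector times(nRec), outL(nRec), outH(nRec), outLog(nRec);
  double NL = n0L, NH = n0H, logDil = 0.0;
  bool extinct = false;

  times[0] = 0.0; outL[0] = NL; outH[0] = NH; outLog[0] = 0.0;

  for (int k = 1; k < nRec; ++k) {
    const double t0 = (k - 1) * recordInterval;
    const double t1 = k * recordInterval;
    double t = t0;
    if (!extinct) {
      for (;;) {
        const double aL = gL * NL, aH = gH * NH, aR = r * NL, aF = f * NH;
        const double total = aL + aH + aR + aF;
        if (total <= 0.0) break;
        t += R::rexp(1.0 / total);
        if (t > t1) break;
        const double u = unif_rand() * total;
        if (u < aL) {
          NL += 1.0;
        } else if (u < aL + aH) {
          NH += 1.0;
        } else if (u < aL + aH + aR) {
          NL -= 1.0; NH += 1.0;
        } else {
          NH -= 1.0; NL += 1.0;
        }
        if (NL + NH <= 0.0) { extinct = true; break; }
      }
    }
    times[k] = t1; outL[k] = NL; outH[k] = NH; outLog[k] = logDil;
    if (!extinct && dilutionTarget > 0.0 && NL + NH > dilutionTarget) {
      const double N = NL + NH;
      const double p = dilutionTarget / N;
      double newL = R::rbinom(NL, p);
      double newH = R::rbinom(NH, p);
      if (newL + newH <= 0.0) {
        // keep at least one cell so the culture is not lost to subsampling
        if (NL >= NH) newL = 1.0; else newH = 1.0;
      }
      logDil += std::log(N / (newL + newH));
      NL = newL; NH = newH;
    }
  }

  return List::create(_["times"] = times, _["nL"] = outL, _["nH"] = outH,
                      _["logDilution"] = outLog, _["extinct"] = extinct);
}
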