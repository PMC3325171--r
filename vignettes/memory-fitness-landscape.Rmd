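---
title: "Cellular memory and the environmental fitness landscape of a bistable resistance circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular memory and the environmental fitness landscape of a bistable resistance circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscape)
```

## The system and the question

fitscape analyzes cell populations carrying an inducible, bistable
positive-feedback gene circuit in budding yeast. The circuit drives a
bifunctional protein: a fluorescent reporter fused to a Zeocin-resistance
protein, so a cell's fluorescence F is a proxy for how protected it is from
the antibiotic. Above a low inducer (ATc) threshold the population splits
into coexisting low- and high-expressing subpopulations, and single cells
stochastically switch between them. Two notions of fitness then come apart:

* **instantaneous (cellular) fitness** — the typical division rate of a
  single cell at fluorescence F in a given environment, written
  $g(F) = g_0\,\gamma_1(F,Z)\,\gamma_2(F,C)$;
* **overall population fitness** — the exponential growth rate of the whole
  population, which emerges from single-cell division *and* switching.

The package's central question is how to predict overall population fitness
over a two-dimensional environment grid (inducer concentration C, antibiotic
concentration Z) from measurements taken in each environment *alone* — and
why that prediction fails unless the nongenetic memory of the expression
states is taken into account.

## Models

### Fitness from growth curves

With cell counts $N(t)$ sampled every $\Delta t$ hours (cultures are
resuspended every 12 h to stay in exponential phase), fitness is
$g_E = \ln(N_{k+1}/N_k)/\Delta t$ per interval, or more robustly the OLS
slope of $\ln N$ versus $t$. For antibiotic-exposure curves the pipeline
retains the last six time points to avoid the transient right after drug
onset (`fitnessLinearFit(curve, lastN = 6)`).

### Marginal toxicities

Two semi-phenomenological fitness-reduction factors:

* **Antibiotic, $\gamma_1(F, Z) = 1/(1 + \chi Z_i^{\varphi})$.** The free
  intracellular antibiotic $Z_i$ follows from a mass-action steady state:
  membrane exchange at rate $h_Z$, irreversible binding to the resistance
  protein at rate $s$, protein turnover at rate $d$, under the constraint
  $F = R_u + B$ (free plus bound protein). Substituting
  $R_u = F/(1 + sZ_i/d)$ into the exchange balance
  $h_Z(Z - Z_i) = s Z_i R_u$ gives a quadratic in $Z_i$ whose unique root
  in $[0, Z]$ is evaluated in closed, cancellation-safe form. Defaults:
  $\varphi = 1.182$, $\chi = 5.028\times10^{-8}$, $s = 1.2732\times10^{6}$,
  with $h_Z = 0.5$ and $d = 0.25$ held fixed.
* **Inducer-bound transactivator,
  $\gamma_2(F, C) = 1/(1 + \alpha \hat F\, C/(\beta + C))$** with
  $\hat F = F/F_{\mathrm{ref}}$: activated transactivator molecules are
  toxic in proportion to their abundance (fluorescence as proxy) and to
  inducer occupancy of the activator. Defaults $\alpha = 936$,
  $\beta = 5.8$ ng/ml.

The joint effect is the Bliss product $\gamma = \gamma_1\gamma_2$ (the two
toxicities act through unrelated mechanisms); `gammaJoint()` accepts a
pluggable combiner for non-multiplicative interaction variants.

**Unit scales.** The kinetic constants above act on intracellular
copy-number-like scales, while the package's inputs are instrument units
(fluorescence a.u.) and medium concentrations (mg/ml). Three documented
calibration factors bridge them: `zeocinUnits` ($5\times10^6$ model units
per mg/ml), `fluorUnits` ($2\times10^5$ per a.u.) in the Zeocin model, and
`fluorRef` ($10^6$ a.u.) in the transactivator model. They were fixed once,
by requiring the model to reproduce the characterized system's behavior:
an uninduced population at 2 mg/ml Zeocin retains roughly 10 % of its
drug-free fitness, protection becomes essentially complete for cells whose
expression sits above the inter-mode valley, and — the strongest check —
the cellular-current calibration at balanced induction then lands on
switching rates of $r \approx 0.03\,h^{-1}$ and $f \approx 6\times10^{-4}\,
h^{-1}$, matching the rates measured independently by sorting-relaxation
fits. With these scales the whole pipeline is quantitatively
self-consistent; none of them is re-tuned anywhere.

### Fast-switching prediction

If switching were much faster than division, the stationary fluorescence
distribution $p(F)$ would survive selection and overall fitness would be
the weighted average
$$g_T = g_0 \sum_F \gamma(F, C, Z)\, p(F),$$
computed over log-spaced histogram bins at their geometric centers
(`overallFitness()`).

### Cellular currents and memory

For a stable reporter, cells leave the high-expression state mainly by
growth dilution, drifting down in fluorescence at speed $\theta g$ at the
threshold $\theta$. The downward cellular current is therefore
$$I_{H\to L} = \theta\, g_0\gamma_2(\theta, C)\,
  \left.\frac{\partial N}{\partial F}\right|_{\theta^+},$$
with the density read from the smoothed histogram immediately above the
threshold. When instantaneous fitness varies across the distribution, a
stationary shape additionally requires a compensating net current: cells
produced in excess below the threshold must flow upward,
$$I_{net} = \int_{F<\theta} (g(F) - g_T)\, N(F)\, dF$$
(trapezoidal quadrature), and $I_{L\to H} = I_{H\to L} + I_{net}$. The
memory of each state is the mean waiting time before an arbitrary occupant
leaves it, $\tau_H = N_H / I_{H\to L}$ and $\tau_L = N_L / I_{L\to H}$.
Memory is estimated from antibiotic-free distributions, so the dilution
rate at the threshold uses the inducer marginal $g_0\gamma_2$ only
(configurable).

### Two-state population dynamics

Low-state cells divide at $g_L$ and rise at $r$; high-state cells divide at
$g_H$ and fall at $f$. The linear system has eigenvalues
$$a_{1,2} = \tfrac12\Big[(g_L - r + g_H - f) \pm
  \sqrt{(g_L - r - g_H + f)^2 + 4rf}\Big],$$
and the asymptotic population fitness is $g_T = a_1$. The subpopulation
ratio $R(t) = N_L/N_H$ has a closed form used both to generate synthetic
sorting-relaxation data and to fit switching rates from them; following
the measurement protocol, each sorted arm's log-ratio is normalized by the
unsorted arm's log-ratio at the same time point times the mean unsorted
log-ratio, and $(r, f)$ are fit jointly to both sorted arms by Nelder–Mead
least squares with case-resampling bootstrap CIs over time points (the
measurement protocol reports uncertainties without naming a method; the
bootstrap is this package's choice).

From a single lineage's perspective (no fitness weighting), the
high-state probability obeys $\dot p_H = r(1-p_H) - f p_H$, giving the
closed-form window-averaged occupancy in `lineageOccupancy()`. Because
selection weights population snapshots but not lineages, lineage occupancy
exceeds the population high fraction whenever $g_L > g_H$ — one of the
standing property tests.

### Memory-aware landscape

For each inducer level, `calibrateTwoState()` converts the Zeocin-free
stationary distribution into a condition-specific two-state model:
$r = 1/\tau_L$, $f = 1/\tau_H$ from the cellular-current memories, and
$g_L, g_H$ from the joint toxicity evaluated at the subpopulation mean
fluorescences (the reduction of the full $p(F)$ to two representative
fluorescences is a design choice; means are robust and reproduce the
measured rates). The memory-aware surface is $a_1$ over the (C, Z) grid;
selection acts only through $g_L, g_H$ while the switching structure is
fixed by antibiotic-free memories. Conditions without any high-expressor
mass are treated as single-state (prediction $g_L$): an eigenvalue that
assumes an occupied protected state would be meaningless when no cell can
seed it. Memory at unmeasured inducer levels is interpolated log-linearly
(with a warning).

## The synthetic study system

No public single-cell or growth data exist for this circuit, so the
generators define a calibrated reference system with known ground truth:

* **Dose response.** Expression is unimodal low below the bistability
  onset (1 ng/ml); above it the high-expressor fraction follows a Hill
  curve, $0.95\, C^{1.8}/(10^{1.8} + C^{1.8})$ — about 1.5 % at onset,
  balanced (≈1:1) at 10 ng/ml, 0.95 at saturation.
* **Mixture.** Log-normal modes (log10 scale) at 8 and 300 a.u. with
  widths 0.18 and 0.22 decades — about 1.6 decades apart, placing the
  inter-mode valley near the constant classification threshold of
  50 a.u. Scatter channels are correlated log-normals driven by a latent
  cell-size factor. The distributional family of each mode is this
  package's choice; flow-cytometry modes are conventionally near
  log-normal.
* **Growth.** $g_0 = 0.4\,h^{-1}$ (doubling ≈ 1.7 h, brisk but realistic
  for yeast in rich medium), sampled every 12 h with multiplicative
  log-normal count noise of CV 0.1 (hemocytometer-scale error). Sorting
  subpopulation *ratios* instead carry CV 0.01, since they derive from
  cytometry fractions over ~10^5 events, not from absolute counts.
* **Stochastic truth.** `simulateBirthSwitch()` is an exact Gillespie
  realization of the birth–switch process (population sizes stay ≤10^6
  thanks to the every-12-h dilution built into the protocol, with the
  cumulative dilution factor retained). `simulateDilutionLineages()` is a
  fluorescence-resolved single-cell oracle: a telegraph production state
  with fast activation (upward jumps into the high mode) and pure-dilution
  decay toward a basal level when production is off — exactly the physical
  picture the current estimator assumes, so its counted threshold
  crossings and residence times provide an independent check of the
  estimator.
* **Sorting.** Sort purity defaults to 0.99 (unreported in the protocol;
  modern sorters achieve ≥99 %).

What the generators do *not* emulate: intracellular promoter/mRNA
kinetics, cell-cycle and size structure, autofluorescence background,
instrument compensation, or day-to-day batch effects. Passing tests
demonstrate internal consistency of the estimators on data obeying the
model's assumptions, not performance on real cytometry files.

## Numerical choices and degenerate cases

* Histograms: 256 log-spaced half-open bins over [1, 10^4] a.u. (binning
  is unreported in the protocol; this follows 4-decade cytometer
  convention). Events out of range or non-positive are dropped and
  counted.
* Bimodality: 32-point centered moving average with shrinking edge
  windows; smoothed bins carry variance = expectation/32 (near-Poisson bin
  counts); a valley is accepted when $z = (\mu_{max}-\mu_{min})/
  \sqrt{(\mu_{max}+\mu_{min})/32} > 4$ against *both* flanking maxima (the
  two-sample form is the more conservative reading of the published z
  test). Threshold ties break toward lower fluorescence; events exactly at
  the threshold count as high. False-positive rate on unimodal inputs is
  ≤5 % by standing test.
* Currents: before current evaluation the histogram is smoothed with a
  gentle Gaussian kernel (SD 2 bins) to fill empty valley bins; if the raw
  bin above the threshold was empty, $\tau_H$ is flagged as a conservative
  lower estimate. The density "immediately above" the threshold is the
  first bin fully above it, divided by its width.
* Memory resolution: at minimal induction the valley holds a handful of
  events even at 10^5 cells, so $\tau_H$ there is noisy (and conservative);
  the dose-response tests therefore assert the rising $\tau_H$ trend from
  onset through balanced induction and the order-of-magnitude
  $\tau_H/\tau_L$ gap, not strict monotonicity into the saturated regime.
* Two-state algebra: the 2×2 eigensystem is closed-form; repeated
  eigenvalues ($r = f = 0$, $g_L = g_H$) use the defective-matrix limit;
  $R(t)$ is computed with $e^{a_1 t}$ factored out so century-long
  horizons cannot overflow; $t = 0$ values are returned exactly.
* Optimization: Nelder–Mead on log-parameters, five log-spaced multistarts
  plus a polish for the toxicity fits; a 2×2 start grid plus polish for
  the switching-rate fit, with bootstrap refits warm-started at the full
  fit. Zero ratios (perfect sorts) enter the fit only through the initial
  condition.
* Degenerate inputs: extinction truncates and flags trajectories;
  $r = f = 0$ lineages are degenerate with a warning; zero currents yield
  infinite memory (flagged, no error); infinite memory maps to zero rate.

## Problem sizes

The standing test-suite and the acceptance analysis use: 10^5-event
distributions (2×10^4 for Monte-Carlo cross-checks), ensembles of 200
stochastic trajectories against the ODE oracle, 20-seed recovery studies
for switching rates and toxicity parameters, 30 bootstrap-coverage
replicates at 99 draws, and a benchmark of 11 inducer levels × (10^4
cells, 72 h) exact simulations per seed. These sizes give sampling errors
comfortably below the asserted tolerances while keeping a full run in
minutes.

## Known limitations

* The printed forms of $\gamma_1$, $\gamma_2$ and the current-correction
  integrals are reconstructions consistent with every stated qualitative
  property; alternative forms can be swapped behind `gammaZeocin()` /
  `gammaAtc()`.
* $(\chi, s, \varphi)$ are not jointly identifiable from a single
  uninduced marginal curve — with no high-expressor mass, $s$ barely
  moves the fit. Recovery tests assert $\varphi$ and $\chi$ (and the
  fitted curve), not $s$.
* Reciprocal current-based memories and sorting-fit rates agree to within
  estimator bias (~10–30 %), not exactly; the current estimator is by
  construction a conservative lower bound for $\tau_H$.
* The fluctuating-environment simulator integrates the two-state model
  piecewise-deterministically; demographic noise during episodes is
  ignored (it is negligible at the population sizes simulated).
* No FCS file ingestion: event tables enter as plain data (CSV/vectors).
  Compensation, unmixing and doublet removal beyond the elliptical gate
  are out of scope.
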