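# fitscape

Mapping the environmental fitness landscape of a bistable drug-resistance
gene circuit.

## The problem

A synthetic positive-feedback circuit in yeast drives a bifunctional
protein — a fluorescent reporter fused to a Zeocin-resistance enzyme — so
single-cell fluorescence F reports how protected each cell is. Above a low
inducer (ATc) threshold the population becomes bimodal: low and high
expressors coexist and single cells stochastically switch between the
states. Population growth rate (fitness) in a combined inducer + antibiotic
environment then depends not only on *how many* cells are protected, but on
*how long* individual cells remember their expression state.

fitscape implements the full analysis chain for this class of system, for
anyone studying bet-hedging, persistence, or nongenetic drug resistance
with flow cytometry and growth curves:

1. **Cytometry** — elliptical scatter gating, log-binned histograms,
   moving-average smoothing, a z-test-based bimodality detector and
   threshold selection, subpopulation statistics (`gateEvents`,
   `buildHistogram`, `bimodalityTest`, `classifySubpopulations`).
2. **Fitness from growth curves** — pointwise `ln(N_{k+1}/N_k)/Δt` and OLS
   log-slope estimators, R² model scoring (`fitnessPointwise`,
   `fitnessLinearFit`, `rSquared`).
3. **Instantaneous fitness model** — marginal reductions for the
   antibiotic, `γ1(F,Z) = 1/(1 + χ Z_i^φ)` with a mass-action
   intracellular steady state, and for the inducer-bound transactivator,
   `γ2(F,C) = 1/(1 + α F̂ C/(β+C))`, combined by Bliss independence, plus
   Nelder–Mead fitting of both marginals (`gammaZeocin`, `gammaAtc`,
   `fitZeocinToxicity`, `fitAtcToxicity`).
4. **Cellular currents and memory** — the downward current
   `I_H→L = θ g0 γ2(θ,C) ∂N/∂F|θ+`, fitness-corrected upward currents, and
   state memories `τ_H = N_H/I_H→L`, `τ_L = N_L/I_L→H`
   (`cellularCurrents`, `estimateMemory`, `memoryDoseResponse`).
5. **Two-state population dynamics** — closed-form eigensystem of
   `[[g_L−r, f], [r, g_H−f]]`, overall fitness as the dominant eigenvalue
   `a1`, switching-rate fitting from sorting-relaxation time courses with
   bootstrap CIs, lineage occupancy, fluctuating environments
   (`solveTwoState`, `populationFitness`, `fitSwitchingRates`,
   `lineageOccupancy`, `simulateFluctuatingEnvironment`).
6. **Landscape prediction** — fast-switching vs memory-aware fitness
   surfaces over (ATc, Zeocin), the drug-resistance "sweet spot", model
   comparison and selection reshaping (`predictSurface`, `findSweetSpot`,
   `compareModels`, `selectionReshaping`).
7. **Synthetic data with ground truth** — exact Gillespie birth–switch
   simulation (Rcpp), single-cell lineages, stationary event tables,
   growth curves and sorting experiments (`simulateBirthSwitch`,
   `generateStationaryEvents`, `generateSortingExperiment`,
   `simulateDilutionLineages`).

See the vignette (`vignettes/memory-fitness-landscape.Rmd`) for the models,
assumptions, parameter defaults and numerical choices.

## Worked example

Generate a stationary single-cell sample of the calibrated reference
circuit at balanced induction (10 ng/ml ATc), estimate its memories, and
predict its fitness under 2 mg/ml Zeocin:

```r
library(fitscape)

ev   <- generateStationaryEvents(circuitMixtureSpec(atc = 10), seed = 1, atc = 10)
dist <- buildHistogram(ev)

bimodalityTest(smoothHistogram(dist))
#> BimodalityResult: bimodal; 1 candidate threshold(s); selected 42.94 a.u.

classifySubpopulations(ev, 50)
#> SubpopulationSummary (theta = 50 a.u.): N_L = 52509, N_H = 47491, R = 1.106
#>   mean = 166.8 a.u., CV = 1.256

estimateMemory(dist)
#> MemoryEstimate (ATc 10): tauL = 32.96 h, tauH = 1916 h

cal <- calibrateTwoState(dist, atc = 10, zeocin = 2)
cal$params
#> TwoStateParams: r = 0.03034, f = 0.0005218, gL = 0.04195, gH = 0.3327 per hour
populationFitness(cal$params)
#> [1] 0.3322
```

The detected threshold sits in the inter-mode valley (~50 a.u.); the
subpopulations are nearly balanced (R ≈ 1.1), yet the memories are wildly
asymmetric — the high state persists ~2000 h while the low state persists
~33 h — so balance is maintained by fast upward switching compensating the
high state's fitness cost, not by symmetric rates. Under antibiotic, the
protected high state dominates and the population grows at 0.33/h even
though the *average* cell would barely grow.

The end-to-end benchmark compares both predictors against exact stochastic
simulation of the calibrated system (11 ATc levels, 2 mg/ml Zeocin, 10^4
cells for 72 h with 12-h resuspensions):

```r
b <- memoryBenchmark(seed = 1)
head(b$table, 4)
#>   atc predMem predFast simulated
#> 1   0  0.0422   0.0423    0.0427
#> 2   2  0.3685   0.0582    0.3655
#> 3   4  0.3529   0.0901    0.3520
#> 4   6  0.3435   0.1238    0.3432
c(b$r2Mem, b$r2Fast)
#> [1]  0.9998 -2.97
```

The memory-aware eigenvalue predictor explains >99.9 % of the variance in
simulated fitness; the fast-switching average — which assumes the
expression distribution survives selection — does worse than predicting
the mean.

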