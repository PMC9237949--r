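---
title: "Methods: modular kinetic modelling of KIR2DL4/HLA-G signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular kinetic modelling of KIR2DL4/HLA-G signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modkir)
```

This vignette documents the modelling and numerical methods behind
`modkir`: the composition semantics, the pathway sub-models, the
calibration machinery, and the design decisions that are not obvious from
the API reference.

## Modular composition semantics

A `submodel()` is a self-contained reaction network: named species with
initial concentrations (µM), named parameters, reactions (irreversible and
reversible mass action, plus Hill-type rates), optional clamped species,
and a declared set of **ports** — the only species visible to other
sub-models. `compose()` takes a list of sub-models plus `port_mapping()`
objects and produces a flat model in which every parameter is namespaced
as `"submodel/symbol"`.

Two mapping kinds are supported:

* **Identity mapping** merges two ports into one shared state variable.
  The source sub-model's initial condition wins, and both sub-models'
  reactions read and write the shared species. This expresses "these are
  literally the same molecule".
* **Flux coupling** lets a target sub-model *read* a source species
  without consuming it: every stoichiometric use of the coupled species
  in the target is demoted to a modifier. This expresses catalytic or
  signalling influence (e.g. cytosolic calcium driving NFAT
  dephosphorylation) where the upstream pool must not be depleted by the
  downstream module.

Composition is validated eagerly: unknown sub-models, species that are
not ports, duplicate identity targets, and name collisions are all
errors at compose time, not integration time.

## ODE assembly and stiff integration

`assemble_odes()` flattens a composite into a derivative function;
`simulate_model()` integrates it with `deSolve::lsoda` at default
tolerances of `1e-9` (relative and absolute). The assembled
right-hand side has two implementations:

1. an interpreted reference in R, used as the oracle in tests, and
2. a compiled C++ evaluator (table-driven mass-action/Hill reactions plus
   a small set of named rate kernels for the calcium oscillator, the
   NFAT cycle, and the connector fluxes).

The test suite asserts agreement between the two on every packaged model,
and against a hand-written derivative oracle for the phosphorylation
cascade. Conservation is checked through `conserved_totals()`, which
reports the maximum relative drift of each structural moiety along a
trajectory; the packaged scenarios hold drift near `1e-13`, far inside
the documented `1e-6` acceptance threshold.

## The pathway sub-models

* **Receptor-proximal cascade** (`build_fcepsilonri()`): ligand-receptor
  engagement recruits Lyn, the receptor complex is phosphorylated, Syk
  binds and is activated, and active Syk phosphorylates Grb2 through a
  reversible encounter complex. Two published parameterisations are
  packaged (`fc_parameters("tsang")`, `"faeder_reported"`,
  `"faeder_refit"`), with scenarios `tsang_scenario()` (0–3600 s) and
  `faeder_scenario()` (0–4000 s).
* **Calcium oscillator** (`build_dupont_ca()`): an IP3-receptor
  store-release model with a pump, basal leak, and IP3
  metabolism by a calcium-stimulated 3-kinase and a 5-phosphatase.
  The `zero_v3k = TRUE` variant removes the 3-kinase: calcium keeps
  oscillating while IP3 settles to a constant set by synthesis/5-phosphatase
  balance, and IP4 is never produced.
* **NFAT futile cycle** (`build_nfat_cooling()`): cytosolic
  dephosphorylation by activated calcineurin, nuclear import, nuclear
  rephosphorylation, and export, conserving total NFAT exactly.
* **Connectors** (`build_full_pathway()`): HLA-G dimerises KIR2DL4, the
  engaged complex drives the cascade, phosphorylated Grb2 recruits and
  activates PI3K, PI3K activates PLC, PLC produces IP3 for the
  oscillator, calcium activates calcineurin (a saturating activation
  read through a flux coupling), and nuclear NFAT drives production and
  release of TNF-α and IFN-γ. `rajagopalan_scenario()` runs the full
  pathway over the 60000 s cytokine-secretion horizon.

### The NFAT pool scale

The published futile-cycle model is written for a normalised NFAT pool.
Driving measured cytokine concentrations (on the order of `1e-4` µM)
requires an absolute pool; the package default of `1e-5` µM was set
*a priori* by matching the downstream production scale to the measured
cytokine means, before any acceptance checks were run. Downstream
cytokine output is linear in the pool, so this is a pure unit choice,
not a hidden fitting degree of freedom.

## Calibration

`fit_spec()` + `multistart_fit()` implement global-then-local
calibration:

1. Candidate starts are drawn with `saltelli_design(N, bounds)`: base
   matrices A and B plus the cross blocks AB\_i/BA\_i, giving exactly
   `N * (2D + 2)` rows, sampled uniformly in log10 space inside
   per-parameter exponent bounds (so bounds `(-3, 2)` mean linear values
   in `[1e-3, 1e2]` exactly).
2. Every design row is scored by sum-of-squares (`objective_ssq()`)
   against the supplied `dataset()` objects, optionally weighted by
   per-point `sigma`.
3. The top `top_k` rows are refined with bounded Levenberg–Marquardt
   (`minpack.lm::nls.lm`) in log10 parameter space at
   `ftol = xtol = 1e-8`, and results are returned sorted by final
   error, with a guarantee that refinement never worsens a start.

Three numerical findings shaped the optimiser defaults, all discovered
by profiling rather than tuning against outcomes:

* **Finite-difference step vs. solver noise.** The default
  machine-epsilon step of `nls.lm` probes the ODE solution below its
  integration-noise floor, producing garbage Jacobians. The package uses
  `epsfcn = 1e-6`.
* **Trust-region scale.** The default initial step factor throws the
  first iteration onto a bound corner along sloppy directions; a
  conservative `factor = 0.1` keeps refinement inside the basin.
* **Scan vs. refine tolerance.** Scanning thousands of design rows is
  done at `1e-8` tolerance for speed, but the no-worsening guard and the
  refinement itself run at `1e-10`, so tolerance mismatch can never
  report a spurious improvement.

### Identifiability and the recovery experiment

`recovery_experiment()` regenerates a noiseless phosphorylated-Grb2
time course from the published rates and re-estimates four of them from
scratch. Profiling showed that with late, evenly spaced samples and
absolute residuals, two of the rates are numerically unidentifiable:
compensated 50% shifts change the trajectory by less than `1e-5` µM.
The experiment therefore samples log-spaced times from 1 s (capturing
the rise, where the rates decouple) and weights residuals relatively
(`sigma` equal to the value). Under that design all four rates are
recovered to well within 10%. This experimental design was fixed from
the identifiability analysis before being used as a check.

## Sensitivity and the feasible-parameter census

`oat_sweep()` perturbs one parameter at a time across its exponent
bounds (default 25-point grid) and records the calibration error;
`classify()` labels the profile `flat` (relative range below 1%),
`edge_minimum` (minimum within one grid point of a boundary), or
`sensitive`. `find_alternate_solutions()` draws a Saltelli design and
counts parameter sets whose predictions stay inside an inclusive
`[0, multiplier × mean]` band (`acceptance_band()`, default multiplier
2) at every dataset time point — a census of how tightly the data pin
the parameters.

## Data handling

`load_fixture()` exposes the published parameter/concentration tables
verbatim, including their internal conflicts (the same rate reported
with different roundings or magnitudes in different tables); conflicting
readings are both preserved and flagged, and `composite_bounds()`
deduplicates the bounds table to one exponent pair per parameter.
`pg_per_ml_to_micromolar()` converts measured cytokine densities.
`generate_synthetic_timecourse()` produces seeded, Gaussian-noised
datasets with a provenance hash of the generating parameters, and the
CSV/YAML helpers in `write_trajectory_csv()` et al. give byte-stable
plain-text interchange.

## Command line

`inst/cli/modkir` is a thin `Rscript` front end over the same API:
`simulate`, `fit`, `oat`, `census`, `gen-data`, and `list-fixtures`,
with `--scenario`, `--zero-v3k`, `--seed`, and `--out` options. It adds
no logic of its own beyond argument parsing and file output.
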