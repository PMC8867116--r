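# exokin — kinetic analysis of DNA polymerase proofreading

`exokin` is an R package for pre-steady-state analysis of the kinetic
competition that underlies proofreading in replicative DNA polymerases.
A mismatched primer terminus bound at the polymerase (pol) active site is
either transferred ~35 Å to the 3'–5' exonuclease (exo) active site and
excised, or extended with correct nucleotides until the error is buried
and stably incorporated. The package is aimed at enzyme kineticists who
fit single-turnover rapid-quench (quench-flow) time courses by
simulation, and at anyone who wants to turn fitted rate constants into
statements about replication fidelity.

## The model

Excision of the starting primer follows the branched mass-action scheme

    E + D ⇌ ED_p   (k1, k−1)        binding at the pol site
    E + D ⇌ ED_x   (k2, k−2)        direct binding at the exo site
    ED_p  ⇌ ED_x   (k3, k−3)        intramolecular transfer, K3 = k3/k−3
    ED_x  → E + P  (k_exo ≈ 1000 s⁻¹)  hydrolysis
    ED_p  ⇌ ED_I   (k4, k−4)        off-pathway inhibited complex

fit by simulation with k1 = 300 µM⁻¹s⁻¹, k−1 = k−2 = 0.2 s⁻¹ and k_exo
locked (single-turnover decays constrain binding ratios, not individual
binding rates) and {k2, k3, K3, k4, k−4} floated. Mismatch extension uses
a two-step model — collision complex ⇌ primed pol-site complex → product
— whose equilibrium (the "fraction primed", k1′/(k1′+k−1′)) is
established in a pre-equilibration phase before nucleotide addition.

On top of these schemes the package computes one-way integrated flux
partitions (e.g. the percentage of DNA binding directly into the exo
site, 100·F(D→ED_x)/(F(D→ED_x)+F(D→ED_p))), equilibrium pol-site
occupancy 100/(1+K3), the reverse transfer rate k3/K3, two-temperature
van't Hoff thermodynamics of the transfer (ΔG° = −RT ln K3, ΔH° from the
two-point relation), detection-limited bounds kcat/Km < −ln(1−f)/(c·t),
and an absorbing-Markov-chain "fate" analysis chaining excision against
extension for the terminal and once-buried mismatch to yield the net
fold-contribution of proofreading to fidelity.

Everything runs on a stiff L-stable Rosenbrock integrator with analytic
mass-action Jacobian (Rcpp; rate constants span five orders of
magnitude), validated against an exact Gillespie stochastic oracle, and a
box-constrained Levenberg–Marquardt fitter with multi-start, curvature
standard errors, and honest reporting of ill-conditioned (not-determined)
directions. A synthetic-data module generates quench-flow-like datasets
(5% proportional noise + 0.002 µM floor by default) from bundled
parameter fixtures so the whole pipeline is testable offline.

## Worked example

```r
library(exokin)

p  <- fixture("excision_20C", "1")          # single terminal mismatch, 20 °C
sch <- build_proofreading_scheme(p, conc_E = 1, conc_D = 0.25)

binding_partition(sch)
#> Flux partition from D: 5.749% -> ED_x, 94.25% -> ED_p (one-way)

vant_hoff(0.033, celsius_to_kelvin(4), 0.061, celsius_to_kelvin(20))
#> dG = 6.82 kJ/mol at 293.15 K; dH = 25.9 kJ/mol; dS = 65.2 J/mol/K

mismatch_fate(build_fate_scheme(
  fixture("excision_buried", "n-0"), fixture("excision_buried", "n-1"),
  mismatch_extension_kinetics(kcat = 0.025, Km = 87),
  mismatch_extension_kinetics(kcat_over_Km_limit = 0.1)))
#> Mismatch fate: 99.11% excised, 0.895% extended once then excised,
#>   6.16e-06% buried (upper limit); proofreading contribution >= 1.62e+07-fold
```

Reading: 5.7% of a single-mismatch substrate binds from solution straight
into the exo site (the fast phase of the biphasic decay); transfer out of
the pol site is thermodynamically uphill (ΔG° = +6.8 kJ/mol, ~94% pol-site
occupancy) yet fast enough (k3 = 2.9 s⁻¹, reverse 48 s⁻¹) that ~99% of
terminal mismatches are excised rather than extended, fewer than 1 in
10⁷ are buried past n−1, and proofreading contributes at least 10⁴-fold
to fidelity.

Fitting synthetic noisy data back recovers the generating constants:

```r
gen <- generate_excision(experiment_design("excision_20C", "1",
                                           seed = 1, replicates = 3))
fit_excision(gen, init = p, seed = 1, n_starts = 4)
#> Global fit: converged ...
#>   k3       2.33  +/- 0.31     (truth 2.9, within 2 SE)
```

## Command line

```sh
Rscript inst/cli/exokin simulate --config cfg.json --out out/
# subcommands: simulate, generate, fit, flux, fate, thermo, report
```

Configs are JSON; every output embeds the resolved configuration and
package version, and identical config + seed reproduces files byte for
byte. Exit codes: 0 success, 2 usage error, 3 numerical failure.

## Layout

- `R/scheme.R` — mechanism/parameter types, scheme builders, JSON round trip
- `R/engine.R` — stiff integrator front end, protocols, observables, SSA oracle
- `src/integrator.cpp` — Rosenbrock stepper with analytic Jacobian
- `R/flux.R`, `R/derived.R` — flux partitioning; occupancy/van't Hoff/fate
- `R/fit.R` — fit specs, Levenberg–Marquardt, standard errors, limits
- `R/fixtures.R`, `R/synthetic.R` — published parameter sets, data generator
- `R/workbench.R`, `inst/cli/exokin` — command-line workbench
- `vignettes/proofreading-kinetics.Rmd` — models, numerics, design choices
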