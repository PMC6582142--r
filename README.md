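# mucoflow

Differential haemodynamic modelling of intestinal wall perfusion in R.

Peptic ulcers are circumscribed necroses that appear at stereotyped sites
and with a stereotyped asymmetric shape in one of the best-perfused organs
of the body. `mucoflow` implements the resistor-network explanation: the
submucous arterial plexus is a two-dimensional lateral network fed through
the muscle mantle (conductivity `α`, lowered by wall stress) and drained
into the mucosa (conductivity `ω`, raised by metabolic demand), with
anisotropic lateral resistances `λx`, `λy`. Stationary Kirchhoff balance
for the submucosal pressure gradient `Δp(x,y)` gives the elliptic equation

    α(Δp₀ − Δp) − ωΔp + ∂x[(1/λx) ∂x Δp] + ∂y[(1/λy) ∂y Δp] = 0

and mucosal blood flow is `j_ω = ω·Δp`. Regional conflicts between supply
(`α`) and demand (`ω`) then produce the documented lesion patterns as pure
network phenomena: the asymmetric borderline trough of gastric ulcer
(steep toward the corpus, shallow tail running distally), its mirror image
at the cardia, circumferential ("linear") ulcers where the plexus is
isotropic, central flow dips in collaterally supplied watershed areas of
the duodenal bulb, and — once a viability threshold closes the feedback
loop — a self-limiting, sharply demarcated necrosis with reversed
collateral flow at its margin.

The package provides:

- a finite-volume **Gauss–Seidel/SOR solver** for the heterogeneous
  elliptic system (`solve_gauss_seidel()`), with a sparse direct solve
  (`solve_direct()`) as independent cross-check and a Kirchhoff audit
  (`balance_residuals()`);
- **scenario builders** for the published configurations
  (`scenario_antrum_borderline()`, `scenario_cardia()`,
  `scenario_linear_ulcer()`, `scenario_watershed()`,
  `scenario_necrosis()`) plus seeded random fixtures;
- the **necrosis feedback iteration** (`run_necrosis_iteration()`,
  `find_self_limiting_theta()`);
- **pattern metrics** quantifying the verbal morphology claims
  (`reibungsform_asymmetry()`, `dip_depth()`, `circularity()`,
  `circumferential_extent()`, `steal_index()`, `contrast_enhancement()`);
- TSV/JSON **I/O**, YAML run configs (`read_config()`), ggplot2 renderers,
  and a command-line front end (`inst/cli/mucoflow`).

## Worked example

```r
library(mucoflow)

sc  <- scenario_antrum_borderline()   # corpus ω=5 vs antrum ω=1, α=0.1
sol <- solve_scenario(sc)
sol
#> <mucoflow_solution> 50 x 50 grid
#>   p in [0.0196078, 0.0909091] (delta_p0 = 1)
#>   j_omega in [0.0588587, 0.151427]
#>   iterations = 39, converged = TRUE, max residual = 2.15e-10

reibungsform_asymmetry(axial_profile(sol, 10))
#> [1] 5.267862
circumferential_extent(sol)
#> [1] 0.4
```

On a lesser-curvature row (y = 10) the terminal-flow trough on the antral
side of the mucosal border recovers over 5.3× more cells distally than
proximally — the classic gastric-ulcer asymmetry, steep toward the
acid-secreting corpus. The trough appears only in the 40% of rows where
the submucosal arteries run axially; on the parietal walls (circumferential
arteries, high `λx`) the border leaves no trough. In the isotropic
distal-antrum configuration (`scenario_linear_ulcer()`) the extent is 1.0:
the predicted lesion rings the whole circumference.

The same machinery from the shell:

```sh
inst/cli/mucoflow run --scenario antrum-borderline --out out/
inst/cli/mucoflow metrics --solution out/ --metric reibungsform --row 10
inst/cli/mucoflow free-energy --ph-lumen 1 --ph-plasma 7.4
#> 37.9811 kJ/mol
```

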