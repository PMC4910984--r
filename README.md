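# tumordecay

Kinetics of solid-tumor destruction by cytotoxic lymphocytes: a
saturating fractional-cell-kill law, the geometric decay limits it
implies, and a cellular-automaton experiment that validates them.

## The problem

How fast does an immune cell population destroy a solid tumor? Treating
the lysis as a cell-scale enzymatic reaction (effector = enzyme, tumor
cell = substrate) gives a Hill-type kill law

$$\dot T = -\frac{d\,E^{\lambda}}{s\,T^{\nu}+E^{\lambda}}\,T^{\nu},$$

where $T$ and $E$ are tumor and effector cell counts, $d$ is the maximal
kill rate, $s$ the (inverse) effectiveness of the effectors, and
$\lambda,\nu\in(0,1]$ geometry exponents. Its limits organize the
phenomenology:

* $E_0^\lambda \ll sT^\nu$: **linear** decay at speed $dE_0^\lambda/s$
  (one lymphocyte kills about one cell per hour);
* $E_0^\lambda \gg sT^\nu$, $\nu = 1$: **exponential** decay
  (well-mixed / infiltrated tumors);
* $E_0^\lambda \gg sT^\nu$, $\nu = 1/2$: **parabolic** decay — a 2-D
  tumor fully surrounded by effectors loses one boundary layer per hour,
  so its area obeys $\dot A = -2\pi^{1/2}c\,A^{1/2}$ with $c$ the radial
  erosion speed ($\nu = 2/3$ for a 3-D ball).

The package is for modellers in mathematical oncology who want these
pieces as tested, reusable code: the kill law and its limits
(`kill_params`, `fractional_cell_kill`, `integrate_decay`), analytic and
numerical layer-erosion geometry (`disk_area_map`, `ellipse_area_rate`,
`erode_mask`, `estimate_delta`), a two-phase cellular automaton
(nutrient-limited avascular growth, then frozen-tumor immune lysis:
`morphology_preset`, `grow_tumor`, `place_immune_cells`, `run_lysis`,
`run_experiment`), a single-lymphocyte random-walk toy (`run_walker`),
and least-squares discrimination between power-law and exponential decay
(`fit_decay`, `compare_decay_models`).

## Worked example

Grow a compact ("spherical") tumor to ~9100 cells on a 300×300 lattice,
surround it completely with immune cells, record the lysis, and ask
which decay law describes it:

```r
library(tumordecay)

cfg  <- morphology_preset("spherical")
set.seed(1)
grid <- grow_tumor(cfg)
grid <- place_immune_cells(grid, gamma = 2 * pi, cfg)
ser  <- run_lysis(grid, cfg)
compare_decay_models(ser)
```

```
Decay model comparison
  power law:    d = 1.725, nu = 0.526, SSE = 133098
  exponential:  d = 0.03062,            SSE = 1.30835e+07
  SSE ratio (exp/power) = 98.3 -> preferred: power_law
```

The fitted exponent sits at $\nu \approx 1/2$: the fully covered tumor
decays parabolically, not exponentially (the exponential fit is two
orders of magnitude worse in SSE). Branchier morphologies
(`"papillary"`, `"filamentary"`) expose more interface and decay faster
— their parabolic rate constants order filamentary > papillary >
spherical — while partial immune coverage (`gamma < 2*pi`) pushes the
decay toward the linear limit.

The analytic counterpart, with no simulation:

```r
ser <- synthetic_power_series(d = 2, nu = 0.5, T0 = 9100)
coef(fit_power_law(ser))
#>        d       nu
#> 1.999982 0.500000
```

A thin command-line front end over the same functions lives at
`inst/cli/tumordecay` (subcommands `grow`, `lyse`, `fit`, `decay`,
`geometry`, `walker`; every subcommand honors `--seed`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — grows the full-scale spherical tumor, covers it, records the
lysis, and prints the power-law vs exponential comparison — then writes
its (empty) results object as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/tumor-decay-kinetics.Rmd` documents the model, the
reconstructed automaton rules and their rationale, the fitting protocol,
and known limitations.
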