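# magsort

Desk-scale simulator of **strip-array immunomagnetic cell fractionation**
in a microfluidic channel, for researchers designing or reasoning about
magnetophoretic sorters that resolve *expression levels* rather than
binary positive/negative populations.

A straight 4 mm × 100 µm channel runs 50 µm above 27 soft-magnetic strips
(500 µm wide, 35 µm thick, 1 mm pitch). A laterally decaying background
field (9 mT at the inlet → 35 mT at the last strip) magnetizes the strips,
which concentrate flux at their edges into localized high-gradient capture
zones. A cell carrying `n_b` antibody-coupled superparamagnetic beads
(diameter 2.8 µm, volume `V_b`) experiences the magnetophoretic force

$$\mathbf{F}_m \;=\; n_b\,\mu_0 V_b\,
\frac{3(\chi_b-\chi_f)}{(\chi_b-\chi_f)+3}\;
(\mathbf{H}\cdot\nabla)\mathbf{H},$$

and its trajectory through the coupled field/flow — plane-Poiseuille drag,
Coulomb friction at floor contact, semi-implicit Euler at `Δt = 1e-5` s —
ends either arrested on a strip or at the outlet. Capture strips 1–9,
10–18, 19–27 define the High/Medium/Low bead-load fractions; uncaptured
cells are the Negative fraction. Because bead load tracks surface-marker
(e.g. EpCAM) expression, the per-strip histogram of a population is an
expression-level fractionation.

The package covers:

* `default_device()`, `load_config()` — the reference device and YAML
  configuration (bench units in, SI internally);
* `total_field()`, `field_map()`, `edge_gradient_scan()` — closed-form
  magnetostatics of the magnetized strip array with analytic gradients and
  the force factor `(H·∇)H`;
* `build_flow()`, `sample_band()`, `residence_time()`, `throughput()` —
  laminar flow, sheath-flow flux-split confinement, operating arithmetic;
* `conjugate()`, `magnetophoretic_force()`, `conjugate_susceptibility()` —
  the bead–cell conjugate model;
* `simulate_cell()`, `equilibrium_profile()`, `classify()` — trajectories,
  capture detection, static equilibria, H/M/L/N classification;
* `population_spec()`, `phenotype_preset()`, `run_batch()` — seeded
  synthetic populations (truncated-normal sizes, zero-inflated
  negative-binomial bead loads, free beads) and batch fractionation with
  recovery metrics;
* a thin command-line front end at `inst/cli/magsort.R`
  (`field-map`, `flow`, `trajectory`, `equilibrium`, `batch`, `sweep`).

## Worked example

```r
library(magsort)
dev  <- default_device()        # PBS mode: 3000 + 1000 uL/h
flow <- build_flow(dev)

flow$mean_velocity * 1e3        # 2.778  (mm/s)
residence_time(dev)             # 9.72   (s)

# a 15 um cell with 6 beads, started at mid-channel
tr <- simulate_cell(conjugate(15e-6, 6, dev$materials), c(0, 50e-6), dev)
tr
#> Cell trajectory: captured at strip 9 (x = 8.253 mm, H fraction)
#>   791962 steps of dt = 1e-05 s, final t = 7.920 s

# a seeded synthetic batch of 100 cells (default spec: 15 +/- 3 um,
# zero-inflated negative-binomial bead loads, mean 4)
fr <- run_batch(sample_population(population_spec(100, seed = 17), dev), dev)
fr
#> Batch fractionation of 100 cells
#>   H 24 | M 35 | L 23 | N 18 | indeterminate 0
#>   overall recovery 1.000, positive capture rate 0.820
```

Sweeping bead load for a 15 µm cell maps 1, 2, 3, 4, 5, 6, 8, 10 beads to
capture strips 26, 20, 16, 13, 11, 9, 5, 2: loads of 6–10 land in H, 3–5
in M, 1–2 in L, and unlabelled cells pass through — the bead-load →
region mapping emerges from the force balance, not from any assignment in
the code. `overall recovery` is trajectory accounting (all H+M+L+N cells
over the input; its complement is exactly the indeterminate count), and
`positive capture rate` is the captured share of the cells introduced.

From a shell, the same batch is:

```sh
Rscript inst/cli/magsort.R batch --seed 17 --out run1/
```

which writes `per_strip.csv`, `fractions.csv`, `summary.json` and a
manifest with the fully resolved configuration; rerunning it reproduces
the tables byte for byte.

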