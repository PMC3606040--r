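# bulksolv

Fast analytic bulk-solvent and overall anisotropic scaling of
macromolecular crystallographic structure factors.

## What it does

When refining or evaluating a macromolecular model against diffraction
data, observed amplitudes are compared with a total model structure
factor

```
F_model(s) = k_total(s) [ F_calc(s) + k_mask(s) F_mask(s) ],
k_total    = k_overall * k_isotropic(s) * k_anisotropic(s),
```

where `F_calc` comes from the atomic model, `F_mask` from the binary
bulk-solvent mask, `k_mask` scales the flat solvent contribution, and
`k_total` collects the overall, resolution-dependent and
direction-dependent scales.  `bulksolv` determines every component
analytically:

* **Per resolution bin**, the pair `(K = k_total^-2, k_mask)` minimizing
  `sum((K I_obs - |F_calc + k_mask F_mask|^2)^2)` is found exactly: the
  normal equations reduce to a cubic in `k_mask` whose leading
  coefficient is non-negative by the Cauchy-Schwarz inequality, and the
  admissible root with the smallest residual is selected.  No iterative
  search, no local minima.
* **Anisotropic scaling** `exp(-2 pi^2 h' U h)` is fitted by a
  log-linear solve with crystal-system symmetry constraints derived
  from first principles (`R' U R = U` over the point group), or as the
  12-parameter polynomial `1 + h' V0 h + s^2 h' V1 h` fitted directly
  in amplitude space; an L-BFGS-polished exponential variant is opt-in.
* **Binning** is uniform in `ln(d)` with a per-bin count floor, giving
  the dense low-resolution sampling the solvent signal needs.
  Bin-wise `k_mask` curves are Savitzky-Golay smoothed (skipped when
  monotone) and linearly interpolated in `s^2`; an R-factor grid search
  around the least-squares optimum guards against the two targets'
  minima being in different places.
* **Twinned data**: fractions of N twin domains are estimated by an
  (N+1)-dimensional Lagrange linear system and interleaved with
  scaling; the single-domain path is bit-identical to the untwinned
  one.
* A **synthetic-data generator** produces reflection sets with known
  ground truth for every stage, so the whole pipeline is testable
  offline.

## Worked example

```r
library(bulksolv)

spec <- simulation_spec(n = 8000, d_range = c(2.2, 25),
                        k_sol = 0.35, b_sol = 50,
                        u_aniso = c(3, 3, -3, 0, 0, 0) /
                          (8 * pi^2 * c(60, 60, 90, 1, 1, 1)^2),
                        noise = 0.01, seed = 42)
sim <- simulate_reflections(spec)
res <- run_scaling(sim$inputs)
print(res)
#> scaling_result: R_all = 0.0082 (low 0.0108, high 0.0079), 3 cycle(s), aniso = exp_anal
#>   k_overall = 0.97884, 9 bins, 0 reflections excluded (F_obs <= 0)
#>   flat-solvent fit: k_sol = 0.3653, B_sol = 48.30 A^2
```

The data were generated with a flat-solvent truth of
`k_sol = 0.35`, `B_sol = 50` and 1% amplitude noise; the protocol
converges in three cycles to an R factor at the noise floor (~0.008),
and the two-parameter exponential refitted to the bin-wise `k_mask`
curve recovers the generating values.  `res$bins$table` holds the
per-bin resolution ranges, counts, `K`, raw and smoothed `k_mask`,
`k_isotropic` and bin R factors; `res$k_total`, `res$k_mask`, etc. are
the per-reflection scale components.

Reflection files (the columnar TSV dialect or mmCIF `refln` loops) are
read with `read_reflections()`; a command-line driver is installed at
`inst/cli/bulksolv.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bulksolv.R", package="bulksolv"))')" \
  --input reflections.tsv --aniso poly+exp_anal --json-out result.json
```

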