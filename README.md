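# bcellkinetics

Compartmental kinetic modeling of B-cell maturation with BrdU label
tracking, for immunologists and modelers who ask where peripheral B cells
die. The package implements, as a tested R pipeline, the analysis of
whether the splenic transitional-3 (T3) subset is a common *death niche* —
fed both by newly formed bone-marrow émigrés and by mature follicular B
cells recalled for elimination — rather than a developmental intermediate
on the way to the mature pool.

## The model

Bone-marrow pools (resting/cycling pro-B `B_or`/`B_oc`, cycling/resting
pre-B `B_ec`/`B_er`, immature `B_i`) are fed by a stem-cell source `s`,
proliferate logistically only while cycling (capacities `K_o`, `K_e`), die
only while resting, and export immature cells at rate `δ_i`. The splenic
stage receives the influx `R = δ_i·B_i`, split by fractions `f1, f3, fm`
into the combined T1/T2 pool (`T_1/2`), T3, and mature (`B_m`) pools, with
transitions `δ_23` (T1/2→T3), `δ_2m` (T1/2→mature) and exit/death rates
`μ_1/2, μ_3, μ_m`. Two topologies of the T3↔mature edge compete:

* **mature → T3** (death niche): mature cells re-acquire the T3 phenotype
  at rate `δ_m3` and die there; no flow from T3 into the mature pool;
* **T3 → mature** (legacy): T3 feeds the mature pool at rate `δ_3m`.

All rates are per 6-hour step. Continuous BrdU labeling is tracked by
splitting every pool into unlabeled/labeled streams: divisions of unlabeled
cycling cells produce labeled daughters, label is inherited along every
edge, and labeling never perturbs the totals. Fitting is an exhaustive
constrained grid search minimising the sum of squared deviations between
simulated and observed labeled-cell *numbers*; competing topologies are
compared by the small-sample-corrected Akaike score
`AICc = N·ln(SS/N) + 2M + 2M(M+1)/(N−M−1)` and the two-model weight
`1/(1+exp(−|ΔAICc|/2))`. A synthetic-data generator emulates the in vivo
labeling experiments (per-mouse log-normal measurement noise, observed
total/composition ranges) so fitting and model selection are testable end
to end; the original labeling dataset is not publicly deposited.

## Worked example

```r
library(bcellkinetics)

topo <- model_topology("mature_to_t3")
q    <- reference_parameters("table2_best_fit")

# Calibrate the marrow source so the splenic steady state hits the printed
# T1/2 pool size (1.17e6 cells): required influx R = 0.2 * 1.17e6 / 0.15.
cal <- calibrate_source(reference_parameters("bm_default"), q, topo)
cal
#> <bk_calibration> s = 1.61373e+06 cells per 6 h, influx R = 1.56e+06
#> # A tibble: 3 × 4
#>   subset     count  target relative_mismatch
#>   <chr>      <dbl>   <dbl>             <dbl>
#> 1 T12     1170000  1170000             0
#> 2 T3      1069059. 1430000            -0.252
#> 3 mature 16185000  2510000             5.45
```

The T1/2 target is met exactly; the printed T3 and mature sizes cannot be
met simultaneously under the best-fit rates, so the mismatch is reported
(see the vignette on the tenfold discrepancy between the two printed
mature-pool figures). The maximum recursion flux through the niche — upper
acceptable rate times the 2.5e7-cell mature pool — is
`mature_to_t3_flux(0.004, 2.5e7)` = **1e5 cells per 6 h**.

```r
# Labeling kinetics at the steady state: labeled cells per subset.
sim <- simulate_brdu(cal$p, q, topo, sample_days = c(2, 6, 10, 14))
sim[sim$subset != "T12", c("subset", "time_days", "labeled", "fraction")]
#>   subset time_days  labeled fraction
#> 1 T3             2   18942.  0.0177
#> 2 mature         2   16379.  0.00101
#> 3 T3             6  352710.  0.330
#> 4 mature         6  449664.  0.0278
#> 5 T3            10  620268.  0.580
#> 6 mature        10 1282298.  0.0792
#> 7 T3            14  713581.  0.667
#> 8 mature        14 2179952.  0.135
```

The T3 curve rises much faster than the mature curve: T3 turns over in
days, the mature pool in months — the kinetic signature the fit exploits.

```r
# Synthetic experiment -> constrained grid fit -> topology comparison.
ds   <- generate_dataset(cal$p, q, topo, seed = 1)
cons <- dataset_to_constraints(ds, max_steady_days = 365)
grid <- parameter_grid(q, vary = list(delta_m3 = grid_seq(0, 0.008, 0.001),
                                      mu_3     = grid_seq(0.08, 0.34, 0.01)))
fit  <- grid_search(grid, ds, cons, topo, bm = cal$p)
tidy(fit)
#> # A tibble: 2 × 4
#>   parameter estimate lower upper
#> 1 delta_m3     0.004 0.004 0.004
#> 2 mu_3         0.16  0.16  0.19

qL    <- reference_parameters("legacy_t3_to_mature")
gridL <- parameter_grid(qL, vary = list(delta_3m = grid_seq(0, 0.008, 0.001),
                                        mu_3     = grid_seq(0.08, 0.34, 0.01)))
fitL  <- grid_search(gridL, ds, cons, model_topology("t3_to_mature"),
                     bm = cal$p)
compare_models(fit, fitL)
#> # A tibble: 2 × 5
#>   model                   ss     n     m  aicc
#> 1 mature_to_t3 422961435692.    64     2 1451.
#> 2 t3_to_mature 546441609606.    64     2 1468.
#> preferred: mature_to_t3 (delta AICc = -16.393, probability 100.0%)
```

The fit recovers the generating recursion rate (`δ_m3 = 0.004`, with `μ_3`
one grid step off truth at this noise level and a marginal acceptable range
bracketing it), and AICc decisively prefers the generating topology.
`run_pipeline()` wraps these stages (synthesise → fit both topologies →
compare) and writes the dataset, fit reports, steady-state and kinetics
tables, the mature→T3 flux series and the AICc verdict, all stamped with
seed and config hash. `autoplot()` methods draw time courses, labeling
kinetics and fit-vs-data overlays.

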