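# zosteragrowth

Estimating leaf growth rates of eelgrass (*Zostera marina*) from
shoot-marking campaigns, and quantifying exactly how much the popular
shortcut methods are biased.

Eelgrass productivity is usually measured by marking shoots, retrieving
them about two weeks later, and converting the new leaf tissue into a
growth rate. Field crews rarely measure the full balance directly; they
use one of three proxies:

* the **leaf-marking method** — weigh the new tissue produced above a
  reference mark (misses growth inside the basal sheath and the
  thickening of pre-existing tissue);
* the **allometric method** — project biomass from leaf lengths through
  the power law `ω = α·l^β`;
* the **plastochrone method** — divide the dry weight of the third leaf
  on each shoot by the plastochrone interval `p` (the mean time between
  appearance of successive leaves), `Lgp_s = ω₃ₛ / p`.

This package implements all four estimators (the in situ reference `Lg`
plus the three proxies), and the exact algebra that connects them. For a
shoot `s` the allometric rate decomposes as

    Lga_s = Csap · Lgp_s + Rsap ,   Csap = δ₃ₛ · p / Δt ,
    δ = 1 − (1 − Δl/l(t+Δt))^β ,    Rsap = Σ_{j≠3} δⱼ ωⱼ / Δt ≥ 0 ,

and averaging over the `N` retrieved shoots gives the campaign identity
`Lga = Cap·Lgp + Bap` with `0 ≤ Cap ≤ p/Δt` and `Bap > 0` whenever any
leaf other than the third one grew. Because a single leaf can stand in
for the whole shoot only if every other leaf stopped growing, the
plastochrone proxy carries an unavoidable positive bias whenever
`p ≤ Δt`. Each leaf's biomass gain also splits exactly into new tissue
and maturation,

    Δω = α·(Δl)^β  +  α·l(t+Δt)^β·(δ − λ^β) ,   λ = Δl / l(t+Δt) ,

which links the marking and plastochrone methods
(`Lgm = Cap·Lgp + Bmp`). The package audits every one of these
identities at machine precision, computes the bias bounds
`BLap ≤ Bp ≤ BLap + (p/Δt)·Lgp`, and reports method agreement via RMSE,
Lin's concordance correlation coefficient (with asymptotic confidence
intervals), and regression through the origin.

Because marking datasets of this kind are rarely deposited, the package
ships a seeded synthetic-campaign generator (`simulate_campaigns()`)
that emulates a biweekly field study — ~40 shoots per campaign, 3–6
leaves per shoot, seasonal elongation and leaf appearance, within-sheath
growth, tissue maturation, lognormal weight noise, retrieval losses —
with a ground-truth channel, so every identity, inequality, and method
comparison is verifiable end to end.

## Worked example

```r
library(zosteragrowth)

p <- allometric_params(2e-5, 1.3)      # grams, millimetres
leaf_biomass(300, p)
#> [1] 0.03321143

lf <- leaf_observation(rank = 2, length_start = 250, length_end = 300,
                       dry_weight_end = 0.035)
biomass_increment_allometric(lf, p)    # 0.007008374 g over the interval
growth_decomposition(lf, p)
#> $new_tissue  0.003233635      # allometric biomass of the 50 mm of new length
#> $maturation  0.003774739      # pre-existing tissue growing heavier

sims <- simulate_campaigns(simulation_config(n_campaigns = 6, seed = 11))
season <- estimate_season(sims, p)
season
#> <growth_season> 6 campaigns, 1999-03-01 to 1999-05-10
#>   mean rates (g/d): Lg = 0.002559, Lgm = 0.002433, Lga = 0.002241, Lgp = 0.001468
#>   max identity residual: 6.505e-19 g/d

method_comparison_report(season)
#> <agreement_report> 6 campaigns
#>   marking      RMSE = 0.000126118, rho_c = 0.9417 (0.7926, 0.9845), origin slope = 1.051 (r2 = 1.00)
#>   allometric   RMSE = 0.000322869, rho_c = 0.6849 (0.2643, 0.8866), origin slope = 1.142 (r2 = 0.99)
#>   plastochrone RMSE = 0.00111114, rho_c = 0.1034 (-0.0438, 0.2461), origin slope = 1.730 (r2 = 0.57)
#>   Bm < Ba < Bp in 100% of campaigns; Bp > 0 in 100%
```

The numbers say: over these six spring campaigns the shoots gained on
average 2.6 mg dry weight per day; the marking proxy tracks the in situ
rate closely (concordance 0.94, 5% underestimate), the allometric
projection is next (14% low), and the third-leaf/plastochrone proxy is
far less reproducible and underestimates by over 40% — with every
campaign showing the bias ordering `Bm < Ba < Bp`. All identity
residuals sit at floating-point zero because the decomposition is exact.

`run_pipeline()` glues the steps together (data or simulation in;
`rates.csv`, `bias.csv`, `audit.json`, `report.json` out), with
campaign-structured CSV input via `read_leaf_table()` and YAML
configuration via `load_config()`.

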