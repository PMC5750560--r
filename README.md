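# aquaprog

Probabilistic screening prognosis of radionuclide activity concentrations in
the **bottom sediments** of water bodies receiving routine liquid discharges
from nuclear power plants — and comparison of the modelled distributions
with measured environmental monitoring ranges.

Routine liquid discharges are so small that the radioactivity they add to
the receiving *water* is undetectable; bottom sediments, however, integrate
the discharge over decades through continuous sorption and deposition.
`aquaprog` is for radiological-assessment practitioners who want to check
how conservative the generic screening models actually are against sediment
monitoring data, with parameter uncertainty propagated honestly instead of
a single deterministic number.

## The model

For each nuclide *i* with decay constant λ (1/s), release rate *Q* (Bq/s):

- **Source term.** Five annual discharge values define a triangular
  distribution: `Q ~ Triangular(min, mean, max)` of the observed series.
- **Dispersion** (total water concentration, Bq/m³):
  - reservoir (well-mixed box at equilibrium): `C = Q / (q + λV)`;
  - river (plug flow, shore-dependent): `C = (Q/q) · exp(−λd/U)`, times the
    partial-mixing factor `√(L/d)` for same-shore receptors closer than the
    complete lateral mixing distance `L = 7B²/D`;
  - coast (lateral-Gaussian plume, shoreline reflection):
    `C = Q·e^(−λx/U) / (√(2π)·σ_y·D·U) · [e^(−(y−y0)²/2σ_y²) + e^(−(y+y0)²/2σ_y²)]`
    with `σ_y = α·x^(7/6)`.
- **Sediment** (Bq/kg dry): partition with `Kd` (L/kg, lognormal in
  freshwater) and suspended load `S_s`, then
  `C_bs = f_top · Kd·10⁻³ · C_dis · B(λ,T)` where
  `B(λ,T) = (1 − e^(−λT))/(λT)` is the 30-year build-up factor.
- **Comparison.** Modelled mean ÷ measured-range midpoint = conservatism
  ratio; verdicts `conservative` / `comparable` / `non_conservative` /
  `not_comparable` (below detection limit).
- **Fallout baseline.** `deposit · 2^(−t/T½) / (ρ·depth)` estimates the
  weapons-fallout Cs-137/Sr-90 background that discharge modelling cannot
  (and should not) explain.

Everything stochastic is driven by one root seed with per-(stage, nuclide)
sub-streams, so runs are bit-reproducible and extending a scenario never
perturbs existing results.

## Worked example

```r
library(aquaprog)
cfg  <- load_scenario(system.file("extdata", "scenario_almaraz.yml",
                                  package = "aquaprog"))
prog <- run_assessment(cfg)
print(prog)
#> Probabilistic sediment prognosis - Almaraz (lake scenario)
#>   10000 draws, seed 42; concentrations in Bq/kg dry sediment
#>  nuclide  receptor mean sd ci_lo ci_hi
#>    Co-60 Arrocampo   58 38   9.9   150
#>   Cs-137 Arrocampo  130 71  28.0   300

summary(prog, measured = cfg$measured)[
  c("nuclide", "receptor", "ratio_mean_mid", "verdict")]
#>   nuclide  receptor ratio_mean_mid      verdict
#> 1   Co-60 Arrocampo       2.239326 conservative
#> 2  Cs-137 Arrocampo       2.160515 conservative
```

The Co-60 row says: propagating the plant's triangular release-rate
distribution (39/54/66 Bq/s) through the reservoir box model and the
sediment model with lognormal Kd yields a mean of 58 Bq/kg dry sediment
with a wide 95% interval (9.9–150) dominated by Kd uncertainty; that mean
is ~2.2× the midpoint of the measured range (12–40 Bq/kg), i.e. the
screening model over-predicts about twofold — conservative, as intended.
The Cs-137 verdict is formally "conservative" too, but the measured range
there is dominated by global fallout, which is exactly what the fallout
baseline shows:

```r
sr <- load_nuclide_db()[["Sr-90"]]
fallout_baseline(400, sr, 47)   # 1960s deposit at 40°N, 47 y of decay
#> $deposit_now
#> [1] 129.0716
#> $concentration
#> [1] 1.985717
```

≈130 Bq/m² surviving today, i.e. ≈1.99 Bq/kg in a 5 cm soil layer of
density 1300 kg/m³ — right inside the measured coastal Sr-90 range
(1–3 Bq/kg), so those measurements are fallout, not plant discharge.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","aquaprog.R",package="aquaprog"))') \
    run inst/extdata/scenario_asco.yml --n 10000 --seed 42 --out results.csv
```

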