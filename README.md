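# soilmetals

Heavy-metal pollution, probabilistic human-health risk, and
natural-vs-anthropogenic source apportionment for **paired surface
(0–20 cm) and deep (150–200 cm) agricultural soils**, built for the
question that single-horizon surveys cannot answer: how much of the
anthropogenic metal burden has already migrated below the plough layer,
and what does surface-only monitoring consequently misattribute?

The package is aimed at environmental geochemists and risk assessors
working with paired-depth sampling campaigns of the eight canonical
metals (Cu, Zn, Ni, Pb, Cr, Cd, As, Hg). It implements, as tested and
reusable functions:

* **Pollution indices** — geoaccumulation index
  `I_geo = log2(Cn / 1.5·Bn)`, contamination factor `Cn/Bn`, Hakanson
  single-metal risk `Er = Tr·Cn/Bn` and cumulative `RI = ΣEr`, with
  layer-specific background registries and the standard classification
  scales (Er: 40/80/160/320; RI: 150/300/600/1200).
* **Health risk** — the USEPA four-pathway dose model (soil ingestion,
  dermal contact, dust inhalation, and crop food ingestion via
  bioconcentration factors), `HQ = ADD/RfD`, `HI = ΣHQ`,
  `CR = ADD·SF`, `TCR = ΣCR`, deterministically and by Monte Carlo
  (10,000 iterations; normal/triangular parameter distributions,
  empirical concentration resampling) for children and adults.
* **Source apportionment** — Pearson screening, KMO and Bartlett
  adequacy tests, PCA with varimax rotation (eigenvalue > 1
  retention), and a from-scratch positive matrix factorization solver
  minimizing the uncertainty-weighted objective
  `Q = Σ((x_ij − (GF)_ij)/u_ij)²` under nonnegativity, with
  detection-limit-based uncertainty matrices, multi-restart, and
  explicit resolution of the two-factor rotational ambiguity.
* **Synthetic study generator** — a two-source (natural,
  anthropogenic) paired-depth generator with known ground truth,
  calibrated to published regional summary statistics, so every
  estimator is validated by parameter recovery.

## Worked example

```r
library(soilmetals)

sim <- generate_soil_data(synthetic_config(n_sites = 72), seed = 1)
idx <- pollution_indices(sim$samples)
tapply(idx$ri, idx$layer, mean)
#>     deep  surface
#> 295.6931 389.9711
```

Mean cumulative ecological risk RI ≈ 390 in the surface layer —
"strong" on the Hakanson scale, driven almost entirely by Cd
(`igeo` between 2 and 3, i.e. moderate-to-heavy pollution) — versus
≈ 296 ("moderate") at depth.

```r
r <- monte_carlo_risk(sim$samples, "surface", "child",
                      n_iter = 10000, seed = 1)
round(r$summary, 2)
#>      mean   sd   p05   p50    p95
#> HI  55.96 25.8 18.96 53.29 102.64
#> TCR  0.01  0.0  0.00  0.01   0.01
```

The child hazard index far exceeds the 1.0 threshold; decomposing it
(`risk_contributions(r, "metal")`) attributes ~71% to As through the
food-ingestion pathway, with the caveat that absolute magnitudes
inherit the package's synthetic crop-transfer table.

```r
paired <- pair_layers(sim$samples)
X <- paired$deep
fit <- pmf_fit(X, build_uncertainty(X, delta = 0.1), k = 2,
               n_restarts = 20, seed = 1, mdl = detection_limits())
lab <- assign_factor_labels(fit)
round(lab$contributions["anthropogenic", ], 1)
#>    Cu    Zn    Ni    Pb    Cr    Cd    As    Hg
#>  53.8  39.2  44.0   0.0  43.6 100.0  28.4  52.1
```

Against the generator's truth these recoveries are accurate to a few
percentage points, and the surface/deep comparison
(`compare_layers()`) shows the deep-layer anthropogenic share of As
*rising* by ~7 points — the downward-migration signature the
paired-depth design exists to detect.

The same sequence, with all intermediate tables written under
`results/`, is scripted in `analysis/01_simulate.R` through
`analysis/05_report.R`; `run_pipeline()` performs the full run in one
call and emits a combined JSON + Markdown report.

## Registries

All scientific constants are editable plain-text configuration under
`inst/extdata/`: `background_guangdong.yaml` (layer-specific background
values), `detection_limits.yaml`, `toxicity_hakanson.yaml`,
`exposure_default.yaml` (point/normal/triangular specs per population),
`tox_reference.yaml` (RfD and slope factors per metal and pathway),
`bcf_synthetic.csv` (representative crop bioconcentration factors,
constructed), `reference_summary.csv` and `reference_profiles.csv`
(published regional tables).
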