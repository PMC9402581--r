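# corallux

Corallite-scale light capture and photosynthesis models for depth-generalist
corals.

Reef-building corals such as *Stylophora pistillata* thrive from bright
shallow reefs (~750 µmol photons m⁻² s⁻¹) down to light-starved mesophotic
depths (~45 µmol photons m⁻² s⁻¹), and colonies from the two zones build
distinct corallite-scale skeletons: shallow colonies have larger, deeper,
more tightly packed corallites; mesophotic colonies smaller, shallower, more
widely spaced ones. `corallux` is for coral ecophysiologists and tissue-optics
modellers who want to test, mechanistically, whether that micro-architecture
matters for light harvesting. It provides:

- **Parametric voxel geometry** — laterally periodic corallite-lattice tiles
  (skeleton, contracted tissue, seawater) built from ten morphometric traits
  (calyx diameter CD, theca height TH, septa SL/SW, columella CH, spine
  lattice SS/SPL/SPW, corallite spacing CSC/CSM), plus knock-outs
  (corallite, columella, spines) and trait exchanges between morphotypes.
- **Voxel Monte Carlo photon transport** (Rcpp kernel) — collimated normal
  incidence, per-medium absorption/scattering (µa, µs or µs′ in cm⁻¹),
  Henyey–Greenstein phase function sampled by inverse CDF,

  cos θ = (1 + g² − ((1 − g²)/(1 − g + 2gu))²) / 2g,

  Russian roulette, periodic lateral boundaries, track-length fluence
  estimation, and an exactly closing energy ledger.
- **Photosynthesis scoring** — the peaked P–E relation
  P = P_max · (E/E_opt) · exp(1 − E/E_opt) applied per tissue voxel at
  E = E0·Φ, summarized per tissue voxel.
- **A scenario engine** crossing morphotypes × irradiances × six bio-optical
  scenarios × P–E sets × structural variants into a tidy results table.
- **Synthetic morphometrics + statistics** — a two-depth-group trait-table
  generator (colony random effects, replicate lognormal noise, counter-based
  seeding) and the matching inference: colony-blocked permutation tests,
  PCoA, PERMANOVA (with exhaustive enumeration), SIMPER, Pearson structure —
  all tibble-in / tibble-out with `tidy()`/`glance()`/`autoplot()` support.

## Worked example

```r
library(corallux)

shallow <- build_tile(shallow_params())      # 2x2-corallite tile @ 0.02 mm
shallow
#> <label_volume> 156 x 156 x 96 voxels @ 0.02 mm (3.12 x 3.12 x 1.92 mm)
#>   water 21.5% | tissue 8.0% | skeleton 70.5%

surface_metrics(shallow)
#>   surface_area rugosity tissue_volume porosity
#> 1         16.9     1.74          1.50        0
surface_metrics(build_tile(mesophotic_params()))
#>   surface_area rugosity tissue_volume porosity
#> 1         11.0     1.32         0.690        0
```

The shallow tile is ~1.3× more rugose than the mesophotic one (more
self-shading surface per planar area) and carries twice the tissue volume,
most of it as the polyp plug inside the calyx.

```r
fl <- run_mc(shallow, optical_properties(),
             transport_config(n_photons = 1e5, seed = 1))
fl
#> <fluence_volume> 156 x 156 x 96 @ 0.02 mm, 100000 photons (seed 1)
#>   escaped: top 0.4913 other 0.4599 | absorbed: water 0.0001, tissue 0.0459,
#>   skeleton 0.0028 | roulette net 0.00e+00
```

Under the default optics (tissue µa 1.18, µs′ 10; skeleton µa 0.01, µs′ 15
cm⁻¹; g = 0.9) about half the incident light is backscattered out the top,
and under 5% is absorbed in tissue — the highly scattering, barely absorbing
skeleton dominates the light field.

```r
pe <- pe_defaults()
score_volume(fl, shallow, pe$mesophotic, E0 = 45)$summary   # low light
#> [1] 0.943
score_volume(fl, shallow, pe$shallow, E0 = 750)$summary     # high light
#> [1] 0.0903
```

At 45 µmol photons m⁻² s⁻¹ the tissue sits near the P–E optimum (mean score
0.94 of P_max); at 750 the same architecture is photoinhibited (0.09).

The morphometric side:

```r
tab <- generate_trait_table(trait_generator_spec(seed = 1))   # 2 x 15 colonies
summarize_by_group(tab)[, c("trait", "percent_diff")]         # shallow vs meso
#> CD +51.7%, CSM -36.7%, porosity -47.6%, ...
trait_permanova(tab, n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F = 56.19, p = 0.001 (999 permutations)
```

Scenario matrices run through one call:

```r
specs <- default_scenario_ledger(seeds = 1:3)   # 88 runs per seed
res <- run_scenario_matrix(specs, transport = transport_config(n_photons = 1e6))
autoplot(res)
```

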