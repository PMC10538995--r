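# fiberredox

Fiber-type-specific redox autofluorescence analysis of skeletal muscle
cross-sections.

## What this package is for

Skeletal muscle metabolism can be read optically: reduced NADH
autofluoresces under UV excitation (340–360 nm) and oxidized
FAD-containing flavoproteins (Fp) under blue excitation (440–470 nm).
The balance between the two — the optical redox ratio

```
redox ratio = Fp / (Fp + NADH)        ∈ [0, 1], higher = more oxidized
```

differs between myofiber types (slow-oxidative MHC I, fast-oxidative
MHC IIa, fast-glycolytic MHC IIx) and shifts with exercise. `fiberredox`
turns multichannel section images into per-fiber redox records and
section-level morphometrics, and models them across fiber type and time:

* **Fiber typing** — watershed segmentation of myofibers and rule-based
  MHC classification: MHC I+/IIa− → type I, I−/IIa+ → IIa, double
  negative → IIx, double positive → hybrid (excluded from all analyses).
* **Redox quantification** — background-subtracted per-fiber NADH/Fp
  intensities (saturation-flagged), per-fiber redox ratios, NADH
  calibration-series fitting, collagen stained-area fraction.
* **Capillarization** — capillary detection, contact graphs, capillary
  density (CD), capillary-to-fiber ratio (C:F), capillary contacts (CC),
  sharing factor (SF = CC/C:F), CC per fiber area, and O₂ diffusion
  distances from the distance transform (distance within which 95 % /
  50 % of each fiber's area is served by a capillary).
* **Inference** — linear mixed models (`value ~ time + fiber_type +
  (1 | subject)`), Tukey-adjusted pairwise contrasts on estimated
  marginal means with percent-difference reporting, exercise deltas,
  Spearman correlations.
* **Cohort QC** — Goldberg/Black dietary-plausibility cutoffs (EI:BMR)
  and HOMA-IR.
* **Simulation** — a synthetic-section generator (Voronoi-tessellated
  fibers, planted types/intensities/capillaries/nuclei, Gaussian noise)
  and a cohort generator, both returning planted ground truth, so every
  stage of the pipeline is testable without any imaging data.

Intended users: muscle physiologists and image analysts quantifying
fiber-specific redox state, mitochondrial markers (SDHA/CS flow through
the same per-fiber intensity operation) or capillarization from
immunofluorescence/histology sections.

## Worked example

Simulate a section, run the full image pipeline, and model a cohort:

```r
library(fiberredox)

sec <- generate_section(section_params(seed = 42))
fib <- segment_fibers(sec$channels$mhc1, sec$channels$mhc2a,
                      hint = sec$channels$fp) |>
  classify_fibers(sec$channels$mhc1, sec$channels$mhc2a) |>
  quantify_redox(sec$channels$nadh, sec$channels$fp)
summarise_by_type(fib)
#>   type  n_fibers  nadh    fp redox_ratio area_um2
#> 1 I           22  520.  500.       0.490    3545.
#> 2 IIa         17  510.  420.       0.451    2846.
#> 3 IIx          3  418.  300.       0.418    3902.
```

Type I fibers are the most oxidized (ratio 0.490), IIx the least
(0.418), reproducing the expected stepwise ordering; hybrids and
border-clipped fibers are excluded automatically.

```r
caps  <- detect_capillaries(sec$channels$cap)
panel <- capillary_panel(fib, build_contact_graph(fib, caps),
                         nuclei = nuclei_count(sec$channels$dapi))
#>   capillary_density cf_ratio   cc sharing_factor max_dd_um avg_dd_um
#> 1            521.44     2.47 4.61           1.87     38.09     23.63
```

The C:F ratio of ~2.5 and diffusion distances of ~38/24 µm are the
section's capillary supply metrics; SF × C:F = CC holds exactly.

```r
sim <- generate_cohort(seed = 42)   # 19 subjects x 3 timepoints x 3 types
fit <- fit_redox_lmm(sim$data)
pairwise_contrasts(fit, "fiber_type")
#>   contrast  estimate percent_difference pd_ci_low pd_ci_high p_adjusted
#> 1 I - IIa     0.0305               6.70      5.30       8.11   3.40e-14
#> 2 I - IIx     0.0637              15.1      13.6       16.6    2.31e-14
#> 3 IIa - IIx   0.0332               7.89      6.38       9.40   2.42e-14
```

This cohort was simulated with type I planted 7.2 % above IIa and IIa
8.0 % above IIx on the ratio scale; the Tukey-adjusted contrasts recover
those differences (6.70 % and 7.89 %) with 95 % CIs covering the truth.

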