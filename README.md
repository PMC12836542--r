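# tumouroidr

Non-destructive, continuous quantification of patient-derived tumouroid
(PDT) growth and chemotherapeutic response from time-lapse well-plate
imaging.

PDTs are 3D cultures grown from tumour biopsies in gel droplets and used
for ex vivo drug testing. Instead of destructive endpoint viability assays,
this package quantifies growth from brightfield/confocal Z-stack images
taken repeatedly over the same wells:

1. **Best-focus projection** — each Z-stack collapses to one 2D image by
   copying, per tile, the plane maximizing the variance of the discrete
   Laplacian (objects sit at different depths in the gel).
2. **Segmentation** — an image-specific global threshold
   (`background mode − k · robust spread`, affine-invariant), hole
   filling, 8-connected particle extraction, debris filtering, and
   morphometrics in physical units (area, perimeter, equivalent diameter,
   circularity `4πA/P²` clamped to [0, 1]).
3. **Seven per-well readouts over time** — total covered area, **relative
   total area** (each well divided by its own first-day value — the
   primary growth readout), object count, and per-object mean size,
   diameter, perimeter, circularity; replicate summaries as mean ± SEM.
4. **Dose-response modelling** — treated wells normalized to the vehicle
   control mean, then fitted per sample/day/readout with a five-parameter
   log-logistic model

   y(x) = c + (d − c) / (1 + exp(b · (ln x − ln e)))^f

   with closed-form **ED50** = e·(2^(1/f) − 1)^(1/b) (midpoint of the
   fitted span) and **GI50** (dose where the curve crosses 0.5 of
   control), plus sensitivity rankings under maximal inhibition, ED50 and
   GI50 side by side.

A synthetic plate simulator (`simulate_plate`) renders growing, partially
overlapping dark disks across defocus-blurred Z-planes with known ground
truth (geometry, growth rates, Hill dose-response), so every stage is
testable without real microscopy data. See the methods vignette
(`vignettes/tumouroid-quantification.Rmd`) for the model details and design
rationale.

## Worked example

Simulate a small screening plate (6 doses of SN-38 including vehicle,
2 replicate wells, imaging days 1/5/9, treatment days 2–9, true IC50
10 nM), quantify it, and fit dose-response models:

```r
library(tumouroidr)

base <- file.path(tempdir(), "demo_plate")
sim <- sim_config(image_size = c(192L, 192L), n_planes = 3L, n_objects = 4L,
                  days = c(1, 5, 9), n_replicates = 2L, noise_sd = 0.02,
                  min_separation = 150, rng_seed = 1L)
simulate_plate(sim, dir = base)   # writes TIFF stacks + plate_map.csv

cfg <- run_config(stacks_dir = base,
                  plate_map = file.path(base, "plate_map.csv"),
                  output_dir = file.path(base, "out"),
                  pixel_size = 3, tile_size = 16)
res <- quantify_plate(cfg)
head(res$per_well[, c("well_id", "concentration_nM", "day", "total_area_um2",
                      "relative_total_area", "count", "mean_diameter_um",
                      "mean_circularity")], 6)
#>   well_id concentration_nM day total_area_um2 relative_total_area count
#> 1      A1                0   1          20250               1.000     4
#> 2      A1                0   5          37611               1.857     4
#> 3      A1                0   9          70236               3.468     4
#> 4      B1                0   1          24372               1.000     4
#> 5      B1                0   5          45495               1.867     4
#> 6      B1                0   9          84753               3.477     3
#>   mean_diameter_um mean_circularity
#> 1            79.57           1.0000
#> 2           108.44           1.0000
#> 3           148.16           1.0000
#> 4            87.56           1.0000
#> 5           119.63           0.9954
#> 6           187.25           0.8921
```

Vehicle wells roughly triple their covered area by day 9 (relative total
area ≈ 3.5, anchored at exactly 1 on day 1); two tumouroids in well B1
merge by day 9, dropping the count to 3 and the mean circularity below 1 —
the expected behaviour of threshold-based particle analysis on dense
cultures.

```r
fits <- fit_plate(cfg)
fits$fits[["S1/9/relative_total_area"]]
#> Five-parameter log-logistic dose-response fit
#>    10 points at 5 concentrations; converged
#>       b       c       d       e       f
#>  0.7966  0.3376  1.0073 11.6745  1.5990
#>   rss: 0.002585  ed50: 5.42 nM  gi50: 18.22 nM
```

Under the simulated growth model the day-9 response at dose *c* is
`exp(−2·g·t_treat·I(c))` with inhibition `I` at true IC50 10 nM, which
crosses 50% of control near 16 nM and its own fitted midpoint near 5.5 nM —
both recovered by the fit (GI50 18.2 nM, ED50 5.4 nM) from only 10 noisy
points.

A thin command-line wrapper over the same functions ships in
`inst/cli/tumouroidr` (subcommands `simulate | quantify | fit | report`).

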