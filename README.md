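# nanoheat

Plasmonic nanoparticles convert near-infrared light into heat and are
candidate agents for photothermal cancer therapy: they accumulate in
tumors, and irradiation through tissue then ablates the surrounding
cells. Choosing *which* particle to inject requires comparing candidates
across very different scales — electromagnetic theory, single-particle
heating, and in vivo treatment response. `nanoheat` implements that
comparison platform for R users:

* **optics** — analytic Mie absorption/scattering/extinction
  cross-section spectra for solid gold spheres and silica-core
  gold-shell nanoshells in water, with stable recurrences for the
  strongly absorbing metal (no FEM needed);
* **footprint** — extraction of the melted-footprint radius `D_m` from
  fluorescence images of a supported lipid bilayer around an irradiated
  particle (centroid → rotational average → 50% threshold);
* **thermometry** — the point-source heating relation
  `ΔT(D) = C·I/D`: fitting `C` from footprints (at the melting boundary
  `ΔT(D_m) = T_m − T_ambient`), surface temperatures `ΔT_P = C·I/R`,
  and the experimental absorption cross-section
  `C_abs = 4π·k·R·ΔT_P/I = 4π·k·C`;
* **pet_response** — the early-response statistic for FDG-PET tumor
  volumes: the low-uptake volume `V_low` below the ROI mean − 1.5 SD of
  %ID/g, normalised per animal to baseline;
* **synthetic generators** — seeded, ground-truthed footprint frames,
  heating series and PET phantoms, so every estimator is testable end
  to end.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for result types.

## Worked example

Rank the three study particles (150 nm nanoshell, 150 nm and 80 nm
solid gold spheres) as heaters at the 807 nm therapy wavelength:

```r
library(nanoheat)

bench <- run_benchmark(
  list(particle_nanoshell(), particle_solid_gold(150),
       particle_solid_gold(80)),
  wavelengths_nm = c(807, 1064))
bench
#> <nanoheat_benchmark> 3 particle(s), ranked by C_abs at 807 nm
#>  rank   particle wavelength_nm C_abs_nm2 C_sca_nm2 C_ext_nm2 R_nm
#>     1 AuNS_150nm           807   13790.0  102900.0    116600   75
#>     2 AuNP_150nm           807    2455.0   45300.0     47760   75
#>     3  AuNP_80nm           807     236.5     803.6      1040   40
```

The nanoshell absorbs ~5.6× more than the equal-size solid sphere at
807 nm (~3× at 1064 nm), and the 80 nm sphere sits an order of
magnitude below the 150 nm one — the ordering that drives the in vivo
outcome.

Single-particle thermometry on synthetic frames with known truth
(`C_true = 5.38e-16 K·m³/W`, Gaussian noise):

```r
sim <- make_footprint_series(
  C_true = 5.38e-16, intensities_W_cm2 = c(1.5, 2.2, 3.0) * 1e6,
  scene = footprint_scene(noise = "gaussian", noise_sd = 5, seed = 7))
fps <- dplyr::bind_rows(lapply(sim$frames, analyze_frame))
fit <- fit_C(fps, thermal_environment(), R_nm = 75)
cross_section_from_model(fit)
#> [1] 5724 5755 5767        # nm^2, from C_abs = 4*pi*k*C
surface_temperature(fit, fps$intensity_W_cm2)
#> # A tibble: 3 × 3
#>   dT_surface_K T_surface_C saturated
#> 1         107.        133. FALSE
#> 2         157.        184. FALSE
#> 3         215.        241. TRUE
```

The footprint radius grows linearly with laser intensity, each frame
returns the same heating constant to better than 1%, and the hottest
point is flagged: above ~240 °C the linear point-source model is an
extrapolation.

PET response on a scripted treated animal (50 mm³ necrotic core at
baseline, +100 mm³ ablation lesion at day 0):

```r
pair <- make_treatment_pair(seed = 2)
base <- low_uptake_volume(pair$baseline$volume, pair$baseline$roi)
day0 <- low_uptake_volume(pair$day0$volume, pair$day0$roi)
relative_change(day0, base)
#> [1] 2.9                   # the low-uptake volume triples
```

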