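# spinetrack

Offline software core of a biomechanical spine-testing rig, as an R
package. A vertebral specimen is loaded stepwise in seven modes —
flexion, extension, left/right lateral bending, left/right axial torsion
and axial compression — while strain gauges record the applied force and
cameras watch markers fixed to the vertebrae. spinetrack implements
everything downstream of the hardware, for biomechanics labs that want
the analysis chain to be scriptable, seeded and testable:

* **Synthetic fixtures** — seeded pseudo-speckle targets of a given
  brightness SD, marker-disc scenes with exactly known centers, rigid
  sub-pixel image shifts, noisy strain-gauge tables and linear-specimen
  load protocols (`gen_speckle()`, `gen_disc_scene()`, `shift_image()`,
  `gen_gauge_data()`, `simulate_load_steps()`).
* **Marker-disc tracking** — Sobel edge enhancement, inclusive band
  thresholding, morphological opening, 8-connected centroid search and
  greedy nearest-neighbour track assembly (`detect_discs()`,
  `assemble_tracks()`).
* **Pseudo-speckle displacement** — sub-pixel planar displacement from a
  before/after image pair by Fourier fringe analysis
  (`measure_displacement()`).
* **Gauge calibration** — closed-form least-squares voltage-to-force
  fits with an error audit (`fit_linear()`, `calibration_error()`).
* **Instant rigidity** — per-step load/deformation ratios for all seven
  modes, stepwise averaging, repeat summaries and intact-vs-treated
  normalization (`run_protocol()`, `normalize_to_intact()`).

## The two measurement principles

**Instant rigidity.** Each load step yields a stiffness reading directly:
compression `R_c = F / Δl` (N/mm); torsion and bending through a lever
arm use either the angle form `F·r/φ` (Nm/rad) or, when a camera measures
the arm-tip shift `d` instead of an angle, the shift form `F·r/d`
(Nm/mm). A protocol repeats the sequence (10× by default) and reports
mean ± SD per mode; a treated (e.g. implant-stabilized) specimen is
expressed as a percentage of the intact one.

**Fourier fringes.** For motions of a few pixels, a random
pseudo-speckle target is imaged before and after the motion. If the
second frame is the first shifted by **d**, the power spectrum of the
frame *sum* is modulated by `1 + cos(2π u·d / N)` — interference strips
perpendicular to **d**, spaced `N/|d|` frequency bins apart. The strip
density gives the shift magnitude, the strip pitch its direction, and a
cross-correlation probe recovers the sign that summation destroys.
spinetrack extracts the strips cepstrally (second FFT of the log
spectrum) with sub-bin refinement; recovery on σ = 50 speckle is well
inside 0.5 px and 3° across the 3–32 px working range.

## Worked example

```r
library(spinetrack)

# a speckle target shifted 4 px right and 4 px down (0.05 mm/px optics)
a <- gen_speckle(256, sigma = 50, seed = 1)
b <- shift_image(a, 4, 4)
measure_displacement(a, b, mm_per_px = 0.05)
#> displacement: 5.626 px @ 45.01 deg (sign resolved)
#>   0.2813 mm
#>   fringe contrast 0.191, period 45.50 bins

# gauge calibration and its error audit on held-out loads
cal <- fit_linear(gen_gauge_data(0, 100, seq(0, 2, 0.1), noise_sd = 0.5, seed = 2))
cal
#> Strain-gauge calibration (least squares)
#>   force = -0.0354945 + 100.178 * voltage   [N; N/V]
#>   n = 21, residual SD = 0.5588 N, R^2 = 0.999923
calibration_error(cal, data.frame(voltage = seq(0.2, 2, 0.2),
                                  force = 100 * seq(0.2, 2, 0.2)))
#> [1] 0.1610334

# instant rigidity of a synthetic specimen, intact vs stabilized
intact <- run_protocol(rbind(
  simulate_load_steps("flexion", 2.5, seq(40, 100, 20), arm_m = 0.15, seed = 1),
  simulate_load_steps("compression", 90, seq(40, 100, 20), seed = 2)),
  arms = c(bending = 0.15, torsion = 0.2))
intact
#> Instant rigidity by loading mode
#> flexion           2.495 +/- 0.0274 Nm/mm (10 repeats)
#> compression       89.79 +/- 2.03 N/mm (10 repeats)
```

The true shift above is `(4, 4)`: magnitude `sqrt(32) = 5.657` px at
45°, measured as 5.626 px at 45.01°. The calibration recovers the
programmed 100 N/V law to 0.2 % and the audit reports the worst relative
force error over the held-out loads. The rigidity protocol recovers the
programmed stiffnesses (2.5 Nm/mm, 90 N/mm) within the 2 % displacement
noise of the simulated readout; `normalize_to_intact()` then tabulates a
treated specimen as a percentage of these means.

A command-line front end wrapping the same functions ships in
`inst/cli/spinetrack.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spinetrack.R", package = "spinetrack"))')
Rscript $CLI simulate speckle --out sim
Rscript $CLI displace --before sim/speckle.png --after sim/speckle_shifted.png --out disp.json
Rscript $CLI track --frames 'frames/*.png' --out tracks.csv
Rscript $CLI run --config run.json --out report/
```

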