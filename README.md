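# aliprint

Quantitative analysis of droplet-based bioprinting (DBB) of airway
epithelial cells and the air–liquid-interface (ALI) cultures they form.

Droplet bioprinting deposits cell-laden culture medium pass by pass onto
Transwell inserts; after submerged and ALI culture the cells differentiate
into a pseudostratified, ciliated, mucus-producing epithelium. Judging
such a tissue model requires a battery of quantitative readouts, and this
package implements them as tested, reusable functions:

* **Printability** — the dimensionless-number profile of the bioink/jet
  configuration: Ohnesorge `Oh = η/√(γρL) = √We/Re = 1/Z`, Weber
  `We = ρU²L/γ`, Reynolds `Re = ρUL/η`, Froude `Fr = U/√(gL)`, Bond
  `Bo = ρgL²/γ` and the splashing parameter `K_sp = √(We√Re)`, with the
  regime flags `Bo < 1` (gravity negligible) and `K_sp ≥ 57.7`
  (splashing). Gravimetric droplet sizing and velocity estimation
  included.
* **Ciliary beat frequency** — FFT estimation from ROI intensity traces
  of high-speed recordings (detrend, Hann window, band-limited peak with
  quadratic refinement), plus the cycle-counting route and group-median
  summaries.
* **Tight junctions** — ZO-1 peak-to-peak spacings from fluorescence
  line profiles, with a line-intercept (stereology-corrected) cell
  diameter estimator.
* **Image quantities** — marker area fractions (percent-of-field and per
  10⁵ µm² conventions), LIVE/DEAD viability via blob counting, and
  flow-style DAPI×GFP histocytometry gating.
* **Barrier function** — blank-subtracted, area-normalized TEER
  (Ω·cm²) time courses and FITC-dextran flux-rate regression.
* **Seeding plan** — the pass-number → cell-dose bookkeeping
  (2200 cells/insert/pass).
* **Synthetic data** — seeded `gen_*` generators with ground truth for
  every input above, so each analysis is validated by parameter recovery
  without any real microscopy data.

## Worked example

```r
library(aliprint)

spec <- water_like_medium(droplet_velocity = 2)  # 250 um nozzle
printability_profile(spec)
#> Dimensionless printability profile
#>   Oh       0.0074199
#>   We          13.709
#>   Re             499
#>   Fr          40.386
#>   Bo       0.0084052
#>   Z           134.77
#>   K_sp        17.499
#>   gravity negligible (Bo < 1):   TRUE
#>   splashing (K_sp >= 57.7):      FALSE
```

`Bo ≈ 0.0084` says gravity is irrelevant to droplet spreading at this
nozzle scale; `K_sp ≈ 17.5 < 57.7` says impacts deposit without
splashing — the configuration prints cleanly.

```r
# ciliary beat frequency: simulate a 10 s, 100 fps recording beating at
# 8.83 Hz and recover it
g <- gen_cilia_trace(f0 = 8.83, frame_rate = 100, n_frames = 1024,
                     snr = 5, seed = 42)
cbf_fft(g$trace, band = c(1, 20))
#> CBF estimate: 8.831 Hz (fft; band 1-20 Hz; peak power fraction 0.95)

# pass-number dosing plan
dosing_table()
#>   passes  cells est_print_time_min fraction_of_manual
#> 1     10  22000                  2                0.1
#> 2     20  44000                  4                0.2
#> 3     30  66000                  6                0.3
#> 4     40  88000                  8                0.4
#> 5     50 110000                 10                0.5
```

The recovered 8.831 Hz is within a hundredth of a spectral bin of the
simulated beat frequency; the dosing table shows printed doses spanning
one-tenth to one-half of the 2.2 × 10⁵-cell manual-seeding benchmark.

## Analysis workflow

The `analysis/` directory holds numbered narrative drivers, each a thin
script over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_printability.R         # dimensionless profile, droplet sizing
Rscript analysis/02_seeding_plan.R         # pass-number dosing table
Rscript analysis/03_cbf.R                  # CBF recovery per condition group
Rscript analysis/04_image_quantification.R # junctions, areas, viability, gating
Rscript analysis/05_barrier_function.R     # TEER time course, dextran flux
```

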