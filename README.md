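# neofront

Radiocarbon front tracking and summed-probability demography.

Large radiocarbon datasets carry two entangled signals about the spread of
farming: the *dynamics* of the dispersal (where the front was, and when it
moved) and the *demography* behind it (whether regional population proxies
deviate from the local forager trend when farming arrives). `neofront`
implements a pipeline that reads a date table (lab code, conventional
radiocarbon age, error, site coordinates, period label), and then:

1. **calibrates** every date against a tabulated calibration curve using
   the standard intercept-free Gaussian model — mass at calendar year *t*
   proportional to the normal density of CRA about μ(t) with variance
   σ²_lab + σ²_curve(t) — and stores the density mode;
2. **tracks the front** as a series of cumulative convex hulls of the
   Neolithic points at 100-year steps over 12,000–4,000 cal BP, detects
   **dispersal pulses** from the hull-area dynamics (fractional-growth
   threshold with pause lengths), and partitions the study area into an
   origin polygon plus one ring per pulse, optionally split along
   cultural border lines;
3. builds site-phase binned **Summed Probability Distributions** (SPDs)
   per region, with per-bin or unit-area rescaling, an optional power-law
   taphonomic correction, and exponential growth-rate fits
   *C e^(−rt)* with bootstrap standard errors;
4. runs a **Monte-Carlo significance test** of each region's observed SPD
   against an exponential null fitted to the region's *Mesolithic record
   only*, up to the local Neolithization date: a seeded ensemble of
   simulated SPDs (drawn through the curve with resampled laboratory
   errors) yields a pointwise 95% envelope, significance intervals and a
   rank-based global p-value;
5. ships a ground-truthed **synthetic wave-of-advance generator**
   (forager background, pulsed radial front, three demographic regimes:
   carrying-capacity boost at the origin, staggered colonist boom-bust,
   and adoption with no demographic deviation) so every stage is
   validated by parameter recovery without any external database.

The intended users are archaeologists and quantitative-prehistory
researchers working with `rcarbon`/`Bchron`-style tooling who need the
dispersal-defined regionalisation and the Mesolithic-anchored null in one
tested, seeded pipeline.

## Worked example

A complete run on a generated three-regime world:

```r
library(neofront)

crv <- toy_curve()
calibrate(6130, 40, crv)
#> <cal_density> CRA 6130 +/- 40; mode 6152 cal BP; support 5957-6313 cal BP

w <- generate_world(three_regime_config(seed = 7))
w
#> <synthetic_world> seed 7: 2251 dates (578 Mesolithic, 1673 Neolithic)
#> across 602 sites, 4 rings

rr <- regime_report(w, n_sim = 500, seed = 1007)
rr$pulses[, c("start", "end", "growth")]
#>   start  end    growth
#> 1  9800 9200 6.4022161
#> 2  8800 8100 2.0928659
#> 3  7200 6900 0.5104227
rr$regions[, c("label", "pulse", "n_bins", "p", "predicted", "truth")]
#>   label pulse n_bins           p predicted truth
#> 1    R0     0    252 0.001996008         1     1
#> 2    R1     1     91 0.001996008         2     2
#> 3    R2     2    190 0.001996008         2     2
#> 4    R3     3    640 0.097804391         3     3
```

Reading the output: three dispersal pulses are detected from the
hull-area series (start/end in cal BP; `growth` is the total relative
area gain of the episode). Each recovered region is then tested against
its own Mesolithic null: the origin region `R0` deviates persistently
(regime 1, the carrying-capacity boost), the two colonist rings show
significant transient booms in pulse order (regime 2; p-values sit at the
floor 1/(n_sim+1) ≈ 0.002 of the rank statistic), and the dense-forager
outer ring shows no significant deviation (regime 3, p = 0.098) — all
matching the generator's ground truth.

On real data the same stages are driven from files via `run_config()` +
`run_calibrate()` / `run_front()` / `run_test()` (CSV date table,
IntCal-dialect curve file, optional GeoJSON split lines; outputs are CSV,
GeoJSON and JSON with a manifest recording every setting and seed), or
from the shell through the thin wrapper in `inst/cli/neofront.R`.

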