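---
title: "Front tracking and summed-probability demography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Front tracking and summed-probability demography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofront)
```

`neofront` infers two linked things from a large radiocarbon date table:
the spatio-temporal *dynamics* of an expanding settlement front (where and
when dispersal pulses happened) and the *demography* behind it (whether
regional date densities deviate from the local forager trend when farming
arrives). This vignette explains the models, the tunable parameters and
their defaults, the synthetic world the package validates itself against,
and the known limitations.

## Calibration

A laboratory reports a conventional radiocarbon age (CRA) with a 1-sigma
error. A calibration curve tabulates the expected radiocarbon age
$\mu(t)$ and its own error $\sigma_c(t)$ at each calendar age $t$ (cal BP,
years before 1950; larger is older). We use the standard intercept-free
Gaussian model: the unnormalised posterior mass at calendar year $t$ is

$$w(t) \propto \exp\!\left(-\tfrac12
  \frac{(\mathrm{CRA}-\mu(t))^2}{\sigma_{lab}^2+\sigma_c(t)^2}\right)
  \Big/ \sqrt{\sigma_{lab}^2+\sigma_c(t)^2},$$

normalised to total mass 1 on a 1-year calendar grid (tabulated curves are
linearly interpolated to that grid). Choices worth stating:

* **Grid step 1 yr.** Mode extraction feeds the 100-yr hull stepping, so
  the grid must resolve far below 100 yr; 1 yr is cheap and exact.
* **Support truncation.** The stored support is the smallest contiguous
  window holding at least $1-10^{-5}$ of the mass, then renormalised.
  The constant bounds memory without affecting any downstream statistic at
  the tolerances used anywhere in the package.
* **Mode ties.** The date's point summary is the maximum-mass year; exact
  ties (radiocarbon plateaus) are broken toward the older year, so front
  tracking sees a deterministic earliest arrival.
* **Uncalibration.** Simulated dates draw
  $\mathrm{CRA} \sim N(\mu(t), \sigma_{lab}^2+\sigma_c(t)^2)$ — the curve
  error enters in this single draw and is *not* added again when the
  simulated date is recalibrated, which would double-count it.

A small C++ kernel evaluates exactly this model in batch for the
Monte-Carlo machinery; the R implementation is the reference and the test
suite asserts the two agree to numerical precision.

## Front tracking

For every 100-yr boundary $\tau$ from 12,000 to 4,000 cal BP the package
builds the convex hull of all Neolithic-labelled points with mode age
$\geq \tau$. The point sets are cumulative, so hulls are nested and areas
non-decreasing: the series $A(\tau)$ traces the area ever occupied.
Geometry runs in kilometres on a Lambert azimuthal equal-area plane
centred on the point cloud; at continental scale the planar shoelace area
then equals the spherical area to well under a percent, which the tests
verify against an independent spherical-excess computation.

**Pulse detection.** $A(\tau)$ is scanned forward in time with a
per-step fractional growth threshold (`growth_frac`, default 0.05) and a
pause length (`pause_len`, default 2 steps): a pulse opens at the first
super-threshold step following a full pause and closes when growth stays
sub-threshold for a full pause. Because a growth observed at boundary
$\tau$ means the front moved during $(\tau+100, \tau]$, the reported
start is the older boundary — the date the frontier is first trespassed.
Two guards make the heuristic robust on noisy records: growth before the
first pause (the initial establishment of the founding area) is never
scored, and episodes whose total relative growth stays below
`min_total_growth` (default 0.15; every genuine ring in a radially
expanding world adds 25–80%) are discarded as single-site stragglers.

**Regionalisation.** The origin region is the hull at the first pulse's
start; ring $k$ is the hull at the end of pulse $k$ minus the hull at the
end of pulse $k-1$. Nested hulls make every ring an outer convex polygon
with one convex hole, so the partition is exact by construction: the
tests assert the region areas sum to the final hull area to $10^{-6}$
relative. Cultural splits bisect a region by the line through the ends of
a user-supplied polyline; both the outer polygon and the hole are clipped
by the two half-planes, preserving the partition invariants. Points on
shared boundaries are assigned to the earlier-pulse region — the front
defines first arrival — and sliver fragments below 1 km² are dropped.

## Summed probability distributions

Dates from one site whose CRAs chain with gaps $\leq h$ (default
$h = 200$ ¹⁴C yr) form one site phase; each phase contributes the
arithmetic mean of its members' calibrated densities, so a raw SPD has
total mass equal to the number of site phases and intensively dated sites
do not dominate. SPDs can be rescaled per bin or to unit area for
cross-region comparison.

**Taphonomic correction** divides the density by the power-law survival
curve $n(t) = 5{,}726{,}442\,(t+2{,}176.4)^{-1.3925309}$ and renormalises
to preserve total mass; because survival decays with age the correction
shifts mass toward older years, lowering fitted growth rates.

**Growth rates** come from nonlinear least squares of
$C e^{-r t}$ against the SPD (in cal BP, so $r>0$ is growth toward the
present), with log-linear start values. NLS on the raw curve avoids the
bias a log-linear regression picks up from near-zero cells. The standard
error resamples site phases with replacement (200 refits by default).
Windows adjacent to the chronological brackets are excluded from fits by
an `edge_margin` (default 300 yr): densities there are truncated by the
bracket filter, which otherwise biases the slope.

## The Monte-Carlo SPD test

The demographic null for a region is the exponential trend of its
*Mesolithic* record only, fitted up to the local Neolithization date
(by default the mode of the region's oldest Neolithic date, overridable
by the pulse start the partition provides). Each of `n_sim` simulations
(default 1000; the validation studies use 500) draws the observed number
of site phases from that exponential over the test window, uncalibrates
and recalibrates each through the curve with laboratory errors resampled
from the observed pool, and sums them as singleton phases. Each simulated
SPD is scaled to the observed total mass — the test compares *shapes*,
not absolute date counts — and the pointwise 2.5%/97.5% quantiles form
the 95% envelope.

The global p-value standardises the observed and every simulated SPD by
the ensemble mean and standard deviation; the statistic is the total
standardised mass outside the pointwise 95% band, both tails entering
symmetrically (whether excursions below the envelope should weigh equally
is genuinely ambiguous in the surrounding literature; the symmetric
two-sided statistic is the conservative reading, and the direction of
every excursion is reported separately). The p-value is the +1-corrected
rank among the simulations, so it is never zero and is bounded below by
$1/(n_{sim}+1)$. Grid points with zero ensemble variance carry no
information and are excluded. No automated false-positive remover is
applied: at $\alpha = 0.05$ about 5% of true nulls will appear
significant, and the package's own calibration study (below) measures
exactly that rate rather than patching it heuristically.

## The synthetic wave-of-advance world

Because the kind of database this method targets is not shippable, the
generator builds ground-truthed worlds in which every stage is checkable:

* a founding disc (default 300 km around 35°E 36°N, farmed from 11,700
  cal BP) and six expansion pulses between 10,900 and 6,000 cal BP with
  speeds in 0.5–2.5 km/yr, separated by pauses of at least 400 yr;
* forager sites at regime-dependent density growing at 0.03 %/yr, a rate
  in the range reported for Holocene forager populations; farming
  populations in regime-1 rings grow at 0.05 %/yr;
* three demographic regimes per ring: a persistent carrying-capacity
  boost (×2.5) at and around the origin (regime 1); colonist booms (×6,
  relaxing over 300 yr after the front departs) over a sparse forager
  background (regime 2); and adoption by a dense forager network whose
  date intensity continues unchanged across arrival (regime 3);
* measurement: laboratory errors uniform on 20–120 ¹⁴C yr (the dataset
  filter caps at 150; a configurable fraction of oversized errors
  exercises it), CRAs drawn through a monotone toy curve (identity plus a
  25-yr-amplitude, 900-yr-period wiggle).

Two record-formation mechanisms are modelled explicitly because front
tracking depends on them: colonist sites carry a founding-phase cluster
of dates 60–140 yr after first arrival (pioneer contexts are
preferentially excavated and dated), and a fraction (default 0.15) of
converting forager sites yield one date from the adoption horizon.
Without them, a ring's hull expression lags its true arrival by centuries
— the structural reason pauses shorter than ~400 yr are unresolvable by
100-yr hull stepping under realistic laboratory errors, whatever the
detector settings. The adoption-horizon mechanism concentrates record
mass at the transition and is therefore itself a weak demographic-looking
signal; the three-regime classification study world
(`three_regime_config()`) disables it and enriches the forager record
(`meso_weight = 4`, denser origin foragers) so that regime-3 truth is
strictly trend-continuous and every region can anchor a Mesolithic null.

What passing tests on these worlds do *not* show: real records have
coastlines and topography (fronts are not radial), research-intensity
gradients, taphonomic thinning, and calibration-curve plateaus far
sharper than the toy wiggle. The generator validates the machinery, not
the archaeology.

## Regime classification

A region deviates when its global p-value is below $\alpha = 0.05$, the
observed SPD escapes *above* the envelope between Neolithization and the
young bracket (plus the edge margin), and the excursion is substantial —
peak observed/envelope ratio at least 1.25. The last gate matters for
well-sampled regions, where a tight envelope can be crossed by
fluctuations far too small to constitute a demographic boom. A deviating
origin region is always a persistent trend change (regime 1): dispersal
starts there, so no travelling front ever passes through it and a
deviation cannot be a front transient. Elsewhere a deviation covering at
least 40% of the post-arrival window is regime 1, otherwise a transient
boom (regime 2); everything else follows the forager trend (regime 3).
Boom staggering — each regime-2 ring's boom onset younger than its
predecessor's — is scored against the pulse ordering.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run four studies, sized to be
informative while keeping the whole suite within ordinary desk runtimes:

* **Null calibration**: 200 replicate data sets of ~100 site phases from
  a fixed exponential null, each tested against its own 500-simulation
  ensemble; the false-positive rate at $\alpha = 0.05$ should sit near
  5% (accepted band 2–9%, the binomial noise at 200 replicates).
* **Envelope coverage**: one 500-simulation envelope evaluated on 200
  held-out null SPDs; mean pointwise coverage should sit near 95%.
* **Parameter recovery**: 100 replicates of 500 dates from a known
  exponential; the fitted rate should fall within 2 bootstrap SEs of
  truth in at least 90% of them. Pulse recovery runs the full pipeline on
  default six-pulse worlds (~6,000 trend dates) and requires the exact
  pulse count with every start within one hull step (±100 yr).
* **Regime study**: 50 three-regime worlds, 500 simulations per regional
  test; at least 80% of regions classified correctly and boom staggering
  recovered.

## Known limitations

* The pulse heuristic is a threshold scanner; it cannot resolve pauses
  shorter than the record's expression smear (~2 hull steps), and a world
  whose record starts mid-pulse will miss that pulse.
* Hull-based regions are convex; real dispersal corridors (coastlines,
  river axes) are not, and the convex-hull area conflates them.
* The Mesolithic null is an exponential fitted to a regional SPD; where
  the pre-arrival window is short (the innovation centre) its slope is
  poorly constrained and the extrapolated envelope is wide — the origin
  rule in the classifier exists precisely because excursion geometry is
  unreliable there.
* Rank-based p-values saturate at $1/(n_{sim}+1)$; regions whose
  deviation is overwhelming are all reported at the floor.
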