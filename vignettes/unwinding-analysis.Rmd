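---
title: "Quantifying helicase unwinding from correlated force and kymograph data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying helicase unwinding from correlated force and kymograph data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwindr)
```

## The measurement

A nicked double-stranded DNA molecule is held between two beads at constant
force while a confocal line scan repeatedly images it, producing a
kymograph (time x position raster). The duplex is stained (Sytox), so
regions converted to single-stranded DNA by a helicase appear as growing
*dark regions*; optionally, eGFP-labelled RPA coats the peeled strand and
shows up as bright, growing *spots* in a second channel. At the same time
the instrument records the end-to-end tether length. Because single- and
double-stranded DNA stretch differently, both the length change and the
dark-region span report how many base pairs have been unwound.

`unwindr` turns these signals into event-level numbers: per-fork and total
unwinding rates in bp/s, unidirectional versus bidirectional classification,
the force required to initiate unwinding under a stepped protocol, and
rewinding (reannealing) after protein removal. A calibrated synthetic
generator produces ground-truthed kymographs so every analysis stage is
testable without instrument data.

## Polymer elasticity

Two closed-form models carry every unit conversion.

ssDNA follows an extensible freely jointed chain (eFJC),

$$x_{ss}(F) = L_c\left[\coth\!\left(\frac{bF}{k_BT}\right) -
\frac{k_BT}{bF}\right]\left(1 + \frac{F}{S}\right),$$

with defaults $L_c$ = 0.56 nm/nt, Kuhn length $b$ = 1.5 nm and stretch
modulus $S$ = 800 pN — canonical literature values, config-overridable, and
replaceable by values fitted to a measured force–extension curve with
`fit_force_extension()`. dsDNA uses the extensible worm-like chain in the
Odijk high-force form,

$$x_{ds}(F) = L_c\left[1 - \tfrac12\sqrt{\frac{k_BT}{F P}} +
\frac{F}{S}\right],$$

with $L_c$ = 0.34 nm/bp, $P$ = 50 nm, $S$ = 1200 pN, standard for the
5–40 pN range used here. Temperature is fixed at 298 K
($k_BT$ = 4.114 pN nm). Forces outside (0, 60] pN raise an error rather
than clamping: above ~60 pN dsDNA overstretches and neither model applies,
and below $k_BT/4P \approx 0.02$ pN the Odijk expansion is invalid.

Each unwound base pair replaces one tensioned duplex bp by one tensioned
nucleotide; the complementary nucleotide joins a relaxed coil with zero
end-to-end extension. The tether length therefore changes by
$x_{ss}(F)-x_{ds}(F)$ per unwound bp — about +0.19 nm at 30 pN, negative
below the crossover force (~6.0 pN with the defaults), where the
length-change estimator is refused as ill-conditioned and the dark-region
estimator (`dark span / x_{ss}(F)`, valid at any force) must be used.

```{r elasticity}
polymer_extension(ssdna_params(), 30)   # nm per nt
polymer_extension(dsdna_params(), 30)   # nm per bp
unwound_bp_extension(30)                # nm per unwound bp
crossover_force()
```

## The synthetic generator and its calibrations

`simulate_trace()` draws nick-initiated events on a template
(λ, 48,502 bp, with Poisson-many nicks placed uniformly over the interior
90%; or the 6.4 kbp construct with a single nick 2,200 bp from one end).
Each event samples an initiation-force threshold from the condition's
cumulative curve — events start only once the stepped protocol reaches that
force, with uniform jitter over the first half of the plateau, and
molecules whose threshold exceeds the schedule maximum never unwind (the
"N.U." outcome). Unidirectional events move one fork at a truncated-normal
velocity; bidirectional events draw independent left/right fork velocities
such that their sum follows the calibrated total-expansion distribution,
because a single expanding dark region measures the sum of its two forks.

The packaged calibrations encode the benchmark conditions: helicase alone
at 30 pN (60 ± 9 bp/s, purely unidirectional, ~1.6 events per molecule);
helicase + RPA at 30 pN (53% bidirectional; unidirectional 72 ± 24 bp/s,
bidirectional total 117 ± 25 bp/s, 3.4 events per molecule, eGFP channel
on); and the core-helicase fragment + RPA at 35 pN (42% bidirectional,
slower, with the bidirectional/unidirectional ratio at 1.7 — only the
ratio and "slower than full-length" are reported for this condition, so the
absolute level, 42 bp/s unidirectional, is this package's choice). The
initiation-force curves are likewise package choices shaped by the
qualitative observations (unwinding between 10 and 40 pN without RPA; from
5 pN with RPA).

Rendering: duplex occupancy is mapped to micrometres through the cumulative
per-segment extensions at the current force (the bp → µm map is nonuniform
once ss and ds mix), convolved with a Gaussian PSF (σ = 0.15 µm), scaled to
50 counts/pixel over a 5-count background, and Poisson-noised per pixel.
Pixels outside the current tether extent are rendered at duplex brightness,
standing in for bead scatter and glare, so that dark pixels occur only
where ssDNA is. Spots are Gaussian profiles at each moving fork whose
integrated counts are proportional to the coil size. The length series
follows the tether model exactly (plus Gaussian readout noise, σ = 5 nm).
Pixel size (0.1 µm) and line time (0.1 s) are typical confocal-scanning
values; none are printed in the source material. All randomness flows from
one seed through three fixed substreams (events, switch fates, photon
noise), so identical seed + configuration gives bit-identical output.

What the generator does **not** emulate: photobleaching, intercalator
binding/unbinding kinetics, bead Brownian motion spectra, drift, and
sequence-dependent unwinding. Passing the recovery benchmarks therefore
shows the analysis is unbiased under realistic shot noise and PSF blur with
events that start, stop, collide and rewind — not that it is robust to
instrument drift or photophysics beyond Poisson statistics.

## Tracking

Segmentation thresholds each scan line at half the duplex brightness,
estimated per line as the median of the brightest quartile of the analysis
window (robust both to lamp drift and to dark regions covering most of the
tether). This automates the manual "compare each pixel to a set threshold"
procedure; the fraction (0.5) and an absolute-counts mode are exposed in the
configuration. A 3-pixel median prefilter prevents single-pixel shot noise
from splitting a dark run; edges are refined to subpixel by interpolating
the threshold crossing; 5 pixels at each raster end are excluded as bead
glow. Intervals are linked through time by greedy nearest-neighbour
matching of centres (≤ 5 px jump, ≤ 2 missing lines), and tracks shorter
than 5 lines or never 3 px wide are discarded as artefacts. Spot detection
finds per-line local maxima above background + 3 robust SDs, refines them
with a three-point parabola, links them the same way, and assigns each spot
track to the event whose dark span contains it.

Two guards keep merging dark regions from corrupting event statistics: an
event's track is truncated as soon as its region approaches within 3 px of
*any* other segmented interval (two regions about to fuse — e.g. a
collision — are each analysed only up to that point), and a track that
first appears mid-trace already wide is dropped as the continuation of an
already-merged region rather than a new event (genuine events nucleate from
zero width).

## From tracks to rates and classes

Edge positions are first corrected into the *duplex frame*: growing ssDNA
upstream of a point stretches more than the duplex it replaced, shifting
all downstream material outward by $(x_{ss}-x_{ds})/x_{ss}$ per micrometre
of intervening dark span. Subtracting that (computable from the same line's
segmentation) makes genuinely static edges static — without it, the nick
edge of a left-moving unidirectional fork drifts outward at
$v\,(x_{ss}-x_{ds})$ and would masquerade as a second fork.

The per-event rate is the slope of the *linear region of the increase*:
the series (5-line running median) is restricted to its growth phase (up to
95% of the final level), a BIC-guarded changepoint removes either a short
leading detection artefact (a dark region "catching up" to its true width
while ~1 px wide) or a trailing slower phase left by a stopped fork, and
the longest window with local $R^2 \ge 0.9$ covering at least half the
samples — preferring windows anchored near the event start, where forks are
known active — is fit. Slopes convert as: total rate = width slope /
$x_{ss}(F)$; per-fork rate = |corrected edge slope| / $x_{ds}(F)$, which is
numerically identical to the per-fork ssDNA growth divided by $x_{ss}$.
An event is *ratable* only if a window passes the $R^2$ floor **and** the
fitted growth across it exceeds 0.3 µm; slopes measured over less growth
are dominated by localisation noise and their selection-inflated values
would bias condition means upward. Unratable events are excluded from means
and logged, never imputed.

Classification converts each side's outward duplex-frame displacement to
base pairs and scales both sides pro rata so they account for the full
final dark span (the unwinding that happened before the region became
resolvable belongs to the sides in proportion to their observed motion).
A side qualifies as moving if it exceeds the bp equivalent of 3 pixels of
dark-span growth; both sides moving — or two diverging eGFP spots — means
bidirectional, exactly one means unidirectional, neither means ambiguous.
The bidirectional rate is reported as the total expansion (sum of forks),
with per-fork rates also emitted.

Both bp estimators are computed per event: `bp_dark` from the dark span and
`bp_dL` from the tether-length change between medians of five scan lines
flanking the event (the baseline is taken just before the *extrapolated*
onset, where the width trend crosses zero). Disagreement beyond 10% raises
a QC flag. `summarize_condition()` reports per-class mean ± SD (n − 1),
the bidirectional fraction with a Wilson 95% interval, and the classic
pooled-variance two-sample Student's t-test (Welch behind a flag). Events
are treated as independent even when they share a molecule, matching how
the benchmark means are defined.

Rewinding after a buffer switch is called per event from a one-sided sign
test on successive width differences (significantly shrinking), required to
agree with a tether-length trend opposite to unwinding at that force; the
rewind rate comes from the same linear-region machinery applied to the
shrinking width.

## Numerical choices and problem sizes

* Inversion of the force–extension models uses bracketed root finding with
  tolerance 1e-9 pN (round trips verified to 1e-6 pN).
* Elasticity fits use Levenberg–Marquardt with positivity bounds.
* Static edges are recognised by a 0.05 µm flatness tolerance (half a
  pixel) rather than an $R^2$ criterion, which is undefined for a constant.
* Degenerate inputs error loudly: zero scan lines, constant rasters,
  forces outside the validity windows, conversions at the crossover force.
* The benchmark suites simulate molecules until 40 classified events
  accumulate (typically 12–30 molecules of 60 s at 10 lines/s, rasters of
  roughly 600 × 180 px) — large enough that the recovered means sit well
  inside the stated tolerances, small enough that each suite runs in about
  a minute on one core. The polarity benchmark uses a 160 s noiseless
  trace so the fork always completes its 4,200 bp segment regardless of
  where in the plateau it initiates.

## Known limitations

* Pre-detection merges are invisible: two nicks a few hundred bp apart
  fuse into one region before either is resolvable and are counted (and
  rated) as one event — as they would be by eye.
* The dark-region estimator saturates at the bead margin; events reaching
  it are censored from rate fitting beyond the contact line.
* The length-change estimator is only attributed to events that do not
  overlap another event in time; overlapping events get `NA` there and rely
  on the dark-span estimator.
* Whether a reported bidirectional rate is total expansion or per-fork is
  ambiguous in the field; this package reports total expansion and records
  per-fork rates alongside, and the simulator is calibrated under the same
  convention.
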