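---
title: "Analysing sensillum support-cell physiology with sensilphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sensillum support-cell physiology with sensilphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensilphys)
```

## Scope

Each olfactory sensillum on the *Drosophila* antenna houses one to four
olfactory sensory neurons (OSNs) and three support cells — the thecogen
(sheath), tormogen (socket) and trichogen (shaft) cells. Two kinds of
recordings probe how these cells participate in odor sensing:

1. **Live cation imaging.** Genetically encoded Ca²⁺ (GCaMP6f) or K⁺
   (GINKO1) indicators are driven in a chosen cell type; an open antennal
   preparation is imaged every 5 s for 180 cycles (15 min) while stimuli
   (e.g. the Orco agonist VUAA1) are applied in the bath. The acquisition
   software exports a matrix of average fluorescence per region of interest
   (ROI), including one background region outside the tissue.
2. **Single-sensillum recording (SSR).** Extracellular spike trains from one
   sensillum, 13 s per recording (3 s pre- and 10 s post-stimulus), with
   0.5 s stimulus presentations from a panel of treatments delivered in an
   airstream. Ablating thecogen cells in adults (heatshock-induced
   apoptosis) makes neurons respond to the mechanical air gust itself, so
   dissociating odor responses from gained mechanosensitivity is the central
   analysis problem.

`sensilphys` implements the full downstream analysis for both modalities,
plus a synthetic-data generator that produces both data types with known
ground truth, so every stage is testable end to end without access to raw
recordings.

## The imaging model

For cell ROI $r$ at frame $t$, the background ROI is subtracted per frame,
$F(r,t) = \mathrm{raw}(r,t) - \mathrm{raw}(bg,t)$. The baseline
$F_0(r)$ is the mean of $F(r,\cdot)$ over the **F₀ window** — by default 10
frames (50 s) ending one frame before the first stimulus. The reported
signal is the percent change

$$\Delta F/F_0(r,t) = 100 \cdot \frac{F(r,t) - F_0(r)}{F_0(r)}.$$

Two invariances follow and are enforced by tests: adding a common offset to
all ROIs, or scaling all ROIs by a positive constant, leaves ΔF/F₀
unchanged; and the mean of ΔF/F₀ over the F₀ window is zero for every ROI.
A non-positive $F_0$ is a hard error naming the ROI — it indicates a
mis-drawn background region, not a quantity to push through.

```{r dff-example}
m <- cbind(bg = rep(2, 12), roi1 = c(rep(10, 10), 12, 12))
rec <- imagingRecording(m, frameInterval = 5,
                        events = stimulusEvents("VUAA1", 50, 0, "odor"))
dffMatrix(computeDff(rec, f0Window = 1:10))[11:12, 1]  # (12-2-8)/8 = 25%
```

### Responder classification

Cells are scored by their peak $|\Delta F/F_0|$ within the response window,
in units of the baseline standard deviation; a cell is a **responder** when
the score reaches `responderK` (default 5). The published analyses this
formalizes judged responders by eye, so the threshold is a design choice of
this package; 5 SDs keeps the false-positive probability negligible for a
120-frame search window.

One numerical choice matters here. A single ROI's baseline SD estimated
from 10 frames has 9 degrees of freedom; the ratio of a maximum over ~120
frames to such a noisy denominator is heavy-tailed, and flat cells are then
sporadically called responders no matter the threshold. Because the noise
level is common to all ROIs of a recording (same illumination, same
camera), the default `sdMode = "pooled"` pools the per-ROI baseline
variances across ROIs, which stabilizes the denominator; `"per_roi"` is
available for heterogeneous-noise data. With pooling, classification on the
simulated mixture (58% responders at 30% amplitude over ~2.8% noise)
recovers the generator's truth cell for cell.

### Aggregation, extremum timepoint, dose–response

Replicate (or per-cell) traces are averaged per frame with the standard
error of the mean; at $n = 1$ the SEM is reported as `NA`, not 0, because
the sample SD is undefined. Dose–response curves are read out at a single
frame: the time at which the largest $|\text{mean } \Delta F/F_0|$ across
all conditions is reached (`findExtremumTime`, ties to the earliest frame).
No interpolation is permitted — the readout must be an acquired frame.

Replication structure matters for dose–response extraction: the background
ROI is shared by all cells of a recording, so background noise at the
readout frame shifts a whole recording's mean jointly and does not average
out with more cells. Resolving small between-concentration differences
therefore requires replicate antennae; the package's own checks use 8
replicate recordings of 6 cells per concentration, which places the
smallest programmed amplitude difference about 4 standard errors above the
replicate-to-replicate noise.

## The SSR model

Spike counting uses half-open windows $[a, b)$ throughout, so adjacent
windows never double-count. The response magnitude is the count in
$[t_{on}, t_{on}+1)$ minus the count in $[t_{on}-1, t_{on})$ — an unbiased
estimator of the rate-kernel integral over the first post-stimulus second.

Resting activity has two estimators: total spikes of a stimulus-free 13 s
recording divided by 13, and the summed 1 s pre-stimulus counts across the
16 treatments of one fly divided by 16. Under the Poisson assumption each
estimate has variance count/T²; `restingConsistency` passes when the
estimates differ by at most `consistencyTol` (default 2) pooled standard
errors. Exact enumeration over the two Poisson totals shows this rule
passes 95.45% of the time for a homogeneous train at any rate — the "about
95%" consistency one expects of a 2-SE rule.

Frequency traces bin spikes into 25 ms bins whose grid is **anchored at
stimulus onset**, so traces from different flies align exactly by
construction rather than by post hoc timestamp matching; a final partial
bin is dropped rather than padded, which would inflate its rate.

## The three-step air-gust correction

1. **Raw traces** (25 ms bins) and their peak/AUC within stimulus onset to
   1 s after onset.
2. **Gust correction**: the mean air-gust trace — computed per sensillum,
   pooling flies within a cohort — is subtracted bin-wise from every trace.
   Corrected rates may be negative by design; clipping would bias areas.
   (Whether the published workflow pooled the gust mean within or across
   cohorts is not stated; within-cohort is the default here because the two
   cohorts have different mechanical gains by hypothesis.)
3. **Smoothing**: a centered 400 ms rolling average (`zoo::rollmean`, 16
   bins), defined only where the full window fits, so the trace shortens by
   15 bins and output times are means of contributing bin times. Smoothed
   traces are mined over the widened window of 0.5 s before to 1 s after
   onset, accommodating the shift the rolling mean introduces.

Peaks are maxima over in-window samples; AUC is the trapezoidal integral
(`pracma::trapz`), exact for piecewise-linear rate functions sampled at the
bin nodes. Cohort contrasts (`deltaSummary`) report heatshock-minus-control
means per (sensillum, treatment) for peak and AUC separately; a cell
missing one cohort is flagged absent, never treated as zero.

A statistical caveat the package's checks respect: the *peak* of a
noisy residual trace is a max statistic and is positively biased even when
the residual is zero-mean in every bin. Zero-centering of pure-gust
residuals is therefore assessed on the signed AUC (a symmetric statistic),
and odor-component recovery is assessed after the full three-step workflow
on cohort-mean traces, against the same pipeline applied to the noiseless
expected rate.

## The synthetic generator

The generator exists to give every stage ground truth, not to model
indicator biophysics.

**Imaging.** Each cell's trace is
$\text{background} + \text{baseline}\cdot(1-\beta)^t +
\frac{A}{100}\,\text{baseline} \cdot K(t - t_{on}) + \varepsilon$, with
$K$ a difference-of-exponentials kernel (rise 40 s, decay 240 s) normalized
to peak 1, $\varepsilon$ i.i.d. Gaussian per frame, and photobleaching
$\beta$ off by default. The time constants place the kernel maximum at 86 s
after onset, so on the 5 s frame grid the population extremum falls on the
85 s frame — the dose–response readout time used throughout. Presets fix
the flux direction per cell type and cation: OSNs Ca²⁺ up / K⁺ down;
tormogen cells Ca²⁺ up in a 58% responding subpopulation, K⁺ flat; thecogen
cells Ca²⁺ flat, K⁺ up with a small default amplitude (8% — the real signal
is marginal and unquantified, so this is a deliberately modest free
choice). Dose dependence uses a saturating decay
$A(c) = A_0\,c_{50}/(c_{50}+c)$ with $c_{50} = 30$ mM over
1–150 mM, reproducing the decrease of response magnitude with ambient
K⁺ and the sign mirroring between thecogen cells and OSNs.

**Spikes.** An inhomogeneous Poisson process with rate
$\lambda(t) = r_0 + g_{odor} A(t-t_{on}) + g_{mech} M(t-t_{on})$, where $A$
and $M$ are peak-normalized alpha kernels. Defaults: baseline 8 spikes/s;
odor kernel $\tau = 0.1$ s (response duration ≈ 0.4–0.5 s) with gain 120
spikes/s for a sensillum's diagnostic odorant and 0.2× off-target;
mechanical kernel $\tau = 0.05$ s (a briefer gust transient, which lets the
correction tests distinguish the two components) with gain 20 spikes/s in
control and 70 spikes/s in heatshock cohorts — the gained
mechanosensitivity of thecogen-ablated flies. Sampling is by thinning
(rejection against the rate's upper bound); an independent time-rescaling
simulator serves as the distributional oracle in the tests. The default
design crosses the 16-treatment panel (no treatment, a blank air gust, and
14 odorant presentations including the solvent hexane; only five odorants
are named diagnostic ligands, the rest are synthetic filler labels) with
three sensilla and both cohorts at 9 flies per cell.

What the generator does *not* emulate: indicator binding kinetics and
saturation, temporally correlated noise, motion artifacts, bursting or
refractory spike statistics, and ephaptic interactions between neighboring
neurons. Passing tests therefore demonstrate correctness of the analysis
under the stated statistical model, not robustness to every artifact of
real recordings.

## Problem sizes and numerical choices

The package's checks run at desk scale, chosen to make each property
resolvable rather than to exhaust the conditions: 1000 cells for classifier
operating characteristics; 8 antennae × 6 cells per concentration for
dose–response; 300 simulated flies per rate for resting-activity bias; 500
trials for response-magnitude recovery; a 16 × 2 × 9 design (one sensillum)
for the end-to-end correction. Windows are closed for metric extraction
(the trapezoid needs both endpoints) and half-open for counting; ties in
the extremum search break to the earliest frame; duplicate spike times are
rejected by default as acquisition artifacts. Every constant is carried by
`analysisConfig()` — no stage hides a literal — and all simulations are
bit-reproducible under a seed.

## Known limitations

- The responder threshold and its pooled-SD scoring are this package's
  formalization of a by-eye judgement; on data with strongly
  ROI-dependent noise, use `sdMode = "per_roi"` and expect the 10-frame SD
  caveat above.
- The 400 ms rolling average attenuates genuine sub-400 ms response peaks
  (by design — it is a conservative, response-removing smoother); peak
  comparisons across stages should use the same stage on both sides, as
  `deltaSummary` enforces.
- The smallest neurons (ab1D, ab2B, ab3B) are not separable in this
  framework; exclude them via the design table, as the default design does
  implicitly by modelling the summed large-neuron activity.
- SEM is undefined at $n = 1$ and reported as `NA`; downstream plotting
  must tolerate the gap.
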