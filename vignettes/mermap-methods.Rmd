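---
title: "Methods: microelectrode-recording analysis for STN mapping"
author: "mermap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microelectrode-recording analysis for STN mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During deep-brain-stimulation surgery for Parkinson's disease, five
microelectrodes in a "Ben's Gun" cross are advanced toward the subthalamic
nucleus (STN) in 1 mm steps, from 10 mm above the planned target to 4 mm
below it, recording ~30 s of extracellular voltage per site at 24 kHz.  The
track passes thalamus and zona incerta (low firing, quiet background), the
STN (high firing, loud background, elevated low-beta 13–20 Hz
oscillation), a thin white-matter lamina, and the substantia nigra pars
reticulata (SNr: fast regular firing, elevated gamma 31–49 Hz).  The
package turns each site's trace into a battery of 19 automated parameters
and predicts the target depth (per trajectory) and target trajectory by a
maximum-parameter rule, then scores those predictions against ground
truth with exact-match accuracy, ROC/AUC, and Pearson correlations.

# Pipeline stages and their models

## Artifact removal

The trace is trimmed to 30 s and segmented into non-overlapping 0.5 s
epochs $s(1),\dots,s(l)$.  The variance coefficient
$V_c(k) = \mathrm{var}\,s(k) / \mathrm{var}\,s(k-1)$ (population variance)
is computed once on the original sequence; any epoch with $V_c > 1.8$
(strictly) is discarded.  The rule is deliberately one-sided: the epoch
whose variance *jumped* is the artifact; the subsequent drop is not a
trigger.  Kept epochs are concatenated and each junction left by a removal
is bridged by 2 ms of monotone piecewise-cubic Hermite (pchip)
interpolation through 5 anchor samples per side, which cannot overshoot
the anchors and so cannot manufacture spikes.

Three structural blind spots follow from the rule and are worth knowing:

* the **first epoch** has no coefficient and cannot be screened;
* the **tail half** of an artifact straddling an epoch boundary survives
  (its variance resembles its — rejected — predecessor's);
* the **second of two adjacent** artifact epochs survives for the same
  reason, because coefficients are not recomputed across new junctions.

A further empirical point: with 70–150 µV spikes on a 2–6 µV background,
epoch variance is dominated by spike energy, so natural firing-rate
fluctuation (e.g. Poisson thalamic firing) occasionally trips the 1.8
threshold.  That is inherent to the rule; it costs some clean data and
means "clean on = clean off" holds exactly only on spike-free input.

## Spike detection and sorting

Detection runs on the zero-phase (forward–backward) 4th-order Butterworth
band-pass, 500–5000 Hz.  The threshold is the robust estimate
$\theta = 4\,\mathrm{median}(|x|)/0.6745$; both polarities count.
Contiguous supra-threshold excursions closer than the 1.5 ms lockout are
merged into one event registered at the largest-magnitude extremum — a
large biphasic spike crosses the threshold more than once, and
registering the *first* excursion (the pre-trough lobe) while locking out
the trough would systematically mistime ~1/4 of detections (measured:
recall 0.73 literal vs 1.00 merged on default STN sites).

At $k=4$ pure band-limited Gaussian noise yields ≈1.36 false events/s
(both polarities; ≈0.68/s for one polarity — Rice's formula with the
band's RMS frequency ≈3 kHz times $e^{-k^2/2}$).  On spiking sites the
spikes inflate the median-based $\theta$ slightly, and precision stays
≥0.98.

Waveforms are 64 samples with the extremum at sample 20; a 4-level
orthonormal Haar transform gives 64 coefficients (approximation, then
details coarse→fine).  The 10 most *non-normal* coefficients by the
Lilliefors statistic (KS distance to a fitted normal) are kept:
multimodality across spikes marks shape differences between units.

Clustering is superparamagnetic (SPC): a $q=20$-state Potts model on the
symmetrised $K=11$ nearest-neighbour graph, interactions
$J_{ij} = \tfrac1K \exp(-\lVert x_i - x_j\rVert^2 / 2a^2)$ with $a$ the
mean neighbour distance, simulated by 500 Swendsen–Wang sweeps per
temperature (grid 0–0.25 by 0.01, 10% burn-in, bond probability
$1-e^{-J_{ij}/T}$ between same-state neighbours).  Neighbour pairs whose
state-agreement frequency exceeds 0.5 join the same cluster.  The working
temperature is the **last structural split**: the highest temperature
whose count of non-trivial clusters (≥ max(20, 2% of spikes)) strictly
exceeds every colder count.  Near the dissolution temperature clusters
shed members, so "the hottest temperature with any surviving cluster"
returns fragments — measured on 10σ-separated blobs it yields 1–2 partial
clusters, while the last-split rule recovers all three exactly.  Points
outside surviving clusters are labelled 0; if nothing reaches the minimum
size the site is treated as single-unit.

## Background reconstruction

Each detected spike's window (0.5 ms before to 2.5 ms after) is replaced
by 3 ms of spike-free signal drawn uniformly (seeded) from the same trace
at least 3 ms from every spike window, cross-faded over 0.25 ms at both
edges; the patched trace is then zero-phase low-passed at 500 Hz
(patch-then-filter, in the order the procedure is described).

**Known attenuation**: replacing a fraction $f$ of a narrowband signal
with incoherent donors leaves ≈$(1-f)^2$ of its in-band power.  At 40 Hz
firing, $f \approx 0.11$ and a single STN site's oscillation power reads
≈0.81 of truth; at thalamic rates the bias is within a few percent.
Across a session's site mix the per-band median recovery is within 10%.
Phase-preserving donor selection would remove the bias but the procedure
prescribes random donors.  "No significant spikes remain" is verified
against the *original* spike threshold; re-estimating a threshold on the
residual trace would simply re-find the noise-excursion floor.

## The parameter battery

Per band (low 2–7, alpha 8–12, low beta 13–20, high beta 21–30, beta
13–30, gamma 31–49 Hz) from the Welch PSD of the background (1 s Hamming
windows, 50% overlap, 1 Hz resolution — the minimum resolving the 2–7 Hz
band; segments mean-removed): mean and maximum of the amplitude spectrum
$A(f)=\sqrt{\mathrm{PSD}(f)}$, and the band RMS
$\sqrt{\sum_{f\in\text{band}} \mathrm{PSD}(f)\,\Delta f}$ (inclusive
bins). `Mean_RMS`/`Max_RMS` summarise the five disjoint bands.  From the
pooled spike train (all clusters — the report tables carry one value per
site): mean/max rate over the 0.5 s epoch grid, modal inter-spike
interval (1 ms bins from zero, ties toward the shorter interval, bin
centre reported), burst index $(1000/\mathrm{ISI_{modal}})/\bar r$, and

$$\mathrm{LvR} = \frac{3}{n-1}\sum_{i=1}^{n-1}
\Bigl(1 - \frac{4 I_i I_{i+1}}{(I_i+I_{i+1})^2}\Bigr)
\Bigl(1 + \frac{4R}{I_i+I_{i+1}}\Bigr)$$

with refractoriness constant $R = 5$ ms (the source literature's value;
the procedure never prints one).  LvR is 0 for regular trains, ~1 for
Poisson firing, and invariant to common scaling of intervals and $R$.

## Localization and evaluation

Per parameter and trajectory the predicted depth is the argmax over the
depth series (ties to the dorsal-most depth, flagged); the predicted
trajectory is the one whose own best depth carries the largest value
(ties in fixed order central, anterior, posterior, medial, lateral).
Depth success = exact match with the true target depth; SNr success = the
maximum falls inside the SNr span, a trajectory entering that denominator
only when the parameter is computable on ≥2 SNr depths — the only rule
consistent with per-parameter denominators that vary across a cohort.  AUC is the
Mann–Whitney statistic (identical to ROC trapezoid integration), with
Hanley–McNeil standard errors; correlations are Pearson with explicit
Bonferroni family sizes.

# The synthetic world

No patient recordings are deposited, so validation runs on a generator
with exact ground truth.  Per region (defaults; all config-exposed):

| region | rate (Hz) | units | shape | σ bg (µV) | dominant band (µV²) |
|---|---|---|---|---|---|
| thalamus/ZI | 12 | 1 | 1 | 2.5 | none (0.3 flat) |
| STN | 40 | 1 | 2 | 5 | low beta 4 |
| white matter | 0 | 0 | – | 2 | 0.15 flat |
| SNr | 60 | 1 | 6 | 4 | gamma 4 |

Rates are literature-shaped free parameters (parkinsonian STN 25–45 Hz,
SNr faster and more regular, thalamus/ZI slow; none are printed for these
patients).  Spike trains are gamma renewals with 1 ms dead time; spikes
are biphasic 64-sample templates, peak amplitudes drawn in 70–150 µV
(per-unit sub-ranges and strongly distinct shape variants keep concurrent
units separable, which is what the sorter is owed by construction),
jittered ±10% per spike.  Band oscillations are brick-wall-filtered
Gaussian noise with exactly the configured variance — band-wide power as
in field recordings, not pure tones.  The default layout places the full
track order on the target trajectory (thalamus −10…−5, white matter −4,
STN −3…+1, white matter +2, SNr +3…+4), a short STN span and no SNr on
two neighbours, and no STN on the remaining two.  The STN low-beta
injection peaks at the true target depth (Gaussian profile, σ = 1.2 mm,
floor 0.4) — the dorsolateral beta maximum that makes a *single* depth
the correct answer; `beta_contrast` scales it for degradation
experiments.

Artifacts are additive (spike truth never moves): 50 Hz line bursts at
100 µV or broadband transients of σ = 50 µV, 0.2–0.45 s, Poisson(0.5)
per site.  Amplitudes are absolute because real exogenous interference
dwarfs the neural signal, and because an artifact must dominate even a
spike-rich epoch's variance for the variance-coefficient rule to be able
to see it at all.  Default artifacts sit inside a single epoch, never the
first, never adjacent — i.e. inside the rule's competence; its structural
blind spots (above) are documented, not silently exercised.

What a green test does *not* establish: performance on real MER with
electrode drift, non-stationary firing, overlapping spike waveforms,
vendor hardware filtering, or artifact families outside the two modelled
ones; nor cohort-level clinical accuracies, which would require the
unavailable patient recordings.

# Numerical choices

* Butterworth filters are designed by bilinear transform (coefficients
  match scipy to printed precision) and applied forward–backward with
  steady-state initial conditions — no start-up transient, zero phase.
* Population variance (÷N) throughout the artifact stage; the ratio is
  convention-insensitive, fixed for reproducibility.
* Welch: 1 s / 50% / Hamming; in-band bins are inclusive of both edges.
* SPC uses R's RNG (seeded per call); `(config, seed)` determines every
  sample of the generator, and the pipeline derives stage seeds from the
  master seed by a byte-sum offset of the stage name.
* Degenerate inputs: zero-variance epochs are rejected without condemning
  their successors; sites with <2 usable spikes skip clustering (single
  cluster); missing ISI statistics propagate as empty CSV cells.

# Known limitations

The one-sided, non-recomputed variance rule's blind spots; narrowband
power attenuation proportional to the patched fraction at high firing
rates; the ~1.4/s noise-event floor of the 4σ both-polarity detector;
spike-count-driven epoch rejections on low-rate Poisson sites; and the
maximum-parameter rule's sensitivity to any single corrupted site (it is
an argmax — one bad epoch that survives screening can relocate a
trajectory's prediction).
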