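---
title: "Recurrence-based directed EEG networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-based directed EEG networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmdnet)
```

## The scientific problem

During a perceptual decision — here, classifying an ambiguous Necker cube as
left- or right-oriented — cortical regions transiently couple into a
large-scale functional network. `rmdnet` reconstructs that network from
multichannel EEG at the sensor level and relates its formation to the
subject's reaction time (RT). The analysis chain is:

1. **Band-power envelopes.** Each 4-s trial (1 s pre-stimulus baseline,
   3 s post-stimulus) is wavelet-transformed with a complex Morlet of
   central frequency $\omega_0 = 2\pi$,
   $W(f,t_0) = \sqrt{f}\int x(t)\,\psi^*\!\big(f(t-t_0)\big)\,dt$, and the
   amplitude $|W(f,t)|$ is integrated over the alpha (8–12 Hz) and beta
   (15–30 Hz) bands to give envelopes $E^{\alpha}(t)$, $E^{\beta}(t)$.
   The amplitude is integrated as such, not squared — `band_power()` calls
   this out prominently, and `squared = TRUE` switches to the
   $|W|^2$ convention.
2. **Recurrence-based measure of dependence (RMD).** For a channel pair
   $(x, y)$ and a time window, each envelope gets a recurrence matrix
   $R(i,j) = \Theta\!\left(\varepsilon - |E(t_i) - E(t_j)|\right)$; marginal
   densities are row means, the joint density is the row mean of the
   elementwise product, and
   $\mathrm{RMD} = \log_2 \frac{1}{N}\sum_i
   \frac{P_{xy}(i)}{P_x(i)P_y(i)}$. RMD is 0 in expectation under
   independence and positive under functional dependence. A lag
   $\tau \neq 0$ shifts $y$ against $x$; the maximizing lag $\tau^*$ gives
   the coupling direction ($x$ drives $y$ when $\tau^* > 0$). Zero lag is
   never evaluated, which suppresses instantaneous field-spread
   correlations by construction.
3. **Link statistics.** For $K = 20$ trials per condition, the
   lag-maximized $\mathrm{RMD}^*$ in each sliding 1-s task window is
   compared to the 1-s pre-stimulus baseline by a paired t test; the
   family of all channel pairs within a window is corrected by
   max-statistic permutation (sign-flips of the per-trial differences).
   Significant links are classified by the sign of the median change into
   increasing ($M_{inc}$) and decreasing ($M_{dec}$) directed networks.
4. **Timeline.** $R(t) = \Sigma M_{inc} / \Sigma M_{dec}$; $t_1$ is the
   first time $R$ exceeds 1 for two consecutive windows, $t_3$ the time of
   maximal $R$ on $[t_1, \mathrm{end}]$, and $t_2$ the midpoint. Outgoing
   degrees $D_i = \sum_j M_{inc}(i,j)$, averaged over seven longitudinal
   scalp regions (O, P, Cp, C, Fc, F, Fp), localize the drivers.

Reaction-time conditions follow the stimulus-ambiguity design: HC trials
(ambiguity $g \in \{0.4, 0.45, 0.55, 0.6\}$) versus LC trials
($g \in \{0, 0.15, 0.85, 1\}$); SH1 are HC trials with RT between the 75th
and 97.5th HC percentiles, SH2/SE2 are HC/LC trials with RT between the two
class medians, and each condition is subsampled to exactly $K$ trials.

## What the synthetic generator emulates — and what it does not

Real recordings for this paradigm are not publicly deposited, so the
package ships a generator with *planted, known* structure; every stage of
the pipeline is validated by parameter recovery against it.

Per channel and band the generator produces a slow non-negative envelope
(white noise, zero-phase low-passed at 4 Hz, unit-scaled, rectified)
modulating a band carrier (10 Hz for alpha, 22.5 Hz for beta), plus $1/f$
background noise. Couplings act on envelopes, not carriers, because the
analysis measures spectral-power dependence, not phase. An *increasing*
link makes the target's envelope a gain-weighted, lagged copy of the
source's envelope from the coupling onset $t_c$ onward; a *decreasing*
link gives source and target a lagged shared envelope component during the
baseline only. The decreasing mechanism uses a lagged common component
deliberately: the analysis excludes zero lag, so an unlagged shared
envelope would be (by design) invisible to it.

The generator does **not** model volume conduction, eye-blink or EMG
artifacts, per-subject spectra, or broadband carriers. Passing recovery
tests therefore demonstrates that the *statistical machinery* works on
signals with the assumed envelope structure; it does not certify
performance on artifact-laden recordings.

### The in-band signal-to-noise default

`snr` is the ratio of band-carrier variance to $1/f$-noise variance within
8–30 Hz. Neither a physical amplitude scale nor an SNR is prescribed for
this paradigm, so the default had to be chosen. We chose `snr = 50` — a
clear-rhythm regime — on the basis of an information-budget analysis: with
1-s windows and 4-Hz envelopes, a window carries only ~8 effective
envelope samples, and at `snr = 3` even an oracle statistic (exhaustive
lagged correlation applied to the extracted envelopes) reaches a paired
$t \approx 3$ for a gain-1 planted link, far below the 465-test
max-statistic threshold ($\approx 5.6$ at $K = 20$). A generator whose
planted ground truth is unrecoverable *in principle* cannot exercise the
pipeline, which is its purpose. At `snr = 50` a fully-coupled window gives
$t \approx 7$ and recovery is reliable. Envelope-level properties (lag and
direction recovery) are still validated at `snr = 3`, where they hold with
headroom.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fs` | 250 | Hz | recording rate; trials are 4 s = 1000 samples |
| bands | 8–12, 15–30 | Hz | alpha / beta band edges |
| `decimate` | 10 | — | envelope rate 25 Hz; envelopes live below 4 Hz, and an 8-Hz zero-phase low-pass precedes subsampling |
| `target_rr` | 0.30 | — | recurrence rate of the fixed-rate threshold (below) |
| `tau_max` | 0.2 | s | lag-scan range (5 samples at the 25-Hz envelope rate) |
| `window_length` / `window_step` | 1 / 0.1 | s | sliding task windows over \[0, 3\] s, labeled by center; baseline is \[−1, 0\] s |
| `K` | 20 | trials | per-condition sample for the paired test |
| `n_perm` | 2000 | — | permutations for the max-statistic null |
| `alpha` | 0.05 | — | two-sided family-wise level |

### Why a recurrence rate of 0.30

The fixed-recurrence-rate construction makes densities comparable across
trials and channels. The *value* of the rate, however, interacts strongly
with the window length. At the 25-Hz envelope rate a 1-s window has
$N = 25$ samples; a rate of 0.10 leaves ~2–3 recurrences per matrix row,
the density ratios are estimated from almost nothing, and the
lag-maximized RMD saturates: in simulation the separation between gain-1
coupled pairs and independent pairs collapses to an effect size of
$d \approx 0.25$, and no planted link survives the multiple-comparison
threshold. At a rate of 0.30 (~8 recurrences per row) the same comparison
gives $d \approx 1.7$–2.3 and planted networks are recovered. The rate
also controls the finite-size independence bias: for i.i.d. series the
unit diagonal of the recurrence matrix inflates the measure by
$\approx \log_2\!\big(1 + 1/(N\,\mathrm{rr}^2)\big)$, i.e. 0.22 at
$N = 500$, rr = 0.10, but only 0.016 at rr = 0.30. Hence 0.30 is the
package default; the parameter remains configurable. Note that this bias
is common to baseline and task windows and cancels in the paired
contrast, so inference is insensitive to it either way.

## Numerical choices

* **Percentiles** use linear interpolation between closest ranks (R's
  default convention, type 7), applied to raw RTs; interval endpoints are
  inclusive on both sides so boundary trials are never silently dropped.
* **Filtering** is zero-phase throughout (`signal::filtfilt`), so no
  filter delay can bias the event-locked timeline.
* **Wavelet kernels** are truncated at $|\eta| \le 5$ (Gaussian tail
  $< 4\times10^{-6}$); each frequency's cone-of-influence half-width is
  reported in the `spectral_map`.
* **Lag-scan ties**: lags are visited in order of increasing $|\tau|$ with
  the positive sign first, and only a strictly larger RMD displaces the
  incumbent — the smallest lag wins ties, a $+\tau$/$-\tau$ tie resolves
  to "x drives y" and is flagged ambiguous.
* **Degenerate inputs**: constant envelope segments give an all-recurrent
  matrix with a warning; zero-variance paired differences are flagged and
  assigned a signed sentinel statistic rather than dropped or passed.
* **Sentinel ratios**: $R = n/0$ is reported as `Inf` and still counts as
  a unity crossing (equivalent to the integer comparison
  $\Sigma M_{inc} > \Sigma M_{dec}$); $0/0$ is `NaN` and never crosses.
* **Window realization**: window starts in seconds are rounded to the
  nearest envelope sample; windows are labeled by their centers.
* **Seeds**: one per stochastic stage (simulation, condition subsampling,
  permutation; the permutation seed for window $w$ is `seed + w`), and all
  seeded functions restore the caller's RNG state.
* **Baseline lag treatment**: the baseline RMD uses the same lag
  maximization as the task windows, so selection inflation is symmetric
  between the two arms of the paired test.
* **$t_2$** is the midpoint $t_1 + (t_3 - t_1)/2$: a transient-topology
  *instant* must lie inside $[t_1, t_3]$, which a bare duration
  $(t_3-t_1)/2$ would not.
* **Unity-crossing debounce**: $t_1$ requires two consecutive windows with
  $R > 1$; a single noisy window cannot set the network-formation onset.

## Problem sizes used in validation

The validation suite runs every oracle-equivalence check at
$N \le 200$, RMD analytic checks at $N \le 500$ over 100 seeds, lag
recovery at 100 seeded runs per planted lag, family-wise-error control at
200 simulated 31-channel sessions with 500 permutations, and end-to-end
frontal-hub recovery at 20 seeded 31-channel sessions with $K = 20$ and
500 permutations. These sizes give Monte-Carlo standard errors comfortably
inside the asserted margins while keeping the full suite in the
tens-of-minutes range on a single core; the pipeline defaults
(`n_perm = 2000`, 350-trial sessions) are what an actual analysis would
use.

## Known limitations

* **Timeline latency.** Detecting a step-like coupling onset requires most
  of a 1-s window to be coupled: in simulation the per-window paired $t$
  ramps roughly as 1.6 → 2.8 → 4.3 → 5.2 → 6.8 → 7.8 as the coupled
  fraction grows from 50% to 100%. With windows labeled by their centers,
  the recovered $t_1$ therefore trails a coupling onset by ~0.2–0.3 s at
  realistic power. $t_1$ is best read as "the network is demonstrably
  formed by $t_1$", not as an unbiased onset estimate; comparisons of
  $t_1$ *between* conditions or bands share the bias and remain valid.
* **Common-driver links.** Two targets of one source are genuinely
  dependent, so the fitted $M_{inc}$ can contain more links than were
  planted; directions among co-driven targets are ambiguous. This is a
  property of any pairwise dependence measure, not of the implementation.
* **Absolute RMD values** carry the finite-size bias discussed above;
  only task-minus-baseline contrasts are interpreted.
* **Sensor space.** No source localization is attempted; "region" means a
  scalp sensor region, not a cortical structure.

## A minimal end-to-end run

```{r, eval = FALSE}
spec <- preset_frontal_hub_spec(onset_time = 0.6)
trials <- simulate_eeg_trials(spec, n_channels = 31, fs = 250,
                              n_trials = 20, seed = 1)
fit <- rmdnet(trials, band = "beta", n_perm = 500, seed = 1)
summary(fit)
plot(fit)
```

The full study pipeline — behavioral simulation, condition assignment,
both bands, all three conditions, artifact screening and on-disk artifacts
with provenance hashes — is `run_pipeline(pipeline_config(...))`.
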