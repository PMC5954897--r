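---
title: "Stochastic motor engagement on phagosomes: models, synthetic traces and detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic motor engagement on phagosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagotrap)
```

## The scientific problem

A phagosome held in an optical trap is pulled alternately toward the
microtubule plus end (kinesin) and minus end (dynein). Individual stalls
are separated by inactive periods at the trap centre, and reversals with
an inactive time shorter than 0.5 s ("rapid reversals") are common. The
package implements a quantitative account of this behaviour in which no
coordination machinery is needed: motors engage the microtubule
stochastically and independently, and the observed statistics follow from
how many motors happen to sit inside the small membrane patch that can
reach the microtubule.

Three model layers feed into each other:

1. **Occupancy geometry.** Motors are uniformly distributed over the
   cargo surface; each lands in the contact zone independently with
   probability $p = A_\mathrm{contact} / 4\pi R^2$. Occupancy counts are
   binomial, and the probability that a dynein team of at least $m_D$ *and*
   a kinesin team of at least $m_K$ are simultaneously available is the
   product of two binomial tails. `joint_reversal_probability()` evaluates
   this exactly (via `pbinom`, never a normal approximation — the
   $n = 240$ tail must be exact for the headline 0.74).
2. **Binding kinetics.** Each motor in the zone attaches with rate
   $K_{ON}$ and detaches with rate $K_{OFF}$, giving the mean-field
   occupancy $C(t) = C_{eq}\,(1 - e^{-(K_{ON}+K_{OFF})t})$ with
   $C_{eq} = K_{ON}/(K_{ON}+K_{OFF})$. The same process, treated exactly,
   is a birth–death chain; `first_passage_analytic()` gives the exact mean
   first-passage time to $m$ motors bound through the standard hitting-time
   recursion, and `first_passage_mc()` verifies it by Gillespie simulation.
   The two routes are kept deliberately independent so each tests the
   other.
3. **Coin-toss event statistics.** Successive stall directions are modelled
   as independent draws with $P(K) = q$; the fair coin $q = 0.5$ gives each
   consecutive pair type (DD, DK, KD, KK) a 25% share. The "unfairness" $q$
   is a first-class parameter because biasing it is the natural regulatory
   knob for net transport direction.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| cargo diameter | 750 | nm | early-phagosome size class |
| $A_\mathrm{contact}$ | 0.08 | µm² | membrane patch able to reach the MT |
| contact fraction $p$ | 0.04 | — | working value; the exact area ratio is 0.0453 (see below) |
| $N_D$, $N_K$ | 240, 40 | motors | surface-area scaling from small-vesicle counts; $N_K = N_D/6$ |
| team thresholds $m_D$, $m_K$ | 6, 1 | motors | weakest teams able to win/force a reversal |
| dynein $K_{ON}$, $K_{OFF}$ | 1.6, 0.27 | s⁻¹ | literature rates; $C_{eq} = 0.86$, $t_c = 0.53$ s |
| kinesin $K_{ON}$, $K_{OFF}$ | 5, 1 | s⁻¹ | literature rates; $C_{eq} = 0.83$, $t_c = 0.17$ s |
| unitary forces | 1.1 (dynein), 6 (kinesin) | pN | single-motor stall forces |
| trap stiffness $K_T$ | 0.02 | pN/nm | free parameter of the instrument |
| sampling rate | 2000 | Hz | detector rate |
| rapid-reversal threshold | 0.5 | s | matches the dynein characteristic binding time |

Two deliberate choices deserve comment:

* **$p = 0.04$, not 0.0453.** The geometric ratio
  $0.08/(4\pi\,0.375^2) = 0.0453$; the model's working value rounds this
  to "4% of the surface". Both are computable (`contact_fraction()`
  returns the exact ratio; `occupancy_model()` defaults to 0.04) so the
  discrepancy is exposed rather than hidden. All headline numbers use
  0.04.
* **Exact rather than rounded kinetics.** Printed summaries of $C_{eq}$
  and $t_c$ round to two digits (0.85, 0.53 s, 0.16 s); the package always
  computes from the rates and rounds only for display.

## What the synthetic-data generator emulates

`generate_trace()` builds a trap record event by event, following a
coin-toss label sequence:

* **Thermal bath.** The trapped bead is an Ornstein–Uhlenbeck process with
  stationary SD $\sqrt{k_BT/K_T}$ (≈14.3 nm at the defaults) and
  relaxation time $\gamma/K_T$. The discrete update uses the exact AR(1)
  transition, not an Euler step, so autocorrelation tests are unbiased at
  0.5-ms sampling. Drag comes from Stokes' law with an effective viscosity
  of 3× water to represent assay buffer near a surface; this is a
  configurable package choice, as no measured value is available.
  Detector noise (2 nm SD) is added on top.
* **Stalls.** A motor team with linear force–velocity
  $v(F) = v_0(1 - F/F_\mathrm{stall})$ pulls the bead along an exponential
  approach to the plateau $X = F_\mathrm{stall}/K_T$. The rise duration is
  solved (by `uniroot`, to machine tolerance) so that the width of the
  force record at half-maximal force equals the programmed $T_{STALL}$
  exactly in the noise-free limit. Because the approach is asymptotic, the
  *realized* peak force $X(1-e^{-T/\tau})$ is slightly below the nominal
  team force; the ground truth records both, and recovery is scored
  against the realized value — that is what a trap record contains.
* **Team forces.** Kinesin teams of 1 or 2 motors (6 / 12 pN) are drawn
  with the single/multi ratio implied by the occupancy model's team-size
  probabilities (0.326 : 0.479 ≈ 40:60). Dynein is recruited in pairs —
  force multiples of 2.2 pN with the main weight at 6.6 pN — unless
  `dynein_pairs = FALSE`, which produces the 1.1 / 2.2 pN single/pair
  forces seen after partial dynein inhibition.
* **Fly-backs.** After detachment the bead either relaxes freely
  ($\gamma/K_T \approx 1$ ms; outside the 2-SD centre band for ~2.5 ms) or
  is resisted by still-engaged opposing motors (tug-of-war), modelled as a
  linear ramp timed to keep the bead outside the band for a programmed
  20–80 ms. During tug-of-war ramps the thermal noise is damped (scale
  0.5): with motors engaged on both sides the linkage is stiffer than the
  bare trap. This is a phenomenological stand-in for a full two-team
  mechanical model — the detector only requires two separable fly-back
  populations, which is also all the experimental classification uses.
* **Inactive gaps.** With probability `p_rr` (default: the occupancy
  model's joint reversal probability, 0.7406) the gap after an event is
  drawn below 0.5 s from a truncated exponential whose mean is the dynein
  characteristic binding time; otherwise 0.5 s plus an exponential tail of
  mean 1.5 s. Gap durations are laid down so that the *detector-visible*
  dwell inside the centre band equals the programmed value (the fly-back
  tail inside the band and the next rise's exit are compensated
  analytically).
* **Premature detachments.** With a small probability a kinesin stall is
  preceded by a sub-threshold partial rise that detaches while still
  moving fast — the signature used to recognise premature events.

**What is not emulated:** discrete 8-nm stepping, ATP dependence,
load-dependent (catch-bond) detachment, slow instrumental drift, QPD
nonlinearity, and real inter-event correlations if any exist. Passing
recovery tests therefore show that the pipeline is correct and unbiased
*for data obeying the stated model*, not that the model is the only one
compatible with real records.

## The detection pipeline and its numerical choices

* **Centre calibration** finds the densest position cluster of the
  median-filtered trace, then the longest contiguous dwell in it.
  Candidate dwells must behave thermally — the median filter must remove
  most of their variance, and their two halves must not drift — which
  rejects slow motor-driven ramps. Noise-free or pre-characterised traces
  can bypass this with an explicit `center_calibration()`.
* **Segmentation** uses hysteresis: an event opens when the 5-ms
  median-filtered excursion exceeds 2 centre-SDs and closes when it falls
  below 1 SD, which prevents chatter at the band edge. Excursions shorter
  than 10 ms are ignored as noise.
* **Stall force** is the median of the filtered force over the last
  100 ms of the force plateau, after a rough pass excludes slow tug-of-war
  decays from the window. The raw sample maximum is biased upward by
  thermal noise (~0.3 pN at the defaults) and the early rise downward;
  the plateau median is within ~1% of the realized force. The unfiltered
  maximum is still used for the 3-pN acceptance gate, mirroring the
  "maximum force" criterion.
* **Release** (detachment) is the last crossing of the plateau minus a
  2-sigma filtered-noise margin. The margin adapts to the trace: the
  filtered-noise SD is measured on the calibration segment.
* **Thresholds**: stalls must exceed 3 pN and 0.5 s half-max width in
  both directions by default; the `low_force_minus` profile (0.7 pN,
  0.3 s) is for datasets where ~1.1-pN single-dynein events must be
  counted. Premature candidates are flagged when their pre-detachment
  velocity (least-squares slope over 0.2 s) exceeds 3× the median plateau
  velocity of accepted stalls (floor 100 nm/s) and are merged into the
  following same-direction stall, so a premature + full pair counts once.
* **Pairing**: consecutive accepted stalls form overlapping pairs (s
  stalls give s−1 pairs), never across traces. A pair with no detected
  inactive interval gets gap 0 and is a rapid reversal by definition.
* **Fly-back classification**: default fixed cutoff 5 ms (the upper bound
  of unopposed fly-backs); alternatively a 1-D two-class split of log
  fly-back times maximising between-class variance (Otsu's criterion),
  falling back to the threshold below 4 values. Measured fly-back times
  carry ~2 ms of release-detection latency, so a small fraction of free
  fly-backs lands just above 5 ms; the two populations remain separated by
  an order of magnitude.
* **Two-Gaussian force fits** use a maximum-likelihood mixture
  (unequal variances, EM via mclust); a fit whose component means are
  closer than twice the mean component SD is flagged degenerate.
* **Group comparisons** use Student's unpaired two-tailed t test with
  pooled variance; zero-variance input is flagged rather than tested.

## Statistical conventions in the test-suite

Stochastic checks run at fixed seeds and 3-sigma tolerances. One
refinement: for overlapping pair fractions of a fair coin the correct
variance is *not* binomial — adjacent pairs share a toss, giving variance
$5n/16$ for DD/KK and $n/16$ for DK/KD counts at $n$ tosses. The
acceptance test for the 25% pair fractions uses these exact variances.

Problem sizes were chosen as the smallest that make the 3-sigma bands
scientifically meaningful: $10^5$ tosses for pair fractions, $10^4$
replicates for the Monte-Carlo first-passage check, and 48 synthetic
traces of 101 events (≈2400 detected reversal pairs) for the end-to-end
check that the detected first-bin fraction converges to the programmed
joint probability of 0.7406.

## Known limitations

* The contact-zone geometry is an input, not derived; cargo sizes other
  than 750 nm need their own $A_\mathrm{contact}$.
* Binding kinetics ignore load dependence; dynein's catch bond enters the
  narrative of tug-of-war outcomes but not the rate model.
* The tug-of-war fly-back is phenomenological; fly-back *durations* are
  meaningful, fly-back *trajectories* are not.
* Mean-field and Gillespie layers assume motors are independent and
  identical; cooperative recruitment (dynein pairs) is represented only in
  the force taxonomy of the generator.
* Real trap records may contain drift and nonstationary noise that the
  centre calibration does not model; the explicit-segment escape hatch
  exists for such data.
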