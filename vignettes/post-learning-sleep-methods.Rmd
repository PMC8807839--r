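---
title: "Methods: scoring post-learning sleep, courtship memory and circuit connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring post-learning sleep, courtship memory and circuit connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plsleep)
library(dplyr)
```

plsleep implements the complete quantitative stack of a *Drosophila*
post-learning-sleep study: courtship conditioning induces long-term memory
(LTM) only after sufficiently long training, consolidation is accompanied by
a transient sleep increase in the 1–3 h window after training ends (TP1-3),
and the underlying circuit is probed with a luminescence activity reporter,
stimulus-locked calcium imaging, and connectome synapse counts. Every stage
is a plain function over a data frame, and a family of generators simulates
each raw-data modality with known ground truth, so the whole pipeline is
testable without any recordings.

All time axes are aligned so that `t = 0` is the end of training, and all
binning uses half-open intervals `[start, start + len)` anchored at 0. This
one convention decides every boundary question in the package: a minute
belongs to exactly one 30-min bin, a 30-min bin belongs to TP1-3 iff its
start lies in `[1 h, 3 h)` (bins starting at 60, 90, 120, 150 min), and the
15-min luminescence grid puts exactly 8 samples into TP1-3.

## Sleep scoring from locomotion

The tracker emits displacement per video frame (nominally 5 Hz). Scoring has
three stages, each with one tunable constant:

* `bin_minutes()` sums displacement into 60-s bins; a minute is **active**
  iff it moved at least `threshold_mm = 3.6` mm. The boundary value counts
  as active: "no locomotion" is read as strictly sub-threshold. Whether the
  original tracker treats exactly 3.6 mm as active is not determinable, so
  the threshold and its direction are a single configurable comparison.
* `score_sleep()` marks a minute **asleep** iff it lies in a maximal run of
  `min_run = 5` or more consecutive inactive minutes.
* `pool_sleep()` counts asleep minutes per `bin_min = 30` minutes.

Missing data are handled conservatively. A minute with fewer than half its
expected frames is *invalid*; invalid minutes break sleep runs, so dropped
frames can never fabricate sleep. Runs truncated by the recording boundary
count only if the observed part already reaches 5 min — unobserved
immobility is never assumed. An incomplete trailing minute is discarded.

`delta_sleep()` computes the per-fly contrast
$\Delta \mathrm{Sleep}(f, b) = \mathrm{sleep}(f, b) - \overline{\mathrm{sleep}}_{\mathrm{ctrl}}(b)$
against the mean of a control cohort, bin by bin; `window_mean()` averages
it over TP1-3; `group_tests()` runs the associated battery: a two-sided
Wilcoxon signed-rank test per group (H~0~: median 0) and two-sided rank-sum
tests between groups. For n ≤ 15 non-zero values the signed-rank p-value is
computed by exact enumeration of sign assignments on midranks — unlike the
usual implementation this stays exact under ties, which matter here because
window means of small integer counts tie often. Larger groups use the
normal approximation with continuity correction. An all-zero group has an
undefined statistic and is flagged with p = 1 rather than an error, so a
flat cohort cannot crash a batch analysis.

`activation_delta()` covers the optogenetic variant: each illuminated fly's
hour-2 sleep minus the mean hour-2 sleep of the never-illuminated cohort.

## Sleep depth: P(doze) and P(wake)

`transition_probs()` estimates, per 30-min window, the per-minute
probability of falling asleep (active → non-active) and waking
(non-active → active). Two design points deserve emphasis:

* **State basis.** The transition analysis calls a minute active iff its
  locomotion is *greater than zero* — not the 3.6 mm sleep threshold. The
  defining sentence of this statistic is written in terms of raw locomotion,
  but it sits next to the 5-min-rule state definition, so the alternative
  reading (transitions between sleep/wake states) is also implemented as
  `state_basis = "sleep_state"`. The default is `"activity"`; neither is
  asserted to be the original.
* **Denominators.** A "ratio of transitions" must be normalized by
  opportunities to lie in [0, 1], so each probability divides transition
  counts by source minutes *with an observed successor*. The successor of a
  window's last minute is taken from the next window when recorded — counts
  are made on the undivided series and attributed to the source minute's
  window, so windowed counts concatenate exactly to whole-series counts.
  Windows with no source minutes of a kind yield `NA`, never 0, and `NA`
  propagates through `delta_transition()` rather than being imputed.

## Courtship memory: SI and permutation tests

The courtship index (CI) is the percentage of a 10-min test spent courting;
memory is the suppression index over trained (CI^+^) and naive (CI^−^)
populations:

$$\mathrm{SI} = 100 \left(1 - \frac{\mathrm{median}(CI^+)}{\mathrm{median}(CI^-)}\right).$$

`perm_test_si_zero()` tests H~0~: SI = 0 by pooling all CIs and reassigning
them at random to groups of the original sizes, 100,000 times by default;
the two-sided p-value is $(1 + \#\{|SI_\pi| \ge |SI_{obs}|\})/(n_{perm}+1)$.
The add-one correction keeps p in (0, 1]. Numerical choices:

* A permuted naive group with median 0 leaves SI undefined; such replicates
  are assigned the maximal-suppression sentinel |SI| = 100 instead of being
  discarded, keeping the permutation count fixed. This only matters for
  pools with many zero CIs.
* Pooled values are sorted before permuting, so p depends on the data as
  multisets and the seed, never on input order; given both, results are
  bitwise reproducible. The inner loop is compiled (Fisher–Yates driven by
  R's RNG, medians by partial selection), which makes the default 100,000
  permutations effectively free.
* Because SI is bounded above by 100 but unbounded below, the |SI| criterion
  is asymmetric and somewhat conservative for small, strongly separated
  groups (a permuted median inversion can produce SI far below −100). This
  is a property of the statistic as defined, not of the implementation; the
  calibration tests confirm correct type-I control.

`perm_test_si_equal()` tests H~0~: SI~exp~ = SI~ctrl~ with the statistic
SI~exp~ − SI~ctrl~. The published description covers only the single-SI
shuffle, so the two-arm scheme had to be chosen: arm labels are permuted
independently within the pooled trained flies and within the pooled naive
flies, preserving group sizes. This leaves the trained/naive structure —
which is not under test — intact, and reduces to the usual two-sample
permutation scheme on each condition. The scheme is declared, not claimed
identical to the original script.

## Luminescence reporter traces

Plates carry at least three empty wells; `subtract_background()` removes
their mean trace pointwise (warning below three, error at zero).
`normalize_luminescence()` divides by a single scalar: the time average of
the pointwise mean naive trace. The defining sentence ("the mean of the
average luminescence trace") supports a scalar rather than a per-time-point
vector, and a scalar preserves trace shape; the averaging span defaults to
the full session and is configurable (`norm_window`) because the original
span is unstated. By construction the naive grand mean of normalized
luminescence is exactly 1, and the result is invariant to plate-wide
additive offsets and multiplicative gain. A dead-well QC was considered and
left out: the assay as described has none, and silently dropping wells
would change group sizes.

`window_contrast()` averages each well over TP1-3 and compares every
training-duration cohort to the naive cohort with a two-sided Student
t-test (equal variances), the test used for these data throughout.

## Calcium imaging and functional connectivity

`compute_dff()` uses $\Delta F/F = (f(t) - F_0)/F_0$ with $F_0$ the mean of
the session's first 10 s — the pre-stimulation baseline of the whole
session, not a per-epoch baseline (per-epoch re-baselining is available via
repeated calls on cut segments but is not the default, matching the
definition). `epoch_average()` aligns the six 5-s pulse epochs (onsets at
10, 40, …, 160 s of the 200-s session) on a common onset-relative grid by
nearest sample and averages pointwise.

`connectivity_call()` compares per-fly baseline activity (mean ΔF/F of the
10 s before the first pulse) with stimulated activity (mean ΔF/F over the
union of the six pulse intervals) across flies: significant at α = 0.05 and
positive → excitatory; negative → inhibitory; otherwise none. Choices made
where the description is open:

* **Paired by default.** Baseline and stimulated values come from the same
  fly, and pairing is the more powerful and more defensible comparison; the
  unpaired two-sample variant is available (`paired = FALSE`) since the
  original wording is compatible with either.
* **Test selection.** "t-test or Wilcoxon" is resolved by `test = "auto"`:
  Student's t when a Shapiro normality check (at 0.05) does not reject,
  Wilcoxon otherwise; both are directly selectable. The Wilcoxon branch
  uses the exact distribution whenever tie-free — at the typical n of 5–9
  flies the normal approximation is anticonservative and would inflate
  false-positive connectivity calls.

`spontaneous_activity()` is deliberately minimal: the mean raw intensity
over a 60-s recording, the summary used for resting-state comparisons.

## Connectome edge filtering

`filter_pairs()` keeps directed neuron pairs with at least `min_syn = 9`
synapses. "A threshold of 9" is read inclusively (9 is the smallest
retained count); the threshold is an argument, and results carry it, so the
exclusive reading costs one keystroke. `aggregate_types()` sums retained
weights per directed (pre-type, post-type) pair and counts surviving neuron
pairs; absent type pairs are absent rather than zero, reciprocal directions
are never merged, and aggregation conserves weight exactly.

## The synthetic cohorts: what they emulate, and what not

The generators reproduce the *statistical shape* of each modality:

* `sim_minute_states()` / `sim_locomotion()`: a two-state Markov chain over
  minutes with baseline per-minute P(doze) = 0.1 and P(wake) = 0.3
  (stationary inactive fraction 0.25, plausible daytime fly behaviour);
  active minutes emit frame displacements summing to a log-normal distance
  (median 6 mm, σ~log~ = 0.4), so ~10% of active minutes fall below the
  3.6 mm threshold — the threshold's imperfect separation is intentional.
  Window-local overrides of the transition probabilities plant effects such
  as TP1-3 sleep deepening.
* `sim_trained_study()` assembles the full design: one shared naive cohort
  and trained cohorts for 1, 2, 4, 6 h, with deepening (P(doze) 0.1 → 0.3,
  P(wake) 0.3 → 0.15, TP1-3 only) planted in the 4-h and 6-h cohorts only.
  One sizing rule matters: ΔSleep subtracts the *same* control mean from
  every fly of a cohort, so control-mean noise shifts a cohort's deltas
  coherently and inflates the per-fly signed-rank false-positive rate by
  roughly $\sqrt{1 + n_e/n_c}$. With equal cohorts of ~45 flies that factor
  is 1.41 (an effective level of ~0.16 at nominal 0.05) — a property worth
  knowing when interpreting single experiments. The generator therefore
  defaults to a 12:1 control:trained ratio (144 vs 12), keeping the factor
  below 1.05 so that unplanted cohorts test close to nominal level.
* `sim_courtship()`: Beta-distributed CIs scaled to [0, 100], shapes solved
  from target medians (trained 30%, naive 70% by default, an SI of 57%).
* `sim_luminescence()`: AR(1) background plus white noise in every well; fly
  wells add a baseline signal and a Gaussian TP1-3 bump whose amplitude
  follows one of three duration laws — `linear` (growing with training
  duration), `peaked` (maximal at 2 h), `step` (zero below 4 h) — emulating
  the three qualitative reporter profiles of the study's neuron classes.
* `sim_calcium()`: a saturating-rise/exponential-decay kernel locked to the
  six-pulse protocol, signed amplitude, Gaussian noise.
* `sim_connectome()`: all neuron pairs between four cell types of a
  feed-forward circuit, Poisson(20) weights on planted type edges and
  Poisson(2) elsewhere.

What they do **not** emulate: circadian modulation and light/dark
transitions, arousal-threshold structure and bout-duration heavy tails,
plate-position and evaporation artifacts, bleaching and motion in imaging,
and the spatial statistics of real connectomes. Consequently, passing tests
demonstrate that the *procedures* are correct and calibrated under the
declared models — not that the biological effect sizes are realistic beyond
the planted ones.

## Problem sizes in the test suite

The validation suite runs the scoring oracle on 1,000 random 600-minute
state strings; transition-probability recovery on 200 flies × 12 h of
minute states; permutation-test calibration on 1,000 null data sets of
40 + 40 Beta CIs at 2,000 permutations each; connectivity-call recovery on
200 simulations per signed regime and 1,000 for the null regime (7 flies,
±3σ or 0 effects); and 100 replicate training studies (four cohorts of 12
plus 144 naive controls, 3 h at 1 Hz) for the duration-dependent TP1-3
pattern. These sizes were chosen so that Monte-Carlo error is small against
each test's acceptance band while the whole suite stays comfortably
runnable on a laptop.

## Known limitations

* The two-arm permutation scheme and the activity basis of P(doze)/P(wake)
  are declared choices among readings the source description leaves open.
* `epoch_average()` uses nearest-sample alignment; at 1 Hz volume rates
  sub-sample jitter of pulse onsets is not corrected.
* The signed-rank exact enumeration is O(2^n) and capped at n = 15; beyond
  that the normal approximation is used, which is standard but not exact.
* `group_tests()` applies no multiplicity correction across cohorts — the
  study's own convention — so families of contrasts should be interpreted
  accordingly.

```{r example-pipeline}
study <- sim_trained_study(seed = 1)
bins <- bin_minutes(study$data, sample_rate = 1) |>
  score_sleep() |>
  pool_sleep()
naive <- filter(bins, condition == "naive")
tp13 <- purrr::map_dfr(c("1h", "2h", "4h", "6h"), function(ch) {
  delta_sleep(filter(bins, condition == ch), naive) |>
    window_mean() |>
    mutate(condition = ch)
})
group_tests(tp13, value, condition)
```
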