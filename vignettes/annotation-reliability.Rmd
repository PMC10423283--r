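---
title: "Annotation reliability over Plutchik dyads: model, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation reliability over Plutchik dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadqc)
```

## The setting

A pool of raters annotates images with exactly one of eight emotion
dyads — paired near-synonyms standing for the eight basic Plutchik
categories (1:Anger/Rage, 2:Engagement/Anticipation,
3:Disgust/Disconnection, 4:Fear/Worry, 5:Joy/Affection,
6:Sadness/Discouragement, 7:Surprise/Amazement, 8:Trust/Peace). The
campaign runs in daily sessions: every rater attending a day sees that
day's batch of 56 images, six of which are known-answer *control images*,
plus one image repeated a second time (57 presentations). Dyad ids are
fixed I/O identifiers; the circular wheel geometry is carried separately
as positions 0–7, with each antagonist pair (joy↔sadness, trust↔disgust,
fear↔anger, surprise↔anticipation) four steps apart. The ids are not in
wheel order — the id order is the alphabetical category order used in all
tables — which is why the catalog stores both.

`dyadqc` implements the two quality-control layers applied to such
campaigns, with the statistics used to evaluate them.

## Per-image agreement

For an image with vote counts $c_1,\dots,c_8$ and $n=\sum_j c_j$ raters,
observed agreement is the fraction of agreeing rater pairs

$$P_{obs} = \frac{\sum_j c_j^2 - n}{n(n-1)},$$

and the chance-corrected coefficient uses **uniform** chance agreement
$1/8$ over the $K = 8$ categories:

$$\kappa = \frac{P_{obs} - 1/8}{1 - 1/8} \in [-1/7,\, 1].$$

Uniform chance, rather than the marginal-based chance of the classic
pooled multi-rater kappa, is the convention under which a *single image*
has a well-defined kappa at all — there is one "subject" per computation,
so category marginals estimated from that same vote vector would make the
statistic degenerate (for the concentrated example below, marginal-based
chance would even turn strong agreement into a negative coefficient). We
verified the convention against an exhaustive pair-counting oracle, and
the worked vote vector (1, 1, 1, 0, 23, 0, 3, 1) indeed gives
$\kappa = 0.53$ at two decimals:

```{r kappa}
per_image_kappa(c(1, 1, 1, 0, 23, 0, 3, 1))$kappa
```

Qualitative bands follow Landis–Koch: Poor ($\kappa<0$), Slight
($0\le\kappa\le0.2$), Fair ($\le0.4$), Moderate ($\le0.6$), Substantial
($<0.8$), Almost Perfect ($\ge0.8$). The half-open band edges are chosen
to be consistent with the extreme per-band values observed in the
campaign this pipeline reproduces (e.g. 0.7971 is still Substantial,
0.8021 is Almost Perfect). Aggregate agreement is reported as the
*unweighted mean* of per-image kappas: rater counts vary by image once
sessions are discarded, so a pooled classic Fleiss statistic is not
defined here. For per-dyad reporting, images are grouped by their modal
(most-voted) dyad, ties resolved to the lowest id — a convention, as tie
handling is not dictated by the procedure.

## Attentiveness promotion (AP)

Control images are fixed in a pilot: an image qualifies when at least 4
of the 5 pilot raters coincide on one dyad (`select_controls()`, threshold
configurable). In the main campaign a session is **valid** iff

* the repeated image received the same dyad on both presentations, and
* at least 5 of the 6 control images were answered with the expected dyad.

Invalid sessions are discarded wholesale (`apply_ap()`); the repeated
image of a valid session is collapsed to its first presentation (inert,
since validity implies the two votes agree, but stated for determinism).
Control presentations count toward the public tallies: controls are
regular subset images, and no exclusion rule applies to them. Pilot votes
are *not* merged into the main tallies. A control that happens to also be
the repeated image is allowed; both rules apply independently.

For a fully inattentive rater voting uniformly, the probability of
passing is
$\tfrac18\left[6\cdot\tfrac78\left(\tfrac18\right)^5 + \left(\tfrac18\right)^6\right] \approx 2.05\times10^{-5}$ —
the acceptance suite confirms the simulated pass rate against this closed
form over one million sessions.

## Reliability enhancement (RE)

Even attentive sessions leave images with stray votes, including votes on
the wheel-opposite dyad — consistent with raters projecting their own
emotional response rather than reporting the depicted person's. The RE
filter standardises each image's 8-vector of counts,

$$Z_j = \frac{c_j - \mu}{\sigma},$$

and keeps exactly the dyads with $Z_j \ge 0$, i.e. counts at or above the
per-image mean; votes on the other dyads are removed (raters dropped, not
reassigned) and kappa is recomputed on the survivors with $K=8$ and
uniform chance unchanged. Numerical conventions, all inert for the kept
set but fixed for reproducible reporting:

* $\mu$ and $\sigma$ run over the **full 8-vector including zeros** —
  the only reading under which $Z \ge 0$ is a nontrivial filter for
  sparse vectors;
* $\sigma$ is the population form (divisor 8); when $\sigma = 0$ (flat
  vector) all $Z_j$ are defined as 0, so the filter is the identity;
* the kept set always contains the modal dyad (max ≥ mean), hence is
  never empty, and with $n \ge 2$ input votes the surviving total is
  always ≥ 2, so the post-filter kappa is always defined (the guard in
  `apply_re()` is defensive);
* the filter is *not* idempotent in general — survivors may fall below
  their new mean — and the tests assert idempotence exactly where the
  fixed-point condition holds.

A two-dyad 15/10 split illustrates the post-filter convention: kappa is
exactly $3/7 \approx 0.4286$.

```{r re}
apply_re(c(15, 10, 0, 0, 0, 0, 0, 0))$kappa_post$kappa
```

Empirically the filter never decreases kappa — over 10,000 random vote
vectors at the campaign's rater counts (15–35) the suite logs zero
counterexamples — though we treat this as a tested property, not a
theorem.

## Balanced subset selection

First-pass labels use the original 26-word vocabulary; each word maps to
exactly one dyad (group sizes 3, 2, 4, 3, 4, 4, 2, 4 in id order;
spellings follow the source tables verbatim, matched case-insensitively).
Per image, the vote percentage per dyad is computed and the argmax dyad
(ties to lowest id) is its representative emotion; the percentage rather
than an agreement coefficient is used because first-pass rater counts per
image are highly unbalanced. The subset takes the `quota` top images per
dyad, ranked by representative percentage descending with image id as
tie-break — the source procedure does not state its ranking among
eligible images, so this rule is our declared convention; it is
deterministic and scale-invariant (duplicating every record changes
nothing).

## The synthetic campaign generator

`simulate_annotations()` emulates the statistical structure the analysis
assumes, with ground truth for parameter-recovery testing:

* images are partitioned into daily batches (`n_images = n_days ×
  images_per_session`); six images per batch are controls whose expected
  dyad is the truth; every rater of a day annotates the full batch plus
  one repeated non-control image, in randomised order;
* attentiveness is drawn **per rater-session** (the discard unit is the
  annotator-day, so finer modelling would be untestable through this
  pipeline); inattentive sessions vote uniformly and independently on
  every presentation, controls and both copies of the repeat included;
* attentive raters vote each distinct image once — their repeat is
  consistent by construction — from a four-level wheel-distance mixture:
  the true dyad with `p_true` (default 0.8), a distance-1 neighbour with
  `p_adjacent` (0.10, split equally), the opposite dyad with `p_opposite`
  (0.05, the projection effect), and the residual mass uniformly over the
  four remaining dyads; controls are answered correctly with
  `p_control_correct` (0.95);
* defaults mirror the campaign scale: 1,120 images, 20 days, 28
  raters/day, 56 images/session, `inattentive_rate` 0.10 — the campaign
  reported a minimum of 15 attending raters per day and session discard
  was a visible but minor fraction, which a 10% inattention rate with a
  ~2×10⁻⁵ survival probability reproduces. The generative probabilities
  are this package's own modelling choices (the source procedure gives
  only a qualitative dispersion/projection account); they were fixed once
  at values a rater-behaviour study would call realistic and are exposed
  as configuration, not tuned.

Everything is reproducible from the single `seed` (identical output
tables on identical configuration).

What the simulator does **not** emulate: variable daily attendance,
per-rater (as opposed to per-session) reliability, demographic rater
covariates, content-driven image difficulty, or correlated errors between
raters. Passing tests therefore demonstrate that the pipeline's logic and
statistics behave as specified under the assumed voting model — not that
the filter's dataset-level gains on any particular human campaign
(e.g. its printed mean-kappa uplift) are reproduced, which would require
the deposited human annotations.

## Problem sizes used in the tests

The oracle-equivalence check enumerates all 125,961 vote vectors with 2–12
raters against exhaustive pair counting. Filter monotonicity uses 10,000
multinomial vote vectors with 15–35 raters. The AP closed form is checked
over 10⁶ simulated sessions (batched, 8 images per session — session
length is configurable and only the controls and the repeat enter the
validity rule). Recovery runs use 200-image campaigns at 28 raters/day;
the end-to-end default is the full 1,120-image scale, which runs in under
a second.

## Known limitations

* Per-image kappa with uniform chance is not comparable to pooled
  marginal-chance Fleiss kappa values from other studies.
* The RE filter can, by construction, leave a single dyad with very few
  votes as "unanimous" (kappa 1); downstream users should weight by the
  surviving rater count where that matters.
* The 26-word mapping is fixed; vocabularies from other corpora need
  their own catalog resource.
* `n_images` must currently tile exactly into daily batches; campaigns
  with overlapping daily image sets are not modelled.
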