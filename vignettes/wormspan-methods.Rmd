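---
title: "Quantifying stress resilience and healthspan in C. elegans with wormspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress resilience and healthspan in C. elegans with wormspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormspan)
```

## The problem

Ageing in *C. elegans* shows up long before death: animals lose the
ability to survive an acute stressor, their locomotion degrades, and
proteotoxic models (polyQ, amyloid-beta) become paralyzed. wormspan
packages four quantitative readouts of this decline so that survival
assays, tracking videos (reduced to centroid trajectories), and
transcriptomic follow-up can be analysed with one tested toolchain:

1. **Survival resilience (S/L)** — how much of its potential life a
   population retains under a lethal stressor.
2. **Locomotion frailty** — directional shifts, paralysis calls, and the
   direction rescue index from centroid tracks.
3. **Total fitness** — five health metrics normalized to control and
   averaged into one score.
4. **Regulatory scan** — which differentially expressed genes carry
   SKN-1/Nrf binding consensus sites in their promoters.

## The S/L survival-resilience statistic

For a stressed population with Kaplan-Meier survival curve
$S_\mathrm{stress}(t)$ and an unstressed population with life-span curve
$S_\mathrm{life}(t)$, resilience is the ratio of the two areas under the
curves:

$$
S/L \;=\; \frac{\mathrm{AUC}_\mathrm{stress\ span}}
               {\mathrm{AUC}_\mathrm{life\ span}},
\qquad \mathrm{AUC} = \int_0^{T} S(t)\,dt .
$$

$S/L < 1$ (a left-shifted stress curve) is a **loss** of resilience;
$S/L > 1$ a **gain**. For a treated, stress-exposed group the same ratio
with the treatment curve in the numerator measures treatment benefit, and
the percent change between two ratios sharing the life-span denominator
equals the percent change between the corresponding AUCs
(`delta_auc_pct()`).

Key numerical decisions, made here because assay write-ups rarely state
them:

* **Integration** is the exact rectangle sum of the right-continuous KM
  step function — never trapezoids, which would be wrong for a step
  function. With complete follow-up ("scored until all dead", the usual
  design) the AUC then equals mean survival *exactly*; the test suite
  asserts this identity to 1e-12.
* **Censoring**: if animals remain alive at the end of follow-up, the
  curve is integrated to the last observed time (the restricted-mean
  convention) and the curve is flagged `fully_observed = FALSE` so the
  truncation is visible downstream.
* **Ties** between deaths and censorings at the same time are resolved
  deaths-first, the standard product-limit convention.
* **Classification** of a ratio as loss/neutral/gain uses a tiny tie
  band (`tie_tol = 1e-9`) around 1, since the ratio is continuous.
* **Uncertainty**: the assay literature reports no interval method for
  S/L, so the package uses a subject-level bootstrap (resampling animals
  with replacement within each group, percentile interval, default 1000
  replicates) with a mandatory explicit seed.
* **Literature records** that report only mean spans (not full curves)
  are handled by `dose_resilience_profile()` with S/L = mean stress span
  / mean life span, which is exact for fully observed curves. Records
  are classified loss when S/L < 1 and maintain-or-promote when
  S/L ≥ 1. When full curves are available, pooled animals (with
  replicate provenance kept in the subject ids) are the default input
  path; mean-of-replicate-curves analyses can be run by estimating
  curves per replicate and averaging the AUCs.

Group comparisons use the log-rank (Mantel-Cox) test with 1 df and no
continuity correction, via the `survival` package; the test suite checks
it against an independent hand tabulation of the observed-minus-expected
formula over pooled risk sets.

```{r sl-example}
ctl <- simulate_cohort(200, rate = 0.08, seed = 1, group = "control")
str <- simulate_cohort(200, rate = 0.16, seed = 2, group = "stress")
res <- s_over_l(km_estimate(str), km_estimate(ctl), n_boot = 200, seed = 3,
                source_events = list(stress = str, control = ctl))
res
```

With a doubled hazard the population ratio of mean survivals is 0.5, and
the estimate converges to it as cohorts grow (the acceptance checks run
20 studies of 5000 animals per arm and require a mean absolute deviation
below 0.05).

## Locomotion metrics

Tracks are time-stamped centroid positions (mm) at a known frame rate.
Three decisions matter:

* **Instantaneous speed** is the Euclidean displacement between
  consecutive frames over elapsed time. Speeds are unsmoothed by
  default; tracker jitter inflates the slow-speed fraction, so a window-3
  rolling median is available and the choice is recorded in outputs.
* **Directional shifts.** Commercial trackers emit a "Direction" count
  without defining the operator. Here a shift is a transition where the
  angle between successive displacement vectors exceeds 90 degrees
  (strict), with steps below a 0.005-mm noise floor skipped entirely —
  they do not define a heading. The 90-degree default targets reversals,
  the locomotory feature that increases with age and neurodegeneration;
  both the angle and the floor are tunable. This operator is a
  documented stand-in for the tracker's internal definition, not a claim
  about it.
* **Paralysis** follows the published rule: a worm is paralyzed when
  *more than* 80% of its instantaneous speeds are below 0.015 mm/s. The
  boundary is strict — exactly 80% slow frames is still motile — and
  calls are monotone in the speed threshold.

The **direction rescue index** normalizes a treated group against the
untreated control: the fraction of treated animals whose shift count
falls strictly below the control mean. Under the null (treated counts
drawn from the control law, symmetric and continuous) the index sits
near 0.5; 1.0 is complete rescue. All metrics are invariant under rigid
motions of the coordinate frame, which the suite asserts numerically.

## Total fitness

Five health metrics — normalized body size, crawling speed, a direction
score, swimming speed, thrashing frequency — are each expressed as a
treated/control ratio $M_i^t / M_i^c$ and averaged:

$$
\mathrm{Total\ fitness} = \frac{1}{5}\sum_{i=1}^{5} \frac{M_i^t}{M_i^c}.
$$

The mean-of-ratios reading is the only one consistent with the control
baseline being exactly 1.0, and the suite checks the linear
decomposition (scaling one treated metric by $c$ moves the score by
$(c-1) M_i^t / (5 M_i^c)$). Because raw directional-shift counts rise
with frailty, the direction slot must hold a score oriented so that
higher = fitter — the direction rescue index when a control reference
exists, else an inverse shift ratio; the basis is carried as panel
metadata. Thrashing (body bends/s) requires posture-aware tracking and
is accepted as a precomputed scalar rather than derived from centroids.

## Regulatory scan

Differential-expression tables are filtered at fold change ≥ 2
(equivalently $|\log_2 FC| \ge 1$; the suite asserts the equivalence to
1e-12) and FDR ≤ 0.05, both inclusive. Promoters are the 1,500 bases
immediately upstream of a gene's 5' end, strand-aware,
reverse-complemented for minus-strand genes, truncated (and flagged) at
contig edges; annotation input is 1-based inclusive, all outputs 0-based
half-open.

The SKN-1/Nrf consensus motifs `TTDTCATC` (D = A/G/T) and `WWTRTCAT`
(W = A/T, R = A/G) are scanned by exact degenerate matching
(`Biostrings`), case-insensitively, with `N` in the subject never
matching. Both strands are scanned by default — the common practice of
promoter-scanning tools — with a flag to restrict to the forward strand;
the anchor is the feature 5' end. Overlapping matches all count, and
"presence" means at least one site. A gene without a supplied promoter
is reported *unknown*, never zero. The scanner is verified against a
brute-force window-by-window expansion oracle on 1,000 random 1.5-kb
sequences, and minus-strand hits are checked to mirror forward hits of
the reverse-complemented motif.

```{r scan-example}
scan_motifs(c(promoter = "AATTATCATCAAGATGACAA"))
```

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with the statistical structure the
pipeline assumes, plus ground truth for closure tests:

* `simulate_cohort()` — exponential or Gompertz death times
  (hazard $h(t) = a e^{bt}$; the parameterization is stated because
  conventions vary), optional censoring horizon.
* `simulate_tracks()` — motile worms as a correlated random walk
  (wrapped-normal heading increments, sd 0.15 rad/frame; Poisson
  reversals flipping the heading by 180 degrees plus small noise;
  per-frame speeds around 0.12 mm/s, typical of crawling wild-type
  adults) and paralyzed worms as in-place jitter near 0.002 mm/s, far
  below the 0.015 mm/s threshold. Defaults mirror the assay geometry:
  30-s recordings, ~30 animals per condition.
* `generate_regulatory()` — i.i.d. background promoters at GC 0.36
  (approximately the *C. elegans* genome), planted non-overlapping motif
  copies on random strands, and a DE table mixing true effects
  ($|\log_2 FC| = 1 + \mathrm{Exp}(1)$, FDR ~ U(0, 0.01)) with nulls
  ($\log_2 FC \sim N(0, 0.3)$, FDR ~ U(0, 1)).

All generators are deterministic under a fixed seed and leave the
caller's RNG stream untouched. They emulate the *statistical* structure
only: no body posture, no pharyngeal pumping, no read-level
transcriptome counts, no linkage between promoter sites and expression
effect sizes. Passing closure tests therefore demonstrates that the
pipeline recovers known truth under its own assumptions — not that real
tracker output or real RNA-seq meets those assumptions.

## Problem sizes and tolerances

The test suite and the acceptance script use cohorts of 5,000 animals
per arm across 20 simulated studies for parameter recovery (tolerance
0.05 on the recovered ratio), 1,000 random 1.5-kb promoters for scanner
equivalence (exact agreement required), 300 promoters for background
false-positive calibration (binomial error around the analytic rate
$|\mathrm{expansion}|/4^8$ per position per strand), and 200 tracked
worms for paralysis closure (sensitivity and specificity ≥ 0.99). These
sizes give comfortable statistical resolution for each check while
keeping a full run in the tens of seconds.

## Known limitations

* The directional-shift operator is a stand-in for unspecified tracker
  internals; absolute shift counts are comparable within analyses run
  with the same settings, not across tools.
* Restricted-mean AUCs from heavily censored curves underestimate mean
  survival; compare only curves truncated at comparable horizons.
* The regulatory scan is presence/absence of an exact degenerate match —
  no position-weight-matrix scoring, no enrichment statistics against a
  background gene set.
* S/L inference is nonparametric; no Cox or parametric survival models
  are fitted.
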