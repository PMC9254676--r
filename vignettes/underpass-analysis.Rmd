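---
title: "Modelling wildlife underpass use and testing the prey-trap hypothesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wildlife underpass use and testing the prey-trap hypothesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underpassr)
```

## The problem

Road underpasses are installed so that wildlife can cross highways safely,
but monitoring data rarely say on their own whether a structure is "used a
lot": detections in a culvert only mean something relative to how often the
same species walks past a camera in the adjoining forest. A second worry is
the *prey-trap hypothesis*: underpasses funnel animal movement into a
confined, predictable place, so predators (in eastern Australian systems,
principally the red fox) might learn to hunt there.

`underpassr` implements the full analysis chain for a camera-trap monitoring
design with paired cameras in each underpass end and single cameras at
random forest reference sites, at one or more locations:

1. collate raw camera records into independent **passes**;
2. build weekly **detection histories** and nightly detection tables;
3. fit and rank **weekly detection-probability models** by AICc;
4. test nightly predator–prey **co-detection independence** with an exact
   binomial test, plus descriptive prey-activity comparisons.

A seeded synthetic generator reproduces the statistical structure this
chain assumes, so every stage is testable without field data.

## Pass collation

A *pass* is one independent traverse or detection. Rules, in order:

* Records of the same species at the same camera belong to one pass unless
  **at least 30 minutes** have elapsed since the previous contributing
  record, or the observer flagged a distinct individual (size or markings).
  Exactly 30 minutes starts a new pass — the rule is "30 min had elapsed".
* Observer-judged turn-arounds (the animal entered and backed out) are
  supplied as an exclusion list and dropped; that judgement cannot be
  automated from tabular data.
* Multiple individuals in one image make the pass count as that many
  detections (`n_individuals`, the maximum over contributing images).
* In an underpass, the two end cameras may both record one traverse.
  Passes at opposite ends within a **matching window** whose directions are
  not contradictory merge into one pass. Matching is greedy in time order
  with earliest-candidate preference and each pass merges at most once, so
  the operation is idempotent.

The matching window is not part of the field protocol and had to be chosen
here: the default is **15 minutes**, on the reasoning that passage through
a 20–50 m structure is much faster than ambling past a forest camera, so
genuine double-captures are seconds to a few minutes apart while 15 minutes
still stays well below the 30-minute independence scale. It is configurable
(`match_underpass_ends(window_minutes = )`), and the pipeline run log
records the value used. "Contradictory" directions means both passes carry
a known traverse direction and they differ; an `unknown` direction never
blocks a merge.

Annualized rates are `detections / operational_weeks * 52`, reported to one
decimal place, the same normalization as the field's "passes per 52 weeks"
tables.

## Weekly detection models

Detection histories put sites in rows and weekly occasions in columns, each
cell `1` (detected), `0` (surveyed, not detected) or missing (`-` in the
CSV form) when the site had zero operational camera coverage that week.
Weeks with partial coverage count as surveyed; only malfunction, theft or
non-deployment makes an occasion missing. All sites share one occasion
calendar anchored on the earliest deployment.

The model is the single-season occupancy likelihood for one site history
$y_{i1},\dots,y_{iT}$ with occupancy probability $\psi$ and per-occasion
detection probability $p_{it}$:

$$
L_i = \psi \prod_{t \in \text{surveyed}} p_{it}^{y_{it}} (1-p_{it})^{1-y_{it}}
      \; + \; (1-\psi)\, \mathbf{1}\{\text{all } y_{it} = 0\}.
$$

Because the species of interest are detected at essentially every site,
$\psi$ is not the quantity of interest and is typically **fixed at 1**;
when it is estimated and runs to the boundary ($\hat\psi > 1 - 10^{-6}$)
the model is automatically refitted with $\psi = 1$ and the fit records
that. Detection structures:

* **null** — one $p$ at all sites;
* **underpass** — one $p$ for underpasses, one for forest sites;
* **patchy** — site-specific $p$, usually reduced to a few groups (below);
* any structure **+season** — an additive austral-season effect on the
  log-odds scale, with spring–summer (September–February) as the reference
  level; used for the lace monitor, which is inactive in the cooler months.

Fitting is by BFGS on the log-odds scale from zero-valued starts with up to
5 jittered restarts; SEs come from the inverse observed information, with
delta-method SEs for $p$. Groups whose surveyed cells are all 0 or all 1
are separated cases: the estimate is reported at the boundary with an
infinite SE and held out of the optimization. Tests check the maximized
likelihood against a dense grid-search oracle (tolerance $10^{-4}$ on
histories up to 3 sites × 4 occasions).

`reduce_patchy_groups()` reconstructs the reduction step used in practice:
sites whose $\hat p \pm 1\,\mathrm{SE}$ intervals overlap are merged by
single linkage (connected components of the interval-overlap graph). This
is deterministic, but it is a reconstruction of a described heuristic, not
a claim of equivalence with any particular published grouping.

Models are compared with the small-sample corrected AIC,
$\mathrm{AICc} = -2\log L + 2K + 2K(K+1)/(n-K-1)$, ranked ascending;
$\Delta\mathrm{AICc} < 2$ flags equally plausible models and
$\Delta\mathrm{AICc} > 10$ essentially no support. Two conventions are
deliberate and echoed in every run log because standard occupancy software
uses them without saying so:

* the **effective sample size is the number of sites** ($n$ in the
  correction term);
* **$K$ counts $\psi$ even when fixed at 1** (so the null model reports
  $K = 2$); the free-parameter count is kept separately (`K_free`).

## The prey-trap tests

Three predictions are testable from the detection data:

1. *Predators are detected more at underpasses than in forest* — compare
   the underpass model against patchy/null in the AICc ranking and inspect
   the estimates ([fit_detection()], [rank_models()]).
2. *Predator activity aligns with prey activity across underpasses* —
   descriptive: [prey_activity_alignment()] sums annualized rates of the
   potential prey species per underpass (reported as integer detections per
   year) and forms pairwise ratios (1 d.p., computed before rounding).
3. *Predator and prey use the same underpass on the same nights more than
   independence predicts* — the co-detection test below.

A **night** runs 17:00–07:00 and is indexed by the date of its 17:00 start;
daytime records belong to no night. For a predator group and a prey group
at one underpass, over the covered nights: $a$ = nights the predator was
detected, $b$ = nights the prey was detected, $c$ = nights both were,
$d = a + b - c$ sample nights. The expected probability of joint detection
is $(a/d)(b/d)$ (kept as an exact rational until report time, 3 d.p.), the
observed is $c/d$, and an exact binomial test with $d$ trials and success
probability $(a/d)(b/d)$ gives a one-tailed p-value: the lower tail
$P(X \le c)$ when observed < expected, the upper tail otherwise, ties
reported with the smaller tail. Pairs are only tested where both groups
have at least `min_nights` detected nights (default 20, configurable) so
sparse data cannot decide the outcome; the field protocol says only
"frequently detected", so the threshold is a package default, logged.

### A structural property of this statistic

With $d = a + b - c$, valid counts ($c \le \min(a, b)$) satisfy
$(a-c)(b-c) \ge 0$, i.e. $c\,d = c(a+b-c) \le ab$, i.e.
$c/d \le (a/d)(b/d)$ — **observed can never exceed expected** (equality
only when $c = a$ or $c = b$). More quantitatively, if predator and prey are truly
independent each night with margins $p_a, p_b$ over the covered nights,
then as the number of nights grows

$$
\frac{\text{observed}}{\text{expected}} \longrightarrow s
  = p_a + p_b - p_a p_b \;<\; 1,
$$

because conditioning the sample on "at least one group detected" inflates
both margins. The one-tailed test against $(a/d)(b/d)$ is therefore
anti-conservative for "avoidance": it rejects downward with probability
approaching 1 as $d$ grows even under independence. The package implements
the statistic exactly as defined because that is the method being
reproduced, and the test suite demonstrates both its exactness (tails match
full enumeration at $d \le 12$ to $10^{-12}$) and this bias (the
calibration check under simulated independence fails, by construction, with
mean observed−expected ≈ $p_a p_b (s-1)/s^2$). Interpreting a significant
"below expected" result as behavioural avoidance should take this into
account; a calibrated alternative is to use all covered nights as $d$.

[interval_stats()] reports, for nights when both groups were detected, the
minimum absolute gap in minutes between any predator and any prey pass that
night (mean ± SE across nights). The estimator behind the published
"mean interval" values is not defined in the field description; this
per-night nearest-neighbour definition is the package's choice, and those
published values are deliberately not used as acceptance targets.

## The synthetic generator

[simulate_records()] emulates the design's statistical structure:

* sites of class underpass (paired end cameras A/B) or forest (one camera);
* a species' site-specific encounter rate $r$ (expected passes per 24 h)
  gives nightly/daily presence with probability $1 - e^{-r}$; given
  presence, the pass count is $1 + \text{Poisson}(\max(0, r-1))$, so the
  presence margins stay exact while the count scale is roughly preserved;
* predator–prey pairs at a site are coupled night-by-night through the 2×2
  odds-ratio root [solve_joint_probability()] (`codetect_odds_ratio`: 1 =
  independence, < 1 = avoidance);
* event times are uniform within the diel window (nocturnal 17:00–07:00,
  diurnal 07:00–17:00; paired-end sites reserve a ~5-minute end margin so
  the duplicate stays inside the window, and the final study night is
  truncated at midnight so nothing falls outside the study);
* an underpass traverse is captured at the second end with probability
  `end_double_capture_prob`, offset uniformly by 0.5–5 minutes (inside the
  15-minute matching window, so duplicates are collapsible);
* spring–summer-only species emit nothing in March–August; outage windows
  silence a camera completely.

Identical configurations (including the seed) give byte-identical record
streams. `default_sim_config()` sketches a compact two-location system
("Port", "Grafton") with a wallaby, a bandicoot, a fox and a lace monitor;
its encounter rates are loose order-of-magnitude analogues of published
annualized detection tables (an underpass wallaby at ~0.45 passes/day ≈
160/52 weeks) and are **not** estimates of any real system.

What the simulator does *not* emulate — and hence what passing tests do not
establish about field data: movement and home ranges (no spatial
autocorrelation between neighbouring sites), behavioural responses other
than the nightly odds ratio (no time-of-night avoidance), observer error in
species identification or direction, multi-animal group dynamics beyond an
occasional 2-individual image, and seasonal drift in encounter rates for
year-round species.

## Numerical and reporting choices

* Timestamps are timezone-naive local time (ISO 8601); internally UTC so
  arithmetic never crosses a DST boundary.
* Optimizer: BFGS, relative tolerance $10^{-12}$, zero starts, ≤ 5
  jittered restarts; $\psi$ fixed at 1 when its estimate exceeds
  $1 - 10^{-6}$; boundary detection probabilities clamped at $10^{-12}$
  inside the likelihood.
* Ranking ties broken by smaller $K$, then model name.
* Rounding happens only at report time: rates 1 d.p., expected/observed
  proportions 3 d.p., AICc tables 2 d.p.
* Test-suite problem sizes: parameter recovery uses 6 sites × 50 weeks;
  model-selection recovery 100 replicates of the same; co-detection power
  and calibration 200 replicates of ~460–500 nights; simulator margin/OR
  recovery ~2000 nights. These sizes give Monte-Carlo errors comfortably
  below the tested tolerances while keeping the default suite fast.

## Known limitations

* The co-detection statistic's downward bias under independence, above.
* AICc's effective-sample-size convention ($n$ = sites) is itself debated;
  with ~10–15 sites the correction term is material, which is why the
  convention is logged rather than silent.
* The patchy-reduction heuristic is estimator-driven; with noisy per-site
  estimates the reduced grouping is data-dependent, and its $K$ does not
  account for that selection step (the same is true of the practice it
  reconstructs).
* The end-matching window and the direction-conflict rule are package
  defaults for quantities the field protocol leaves unstated; both are
  configurable and logged.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- list(
  sim = default_sim_config(seed = 1, study_weeks = 104),
  group_map = list(swamp_wallaby = "prey_wallaby", bandicoot = "prey_small",
                   red_fox = "predator", lace_monitor = "neither"),
  prey_groups = c("prey_small", "prey_wallaby"),
  seasonal_species = "lace_monitor")
res <- run_pipeline(cfg, "report")
res$rankings$swamp_wallaby
res$codetection
```

The output directory then holds the record, pass and rate tables, one
history matrix and model-selection table per species, the detection
estimates of each best model, the co-detection table, and `run_log.txt`
with every defaulted decision.
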