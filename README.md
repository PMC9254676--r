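# underpassr

Camera-trap analysis of wildlife road underpass use against forest
reference sites, including the prey-trap hypothesis tests.

Monitoring programmes for road crossing structures produce streams of
time-stamped camera records from paired cameras inside underpasses and
single cameras at random forest sites. `underpassr` turns those records
into the standard analysis products of this design:

* **Pass collation** — independent passes via the 30-minute separation
  rule, distinct-individual overrides, turn-around exclusions, and
  paired-end deduplication within a configurable matching window; then
  annualized rates (`detections / operational_weeks × 52`).
* **Detection histories** — site × week matrices over {1, 0, missing}
  ("`-`" in CSV), with missing occasions wherever a site had no operational
  camera that week; and nightly (17:00–07:00) detection tables.
* **Detection modelling** — the single-season occupancy likelihood
  `ψ ∏ p^y (1−p)^(1−y) + (1−ψ) 1{all 0}` with occupancy usually fixed at 1,
  fitted by maximum likelihood for null / underpass-vs-forest / patchy
  (site-group) structures, optionally with an austral-season effect on the
  log-odds; ranked by `AICc = −2logL + 2K + 2K(K+1)/(n−K−1)` with Akaike
  weights (n = number of sites; K counts ψ even when fixed).
* **Prey-trap tests** — for a predator group and a prey group at one
  underpass, with `a` predator nights, `b` prey nights, `c` joint nights
  and `d = a + b − c` sample nights, an exact one-tailed binomial test of
  the observed joint proportion `c/d` against the expected `(a/d)(b/d)`;
  plus prey-activity sums/ratios across underpasses and per-night
  predator–prey interval statistics.
* **A seeded synthetic generator** — nightly Bernoulli presence from
  encounter rates, predator–prey coupling through a 2×2 odds ratio
  (`solve_joint_probability()`), diel and seasonal activity windows, camera
  outages and paired-end double captures, so the whole pipeline is
  exercisable and testable without field data.

See the vignette (`vignettes/underpass-analysis.Rmd`) for the model
details, the defaulted conventions (matching window, AICc sample size, K
convention) and a derivation of a structural downward bias in the
co-detection statistic that matters when interpreting "avoidance" results.

## Worked example

```r
library(underpassr)

cfg <- default_sim_config(seed = 1, study_weeks = 104)
records <- simulate_records(cfg)          # 4845 records
passes  <- match_underpass_ends(collate_passes(records))   # 3078 passes

dep <- sim_deployments(cfg)
h <- build_weekly_history(passes[passes$species_id == "swamp_wallaby", ],
                          dep, cfg$outages)
h <- set_site_class(h, setNames(cfg$sites$site_class, cfg$sites$site_id))

f_null   <- fit_detection(h, "null")
f_up     <- fit_detection(h, "underpass")
red      <- reduce_patchy_groups(fit_detection(h, "patchy"))
f_patchy <- fit_detection(h, groups = red, name = "patchy")
rank_models(list(f_null, f_up, f_patchy))
#> Model selection (weekly detection)
#>      Model   AICc  dAICc    W K
#>     patchy 615.31   0.00 0.50 3
#>  underpass 615.31   0.00 0.50 3
#>       null 812.33 197.02 0.00 2
```

The null model (one detection probability everywhere) has essentially no
support (ΔAICc = 197). The reduced patchy model and the underpass model tie
(weight 0.50 each) because in this synthetic system all underpasses share
one encounter rate and all forest sites another, so the data-driven site
grouping recovers exactly the underpass/forest split:

```r
f_patchy
#> Weekly detection model 'patchy' (psi fixed)
#>   8 sites x 104 occasions; logL = -301.66; K = 3; AICc = 615.31
#>   weekly detection probability (spring-summer reference):
#>     g1           p = 0.564 (SE 0.028)
#>     g2           p = 0.96 (SE 0.009)
```

i.e. a weekly detection probability of 0.96 in the underpasses versus 0.56
in the forest. The nightly co-detection test at one underpass:

```r
nt <- build_nightly_table(passes, dep, cfg$outages,
        c(swamp_wallaby = "prey_wallaby", bandicoot = "prey_small",
          red_fox = "predator", lace_monitor = "neither"))
independence_test(codetection_counts(nt, "Port-U2", "predator", "prey_wallaby"))
#> Exact binomial test of nightly co-detection independence
#>   Port-U2: predator vs prey_wallaby, n = 339 sample nights
#>   expected 0.244, observed 0.121 (below-expected), one-tailed p = 1.177e-08
```

This simulation used an odds ratio of 1 (true independence), yet the test
rejects downward — a deliberate illustration of the statistic's structural
bias when the sample nights are defined as `d = a + b − c` (see the
vignette). `run_pipeline(cfg, out_dir)` chains all stages and writes every
table plus a run log of the defaulted decisions.

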