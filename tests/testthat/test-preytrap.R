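# Prey-trap hypothesis machinery: co-detection counts, the exact binomial
# independence test, activity alignment, and interval statistics.

mk_nightly <- function(pred_nights, prey_nights, all_nights) {
  nt <- data.frame(site_id = "U1", night = all_nights, covered = TRUE)
  nt$predator <- as.integer(nt$night %in% pred_nights)
  nt$prey <- as.integer(nt$night %in% prey_nights)
  attr(nt, "groups") <- c("predator", "prey")
  nt
}

test_that("co-detection counts enumerate a, b, c, d", {
  d0 <- as.Date("2015-01-01")
  nt <- mk_nightly(d0 + c(1, 2, 3), d0 + c(3, 4), d0 + 1:10)
  cnt <- codetection_counts(nt, "U1", "predator", "prey", min_nights = 1)
  expect_equal(c(cnt$a, cnt$b, cnt$c, cnt$d), c(3L, 2L, 1L, 4L))
  # disjoint nights: c = 0, d = a + b
  nt <- mk_nightly(d0 + 1:3, d0 + 4:5, d0 + 1:10)
  cnt <- codetection_counts(nt, "U1", "predator", "prey", min_nights = 1)
  expect_equal(c(cnt$c, cnt$d), c(0L, 5L))
  # identical night sets: a = b = c = d, expected = observed = 1
  nt <- mk_nightly(d0 + 1:4, d0 + 1:4, d0 + 1:10)
  cnt <- codetection_counts(nt, "U1", "predator", "prey", min_nights = 1)
  expect_equal(c(cnt$a, cnt$b, cnt$c, cnt$d), rep(4L, 4))
  tst <- independence_test(cnt)
  expect_equal(tst$expected, 1)
  expect_equal(tst$observed, 1)
  expect_equal(tst$p_value, 1)
  # sparse pairs fail the eligibility rule
  cnt <- codetection_counts(nt, "U1", "predator", "prey", min_nights = 20)
  expect_false(cnt$testable)
  # uncovered nights never count
  nt$covered[nt$night == d0 + 1] <- FALSE
  cnt <- codetection_counts(nt, "U1", "predator", "prey", min_nights = 1)
  expect_equal(cnt$a, 3L)
})

test_that("one-tailed binomial p-values are exact", {
  # c = 1, d = 5, expected 0.5: P(X <= 1) = 6/32
  t15 <- codetection_tails(1, 5, 0.5)
  expect_equal(t15$lower, 6 / 32)
  # full-enumeration oracle at d <= 12
  set.seed(3)
  for (rep in 1:60) {
    d <- sample(1:12, 1)
    c <- sample(0:d, 1)
    prob <- stats::runif(1)
    got <- codetection_tails(c, d, prob)
    want <- enum_tails(c, d, prob)
    expect_equal(got$lower, want$lower, tolerance = 1e-12)
    expect_equal(got$upper, want$upper, tolerance = 1e-12)
  }
})

test_that("test direction follows the data and the lower tail is monotone in c", {
  mk <- function(a, b, c) {
    x <- list(site = "U1", predator = "predator", prey = "prey",
              a = a, b = b, c = c, d = a + b - c, n_covered = NA,
              testable = TRUE)
    class(x) <- "codetection_counts"
    x
  }
  below <- independence_test(mk(40, 50, 5))
  expect_equal(below$direction, "below-expected")
  expect_equal(below$p_value, below$tails$lower)
  # with d = a + b - c, observed = c/d never exceeds expected = ab/d^2
  # ((a-c)(b-c) >= 0); equality holds iff c = a or c = b, reported as a tie
  set.seed(9)
  for (r in 1:50) {
    a <- sample(1:40, 1); b <- sample(1:40, 1); cc <- sample(0:min(a, b), 1)
    tst <- independence_test(mk(a, b, cc))
    expect_lte(tst$observed, tst$expected + 1e-12)
  }
  tie <- independence_test(mk(40, 50, 40))
  expect_equal(tie$observed, tie$expected)
  expect_equal(tie$direction, "above-expected")
  expect_equal(tie$p_value, min(tie$tails$lower, tie$tails$upper))
  # holding a, b, d fixed, the lower tail is non-decreasing in c
  d <- 60; a <- 30; b <- 40
  pv <- vapply(0:10, function(cc)
    codetection_tails(cc, d, (a / d) * (b / d))$lower, 0)
  expect_true(all(diff(pv) >= 0))
  # no sample nights at all is untestable
  expect_error(independence_test(mk(0, 0, 0)), "d = 0")
  # expected 0 with no joint detections: certain event, p = 1
  none <- independence_test(mk(5, 0, 0))
  expect_equal(none$expected, 0)
  expect_equal(none$p_value, 1)
  expect_false(none$degenerate)
})

test_that("strong avoidance is detected in at least 90% of replicates", {
  # margins 0.3 / 0.35 over 460 covered nights give d ~ 250
  set.seed(202)
  n_nights <- 460L
  p1 <- 0.30; p2 <- 0.35
  p11 <- solve_joint_probability(p1, p2, 0.05)
  hits <- replicate(200, {
    pred <- stats::runif(n_nights) < p1
    prey <- ifelse(pred, stats::runif(n_nights) < p11 / p1,
                   stats::runif(n_nights) < (p2 - p11) / (1 - p1))
    a <- sum(pred); b <- sum(prey); cc <- sum(pred & prey)
    x <- list(site = "U1", predator = "predator", prey = "prey",
              a = a, b = b, c = cc, d = a + b - cc, n_covered = n_nights,
              testable = TRUE)
    class(x) <- "codetection_counts"
    tst <- independence_test(x)
    tst$direction == "below-expected" && tst$p_value <= 0.001
  })
  expect_gte(mean(hits), 0.9)
})

test_that("prey activity sums and ratios come from the rate table", {
  rates <- data.frame(
    site_id = rep(c("U1", "U2"), each = 3),
    species_id = rep(c("wallaby", "bandicoot", "pademelon"), 2),
    rate = c(100.0, 50.5, 10.1, 20.2, 5.0, 4.9))
  pa <- prey_activity_alignment(rates, c("wallaby", "bandicoot", "pademelon"),
                                c("U1", "U2"))
  expect_equal(unname(pa$sum), c(161, 30))
  expect_equal(pa$ratio["U1", "U2"], round(160.6 / 30.1, 1))
  expect_equal(pa$ratio["U1", "U1"], 1.0)
  expect_error(prey_activity_alignment(rates, c("wallaby", "koala"), "U1"),
               "koala")
})

test_that("interval statistics take the per-night nearest gap", {
  gm <- c(red_fox = "predator", pademelon = "prey")
  p <- rbind(
    pass("2015-01-06T22:00:00", species = "red_fox"),
    pass("2015-01-06T23:30:00", species = "pademelon"),   # gap 90
    pass("2015-01-07T22:00:00", species = "red_fox"),
    pass("2015-01-07T21:00:00", species = "pademelon"),
    pass("2015-01-08T02:00:00", species = "pademelon"))   # min gap 60
  s <- interval_stats(p, "U1", gm, "predator", "prey")
  expect_equal(sort(s$gaps), c(60, 90))
  expect_equal(s$mean, 75)
  expect_equal(s$se, stats::sd(c(60, 90)) / sqrt(2))
  # brute-force all-pairs oracle on a simulated stream
  cfg <- pair_config(seed = 51, weeks = 20, p_pred = 0.4, p_prey = 0.5,
                     double_prob = 0)
  r <- simulate_records(cfg)
  pp <- match_underpass_ends(collate_passes(r))
  st <- interval_stats(pp, "U1", c(fox = "predator", bandicoot = "prey"),
                       "predator", "prey")
  night <- assign_night(pp$timestamp)
  brute <- c()
  for (nt in unique(night)) {
    tp <- pp$timestamp[night == nt & pp$species_id == "fox"]
    ty <- pp$timestamp[night == nt & pp$species_id == "bandicoot"]
    if (length(tp) && length(ty)) {
      brute <- c(brute, min(abs(outer(as.numeric(tp), as.numeric(ty),
                                      "-"))) / 60)
    }
  }
  expect_equal(sort(st$gaps), sort(brute))
  expect_gte(st$n_nights, 2)
  # under two qualifying nights the statistics are undefined
  s1 <- interval_stats(p[1:2, ], "U1", gm, "predator", "prey")
  expect_equal(s1$n_nights, 1L)
  expect_true(is.na(s1$se))
})
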