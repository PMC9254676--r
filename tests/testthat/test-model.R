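# Detection-probability models: likelihood, fitting, AICc, ranking,
# patchy-group reduction.

test_that("site likelihood matches direct arithmetic", {
  # psi = 1, history [1, 0]: log(p (1-p)); maximized at p = 0.5
  f <- function(p) site_loglik(c(1, 0), p)
  expect_equal(f(0.3), log(0.3 * 0.7))
  grid <- seq(0.01, 0.99, by = 0.001)
  expect_equal(grid[which.max(vapply(grid, f, 0))], 0.5, tolerance = 1e-3)
  # psi = 0.5, all-zero history of length 2, p = 0.5
  expect_equal(site_loglik(c(0, 0), 0.5, psi = 0.5), log(0.625))
  # missing occasions are skipped
  expect_equal(site_loglik(c(1, NA, 0), 0.4), log(0.4 * 0.6))
  expect_warning(v <- site_loglik(c(NA, NA), 0.4), "all-missing")
  expect_equal(v, 0)
})

test_that("constant-p MLE equals detections / surveyed occasions", {
  y <- matrix(c(1, 1, 1, rep(0, 7)), nrow = 1)  # 3 of 10
  h <- detection_history(y)
  fit <- fit_detection(h, "null")
  expect_equal(fit$estimates$p, 0.3, tolerance = 1e-5)
  # grid-search oracle agrees
  grid <- seq(0.001, 0.999, by = 1e-4)
  ll <- vapply(grid, function(p) site_loglik(y[1, ], p), 0)
  expect_equal(grid[which.max(ll)], 0.3, tolerance = 1e-3)
})

test_that("maximized log-likelihood matches a dense grid search", {
  y <- matrix(c(1, 0, 1, NA,
                0, 0, 1, 1,
                1, 1, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), NULL))
  h <- detection_history(y)
  # one-group model: 1-d grid
  f_null <- fit_detection(h, "null")
  grid <- seq(0.001, 0.999, by = 5e-4)
  ll1 <- max(vapply(grid, function(p)
    sum(apply(y, 1, site_loglik, p = p)), 0))
  expect_equal(f_null$logLik, ll1, tolerance = 1e-4)
  # two-group model: 2-d grid
  groups <- c(s1 = "a", s2 = "b", s3 = "a")
  f2 <- fit_detection(h, groups = groups)
  g2 <- seq(0.005, 0.995, by = 2e-3)
  ll2 <- max(outer(g2, g2, Vectorize(function(pa, pb)
    site_loglik(y[1, ], pa) + site_loglik(y[2, ], pb) +
      site_loglik(y[3, ], pa))))
  expect_equal(f2$logLik, ll2, tolerance = 1e-4)
})

test_that("nested detection structures never lose likelihood", {
  cfg <- default_sim_config(seed = 23, study_weeks = 30)
  p <- match_underpass_ends(collate_passes(simulate_records(cfg)))
  dep <- sim_deployments(cfg)
  h <- build_weekly_history(p[p$species_id == "swamp_wallaby", ], dep,
                            cfg$outages)
  h <- set_site_class(h, stats::setNames(cfg$sites$site_class,
                                         cfg$sites$site_id))
  f0 <- fit_detection(h, "null")
  f1 <- fit_detection(h, "underpass")
  f2 <- fit_detection(h, "patchy")
  expect_lte(f0$logLik, f1$logLik + 1e-6)
  expect_lte(f1$logLik, f2$logLik + 1e-6)
  # one group for all sites is a reparameterization of the null
  fg <- fit_detection(h, groups = stats::setNames(
    rep("g", length(h$sites)), h$sites))
  expect_equal(fg$logLik, f0$logLik, tolerance = 1e-6)
})

test_that("AICc arithmetic, boundary and monotonicity", {
  expect_equal(aicc(-10, 2, 11), 25.5)
  expect_equal(aicc(-10, 0, 11), 20)
  ks <- 1:5
  vals <- vapply(ks, function(k) aicc(-10, k, 11), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(-10, 10, 11), "undefined")
})

test_that("missing occasions and psi conventions behave as documented", {
  y <- matrix(c(1, 0, 1, 0, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  h <- detection_history(y)
  f <- fit_detection(h, "null")
  # an all-missing occasion changes nothing
  y2 <- cbind(y, NA)
  h2 <- detection_history(y2)
  f2 <- fit_detection(h2, "null")
  expect_equal(f$estimates$p, f2$estimates$p, tolerance = 1e-8)
  expect_equal(f$logLik, f2$logLik, tolerance = 1e-8)
  # K counts psi even when fixed: null model has K = 2
  expect_equal(f$K, 2L)
  expect_equal(f$K_free, 1L)
  # estimated psi runs to the boundary when every site has detections
  fe <- fit_detection(h, "null", occupancy = "estimated")
  expect_true(fe$psi_fixed_at_boundary)
  expect_equal(fe$psi, 1)
  expect_equal(fe$K, 2L)
})

test_that("separated groups sit at the probability bound with infinite SE", {
  y <- matrix(c(1, 0, 1, 0,
                0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  h <- detection_history(y)
  f <- fit_detection(h, "patchy")
  est <- f$estimates[match(c("s1", "s2"), f$estimates$group), ]
  expect_equal(est$p[2], 0)
  expect_true(is.infinite(est$se_p[2]))
  expect_true(est$boundary[2])
  expect_equal(est$p[1], 0.5, tolerance = 1e-5)
})

test_that("group estimates recover the truth within 95% Wald intervals", {
  set.seed(101)
  p_true <- c(a = 0.8, b = 0.2)
  y <- rbind(
    matrix(rbinom(3 * 50, 1, 0.8), nrow = 3),
    matrix(rbinom(3 * 50, 1, 0.2), nrow = 3))
  rownames(y) <- paste0("s", 1:6)
  h <- detection_history(y)
  groups <- stats::setNames(rep(c("a", "b"), each = 3), rownames(y))
  f <- fit_detection(h, groups = groups)
  for (g in c("a", "b")) {
    e <- f$estimates[f$estimates$group == g, ]
    expect_lt(abs(e$p - p_true[[g]]), 1.96 * e$se_p)
  }
  # bias shrinks with more data (parameter recovery at two sample sizes)
  err <- function(wk) {
    yy <- rbind(matrix(rbinom(3 * wk, 1, 0.8), nrow = 3),
                matrix(rbinom(3 * wk, 1, 0.2), nrow = 3))
    rownames(yy) <- paste0("s", 1:6)
    ff <- fit_detection(detection_history(yy), groups = groups)
    sum(abs(ff$estimates$p[match(c("a", "b"), ff$estimates$group)] -
              p_true))
  }
  e_small <- mean(replicate(20, err(15)))
  e_big <- mean(replicate(20, err(150)))
  expect_lt(e_big, e_small)
})

test_that("season covariate shifts detection on the log-odds scale", {
  set.seed(7)
  # 52 weekly occasions: detection much higher in spring-summer
  h0 <- detection_history(matrix(0, 4, 52),
                          week_start = as.Date("2015-01-05"))
  aw <- h0$season == "autumn-winter"
  p_occ <- ifelse(aw, 0.05, 0.6)
  y <- t(replicate(4, rbinom(52, 1, p_occ)))
  rownames(y) <- paste0("s", 1:4)
  h <- detection_history(y, week_start = as.Date("2015-01-05"))
  f <- fit_detection(h, "null", season = TRUE)
  expect_lt(f$beta_season, 0)  # autumn-winter depresses detection
  expect_equal(f$K, 3L)
  pr <- predict(f, data.frame(site = "s1",
                              season = c("spring-summer", "autumn-winter")))
  expect_gt(pr$p[1], pr$p[2])
  expect_equal(pr$p[1], 0.6, tolerance = 0.15)
  expect_equal(pr$p[2], 0.05, tolerance = 0.05)
  # season model strictly improves the likelihood over the null
  f0 <- fit_detection(h, "null")
  expect_gt(f$logLik, f0$logLik)
})

test_that("model ranking orders by AICc with weights and support flags", {
  set.seed(33)
  y <- matrix(rbinom(6 * 20, 1, 0.4), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  h <- detection_history(y, site_class = stats::setNames(
    rep(c("underpass", "forest"), each = 3), paste0("s", 1:6)))
  f0 <- fit_detection(h, "null")
  f1 <- fit_detection(h, "underpass")
  rk <- rank_models(list(f1, f0))
  expect_equal(rk$delta[1], 0)
  expect_equal(sum(rk$weight), 1)
  expect_true(all(diff(rk$AICc) >= 0))
  # equal-AICc fits split the weight evenly
  aw <- akaike_weights(c(100, 100))
  expect_equal(aw$weight, c(0.5, 0.5))
  # a huge delta annihilates the weight (reported two-model contrast)
  aw2 <- akaike_weights(c(1097.30, 1205.85))
  expect_equal(aw2$delta, c(0, 108.55))
  expect_equal(round(aw2$weight, 2), c(1, 0))
  # mismatched histories refuse to rank
  h2 <- detection_history(y[, 1:10])
  expect_error(rank_models(list(f0, fit_detection(h2, "null"))), "differing")
})

test_that("patchy reduction merges sites with overlapping p +/- SE", {
  mk_fit <- function(p, se) {
    sites <- paste0("s", seq_along(p))
    structure(list(
      site_group = stats::setNames(sites, sites),
      estimates = data.frame(group = sites, beta = NA, se_beta = NA,
                             p = p, se_p = se,
                             boundary = !is.finite(se))),
      class = "detection_fit")
  }
  g <- reduce_patchy_groups(mk_fit(c(0.5, 0.55), c(0.1, 0.1)))
  expect_equal(length(unique(g)), 1L)
  g <- reduce_patchy_groups(mk_fit(c(0.2, 0.8), c(0.05, 0.05)))
  expect_equal(length(unique(g)), 2L)
  # single-linkage chain: pairwise overlaps join all three
  g <- reduce_patchy_groups(mk_fit(c(0.2, 0.35, 0.5), c(0.1, 0.1, 0.1)))
  expect_equal(length(unique(g)), 1L)
  # disjoint middle splits the chain
  g <- reduce_patchy_groups(mk_fit(c(0.1, 0.5, 0.9), c(0.05, 0.05, 0.05)))
  expect_equal(length(unique(g)), 3L)
  # boundary site (infinite SE) is a zero-width interval at its estimate
  g <- reduce_patchy_groups(mk_fit(c(0, 0, 0.5), c(Inf, Inf, 0.1)))
  expect_equal(unname(g[1]), unname(g[2]))
  expect_false(g[1] == g[3])
})

test_that("fitted-model methods are coherent", {
  set.seed(5)
  y <- matrix(rbinom(4 * 30, 1, 0.35), nrow = 4,
              dimnames = list(paste0("s", 1:4), NULL))
  h <- detection_history(y)
  f <- fit_detection(h, "null")
  expect_s3_class(f, "detection_fit")
  expect_equal(unname(AICc(f)), aicc(f$logLik, f$K, 4))
  expect_named(coef(f), "logit_p:all")
  expect_equal(attr(logLik(f), "df"), f$K_free)
  pr <- predict(f)
  expect_equal(nrow(pr), 4L)
  expect_true(all(pr$p > 0 & pr$p < 1))
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_equal(dim(sim[[1]]$y), dim(y))
  expect_output(print(f), "Weekly detection model")
  expect_output(print(summary(f)), "log-odds coefficients")
})
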