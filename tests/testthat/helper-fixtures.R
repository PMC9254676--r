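# Small programmatic fixtures shared across test files.

# a camera record row with sensible defaults
rec <- function(ts, site = "U1", class = "underpass", camera = "U1-A",
                end = "A", species = "swamp_wallaby", n = 1L,
                direction = "toward", distinct = FALSE) {
  data.frame(site_id = site, site_class = class, camera_id = camera,
             end_label = end, species_id = species,
             timestamp = underpassr:::parse_timestamp(ts),
             n_individuals = n, direction = direction,
             distinct_individual_flag = distinct)
}

recs <- function(...) do.call(rbind, list(...))

# a pass row (for end-matching tests without going through collation)
pass <- function(ts, site = "U1", class = "underpass", end = "A",
                 species = "swamp_wallaby", direction = "unknown", n = 1L) {
  data.frame(site_id = site, site_class = class, species_id = species,
             camera_id = paste0(site, "-", end), contributing_ends = end,
             timestamp = underpassr:::parse_timestamp(ts),
             direction = direction, n_individuals = n, n_records = 1L)
}

# deployment covering [start, start + weeks) for the given cameras
deploy <- function(site, cameras, start = "2015-01-05T00:00:00", weeks = 10) {
  s <- underpassr:::parse_timestamp(start)
  data.frame(site_id = site, camera_id = cameras, start = s,
             end = s + weeks * 7 * 86400)
}

# minimal two-species nocturnal sim config on one underpass site, tuned so
# each active night yields exactly one traverse (rate <= 1 => Poisson(0))
pair_config <- function(seed, weeks, p_pred, p_prey, odds_ratio = 1,
                        double_prob = 0.7) {
  sim_config(
    sites = data.frame(site_id = "U1", site_class = "underpass",
                       n_cameras = 2L),
    species = data.frame(species_id = c("fox", "bandicoot"),
                         diel = "nocturnal", seasonal = "year-round",
                         role = c("predator", "prey")),
    rates = data.frame(site_id = "U1",
                       species_id = c("fox", "bandicoot"),
                       rate = -log(1 - c(p_pred, p_prey))),
    study_start = as.Date("2015-01-05"), study_weeks = weeks,
    end_double_capture_prob = double_prob, codetect_odds_ratio = odds_ratio,
    seed = seed)
}

# empirical odds ratio of a 2x2 presence table
empirical_or <- function(x, y) {
  n11 <- sum(x & y); n00 <- sum(!x & !y)
  n10 <- sum(x & !y); n01 <- sum(!x & y)
  (n11 * n00) / (n10 * n01)
}

# brute-force binomial tail by full outcome enumeration (d <= 12)
enum_tails <- function(c, d, prob) {
  outcomes <- 0:d
  pmf <- choose(d, outcomes) * prob^outcomes * (1 - prob)^(d - outcomes)
  list(lower = sum(pmf[outcomes <= c]), upper = sum(pmf[outcomes >= c]))
}
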