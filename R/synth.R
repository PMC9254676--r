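# Synthetic camera-trap data generator.
#
# Emulates the monitoring design the analysis assumes: paired-end cameras in
# underpasses, single cameras at forest reference sites, nocturnal mammals
# and a diurnal, warm-season reptile, camera outages, and a tunable nightly
# predator-prey dependence expressed as a 2x2 odds ratio.

#' Joint nightly presence probability for a given odds ratio
#'
#' Solves for `p11 = P(predator and prey both active on a night)` such that
#' the 2x2 table with margins `p_pred`, `p_prey` has the requested odds
#' ratio: `p11 * p00 / (p10 * p01) = odds_ratio`. This is the admissible
#' root of the quadratic `(OR-1) x^2 - (1 + (OR-1)(p1+p2)) x + OR p1 p2 = 0`,
#' constrained to the Frechet bounds
#' `max(0, p1+p2-1) <= p11 <= min(p1, p2)`.
#'
#' An odds ratio of 1 gives independence (`p11 = p1 * p2`); values below 1
#' give avoidance, above 1 attraction. Margins exactly 0 or 1 degenerate to
#' the product.
#'
#' @param p_pred,p_prey marginal nightly presence probabilities in \[0, 1\].
#' @param odds_ratio positive real; 1 = independence.
#' @return the joint probability `p11`.
#' @export
#' @examples
#' solve_joint_probability(0.5, 0.5, 1)   # 0.25
#' solve_joint_probability(0.5, 0.5, 9)   # 0.375
solve_joint_probability <- function(p_pred, p_prey, odds_ratio) {
  if (!is.numeric(odds_ratio) || length(odds_ratio) != 1L || is.na(odds_ratio) ||
      odds_ratio <= 0) {
    stop("odds_ratio must be a single positive number")
  }
  if (any(c(p_pred, p_prey) < 0) || any(c(p_pred, p_prey) > 1) ||
      anyNA(c(p_pred, p_prey))) {
    stop("margins must lie in [0, 1]")
  }
  # degenerate margins: table collapses, independence product is exact
  if (p_pred %in% c(0, 1) || p_prey %in% c(0, 1) || odds_ratio == 1) {
    return(p_pred * p_prey)
  }
  a <- odds_ratio - 1
  b <- 1 + (p_pred + p_prey) * a
  disc <- b^2 - 4 * odds_ratio * a * p_pred * p_prey
  x <- (b - sqrt(max(disc, 0))) / (2 * a)
  lo <- max(0, p_pred + p_prey - 1)
  hi <- min(p_pred, p_prey)
  min(max(x, lo), hi)
}

#' Specify a synthetic camera-trap study
#'
#' @param sites data.frame with columns `site_id`, `site_class`
#'   (`"underpass"` or `"forest"`) and `n_cameras` (2 = paired ends; forest
#'   sites must have exactly 1).
#' @param species data.frame with columns `species_id`, `diel`
#'   (`"nocturnal"` = active 17:00-07:00, `"diurnal"` = 07:00-17:00),
#'   `seasonal` (`"year-round"` or `"spring-summer"`; the latter emit
#'   nothing March-August) and `role` (`"prey"`, `"predator"`, `"neither"`).
#' @param rates data.frame with columns `site_id`, `species_id`, `rate`:
#'   expected passes per 24 h at that site. Missing combinations get rate 0.
#'   A rate `r` implies nightly presence probability `1 - exp(-r)`.
#' @param study_start Date (or string) of the first monitored day.
#' @param study_weeks positive integer number of weeks.
#' @param outages optional data.frame `site_id, camera_id, start, end` of
#'   camera downtime; no records are generated inside these windows.
#' @param end_double_capture_prob probability in \[0,1\] that an underpass
#'   traverse is recorded at both ends.
#' @param codetect_odds_ratio positive real: nightly predator-prey
#'   dependence (1 = independence, < 1 = avoidance).
#' @param seed integer RNG seed; identical configs give identical streams.
#' @return an object of class `sim_config`.
#' @seealso [simulate_records()], [default_sim_config()]
#' @export
sim_config <- function(sites, species, rates, study_start, study_weeks,
                       outages = NULL, end_double_capture_prob = 0.7,
                       codetect_odds_ratio = 1, seed = 1L) {
  sites <- as.data.frame(sites)
  species <- as.data.frame(species)
  rates <- as.data.frame(rates)
  stopifnot(all(c("site_id", "site_class", "n_cameras") %in% names(sites)),
            all(c("species_id", "diel", "seasonal", "role") %in% names(species)),
            all(c("site_id", "species_id", "rate") %in% names(rates)))
  if (!all(sites$site_class %in% c("underpass", "forest"))) {
    stop("site_class must be 'underpass' or 'forest'")
  }
  if (!all(sites$n_cameras %in% c(1L, 2L))) stop("n_cameras must be 1 or 2")
  if (any(sites$site_class == "forest" & sites$n_cameras != 1L)) {
    stop("forest sites must have exactly 1 camera")
  }
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id")
  if (!all(species$diel %in% c("nocturnal", "diurnal"))) {
    stop("diel must be 'nocturnal' or 'diurnal'")
  }
  if (!all(species$seasonal %in% c("year-round", "spring-summer"))) {
    stop("seasonal must be 'year-round' or 'spring-summer'")
  }
  if (!all(species$role %in% c("prey", "predator", "neither"))) {
    stop("role must be 'prey', 'predator' or 'neither'")
  }
  if (any(rates$rate < 0)) stop("encounter rates must be >= 0")
  if (!all(rates$site_id %in% sites$site_id)) stop("rates reference unknown site")
  if (!all(rates$species_id %in% species$species_id)) {
    stop("rates reference unknown species")
  }
  study_weeks <- as.integer(study_weeks)
  if (is.na(study_weeks) || study_weeks < 1L) stop("study_weeks must be >= 1")
  if (end_double_capture_prob < 0 || end_double_capture_prob > 1) {
    stop("end_double_capture_prob must be in [0, 1]")
  }
  if (codetect_odds_ratio <= 0) stop("codetect_odds_ratio must be > 0")
  outages <- normalize_intervals(outages, "outages")
  cfg <- list(sites = sites, species = species, rates = rates,
              study_start = as.Date(study_start), study_weeks = study_weeks,
              outages = outages,
              end_double_capture_prob = end_double_capture_prob,
              codetect_odds_ratio = codetect_odds_ratio,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic camera-trap study configuration\n")
  cat(sprintf("  %d sites (%d underpass, %d forest), %d species, %d weeks from %s\n",
              nrow(x$sites), sum(x$sites$site_class == "underpass"),
              sum(x$sites$site_class == "forest"), nrow(x$species),
              x$study_weeks, format(x$study_start)))
  cat(sprintf("  end double-capture prob %.2f, co-detection odds ratio %.3g, seed %d\n",
              x$end_double_capture_prob, x$codetect_odds_ratio, x$seed))
  invisible(x)
}

#' Default two-location synthetic study
#'
#' A compact stand-in for the monitored system: underpass and forest sites at
#' two locations ("Port", "Grafton"), nocturnal macropod/bandicoot prey, a
#' nocturnal fox predator, and a diurnal spring-summer lace monitor.
#' Encounter rates are loose, order-of-magnitude analogues of published
#' annualized detection rates, not estimates of the study system.
#'
#' @param seed integer RNG seed.
#' @param study_weeks number of monitored weeks (default 104).
#' @param codetect_odds_ratio nightly predator-prey odds ratio (default 1).
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, study_weeks = 104L,
                               codetect_odds_ratio = 1) {
  sites <- data.frame(
    site_id = c("Port-U1", "Port-U2", "Port-U3", "Port-F1", "Port-F2",
                "Grafton-U1", "Grafton-U2", "Grafton-F1"),
    site_class = c("underpass", "underpass", "underpass", "forest", "forest",
                   "underpass", "underpass", "forest"),
    n_cameras = c(2L, 2L, 2L, 1L, 1L, 2L, 2L, 1L)
  )
  species <- data.frame(
    species_id = c("swamp_wallaby", "bandicoot", "red_fox", "lace_monitor"),
    diel = c("nocturnal", "nocturnal", "nocturnal", "diurnal"),
    seasonal = c("year-round", "year-round", "year-round", "spring-summer"),
    role = c("prey", "prey", "predator", "neither")
  )
  # expected passes per 24 h; underpasses busier for wallaby/monitor,
  # fox concentrated in underpasses, bandicoots similar everywhere
  base <- expand.grid(site_id = sites$site_id,
                      species_id = species$species_id,
                      stringsAsFactors = FALSE)
  underpass <- sites$site_class[match(base$site_id, sites$site_id)] == "underpass"
  base$rate <- 0
  base$rate[base$species_id == "swamp_wallaby"] <-
    ifelse(underpass[base$species_id == "swamp_wallaby"], 0.45, 0.12)
  base$rate[base$species_id == "bandicoot"] <-
    ifelse(underpass[base$species_id == "bandicoot"], 0.10, 0.12)
  base$rate[base$species_id == "red_fox"] <-
    ifelse(underpass[base$species_id == "red_fox"], 0.15, 0.01)
  base$rate[base$species_id == "lace_monitor"] <-
    ifelse(underpass[base$species_id == "lace_monitor"], 0.20, 0.02)
  outages <- data.frame(
    site_id = "Port-U1", camera_id = "Port-U1-A",
    start = "2014-06-18T00:00:00", end = "2014-08-06T00:00:00"
  )
  sim_config(sites, species, base, study_start = as.Date("2014-01-06"),
             study_weeks = study_weeks, outages = outages,
             end_double_capture_prob = 0.7,
             codetect_odds_ratio = codetect_odds_ratio, seed = seed)
}

# camera ids for a site
site_cameras <- function(site_id, n_cameras) {
  if (n_cameras == 2L) paste0(site_id, "-", c("A", "B")) else paste0(site_id, "-C")
}

#' Simulate a camera-trap record stream
#'
#' Per site x species, activity is nightly (or daily, for diurnal species)
#' Bernoulli presence with probability `1 - exp(-rate)`; predator-prey pairs
#' at a site are coupled through [solve_joint_probability()] at the
#' configured odds ratio. Given presence, the number of passes is
#' `1 + Poisson(max(0, rate - 1))` and event times are uniform within the
#' species' diel window (nocturnal 17:00-07:00, diurnal 07:00-17:00).
#' Underpass traverses are duplicated at the second end with probability
#' `end_double_capture_prob` and a uniform 0.5-5 minute offset. Records
#' falling in a camera's outage windows are dropped. Spring-summer-only
#' species emit nothing March-August.
#'
#' @param config a [sim_config()].
#' @return data.frame of camera records (site_id, site_class, camera_id,
#'   end_label, species_id, timestamp, n_individuals, direction,
#'   distinct_individual_flag), sorted by site, camera, time. The latent
#'   per-day presence table is attached as `attr(, "presence")` and the
#'   outage log as `attr(, "outages")`.
#' @export
simulate_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # localize RNG so the stream is reproducible and callers are undisturbed
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  days <- seq(config$study_start, by = 1L,
              length.out = 7L * config$study_weeks)
  n_days <- length(days)
  months <- as.integer(format(days, "%m"))
  study_end <- as.POSIXct(as.character(config$study_start + 7L * config$study_weeks),
                          tz = "UTC")
  study_begin <- as.POSIXct(as.character(config$study_start), tz = "UTC")

  # warn about sites whose every camera is fully under outage
  for (i in seq_len(nrow(config$sites))) {
    cams <- site_cameras(config$sites$site_id[i], config$sites$n_cameras[i])
    dep <- data.frame(site_id = config$sites$site_id[i], camera_id = cams,
                      start = study_begin, end = study_end)
    op <- camera_operational(dep, config$outages)
    if (nrow(op) == 0L) {
      warning("site ", config$sites$site_id[i],
              " has no operational camera time; it will be unanalyzable")
    }
  }

  rate_of <- function(site, sp) {
    r <- config$rates$rate[config$rates$site_id == site &
                             config$rates$species_id == sp]
    if (length(r)) r[1] else 0
  }

  rec <- list()
  pres <- list()
  for (si in seq_len(nrow(config$sites))) {
    site <- config$sites$site_id[si]
    sclass <- config$sites$site_class[si]
    ncam <- config$sites$n_cameras[si]
    cams <- site_cameras(site, ncam)

    sp_tab <- config$species
    sp_tab$rate <- vapply(sp_tab$species_id, function(s) rate_of(site, s), 0)
    sp_tab$p <- 1 - exp(-sp_tab$rate)
    # seasonal gating mask per day (TRUE = allowed to be active)
    allow <- function(k) {
      if (sp_tab$seasonal[k] == "spring-summer") !(months %in% GATED_MONTHS)
      else rep(TRUE, n_days)
    }

    # the site's coupling predator: first predator with positive rate
    pred_k <- which(sp_tab$role == "predator" & sp_tab$p > 0)[1]
    pred_active <- rep(FALSE, n_days)
    if (!is.na(pred_k)) {
      pred_active <- stats::runif(n_days) < sp_tab$p[pred_k]
      pred_active <- pred_active & allow(pred_k)
    }

    for (k in seq_len(nrow(sp_tab))) {
      p_sp <- sp_tab$p[k]
      if (p_sp == 0) next
      if (!is.na(pred_k) && k == pred_k) {
        active <- pred_active
      } else if (sp_tab$role[k] == "prey" && !is.na(pred_k) &&
                 config$codetect_odds_ratio != 1 &&
                 sp_tab$p[pred_k] < 1 && p_sp < 1) {
        p11 <- solve_joint_probability(sp_tab$p[pred_k], p_sp,
                                       config$codetect_odds_ratio)
        p_given <- p11 / sp_tab$p[pred_k]
        p_not <- (p_sp - p11) / (1 - sp_tab$p[pred_k])
        u <- stats::runif(n_days)
        active <- ifelse(pred_active, u < p_given, u < p_not) & allow(k)
      } else {
        active <- (stats::runif(n_days) < p_sp) & allow(k)
      }
      pres[[length(pres) + 1L]] <- data.frame(
        site_id = site, species_id = sp_tab$species_id[k], day = days,
        present = active
      )
      idx <- which(active)
      if (!length(idx)) next
      lam <- max(0, sp_tab$rate[k] - 1)
      n_ev <- 1L + stats::rpois(length(idx), lam)
      day_of_ev <- rep(days[idx], n_ev)
      nev <- length(day_of_ev)
      base <- as.POSIXct(as.character(day_of_ev), tz = "UTC")
      # paired-end sites reserve a small end margin so the delayed
      # duplicate record stays inside the diel window
      margin <- if (ncam == 2L) 301 else 0
      win <- if (sp_tab$diel[k] == "nocturnal") 14 * 3600 else 10 * 3600
      win_start <- if (sp_tab$diel[k] == "nocturnal") 17 * 3600 else 7 * 3600
      win <- rep(win, nev)
      if (sp_tab$diel[k] == "nocturnal") {
        # the final night is truncated at midnight so no record falls
        # after the study window closes
        win[day_of_ev == days[n_days]] <- 7 * 3600
      }
      ts <- base + win_start + floor(stats::runif(nev) * (win - margin))
      dir <- sample(c("toward", "away"), nev, replace = TRUE)
      n_ind <- 1L + stats::rbinom(nev, 1L, 0.05)
      if (ncam == 2L) {
        primary <- sample(cams, nev, replace = TRUE)
        dup <- stats::runif(nev) < config$end_double_capture_prob
        other <- ifelse(primary == cams[1], cams[2], cams[1])
        off <- floor(stats::runif(nev, 0.5, 5) * 60)
        r1 <- data.frame(site_id = site, site_class = sclass,
                         camera_id = primary,
                         end_label = substring(primary, nchar(primary)),
                         species_id = sp_tab$species_id[k], timestamp = ts,
                         n_individuals = n_ind, direction = dir,
                         distinct_individual_flag = FALSE)
        r2 <- r1[dup, , drop = FALSE]
        if (nrow(r2)) {
          r2$camera_id <- other[dup]
          r2$end_label <- substring(r2$camera_id, nchar(r2$camera_id))
          r2$timestamp <- r2$timestamp + off[dup]
        }
        rec[[length(rec) + 1L]] <- rbind(r1, r2)
      } else {
        rec[[length(rec) + 1L]] <- data.frame(
          site_id = site, site_class = sclass, camera_id = cams[1],
          end_label = "none", species_id = sp_tab$species_id[k],
          timestamp = ts, n_individuals = n_ind, direction = dir,
          distinct_individual_flag = FALSE)
      }
    }
  }

  records <- if (length(rec)) do.call(rbind, rec) else data.frame(
    site_id = character(), site_class = character(), camera_id = character(),
    end_label = character(), species_id = character(),
    timestamp = parse_timestamp(character()), n_individuals = integer(),
    direction = character(), distinct_individual_flag = logical())

  # outage masking and study-window clipping
  if (nrow(records)) {
    keep <- records$timestamp < study_end
    if (nrow(config$outages)) {
      for (j in seq_len(nrow(config$outages))) {
        o <- config$outages[j, ]
        keep <- keep & !(records$camera_id == o$camera_id &
                           records$timestamp >= o$start &
                           records$timestamp < o$end)
      }
    }
    records <- records[keep, , drop = FALSE]
    records <- records[order(records$site_id, records$camera_id,
                             records$species_id, records$timestamp), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  presence <- if (length(pres)) do.call(rbind, pres) else NULL
  attr(records, "presence") <- presence
  attr(records, "outages") <- config$outages
  attr(records, "study_start") <- config$study_start
  attr(records, "study_weeks") <- config$study_weeks
  records
}

#' Camera deployment table implied by a simulation config
#'
#' Every camera of every site is deployed for the full study window; outages
#' are supplied separately. Convenience for feeding
#' [build_weekly_history()] and [build_nightly_table()].
#'
#' @param config a [sim_config()].
#' @return data.frame `site_id, camera_id, start, end`.
#' @export
sim_deployments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(seq_len(nrow(config$sites)), function(i) {
    cams <- site_cameras(config$sites$site_id[i], config$sites$n_cameras[i])
    data.frame(site_id = config$sites$site_id[i], camera_id = cams)
  })
  out <- do.call(rbind, rows)
  out$start <- as.POSIXct(as.character(config$study_start), tz = "UTC")
  out$end <- out$start + as.difftime(7L * config$study_weeks, units = "days")
  out
}
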