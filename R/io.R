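# File formats, configuration and the end-to-end pipeline.
#
# All tables are plain CSV (comma separator, UTF-8, "." decimal). The
# history matrix uses "-" as its missing code. Timestamps are ISO 8601
# local time without timezone.

RECORD_COLS <- c("site_id", "site_class", "camera_id", "end_label",
                 "species_id", "timestamp", "n_individuals", "direction",
                 "distinct_individual_flag")

#' Read / write camera record tables
#'
#' Unknown columns are preserved on read but ignored by the analysis.
#'
#' @param path file path.
#' @param records data.frame of camera records.
#' @return `read_records()` returns the record data.frame with parsed
#'   timestamps; `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(RECORD_COLS, names(x))
  if (length(miss)) stop("record file lacks column(s): ",
                         paste(miss, collapse = ", "))
  x$timestamp <- parse_timestamp(x$timestamp)
  x$distinct_individual_flag <- as.logical(x$distinct_individual_flag)
  x
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  out <- records
  out$timestamp <- format_timestamp(parse_timestamp(out$timestamp))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write camera outage and deployment interval tables
#'
#' Both use columns `site_id, camera_id, start, end`.
#'
#' @param path file path.
#' @param intervals data.frame of intervals.
#' @return `read_intervals()` returns the parsed data.frame.
#' @export
read_intervals <- function(path) {
  normalize_intervals(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_intervals
#' @export
write_intervals <- function(intervals, path) {
  out <- normalize_intervals(intervals)
  out$start <- format_timestamp(out$start)
  out$end <- format_timestamp(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write pass tables
#'
#' @param path file path.
#' @param passes data.frame of passes from [collate_passes()].
#' @return `read_passes()` returns the parsed data.frame.
#' @export
read_passes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- parse_timestamp(x$timestamp)
  x$contributing_ends[is.na(x$contributing_ends)] <- ""
  x
}

#' @rdname read_passes
#' @export
write_passes <- function(passes, path) {
  out <- passes
  out$timestamp <- format_timestamp(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a weekly detection history matrix
#'
#' One row per site; cells are `1`, `0`, or `-` for missing occasions.
#' Column headers are the occasion week-start dates.
#'
#' @param history a `detection_history`.
#' @param path file path.
#' @param site_class optional named vector recorded alongside on read.
#' @return `read_history()` reconstructs the `detection_history`.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "detection_history"))
  m <- history$y
  cells <- ifelse(is.na(m), "-", as.character(m))
  df <- data.frame(site_id = rownames(m),
                   site_class = unname(history$site_class[rownames(m)]),
                   cells, check.names = FALSE)
  names(df) <- c("site_id", "site_class", format(history$occasions))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  occasions <- as.Date(names(df)[-(1:2)])
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  m[m == "-"] <- NA
  y <- matrix(as.numeric(m), nrow = nrow(df),
              dimnames = list(df$site_id, format(occasions)))
  structure(list(y = y, occasions = occasions, season = season_of(occasions),
                 sites = df$site_id,
                 site_class = stats::setNames(df$site_class, df$site_id)),
            class = "detection_history")
}

#' Read a pipeline configuration file
#'
#' YAML with nested sections mirroring the arguments of [run_pipeline()];
#' see the package vignette for the layout.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

ranking_table <- function(ranking) {
  data.frame(model = ranking$model, AICc = round(ranking$AICc, 2),
             dAICc = round(ranking$delta, 2), W = round(ranking$weight, 2),
             K = ranking$K)
}

#' Run the full underpass-use analysis pipeline
#'
#' simulate-or-read records, collate passes, deduplicate paired ends, build
#' weekly histories, fit and rank detection models, and run the nightly
#' co-detection independence tests. All stage outputs are written as CSV
#' under `out_dir` together with a run log that echoes every defaulted
#' analysis decision, so the report is auditable and every number is
#' re-derivable from the intermediate files.
#'
#' @param config named list (or a `sim_config` for a pure simulation run)
#'   with elements: `sim` (a [sim_config()]) or `records_file` +
#'   `deployments_file` (+ optional `outages_file`); `match_window_minutes`
#'   (default 15); `group_map` (named list/vector species -> group;
#'   required for co-detection tests); `predator_group` (default
#'   `"predator"`); `prey_groups` (character vector); `species_to_model`
#'   (default: all detected); `seasonal_species` (fitted with +season
#'   models); `min_nights` (eligibility, default 20).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the passes, rate table, histories,
#'   rankings, detection-estimate tables and co-detection results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (inherits(config, "sim_config")) config <- list(sim = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    if (!inherits(sim, "sim_config")) stop("config$sim must be a sim_config")
    records <- simulate_records(sim)
    deployments <- sim_deployments(sim)
    outages <- sim$outages
    note("input: simulated records (seed %d, %d weeks)", sim$seed,
         sim$study_weeks)
  } else {
    records <- read_records(config$records_file)
    deployments <- read_intervals(config$deployments_file)
    outages <- if (!is.null(config$outages_file))
      read_intervals(config$outages_file) else NULL
    note("input: records from %s", config$records_file)
  }
  write_records(records, file.path(out_dir, "records.csv"))

  # --- collation ------------------------------------------------------------
  window <- config$match_window_minutes %||% 15
  note("pass separation rule: >= 30 min or distinct individual (default)")
  note("end-matching window: %g min%s", window,
       if (is.null(config$match_window_minutes)) " (default)" else "")
  passes <- collate_passes(records)
  passes <- match_underpass_ends(passes, window_minutes = window)
  write_passes(passes, file.path(out_dir, "passes.csv"))

  op <- camera_operational(deployments, outages)
  site_weeks <- vapply(sort(unique(deployments$site_id)), function(s) {
    ivs <- op[op$site_id == s, , drop = FALSE]
    if (nrow(ivs) == 0L) return(0)
    # site-level coverage: union over cameras
    u <- ivs[1, c("start", "end"), drop = FALSE]
    for (i in seq_len(nrow(ivs))[-1]) {
      gap <- interval_subtract(ivs[i, c("start", "end")], u)
      u <- rbind(u, gap)
    }
    sum(as.numeric(u$end) - as.numeric(u$start)) / (7 * 86400)
  }, 0)
  dead <- names(site_weeks)[site_weeks <= 0]
  if (length(dead)) {
    note("excluded site(s) with zero operational weeks: %s",
         paste(dead, collapse = ", "))
    deployments <- deployments[!(deployments$site_id %in% dead), , drop = FALSE]
    passes <- passes[!(passes$site_id %in% dead), , drop = FALSE]
  }
  rates <- annualized_rates(passes, site_weeks[site_weeks > 0])
  utils::write.csv(rates, file.path(out_dir, "rate_table.csv"),
                   row.names = FALSE, quote = FALSE)

  all_sites <- sort(unique(deployments$site_id))
  if (!is.null(config$sim)) {
    site_class <- stats::setNames(
      config$sim$sites$site_class[match(all_sites, config$sim$sites$site_id)],
      all_sites)
  } else {
    site_class <- stats::setNames(
      records$site_class[match(all_sites, records$site_id)], all_sites)
  }

  # --- detection modelling ----------------------------------------------------
  species_list <- config$species_to_model %||% sort(unique(passes$species_id))
  seasonal <- config$seasonal_species %||% character()
  note("AICc effective sample size: number of sites; K counts psi even when fixed")
  rankings <- list()
  estimates <- list()
  histories <- list()
  for (sp in species_list) {
    sp_pass <- passes[passes$species_id == sp, , drop = FALSE]
    h <- build_weekly_history(sp_pass, deployments, outages)
    h <- set_site_class(h, site_class[!is.na(site_class)])
    histories[[sp]] <- h
    write_history(h, file.path(out_dir, paste0("history_", sp, ".csv")))
    fits <- list(fit_detection(h, "null"), fit_detection(h, "underpass"))
    full <- fit_detection(h, "patchy")
    red <- reduce_patchy_groups(full)
    fits <- c(fits, list(fit_detection(h, groups = red, name = "patchy")))
    if (sp %in% seasonal) {
      fits <- c(fits,
                list(fit_detection(h, groups = red, season = TRUE,
                                   name = "patchy"),
                     fit_detection(h, "null", season = TRUE, name = "season")))
    }
    ok <- vapply(fits, function(f)
      !inherits(try(AICc(f), silent = TRUE), "try-error"), TRUE)
    if (any(!ok)) note("%s: %d fit(s) dropped from ranking (AICc undefined)",
                       sp, sum(!ok))
    if (sum(ok) >= 2L) {
      rk <- rank_models(fits[ok])
      rankings[[sp]] <- rk
      utils::write.csv(ranking_table(rk),
                       file.path(out_dir, paste0("model_selection_", sp, ".csv")),
                       row.names = FALSE, quote = FALSE)
      best <- attr(rk, "fits")[[1]]
    } else {
      note("%s: too few rankable models, reporting the most general fit", sp)
      best <- fits[[length(fits)]]
    }
    est <- predict(best)
    est$p <- round(est$p, 3)
    est$se <- round(est$se, 3)
    estimates[[sp]] <- est
    utils::write.csv(est,
                     file.path(out_dir, paste0("detection_estimates_", sp, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  # --- prey-trap co-detection tests -----------------------------------------
  codetect <- NULL
  if (!is.null(config$group_map)) {
    gm <- unlist(config$group_map)
    nightly <- build_nightly_table(passes, deployments, outages, gm)
    pred <- config$predator_group %||% "predator"
    preys <- config$prey_groups %||% setdiff(attr(nightly, "groups"), pred)
    min_nights <- config$min_nights %||% 20L
    note("co-detection eligibility: >= %d detected nights per group%s",
         min_nights, if (is.null(config$min_nights)) " (default)" else "")
    ups <- names(site_class)[!is.na(site_class) & site_class == "underpass"]
    rows <- list()
    for (u in ups) {
      for (pg in preys) {
        cnt <- codetection_counts(nightly, u, pred, pg, min_nights)
        if (!cnt$testable) next
        tst <- independence_test(cnt)
        rows[[length(rows) + 1L]] <- data.frame(
          site = u, prey = pg, n = cnt$d,
          expected = round(tst$expected, 3), observed = round(tst$observed, 3),
          direction = tst$direction, p_value = signif(tst$p_value, 3))
      }
    }
    if (length(rows)) {
      codetect <- do.call(rbind, rows)
      utils::write.csv(codetect, file.path(out_dir, "codetection_tests.csv"),
                       row.names = FALSE, quote = FALSE)
    } else {
      note("no underpass x prey pair met the co-detection eligibility rule")
    }
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(records = records, passes = passes, rates = rates,
                 histories = histories, rankings = rankings,
                 estimates = estimates, codetection = codetect,
                 log = log_lines))
}

#' Reported annualized detection rates bundled with the package
#'
#' The per-52-week detection rates reported for the Port Macquarie ("Port")
#' and Grafton underpass/forest monitoring programme, in long format. These
#' are inputs for the descriptive prey-activity comparisons
#' ([prey_activity_alignment()]); empty cells (sites not monitored at a
#' location) are dropped.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return data.frame `location, site, site_id, species_id, rate` where
#'   `site` is the short column label (F1..U7) and `site_id` is
#'   `location-site`.
#' @export
read_reported_rates <- function(path = system.file(
  "extdata", "port_grafton_rates_per52wk.csv", package = "underpassr")) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  site_cols <- setdiff(names(w), c("location", "species_id"))
  out <- do.call(rbind, lapply(site_cols, function(s) {
    data.frame(location = w$location, site = s, species_id = w$species_id,
               rate = suppressWarnings(as.numeric(w[[s]])))
  }))
  out <- out[!is.na(out$rate), , drop = FALSE]
  out$site_id <- paste(out$location, out$site, sep = "-")
  rownames(out) <- NULL
  out[, c("location", "site", "site_id", "species_id", "rate")]
}
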