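# Weekly detection histories (for detection modelling) and nightly
# detection tables (for the co-detection independence test).

#' Assign a timestamp to its monitoring night
#'
#' A night spans 17:00-07:00 and is indexed by the calendar date of its
#' 17:00 start: times in \[17:00, 24:00) map to that date, times in
#' \[00:00, 07:00) map to the previous date, and daytime records
#' (\[07:00, 17:00)) map to no night (`NA`).
#'
#' @param timestamp POSIXct (or parseable) vector.
#' @return Date vector with `NA` for daytime records.
#' @export
#' @examples
#' assign_night(c("2015-03-10T23:30:00", "2015-03-11T03:00:00",
#'                "2015-03-11T12:00:00"))
assign_night <- function(timestamp) {
  t <- parse_timestamp(timestamp)
  d <- as.Date(t, tz = "UTC")
  h <- as.integer(format(t, "%H", tz = "UTC"))
  out <- d
  out[h < 7] <- d[h < 7] - 1L
  out[h >= 7 & h < 17] <- NA
  out
}

#' Build a weekly detection history
#'
#' One row per site, one column per weekly occasion. A cell is 1 if the
#' site had at least one pass that week, 0 if it was operational for any
#' part of the week with no pass, and missing (`NA`) if it had zero
#' operational coverage that week (malfunction, theft, not yet deployed, or
#' removed). Supply passes for a single species or pooled group.
#'
#' @param passes data.frame of passes (one species/group).
#' @param deployments data.frame `site_id, camera_id, start, end` of camera
#'   deployment windows; sites are taken from here, so never-detected sites
#'   still appear.
#' @param outages optional data.frame `site_id, camera_id, start, end`.
#' @param week_start first occasion start date; defaults to the earliest
#'   deployment date, so occasions share one network-wide calendar.
#' @param n_weeks number of occasions; defaults to cover all deployments.
#' @return an object of class `detection_history`: list with `y` (site x
#'   occasion matrix of 1/0/NA), `occasions` (week start Dates), `season`
#'   (per-occasion `"spring-summer"`/`"autumn-winter"` from the week's start
#'   month), `sites` and named `site_class`.
#' @export
build_weekly_history <- function(passes, deployments, outages = NULL,
                                 week_start = NULL, n_weeks = NULL) {
  deployments <- normalize_intervals(deployments, "deployments")
  if (nrow(deployments) == 0L) stop("no deployments supplied")
  op <- camera_operational(deployments, outages)
  sites <- sort(unique(deployments$site_id))
  week_start <- as.Date(week_start %||%
                          as.Date(min(deployments$start), tz = "UTC"))
  if (is.null(n_weeks)) {
    span <- as.numeric(difftime(max(deployments$end),
                                as.POSIXct(as.character(week_start), tz = "UTC"),
                                units = "days"))
    n_weeks <- ceiling(span / 7)
  }
  n_weeks <- as.integer(n_weeks)
  occasions <- week_start + 7L * (0:(n_weeks - 1L))

  if (nrow(passes)) {
    ts <- parse_timestamp(passes$timestamp)
    lo <- as.POSIXct(as.character(week_start), tz = "UTC")
    hi <- lo + as.difftime(7L * n_weeks, units = "days")
    bad <- ts < lo | ts >= hi
    if (any(bad)) {
      stop("pass timestamp outside the occasion calendar: ",
           format_timestamp(ts[which(bad)[1]]))
    }
  }

  y <- matrix(NA_real_, nrow = length(sites), ncol = n_weeks,
              dimnames = list(sites, format(occasions)))
  for (s in sites) {
    ivs <- op[op$site_id == s, , drop = FALSE]
    for (w in seq_len(n_weeks)) {
      w0 <- as.POSIXct(as.character(occasions[w]), tz = "UTC")
      w1 <- w0 + as.difftime(7L, units = "days")
      if (interval_overlap_secs(ivs, w0, w1) > 0) y[s, w] <- 0
    }
  }
  if (nrow(passes)) {
    widx <- as.integer(floor(as.numeric(difftime(
      parse_timestamp(passes$timestamp),
      as.POSIXct(as.character(week_start), tz = "UTC"), units = "days")) / 7)) + 1L
    for (i in seq_along(widx)) {
      s <- passes$site_id[i]
      if (!s %in% sites) next
      y[s, widx[i]] <- 1
    }
  }
  site_class <- NULL
  if ("site_class" %in% names(passes) && nrow(passes)) {
    site_class <- stats::setNames(
      passes$site_class[match(sites, passes$site_id)], sites)
  }
  if ("site_class" %in% names(deployments)) {
    site_class <- stats::setNames(
      deployments$site_class[match(sites, deployments$site_id)], sites)
  }
  if (is.null(site_class)) {
    site_class <- stats::setNames(rep(NA_character_, length(sites)), sites)
  }
  structure(list(y = y, occasions = occasions,
                 season = season_of(occasions),
                 sites = sites, site_class = site_class),
            class = "detection_history")
}

#' Construct a detection history from a matrix
#'
#' Low-level constructor for simulation studies and tests: wraps a site x
#' occasion matrix of 1/0/NA directly.
#'
#' @param y numeric matrix (rows = sites, columns = weekly occasions) of
#'   1/0 with `NA` for missing occasions; row names are site ids.
#' @param week_start Date of the first occasion (default 2015-01-05, an
#'   arbitrary Monday).
#' @param site_class optional named `"underpass"`/`"forest"` vector.
#' @return a `detection_history`.
#' @export
detection_history <- function(y, week_start = as.Date("2015-01-05"),
                              site_class = NULL) {
  y <- as.matrix(y)
  if (is.null(rownames(y))) rownames(y) <- paste0("site", seq_len(nrow(y)))
  stopifnot(all(y %in% c(0, 1, NA)))
  occasions <- as.Date(week_start) + 7L * (seq_len(ncol(y)) - 1L)
  colnames(y) <- format(occasions)
  sites <- rownames(y)
  if (is.null(site_class)) {
    site_class <- stats::setNames(rep(NA_character_, length(sites)), sites)
  }
  structure(list(y = y, occasions = occasions, season = season_of(occasions),
                 sites = sites, site_class = site_class[sites]),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("Weekly detection history: %d sites x %d occasions (%s to %s)\n",
              nrow(x$y), ncol(x$y), format(x$occasions[1]),
              format(x$occasions[length(x$occasions)] + 6L)))
  n1 <- sum(x$y == 1, na.rm = TRUE); n0 <- sum(x$y == 0, na.rm = TRUE)
  cat(sprintf("  cells: %d detected, %d surveyed-not-detected, %d missing\n",
              n1, n0, sum(is.na(x$y))))
  invisible(x)
}

#' @export
as.matrix.detection_history <- function(x, ...) x$y

#' Set or replace site classes on a detection history
#'
#' @param history a `detection_history`.
#' @param site_class named character vector (`"underpass"`/`"forest"`).
#' @return the updated history.
#' @export
set_site_class <- function(history, site_class) {
  stopifnot(inherits(history, "detection_history"))
  history$site_class[names(site_class)] <- site_class
  history
}

#' Build a nightly detection table for predator and prey groups
#'
#' For each site and night (17:00-07:00, indexed by the 17:00 date), flags
#' whether any species of each analysis group was detected. A night is
#' covered when at least one camera at the site was operational for any
#' part of the night window; uncovered nights carry no flags and are
#' excluded from co-detection counts.
#'
#' @param passes data.frame of passes (any species mix).
#' @param deployments data.frame `site_id, camera_id, start, end`.
#' @param outages optional outage table.
#' @param group_map named character vector mapping `species_id` to an
#'   analysis group (e.g. `c(red_fox = "predator", bandicoot = "prey_small")`).
#'   Species mapped to `"neither"` are ignored; species absent from the map
#'   raise an error.
#' @return data.frame with columns `site_id`, `night` (Date), `covered`
#'   (logical) and one 0/1 column per group; group names in
#'   `attr(, "groups")`.
#' @export
build_nightly_table <- function(passes, deployments, outages = NULL,
                                group_map) {
  deployments <- normalize_intervals(deployments, "deployments")
  op <- camera_operational(deployments, outages)
  if (nrow(passes)) {
    unknown <- setdiff(unique(passes$species_id), names(group_map))
    if (length(unknown)) {
      stop("species missing from group map: ", paste(unknown, collapse = ", "))
    }
  }
  groups <- sort(setdiff(unique(group_map), "neither"))
  sites <- sort(unique(deployments$site_id))
  d0 <- as.Date(min(deployments$start), tz = "UTC")
  d1 <- as.Date(max(deployments$end), tz = "UTC")
  nights <- seq(d0, d1, by = 1L)

  out <- expand.grid(night = nights, site_id = sites, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c("site_id", "night")]
  out$covered <- FALSE
  for (s in sites) {
    ivs <- op[op$site_id == s, , drop = FALSE]
    w0 <- as.POSIXct(as.character(nights), tz = "UTC") + 17 * 3600
    w1 <- w0 + 14 * 3600
    cov <- vapply(seq_along(nights), function(i)
      interval_overlap_secs(ivs, w0[i], w1[i]) > 0, TRUE)
    out$covered[out$site_id == s] <- cov
  }
  for (g in groups) out[[g]] <- 0L
  if (nrow(passes)) {
    night <- assign_night(passes$timestamp)
    grp <- unname(group_map[passes$species_id])
    keep <- !is.na(night) & grp %in% groups
    if (any(keep)) {
      key_out <- paste(out$site_id, out$night)
      key_p <- paste(passes$site_id[keep], night[keep])
      gk <- grp[keep]
      for (g in groups) {
        hit <- unique(key_p[gk == g])
        out[[g]][key_out %in% hit & out$covered] <- 1L
      }
    }
  }
  attr(out, "groups") <- groups
  out
}
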