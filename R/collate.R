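# Collation of raw camera records into independent passes, paired-end
# deduplication, and annualized detection-rate tables.

#' Collate camera records into independent passes
#'
#' Successive records of the same species at the same camera belong to one
#' pass unless at least `min_interval_minutes` (default 30; exactly 30
#' starts a new pass) have elapsed since the previous contributing record,
#' or the record is flagged as a distinct individual (e.g. differences in
#' size or markings). A pass's detection count is its `n_individuals`, the
#' maximum seen in any contributing image. Turn-around events judged by the
#' observer are supplied as `exclusions` and dropped before collation.
#' Exact duplicate rows are dropped with a message.
#'
#' @param records data.frame of camera records with columns `site_id`,
#'   `site_class`, `camera_id`, `end_label`, `species_id`, `timestamp`,
#'   `n_individuals`, `direction`, `distinct_individual_flag`.
#' @param exclusions optional data.frame with columns `camera_id`,
#'   `species_id`, `timestamp` identifying records to drop (turn-arounds).
#' @param min_interval_minutes separation (minutes) defining a new pass.
#' @return data.frame of passes: `site_id`, `site_class`, `species_id`,
#'   `camera_id`, `contributing_ends`, `timestamp` (first contributing
#'   record), `direction`, `n_individuals`, `n_records`.
#' @export
collate_passes <- function(records, exclusions = NULL,
                           min_interval_minutes = 30) {
  need <- c("site_id", "site_class", "camera_id", "end_label", "species_id",
            "timestamp", "n_individuals", "direction",
            "distinct_individual_flag")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)
  records$timestamp <- parse_timestamp(records$timestamp)
  if (any(records$n_individuals < 1)) stop("n_individuals must be >= 1")

  key <- paste(records$camera_id, records$species_id,
               format_timestamp(records$timestamp), records$n_individuals,
               records$direction, records$distinct_individual_flag)
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    message("dropping ", ndup, " exact duplicate record(s)")
    records <- records[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(exclusions) && nrow(exclusions)) {
    ex <- paste(exclusions$camera_id, exclusions$species_id,
                format_timestamp(parse_timestamp(exclusions$timestamp)))
    k2 <- paste(records$camera_id, records$species_id,
                format_timestamp(records$timestamp))
    records <- records[!(k2 %in% ex), , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    return(data.frame(site_id = character(), site_class = character(),
                      species_id = character(), camera_id = character(),
                      contributing_ends = character(),
                      timestamp = parse_timestamp(character()),
                      direction = character(), n_individuals = integer(),
                      n_records = integer()))
  }
  # canonical sort: output invariant to input row order
  records <- records[order(records$site_id, records$camera_id,
                           records$species_id, records$timestamp,
                           records$direction, records$n_individuals), ,
                     drop = FALSE]

  grp <- paste(records$camera_id, records$species_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), grp), function(idx) {
    r <- records[idx, , drop = FALSE]
    gap <- c(Inf, diff(as.numeric(r$timestamp)) / 60)
    new_pass <- gap >= min_interval_minutes | r$distinct_individual_flag
    new_pass[1] <- TRUE
    pid <- cumsum(new_pass)
    first <- !duplicated(pid)
    dir <- vapply(split(r$direction, pid), function(d) {
      known <- d[d != "unknown"]
      if (length(known)) known[1] else "unknown"
    }, "")
    data.frame(
      site_id = r$site_id[first],
      site_class = r$site_class[first],
      species_id = r$species_id[first],
      camera_id = r$camera_id[first],
      contributing_ends = ifelse(r$end_label[first] == "none", "",
                                 r$end_label[first]),
      timestamp = r$timestamp[first],
      direction = unname(dir),
      n_individuals = as.integer(tapply(r$n_individuals, pid, max)),
      n_records = as.integer(tapply(pid, pid, length))
    )
  })
  passes <- do.call(rbind, out)
  passes <- passes[order(passes$site_id, passes$species_id, passes$timestamp,
                         passes$camera_id), , drop = FALSE]
  rownames(passes) <- NULL
  passes
}

#' Merge passes recorded at both ends of an underpass
#'
#' Within a site and species, a pass at end A and a pass at end B whose
#' first-record timestamps differ by at most `window_minutes` and whose
#' directions are not contradictory (both known and unequal) are counted as
#' one pass. Each pass merges at most once; matching is greedy in time
#' order with earliest-candidate preference. Forest passes (no end label)
#' are returned unchanged. Applying the operation twice equals applying it
#' once, since merged passes carry both ends and are no longer mergeable.
#'
#' @param passes output of [collate_passes()].
#' @param window_minutes matching window (default 15; the separation rule
#'   operates per camera, so the window only deduplicates across ends).
#' @return data.frame of passes with `contributing_ends` of merged passes
#'   set to `"A,B"` and `n_individuals` the maximum of the pair.
#' @export
match_underpass_ends <- function(passes, window_minutes = 15) {
  if (nrow(passes) == 0L) return(passes)
  single_end <- passes$contributing_ends %in% c("A", "B")
  grp <- paste(passes$site_id, passes$species_id, sep = "\r")
  drop <- logical(nrow(passes))
  for (idx in split(seq_len(nrow(passes)), grp)) {
    idx <- idx[single_end[idx]]
    if (length(idx) < 2L) next
    idx <- idx[order(passes$timestamp[idx])]
    matched <- logical(length(idx))
    for (i in seq_along(idx)) {
      if (matched[i]) next
      ii <- idx[i]
      for (j in seq_along(idx)) {
        if (j <= i || matched[j]) next
        jj <- idx[j]
        dt <- abs(as.numeric(passes$timestamp[jj]) -
                    as.numeric(passes$timestamp[ii])) / 60
        if (dt > window_minutes) break  # sorted: later ones even further
        if (passes$contributing_ends[jj] == passes$contributing_ends[ii]) next
        d1 <- passes$direction[ii]; d2 <- passes$direction[jj]
        if (d1 != "unknown" && d2 != "unknown" && d1 != d2) next
        # merge jj into ii
        matched[i] <- matched[j] <- TRUE
        passes$contributing_ends[ii] <- "A+B"
        passes$n_individuals[ii] <- max(passes$n_individuals[ii],
                                        passes$n_individuals[jj])
        passes$n_records[ii] <- passes$n_records[ii] + passes$n_records[jj]
        if (d1 == "unknown" && d2 != "unknown") passes$direction[ii] <- d2
        drop[jj] <- TRUE
        break
      }
    }
  }
  out <- passes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annualized detection rates per site and species
#'
#' The detection count for a site x species is the sum of `n_individuals`
#' over its passes; the annualized rate is `count / operational_weeks * 52`,
#' reported to one decimal place.
#'
#' @param passes data.frame of passes (after end matching).
#' @param operational_weeks named numeric vector (names = site ids) or
#'   data.frame with columns `site_id`, `weeks`.
#' @return data.frame `site_id, species_id, detections, weeks, rate` (rate
#'   per 52 weeks, 1 d.p.). Sites with zero or missing operational weeks are
#'   excluded with a warning.
#' @export
annualized_rates <- function(passes, operational_weeks) {
  if (is.data.frame(operational_weeks)) {
    wk <- stats::setNames(operational_weeks$weeks, operational_weeks$site_id)
  } else {
    wk <- operational_weeks
  }
  sites <- unique(passes$site_id)
  bad <- sites[!(sites %in% names(wk)) | wk[sites] <= 0 | is.na(wk[sites])]
  if (length(bad)) {
    warning("excluding site(s) with zero/unknown operational weeks: ",
            paste(bad, collapse = ", "))
    passes <- passes[!(passes$site_id %in% bad), , drop = FALSE]
  }
  if (nrow(passes) == 0L) {
    return(data.frame(site_id = character(), species_id = character(),
                      detections = integer(), weeks = numeric(),
                      rate = numeric()))
  }
  agg <- stats::aggregate(n_individuals ~ site_id + species_id, data = passes,
                          FUN = sum)
  names(agg)[3] <- "detections"
  agg$weeks <- as.numeric(wk[agg$site_id])
  agg$rate <- round(agg$detections / agg$weeks * 52, 1)
  agg <- agg[order(agg$site_id, agg$species_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
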