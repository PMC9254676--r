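# Shared helpers: timestamps, seasons, interval arithmetic.
# All timestamps in the package are timezone-naive local times; internally
# they are POSIXct in "UTC" so arithmetic never crosses a DST boundary.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

#' Parse timestamps to the package's internal representation
#'
#' Accepts POSIXct, Date, or ISO 8601 character ("2015-03-10T23:30:00" or
#' with a space separator). Returned values are POSIXct in UTC, used as
#' naive local time.
#'
#' @param x vector of timestamps.
#' @return POSIXct vector (tz = "UTC").
#' @keywords internal
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp(s): ",
         paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  }
  out
}

format_timestamp <- function(x) format(x, TS_FORMAT, tz = "UTC")

#' Austral season of a date
#'
#' Spring-summer is September-February, autumn-winter is March-August.
#'
#' @param x Date or POSIXct vector.
#' @return character vector, `"spring-summer"` or `"autumn-winter"`.
#' @export
#' @examples
#' season_of(as.Date(c("2015-01-15", "2015-06-15")))
season_of <- function(x) {
  m <- as.integer(format(as.Date(x, tz = "UTC"), "%m"))
  ifelse(m >= 3 & m <= 8, "autumn-winter", "spring-summer")
}

# months in which spring-summer-only species are absent
GATED_MONTHS <- 3:8

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- interval arithmetic (used for camera coverage) -------------------------

# intervals: data.frame with POSIXct columns start, end (start <= end)
# returns the set difference a \ b as a data.frame of the same shape
interval_subtract <- function(a, b) {
  if (nrow(a) == 0L || is.null(b) || nrow(b) == 0L) return(a)
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    segs <- data.frame(start = a$start[i], end = a$end[i])
    for (j in seq_len(nrow(b))) {
      keep <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        bs <- b$start[j]; be <- b$end[j]
        if (be <= s || bs >= e) {          # no overlap
          keep[[length(keep) + 1L]] <- data.frame(start = s, end = e)
        } else {
          if (bs > s) keep[[length(keep) + 1L]] <- data.frame(start = s, end = bs)
          if (be < e) keep[[length(keep) + 1L]] <- data.frame(start = be, end = e)
        }
      }
      segs <- if (length(keep)) do.call(rbind, keep) else
        data.frame(start = a$start[0], end = a$end[0])
      if (nrow(segs) == 0L) break
    }
    pieces[[i]] <- segs
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# total overlap (seconds) of intervals with window [w0, w1)
interval_overlap_secs <- function(intervals, w0, w1) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  lo <- pmax(as.numeric(intervals$start), as.numeric(w0))
  hi <- pmin(as.numeric(intervals$end), as.numeric(w1))
  sum(pmax(0, hi - lo))
}

# normalize a deployments/outages table: site_id, camera_id, start, end
normalize_intervals <- function(x, what = "interval") {
  if (is.null(x) || nrow(x) == 0L) {
    return(data.frame(site_id = character(), camera_id = character(),
                      start = parse_timestamp(character()),
                      end = parse_timestamp(character())))
  }
  need <- c("site_id", "camera_id", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(what, " table lacks column(s): ",
                         paste(miss, collapse = ", "))
  x$start <- parse_timestamp(x$start)
  x$end <- parse_timestamp(x$end)
  if (any(x$end < x$start)) stop(what, " intervals must have start <= end")
  x
}

# per-camera operational intervals: deployments minus that camera's outages
camera_operational <- function(deployments, outages = NULL) {
  deployments <- normalize_intervals(deployments, "deployments")
  outages <- normalize_intervals(outages, "outages")
  out <- list()
  for (i in seq_len(nrow(deployments))) {
    cam <- deployments$camera_id[i]
    site <- deployments$site_id[i]
    a <- deployments[i, c("start", "end")]
    b <- outages[outages$camera_id == cam & outages$site_id == site,
                 c("start", "end")]
    segs <- interval_subtract(a, b)
    if (nrow(segs)) {
      segs$site_id <- site
      segs$camera_id <- cam
      out[[length(out) + 1L]] <- segs[, c("site_id", "camera_id", "start", "end")]
    }
  }
  if (!length(out)) {
    return(normalize_intervals(NULL))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
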