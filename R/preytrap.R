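# Tests of the prey-trap hypothesis: nightly predator-prey co-detection
# counts, the exact one-tailed binomial independence test, prey-activity
# alignment sums/ratios across underpasses, and nightly predator-prey
# interval statistics.

#' Nightly co-detection counts for a predator and a prey group
#'
#' Over the covered nights of a site, counts the nights a predator was
#' detected (`a`), a prey was detected (`b`), both were detected (`c`), and
#' the number of sample nights `d = a + b - c`. An eligibility rule (at
#' least `min_nights` detected nights for each group, default 20) gates
#' which site x group pairs are testable, so the outcome is not driven by
#' sparse data.
#'
#' @param nightly a nightly table from [build_nightly_table()].
#' @param site site id.
#' @param predator,prey group column names in the nightly table.
#' @param min_nights minimum detected nights per group for testability.
#' @return object of class `codetection_counts`: list with `site`,
#'   `predator`, `prey`, `a`, `b`, `c`, `d`, `n_covered`, `testable`.
#' @export
codetection_counts <- function(nightly, site, predator, prey,
                               min_nights = 20L) {
  groups <- attr(nightly, "groups") %||% setdiff(names(nightly),
                                                 c("site_id", "night", "covered"))
  if (!all(c(predator, prey) %in% groups)) {
    stop("predator/prey group not present in the nightly table")
  }
  x <- nightly[nightly$site_id == site & nightly$covered, , drop = FALSE]
  a <- sum(x[[predator]] == 1L)
  b <- sum(x[[prey]] == 1L)
  cc <- sum(x[[predator]] == 1L & x[[prey]] == 1L)
  d <- a + b - cc
  out <- list(site = site, predator = predator, prey = prey,
              a = a, b = b, c = cc, d = d, n_covered = nrow(x),
              testable = a >= min_nights && b >= min_nights && d >= 1L)
  class(out) <- "codetection_counts"
  out
}

#' @export
print.codetection_counts <- function(x, ...) {
  cat(sprintf("Co-detection counts at %s (%s vs %s): a=%d b=%d c=%d d=%d%s\n",
              x$site, x$predator, x$prey, x$a, x$b, x$c, x$d,
              if (x$testable) "" else " [not testable]"))
  invisible(x)
}

#' One-tailed exact binomial tail probabilities for a co-detection count
#'
#' Under independence the number of joint-detection nights is binomial with
#' `d` trials and success probability `expected`. The lower tail is
#' `P(X <= c)`, the upper tail `P(X >= c)`.
#'
#' @param c observed joint-detection nights.
#' @param d number of sample nights (trials).
#' @param expected null success probability, `(a/d) * (b/d)`.
#' @return list with `lower` and `upper` tail probabilities.
#' @export
codetection_tails <- function(c, d, expected) {
  stopifnot(d >= 1, c >= 0, c <= d, expected >= 0, expected <= 1)
  list(lower = stats::pbinom(c, d, expected),
       upper = stats::pbinom(c - 1, d, expected, lower.tail = FALSE))
}

#' Exact binomial test of nightly co-detection independence
#'
#' Expected joint-detection probability under independence is
#' `(a/d) * (b/d)` (kept as an exact rational before any rounding);
#' observed is `c/d`. The one-tailed p-value is the lower tail
#' `P(X <= c)` when observed < expected, else the upper tail `P(X >= c)`;
#' a tie (observed = expected) reports the smaller tail with direction
#' above-expected. Both tails are stored.
#'
#' @param counts a `codetection_counts`.
#' @return object of class `codetection_test` with the counts, `expected`,
#'   `observed`, `direction` (`"below-expected"`/`"above-expected"`),
#'   `p_value`, `tails` and a `degenerate` flag (expected 0 with c > 0).
#' @export
independence_test <- function(counts) {
  stopifnot(inherits(counts, "codetection_counts"))
  if (counts$d < 1L) stop("untestable pair: d = 0 sample nights")
  a <- counts$a; b <- counts$b; cc <- counts$c; d <- counts$d
  expected <- (a / d) * (b / d)
  observed <- cc / d
  tails <- codetection_tails(cc, d, expected)
  degenerate <- expected == 0 && cc > 0
  if (observed < expected) {
    direction <- "below-expected"; p <- tails$lower
  } else if (observed > expected) {
    direction <- "above-expected"; p <- tails$upper
  } else {
    direction <- "above-expected"; p <- min(tails$lower, tails$upper)
  }
  out <- list(counts = counts, expected = expected, observed = observed,
              direction = direction, p_value = p, tails = tails,
              degenerate = degenerate)
  class(out) <- "codetection_test"
  out
}

#' @export
print.codetection_test <- function(x, ...) {
  cat("Exact binomial test of nightly co-detection independence\n")
  cat(sprintf("  %s: %s vs %s, n = %d sample nights\n", x$counts$site,
              x$counts$predator, x$counts$prey, x$counts$d))
  cat(sprintf("  expected %.3f, observed %.3f (%s), one-tailed p = %.4g%s\n",
              x$expected, x$observed, x$direction, x$p_value,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' Prey activity sums and ratios across underpasses
#'
#' Sums the annualized detection rates of a list of potential prey species
#' per underpass (reported to the nearest integer, detections per year) and
#' forms pairwise ratios (1 d.p., computed from the exact sums before
#' rounding).
#'
#' @param rates a rate table (`site_id, species_id, rate`), e.g. from
#'   [annualized_rates()].
#' @param prey_species character vector of prey species ids; each must
#'   appear somewhere in the rate table (missing combinations at a given
#'   underpass count 0).
#' @param underpasses character vector of underpass site ids.
#' @return object of class `prey_activity`: list with `sum_exact`,
#'   `sum` (rounded, D/Y) and `ratio` (matrix, 1 d.p., rows / columns).
#' @export
prey_activity_alignment <- function(rates, prey_species, underpasses) {
  missing_sp <- setdiff(prey_species, unique(rates$species_id))
  if (length(missing_sp)) {
    stop("prey species missing from the rate table: ",
         paste(missing_sp, collapse = ", "))
  }
  x <- rates[rates$species_id %in% prey_species &
               rates$site_id %in% underpasses, , drop = FALSE]
  sums <- vapply(underpasses, function(u)
    sum(x$rate[x$site_id == u]), 0)
  ratio <- round(outer(sums, sums, "/"), 1)
  dimnames(ratio) <- list(underpasses, underpasses)
  out <- list(sum_exact = sums, sum = round(sums), ratio = ratio,
              prey_species = prey_species)
  class(out) <- "prey_activity"
  out
}

#' @export
print.prey_activity <- function(x, ...) {
  cat("Prey activity (detections per year) by underpass\n")
  for (u in names(x$sum)) cat(sprintf("  %-12s %d D/Y\n", u, x$sum[[u]]))
  cat("Pairwise ratios (row / column):\n")
  print(x$ratio)
  invisible(x)
}

#' Nightly predator-prey interval statistics
#'
#' For each night on which both the predator and the prey group were
#' detected at the site, takes the minimum absolute time gap (minutes)
#' between any predator pass and any prey pass that night, then reports the
#' mean and SE across nights. With fewer than two qualifying nights the
#' statistics are undefined (`NA`).
#'
#' @param passes data.frame of passes.
#' @param site site id.
#' @param group_map named character vector mapping species to groups.
#' @param predator,prey group names.
#' @return object of class `interval_stats`: list with `gaps` (per-night
#'   minima, minutes), `mean`, `se`, `n_nights`.
#' @export
interval_stats <- function(passes, site, group_map, predator, prey) {
  x <- passes[passes$site_id == site, , drop = FALSE]
  grp <- unname(group_map[x$species_id])
  night <- assign_night(x$timestamp)
  keep <- !is.na(night) & grp %in% c(predator, prey)
  x <- x[keep, , drop = FALSE]; grp <- grp[keep]; night <- night[keep]
  gaps <- c()
  for (nt in unique(night)) {
    tp <- parse_timestamp(x$timestamp[night == nt & grp == predator])
    ty <- parse_timestamp(x$timestamp[night == nt & grp == prey])
    if (length(tp) && length(ty)) {
      gaps <- c(gaps, min(abs(outer(as.numeric(tp), as.numeric(ty), "-"))) / 60)
    }
  }
  n <- length(gaps)
  out <- list(site = site, predator = predator, prey = prey, gaps = gaps,
              n_nights = n,
              mean = if (n >= 1) mean(gaps) else NA_real_,
              se = if (n >= 2) stats::sd(gaps) / sqrt(n) else NA_real_)
  class(out) <- "interval_stats"
  out
}

#' @export
print.interval_stats <- function(x, ...) {
  cat(sprintf("Nightly %s-%s interval at %s: ", x$predator, x$prey, x$site))
  if (x$n_nights >= 2) {
    cat(sprintf("mean %.0f +/- %.0f (SE) min over %d nights\n",
                x$mean, x$se, x$n_nights))
  } else {
    cat("undefined (<2 nights with both groups detected)\n")
  }
  invisible(x)
}
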