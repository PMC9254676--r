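# Weekly detection-probability models.
#
# A single-season occupancy-style likelihood where interest centres on the
# per-occasion (weekly) detection probability p; the occupancy probability
# psi is typically fixed at 1 because the species is known present at most
# sites. Detection structures: null (one p everywhere), underpass
# (underpass vs forest), patchy (site- or site-group-specific p), each
# optionally with an additive austral-season effect on the log-odds scale.
# Models are ranked by AICc.

#' Log-likelihood contribution of one site's detection history
#'
#' `log( psi * prod_t p_t^y_t (1-p_t)^(1-y_t) + (1-psi) * I(all y_t = 0) )`
#' with the product over non-missing occasions only. A row with no
#' surveyed occasion contributes 0, with a warning.
#'
#' @param y numeric vector of 1/0 with `NA` for missing occasions.
#' @param p detection probability: scalar or one value per occasion.
#' @param psi occupancy probability in (0, 1\].
#' @return scalar log-likelihood contribution.
#' @export
site_loglik <- function(y, p, psi = 1) {
  obs <- !is.na(y)
  if (!any(obs)) {
    warning("all-missing detection history row contributes 0")
    return(0)
  }
  if (length(p) == 1L) p <- rep(p, length(y))
  p <- p[obs]; y <- y[obs]
  ll_det <- sum(y * log(p) + (1 - y) * log1p(-p))
  if (all(y == 0)) {
    log(psi * exp(ll_det) + (1 - psi))
  } else {
    log(psi) + ll_det
  }
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1)`. The effective sample size
#' `n` is the number of sites (the convention of common occupancy software;
#' the choice matters only for the correction term and is echoed in
#' reports).
#'
#' @param logL maximized log-likelihood.
#' @param K number of parameters.
#' @param n effective sample size; must exceed `K + 1`.
#' @return the AICc value.
#' @export
#' @examples
#' aicc(-10, 2, 11)  # 25.5
aicc <- function(logL, K, n) {
  if (n <= K + 1) stop("AICc undefined: n must exceed K + 1")
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from a set of AICc values
#'
#' @param aicc_values numeric vector of AICc values for models fitted to the
#'   same data.
#' @return list with `delta` (AICc differences from the best model) and
#'   `weight` (normalized model weights).
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

# resolve a model keyword to a named site -> group assignment
resolve_groups <- function(history, model, groups, name) {
  sites <- history$sites
  if (!is.null(groups)) {
    miss <- setdiff(sites, names(groups))
    if (length(miss)) stop("groups lacks site(s): ", paste(miss, collapse = ", "))
    return(list(groups = groups[sites], name = name %||% "custom"))
  }
  switch(model,
    null = list(groups = stats::setNames(rep("all", length(sites)), sites),
                name = name %||% "null"),
    underpass = {
      sc <- history$site_class[sites]
      if (anyNA(sc)) stop("underpass model needs site_class on the history")
      list(groups = stats::setNames(sc, sites), name = name %||% "underpass")
    },
    patchy = list(groups = stats::setNames(sites, sites),
                  name = name %||% "patchy"),
    stop("unknown model keyword: ", model)
  )
}

#' Fit a weekly detection-probability model
#'
#' Maximizes the sum over sites of [site_loglik()] by quasi-Newton (BFGS)
#' optimization on the log-odds scale, starting from zero-valued log-odds
#' with up to 5 jittered restarts. Standard errors come from the inverse of
#' the observed information (numerical Hessian); per-group weekly detection
#' probabilities and their delta-method SEs are reported for the reference
#' (spring-summer) season. Groups whose surveyed cells are all 0 or all 1
#' are separated: their estimate is reported at the probability bound with
#' an infinite SE and they are held out of the optimization.
#'
#' When `occupancy = "estimated"` and the estimate runs to the boundary
#' (psi > 1 - 1e-6), the model is refitted with psi fixed at 1 and the fit
#' records that. By reporting convention `K` counts psi even when fixed
#' (so the null model has K = 2); the free-parameter count is kept in
#' `K_free`.
#'
#' @param history a `detection_history` from [build_weekly_history()].
#' @param model `"null"`, `"underpass"` or `"patchy"`; ignored when
#'   `groups` is given.
#' @param groups optional named character vector assigning each site to a
#'   detection group (a custom/reduced patchy structure).
#' @param season logical: add an additive autumn-winter effect on the
#'   log-odds of detection (spring-summer is the reference level).
#' @param occupancy `"fixed"` (psi = 1) or `"estimated"`.
#' @param name optional model label used in rankings.
#' @param n_restarts maximum jittered restarts after a failed convergence.
#' @return an object of class `detection_fit`.
#' @export
fit_detection <- function(history, model = c("null", "underpass", "patchy"),
                          groups = NULL, season = FALSE,
                          occupancy = c("fixed", "estimated"), name = NULL,
                          n_restarts = 5L) {
  stopifnot(inherits(history, "detection_history"))
  model <- match.arg(model)
  occupancy <- match.arg(occupancy)
  g <- resolve_groups(history, model, groups, name)
  site_group <- g$groups
  model_name <- if (season) paste0(g$name, "+season") else g$name

  y <- history$y
  aw <- history$season == "autumn-winter"
  n_sites <- nrow(y)
  glev <- unique(unname(site_group))
  gidx <- match(site_group[rownames(y)], glev)

  # separation: groups with all-0 or all-1 surveyed cells
  bound <- rep(NA_real_, length(glev))
  for (k in seq_along(glev)) {
    cells <- y[gidx == k, , drop = FALSE]
    cells <- cells[!is.na(cells)]
    if (length(cells) && all(cells == 0)) bound[k] <- 0
    if (length(cells) && all(cells == 1)) bound[k] <- 1
  }
  free_g <- which(is.na(bound))
  est_psi <- occupancy == "estimated"

  npar <- length(free_g) + as.integer(season) + as.integer(est_psi)
  EPS <- 1e-12
  make_negll <- function(est_psi) {
    function(theta) {
      beta <- rep(NA_real_, length(glev))
      beta[free_g] <- theta[seq_along(free_g)]
      bs <- if (season) theta[length(free_g) + 1L] else 0
      psi <- if (est_psi) stats::plogis(theta[npar]) else 1
      ll <- 0
      for (i in seq_len(n_sites)) {
        k <- gidx[i]
        if (is.na(bound[k])) {
          eta <- beta[k] + bs * aw
          p <- stats::plogis(eta)
        } else {
          p <- rep(min(max(bound[k], EPS), 1 - EPS), ncol(y))
        }
        ll <- ll + suppressWarnings(site_loglik(y[i, ], p, psi))
      }
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }

  run_opt <- function(est_psi) {
    np <- length(free_g) + as.integer(season) + as.integer(est_psi)
    negll <- make_negll(est_psi)
    if (np == 0L) {
      return(list(par = numeric(0), value = negll(numeric(0)),
                  convergence = 0L, np = np, negll = negll))
    }
    start <- rep(0, np)
    best <- NULL
    for (r in 0:n_restarts) {
      th0 <- if (r == 0) start else start + stats::rnorm(np, 0, 0.5)
      o <- try(stats::optim(th0, negll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value - 1e-9) best <- o
      if (!is.null(best) && best$convergence == 0L && r >= 0) break
    }
    if (is.null(best)) stop("detection model failed to converge")
    best$np <- np
    best$negll <- negll
    best
  }

  opt <- run_opt(est_psi)
  psi_fixed_at_boundary <- FALSE
  if (est_psi && opt$np > 0L) {
    psi_hat <- stats::plogis(opt$par[opt$np])
    if (psi_hat > 1 - 1e-6) {
      est_psi <- FALSE
      psi_fixed_at_boundary <- TRUE
      npar <- length(free_g) + as.integer(season)
      opt <- run_opt(FALSE)
    }
  }

  # covariance from the observed information
  vc <- matrix(NA_real_, opt$np, opt$np)
  if (opt$np > 0L) {
    H <- try(stats::optimHess(opt$par, opt$negll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vi <- try(solve(H), silent = TRUE)
      if (!inherits(vi, "try-error")) vc <- vi
    }
  }

  beta <- rep(NA_real_, length(glev))
  se_beta <- rep(NA_real_, length(glev))
  beta[free_g] <- opt$par[seq_along(free_g)]
  se_beta[free_g] <- sqrt(pmax(diag(vc)[seq_along(free_g)], 0))
  beta_season <- if (season) opt$par[length(free_g) + 1L] else NA_real_
  se_season <- if (season) sqrt(max(diag(vc)[length(free_g) + 1L], 0)) else NA_real_
  psi <- 1
  se_psi <- NA_real_
  if (est_psi && opt$np > 0L) {
    lp <- opt$par[opt$np]
    psi <- stats::plogis(lp)
    se_psi <- psi * (1 - psi) * sqrt(max(diag(vc)[opt$np], 0))
  }

  p_hat <- ifelse(is.na(bound), stats::plogis(beta), bound)
  se_p <- ifelse(is.na(bound), p_hat * (1 - p_hat) * se_beta, Inf)

  estimates <- data.frame(
    group = glev, beta = beta, se_beta = se_beta,
    p = p_hat, se_p = se_p, boundary = !is.na(bound)
  )
  K <- length(glev) + as.integer(season) + 1L  # psi always counted
  fit <- list(
    name = model_name, model = model, season = season,
    occupancy = if (est_psi) "estimated" else "fixed",
    psi_fixed_at_boundary = psi_fixed_at_boundary,
    site_group = site_group, estimates = estimates,
    beta_season = beta_season, se_season = se_season,
    psi = psi, se_psi = se_psi,
    logLik = -opt$value, K = K, K_free = opt$np,
    n_sites = n_sites, n_occasions = ncol(y),
    vcov = vc, convergence = opt$convergence,
    history = history
  )
  class(fit) <- "detection_fit"
  fit
}

#' @export
print.detection_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Weekly detection model '%s' (psi %s%s)\n", x$name,
              x$occupancy,
              if (x$psi_fixed_at_boundary) ", fixed at boundary" else ""))
  ic <- tryCatch(sprintf("%.2f", AICc(x)), error = function(e) "undefined (n <= K+1)")
  cat(sprintf("  %d sites x %d occasions; logL = %.2f; K = %d; AICc = %s\n",
              x$n_sites, x$n_occasions, x$logLik, x$K, ic))
  est <- x$estimates
  cat("  weekly detection probability (spring-summer reference):\n")
  for (i in seq_len(nrow(est))) {
    cat(sprintf("    %-12s p = %s (SE %s)%s\n", est$group[i],
                format(round(est$p[i], digits)),
                format(round(est$se_p[i], digits)),
                if (est$boundary[i]) " [at boundary]" else ""))
  }
  if (x$season) {
    cat(sprintf("  autumn-winter log-odds effect: %.3f (SE %.3f)\n",
                x$beta_season, x$se_season))
  }
  invisible(x)
}

#' @export
coef.detection_fit <- function(object, ...) {
  out <- stats::setNames(object$estimates$beta,
                         paste0("logit_p:", object$estimates$group))
  if (object$season) out <- c(out, logit_p_season = object$beta_season)
  if (object$occupancy == "estimated") out <- c(out, psi = object$psi)
  out
}

#' @export
logLik.detection_fit <- function(object, ...) {
  structure(object$logLik, df = object$K_free, nobs = object$n_sites,
            class = "logLik")
}

#' @export
vcov.detection_fit <- function(object, ...) object$vcov

#' @export
summary.detection_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.detection_fit")
}

#' @export
print.summary.detection_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n  log-odds coefficients:\n")
  est <- f$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("    %-12s beta = %8.3f (SE %s)\n", est$group[i], est$beta[i],
                format(round(est$se_beta[i], 3))))
  }
  cat("\n  site -> group assignment:\n")
  gr <- split(names(f$site_group), unname(f$site_group))
  for (g in names(gr)) {
    cat(sprintf("    %-12s %s\n", g, paste(gr[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Per-site detection probabilities from a fitted model
#'
#' @param object a `detection_fit`.
#' @param newdata optional data.frame with columns `site` and optionally
#'   `season` (`"spring-summer"` or `"autumn-winter"`); defaults to every
#'   site of the fitted history at the reference season.
#' @param ... unused.
#' @return data.frame `site, group, season, p, se`.
#' @export
predict.detection_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- data.frame(site = names(object$site_group),
                          season = "spring-summer")
  }
  if (is.null(newdata$season)) newdata$season <- "spring-summer"
  grp <- unname(object$site_group[newdata$site])
  if (anyNA(grp)) stop("unknown site in newdata")
  idx <- match(grp, object$estimates$group)
  beta <- object$estimates$beta[idx]
  se_b <- object$estimates$se_beta[idx]
  aw <- newdata$season == "autumn-winter"
  eta <- beta + ifelse(aw & object$season, object$beta_season, 0)
  # delta-method SE; season covariance folded in where applicable
  se_eta <- se_b
  if (object$season && any(aw)) {
    kf <- length(unique(object$estimates$group[!object$estimates$boundary]))
    free_groups <- object$estimates$group[!object$estimates$boundary]
    jpos <- match(grp, free_groups)
    spos <- length(free_groups) + 1L
    v <- object$vcov
    se_eta <- vapply(seq_along(grp), function(i) {
      if (is.na(jpos[i])) return(Inf)
      if (aw[i]) sqrt(max(v[jpos[i], jpos[i]] + v[spos, spos] +
                            2 * v[jpos[i], spos], 0))
      else sqrt(max(v[jpos[i], jpos[i]], 0))
    }, 0)
  }
  p <- stats::plogis(eta)
  bdry <- object$estimates$boundary[idx]
  p[bdry] <- object$estimates$p[idx][bdry]
  se <- ifelse(bdry, Inf, p * (1 - p) * se_eta)
  data.frame(site = newdata$site, group = grp, season = newdata$season,
             p = p, se = se)
}

#' @export
plot.detection_fit <- function(x, ...) {
  pr <- predict(x)
  ord <- order(pr$site)
  pr <- pr[ord, ]
  n <- nrow(pr)
  se <- ifelse(is.finite(pr$se), pr$se, 0)
  graphics::plot(seq_len(n), pr$p, ylim = c(0, min(1, max(pr$p + se) * 1.1)),
                 pch = 19, xaxt = "n", xlab = "",
                 ylab = "Weekly detection probability",
                 main = x$name, ...)
  graphics::axis(1, at = seq_len(n), labels = pr$site, las = 2, cex.axis = 0.8)
  graphics::arrows(seq_len(n), pr$p, seq_len(n), pr$p + se, angle = 90,
                   length = 0.04, code = 2)
  invisible(pr)
}

#' Simulate detection histories from a fitted model
#'
#' @param object a `detection_fit`.
#' @param nsim number of simulated histories.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `detection_history` objects with the fitted structure;
#'   missing cells of the original history stay missing.
#' @export
simulate.detection_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  h <- object$history
  pr <- lapply(c("spring-summer", "autumn-winter"), function(s)
    predict(object, data.frame(site = h$sites, season = s))$p)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    hh <- h
    occ_aw <- h$season == "autumn-winter"
    for (i in seq_along(h$sites)) {
      z <- stats::rbinom(1, 1, object$psi)
      p <- ifelse(occ_aw, pr[[2]][i], pr[[1]][i])
      row <- z * stats::rbinom(ncol(h$y), 1, p)
      row[is.na(h$y[i, ])] <- NA
      hh$y[i, ] <- row
    }
    out[[r]] <- hh
  }
  if (nsim == 1) out[[1]] else out
}

#' AICc of a fitted detection model
#'
#' Uses the number of sites as the effective sample size and the reporting
#' parameter count `K` (psi included even when fixed).
#'
#' @param fit a `detection_fit`.
#' @return the AICc value.
#' @export
AICc <- function(fit) {
  stopifnot(inherits(fit, "detection_fit"))
  aicc(fit$logLik, fit$K, fit$n_sites)
}

#' Rank detection models by AICc
#'
#' Sorts fits (all on the same history) by ascending AICc, computes AICc
#' differences and Akaike weights, and flags models with delta < 2 as
#' equally plausible and delta > 10 as having essentially no support.
#' Ties are broken by smaller K, then by name.
#'
#' @param fits list of `detection_fit` objects on the same history.
#' @return data.frame of class `model_ranking` with columns `model`,
#'   `AICc`, `delta`, `weight`, `K`, `logLik`, `plausible`, `no_support`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, TRUE, "detection_fit")))
  y0 <- fits[[1]]$history$y
  same <- vapply(fits, function(f) identical(f$history$y, y0), TRUE)
  if (!all(same)) stop("models were fitted to differing detection histories")
  tab <- data.frame(
    model = vapply(fits, function(f) f$name, ""),
    AICc = vapply(fits, AICc, 0),
    K = vapply(fits, function(f) f$K, 0L),
    logLik = vapply(fits, function(f) f$logLik, 0)
  )
  ord <- order(tab$AICc, tab$K, tab$model)
  tab <- tab[ord, ]
  aw <- akaike_weights(tab$AICc)
  tab$delta <- aw$delta
  tab$weight <- aw$weight
  tab$plausible <- tab$delta < 2
  tab$no_support <- tab$delta > 10
  tab <- tab[, c("model", "AICc", "delta", "weight", "K", "logLik",
                 "plausible", "no_support")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("model_ranking", "data.frame")
  tab
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Model selection (weekly detection)\n")
  disp <- data.frame(Model = x$model, AICc = sprintf("%.2f", x$AICc),
                     dAICc = sprintf("%.2f", x$delta),
                     W = sprintf("%.2f", x$weight), K = x$K)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Reduce a full patchy model to groups of similar sites
#'
#' Sites whose estimate +/- 1 SE intervals overlap are merged by
#' single-linkage (connected components of the interval-overlap graph
#' become groups). Sites at a probability boundary (infinite SE) are
#' treated as zero-width intervals at their estimate. Deterministic.
#'
#' @param fit a full patchy `detection_fit` (one group per site).
#' @return named character vector assigning each site to a reduced group
#'   (`"g1"`, `"g2"`, ... in ascending order of detection probability),
#'   suitable for `fit_detection(history, groups = ...)`. Degenerate case:
#'   all sites merge into one group (the null structure).
#' @export
reduce_patchy_groups <- function(fit) {
  stopifnot(inherits(fit, "detection_fit"))
  est <- fit$estimates
  sites <- names(fit$site_group)
  idx <- match(unname(fit$site_group[sites]), est$group)
  p <- est$p[idx]
  se <- est$se_p[idx]
  se[!is.finite(se)] <- 0
  lo <- p - se; hi <- p + se
  ord <- order(lo, hi, sites)
  comp <- integer(length(sites))
  cur <- 0L
  max_hi <- -Inf
  for (i in ord) {
    if (lo[i] > max_hi) {
      cur <- cur + 1L
      max_hi <- hi[i]
    } else {
      max_hi <- max(max_hi, hi[i])
    }
    comp[i] <- cur
  }
  # label groups g1.. in ascending mean p
  mp <- tapply(p, comp, mean)
  relabel <- stats::setNames(paste0("g", rank(mp, ties.method = "first")),
                             names(mp))
  stats::setNames(unname(relabel[as.character(comp)]), sites)
}
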