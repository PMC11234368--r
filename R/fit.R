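summary_rows <- function(summary, region) {
  stopifnot(inherits(summary, "clone_summary"))
  s <- summary[summary$region == region, , drop = FALSE]
  if (!nrow(s)) stop("no rows for region '", region, "' in summary")
  s[order(s$chase_day), , drop = FALSE]
}

boot_series <- function(summary, region, observable) {
  bk <- attr(summary, "boot")[[region]]
  if (is.null(bk)) return(NULL)
  bk[, , observable, drop = TRUE]
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Estimate the average division interval from cell-fraction series
#'
#' Every division of a labeled basal cell adds one labeled cell to the
#' tissue, so over a window in which shedding is negligible the
#' per-basal-cell division rate is the growth of the labeled total cell
#' fraction per unit of integrated labeled basal fraction:
#' \eqn{\rho_{div} = \Delta f_{tot} / \int f_{BL}\,dt} (trapezoidal rule on
#' the observed chase days).  The division interval is \eqn{1/\rho_{div}}.
#' If suprabasal shedding at a known rate \eqn{k} is *not* negligible in
#' the window, pass `shed_rate`: since `f_total - f_basal` counts the
#' suprabasal cells, adding back the shed cells
#' \eqn{k \int (f_{tot} - f_{BL}) dt} to \eqn{\Delta f_{tot}} makes the
#' estimator unbiased in expectation.  The standard error is propagated
#' from the clone-level bootstrap replicates of the summary.
#'
#' @param summary a [summarize_clones()] result.
#' @param window chase-day window `c(t_a, t_b)` (days).
#' @param shed_rate known per-suprabasal-cell shedding rate (/day) for the
#'   loss correction; 0 assumes shedding negligible in the window.
#' @param region summary stratum to use.
#' @return A list of class `"division_interval"`: `interval` (days per
#'   division), `rate` (/day), `se` (days), `window`, `n_points`.
#' @export
division_interval <- function(summary, window = c(3.5, 30), shed_rate = 0,
                              region = "pooled") {
  s <- summary_rows(summary, region)
  keep <- s$chase_day >= window[1] & s$chase_day <= window[2] &
    is.finite(s$f_total) & is.finite(s$f_basal)
  s <- s[keep, , drop = FALSE]
  if (nrow(s) < 3) stop("need >= 3 chase points inside the window")
  est <- function(ft, fb) {
    shed_loss <- shed_rate * trapz(s$chase_day, pmax(ft - fb, 0))
    rho <- (ft[length(ft)] - ft[1] + shed_loss) / trapz(s$chase_day, fb)
    1 / rho
  }
  if (any(diff(s$f_total) < 0))
    warning("f_total is not increasing throughout the window; ",
            "division-interval estimate may be unreliable")
  interval <- est(s$f_total, s$f_basal)
  se <- NA_real_
  bt <- boot_series(summary, region, "f_total")
  bb <- boot_series(summary, region, "f_basal")
  if (!is.null(bt)) {
    idx <- match(s$chase_day, attr(summary, "chase_days"))
    reps <- vapply(seq_len(nrow(bt)), function(r)
      est(bt[r, idx], bb[r, idx]), 0)
    se <- sd(reps[is.finite(reps)])
  }
  structure(list(interval = interval, rate = 1 / interval, se = se,
                 window = window, n_points = nrow(s), region = region),
            class = "division_interval")
}

#' @export
print.division_interval <- function(x, ...) {
  cat(sprintf(
    "Division interval: %.2f +/- %.2f days (window %g-%g d, %d points)\n",
    x$interval, x$se, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Exponential half-life of a labeled cell fraction
#'
#' Ordinary least squares of \eqn{\log_2} of the chosen observable on chase
#' time from `t_start` onwards; the half-life is \eqn{-1/\mathrm{slope}}.
#' Zero or negative observations are dropped with a warning.  The standard
#' error is propagated from the clone-level bootstrap replicates.
#'
#' @param summary a [summarize_clones()] result.
#' @param t_start first chase day entering the fit (days).
#' @param observable `"f_basal"` or `"f_total"`.
#' @param region summary stratum to use.
#' @return A list of class `"half_life"`: `half_life` (days), `se`,
#'   `slope` (log2 units/day), `n_points`.
#' @export
half_life <- function(summary, t_start = 60,
                      observable = c("f_basal", "f_total"),
                      region = "pooled") {
  observable <- match.arg(observable)
  s <- summary_rows(summary, region)
  s <- s[s$chase_day >= t_start, , drop = FALSE]
  y <- s[[observable]]
  if (any(!is.finite(y) | y <= 0)) {
    warning("dropping chase day(s) with zero/missing ", observable)
    s <- s[is.finite(y) & y > 0, , drop = FALSE]
  }
  if (nrow(s) < 3) stop("need >= 3 positive points with t >= t_start")
  est <- function(t, y) {
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 2) return(NA_real_)
    -1 / coef(lm(log2(y[ok]) ~ t[ok]))[2]
  }
  hl <- est(s$chase_day, s[[observable]])
  se <- NA_real_
  bk <- boot_series(summary, region, observable)
  if (!is.null(bk)) {
    idx <- match(s$chase_day, attr(summary, "chase_days"))
    reps <- vapply(seq_len(nrow(bk)), function(r) est(s$chase_day, bk[r, idx]), 0)
    reps <- reps[is.finite(reps) & reps > 0]
    se <- sd(reps)
  }
  structure(list(half_life = unname(hl), se = se,
                 slope = unname(-1 / hl), observable = observable,
                 t_start = t_start, n_points = nrow(s), region = region),
            class = "half_life")
}

#' @export
print.half_life <- function(x, ...) {
  cat(sprintf("Exponential half-life of %s: %.1f +/- %.1f days (t >= %g d)\n",
              x$observable, x$half_life, x$se, x$t_start))
  invisible(x)
}

gauss_block_nll <- function(y, p, se) {
  z <- (y - p) / se
  sum(0.5 * z^2 + log(se) + 0.5 * log(2 * pi))
}

fix_weights <- function(se, what) {
  bad <- !is.finite(se) | se <= 0
  if (all(bad)) {
    warning("degenerate ", what, " weights; falling back to unweighted fit")
    se[] <- 1
  }
  se
}

# drop observations whose bootstrap SE is degenerate (e.g. a chase day with
# a single surviving clone); keep everything when none or all are usable
drop_degenerate <- function(t, y, se, what) {
  se <- fix_weights(se, what)
  bad <- !is.finite(se) | se <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " ", what,
            " point(s) with degenerate bootstrap SE")
    t <- t[!bad]; y <- y[!bad]; se <- se[!bad]
  }
  list(t = t, y = y, se = se)
}

#' Fit the critical birth-death model
#'
#' Joint weighted least squares of the neutral-drift signatures
#' \eqn{\bar n(t) = 1 + r (t - t_0)} and
#' \eqn{S(t) = s_0 / (1 + r (t - t_0))} against observed mean basal clone
#' size and clone survival from `t_start` onwards, with weights
#' \eqn{1/\mathrm{SE}^2} and a Gaussian log-likelihood.  A residual
#' chi-square lack-of-fit p-value is reported; a biphasic population shows
#' systematic lack of fit.
#'
#' @param summary a [summarize_clones()] result.
#' @param t_start first chase day entering the fit (default 30 days, after
#'   any initial labeling transient).
#' @param region summary stratum to use.
#' @return An object of class `"bd_fit"` with `model_id = "cbdm"`, fitted
#'   `params` (`r`, `s0`), `se`, `loglik`, lack-of-fit `gof`, and the
#'   fitted data.
#' @export
fit_cbdm <- function(summary, t_start = 30, region = "pooled") {
  s <- summary_rows(summary, region)
  t0 <- attr(summary, "baseline_day")
  keep <- s$chase_day >= t_start & is.finite(s$mean_basal_size) &
    is.finite(s$survival)
  s <- s[keep, , drop = FALSE]
  if (nrow(s) < 3) stop("need >= 3 chase points with t >= t_start")
  se_n <- fix_weights(s$se_mean_basal_size, "clone-size")
  se_s <- fix_weights(s$se_survival, "survival")
  bad <- !is.finite(se_n) | se_n <= 0 | !is.finite(se_s) | se_s <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " chase day(s) with degenerate bootstrap SE")
    s <- s[!bad, , drop = FALSE]; se_n <- se_n[!bad]; se_s <- se_s[!bad]
    if (nrow(s) < 3) stop("need >= 3 chase points with usable weights")
  }
  dt <- s$chase_day - t0
  nll <- function(th) {
    r <- th[1]; s0 <- th[2]
    p_n <- 1 + r * dt
    p_s <- s0 / p_n
    v <- gauss_block_nll(s$mean_basal_size, p_n, se_n) +
      gauss_block_nll(s$survival, p_s, se_s)
    if (!is.finite(v)) 1e10 else v
  }
  r0 <- max((s$mean_basal_size[nrow(s)] - 1) / max(dt), 1e-4)
  ctl <- list(factr = 1e2, ndeps = rep(1e-7, 2))
  opt <- optim(c(r0, 1), nll, method = "L-BFGS-B",
               lower = c(1e-6, 1e-3), upper = c(5, 10), control = ctl)
  H <- tryCatch(stats::optimHess(opt$par, nll,
                                 control = list(ndeps = rep(1e-5, 2))),
                error = function(e) matrix(NA, 2, 2))
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, 2))
  r <- opt$par[1]; s0 <- opt$par[2]
  z2 <- sum(((s$mean_basal_size - (1 + r * dt)) / se_n)^2,
            ((s$survival - s0 / (1 + r * dt)) / se_s)^2)
  df <- 2 * nrow(s) - 2
  structure(list(model_id = "cbdm", params = c(r = r, s0 = s0),
                 se = setNames(se, c("r", "s0")), T = NA_real_,
                 loglik = -opt$value,
                 n_obs = 2 * nrow(s),
                 gof = list(chisq = z2, df = df,
                            p = pchisq(z2, df, lower.tail = FALSE)),
                 baseline_day = t0,
                 data = list(chase_day = s$chase_day,
                             mean_basal_size = s$mean_basal_size,
                             survival = s$survival,
                             se_n = se_n, se_s = se_s)),
            class = "bd_fit")
}

labeling_code <- function(labeling) {
  match(labeling, c("equal", "pre_transition", "post_transition")) - 1L
}

gbdm_model_id <- function(labeling) {
  c(equal = "gbdm_equal", pre_transition = "gbdm_pre",
    post_transition = "gbdm_post")[labeling]
}

gbdm_fit_data <- function(summary, region) {
  s <- summary_rows(summary, region)
  t0 <- attr(summary, "baseline_day")
  f <- s[s$chase_day != t0 & is.finite(s$f_basal), , drop = FALSE]
  n <- s[is.finite(s$mean_basal_size), , drop = FALSE]
  fb <- drop_degenerate(f$chase_day, f$f_basal, f$se_f_basal, "cell-fraction")
  nb <- drop_degenerate(n$chase_day, n$mean_basal_size,
                        n$se_mean_basal_size, "clone-size")
  list(t0 = t0, t_f = fb$t, y_f = fb$y, se_f = fb$se,
       t_n = nb$t, y_n = nb$y, se_n = nb$se)
}

#' Fit the generalized (biphasic) birth-death model
#'
#' Maximum-likelihood fit of a biphasic schedule with free rates
#' \eqn{(\lambda_1, \mu_1)} before and \eqn{(\lambda_2, \mu_2)} after a
#' fixed transition age `T`, under the chosen labeling model, against
#' [predict_observables()].  The extinction phase is kept subcritical by
#' parameterizing \eqn{\mu_2 = \lambda_2 + \delta_2}, \eqn{\delta_2 > 0}.
#' The post-transition labeling model is the monophasic model
#' (\eqn{\lambda_1 = \lambda_2}, \eqn{\mu_1 = \mu_2}; 2 free rate
#' parameters).
#'
#' Two likelihoods are available.  The default, `"counts"`, is the exact
#' sampling distribution the model implies for a sparse-labeling
#' cross-sectional design: the number of surviving labeled clones per
#' cohort is Poisson with mean proportional to model survival (the scale
#' is profiled out analytically), and surviving basal clone sizes are
#' geometric with the mixture mean size — the neutral-competition law.
#' This needs no variance estimates and is well calibrated even at chase
#' days with a handful of surviving clones.  The `"gaussian"` alternative
#' is a weighted least-squares likelihood of the summary series
#' \{`f_basal`, `mean_basal_size`\} with bootstrap-SE weights, the fraction
#' series anchored to the baseline chase day (survival is not fitted — it
#' equals `f_basal / mean_basal_size` and would double-count).
#'
#' Optimization uses bounded quasi-Newton (`L-BFGS-B`) from `n_starts`
#' seeded random starts.  Standard errors come from the observed
#' information (inverse Hessian) or, with `se_method = "bootstrap"` under
#' the Gaussian likelihood, from refitting clone-bootstrap replicate
#' series.  Profile-likelihood confidence intervals are reported for the
#' two net rates \eqn{\lambda_1-\mu_1} and \eqn{\mu_2-\lambda_2}.
#'
#' @param summary a [summarize_clones()] result.
#' @param labeling labeling model (see [age_density()]).
#' @param T transition age (days); fixed, never fitted.
#' @param region summary stratum to use.
#' @param likelihood `"counts"` (exact Poisson/geometric) or `"gaussian"`
#'   (weighted least squares on summary series).  Falls back to
#'   `"gaussian"` when the summary carries no per-clone sizes.
#' @param n_starts number of multi-start optimizations.
#' @param se_method `"hessian"` or `"bootstrap"` (Gaussian only).
#' @param n_boot bootstrap refits when `se_method = "bootstrap"`.
#' @param ci_level level of the profile-likelihood intervals.
#' @return An object of class `"bd_fit"`: `params`
#'   (`lambda1`, `mu1`, `lambda2`, `mu2`), `se`, `loglik`, `derived`
#'   (net rates with SEs, profile CIs and, for biphasic fits,
#'   [steady_state()] quantities), and the fitted data.
#' @export
fit_gbdm <- function(summary,
                     labeling = c("equal", "pre_transition", "post_transition"),
                     T = 45, region = "pooled",
                     likelihood = c("counts", "gaussian"), n_starts = 10,
                     se_method = c("hessian", "bootstrap"), n_boot = 100,
                     ci_level = 0.95) {
  labeling <- match.arg(labeling)
  se_method <- match.arg(se_method)
  likelihood <- match.arg(likelihood)
  sizes_all <- attr(summary, "sizes")[[region]]
  if (likelihood == "counts" && is.null(sizes_all)) {
    likelihood <- "gaussian"
    message("summary carries no per-clone sizes; using the Gaussian likelihood")
  }
  post <- labeling == "post_transition"
  code <- labeling_code(labeling)
  gl <- gl_rule(20L)
  if (likelihood == "counts") {
    sr <- summary_rows(summary, region)
    cd <- attr(summary, "chase_days")
    area <- attr(summary, "area")
    obs_days <- sr$chase_day[sr$n_clones > 0]
    if (length(obs_days) < 5 || min(obs_days) >= T || max(obs_days) <= T)
      stop("need observables at >= 5 chase days spanning the transition age")
    K <- sr$n_surviving[match(cd, sr$chase_day)]
    # a chase day with no recorded clones has no identifiable cohort/area;
    # it carries no usable count information and is dropped
    keep <- is.finite(area) & area > 0
    size_day <- integer(0); size_val <- integer(0)
    jj <- 0L
    for (j in seq_along(cd)) {
      if (!keep[j]) next
      v <- sizes_all[[j]]
      size_day <- c(size_day, rep.int(jj, length(v)))
      size_val <- c(size_val, as.integer(v))
      jj <- jj + 1L
    }
    d <- list(t0 = attr(summary, "baseline_day"), likelihood = "counts",
              days = cd[keep], K = K[keep], area = area[keep],
              size_day = size_day, size_val = size_val)
    nll_full <- function(th)  # th = (l1, m1, l2, d2)
      gbdm_counts_negloglik_cpp(th, T, code, d$days, d$K, d$area,
                                d$size_day, d$size_val, gl$x, gl$w)
  } else {
    d <- gbdm_fit_data(summary, region)
    d$likelihood <- "gaussian"
    days <- sort(unique(c(d$t_f, d$t_n)))
    if (length(days) < 5 || min(days) >= T || max(days) <= T)
      stop("need observables at >= 5 chase days spanning the transition age")
    nll_full <- function(th)  # th = (l1, m1, l2, d2)
      gbdm_negloglik_cpp(th, T, code, d$t_f, d$y_f, d$se_f,
                         d$t_n, d$y_n, d$se_n, d$t0, gl$x, gl$w)
  }
  nll <- if (post) function(th) nll_full(c(th[1], th[1] + th[2], th)) else nll_full
  npar <- if (post) 2L else 4L
  lower <- if (post) c(0, 1e-5) else c(0, 0, 0, 1e-5)
  upper <- rep(1, npar)
  starts <- matrix(exp(runif(n_starts * npar, log(0.004), log(0.4))),
                   nrow = n_starts)
  starts[1, ] <- if (post) c(0.05, 0.02) else c(0.1, 0.07, 0.05, 0.02)
  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(factr = 1e2, maxit = 1000,
                           ndeps = rep(1e-7, npar))),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    stop("GBDM fit failed to converge from any start")
  th <- best$par
  full <- if (post) c(th[1], th[1] + th[2], th) else th
  params <- c(lambda1 = full[1], mu1 = full[2],
              lambda2 = full[3], mu2 = full[3] + full[4])
  H <- tryCatch(stats::optimHess(th, nll,
                                 control = list(ndeps = rep(1e-5, npar))),
                error = function(e) NULL)
  V <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  th_se <- if (!is.null(V)) sqrt(pmax(diag(V), 0)) else rep(NA_real_, npar)
  boot_reps <- NULL
  if (se_method == "bootstrap" && likelihood == "counts") {
    warning("bootstrap SEs are only available under the Gaussian likelihood; ",
            "using Hessian SEs")
    se_method <- "hessian"
  }
  if (se_method == "bootstrap") {
    bf <- boot_series(summary, region, "f_basal")
    bn <- boot_series(summary, region, "mean_basal_size")
    cd <- attr(summary, "chase_days")
    reps <- matrix(NA_real_, min(n_boot, nrow(bf)), npar)
    for (r in seq_len(nrow(reps))) {
      yf <- bf[r, match(d$t_f, cd)]; yn <- bn[r, match(d$t_n, cd)]
      okf <- is.finite(yf); okn <- is.finite(yn)
      nb <- function(thb) {
        thf <- if (post) c(thb[1], thb[1] + thb[2], thb) else thb
        gbdm_negloglik_cpp(thf, T, code, d$t_f[okf], yf[okf], d$se_f[okf],
                           d$t_n[okn], yn[okn], d$se_n[okn], d$t0, gl$x, gl$w)
      }
      o <- tryCatch(optim(th, nb, method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(factr = 1e2,
                                         ndeps = rep(1e-7, npar))),
                    error = function(e) NULL)
      if (!is.null(o)) reps[r, ] <- o$par
    }
    th_se <- apply(reps, 2, sd, na.rm = TRUE)
    boot_reps <- reps
  }
  # SEs for the net rates: bootstrap replicate spread when available,
  # otherwise delta method on the inverse Hessian
  if (post) {
    se <- setNames(th_se[c(1, 2, 1, 2)], names(params))
    if (is.null(boot_reps) && !is.null(V))
      se["mu1"] <- se["mu2"] <- sqrt(max(V[1, 1] + V[2, 2] + 2 * V[1, 2], 0))
    if (!is.null(boot_reps))
      se["mu1"] <- se["mu2"] <- sd(boot_reps[, 1] + boot_reps[, 2], na.rm = TRUE)
    net1 <- c(est = -th[2], se = th_se[2])
    net2 <- c(est = th[2], se = th_se[2])
  } else {
    se <- setNames(c(th_se[1:3], NA), names(params))
    if (!is.null(boot_reps)) {
      se["mu2"] <- sd(boot_reps[, 3] + boot_reps[, 4], na.rm = TRUE)
      net1 <- c(est = th[1] - th[2],
                se = sd(boot_reps[, 1] - boot_reps[, 2], na.rm = TRUE))
    } else {
      if (!is.null(V)) {
        se["mu2"] <- sqrt(max(V[3, 3] + V[4, 4] + 2 * V[3, 4], 0))
        net1 <- c(est = th[1] - th[2],
                  se = sqrt(max(V[1, 1] + V[2, 2] - 2 * V[1, 2], 0)))
      } else {
        net1 <- c(est = th[1] - th[2], se = NA_real_)
      }
    }
    net2 <- c(est = th[4], se = th_se[4])
  }
  # profile-likelihood confidence intervals for the net rates: walk
  # outward from the MLE, re-maximizing over the remaining parameters
  # (warm-started), until the profile deviance crosses the chi-square cut
  profile_ci <- function(which, level = ci_level) {
    thr <- stats::qchisq(level, 1)
    mle_val <- if (which == "net1") {
      if (post) -th[2] else th[1] - th[2]
    } else th[npar]
    assemble <- function(v, free) {
      # free params given the fixed net value v
      if (post) {
        if (which == "net1") c(free[1], free[1] - v, free[1], -v)
        else c(free[1], free[1] + v, free[1], v)
      } else {
        if (which == "net1") c(free[1] + v, free[1], free[2], free[3])
        else c(free[1], free[2], free[3], v)
      }
    }
    free0 <- if (post) th[1] else if (which == "net1") th[c(2, 3, 4)] else th[1:3]
    nfree <- length(free0)
    prof <- function(v, start_free) {
      lo <- rep(0, nfree); hi <- rep(1, nfree)
      if (!post && which == "net1") lo[1] <- max(0, -v)
      if (!post && which == "net2") hi <- c(1, 1, 1)
      if (post && which == "net1" && v >= 0) return(list(val = Inf, free = start_free))
      start_free <- pmin(pmax(start_free, lo), hi)
      o <- tryCatch(optim(start_free,
                          function(fr) nll_full(assemble(v, fr)),
                          method = "L-BFGS-B", lower = lo, upper = hi,
                          control = list(factr = 1e2,
                                         ndeps = rep(1e-7, nfree))),
                    error = function(e) NULL)
      if (is.null(o)) list(val = Inf, free = start_free)
      else list(val = o$value, free = o$par)
    }
    step <- if (which == "net1") 0.02 else 0.002
    lim <- if (which == "net1") c(-1, 1) else c(1e-5, 1)
    walk <- function(dir) {
      v <- mle_val; fr <- free0; dev_prev <- 0
      repeat {
        v2 <- v + dir * step
        atlim <- FALSE
        if (v2 <= lim[1]) { v2 <- lim[1]; atlim <- TRUE }
        if (v2 >= lim[2]) { v2 <- lim[2]; atlim <- TRUE }
        if (v2 == v) return(v)
        p <- prof(v2, fr)
        dev <- 2 * (p$val - loglik_max)
        if (!is.finite(dev)) return(v)
        if (dev > thr)  # linear interpolation to the crossing
          return(v + dir * abs(v2 - v) *
                   max(0, min(1, (thr - dev_prev) / (dev - dev_prev))))
        if (atlim) return(v2)
        v <- v2; fr <- p$free; dev_prev <- dev
      }
    }
    c(lower = walk(-1), upper = walk(+1))
  }
  loglik_max <- best$value  # negative loglik at the optimum
  ci_net1 <- profile_ci("net1")
  ci_net2 <- profile_ci("net2")

  fitted_schedule <- rate_schedule(start = c(0, T),
                                   lambda = params[c("lambda1", "lambda2")],
                                   mu = params[c("mu1", "mu2")],
                                   transition_age = T)
  derived <- list(net_pre = net1, net_post = net2,
                  ci_net_pre = ci_net1, ci_net_post = ci_net2)
  if (!post) {
    ssd <- tryCatch(steady_state(fitted_schedule), error = function(e) NULL)
    if (!is.null(ssd))
      derived <- c(derived, list(amp_fold = ssd$amp_fold,
                                 frac_post = ssd$frac_post, nu = ssd$nu))
  }
  structure(list(model_id = unname(gbdm_model_id(labeling)),
                 labeling = labeling, params = params, se = se, T = T,
                 loglik = -best$value, likelihood = likelihood,
                 n_free = npar + (likelihood == "counts"),
                 n_obs = if (likelihood == "counts")
                   sum(d$K > 0) + length(d$size_val)
                 else length(d$t_f) + length(d$t_n),
                 derived = derived, schedule = fitted_schedule,
                 baseline_day = d$t0, data = d),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat("Birth-death model fit: ", x$model_id, "\n", sep = "")
  p <- data.frame(estimate = x$params, se = x$se)
  print(signif(p, 4))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  if (!is.null(x$gof))
    cat(sprintf("  lack-of-fit chi-square: %.2f on %d df (p = %.3g)\n",
                x$gof$chisq, x$gof$df, x$gof$p))
  if (!is.null(x$derived$amp_fold))
    cat(sprintf("  amplification fold %.2f; %.1f%% of cells past transition; nu = %.4g/day\n",
                x$derived$amp_fold, 100 * x$derived$frac_post, x$derived$nu))
  invisible(x)
}

#' Model-predicted observables from a fitted model
#'
#' @param fit a `"bd_fit"` from [fit_gbdm()] or [fit_cbdm()].
#' @param chase_days chase times (days).
#' @return A data frame as from [predict_observables()], with `f_basal`
#'   anchored to the fit's baseline day.
#' @export
fitted_observables <- function(fit, chase_days) {
  stopifnot(inherits(fit, "bd_fit"))
  if (fit$model_id == "cbdm") {
    p <- cbdm_predict(fit$params[["r"]], chase_days)
    p$survival <- fit$params[["s0"]] / (1 + fit$params[["r"]] *
                                          (chase_days - fit$baseline_day))
    p$mean_basal_size <- 1 + fit$params[["r"]] * (chase_days - fit$baseline_day)
    return(p)
  }
  p <- predict_observables(fit$schedule, fit$labeling,
                           c(fit$baseline_day, chase_days))
  f0 <- p$f_basal[1]; s0 <- p$survival[1]
  p <- p[-1, , drop = FALSE]
  p$f_basal <- p$f_basal / f0
  p$survival <- p$survival / s0
  rownames(p) <- NULL
  p
}

#' Likelihood-ratio and AIC comparison of fitted models
#'
#' The post-transition labeling model is the monophasic null nested in
#' either biphasic model with 2 extra free parameters; it is compared by a
#' likelihood-ratio test with a chi-square(2) reference.  The two biphasic
#' models (equal vs pre-transition labeling) are not nested and are
#' compared by AIC only.
#'
#' @param fits list of `"bd_fit"` objects fitted to the same data.
#' @return A list of class `"model_comparison"` with elements `lrt`
#'   (statistic \eqn{2\Delta\ell}, dof, p, confidence \eqn{1-p} per nested
#'   pair) and `aic`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "bd_fit")))
  ids <- vapply(fits, `[[`, "", "model_id")
  names(fits) <- ids
  gb <- fits[startsWith(ids, "gbdm")]
  if (length(gb) > 1) {
    dat <- lapply(gb, `[[`, "data")
    if (!all(vapply(dat[-1], identical, TRUE, dat[[1]])))
      stop("fits were not computed on identical data and weights")
  }
  lrt <- NULL
  if ("gbdm_post" %in% ids) {
    ll0 <- fits[["gbdm_post"]]$loglik
    alt <- intersect(c("gbdm_equal", "gbdm_pre"), ids)
    lrt <- do.call(rbind, lapply(alt, function(a) {
      stat <- max(2 * (fits[[a]]$loglik - ll0), 0)
      dof <- fits[[a]]$n_free - fits[["gbdm_post"]]$n_free
      p <- pchisq(stat, dof, lower.tail = FALSE)
      data.frame(model = a, null = "gbdm_post", stat = stat, dof = dof,
                 p = p, confidence = 1 - p)
    }))
  }
  aic <- data.frame(
    model = ids,
    n_free = vapply(fits, function(f)
      f$n_free %||% length(f$params), 0),
    loglik = vapply(fits, `[[`, 0, "loglik"))
  aic$aic <- 2 * aic$n_free - 2 * aic$loglik
  aic <- aic[order(aic$aic), ]
  rownames(aic) <- NULL
  structure(list(lrt = lrt, aic = aic), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  if (!is.null(x$lrt)) {
    cat("Likelihood-ratio tests vs the monophasic (post-transition) model:\n")
    print(transform(x$lrt, stat = signif(stat, 4), p = signif(p, 3),
                    confidence = signif(confidence, 4)))
  }
  cat("AIC table:\n")
  print(transform(x$aic, loglik = round(loglik, 2), aic = round(aic, 2)))
  invisible(x)
}

#' Goodness of fit to the neutral-competition clone-size law
#'
#' Kolmogorov-style comparison of the empirical clone-size distribution at
#' one chase day with the geometric law [clone_size_cdf()] evaluated at the
#' observed mean size: the statistic is the maximum gap on the integer
#' support, and its p-value comes from a parametric bootstrap (resampling
#' the fitted law at the observed clone count, re-estimating the mean each
#' time).
#'
#' @param table a [clone_table()].
#' @param chase_day chase day to test.
#' @param form `"general"` (geometric) or `"asymptotic"` (neutral-drift
#'   limit).
#' @param layer clone-size layer, as in [empirical_cdf()].
#' @param n_boot parametric bootstrap resamples.
#' @param seed optional seed (caller RNG restored).
#' @return A list of class `"neutrality_gof"`: `stat` (max CDF gap),
#'   `p.value`, `nbar`, `n_clones`.  Fewer than 20 surviving clones
#'   triggers an underpowered warning.
#' @export
neutrality_gof <- function(table, chase_day,
                           form = c("general", "asymptotic"),
                           layer = c("basal", "total"),
                           n_boot = 2000, seed = NULL) {
  form <- match.arg(form)
  layer <- match.arg(layer)
  ec <- empirical_cdf(table, chase_day, layer)
  if (ec$n_clones < 20)
    warning("fewer than 20 surviving clones: neutrality test is underpowered")
  ks_stat <- function(sizes) {
    nb <- mean(sizes)
    if (nb < 1 + 1e-12) return(0)
    supp <- sort(unique(sizes))
    emp <- cumsum(tabulate(factor(sizes, levels = supp))) / length(sizes)
    model <- clone_size_cdf(nb, supp, form)
    # check both sides of each empirical step
    max(abs(emp - model), abs(c(0, emp[-length(emp)]) - model))
  }
  rec <- table$records[table$records$chase_day == chase_day, , drop = FALSE]
  sizes <- switch(layer, basal = rec$basal[rec$basal >= 1],
                  total = rec$basal + rec$suprabasal)
  stat <- ks_stat(sizes)
  with_local_seed(seed, {
    q <- 1 - 1 / ec$nbar
    reps <- vapply(seq_len(n_boot), function(i)
      ks_stat(rgeom(ec$n_clones, 1 - q) + 1L), 0)
    p <- (sum(reps >= stat - 1e-12) + 1) / (n_boot + 1)
    structure(list(stat = stat, p.value = p, nbar = ec$nbar,
                   n_clones = ec$n_clones, form = form, layer = layer,
                   chase_day = chase_day),
              class = "neutrality_gof")
  })
}

#' @export
print.neutrality_gof <- function(x, ...) {
  cat(sprintf(
    "Neutral-competition GOF (day %g, %s, %s law): D = %.3f, p = %.3g (%d clones, nbar = %.2f)\n",
    x$chase_day, x$layer, x$form, x$stat, x$p.value, x$n_clones, x$nbar))
  invisible(x)
}
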