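#' Configuration for the cross-sectional experiment simulator
#'
#' Collects everything the synthetic-data generator needs: the rate
#' schedule (including the neutral division rate `sigma` per phase), the
#' suprabasal shedding rate, the labeling model, the target number of
#' labeled clones per chase cohort, the chase-day schedule, and the
#' interscale:scale labeling ratio.
#'
#' @param schedule a [rate_schedule()].
#' @param shed_rate per-suprabasal-cell shedding rate (events/day).
#' @param labeling labeling model (see [age_density()]).
#' @param clones_per_day expected labeled clones per chase cohort (the
#'   realized number is Poisson).
#' @param chase_days cross-sectional chase schedule (days).
#' @param region_ratio named numeric vector `c(interscale = , scale = )`
#'   of labeling proportions.
#' @return An object of class `"simulator_config"`.
#' @export
simulator_config <- function(schedule, shed_rate = 1 / 30,
                             labeling = c("equal", "pre_transition",
                                          "post_transition"),
                             clones_per_day = 80,
                             chase_days = c(3.5, 7, 14, 30, 60, 90, 180, 365),
                             region_ratio = c(interscale = 1, scale = 1)) {
  labeling <- match.arg(labeling)
  stopifnot(inherits(schedule, "rate_schedule"))
  if (shed_rate < 0) stop("shed_rate must be nonnegative")
  if (clones_per_day < 1) stop("clones_per_day must be >= 1")
  if (!all(c("interscale", "scale") %in% names(region_ratio)) ||
      any(region_ratio < 0) || sum(region_ratio) <= 0)
    stop("region_ratio must be a nonnegative named vector over interscale/scale")
  structure(list(schedule = schedule, shed_rate = shed_rate,
                 labeling = labeling, clones_per_day = clones_per_day,
                 chase_days = sort(chase_days),
                 region_ratio = region_ratio[c("interscale", "scale")]),
            class = "simulator_config")
}

#' Study-condition presets for the two marked lineages
#'
#' `ta_biphasic_config()` emulates the biphasic transit-amplifying
#' (Aspm-like) lineage: an amplification phase with net growth
#' \eqn{\ln 4/45} per day (4-fold basal amplification by the 45-day
#' transition), then a subcritical extinction phase with net decline
#' \eqn{\ln 2/57} per day (57-day basal half-life), a birth rate dropped
#' more than 3-fold at the transition, and a surviving-clone mean size
#' plateau of \eqn{\mu_2/(\mu_2-\lambda_2) = 2.5} basal cells.  The total
#' division rate (\eqn{\lambda+\sigma}) is 0.25/day in both phases (one
#' division per 4 days); most divisions are neutral (asymmetric or
#' delaminating), as observed in live imaging.  `sc_critical_config()`
#' emulates the self-renewing stem-cell (Dlx1-like) lineage: balanced
#' constant rates with one division per 13 days
#' (\eqn{\lambda+\sigma = 1/13}).
#'
#' @param clones_per_day expected labeled clones per chase cohort.
#' @param ... passed on to [simulator_config()].
#' @return A [simulator_config()].
#' @export
ta_biphasic_config <- function(clones_per_day = 80, ...) {
  delta <- log(2) / 57             # extinction-phase net decline
  lambda2 <- 1.5 * delta           # plateau mu2/(mu2-lambda2) = 2.5
  mu2 <- 2.5 * delta
  lambda1 <- 0.06
  mu1 <- lambda1 - log(4) / 45     # 4-fold amplification by transition
  sc <- rate_schedule(start = c(0, 45),
                      lambda = c(lambda1, lambda2),
                      mu = c(mu1, mu2),
                      sigma = c(0.25 - lambda1, 0.25 - lambda2),
                      transition_age = 45)
  simulator_config(sc, clones_per_day = clones_per_day, ...)
}

#' @rdname ta_biphasic_config
#' @export
sc_critical_config <- function(clones_per_day = 80, ...) {
  sc <- rate_schedule(lambda = 0.02, mu = 0.02, sigma = 1 / 13 - 0.02)
  simulator_config(sc, clones_per_day = clones_per_day, ...)
}

#' Sample founder clonal ages for a labeling model
#'
#' Draws clonal ages at labeling from the steady-state age density of the
#' chosen labeling model (see [age_density()]) by inverse-CDF sampling on
#' the piecewise-exponential closed form.
#'
#' @param steady a [steady_state()].
#' @param labeling labeling model.
#' @param n number of draws.
#' @return Numeric vector of clonal ages (days).
#' @export
sample_labeling_age <- function(steady,
                                labeling = c("equal", "pre_transition",
                                             "post_transition"),
                                n) {
  labeling <- match.arg(labeling)
  stopifnot(inherits(steady, "steady_state"))
  sc <- steady$schedule
  win <- labeling_window(labeling, sc$transition_age)
  # piecewise-exponential segments of m(a) restricted to the window
  sc2 <- split_schedule(sc, sc$transition_age)
  prof <- schedule_age_profile(sc2)
  lo <- pmax(sc2$start, win[1])
  hi <- pmin(c(sc2$start[-1], Inf), win[2])
  keep <- which(hi > lo)
  mass <- vapply(keep, function(j) age_profile_mass(prof, lo[j], hi[j]), 0)
  seg <- keep[sample.int(length(keep), n, replace = TRUE, prob = mass)]
  u <- runif(n)
  g <- prof$g[seg]
  a <- numeric(n)
  fin <- is.finite(hi[seg])
  # invert int_lo^a e^{g s} ds = u * int_lo^hi within each segment
  d <- hi[seg] - lo[seg]
  egd <- exp(g * d)
  a[fin] <- lo[seg[fin]] + ifelse(abs(g[fin]) < 1e-14,
                                  u[fin] * d[fin],
                                  log1p(u[fin] * (egd[fin] - 1)) / g[fin])
  if (any(!fin)) {
    # unbounded tail: g < 0, truncated exponential from lo
    gi <- g[!fin]
    a[!fin] <- lo[seg[!fin]] + log1p(-u[!fin]) / gi
  }
  a
}

schedule_of <- function(config) config$schedule

#' Simulate one clone by exact Gillespie dynamics
#'
#' Simulates a clone founded by a single labeled basal cell of clonal age
#' `a0`, observed after `t_obs` days of chase.  Per-basal-cell events are
#' birth (`basal + 1`), death (`basal - 1`, `suprabasal + 1`) and neutral
#' division (`suprabasal + 1`); suprabasal cells are shed (`suprabasal -
#' 1`) at `shed_rate`.  Rates follow the schedule at the clone's current
#' clonal age; waiting times are capped at phase boundaries.  Uses R's RNG
#' (reproducible under `set.seed()`).
#'
#' @param config a [simulator_config()].
#' @param a0 founder clonal age at labeling (days).
#' @param t_obs chase duration (days).
#' @param audit if `TRUE`, also return the full event log.
#' @return Named integer vector `c(basal, suprabasal)`, or with
#'   `audit = TRUE` a list with counts and an event data frame (`time`,
#'   `type`, `d_basal`, `d_suprabasal`, `d_total`).
#' @export
simulate_clone <- function(config, a0, t_obs, audit = FALSE) {
  stopifnot(inherits(config, "simulator_config"))
  if (a0 < 0 || t_obs < 0) stop("a0 and t_obs must be nonnegative")
  sc <- config$schedule
  if (!audit) {
    m <- sim_clones_cpp(sc$start, sc$lambda, sc$mu, sc$sigma,
                        config$shed_rate, a0, t_obs)
    return(c(basal = unname(m[1, 1]), suprabasal = unname(m[1, 2])))
  }
  r <- sim_clone_audit_cpp(sc$start, sc$lambda, sc$mu, sc$sigma,
                           config$shed_rate, a0, t_obs)
  ev <- data.frame(time = r$time,
                   type = c("birth", "death", "neutral", "shed")[r$type],
                   d_basal = r$d_basal, d_suprabasal = r$d_suprabasal)
  ev$d_total <- ev$d_basal + ev$d_suprabasal
  list(basal = r$basal, suprabasal = r$suprabasal, events = ev)
}

#' Generate a cross-sectional lineage-tracing experiment
#'
#' Emulates a sparse-labeling pulse-chase experiment: for each chase day an
#' independent cohort of labeled clones is drawn (Poisson around
#' `clones_per_day`), each clone starting as exactly one labeled basal cell
#' whose clonal age is sampled from the labeling model's steady-state age
#' density (for a single-phase schedule rates do not depend on age and the
#' founder age is irrelevant).  Each clone is simulated by [simulate_clone()]
#' to its cohort's chase day; clones with no remaining cells are dropped
#' from the records (their loss is visible as declining clones per area),
#' and regions are assigned at the configured ratio with identical dynamics
#' in both.
#'
#' @param config a [simulator_config()].
#' @param seed optional seed (caller RNG restored).
#' @return A [clone_table()]; `attr(, "truth")` records the configuration,
#'   the number of clones labeled per cohort, and the founder ages, for
#'   parameter-recovery studies.
#' @export
generate_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulator_config"))
  sc <- config$schedule
  multi <- n_phases(sc) > 1
  ss <- if (multi) steady_state(sc) else NULL
  with_local_seed(seed, {
    p_inter <- config$region_ratio["interscale"] / sum(config$region_ratio)
    rows <- list(); n_labeled <- integer(0); ages <- list()
    for (d in config$chase_days) {
      n0 <- rpois(1, config$clones_per_day)
      n_labeled <- c(n_labeled, n0)
      if (n0 == 0) { ages <- c(ages, list(numeric(0))); next }
      a0 <- if (multi) sample_labeling_age(ss, config$labeling, n0) else
        rep(0, n0)
      ages <- c(ages, list(a0))
      m <- sim_clones_cpp(sc$start, sc$lambda, sc$mu, sc$sigma,
                          config$shed_rate, a0, rep(d, n0))
      alive <- m[, 1] + m[, 2] >= 1
      if (!any(alive)) next
      k <- sum(alive)
      rows[[length(rows) + 1]] <- data.frame(
        clone_id = sprintf("d%g_c%03d", d, seq_len(k)),
        cohort_id = sprintf("cohort_d%g", d),
        chase_day = d,
        region = ifelse(runif(k) < p_inter, "interscale", "scale"),
        basal = m[alive, 1], suprabasal = m[alive, 2])
    }
    rec <- do.call(rbind, rows)
    if (is.null(rec)) stop("no clones survived in any cohort")
    tab <- clone_table(rec, schedule = config$chase_days)
    attr(tab, "truth") <- list(config = config, n_labeled =
                                 setNames(n_labeled, config$chase_days),
                               founder_ages = ages)
    tab
  })
}
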