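#' Propagate a single-ancestor clone under a birth-death schedule
#'
#' Closed-form (Kendall-type) solution of the linear birth-death process
#' with piecewise-constant rates.  A clone founded by one basal cell of
#' clonal age `a0` is observed after a chase of `t` days.  With
#' \eqn{\rho(t) = \int_0^t (\lambda-\mu)\,ds} evaluated along ages
#' \eqn{a_0 \ldots a_0+t} and \eqn{I(t) = \int_0^t \mu(s) e^{-\rho(s)} ds},
#' the expected basal clone size is \eqn{M = e^{\rho}}, the extinction
#' probability \eqn{\alpha = I/(1+I)}, and the mean size among surviving
#' clones \eqn{\bar n = M(1+I)}.  The surviving-clone size distribution is
#' geometric with mean \eqn{\bar n} for any piecewise-constant schedule
#' (neutral competition); see [clone_size_cdf()].
#'
#' @param schedule a [rate_schedule()].
#' @param a0 clonal age(s) at labeling (days).
#' @param t chase duration(s) (days); recycled against `a0`.
#' @return A data frame of class `"bd_result"` with columns `a0`, `t`,
#'   `M` (unconditional mean), `alpha` (extinction probability),
#'   `beta` (geometric tail parameter, `1 - 1/nbar`) and `nbar`
#'   (conditional mean size of surviving clones).
#' @examples
#' sc <- rate_schedule(lambda = 0.2, mu = 0.2)
#' bd_propagate(sc, a0 = 0, t = 10)  # critical: M = 1, nbar = 1 + mu t = 3
#' @export
bd_propagate <- function(schedule, a0, t) {
  stopifnot(inherits(schedule, "rate_schedule"))
  n <- max(length(a0), length(t))
  a0 <- rep_len(as.numeric(a0), n)
  t <- rep_len(as.numeric(t), n)
  if (any(a0 < 0) || any(t < 0) || anyNA(a0) || anyNA(t))
    stop("a0 and t must be nonnegative")
  m <- bd_propagate_cpp(schedule$start, schedule$lambda, schedule$mu, a0, t)
  out <- data.frame(a0 = a0, t = t, M = m[, "M"], alpha = m[, "alpha"],
                    nbar = m[, "nbar"])
  out$beta <- 1 - 1 / out$nbar
  class(out) <- c("bd_result", "data.frame")
  out[, c("a0", "t", "M", "alpha", "beta", "nbar")]
}

#' Cumulative clone-size law under neutral competition
#'
#' Under neutral competition (stochastic, independent basal fate choices),
#' surviving basal clones with mean size \eqn{\bar n} follow a geometric
#' size law: the fraction of clones with size at most `n` is
#' \eqn{C(n) = 1 - (1 - 1/\bar n)^n} (`form = "general"`), valid at all
#' chase times even when rates change with clonal age.  When additionally
#' the rates are balanced and \eqn{\bar n} grows large (neutral drift), the
#' law approaches its scaling limit \eqn{C(n) = 1 - e^{-n/\bar n}}
#' (`form = "asymptotic"`).
#'
#' @param nbar mean surviving clone size (must be \eqn{\ge 1}).
#' @param n integer clone size(s).
#' @param form `"general"` (geometric) or `"asymptotic"` (exponential limit).
#' @return `C(n)` in \[0, 1\], vectorized over `n`.
#' @export
clone_size_cdf <- function(nbar, n, form = c("general", "asymptotic")) {
  form <- match.arg(form)
  if (!is.numeric(nbar) || length(nbar) != 1 || is.na(nbar) || nbar < 1)
    stop("nbar must be a single number >= 1")
  if (any(n < 0)) stop("n must be nonnegative")
  if (form == "general") 1 - (1 - 1 / nbar)^n else 1 - exp(-n / nbar)
}

# closed-form integral of the age profile m(a) = exp(int_0^a (lambda-mu))
# over [lo, hi]; also exposes log m at phase starts
schedule_age_profile <- function(schedule) {
  g <- schedule$lambda - schedule$mu
  K <- length(g)
  widths <- diff(c(schedule$start, Inf))
  log_m0 <- c(0, cumsum(g[-K] * widths[-K]))  # log m at each phase start
  list(g = g, start = schedule$start, log_m0 = log_m0, K = K)
}

age_profile_mass <- function(prof, lo, hi) {
  if (hi <= lo) return(0)
  total <- 0
  for (j in seq_len(prof$K)) {
    a <- max(lo, prof$start[j])
    b <- if (j < prof$K) min(hi, prof$start[j + 1]) else hi
    if (b <= a) next
    g <- prof$g[j]
    m_a <- exp(prof$log_m0[j] + g * (a - prof$start[j]))
    total <- total + if (is.finite(b)) {
      m_a * if (abs(g) < 1e-14) (b - a) else (exp(g * (b - a)) - 1) / g
    } else {
      if (g >= 0) return(Inf)
      m_a / (-g)
    }
  }
  total
}

#' Homeostatic steady state of a non-self-renewing population
#'
#' A transit-amplifying population whose clones eventually go extinct can
#' only be homeostatic if it is replenished by nascent founder cells at a
#' constant rate.  At steady state the density of cells over clonal age is
#' proportional to the expected per-clone basal size
#' \eqn{m(a) = e^{\int_0^a (\lambda - \mu)}}.  This function computes, in
#' closed form per phase: the nascent-cell influx `nu` (nascent clones per
#' basal cell per day, \eqn{1/\int_0^\infty m}), the pre-transition
#' amplification fold `amp_fold` (\eqn{m(T)}), and the fraction of cells in
#' the extinction phase `frac_post`
#' (\eqn{\int_T^\infty m / \int_0^\infty m}).  The last phase of the
#' schedule must be strictly subcritical (\eqn{\mu > \lambda}), otherwise
#' the steady-state integrals diverge and an error is thrown.
#'
#' @param schedule a [rate_schedule()] with subcritical final phase.
#' @return An object of class `"steady_state"` with fields `nu`,
#'   `amp_fold`, `frac_post`, `total_mass`, `pre_mass`, `post_mass` and the
#'   originating `schedule`.
#' @examples
#' sc <- rate_schedule(start = c(0, 45),
#'                     lambda = c(log(4) / 45, 0), mu = c(0, log(2) / 57))
#' steady_state(sc)  # amp_fold = 4, frac_post ~ 0.77, nu ~ 0.0023/day
#' @export
steady_state <- function(schedule) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (!subcritical_tail(schedule))
    stop("steady state diverges: final phase must have mu > lambda")
  Tt <- schedule$transition_age
  prof <- schedule_age_profile(schedule)
  pre <- age_profile_mass(prof, 0, Tt)
  post <- age_profile_mass(prof, Tt, Inf)
  total <- pre + post
  if (!is.finite(total) || total <= 0)
    stop("steady state diverges: age-profile mass is not finite")
  j <- phase_at(schedule, Tt)
  amp <- exp(prof$log_m0[j] + prof$g[j] * (Tt - schedule$start[j]))
  structure(list(nu = 1 / total, amp_fold = amp, frac_post = post / total,
                 total_mass = total, pre_mass = pre, post_mass = post,
                 schedule = schedule),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Homeostatic steady state (transition age ",
      x$schedule$transition_age, " d)\n", sep = "")
  cat(sprintf("  nascent influx nu    : %.4g /basal cell/day\n", x$nu))
  cat(sprintf("  amplification fold   : %.4g\n", x$amp_fold))
  cat(sprintf("  cells past transition: %.1f%%\n", 100 * x$frac_post))
  invisible(x)
}

#' Clonal-age density seen by a labeling model
#'
#' A CreER pulse marks cells in proportion to their abundance in the
#' homeostatic population, possibly restricted by a labeling bias: `equal`
#' marks all clonal ages (density proportional to the steady-state age
#' profile `m(a)`), `pre_transition` marks only cells in the amplification
#' phase (`a < T`) and `post_transition` only cells in the extinction phase
#' (`a >= T`).
#'
#' @param steady a [steady_state()].
#' @param a clonal age(s) (days).
#' @param labeling `"equal"`, `"pre_transition"` or `"post_transition"`.
#' @return Normalized density values at `a`.
#' @export
age_density <- function(steady, a,
                        labeling = c("equal", "pre_transition", "post_transition")) {
  labeling <- match.arg(labeling)
  stopifnot(inherits(steady, "steady_state"))
  sc <- steady$schedule
  Tt <- sc$transition_age
  prof <- schedule_age_profile(sc)
  j <- phase_at(sc, a)
  m <- exp(prof$log_m0[j] + prof$g[j] * (a - prof$start[j]))
  norm <- switch(labeling, equal = steady$total_mass,
                 pre_transition = steady$pre_mass,
                 post_transition = steady$post_mass)
  keep <- switch(labeling, equal = rep(TRUE, length(a)),
                 pre_transition = a < Tt, post_transition = a >= Tt)
  ifelse(keep, m / norm, 0)
}

labeling_window <- function(labeling, transition_age) {
  switch(labeling,
         equal = c(0, Inf),
         pre_transition = c(0, transition_age),
         post_transition = c(transition_age, Inf))
}

#' Model-predicted summary observables for a labeled cohort
#'
#' Predicts the relative labeled basal-cell fraction, clone survival and
#' mean surviving basal clone size at given chase times, for clones whose
#' founder ages at labeling are drawn from the steady-state age density of
#' the chosen labeling model: \eqn{f_{BL}(t) = \int p(a_0) M(t|a_0) da_0}
#' (equal to 1 at \eqn{t=0}),
#' \eqn{S(t) = \int p(a_0) (1-\alpha(t|a_0)) da_0}, and
#' \eqn{\bar n(t) = f_{BL}(t)/S(t)}.  The founder-age integral is evaluated
#' by composite Gauss-Legendre quadrature on the bounded age region, split
#' at phase boundaries and at integrand kinks; the constant-rate tail
#' beyond the last phase boundary is added in closed form.
#'
#' @param schedule a [rate_schedule()] whose final phase is subcritical.
#' @param labeling labeling model (see [age_density()]).
#' @param chase_days chase times (days).
#' @param gl_order Gauss-Legendre order per smooth segment.
#' @return A data frame with columns `chase_day`, `f_basal`, `survival`,
#'   `mean_basal_size`.
#' @export
predict_observables <- function(schedule,
                                labeling = c("equal", "pre_transition", "post_transition"),
                                chase_days, gl_order = 20L) {
  labeling <- match.arg(labeling)
  stopifnot(inherits(schedule, "rate_schedule"))
  if (any(chase_days < 0)) stop("chase_days must be nonnegative")
  K <- n_phases(schedule)
  if (K == 1) {
    # constant rates: founder age is irrelevant
    r <- bd_propagate(schedule, a0 = 0, t = chase_days)
    return(data.frame(chase_day = chase_days, f_basal = r$M,
                      survival = 1 - r$alpha,
                      mean_basal_size = r$M / (1 - r$alpha)))
  }
  ss <- steady_state(schedule)
  Tt <- schedule$transition_age
  prof <- schedule_age_profile(schedule)
  win <- labeling_window(labeling, Tt)
  a_tail <- max(schedule$start)               # final (constant-rate) phase start
  num_lo <- win[1]
  num_hi <- min(win[2], a_tail)
  tail_lo <- max(win[1], a_tail)
  tail_mass <- if (win[2] > tail_lo) age_profile_mass(prof, tail_lo, win[2]) else 0
  W <- age_profile_mass(prof, max(0, num_lo), num_hi) + tail_mass
  gl <- gl_rule(gl_order)
  lamK <- schedule$lambda[K]; muK <- schedule$mu[K]
  out <- vapply(chase_days, function(t) {
    f <- 0; sv <- 0
    if (tail_mass > 0) {
      r <- bd_propagate_cpp(0, lamK, muK, 0, t)
      f <- f + tail_mass * r[, "M"]
      sv <- sv + tail_mass * (1 - r[, "alpha"])
    }
    if (num_hi > num_lo) {
      # break the founder-age region at phase starts and at integrand kinks
      # (ages from which the chase crosses a phase boundary exactly at t)
      brk <- sort(unique(c(num_lo, num_hi, Tt,
                           schedule$start, schedule$start - t)))
      brk <- brk[brk >= num_lo & brk <= num_hi]
      for (s in seq_len(length(brk) - 1)) {
        len <- brk[s + 1] - brk[s]
        if (len <= 0) next
        a0 <- brk[s] + len * gl$x
        j <- phase_at(schedule, a0)
        m <- exp(prof$log_m0[j] + prof$g[j] * (a0 - prof$start[j]))
        r <- bd_propagate_cpp(schedule$start, schedule$lambda, schedule$mu,
                              a0, rep(t, length(a0)))
        f <- f + len * sum(gl$w * m * r[, "M"])
        sv <- sv + len * sum(gl$w * m * (1 - r[, "alpha"]))
      }
    }
    c(f, sv) / W
  }, numeric(2))
  data.frame(chase_day = chase_days, f_basal = out[1, ],
             survival = out[2, ], mean_basal_size = out[1, ] / out[2, ])
}

#' Critical birth-death model predictions
#'
#' The critical (balanced, constant-rate) birth-death model of a
#' self-renewing population: mean surviving basal clone size grows linearly,
#' \eqn{\bar n(t) = 1 + rt}, clone survival decays inversely,
#' \eqn{S(t) = 1/(1+rt)}, and the labeled basal fraction is conserved,
#' \eqn{f_{BL}(t) = 1} — the neutral-drift signature.
#'
#' @param r balanced birth/death rate (events/cell/day, > 0).
#' @param chase_days chase times (days).
#' @return A data frame with columns `chase_day`, `f_basal`, `survival`,
#'   `mean_basal_size`.
#' @export
cbdm_predict <- function(r, chase_days) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r <= 0)
    stop("r must be a single positive rate")
  if (any(chase_days < 0)) stop("chase_days must be nonnegative")
  nbar <- 1 + r * chase_days
  data.frame(chase_day = chase_days, f_basal = rep(1, length(chase_days)),
             survival = 1 / nbar, mean_basal_size = nbar)
}
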