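#' Piecewise-constant birth-death rate schedule
#'
#' A rate schedule describes the per-basal-cell event rates of a clone as a
#' function of its clonal age (time since the clone's founding nascent cell
#' entered the lineage).  Within each phase the rates are constant:
#' `lambda` is the birth rate (symmetric division keeping both daughters in
#' the basal layer, BL+1), `mu` the death rate (loss of a basal cell to the
#' suprabasal compartment, BL-1/sBL+1), and `sigma` the neutral division
#' rate (asymmetric division or symmetric division with delamination of one
#' daughter, sBL+1, BL unchanged).  `lambda` and `mu` alone govern basal
#' clone size; `sigma` only feeds the suprabasal compartment.
#'
#' The `transition_age` marks the boundary between the amplification phase
#' (net growth, births exceed deaths) and the extinction phase of a
#' transit-amplifying progenitor; it defaults to 45 days and is a fixed
#' modeling choice, not a fitted parameter.
#'
#' @param start numeric vector of phase start ages (days); the first must
#'   be 0 and the ages strictly increasing.
#' @param lambda,mu,sigma nonnegative per-cell rates (events/cell/day), one
#'   per phase (`sigma` is recycled).
#' @param transition_age amplification-to-extinction boundary (days).
#' @return An object of class `"rate_schedule"`.
#' @examples
#' # biphasic transit-amplifying schedule: 4-fold amplification over 45 days,
#' # then extinction with a 57-day basal half-life
#' sc <- rate_schedule(start = c(0, 45),
#'                     lambda = c(0.12, 0.05),
#'                     mu     = c(0.12 - log(4) / 45, 0.05 + log(2) / 57),
#'                     sigma  = c(0.13, 0.10))
#' sc
#' @export
rate_schedule <- function(start = 0, lambda, mu, sigma = 0,
                          transition_age = 45) {
  K <- length(start)
  lambda <- rep_len(as.numeric(lambda), K)
  mu <- rep_len(as.numeric(mu), K)
  sigma <- rep_len(as.numeric(sigma), K)
  start <- as.numeric(start)
  if (start[1] != 0) stop("first phase must start at age 0")
  if (K > 1 && any(diff(start) <= 0)) stop("phase start ages must be strictly increasing")
  if (any(c(lambda, mu, sigma) < 0) || anyNA(c(lambda, mu, sigma)))
    stop("all rates must be nonnegative")
  if (!is.numeric(transition_age) || transition_age < 0)
    stop("transition_age must be a nonnegative number")
  structure(list(start = start, lambda = lambda, mu = mu, sigma = sigma,
                 transition_age = transition_age),
            class = "rate_schedule")
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat("Birth-death rate schedule (", length(x$start), " phase",
      if (length(x$start) > 1) "s", ", transition age ",
      x$transition_age, " d)\n", sep = "")
  print(data.frame(start_age = x$start, lambda = x$lambda, mu = x$mu,
                   sigma = x$sigma, net = x$lambda - x$mu))
  invisible(x)
}

n_phases <- function(schedule) length(schedule$start)

# rates in force at a given clonal age (vectorized)
phase_at <- function(schedule, age) {
  findInterval(age, schedule$start, rightmost.closed = FALSE)
}

# insert a phase boundary at `age` (no-op if already a boundary)
split_schedule <- function(schedule, age) {
  if (age <= 0 || age %in% schedule$start) return(schedule)
  j <- phase_at(schedule, age)
  ord <- order(c(schedule$start, age))
  rate_schedule(start = c(schedule$start, age)[ord],
                lambda = c(schedule$lambda, schedule$lambda[j])[ord],
                mu = c(schedule$mu, schedule$mu[j])[ord],
                sigma = c(schedule$sigma, schedule$sigma[j])[ord],
                transition_age = schedule$transition_age)
}

# TRUE if the final phase is strictly subcritical (mu > lambda)
subcritical_tail <- function(schedule) {
  K <- n_phases(schedule)
  schedule$mu[K] > schedule$lambda[K]
}

#' Read or write a rate schedule as a YAML config
#'
#' @param path file path.
#' @param schedule a [rate_schedule()].
#' @return `read_rate_schedule()` returns a `rate_schedule`;
#'   `write_rate_schedule()` returns `path` invisibly.
#' @export
read_rate_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  ph <- cfg$phases
  rate_schedule(start = vapply(ph, `[[`, 0, "start"),
                lambda = vapply(ph, `[[`, 0, "lambda"),
                mu = vapply(ph, `[[`, 0, "mu"),
                sigma = vapply(ph, function(p) p$sigma %||% 0, 0),
                transition_age = cfg$transition_age %||% 45)
}

#' @rdname read_rate_schedule
#' @export
write_rate_schedule <- function(schedule, path) {
  cfg <- list(
    phases = lapply(seq_along(schedule$start), function(j) {
      list(start = schedule$start[j], lambda = schedule$lambda[j],
           mu = schedule$mu[j], sigma = schedule$sigma[j])
    }),
    transition_age = schedule$transition_age)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
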