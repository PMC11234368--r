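# shared fixtures and small independent oracles

# canonical biphasic transit-amplifying schedule used across tests
biphasic_schedule <- function() {
  rate_schedule(start = c(0, 45),
                lambda = c(0.06, 1.5 * log(2) / 57),
                mu = c(0.06 - log(4) / 45, 2.5 * log(2) / 57),
                sigma = c(0.19, 0.25 - 1.5 * log(2) / 57),
                transition_age = 45)
}

# monophasic (constant-rate, subcritical) NSR schedule
monophasic_schedule <- function() {
  delta <- log(2) / 57
  rate_schedule(lambda = 1.5 * delta, mu = 2.5 * delta,
                sigma = 0.25 - 1.5 * delta)
}

# build a clone table directly from per-day basal/suprabasal count vectors
toy_table <- function(days, basal, suprabasal = NULL, region = "interscale") {
  stopifnot(length(days) == length(basal))
  if (is.null(suprabasal)) suprabasal <- lapply(basal, function(b) rep(0, length(b)))
  rec <- do.call(rbind, lapply(seq_along(days), function(i) {
    nb <- length(basal[[i]])
    if (nb == 0) return(NULL)
    data.frame(clone_id = sprintf("d%g_c%d", days[i], seq_len(nb)),
               cohort_id = sprintf("coh%g", days[i]),
               chase_day = days[i],
               region = rep_len(region, nb),
               basal = basal[[i]], suprabasal = suprabasal[[i]])
  }))
  clone_table(rec, schedule = days)
}

# Monte-Carlo standard errors for simulated clone batches
mc_se_mean <- function(x) sd(x) / sqrt(length(x))
mc_se_prop <- function(p, n) sqrt(p * (1 - p) / n)

# chi-square goodness of fit of integer sizes to the geometric law with
# mean nbar (tail bins pooled to keep expected counts >= 5)
geom_gof_p <- function(sizes, nbar) {
  q <- 1 - 1 / nbar
  n <- length(sizes)
  kmax <- max(sizes)
  probs <- (1 - q) * q^(seq_len(kmax) - 1)
  probs[kmax] <- probs[kmax] + q^kmax   # fold the tail into the last bin
  obs <- tabulate(sizes, nbins = kmax)
  # pool from the right until expected counts are >= 5
  exp_ct <- probs * n
  while (length(exp_ct) > 2 && exp_ct[length(exp_ct)] < 5) {
    k <- length(exp_ct)
    exp_ct[k - 1] <- exp_ct[k - 1] + exp_ct[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    exp_ct <- exp_ct[-k]; obs <- obs[-k]
  }
  stat <- sum((obs - exp_ct)^2 / exp_ct)
  # one parameter (nbar) estimated from the data
  pchisq(stat, df = length(exp_ct) - 2, lower.tail = FALSE)
}

# simulate a batch of clones directly through the Gillespie kernel
sim_batch <- function(schedule, n, a0, t, sigma = NULL, shed = 0) {
  cfg <- simulator_config(schedule, shed_rate = shed, clones_per_day = n,
                          chase_days = unique(c(3.5, t)))
  sc <- cfg$schedule
  clonebd:::sim_clones_cpp(sc$start, sc$lambda, sc$mu, sc$sigma, shed,
                           rep(a0, n), rep(t, n))
}
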