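# hand-built summary series (no per-clone data behind it)
synthetic_summary <- function(days, f_basal, mean_basal_size, survival = NA,
                              f_total = NA, se = 0.02, baseline = days[1]) {
  s <- data.frame(region = "pooled", chase_day = days, n_clones = 100L,
                  n_surviving = 100L, f_basal = f_basal, f_total = f_total,
                  mean_basal_size = mean_basal_size, survival = survival,
                  se_f_basal = se, se_f_total = se,
                  se_mean_basal_size = se, se_survival = se)
  attr(s, "baseline_day") <- baseline
  attr(s, "chase_days") <- days
  class(s) <- c("clone_summary", "data.frame")
  s
}

test_that("division interval reproduces hand-computed trapezoid values", {
  s <- synthetic_summary(days = c(0, 10, 20, 30),
                         f_basal = rep(1, 4),
                         mean_basal_size = rep(1, 4),
                         f_total = c(1, 4, 7, 10))
  di <- division_interval(s, window = c(0, 30))
  expect_equal(di$rate, 0.3, tolerance = 1e-12)
  expect_equal(di$interval, 10 / 3, tolerance = 1e-12)

  # ramping basal fraction: trapezoid integral fixes the value exactly
  s2 <- synthetic_summary(days = c(0, 20, 40, 60),
                          f_basal = c(1, 1.7, 1.7, 1.7),
                          mean_basal_size = rep(1, 4),
                          f_total = c(1, 3, 6, 9))
  fb_int <- 20 * (1 + 1.7) / 2 + 20 * 1.7 + 20 * 1.7
  di2 <- division_interval(s2, window = c(0, 60))
  expect_equal(di2$rate, 8 / fb_int, tolerance = 1e-12)

  # invariance to uniform rescaling of both fraction series
  s3 <- s
  s3$f_basal <- s$f_basal * 5; s3$f_total <- s$f_total * 5
  expect_equal(division_interval(s3, window = c(0, 30))$interval,
               di$interval, tolerance = 1e-12)

  s4 <- s; s4$f_total <- c(1, 4, 3, 10)
  expect_warning(division_interval(s4, window = c(0, 30)), "not increasing")
  expect_error(division_interval(s, window = c(0, 5)), ">= 3 chase points")
})

test_that("half-life estimation is exact on exponential series", {
  days <- c(60, 90, 180, 365)
  s <- synthetic_summary(days = c(3.5, days),
                         f_basal = c(1, 2^(-days / 57)),
                         mean_basal_size = rep(1, 5))
  expect_equal(half_life(s, t_start = 60)$half_life, 57, tolerance = 1e-9)

  s2 <- synthetic_summary(days = c(3.5, days),
                          f_basal = c(1, exp(-days / 100)),
                          mean_basal_size = rep(1, 5))
  expect_equal(half_life(s2, t_start = 60)$half_life, log(2) * 100,
               tolerance = 1e-9)

  # uniform rescaling leaves the half-life unchanged
  s3 <- s; s3$f_basal <- s$f_basal * 0.1
  expect_equal(half_life(s3, t_start = 60)$half_life, 57, tolerance = 1e-9)

  # zero observations are dropped with a warning
  s4 <- s; s4$f_basal[3] <- 0
  expect_warning(half_life(s4, t_start = 3.5), "dropping")
})

test_that("the critical model is recovered exactly from noiseless curves", {
  days <- c(30, 60, 90, 180, 365)
  r <- 0.05; t0 <- 3.5
  s <- synthetic_summary(days = c(t0, days), f_basal = rep(1, 6),
                         mean_basal_size = c(1, 1 + r * (days - t0)),
                         survival = c(1, 1 / (1 + r * (days - t0))),
                         se = NA)
  expect_warning(expect_warning(fit <- fit_cbdm(s), "unweighted"),
                 "unweighted")
  expect_equal(unname(fit$params["r"]), 0.05, tolerance = 1e-5)
  expect_equal(unname(fit$params["s0"]), 1, tolerance = 1e-4)
})

test_that("critical fits recover simulated stem-cell dynamics but reject biphasic ones", {
  set.seed(16)
  tab <- generate_experiment(sc_critical_config(clones_per_day = 215))
  s <- summarize_clones(tab, n_boot = 300)
  fit <- fit_cbdm(s)
  expect_lt(abs(fit$params[["r"]] - 0.02), 2 * fit$se[["r"]])
  expect_gt(fit$gof$p, 0.01)

  taba <- generate_experiment(ta_biphasic_config(clones_per_day = 300))
  sa <- summarize_clones(taba, n_boot = 300)
  fita <- suppressWarnings(fit_cbdm(sa))
  expect_lt(fita$gof$p, 0.05)     # systematic lack of fit
})

test_that("noiseless model curves are recovered to four significant digits", {
  sc <- biphasic_schedule()
  days <- c(3.5, 7, 14, 30, 60, 90, 180, 365)
  p <- predict_observables(sc, "equal", c(3.5, days))
  s <- synthetic_summary(days, f_basal = p$f_basal[-1] / p$f_basal[1],
                         mean_basal_size = p$mean_basal_size[-1])
  set.seed(18)
  expect_message(fit <- fit_gbdm(s, "equal"), "Gaussian")
  expect_equal(unname(fit$params),
               c(sc$lambda[1], sc$mu[1], sc$lambda[2], sc$mu[2]),
               tolerance = 1e-4)
})

test_that("biphasic fits detect a birth-rate drop at the transition", {
  set.seed(19)
  tab <- generate_experiment(ta_biphasic_config(clones_per_day = 300))
  s <- summarize_clones(tab, n_boot = 50)
  fit <- suppressWarnings(fit_gbdm(s, "equal"))
  # truth has a 3.3-fold birth-rate drop; expect at least 1.5-fold recovered
  expect_gt(fit$params[["lambda1"]], 1.5 * fit$params[["lambda2"]])
  expect_gt(fit$derived$net_pre[["est"]], 0)
  # extinction net rate is well identified at paper scale
  expect_lt(abs(fit$derived$net_post[["est"]] - log(2) / 57),
            0.3 * log(2) / 57)
  expect_lt(fit$derived$ci_net_post[["lower"]],
            fit$derived$ci_net_post[["upper"]])
})

test_that("monophasic fitted clone size relaxes monotonically to its asymptote", {
  set.seed(20)
  tab <- generate_experiment(simulator_config(monophasic_schedule(),
                                              clones_per_day = 150))
  s <- summarize_clones(tab, n_boot = 50)
  fit <- suppressWarnings(fit_gbdm(s, "post_transition"))
  curve <- fitted_observables(fit, seq(1, 400, by = 5))
  expect_true(all(diff(curve$mean_basal_size) > -1e-9))
  lam <- fit$params[["lambda2"]]; mu <- fit$params[["mu2"]]
  expect_lt(max(curve$mean_basal_size), mu / (mu - lam) + 1e-6)
})

test_that("model comparison handles ties, nesting and data fingerprints", {
  set.seed(22)
  tab <- generate_experiment(ta_biphasic_config(clones_per_day = 120))
  s <- summarize_clones(tab, n_boot = 50)
  fe <- suppressWarnings(fit_gbdm(s, "equal"))
  fo <- suppressWarnings(fit_gbdm(s, "post_transition"))
  cm <- compare_models(list(fe, fo))
  expect_equal(cm$lrt$dof, 2)
  expect_equal(cm$lrt$confidence, 1 - cm$lrt$p)

  # identical log-likelihoods give a null test
  fo2 <- fo; fo2$model_id <- "gbdm_equal"; fo2$n_free <- 5
  cm0 <- compare_models(list(fo2, fo))
  expect_equal(cm0$lrt$stat, 0)
  expect_equal(cm0$lrt$p, 1)
  expect_equal(cm0$lrt$confidence, 0)

  # fits on different data refuse to be compared
  tab2 <- generate_experiment(ta_biphasic_config(clones_per_day = 120),
                              seed = 99)
  s2 <- summarize_clones(tab2, n_boot = 50)
  fe2 <- suppressWarnings(fit_gbdm(s2, "equal"))
  expect_error(compare_models(list(fe2, fo)), "identical data")
})

test_that("the likelihood-ratio statistic ignores uniform weight rescaling", {
  sc <- biphasic_schedule()
  days <- c(3.5, 7, 14, 30, 60, 90, 180, 365)
  p <- predict_observables(sc, "equal", c(3.5, days))
  set.seed(23)
  noise <- rnorm(8, 0, 0.03)
  f <- p$f_basal[-1] / p$f_basal[1] + noise
  s1 <- synthetic_summary(days, f_basal = f,
                          mean_basal_size = p$mean_basal_size[-1], se = 0.05)
  s2 <- synthetic_summary(days, f_basal = f,
                          mean_basal_size = p$mean_basal_size[-1], se = 0.15)
  lrt_of <- function(s) {
    set.seed(31)
    fe <- suppressMessages(fit_gbdm(s, "equal"))
    fo <- suppressMessages(fit_gbdm(s, "post_transition"))
    2 * (fe$loglik - fo$loglik)
  }
  expect_equal(lrt_of(s1), lrt_of(s2), tolerance = 1e-3)
})

test_that("neutral-competition goodness of fit is calibrated and has power", {
  set.seed(24)
  # calibration on genuinely geometric data
  ps <- replicate(100, {
    sizes <- rgeom(200, 1 / 3) + 1L
    neutrality_gof(toy_table(days = 0, basal = list(sizes)), 0,
                   n_boot = 200)$p.value
  })
  expect_gte(mean(ps > 0.05), 0.9)

  # power against a 50/50 mixture of narrow and broad geometric laws
  rej <- replicate(40, {
    sizes <- c(rgeom(100, 1 / 1.2), rgeom(100, 1 / 12)) + 1L
    neutrality_gof(toy_table(days = 0, basal = list(sizes)), 0,
                   n_boot = 200)$p.value < 0.05
  })
  expect_gt(mean(rej), 0.5)

  single <- toy_table(days = 0, basal = list(3L))
  expect_warning(neutrality_gof(single, 0, n_boot = 50), "underpowered")
})
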