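test_that("single-ancestor propagation matches closed-form special cases", {
  # pure death: survivors are always the lone founder
  pd <- bd_propagate(rate_schedule(lambda = 0, mu = 0.1), 0, 10)
  expect_equal(pd$M, exp(-1), tolerance = 1e-12)
  expect_equal(pd$alpha, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(pd$nbar, 1, tolerance = 1e-12)

  # critical process: M = 1, nbar = 1 + mu t, alpha = mu t / (1 + mu t)
  cr <- bd_propagate(rate_schedule(lambda = 0.2, mu = 0.2), 0, 10)
  expect_equal(cr$M, 1, tolerance = 1e-12)
  expect_equal(cr$nbar, 3, tolerance = 1e-12)
  expect_equal(cr$alpha, 2 / 3, tolerance = 1e-12)

  # two-phase net growth: 5 days at +0.1/day then 5 days at -0.02/day
  sc <- rate_schedule(start = c(0, 45), lambda = c(0.2, 0.08),
                      mu = c(0.1, 0.1))
  expect_equal(bd_propagate(sc, 40, 10)$M, exp(0.4), tolerance = 1e-12)

  expect_equal(bd_propagate(sc, 0, 0)$nbar, 1)
  expect_error(bd_propagate(sc, -1, 5), "nonnegative")
})

test_that("M = (1 - alpha) * nbar for arbitrary schedules and times", {
  set.seed(1)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    sc <- rate_schedule(start = c(0, sort(runif(k - 1, 5, 100)))[1:k],
                        lambda = runif(k, 0, 0.2), mu = runif(k, 0, 0.2))
    r <- bd_propagate(sc, runif(1, 0, 60), runif(1, 0, 120))
    # (1 - alpha) loses ~alpha/eps digits when extinction is near-certain,
    # so the reconstruction is accurate to ~1e-9 in the deepest subcritical
    # draws and to machine precision elsewhere
    expect_equal(r$M, (1 - r$alpha) * r$nbar, tolerance = 1e-8)
    expect_equal(r$beta, 1 - 1 / r$nbar, tolerance = 1e-10)
  }
})

test_that("the geometric clone-size law and its neutral-drift limit agree as sizes grow", {
  expect_equal(clone_size_cdf(2, 1:2), c(0.5, 0.75))
  expect_equal(clone_size_cdf(1, 1), 1)      # all surviving clones are singletons
  expect_error(clone_size_cdf(0.5, 1), "nbar")

  for (nb in c(50, 500)) {
    n <- 0:(20 * nb)
    gap <- max(abs(clone_size_cdf(nb, n) - clone_size_cdf(nb, n, "asymptotic")))
    expect_lt(gap, if (nb >= 500) 1e-3 else 0.01)
  }
})

test_that("homeostatic steady state has the closed-form structure", {
  sc <- rate_schedule(start = c(0, 45), lambda = c(log(4) / 45, 0),
                      mu = c(0, log(2) / 57), transition_age = 45)
  ss <- steady_state(sc)
  expect_equal(ss$amp_fold, 4, tolerance = 1e-12)

  # independent oracle: numerical quadrature of the age profile
  m <- function(a) ifelse(a < 45, exp(log(4) / 45 * a),
                          4 * exp(-log(2) / 57 * (a - 45)))
  pre <- integrate(m, 0, 45, rel.tol = 1e-10)$value
  post <- integrate(m, 45, Inf, rel.tol = 1e-10)$value
  expect_equal(ss$frac_post, post / (pre + post), tolerance = 1e-8)
  expect_equal(ss$nu, 1 / (pre + post), tolerance = 1e-8)
  expect_lt(abs(ss$frac_post - 0.77), 0.01)
  expect_lt(abs(ss$nu - 0.0023), 0.0001)

  # balanced rates: no steady state exists
  expect_error(steady_state(rate_schedule(lambda = 0.1, mu = 0.1)),
               "diverges")
})

test_that("labeling-model age densities integrate to one over their windows", {
  ss <- steady_state(biphasic_schedule())
  for (lab in c("equal", "pre_transition", "post_transition")) {
    dens <- function(a) age_density(ss, a, lab)
    total <- integrate(dens, 0, Inf, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_equal(age_density(ss, 50, "pre_transition"), 0)
  expect_equal(age_density(ss, 10, "post_transition"), 0)
})

test_that("predicted observables obey initial conditions and model identities", {
  sc <- biphasic_schedule()
  for (lab in c("equal", "pre_transition", "post_transition")) {
    p0 <- predict_observables(sc, lab, 0)
    expect_equal(p0$f_basal, 1, tolerance = 1e-10)
    expect_equal(p0$survival, 1, tolerance = 1e-10)
    expect_equal(p0$mean_basal_size, 1, tolerance = 1e-10)
  }

  # post-transition labeling is exactly the monophasic model
  tt <- c(3.5, 7, 30, 90, 365)
  post <- predict_observables(sc, "post_transition", tt)
  mono <- predict_observables(rate_schedule(lambda = sc$lambda[2],
                                            mu = sc$mu[2]), "equal", tt)
  expect_equal(post$f_basal, mono$f_basal, tolerance = 1e-9)
  expect_equal(post$survival, mono$survival, tolerance = 1e-9)

  # survival is nonincreasing in chase time for every labeling model
  tt2 <- seq(0, 400, by = 10)
  for (lab in c("equal", "pre_transition", "post_transition")) {
    p <- predict_observables(sc, lab, tt2)
    expect_true(all(diff(p$survival) <= 1e-10))
  }
})

test_that("subcritical clones approach the quasi-stationary mean size", {
  lam <- 0.03; mu <- 0.05
  sc <- rate_schedule(lambda = lam, mu = mu)
  r <- bd_propagate(sc, 0, 2000)
  expect_equal(r$nbar, mu / (mu - lam), tolerance = 1e-6)
})

test_that("the critical birth-death model has its closed-form signatures", {
  p <- cbdm_predict(0.05, c(0, 20))
  expect_equal(p$mean_basal_size, c(1, 2))
  expect_equal(p$survival, c(1, 0.5))
  expect_equal(p$f_basal, c(1, 1))
  expect_equal(p$survival * p$mean_basal_size, c(1, 1))
  expect_error(cbdm_predict(0, 1:3), "positive")
})

test_that("fast two-phase kernel agrees with the general quadrature path", {
  sc <- biphasic_schedule()
  gl <- clonebd:::gl_rule()
  tt <- c(0, 3.5, 14, 44, 45, 46, 120, 365)
  for (lab in c("equal", "pre_transition", "post_transition")) {
    pR <- predict_observables(sc, lab, tt)
    code <- clonebd:::labeling_code(lab)
    pC <- clonebd:::gbdm_predict_cpp(sc$lambda[1], sc$mu[1], sc$lambda[2],
                                     sc$mu[2], 45, tt, code, gl$x, gl$w)
    expect_equal(pR$f_basal, pC[, 1], tolerance = 1e-10)
    expect_equal(pR$survival, pC[, 2], tolerance = 1e-10)
  }
})
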