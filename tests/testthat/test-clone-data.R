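make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

well_formed <- data.frame(
  clone_id = c("c1", "c2", "c3"), cohort_id = c("m1", "m1", "m2"),
  chase_day = c(3.5, 3.5, 30), region = c("scale", "interscale", "scale"),
  basal = c(1L, 2L, 0L), suprabasal = c(0L, 1L, 3L))

test_that("clone tables load, validate and round-trip through CSV", {
  path <- make_csv(well_formed)
  tab <- load_clone_table(path)
  expect_s3_class(tab, "clone_table")
  expect_equal(nrow(tab$records), 3)
  expect_identical(tab$schedule, c(3.5, 30))

  out <- tempfile(fileext = ".csv")
  write_clone_table(tab, out)
  expect_identical(load_clone_table(out)$records, tab$records)
  expect_identical(readLines(out), readLines(path))

  # column remapping for nonstandard headers
  alt <- well_formed
  names(alt)[names(alt) == "basal"] <- "BL_cells"
  p2 <- make_csv(alt)
  tab2 <- load_clone_table(p2, columns = c(basal = "BL_cells"))
  expect_identical(tab2$records, tab$records)
})

test_that("invalid clone records are rejected with informative errors", {
  no_col <- make_csv(well_formed[, -5])
  expect_error(load_clone_table(no_col), "basal")

  zero <- well_formed; zero$basal[1] <- 0L; zero$suprabasal[1] <- 0L
  expect_error(load_clone_table(make_csv(zero)), "zero cells.*row")

  neg <- well_formed; neg$basal[2] <- -1L
  expect_error(load_clone_table(make_csv(neg)), "nonnegative integers.*2")

  frac <- well_formed; frac$suprabasal[3] <- 1.5
  expect_error(load_clone_table(make_csv(frac)), "suprabasal")

  badreg <- well_formed; badreg$region[1] <- "ridge"
  expect_error(load_clone_table(make_csv(badreg)), "region")

  # cross-sectional design: one cohort cannot sit at two chase days
  twoday <- well_formed; twoday$cohort_id <- "m1"
  expect_error(clone_table(twoday), "more than one chase day")
})

test_that("summary observables match hand-computed values", {
  tab <- toy_table(days = c(0, 30),
                   basal = list(rep(1L, 10), c(2L, 2L, 1L, 3L, 1L, 2L, 1L, 2L)))
  s <- summarize_clones(tab, baseline_day = 0, n_boot = 20, seed = 1)
  p <- s[s$region == "pooled", ]
  expect_equal(p$survival, c(1, 0.8))
  expect_equal(p$f_basal, c(1, 1.4))
  expect_equal(p$mean_basal_size, c(1, 1.75))

  # doubling every count at day 30 doubles f_basal, leaves survival alone
  tab2 <- toy_table(days = c(0, 30),
                    basal = list(rep(1L, 10), 2L * c(2L, 2L, 1L, 3L, 1L, 2L, 1L, 2L)))
  p2 <- summarize_clones(tab2, baseline_day = 0, n_boot = 20,
                         seed = 1)
  p2 <- p2[p2$region == "pooled", ]
  expect_equal(p2$f_basal, c(1, 2.8))
  expect_equal(p2$survival, c(1, 0.8))
})

test_that("baseline anchoring and area normalization behave as invariants", {
  set.seed(42)
  tab <- generate_experiment(ta_biphasic_config(clones_per_day = 60))
  s <- summarize_clones(tab, n_boot = 30, seed = 3)
  p <- s[s$region == "pooled", ]
  i0 <- which(p$chase_day == attr(s, "baseline_day"))
  expect_identical(p$f_basal[i0], 1)
  expect_identical(p$survival[i0], 1)

  # uniform area_norm rescaling leaves every observable unchanged
  tab2 <- tab
  tab2$area_norm <- tab$area_norm * 7.3
  s2 <- summarize_clones(tab2, n_boot = 30, seed = 3)
  expect_equal(s2$f_basal, s$f_basal, tolerance = 1e-12)
  expect_equal(s2$f_total, s$f_total, tolerance = 1e-12)
  expect_equal(s2$survival, s$survival, tolerance = 1e-12)

  # a chase day with no clones is flagged missing, not zero
  expect_true(anyNA(p$f_basal) || all(p$n_clones > 0))
})

test_that("bootstrap standard errors shrink as 1/sqrt(n)", {
  set.seed(11)
  se_at <- vapply(c(50, 200, 800), function(n) {
    tab <- generate_experiment(ta_biphasic_config(clones_per_day = n))
    s <- summarize_clones(tab, n_boot = 120)
    p <- s[s$region == "pooled", ]
    p$se_f_basal[p$chase_day == 30]
  }, 0)
  # successive 4-fold n increases should roughly halve the SE
  expect_lt(se_at[2] / se_at[1], 0.75)
  expect_lt(se_at[3] / se_at[2], 0.75)
})

test_that("empirical clone-size CDFs are correct and self-consistent", {
  tab <- toy_table(days = 0, basal = list(c(1L, 1L, 2L, 4L)))
  ec <- empirical_cdf(tab, 0, "basal")
  expect_equal(ec$n, c(1, 2, 4))
  expect_equal(ec$C, c(0.5, 0.75, 1))
  expect_equal(ec$nbar, 2)

  one <- toy_table(days = 0, basal = list(3L))
  ec1 <- empirical_cdf(one, 0)
  expect_equal(ec1$C, 1)
  expect_equal(ec1$nbar, 3)

  # nbar equals sum n * (C(n) - C(n-1)) over the support
  set.seed(5)
  tab2 <- toy_table(days = 0, basal = list(rgeom(200, 1 / 3) + 1L))
  ec2 <- empirical_cdf(tab2, 0)
  expect_equal(sum(ec2$n * diff(c(0, ec2$C))), ec2$nbar, tolerance = 1e-12)

  sup <- toy_table(days = 0, basal = list(0L), suprabasal = list(2L))
  expect_error(empirical_cdf(sup, 0, "basal"), "no surviving")
})

test_that("the even-size bias test detects duplication bias and is calibrated", {
  # 50 clones, all even sizes: gross violation of the geometric law
  tab <- toy_table(days = 0, basal = list(rep(c(2L, 4L), 25)))
  ev <- even_bias_test(tab, 0)
  expect_lt(ev$p.value, 1e-6)

  # sizes actually drawn from a geometric law: p uniform-ish
  set.seed(9)
  ps <- replicate(100, {
    sizes <- rgeom(200, 1 / 2) + 1L
    even_bias_test(toy_table(days = 0, basal = list(sizes)), 0)$p.value
  })
  expect_gte(mean(ps > 0.05), 0.90)

  # no clones of size >= 2: underpowered warning, NA p
  mono <- toy_table(days = 0, basal = list(rep(1L, 30)))
  expect_warning(ev0 <- even_bias_test(mono, 0), "underpowered")
  expect_true(is.na(ev0$p.value))
})

test_that("region comparison is exchangeable under identical dynamics", {
  # exact region copies: permutation statistic can never exceed observed 0
  days <- c(0, 10, 20, 30)
  rec <- do.call(rbind, lapply(days, function(d) {
    b <- rgeom(30, 0.5) + 1L
    data.frame(clone_id = paste0("d", d, "_", seq_len(60)),
               cohort_id = paste0("coh", d), chase_day = d,
               region = rep(c("scale", "interscale"), each = 30),
               basal = rep(b, 2), suprabasal = 0L)
  }))
  tab <- clone_table(rec)
  rc <- region_compare(tab, n_perm = 500, seed = 4)
  expect_gt(rc$p_mean_basal_size, 0.99)

  # same rates in both regions (the tail-skin finding): no signal
  set.seed(14)
  tab2 <- generate_experiment(ta_biphasic_config(clones_per_day = 100))
  rc2 <- region_compare(tab2, n_perm = 1000, seed = 4)
  expect_gt(rc2$p_mean_basal_size, 0.05)
  expect_gt(rc2$p_survival, 0.05)

  # 2-fold different mean sizes at every day: strong signal
  set.seed(15)
  rec3 <- do.call(rbind, lapply(days, function(d) {
    data.frame(clone_id = paste0("d", d, "_", seq_len(200)),
               cohort_id = paste0("coh", d), chase_day = d,
               region = rep(c("scale", "interscale"), each = 100),
               basal = c(rgeom(100, 1 / 2) + 1L, rgeom(100, 1 / 4) + 1L),
               suprabasal = 0L)
  }))
  rc3 <- region_compare(clone_table(rec3), n_perm = 1000, seed = 4)
  expect_lt(rc3$p_mean_basal_size, 0.01)

  single <- toy_table(days = days, basal = replicate(4, list(rep(1L, 5))))
  expect_error(region_compare(single), "both regions")
})
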