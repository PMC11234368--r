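# run expr under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

day_area <- function(table, day) {
  coh <- table$cohorts$cohort_id[table$cohorts$chase_day == day]
  sum(table$area_norm[coh])
}

#' Empirical summary observables of a clone table
#'
#' Computes, per chase day and per region (plus pooled), the observables of
#' a cross-sectional lineage-tracing experiment, each normalized to the
#' baseline chase day: the relative labeled basal cell fraction `f_basal`
#' (summed basal cells per sampled area, divided by its baseline value),
#' the relative labeled total cell fraction `f_total` (basal + suprabasal
#' cells per area, divided by the *basal* baseline so that `f_total` and
#' `f_basal` share one scale and their difference counts suprabasal cells),
#' the surviving-clone fraction `survival` (clones with at least one basal
#' cell per area, relative to baseline), and the mean basal clone size
#' among surviving clones `mean_basal_size`.  By construction `f_basal`
#' and `survival` equal 1 at the baseline day.  Standard errors
#' are nonparametric bootstrap over clones, resampled independently within
#' each chase day.
#'
#' @param table a [clone_table()].
#' @param baseline_day anchor chase day (default: earliest day with data,
#'   conventionally 3.5 days).
#' @param n_boot bootstrap resamples for standard errors.
#' @param seed optional seed for the bootstrap (caller RNG is restored).
#' @return A data frame of class `"clone_summary"` with one row per region
#'   (`"pooled"`, `"scale"`, `"interscale"`) and chase day, columns
#'   `n_clones`, `n_surviving`, the four observables and their `se_*`
#'   bootstrap standard errors.  Chase days with no recorded clones get
#'   `NA` observables (missing, not zero).  Bootstrap replicate series are
#'   kept in `attr(, "boot")` for downstream estimators.
#' @export
summarize_clones <- function(table, baseline_day = NULL, n_boot = 1000,
                             seed = NULL) {
  stopifnot(inherits(table, "clone_table"))
  rec <- table$records
  days <- table$schedule
  if (is.null(baseline_day)) {
    present <- days[vapply(days, function(d) any(rec$chase_day == d), TRUE)]
    if (!length(present)) stop("clone table has no records")
    baseline_day <- min(present)
  }
  if (!baseline_day %in% days || !any(rec$chase_day == baseline_day))
    stop("baseline_day must be a schedule day with at least one clone")
  groups <- c("pooled", intersect(c("scale", "interscale"), unique(rec$region)))
  with_local_seed(seed, {
    res <- list(); boots <- list(); sizes_g <- list()
    for (g in groups) {
      sub <- if (g == "pooled") rec else rec[rec$region == g, , drop = FALSE]
      if (!any(sub$chase_day == baseline_day)) next
      per_day <- lapply(days, function(d) sub[sub$chase_day == d, , drop = FALSE])
      area <- vapply(days, function(d) day_area(table, d), 0)
      stat <- function(idx_list) {
        # idx_list: per-day row indices into per_day (bootstrap or identity)
        b <- s <- ns <- numeric(length(days))
        for (i in seq_along(days)) {
          x <- per_day[[i]][idx_list[[i]], , drop = FALSE]
          b[i] <- sum(x$basal); s[i] <- sum(x$basal + x$suprabasal)
          ns[i] <- sum(x$basal >= 1)
        }
        i0 <- which(days == baseline_day)
        if (b[i0] <= 0 || ns[i0] <= 0)   # degenerate baseline resample
          return(matrix(NA_real_, length(days), 4,
                        dimnames = list(NULL, c("f_basal", "f_total",
                                                "mean_basal_size", "survival"))))
        cbind(f_basal = (b / area) / (b[i0] / area[i0]),
              f_total = (s / area) / (b[i0] / area[i0]),
              mean_basal_size = ifelse(ns > 0, b / ns, NA),
              survival = (ns / area) / (ns[i0] / area[i0]))
      }
      id <- lapply(per_day, function(x) seq_len(nrow(x)))
      obs <- stat(id)
      nc <- vapply(per_day, nrow, 0L)
      obs[nc == 0, ] <- NA
      bk <- array(NA_real_, dim = c(n_boot, length(days), 4),
                  dimnames = list(NULL, NULL, colnames(obs)))
      for (r in seq_len(n_boot)) {
        # Poisson bootstrap: the number of labeled clones recorded per
        # cohort is itself a Poisson draw under sparse labeling, so the
        # resample size is Poisson around the observed count
        idx <- lapply(per_day, function(x) {
          k <- nrow(x)
          if (k == 0) return(integer(0))
          sample.int(k, rpois(1, k), replace = TRUE)
        })
        m <- stat(idx)
        m[nc == 0, ] <- NA
        bk[r, , ] <- m
      }
      se <- apply(bk, c(2, 3), sd, na.rm = TRUE)
      se[nc == 0, ] <- NA
      sizes_g[[g]] <- lapply(per_day, function(x) x$basal[x$basal >= 1])
      res[[g]] <- data.frame(region = g, chase_day = days, n_clones = nc,
                             n_surviving = vapply(per_day, function(x)
                               sum(x$basal >= 1), 0L),
                             obs,
                             se_f_basal = se[, "f_basal"],
                             se_f_total = se[, "f_total"],
                             se_mean_basal_size = se[, "mean_basal_size"],
                             se_survival = se[, "survival"])
      boots[[g]] <- bk
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "baseline_day") <- baseline_day
    attr(out, "chase_days") <- days
    attr(out, "area") <- vapply(days, function(d) day_area(table, d), 0)
    attr(out, "sizes") <- sizes_g
    attr(out, "boot") <- boots
    class(out) <- c("clone_summary", "data.frame")
    out
  })
}

#' Empirical cumulative clone-size distribution
#'
#' The fraction of surviving clones with size at most `n`, in the chosen
#' layer (`basal`: basal cells only, among clones with at least one basal
#' cell; `total`: basal + suprabasal cells), together with the mean size
#' `nbar` — the empirical counterpart of [clone_size_cdf()].
#'
#' @param table a [clone_table()].
#' @param chase_day chase day to evaluate.
#' @param layer `"basal"` or `"total"`.
#' @return A list of class `"clone_ecdf"` with fields `n` (sizes in
#'   support), `C` (cumulative fractions), `nbar`, `n_clones`.
#' @export
empirical_cdf <- function(table, chase_day, layer = c("basal", "total")) {
  layer <- match.arg(layer)
  stopifnot(inherits(table, "clone_table"))
  rec <- table$records[table$records$chase_day == chase_day, , drop = FALSE]
  sizes <- switch(layer, basal = rec$basal[rec$basal >= 1],
                  total = rec$basal + rec$suprabasal)
  if (!length(sizes))
    stop("no surviving clones at chase day ", chase_day)
  n <- sort(unique(sizes))
  C <- cumsum(tabulate(factor(sizes, levels = n))) / length(sizes)
  structure(list(n = n, C = C, nbar = mean(sizes), n_clones = length(sizes),
                 layer = layer, chase_day = chase_day),
            class = "clone_ecdf")
}

#' @export
print.clone_ecdf <- function(x, ...) {
  cat("Empirical clone-size CDF (", x$layer, " layer, day ", x$chase_day,
      "): ", x$n_clones, " clones, nbar = ", signif(x$nbar, 4), "\n", sep = "")
  print(data.frame(n = x$n, C = x$C))
  invisible(x)
}

#' Test for an excess of even-sized basal clones
#'
#' Clone fragmentation or strictly duplicative growth would bias basal
#' clone sizes towards even numbers.  Under the geometric size law implied
#' by neutral competition with observed mean size \eqn{\bar n}, the
#' probability that a clone of size at least 2 is even-sized is
#' \eqn{1/(1+q)} with \eqn{q = 1 - 1/\bar n} — not 1/2.  This test compares
#' the observed even fraction among clones of size >= 2 to that null by an
#' exact two-sided binomial test.
#'
#' @param table a [clone_table()].
#' @param chase_day chase day to test.
#' @return A list of class `"even_bias_test"`: `n_ge2`, `n_even`,
#'   `expected` (null even probability), `p.value`, `nbar`.  Fewer than 20
#'   clones of size >= 2 triggers an underpowered warning (`p.value` is
#'   `NA` when no clone qualifies).
#' @export
even_bias_test <- function(table, chase_day) {
  stopifnot(inherits(table, "clone_table"))
  rec <- table$records[table$records$chase_day == chase_day, , drop = FALSE]
  sizes <- rec$basal[rec$basal >= 1]
  if (!length(sizes)) stop("no surviving clones at chase day ", chase_day)
  nbar <- mean(sizes)
  ge2 <- sizes[sizes >= 2]
  p0 <- 1 / (1 + (1 - 1 / nbar))
  if (length(ge2) < 20)
    warning("fewer than 20 clones of size >= 2: even-bias test is underpowered")
  p <- if (length(ge2) == 0) NA_real_ else
    binom.test(sum(ge2 %% 2 == 0), length(ge2), p = p0)$p.value
  structure(list(n_ge2 = length(ge2), n_even = sum(ge2 %% 2 == 0),
                 observed = if (length(ge2)) mean(ge2 %% 2 == 0) else NA_real_,
                 expected = p0, nbar = nbar, p.value = p,
                 chase_day = chase_day),
            class = "even_bias_test")
}

#' @export
print.even_bias_test <- function(x, ...) {
  cat(sprintf(
    "Even-size bias test (day %g): %d/%d even among clones >= 2 (null %.3f), p = %.3g\n",
    x$chase_day, x$n_even, x$n_ge2, x$expected, x$p.value))
  invisible(x)
}

#' Permutation comparison of clone dynamics between regions
#'
#' Tests whether scale and interscale clones follow the same dynamics by
#' permuting region labels among clones within each chase day.  The test
#' statistics are the sums over chase days of squared between-region
#' differences in mean basal clone size and in the basal-surviving clone
#' fraction.
#'
#' @param table a [clone_table()] with both regions populated at >= 3
#'   common chase days.
#' @param n_perm number of permutations.
#' @param seed optional seed (caller RNG restored).
#' @return A list of class `"region_compare"` with permutation p-values
#'   `p_mean_basal_size` and `p_survival` and the observed statistics.
#' @export
region_compare <- function(table, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(table, "clone_table"))
  rec <- table$records
  both <- vapply(table$schedule, function(d) {
    r <- rec$region[rec$chase_day == d]
    all(c("scale", "interscale") %in% r)
  }, TRUE)
  days <- table$schedule[both]
  if (length(unique(rec$region)) < 2)
    stop("both regions must be present in the table")
  if (length(days) < 3)
    stop("both regions must be populated at >= 3 common chase days")
  per_day <- lapply(days, function(d) rec[rec$chase_day == d, , drop = FALSE])
  stat <- function(region_list) {
    dm <- ds <- 0
    for (i in seq_along(per_day)) {
      x <- per_day[[i]]; rg <- region_list[[i]]
      for_reg <- function(lab) {
        b <- x$basal[rg == lab]
        c(mbs = if (any(b >= 1)) mean(b[b >= 1]) else NA,
          sf = mean(b >= 1))
      }
      a <- for_reg("scale"); b <- for_reg("interscale")
      if (!anyNA(c(a["mbs"], b["mbs"]))) dm <- dm + (a["mbs"] - b["mbs"])^2
      ds <- ds + (a["sf"] - b["sf"])^2
    }
    c(dm, ds)
  }
  with_local_seed(seed, {
    obs <- stat(lapply(per_day, `[[`, "region"))
    cnt <- c(0, 0)
    for (r in seq_len(n_perm)) {
      perm <- lapply(per_day, function(x) sample(x$region))
      cnt <- cnt + (stat(perm) >= obs - 1e-12)
    }
    p <- (cnt + 1) / (n_perm + 1)
    structure(list(p_mean_basal_size = p[1], p_survival = p[2],
                   stat_mean_basal_size = obs[1], stat_survival = obs[2],
                   n_perm = n_perm, chase_days = days),
              class = "region_compare")
  })
}

#' @export
print.region_compare <- function(x, ...) {
  cat(sprintf(
    "Scale vs interscale permutation test (%d permutations, %d chase days)\n",
    x$n_perm, length(x$chase_days)))
  cat(sprintf("  mean basal clone size: p = %.4g\n", x$p_mean_basal_size))
  cat(sprintf("  surviving fraction   : p = %.4g\n", x$p_survival))
  invisible(x)
}
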