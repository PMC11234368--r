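#' Run the simulator and write its outputs
#'
#' Generates a cross-sectional experiment from a [simulator_config()] and
#' writes the clone table as CSV together with a JSON sidecar recording the
#' configuration, the seed, and the true parameters (for recovery studies).
#'
#' @param config a [simulator_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; required so the run is reproducible.
#' @param prefix output file prefix.
#' @return Invisibly, the paths written (`csv`, `truth`).
#' @export
run_simulate <- function(config, out_dir, seed, prefix = "clones") {
  stopifnot(inherits(config, "simulator_config"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- generate_experiment(config, seed = seed)
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  write_clone_table(tab, csv)
  sc <- config$schedule
  truth <- list(
    seed = seed,
    schedule = list(start = sc$start, lambda = sc$lambda, mu = sc$mu,
                    sigma = sc$sigma, transition_age = sc$transition_age),
    shed_rate = config$shed_rate, labeling = config$labeling,
    clones_per_day = config$clones_per_day, chase_days = config$chase_days,
    region_ratio = as.list(config$region_ratio),
    n_labeled = as.list(attr(tab, "truth")$n_labeled))
  tj <- file.path(out_dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv, truth = tj))
}

#' Summarize, fit and compare models on a clone table
#'
#' The full estimation pipeline on one clone-count CSV: empirical summary,
#' division-interval and half-life estimates, the requested model fits
#' (CBDM and/or the three GBDM labeling variants), likelihood-ratio model
#' comparison, and per-chase-day neutral-competition goodness of fit.
#' Writes a machine-readable JSON report and a human-readable text report.
#'
#' @param csv path to a clone-table CSV (see [load_clone_table()]).
#' @param out_dir output directory.
#' @param models character vector among `"cbdm"`, `"gbdm-equal"`,
#'   `"gbdm-pre"`, `"gbdm-post"`, or `"all"`.
#' @param baseline_day anchor chase day (default: earliest observed).
#' @param transition_age fixed transition age for GBDM fits (days).
#' @param seed integer seed for bootstrap/multi-start randomness.
#' @param n_boot bootstrap resamples for summary standard errors.
#' @param prefix output file prefix.
#' @return Invisibly, the report as an R list.
#' @export
run_fit <- function(csv, out_dir, models = "all", baseline_day = NULL,
                    transition_age = 45, seed = 1, n_boot = 1000,
                    prefix = "report") {
  tab <- load_clone_table(csv)
  if (length(unique(tab$records$chase_day)) < 2)
    stop("clone table has a single chase day; nothing to fit")
  if ("all" %in% models)
    models <- c("cbdm", "gbdm-equal", "gbdm-pre", "gbdm-post")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  summary <- summarize_clones(tab, baseline_day = baseline_day,
                              n_boot = n_boot)
  report <- list(seed = seed, baseline_day = attr(summary, "baseline_day"),
                 n_clones = nrow(tab$records))
  di <- tryCatch(division_interval(summary), warning = function(w) {
    suppressWarnings(division_interval(summary))
  }, error = function(e) NULL)
  hl <- tryCatch(half_life(summary), error = function(e) NULL)
  report$division_interval <- if (!is.null(di))
    list(days = di$interval, se = di$se, window = di$window)
  report$half_life <- if (!is.null(hl))
    list(days = hl$half_life, se = hl$se, observable = hl$observable,
         t_start = hl$t_start)
  fits <- list()
  if ("cbdm" %in% models) {
    f <- tryCatch(fit_cbdm(summary), error = function(e) NULL,
                  warning = function(w) suppressWarnings(fit_cbdm(summary)))
    if (!is.null(f)) {
      fits$cbdm <- f
      report$cbdm <- list(params = as.list(f$params), se = as.list(f$se),
                          loglik = f$loglik, lack_of_fit_p = f$gof$p,
                          lack_of_fit = f$gof$p < 0.05)
    }
  }
  lab_of <- c("gbdm-equal" = "equal", "gbdm-pre" = "pre_transition",
              "gbdm-post" = "post_transition")
  for (m in intersect(names(lab_of), models)) {
    f <- tryCatch(
      suppressWarnings(fit_gbdm(summary, lab_of[[m]], T = transition_age)),
      error = function(e) NULL)
    if (is.null(f)) next
    fits[[f$model_id]] <- f
    blk <- list(params = as.list(f$params), se = as.list(f$se),
                loglik = f$loglik,
                net_pre = as.list(f$derived$net_pre),
                net_post = as.list(f$derived$net_post))
    if (!is.null(f$derived$amp_fold))
      blk <- c(blk, list(amp_fold = f$derived$amp_fold,
                         frac_post = f$derived$frac_post, nu = f$derived$nu))
    report[[f$model_id]] <- blk
  }
  if (length(fits) > 1) {
    cmp <- compare_models(unname(fits))
    report$comparison <- list(aic = cmp$aic, lrt = cmp$lrt)
  }
  gof_days <- attr(summary, "chase_days")
  gofs <- lapply(gof_days, function(d)
    tryCatch(suppressWarnings(neutrality_gof(tab, d)),
             error = function(e) NULL))
  ok <- !vapply(gofs, is.null, TRUE)
  report$neutrality <- data.frame(
    chase_day = gof_days[ok],
    stat = vapply(gofs[ok], `[[`, 0, "stat"),
    p = vapply(gofs[ok], `[[`, 0, "p.value"))
  json <- file.path(out_dir, paste0(prefix, ".json"))
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  txt <- file.path(out_dir, paste0(prefix, ".txt"))
  con <- file(txt, "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  cat("Clonal birth-death analysis report\n")
  cat("==================================\n")
  cat(sprintf("input: %s (%d clones), seed %d, baseline day %g\n\n",
              csv, nrow(tab$records), seed, report$baseline_day))
  if (!is.null(di)) print(di)
  if (!is.null(hl)) print(hl)
  cat("\n")
  for (f in fits) { print(f); cat("\n") }
  if (length(fits) > 1) print(compare_models(unname(fits)))
  if (!is.null(report$cbdm) && isTRUE(report$cbdm$lack_of_fit))
    cat("\nWARNING: the critical birth-death model shows systematic lack of fit",
        sprintf("(residual chi-square p = %.3g);", report$cbdm$lack_of_fit_p),
        "the population is not consistent with neutral drift.\n")
  cat("\nNeutral-competition goodness of fit per chase day:\n")
  print(report$neutrality)
  invisible(report)
}
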