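#' Construct a clone-count table
#'
#' A clone table holds one row per labeled clone observed in a whole-mount
#' at one chase time: its basal and suprabasal labeled cell counts, the
#' tail-skin region (scale or interscale), the chase day, and opaque clone
#' and cohort (mouse/experiment) identifiers.  The design is
#' cross-sectional: each chase day is an independent cohort of animals, and
#' a clone with zero cells is never recorded — clone loss shows up as a
#' decline of clones per sampled area.
#'
#' @param records data frame with columns `clone_id`, `cohort_id`,
#'   `chase_day`, `region` (`"scale"` or `"interscale"`), `basal`,
#'   `suprabasal`.
#' @param schedule ordered chase days of the experiment; defaults to the
#'   days present in `records`.
#' @param area_norm named numeric vector of per-cohort relative sampled
#'   areas (dimensionless, default 1 for every cohort).
#' @return An object of class `"clone_table"`.
#' @export
clone_table <- function(records, schedule = NULL, area_norm = NULL) {
  req <- c("clone_id", "cohort_id", "chase_day", "region", "basal", "suprabasal")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[req]
  records$clone_id <- as.character(records$clone_id)
  records$cohort_id <- as.character(records$cohort_id)
  records$chase_day <- as.numeric(records$chase_day)
  records$region <- as.character(records$region)
  for (col in c("basal", "suprabasal")) {
    v <- records[[col]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("column '", col, "' must hold nonnegative integers; bad row(s): ",
           paste(head(bad, 5), collapse = ", "))
    records[[col]] <- as.integer(v)
  }
  bad <- which(!(records$region %in% c("scale", "interscale")))
  if (length(bad))
    stop("unknown region label in row(s): ", paste(head(bad, 5), collapse = ", "))
  bad <- which(records$basal + records$suprabasal < 1)
  if (length(bad))
    stop("clone with zero cells in row(s): ", paste(head(bad, 5), collapse = ", "),
         " (empty clones are never recorded)")
  if (any(records$chase_day < 0 | is.na(records$chase_day)))
    stop("chase_day must be nonnegative")
  if (is.null(schedule)) schedule <- sort(unique(records$chase_day))
  if (!all(records$chase_day %in% schedule))
    stop("every record's chase_day must appear in the schedule")
  # cross-sectional design: a cohort sits at exactly one chase day
  byc <- tapply(records$chase_day, records$cohort_id,
                function(d) length(unique(d)))
  if (any(byc > 1))
    stop("cohort(s) appear at more than one chase day: ",
         paste(names(byc)[byc > 1], collapse = ", "))
  cohorts <- unique(records[c("cohort_id", "chase_day")])
  if (is.null(area_norm)) {
    area_norm <- setNames(rep(1, nrow(cohorts)), cohorts$cohort_id)
  } else {
    if (is.null(names(area_norm)) || !all(cohorts$cohort_id %in% names(area_norm)))
      stop("area_norm must be named by cohort_id and cover every cohort")
    area_norm <- area_norm[cohorts$cohort_id]
  }
  structure(list(records = records, schedule = sort(schedule),
                 cohorts = cohorts, area_norm = area_norm),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat("Clone table: ", nrow(x$records), " clones, ",
      length(unique(x$records$cohort_id)), " cohort(s), chase days {",
      paste(x$schedule, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Read / write clone-count tables as CSV
#'
#' The on-disk format is a plain UTF-8, comma-separated file with a header
#' row naming the six record fields (`clone_id`, `cohort_id`, `chase_day`,
#' `region`, `basal`, `suprabasal`).  `columns` remaps nonstandard headers,
#' e.g. `c(basal = "BL_cells")` if the source file calls the basal count
#' `BL_cells`.
#'
#' @param path CSV file path.
#' @param columns optional named character vector mapping standard field
#'   names to the file's column names.
#' @param table a [clone_table()].
#' @inheritParams clone_table
#' @return `load_clone_table()` returns a validated [clone_table()];
#'   `write_clone_table()` returns `path` invisibly.
#' @export
load_clone_table <- function(path, columns = NULL, schedule = NULL,
                             area_norm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (!columns[[std]] %in% names(df))
        stop("mapped column '", columns[[std]], "' not in file")
      names(df)[names(df) == columns[[std]]] <- std
    }
  }
  req <- c("clone_id", "cohort_id", "chase_day", "region", "basal", "suprabasal")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df[req])) stop("missing values are not allowed in a clone table")
  clone_table(df, schedule = schedule, area_norm = area_norm)
}

#' @rdname load_clone_table
#' @export
write_clone_table <- function(table, path) {
  stopifnot(inherits(table, "clone_table"))
  write.csv(table$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
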