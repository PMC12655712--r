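#' Read a feed-diary CSV
#'
#' One row per event: dyad_id, start and end times, kind, pre/post
#' weights in grams, breast side. Times may be decimal hours
#' (`times = "hours"`, converted to minutes) or already minutes from the
#' diary origin (`times = "minutes"`), or ISO-8601 timestamps
#' (`times = "iso8601"`, converted to minutes from the earliest event).
#'
#' @param path CSV path with columns dyad_id, start_time, end_time, kind,
#'   pre_weight_g, post_weight_g, breast_side.
#' @param times time dialect.
#' @return event tibble with start_min/end_min columns.
#' @export
read_diary_csv <- function(path, times = c("minutes", "hours", "iso8601")) {
  times <- match.arg(times)
  d <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("dyad_id", "start_time", "end_time", "kind",
              "pre_weight_g", "post_weight_g")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    abort(paste0("diary CSV missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  to_min <- switch(
    times,
    minutes = function(x) as.numeric(x),
    hours = function(x) as.numeric(x) * 60,
    iso8601 = function(x) {
      t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
      as.numeric(difftime(t, min(t, na.rm = TRUE), units = "mins"))
    }
  )
  d$start_min <- to_min(d$start_time)
  d$end_min <- to_min(d$end_time)
  if (!"breast_side" %in% names(d)) d$breast_side <- "n/a"
  d |>
    dplyr::select("dyad_id", "start_min", "end_min", "kind",
                  "pre_weight_g", "post_weight_g", "breast_side") |>
    dplyr::arrange(.data$dyad_id, .data$end_min)
}

#' Read a cohort covariate CSV
#'
#' One row per dyad; missing cells empty. Columns follow the dyad-record
#' layout used throughout the package (see [generate_cohort()] for the
#' full set).
#'
#' @param path CSV path.
#' @return cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"dyad_id" %in% names(d)) abort("cohort CSV needs a dyad_id column")
  d
}

#' Write the cohort, diaries and ground truth of a simulated cohort
#'
#' @param cohort a `milk_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "milk_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(cohort$cohort, paths["cohort"])
  readr::write_csv(cohort$ground_truth, paths["ground_truth"])
  if (!is.null(cohort$diaries)) {
    paths <- c(paths, diaries = file.path(dir, "diaries.csv"))
    readr::write_csv(cohort$diaries, paths["diaries"])
  }
  invisible(paths)
}
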