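#' Median, quartiles, and range of a measure
#'
#' Quartiles use linear interpolation between closest order statistics
#' (`stats::quantile` type 7, the common default in mainstream numeric
#' stacks); the underlying studies rarely state their quantile convention,
#' so ours is fixed and documented.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return one-row tibble: `n`, `median`, `q1`, `q3`, `min`, `max`. All
#'   statistics are `NA` when no finite values remain.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, min = NA_real_, max = NA_real_))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 min = min(values), max = max(values))
}

#' Cohort mobility summary table
#'
#' One row per mobility measure with median/IQR/range across participants;
#' the shape of a standard cohort descriptive table. Participants with no
#' retained fixes (`n_points == 0` or `NA` measures) are excluded per
#' measure.
#'
#' @param participant_measures tibble with one row per participant, as
#'   returned by [mobility_measures()] (stacked).
#' @return tibble: `measure`, `n`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
cohort_mobility_table <- function(participant_measures) {
  stopifnot(nrow(participant_measures) >= 1)
  measures <- c("weekly_km", "n_points", "n_unique_locations",
                "observation_days", "points_per_day",
                grep("^pct_outside_", names(participant_measures), value = TRUE))
  measures <- intersect(measures, names(participant_measures))
  dplyr::bind_rows(lapply(measures, function(m) {
    dplyr::bind_cols(tibble::tibble(measure = m),
                     median_iqr(participant_measures[[m]]))
  }))
}

#' Cohort behavior-location summary tables
#'
#' Two complementary summaries over participants reporting each behavior:
#' `counts` gives the number and percentage of reporting participants with
#' exactly one vs two-or-more unique behavior locations and with any report
#' outside each home buffer; `stats` gives median/IQR/range of the report
#' count, unique-location count, and away-report count per radius.
#' Percentages are computed at output; the underlying counts are exact.
#'
#' @param behavior_measures tibble with one row per participant-behavior, as
#'   returned by [behavior_measures()] (stacked).
#' @return list of tibbles `counts` and `stats`; both empty (zero rows) when
#'   no behavior has a reporter.
#' @export
cohort_behavior_table <- function(behavior_measures) {
  empty <- list(counts = tibble::tibble(), stats = tibble::tibble())
  if (is.null(behavior_measures) || nrow(behavior_measures) == 0) return(empty)
  radii <- as.integer(sub("^n_away_(\\d+)m$", "\\1",
                          grep("^n_away_\\d+m$", names(behavior_measures), value = TRUE)))
  counts <- list()
  stats_rows <- list()
  for (b in unique(behavior_measures$behavior)) {
    sub <- behavior_measures[behavior_measures$behavior == b, , drop = FALSE]
    n_rep <- nrow(sub)
    row <- tibble::tibble(
      behavior = b,
      n_reporting = n_rep,
      n_one_location = sum(sub$n_unique_locations == 1),
      pct_one_location = 100 * sum(sub$n_unique_locations == 1) / n_rep,
      n_multi_location = sum(sub$n_unique_locations >= 2),
      pct_multi_location = 100 * sum(sub$n_unique_locations >= 2) / n_rep
    )
    for (r in radii) {
      n_any <- sum(sub[[sprintf("any_away_%dm", r)]])
      row[[sprintf("n_any_away_%dm", r)]] <- n_any
      row[[sprintf("pct_any_away_%dm", r)]] <- 100 * n_any / n_rep
    }
    counts[[b]] <- row
    stat_measures <- c("n_reports", "n_unique_locations",
                       sprintf("n_away_%dm", radii))
    stats_rows[[b]] <- dplyr::bind_rows(lapply(stat_measures, function(m) {
      dplyr::bind_cols(tibble::tibble(behavior = b, measure = m),
                       median_iqr(sub[[m]]))
    }))
  }
  list(counts = dplyr::bind_rows(counts), stats = dplyr::bind_rows(stats_rows))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its default: buffer radii
#' (meters), unique-location radius (meters), region bounding box, weekly
#' denominator, behavior vocabulary, and the optional linkage-gap flag
#' threshold.
#'
#' @param buffer_radii_m strictly increasing home-buffer radii, meters.
#' @param dedup_radius_m unique-location radius, meters.
#' @param bounds a [region_bounds()] object.
#' @param weekly_denominator `"observation_days"` or `"calendar_span"`.
#' @param behaviors allowed behavior labels.
#' @param max_gap_hours optional report-linkage gap threshold (flags, never
#'   drops).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(buffer_radii_m = c(100, 400, 800),
                            dedup_radius_m = 25,
                            bounds = region_bounds(),
                            weekly_denominator = c("observation_days", "calendar_span"),
                            behaviors = c("alcohol", "smoking", "condomless_sex"),
                            max_gap_hours = NULL) {
  stopifnot(all(diff(buffer_radii_m) > 0), all(buffer_radii_m > 0),
            dedup_radius_m > 0)
  structure(
    list(buffer_radii_m = buffer_radii_m,
         dedup_radius_m = dedup_radius_m,
         bounds = bounds,
         weekly_denominator = match.arg(weekly_denominator),
         behaviors = behaviors,
         max_gap_hours = max_gap_hours),
    class = "pipeline_config"
  )
}

#' Run the full activity-space pipeline
#'
#' Reads the three input tables, region-filters fixes, builds per-participant
#' trajectories, computes mobility and behavior-location measures, aggregates
#' cohort tables, and (optionally) writes everything to `out_dir`:
#' `excluded_points.csv`, `participant_measures.csv`, `linked_reports.csv`,
#' `cohort_table.csv`, `behavior_table.csv`, `behavior_counts.csv`, and
#' `run.log` with counts at every stage. The pipeline is deterministic:
#' identical inputs and config give byte-identical outputs.
#'
#' Participants with zero retained fixes are excluded from cohort tables and
#' listed in the run log. A fatal ingest problem (missing column, duplicate
#' home, participant without a home) aborts with an error naming the file or
#' ID.
#'
#' @param gps,homes,reports paths to the three input CSVs.
#' @param out_dir output directory, created if needed; `NULL` to skip
#'   writing.
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `participant_measures`, `behavior_measures`,
#'   `linked_reports`, `excluded_points`, `cohort_table`, `behavior_table`
#'   (the `stats` tibble), `behavior_counts`, `log` (character vector).
#' @export
run_pipeline <- function(gps, homes, reports, out_dir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log <<- c(log, line)
  }

  gps_pts <- suppressMessages(read_gps_log(gps))
  home_tbl <- read_homes(homes)
  report_tbl <- read_reports(reports, vocabulary = config$behaviors)
  say("read: ", nrow(gps_pts), " fixes, ", nrow(home_tbl), " homes, ",
      nrow(report_tbl), " reports")

  ids <- sort(unique(gps_pts$participant_id))
  missing_homes <- setdiff(ids, home_tbl$participant_id)
  if (length(missing_homes) > 0) {
    stop("Participant(s) in GPS log with no home location: ",
         paste(missing_homes, collapse = ", "), call. = FALSE)
  }

  split_fix <- filter_region(gps_pts, config$bounds)
  say("region filter: kept ", nrow(split_fix$kept), ", excluded ",
      nrow(split_fix$excluded))

  pm <- list(); bm <- list(); lr <- list(); empty_ids <- character(0)
  for (id in ids) {
    traj <- suppressWarnings(build_trajectory(
      split_fix$kept[split_fix$kept$participant_id == id, , drop = FALSE], id))
    home <- home_tbl[home_tbl$participant_id == id, , drop = FALSE]
    if (nrow(traj$points) == 0) {
      empty_ids <- c(empty_ids, id)
      next
    }
    pm[[id]] <- mobility_measures(traj, home, config$buffer_radii_m,
                                  config$dedup_radius_m, config$weekly_denominator)
    rep_sub <- report_tbl[report_tbl$participant_id == id, , drop = FALSE]
    linked <- link_reports(rep_sub, traj, home, config$buffer_radii_m,
                           config$max_gap_hours)
    if (nrow(linked) > 0) {
      lr[[id]] <- linked
      bm[[id]] <- behavior_measures(linked, config$buffer_radii_m,
                                    config$dedup_radius_m)
    }
  }
  if (length(empty_ids) > 0) {
    say("excluded from cohort tables (zero retained fixes): ",
        paste(empty_ids, collapse = ", "))
  }
  participant_measures <- dplyr::bind_rows(pm)
  if (nrow(participant_measures) == 0) {
    stop("No participant has any retained GPS fix", call. = FALSE)
  }
  behavior_meas <- dplyr::bind_rows(bm)
  linked_reports <- dplyr::bind_rows(lr)
  say("linked: ", nrow(linked_reports), " of ", nrow(report_tbl), " reports")

  cohort_table <- cohort_mobility_table(participant_measures)
  behav <- cohort_behavior_table(behavior_meas)
  say("cohort: ", nrow(participant_measures), " participants in tables")

  result <- list(
    participant_measures = participant_measures,
    behavior_measures = behavior_meas,
    linked_reports = linked_reports,
    excluded_points = split_fix$excluded,
    cohort_table = cohort_table,
    behavior_table = behav$stats,
    behavior_counts = behav$counts,
    log = log
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(split_fix$excluded, file.path(out_dir, "excluded_points.csv"))
    readr::write_csv(participant_measures, file.path(out_dir, "participant_measures.csv"))
    readr::write_csv(linked_reports, file.path(out_dir, "linked_reports.csv"))
    readr::write_csv(cohort_table, file.path(out_dir, "cohort_table.csv"))
    readr::write_csv(behav$stats, file.path(out_dir, "behavior_table.csv"))
    readr::write_csv(behav$counts, file.path(out_dir, "behavior_counts.csv"))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  invisible(result)
}
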