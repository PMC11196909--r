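# Index of the trajectory fix nearest in time to each report time.
# fix_t must be strictly increasing; ties (a report equidistant between an
# earlier and a later fix) resolve to the earlier fix, since the behavior
# precedes its report.
nearest_fix_index <- function(report_t, fix_t) {
  n <- length(fix_t)
  i <- findInterval(report_t, fix_t)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, n)
  gap_lo <- abs(report_t - fix_t[lo])
  gap_hi <- abs(fix_t[hi] - report_t)
  gap_lo[i == 0L] <- Inf
  ifelse(gap_lo <= gap_hi, lo, hi)
}

#' Link behavior reports to GPS fixes by nearest timestamp
#'
#' Each report is attached to the trajectory fix minimizing the absolute time
#' difference; a tie between an earlier and a later fix goes to the earlier
#' one. Linkage happens after region filtering, so a report can never attach
#' to an excluded fix. There is no maximum temporal gap: the gap is recorded
#' (`gap_seconds`) and, if `max_gap_hours` is given, links exceeding it are
#' flagged (`gap_exceeds_max`), never dropped.
#'
#' @param reports tibble of reports for one participant (`behavior`,
#'   `timestamp`).
#' @param traj that participant's `trajectory`.
#' @param home one-row tibble/list with home `lat`, `lon`.
#' @param buffer_radii_m home-buffer radii in meters.
#' @param max_gap_hours optional gap threshold for flagging.
#' @return tibble with one row per report: `participant_id`, `behavior`,
#'   `report_timestamp`, `linked_timestamp`, `gap_seconds`, `lat`, `lon`,
#'   `distance_to_home_m`, one `outside_<r>m` logical per radius, and
#'   `gap_exceeds_max`. Empty (zero-row) if the trajectory has no fixes,
#'   with a warning: such reports are linkage failures.
#' @export
link_reports <- function(reports, traj, home,
                         buffer_radii_m = c(100, 400, 800),
                         max_gap_hours = NULL) {
  pts <- traj$points
  skeleton <- tibble::tibble(
    participant_id = character(0), behavior = character(0),
    report_timestamp = as.POSIXct(character(0), tz = "UTC"),
    linked_timestamp = as.POSIXct(character(0), tz = "UTC"),
    gap_seconds = numeric(0), lat = numeric(0), lon = numeric(0),
    distance_to_home_m = numeric(0)
  )
  for (r in buffer_radii_m) skeleton[[sprintf("outside_%dm", r)]] <- logical(0)
  skeleton$gap_exceeds_max <- logical(0)
  if (nrow(reports) == 0) return(skeleton)
  if (nrow(pts) == 0) {
    warning("Participant ", traj$participant_id, ": ", nrow(reports),
            " report(s) could not be linked (empty trajectory)", call. = FALSE)
    return(skeleton)
  }
  reports <- reports[order(reports$timestamp), , drop = FALSE]
  idx <- nearest_fix_index(as.numeric(reports$timestamp), as.numeric(pts$timestamp))
  d_home_m <- great_circle_km(pts$lat[idx], pts$lon[idx], home$lat, home$lon) * 1000
  out <- tibble::tibble(
    participant_id = traj$participant_id,
    behavior = reports$behavior,
    report_timestamp = reports$timestamp,
    linked_timestamp = pts$timestamp[idx],
    gap_seconds = abs(as.numeric(reports$timestamp) - as.numeric(pts$timestamp[idx])),
    lat = pts$lat[idx],
    lon = pts$lon[idx],
    distance_to_home_m = d_home_m
  )
  for (r in buffer_radii_m) out[[sprintf("outside_%dm", r)]] <- d_home_m > r
  out$gap_exceeds_max <- if (is.null(max_gap_hours)) FALSE
    else out$gap_seconds > max_gap_hours * 3600
  out
}

#' Per-behavior location measures for one participant
#'
#' For each behavior with at least one linked report: the number of reports,
#' the number of unique locations among the linked fixes (same greedy rule
#' and radius as the mobility measure, applied in report-time order), and the
#' number of reports whose linked fix lies outside each home buffer.
#'
#' @param linked output of [link_reports()] for one participant.
#' @param buffer_radii_m home-buffer radii in meters.
#' @param dedup_radius_m unique-location radius in meters.
#' @return tibble with one row per behavior present: `participant_id`,
#'   `behavior`, `n_reports`, `n_unique_locations`, one `n_away_<r>m` and one
#'   `any_away_<r>m` column per radius.
#' @export
behavior_measures <- function(linked,
                              buffer_radii_m = c(100, 400, 800),
                              dedup_radius_m = 25) {
  behaviors <- unique(linked$behavior)
  rows <- lapply(behaviors, function(b) {
    sub <- linked[linked$behavior == b, , drop = FALSE]
    sub <- sub[order(sub$report_timestamp), , drop = FALSE]
    row <- tibble::tibble(
      participant_id = sub$participant_id[1],
      behavior = b,
      n_reports = nrow(sub),
      n_unique_locations = length(unique_locations(sub, dedup_radius_m))
    )
    for (r in buffer_radii_m) {
      n_away <- sum(sub$distance_to_home_m > r)
      row[[sprintf("n_away_%dm", r)]] <- n_away
      row[[sprintf("any_away_%dm", r)]] <- n_away >= 1
    }
    row
  })
  dplyr::bind_rows(rows)
}
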