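#' Distances between consecutive fixes of a trajectory
#'
#' Great-circle distance from each fix to the previous one; the first fix has
#' no predecessor and contributes nothing.
#'
#' @param traj a [build_trajectory()] object (or any tibble with time-ordered
#'   `lat`/`lon`).
#' @return numeric vector of length `max(0, n - 1)`, kilometers.
#' @export
interpoint_distances <- function(traj) {
  pts <- if (inherits(traj, "trajectory")) traj$points else traj
  n <- nrow(pts)
  if (n < 2) return(numeric(0))
  great_circle_km(pts$lat[-n], pts$lon[-n], pts$lat[-1], pts$lon[-1])
}

#' Average distance traveled per week
#'
#' Total inter-point great-circle distance divided by weeks of observation.
#' The weekly denominator is `observation_days / 7` by default (days with at
#' least one fix, which is what cohort studies report per participant);
#' `"calendar_span"` uses `(last_day - first_day + 1) / 7` instead.
#'
#' @param traj a `trajectory`.
#' @param denominator `"observation_days"` or `"calendar_span"`.
#' @return kilometers per week; `NA` (with a warning) for an empty trajectory.
#' @export
weekly_distance_km <- function(traj, denominator = c("observation_days", "calendar_span")) {
  denominator <- match.arg(denominator)
  if (traj$observation_days < 1) {
    warning("Participant ", traj$participant_id,
            ": no observation days, weekly distance undefined", call. = FALSE)
    return(NA_real_)
  }
  total <- sum(interpoint_distances(traj))
  days <- switch(denominator,
    observation_days = traj$observation_days,
    calendar_span = as.numeric(traj$last_day - traj$first_day) + 1
  )
  total / (days / 7)
}

#' Greedy unique-location deduplication
#'
#' A single chronological pass: the first fix founds the first location; each
#' subsequent fix founds a new location if and only if its great-circle
#' distance to *every* existing representative is at least `radius_m`,
#' otherwise it is absorbed. The default 25 m reflects typical smartphone GPS
#' accuracy (5-20 m), so fixes closer than that are indistinguishable places.
#'
#' @param points tibble of time-ordered fixes with `lat`, `lon`.
#' @param radius_m deduplication radius in meters.
#' @return integer vector of row indices of the representatives, in
#'   first-seen order. `length()` of the result is the unique-location count.
#' @export
unique_locations <- function(points, radius_m = 25) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  lat <- points$lat
  lon <- points$lon
  radius_km <- radius_m / 1000
  rep_idx <- integer(n)
  rep_lat <- numeric(n)
  rep_lon <- numeric(n)
  k <- 1L
  rep_idx[1] <- 1L
  rep_lat[1] <- lat[1]
  rep_lon[1] <- lon[1]
  if (n > 1) {
    for (i in 2:n) {
      d <- great_circle_km(lat[i], lon[i], rep_lat[1:k], rep_lon[1:k])
      if (all(d >= radius_km)) {
        k <- k + 1L
        rep_idx[k] <- i
        rep_lat[k] <- lat[i]
        rep_lon[k] <- lon[i]
      }
    }
  }
  rep_idx[1:k]
}

#' Percent of fixes outside a circular home buffer
#'
#' A fix is "outside" when its great-circle distance to the home coordinate
#' is strictly greater than `radius_m`; a fix exactly on the boundary counts
#' as inside. At buffer scales of a few hundred meters the great-circle and
#' planar ("Euclidean") distances agree to well under a centimeter, so the
#' spherical distance is used uniformly.
#'
#' @param traj a `trajectory` (or tibble of fixes).
#' @param home one-row tibble/list with `lat`, `lon`.
#' @param radius_m buffer radius in meters.
#' @return percentage in \[0, 100\]; `NA` with a warning if there are no fixes.
#' @export
pct_outside_buffer <- function(traj, home, radius_m) {
  pts <- if (inherits(traj, "trajectory")) traj$points else traj
  if (nrow(pts) == 0) {
    warning("Empty trajectory: percent outside buffer undefined", call. = FALSE)
    return(NA_real_)
  }
  d_m <- great_circle_km(pts$lat, pts$lon, home$lat, home$lon) * 1000
  100 * mean(d_m > radius_m)
}

#' All mobility measures for one participant
#'
#' Assembles total and weekly distance, fix count, unique-location count, and
#' percent-outside at each buffer radius into a one-row tibble.
#'
#' @param traj a `trajectory`.
#' @param home one-row tibble/list with the participant's home `lat`, `lon`.
#' @param buffer_radii_m buffer radii in meters, strictly increasing.
#' @param dedup_radius_m unique-location radius in meters.
#' @param weekly_denominator passed to [weekly_distance_km()].
#' @return one-row tibble: `participant_id`, `observation_days`,
#'   `points_per_day` (median fixes per observation day), `n_points`,
#'   `total_km`, `weekly_km`, `n_unique_locations`, and one
#'   `pct_outside_<r>m` column per radius.
#' @export
mobility_measures <- function(traj, home,
                              buffer_radii_m = c(100, 400, 800),
                              dedup_radius_m = 25,
                              weekly_denominator = "observation_days") {
  stopifnot(all(diff(buffer_radii_m) > 0), all(buffer_radii_m > 0))
  pts <- traj$points
  n <- nrow(pts)
  per_day <- if (n > 0) {
    stats::median(as.integer(table(as.Date(pts$timestamp, tz = "UTC"))))
  } else NA_real_
  out <- tibble::tibble(
    participant_id = traj$participant_id,
    observation_days = traj$observation_days,
    points_per_day = as.numeric(per_day),
    n_points = n,
    total_km = sum(interpoint_distances(traj)),
    weekly_km = if (n > 0) weekly_distance_km(traj, weekly_denominator) else NA_real_,
    n_unique_locations = length(unique_locations(pts, dedup_radius_m))
  )
  for (r in buffer_radii_m) {
    out[[sprintf("pct_outside_%dm", r)]] <-
      if (n > 0) pct_outside_buffer(traj, home, r) else NA_real_
  }
  out
}
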