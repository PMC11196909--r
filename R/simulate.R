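#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic GPS/behavior generator. The movement model is
#' a two-level mixture chosen for exact ground truth rather than mechanistic
#' realism: each fix is at home (Gaussian jitter, `home_jitter_m` standard
#' deviation per axis) with probability `p_home`, otherwise displaced from
#' home by a random bearing and a distance of `min_away_km` plus an
#' exponential with mean `local_radius_km` — or, on trip days, placed at that
#' day's long-trip destination. Away fixes are therefore always outside the
#' 100-m home buffer and at-home fixes essentially always inside it, so the
#' generated at-home flag is exact ground truth for the pipeline's
#' classification.
#'
#' @param n_participants cohort size.
#' @param days_range min/max observation days per participant.
#' @param fix_interval_hours min/max of the uniform gap between fixes.
#' @param p_home probability a fix is at the home location.
#' @param home_jitter_m per-axis standard deviation of at-home GPS jitter,
#'   meters.
#' @param local_radius_km mean of the exponential local-excursion distance.
#' @param min_away_km minimum displacement of an away fix (keeps away fixes
#'   outside the 100-m buffer).
#' @param p_trip_day probability a day contains a long trip.
#' @param trip_distance_km min/max long-trip displacement, kilometers.
#' @param behavior_rates named vector, expected reports per week per
#'   behavior.
#' @param p_behavior_home named vector, probability a behavior event occurs
#'   at home.
#' @param region_center lat/lon around which homes are placed.
#' @param home_spread_km radius of the uniform disc of home placement.
#' @param p_day_off probability a day logs no fixes (phone off); off by
#'   default.
#' @param start_date first possible observation date (UTC).
#' @param seed integer seed; each participant gets an independent stream
#'   derived from `(seed, participant_index)`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 46,
                       days_range = c(45, 90),
                       fix_interval_hours = c(1, 2),
                       p_home = 0.1,
                       home_jitter_m = 20,
                       local_radius_km = 3,
                       min_away_km = 0.2,
                       p_trip_day = 0.15,
                       trip_distance_km = c(50, 250),
                       behavior_rates = c(alcohol = 1.0, smoking = 0.4,
                                          condomless_sex = 0.5),
                       p_behavior_home = c(alcohol = 0.3, smoking = 0.3,
                                           condomless_sex = 0.5),
                       region_center = c(lat = -0.55, lon = 31.4),
                       home_spread_km = 30,
                       p_day_off = 0,
                       start_date = as.Date("2016-06-01"),
                       seed = 1L) {
  stopifnot(
    n_participants >= 1,
    days_range[1] <= days_range[2], days_range[1] >= 1,
    fix_interval_hours[1] <= fix_interval_hours[2], fix_interval_hours[1] > 0,
    p_home >= 0, p_home <= 1, p_trip_day >= 0, p_trip_day <= 1,
    trip_distance_km[1] <= trip_distance_km[2],
    all(p_behavior_home >= 0), all(p_behavior_home <= 1),
    all(behavior_rates >= 0), p_day_off >= 0, p_day_off < 1,
    identical(sort(names(behavior_rates)), sort(names(p_behavior_home)))
  )
  structure(as.list(environment()), class = "sim_config")
}

participant_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 131071 + index) %% 2147483647)
}

#' Simulate one participant
#'
#' Generates a home, a fix series (day by day, gaps uniform on
#' `fix_interval_hours`), and behavior reports with exact ground truth. Each
#' behavior event is anchored to one generating fix whose at-home status is
#' drawn from `p_behavior_home`, and its report is stamped a short uniform
#' delay (< half the minimum fix gap) after that fix, so nearest-timestamp
#' linkage provably recovers the generating fix.
#'
#' @param cfg a [sim_config()].
#' @param index participant index in `1:n_participants`; determines the RNG
#'   stream.
#' @return list with `home` (one-row tibble), `points` (tibble with
#'   ground-truth `at_home` flag), `reports` (tibble with ground-truth
#'   `at_home` and generating coordinates).
#' @export
simulate_participant <- function(cfg, index) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(participant_seed(cfg$seed, index))
  id <- sprintf("P%03d", index)

  hp <- destination_point(cfg$region_center[["lat"]], cfg$region_center[["lon"]],
                          stats::runif(1, 0, 360),
                          cfg$home_spread_km * sqrt(stats::runif(1)))
  home <- tibble::tibble(participant_id = id, lat = hp[1, "lat"], lon = hp[1, "lon"])

  n_days <- sample(cfg$days_range[1]:cfg$days_range[2], 1)
  day0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  min_h <- cfg$fix_interval_hours[1]
  max_h <- cfg$fix_interval_hours[2]

  ts <- list(); at_home <- list(); lat <- list(); lon <- list()
  for (d in seq_len(n_days)) {
    if (cfg$p_day_off > 0 && stats::runif(1) < cfg$p_day_off) next
    gaps <- stats::runif(ceiling(24 / min_h) + 1, min_h, max_h)
    tt <- cumsum(gaps)
    tt <- tt[tt < 24]
    m <- length(tt)
    if (m == 0) next
    fix_home <- stats::runif(m) < cfg$p_home
    flat <- numeric(m); flon <- numeric(m)
    if (any(fix_home)) {
      k <- sum(fix_home)
      jit_km <- cfg$home_jitter_m / 1000 * sqrt(-2 * log(stats::runif(k)))
      p <- destination_point(home$lat, home$lon, stats::runif(k, 0, 360), jit_km)
      flat[fix_home] <- p[, "lat"]; flon[fix_home] <- p[, "lon"]
    }
    if (any(!fix_home)) {
      k <- sum(!fix_home)
      if (stats::runif(1) < cfg$p_trip_day) {
        dest <- destination_point(home$lat, home$lon, stats::runif(1, 0, 360),
                                  stats::runif(1, cfg$trip_distance_km[1],
                                               cfg$trip_distance_km[2]))
        jit_km <- 0.05 * sqrt(-2 * log(stats::runif(k)))
        p <- destination_point(dest[1, "lat"], dest[1, "lon"],
                               stats::runif(k, 0, 360), jit_km)
      } else {
        dist_km <- cfg$min_away_km + stats::rexp(k, 1 / cfg$local_radius_km)
        p <- destination_point(home$lat, home$lon, stats::runif(k, 0, 360), dist_km)
      }
      flat[!fix_home] <- p[, "lat"]; flon[!fix_home] <- p[, "lon"]
    }
    ts[[d]] <- day0 + ((d - 1) * 24 + tt) * 3600
    at_home[[d]] <- fix_home
    lat[[d]] <- flat
    lon[[d]] <- flon
  }
  ts <- ts[!vapply(ts, is.null, logical(1))]
  points <- if (length(ts) == 0) {
    tibble::tibble(participant_id = character(0),
                   timestamp = as.POSIXct(character(0), tz = "UTC"),
                   lat = numeric(0), lon = numeric(0), at_home = logical(0))
  } else {
    tibble::tibble(
      participant_id = id,
      timestamp = do.call(c, ts),
      lat = unlist(lat), lon = unlist(lon),
      at_home = unlist(at_home)
    )
  }

  reports <- tibble::tibble(
    participant_id = character(0),
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    behavior = character(0), at_home = logical(0),
    src_lat = numeric(0), src_lon = numeric(0)
  )
  if (nrow(points) > 0) {
    rows <- list()
    for (b in names(cfg$behavior_rates)) {
      n_b <- stats::rpois(1, cfg$behavior_rates[[b]] * n_days / 7)
      if (n_b == 0) next
      want_home <- stats::runif(n_b) < cfg$p_behavior_home[[b]]
      pick <- integer(n_b)
      for (j in seq_len(n_b)) {
        pool <- which(points$at_home == want_home[j])
        if (length(pool) == 0) pool <- seq_len(nrow(points))
        pick[j] <- pool[sample.int(length(pool), 1)]
      }
      offset_s <- stats::runif(n_b, 0, min_h / 2) * 3600
      rows[[b]] <- tibble::tibble(
        participant_id = id,
        timestamp = points$timestamp[pick] + offset_s,
        behavior = b,
        at_home = points$at_home[pick],
        src_lat = points$lat[pick], src_lon = points$lon[pick]
      )
    }
    if (length(rows) > 0) {
      reports <- dplyr::bind_rows(rows)
      reports <- reports[order(reports$timestamp), , drop = FALSE]
    }
  }
  list(home = home, points = points, reports = reports)
}

#' Simulate a cohort and (optionally) write the ingest-schema CSVs
#'
#' Runs [simulate_participant()] for every index and stacks the results.
#' When `out_dir` is given, writes `gps.csv`, `homes.csv`, `reports.csv`
#' (exactly the schemas the ingest functions read) plus `truth.csv` holding
#' the ground truth for both fixes and reports.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory, or `NULL` to return tibbles only.
#' @return (invisibly) list of tibbles `gps`, `homes`, `reports`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir = NULL) {
  sims <- lapply(seq_len(cfg$n_participants), function(i) simulate_participant(cfg, i))
  gps <- dplyr::bind_rows(lapply(sims, function(s) s$points[c("participant_id", "timestamp", "lat", "lon")]))
  homes <- dplyr::bind_rows(lapply(sims, function(s) s$home))
  reports <- dplyr::bind_rows(lapply(sims, function(s) s$reports[c("participant_id", "timestamp", "behavior")]))
  truth_points <- dplyr::bind_rows(lapply(sims, function(s) s$points))
  truth_points$record_type <- "fix"
  truth_points$behavior <- NA_character_
  truth_reports <- dplyr::bind_rows(lapply(sims, function(s) s$reports))
  if (nrow(truth_reports) > 0) {
    truth_reports <- tibble::tibble(
      participant_id = truth_reports$participant_id,
      timestamp = truth_reports$timestamp,
      lat = truth_reports$src_lat, lon = truth_reports$src_lon,
      at_home = truth_reports$at_home,
      record_type = "report", behavior = truth_reports$behavior
    )
  }
  truth <- dplyr::bind_rows(truth_points, truth_reports)
  out <- list(gps = gps, homes = homes, reports = reports, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(gps, file.path(out_dir, "gps.csv"))
    readr::write_csv(homes, file.path(out_dir, "homes.csv"))
    readr::write_csv(reports, file.path(out_dir, "reports.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  invisible(out)
}

#' Relocate fixes outside the region bounds
#'
#' Moves exactly `n_outliers` randomly chosen fixes to coordinates outside
#' `bounds` (emulating international travel or device malfunction), recording
#' which rows were moved. Used to exercise the region filter with a known
#' exclusion count.
#'
#' @param points tibble of fixes.
#' @param n_outliers how many fixes to relocate; must not exceed the number
#'   of fixes.
#' @param seed integer seed for the row choice and destinations.
#' @param bounds the [region_bounds()] the outliers must violate.
#' @return list with `points` (modified tibble) and `outlier_rows` (integer
#'   indices of relocated rows).
#' @export
inject_outliers <- function(points, n_outliers, seed = 1L, bounds = region_bounds()) {
  if (n_outliers > nrow(points)) {
    stop("n_outliers (", n_outliers, ") exceeds number of fixes (",
         nrow(points), ")", call. = FALSE)
  }
  if (n_outliers == 0) return(list(points = points, outlier_rows = integer(0)))
  set.seed(as.integer(seed))
  rows <- sort(sample.int(nrow(points), n_outliers))
  # north of lat_max by a wide margin: mid-northern latitudes
  points$lat[rows] <- stats::runif(n_outliers, bounds$lat_max + 20, bounds$lat_max + 40)
  points$lon[rows] <- stats::runif(n_outliers, -10, 10)
  list(points = points, outlier_rows = rows)
}
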