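#' Default bounding box used to drop fixes far outside the study region
#'
#' A generous envelope around sub-Saharan Africa. The study region has no
#' canonical boundary, so the box is deliberately wide and fully
#' configurable; its purpose is to remove fixes from international travel or
#' device malfunction, not to trace a political border.
#'
#' @param lat_min,lat_max,lon_min,lon_max box edges, decimal degrees.
#' @return a `region_bounds` list.
#' @export
region_bounds <- function(lat_min = -35, lat_max = 20, lon_min = -20, lon_max = 55) {
  stopifnot(lat_min < lat_max, lon_min < lon_max)
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max),
    class = "region_bounds"
  )
}

# Parse a character timestamp column to POSIXct UTC; ISO-8601 offsets
# ("+03:00") are honored and normalised. Returns NA where unparseable.
parse_utc <- function(x) {
  lubridate::ymd_hms(as.character(x), tz = "UTC", quiet = TRUE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("File '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a GPS log
#'
#' Reads a CSV of time-stamped fixes, parses timestamps to UTC, and validates
#' coordinate ranges. Rows that fail to parse are rejected individually, with
#' diagnostics attached as the `"rejects"` attribute (columns `row`,
#' `reason`), never silently dropped.
#'
#' @param path CSV file with one row per fix.
#' @param schema named character vector mapping the canonical names
#'   `participant_id`, `timestamp`, `lat`, `lon` to the file's column names.
#' @return tibble with columns `participant_id` (character), `timestamp`
#'   (POSIXct UTC), `lat`, `lon`; attribute `"rejects"` holds rejected rows.
#' @export
read_gps_log <- function(path,
                         schema = c(participant_id = "participant_id",
                                    timestamp = "timestamp",
                                    lat = "lat", lon = "lon")) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, unname(schema), path)
  df <- tibble::tibble(
    participant_id = as.character(raw[[schema[["participant_id"]]]]),
    timestamp = parse_utc(raw[[schema[["timestamp"]]]]),
    lat = suppressWarnings(as.numeric(raw[[schema[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[schema[["lon"]]]]))
  )
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$timestamp)] <- "unparseable_timestamp"
  reason[is.na(df$lat) | is.na(df$lon)] <- "unparseable_coordinate"
  bad_range <- !is.na(df$lat) & !is.na(df$lon) &
    (abs(df$lat) > 90 | abs(df$lon) > 180)
  reason[bad_range] <- "coordinate_out_of_range"
  reason[is.na(df$participant_id) | df$participant_id == ""] <- "missing_participant_id"

  ok <- is.na(reason)
  rejects <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  if (nrow(rejects) > 0) {
    warning(nrow(rejects), " of ", nrow(df), " GPS rows rejected (",
            paste(unique(rejects$reason), collapse = ", "), ")", call. = FALSE)
  }
  message("read_gps_log: parsed ", sum(ok), " of ", nrow(df), " rows from ", path)
  out <- df[ok, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Read home locations
#'
#' One row per participant. Duplicate participant IDs are a fatal error
#' (which home would be "home"?); an empty file yields an empty table with a
#' warning.
#'
#' @param path CSV with columns `participant_id`, `lat`, `lon`.
#' @return tibble with one row per participant.
#' @export
read_homes <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double()
  ), progress = FALSE)
  check_columns(df, c("participant_id", "lat", "lon"), path)
  dup <- unique(df$participant_id[duplicated(df$participant_id)])
  if (length(dup) > 0) {
    stop("Duplicate home rows for participant(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) warning("Home file '", path, "' is empty", call. = FALSE)
  bad <- abs(df$lat) > 90 | abs(df$lon) > 180 | is.na(df$lat) | is.na(df$lon)
  if (any(bad)) {
    stop("Invalid home coordinates for participant(s): ",
         paste(df$participant_id[bad], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read behavior reports
#'
#' Time-stamped self-initiated behavior reports. Rows whose behavior label is
#' not in `vocabulary`, or whose timestamp does not parse, are rejected with
#' diagnostics in the `"rejects"` attribute.
#'
#' @param path CSV with columns `participant_id`, `timestamp`, `behavior`.
#' @param vocabulary allowed behavior labels.
#' @return tibble of valid reports; attribute `"rejects"` as in
#'   [read_gps_log()].
#' @export
read_reports <- function(path,
                         vocabulary = c("alcohol", "smoking", "condomless_sex")) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("participant_id", "timestamp", "behavior"), path)
  df <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    timestamp = parse_utc(raw$timestamp),
    behavior = as.character(raw$behavior)
  )
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$timestamp)] <- "unparseable_timestamp"
  reason[!df$behavior %in% vocabulary] <- "unknown_behavior"
  ok <- is.na(reason)
  rejects <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  if (nrow(rejects) > 0) {
    warning(nrow(rejects), " of ", nrow(df), " report rows rejected (",
            paste(unique(rejects$reason), collapse = ", "), ")", call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Partition GPS fixes by a bounding box
#'
#' Splits fixes into those inside `bounds` (kept) and those outside
#' (excluded, tagged `out_of_region`). Every input row lands in exactly one
#' of the two outputs.
#'
#' @param points tibble with `lat`, `lon` columns.
#' @param bounds a [region_bounds()] object.
#' @return list with tibbles `kept` and `excluded`; `excluded` gains a
#'   `reason` column.
#' @export
filter_region <- function(points, bounds = region_bounds()) {
  stopifnot(inherits(bounds, "region_bounds"))
  inside <- points$lat >= bounds$lat_min & points$lat <= bounds$lat_max &
    points$lon >= bounds$lon_min & points$lon <= bounds$lon_max
  excluded <- points[!inside, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- "out_of_region"
  else excluded$reason <- character(0)
  list(kept = points[inside, , drop = FALSE], excluded = excluded)
}

#' Build a per-participant trajectory
#'
#' Orders fixes by timestamp, collapses exact-duplicate timestamps to the
#' first occurrence in file order (with a warning), and computes observation
#' days (distinct UTC dates with at least one retained fix).
#'
#' @param points tibble of fixes for a single participant.
#' @param participant_id the participant the fixes belong to; checked against
#'   the data.
#' @return a `trajectory` object: list with `participant_id`, `points`
#'   (time-ordered tibble), `dropped_duplicates`, `observation_days`,
#'   `first_day`, `last_day`.
#' @export
build_trajectory <- function(points, participant_id = unique(points$participant_id)) {
  if (nrow(points) > 0) {
    stopifnot(all(points$participant_id == participant_id))
  }
  ord <- order(points$timestamp)
  pts <- points[ord, , drop = FALSE]
  dup <- duplicated(pts$timestamp)
  dropped <- pts[dup, , drop = FALSE]
  if (nrow(dropped) > 0) {
    warning("Participant ", participant_id, ": collapsed ", nrow(dropped),
            " fix(es) sharing a timestamp with an earlier fix", call. = FALSE)
  }
  pts <- pts[!dup, , drop = FALSE]
  days <- unique(as.Date(pts$timestamp, tz = "UTC"))
  if (nrow(pts) == 0) {
    warning("Participant ", participant_id, ": empty trajectory", call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id)[1],
      points = tibble::as_tibble(pts),
      dropped_duplicates = tibble::as_tibble(dropped),
      observation_days = length(days),
      first_day = if (length(days)) min(days) else as.Date(NA),
      last_day = if (length(days)) max(days) else as.Date(NA)
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> participant", x$participant_id, "-",
      nrow(x$points), "fixes over", x$observation_days, "observation day(s)\n")
  invisible(x)
}
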