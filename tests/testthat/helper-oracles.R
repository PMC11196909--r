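# Independent oracles: deliberately different formulas and loop structures
# from the package implementation, so agreement is evidence, not tautology.

# Spherical law of cosines on the same reference sphere.
slc_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  d2r <- pi / 180
  cosang <- sin(lat1 * d2r) * sin(lat2 * d2r) +
    cos(lat1 * d2r) * cos(lat2 * d2r) * cos((lon2 - lon1) * d2r)
  radius_km * acos(pmin(1, pmax(-1, cosang)))
}

# Brute-force greedy unique-location pass: scalar double loop, slc distance.
oracle_dedup_count <- function(lat, lon, radius_m = 25) {
  n_rep <- 0L
  rep_lat <- numeric(0)
  rep_lon <- numeric(0)
  for (i in seq_along(lat)) {
    absorbed <- FALSE
    for (j in seq_len(n_rep)) {
      if (slc_km(lat[i], lon[i], rep_lat[j], rep_lon[j]) * 1000 < radius_m) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      n_rep <- n_rep + 1L
      rep_lat[n_rep] <- lat[i]
      rep_lon[n_rep] <- lon[i]
    }
  }
  n_rep
}

# Exhaustive nearest-timestamp scan; tie -> earlier fix (smaller index since
# fix times are sorted).
oracle_link_index <- function(report_t, fix_t) {
  gaps <- abs(as.numeric(fix_t) - as.numeric(report_t))
  min(which(gaps == min(gaps)))
}

# Degrees of latitude per meter on the reference sphere (for constructing
# points at known metric offsets).
deg_per_m_lat <- 1 / (pi / 180 * 6371008.8)

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Fix table at given offsets (meters north of an origin), hourly timestamps.
pts_north <- function(offsets_m, origin_lat = 0, origin_lon = 0, id = "X",
                      t0 = utc("2020-01-01 08:00:00")) {
  tibble::tibble(
    participant_id = id,
    timestamp = t0 + 3600 * (seq_along(offsets_m) - 1),
    lat = origin_lat + offsets_m * deg_per_m_lat,
    lon = origin_lon
  )
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
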