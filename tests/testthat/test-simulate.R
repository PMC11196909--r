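test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- sim_config(n_participants = 3, days_range = c(5, 8), seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gps, b$gps)
  expect_identical(a$reports, b$reports)
  expect_identical(a$homes, b$homes)
})

test_that("participants use independent streams: one participant is stable
           when the cohort grows", {
  small <- simulate_participant(sim_config(n_participants = 2, seed = 3,
                                           days_range = c(5, 6)), 2)
  large <- simulate_participant(sim_config(n_participants = 40, seed = 3,
                                           days_range = c(5, 6)), 2)
  expect_identical(small$points, large$points)
})

test_that("a fully home-bound cohort yields ~zero mobility through the pipeline", {
  cfg <- sim_config(n_participants = 2, days_range = c(10, 12),
                    p_home = 1, p_trip_day = 0, behavior_rates = c(alcohol = 1),
                    p_behavior_home = c(alcohol = 1), seed = 23)
  sim <- simulate_cohort(cfg)
  for (id in unique(sim$gps$participant_id)) {
    traj <- build_trajectory(sim$gps[sim$gps$participant_id == id, ], id)
    home <- sim$homes[sim$homes$participant_id == id, ]
    m <- mobility_measures(traj, home)
    expect_equal(m$pct_outside_100m, 0)
    expect_equal(m$pct_outside_800m, 0)
    expect_lt(m$weekly_km, 10)
    # 20-m jitter can scatter fixes slightly beyond the 25-m dedup radius,
    # but never into many distinct locations
    expect_lt(m$n_unique_locations, 20)
  }
})

test_that("fixes per day respect the 1-2 hour logging cadence", {
  cfg <- sim_config(n_participants = 2, days_range = c(30, 30), seed = 29)
  sim <- simulate_cohort(cfg)
  per_day <- table(sim$gps$participant_id, as.Date(sim$gps$timestamp, tz = "UTC"))
  counts <- as.integer(per_day[per_day > 0])
  expect_true(all(counts >= 11 & counts <= 23))
  expect_gt(mean(counts), 13) # expectation ~ 24 / E(gap) = 16
  expect_lt(mean(counts), 19)
})

test_that("cohort files conform to the ingest schemas with zero rejections", {
  dir <- tempfile()
  cfg <- sim_config(n_participants = 5, days_range = c(6, 10), seed = 37)
  sim <- simulate_cohort(cfg, out_dir = dir)
  gps <- suppressMessages(read_gps_log(file.path(dir, "gps.csv")))
  expect_equal(nrow(attr(gps, "rejects")), 0)
  expect_equal(nrow(gps), nrow(sim$gps))
  homes <- read_homes(file.path(dir, "homes.csv"))
  expect_equal(nrow(homes), 5)
  reports <- read_reports(file.path(dir, "reports.csv"))
  expect_equal(nrow(attr(reports, "rejects")), 0)
  expect_equal(nrow(reports), nrow(sim$reports))
  expect_equal(sort(unique(gps$participant_id)), sort(homes$participant_id))

  # conservation: ingested fix counts per participant match emitted counts
  expect_equal(table(gps$participant_id), table(sim$gps$participant_id))

  # zero behavior rates give a header-only report file
  cfg0 <- sim_config(n_participants = 2, days_range = c(5, 6),
                     behavior_rates = c(alcohol = 0, smoking = 0,
                                        condomless_sex = 0),
                     p_behavior_home = c(alcohol = 1, smoking = 1,
                                         condomless_sex = 1), seed = 1)
  sim0 <- simulate_cohort(cfg0)
  expect_equal(nrow(sim0$reports), 0)
})

test_that("ground-truth at-home flags agree with the 100-m classification", {
  cfg <- sim_config(n_participants = 4, days_range = c(15, 20), p_home = 0.4,
                    seed = 43)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth[sim$truth$record_type == "fix", ]
  for (id in unique(truth$participant_id)) {
    sub <- truth[truth$participant_id == id, ]
    home <- sim$homes[sim$homes$participant_id == id, ]
    d_m <- great_circle_km(sub$lat, sub$lon, home$lat, home$lon) * 1000
    expect_identical(d_m <= 100, sub$at_home)
  }
})

test_that("nearest-timestamp linkage recovers each report's generating fix", {
  cfg <- sim_config(n_participants = 3, days_range = c(20, 25),
                    behavior_rates = c(alcohol = 3, smoking = 2,
                                       condomless_sex = 1),
                    p_home = 0.5, seed = 47)
  sim <- simulate_cohort(cfg)
  truth_rep <- sim$truth[sim$truth$record_type == "report", ]
  home0 <- tibble::tibble(lat = 0, lon = 0)
  for (id in unique(truth_rep$participant_id)) {
    traj <- build_trajectory(sim$gps[sim$gps$participant_id == id, ], id)
    reports <- sim$reports[sim$reports$participant_id == id, ]
    linked <- link_reports(reports, traj, home0)
    tr <- truth_rep[truth_rep$participant_id == id, ]
    tr <- tr[order(tr$timestamp), ]
    expect_equal(linked$lat, tr$lat)
    expect_equal(linked$lon, tr$lon)
  }
})

test_that("behavior home-probability extremes drive the any-away table to 100% or 0%", {
  run_cfg <- function(pbh) {
    dir <- tempfile()
    cfg <- sim_config(n_participants = 4, days_range = c(10, 14), p_home = 0.5,
                      behavior_rates = c(alcohol = 4),
                      p_behavior_home = c(alcohol = pbh), seed = 53)
    simulate_cohort(cfg, out_dir = dir)
    suppressMessages(suppressWarnings(run_pipeline(
      file.path(dir, "gps.csv"), file.path(dir, "homes.csv"),
      file.path(dir, "reports.csv"))))
  }
  away <- run_cfg(0)
  expect_equal(away$behavior_counts$pct_any_away_100m, 100)
  home <- run_cfg(1)
  expect_equal(home$behavior_counts$pct_any_away_100m, 0)
})

test_that("longer trips strictly increase median weekly distance across seeds", {
  median_weekly <- function(trip_km, seed) {
    cfg <- sim_config(n_participants = 4, days_range = c(10, 12),
                      p_trip_day = 0.5, trip_distance_km = trip_km,
                      behavior_rates = c(alcohol = 0),
                      p_behavior_home = c(alcohol = 1), seed = seed)
    sim <- simulate_cohort(cfg)
    wk <- vapply(unique(sim$gps$participant_id), function(id) {
      weekly_distance_km(build_trajectory(sim$gps[sim$gps$participant_id == id, ], id))
    }, numeric(1))
    stats::median(wk)
  }
  seeds <- 1:10
  low <- vapply(seeds, function(s) median_weekly(c(5, 10), s), numeric(1))
  high <- vapply(seeds, function(s) median_weekly(c(300, 500), s), numeric(1))
  expect_true(all(high > low))
  expect_lt(stats::wilcox.test(high, low, paired = TRUE,
                               alternative = "greater")$p.value, 0.01)
})

test_that("outlier injection relocates exactly the requested fixes outside bounds", {
  set.seed(3)
  pts <- tibble::tibble(participant_id = "A",
                        lat = runif(200, -5, 5), lon = runif(200, 25, 35))
  none <- inject_outliers(pts, 0)
  expect_identical(none$points, pts)

  out <- inject_outliers(pts, 10, seed = 4)
  expect_equal(length(out$outlier_rows), 10)
  b <- region_bounds()
  moved <- out$points[out$outlier_rows, ]
  expect_true(all(moved$lat > b$lat_max | moved$lat < b$lat_min |
                  moved$lon > b$lon_max | moved$lon < b$lon_min))
  parts <- filter_region(out$points)
  expect_equal(nrow(parts$excluded), 10)
  expect_equal(nrow(parts$kept), 190)

  expect_error(inject_outliers(pts, 300), "exceeds")
})
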