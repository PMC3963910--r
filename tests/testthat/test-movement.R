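make_layers <- function(dates, epi = 23, meta = 13) {
  data.frame(date = as.Date(dates), epi_mean = epi, meta_mean = meta)
}

test_that("excursion frequencies are percentages of defined fixes per fish-day", {
  ts <- as.POSIXct("2010-07-14 05:00", tz = "UTC") + 3600 * seq(0, 14, 2)
  fx <- data.frame(fish_id = "f1", timestamp = ts,
                   epilimnetic = c(TRUE, TRUE, rep(FALSE, 6)))
  rec <- excursion_frequency(fx, make_layers("2010-07-14"))
  expect_equal(rec$excursion_pct, 25)
  expect_equal(rec$n_fixes, 8L)
  expect_equal(rec$epi_mean, 23)
  expect_equal(rec$day_of_year, 195L)
  expect_equal(rec$year, 2010L)

  fx0 <- data.frame(fish_id = "f1", timestamp = ts[1:4],
                    epilimnetic = rep(FALSE, 4))
  expect_equal(excursion_frequency(fx0, make_layers("2010-07-14"))$excursion_pct, 0)
})

test_that("fish-days with no defined occupancy are dropped with a warning", {
  ts <- as.POSIXct("2010-07-14 05:00", tz = "UTC") + 3600 * c(0, 6, 24, 30)
  fx <- data.frame(fish_id = "f1", timestamp = ts,
                   epilimnetic = c(NA, NA, TRUE, FALSE))
  expect_warning(rec <- excursion_frequency(fx, make_layers(c("2010-07-14", "2010-07-15"))),
                 "dropped")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$excursion_pct, 50)
})

test_that("travelled distances are planar Euclidean steps with daily totals", {
  ts <- as.POSIXct("2010-07-14 05:00", tz = "UTC") + 3600 * c(0, 7, 14, 18)
  fx <- data.frame(fish_id = "f1", timestamp = ts,
                   period = c("dawn", "day", "dusk", "night"),
                   easting = c(0, 300, 300, 400) + 7e5,
                   northing = c(0, 400, 500, 500) + 5.1e6)
  td <- travelled_distances(fx)
  expect_equal(td$steps$distance, c(500, 100, 100))
  expect_equal(td$steps$period, c("day", "dusk", "night"))
  expect_equal(td$daily$total_distance, 700)

  one <- travelled_distances(fx[1, ])
  expect_equal(nrow(one$steps), 0L)

  dup <- fx; dup$timestamp[2] <- dup$timestamp[1]
  expect_error(travelled_distances(dup), "ambiguous")
})

test_that("square walks give equal step lengths", {
  ts <- as.POSIXct("2010-07-14", tz = "UTC") + 3600 * c(5, 12, 19, 23)
  fx <- data.frame(fish_id = "f1", timestamp = ts,
                   period = c("dawn", "day", "dusk", "night"),
                   easting = c(0, 100, 100, 0), northing = c(0, 0, 100, 100))
  td <- travelled_distances(fx)
  expect_equal(td$steps$distance, rep(100, 3))
  expect_equal(td$daily$total_distance, 300)
})

test_that("movement summary fills period-by-condition cells, empty cells keep n = 0", {
  steps <- data.frame(date = as.Date("2010-07-14"),
                      period = c("dawn", "dawn", "day"),
                      distance = c(100, 300, 50))
  sm <- summarize_movement(steps, make_layers("2010-07-14", epi = 21), 22.4)
  expect_equal(sm$mean[sm$period == "dawn" & sm$condition == "below"], 200)
  expect_true(all(sm$n[sm$condition == "above"] == 0))
  expect_true(all(is.na(sm$mean[sm$n == 0])))
  expect_equal(sum(sm$n), 3L)
})

test_that("simulated telemetry recovers shorter steps above the threshold", {
  ok <- vapply(1:5, function(s) {
    sim <- simulate_telemetry(n_fish = 8, days = 20, seed = 300 + s)
    td <- travelled_distances(sim$fixes)
    sm <- summarize_movement(td$steps, sim$daily, 22.4)
    blw <- sm$mean[sm$condition == "below" & sm$n > 0]
    abv <- sm$mean[sm$condition == "above" & sm$n > 0]
    mean(blw) > mean(abv)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
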