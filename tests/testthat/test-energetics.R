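p <- physiology_params()

test_that("currency formulas are exact and guarded", {
  expect_equal(rer(100, 10, 300), 0.3)
  expect_equal(ee(100, 10), 9.0)
  expect_equal(rer(5, 5, 10), 0)
  expect_equal(ee(5, 5), 0)
  expect_equal(ee(0, 5), -1)  # lower bound of EE
  expect_error(rer(1, 1, 0), class = "beeforage_undefined_currency")
  expect_error(ee(1, 0), class = "beeforage_undefined_currency")
})

test_that("a single-visit trip reproduces the closed-form budget", {
  # 1 g bee, landed 5 s drink of 35% (14.955 uL), 10 s flight, 1 s approach
  ev <- bind_events(
    ev_row(t = 0, dur = 10000),
    ev_row(t = 10000, dur = 1000, activity = "visit", state = "landed",
           orientation = "horizontal", flower = "H01"),
    ev_row(t = 11000, dur = 5000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "H01"))
  bee <- list(unladen_mass = 1)
  res <- trip_energetics(validate_events(ev), bee,
                         default_treatments()$control, p)
  vol <- 2.991 * 5
  expect_equal(res$visit_volumes, vol, tolerance = 1e-12)
  expect_equal(res$trip$intake, energy_intake(vol, 35, p), tolerance = 1e-12)
  # expenditure: flight 10 s at unladen mass; probe 6 s split around the
  # mass gain mid-drink is bout-level, so the drink is still at unladen mass
  off_s <- offloading_time(vol, 35, p)
  laden <- 1 + vol / 1000 * sucrose_density(35, p)
  exp_oracle <- 0.435 * 1 * 10 + 0.034 * 1 * 6 +
    0.034 * laden * off_s + 0.034 * 1 * p$nest_other_time
  expect_equal(res$trip$expenditure, exp_oracle, tolerance = 1e-12)
  expect_equal(res$trip$trip_time, 16 + off_s + p$nest_other_time,
               tolerance = 1e-12)
  expect_equal(res$trip$rer,
               (res$trip$intake - res$trip$expenditure) / res$trip$trip_time)
  expect_equal(res$trip$ee,
               res$trip$rer * res$trip$trip_time / res$trip$expenditure,
               tolerance = 1e-12)
})

test_that("an all-rest trip burns probe power plus modeled nest time", {
  ev <- ev_row(t = 0, dur = 100000, activity = "rest")
  res <- trip_energetics(validate_events(ev), list(unladen_mass = 0.171),
                         default_treatments()$control, p)
  expect_equal(res$trip$intake, 0)
  expect_equal(res$trip$expenditure,
               0.034 * 0.171 * 100 + 0.034 * 0.171 * 83.8,
               tolerance = 1e-12)
  expect_equal(res$trip$ee, -1)
})

test_that("degenerate trips are rejected", {
  ev <- ev_row(t = 0, dur = 0, activity = "rest")
  expect_error(trip_energetics(validate_events(ev),
                               list(unladen_mass = 0.171),
                               default_treatments()$control, p),
               class = "beeforage_validation")
  expect_error(trip_energetics(validate_events(tiny_trip()),
                               list(unladen_mass = -1),
                               default_treatments()$control, p),
               class = "beeforage_config")
})

test_that("hover sub-intervals are costed at flight rate within a visit", {
  ev <- bind_events(
    ev_row(t = 0, dur = 2000, activity = "visit", state = "hover",
           orientation = "vertical", flower = "V01"),
    ev_row(t = 2000, dur = 3000, activity = "drink", state = "hover",
           orientation = "vertical", flower = "V01"),
    ev_row(t = 5000, dur = 4000, activity = "drink", state = "landed",
           orientation = "vertical", flower = "V01"))
  res <- trip_energetics(validate_events(ev), list(unladen_mass = 0.2),
                         default_treatments()$low_difference, p,
                         mass_updating = FALSE)
  cls <- res$events$power_class
  expect_equal(cls, c("flight", "flight", "probe"))
  expect_equal(res$events$expenditure[1], 0.435 * 0.2 * 2, tolerance = 1e-12)
  expect_equal(res$events$expenditure[3], 0.034 * 0.2 * 4, tolerance = 1e-12)
})

test_that("per-flower per-trip volume is capped across repeat visits", {
  # two long drinks on the same flower, separated enough to be two visits
  ev <- bind_events(
    ev_row(t = 0, dur = 11000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "H01"),
    ev_row(t = 11000, dur = 15000),
    ev_row(t = 26000, dur = 11000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "H01"))
  bee <- list(unladen_mass = 1)  # rate 2.991 uL/s: 11 s -> capped at 15 each
  res <- trip_energetics(validate_events(ev), bee,
                         default_treatments()$control, p)
  expect_equal(res$visit_volumes[1], 15)
  expect_equal(res$visit_volumes[2], 0)  # the flower is empty this trip
  # a different flower is unaffected
  ev2 <- ev
  ev2$flower_id[3] <- "H02"
  res2 <- trip_energetics(validate_events(ev2), bee,
                          default_treatments()$control, p)
  expect_equal(res2$visit_volumes, c(15, 15))
})

test_that("mass updates are bout-level, monotone, and reset per trip", {
  cfg <- small_config(seed = 5)
  sim <- simulate_bee(list(bee_id = "A", treatment = "high_difference",
                           unladen_mass = 0.171), cfg)
  en <- foraging_energetics(validate_events(sim$events),
                            tiny_meta("A", "high_difference"))
  for (tr in unique(en$events$trip)) {
    m <- en$events$mass[en$events$trip == tr]
    expect_true(all(diff(m) >= -1e-12))
    expect_equal(m[1], 0.171)
  }
  # energy conservation: trip totals equal per-visit / per-event sums
  for (tr in unique(en$trips$trip)) {
    row <- en$trips[en$trips$trip == tr, ]
    vv <- en$visits[en$visits$trip == tr, ]
    cm <- concentration_map(default_treatments()$high_difference)
    intake_oracle <- sum(energy_intake(vv$volume, cm[vv$orientation], p))
    expect_equal(row$intake, intake_oracle, tolerance = 1e-9)
    evt <- en$events[en$events$trip == tr, ]
    drk <- evt[evt$bout_volume > 0, , drop = FALSE]
    laden <- 0.171 + sum(drk$bout_volume / 1000 *
                           sucrose_density(cm[drk$orientation], p))
    nest <- 0.034 * laden * row$offload_time + 0.034 * 0.171 * 83.8
    expect_equal(row$expenditure, sum(evt$expenditure) + nest,
                 tolerance = 1e-9)
  }
  # load-independent recomputation changes expenditure only slightly
  en0 <- foraging_energetics(validate_events(sim$events),
                             tiny_meta("A", "high_difference"),
                             mass_updating = FALSE)
  expect_true(all(en0$trips$expenditure <= en$trips$expenditure + 1e-12))
  expect_lt(max(abs(en0$trips$rer - en$trips$rer) / abs(en$trips$rer)), 0.1)
})

test_that("unknown orientations and missing metadata are config errors", {
  expect_error(
    trip_energetics(validate_events(tiny_trip()), list(unladen_mass = 0.2),
                    c(vertical = 35)),
    class = "beeforage_config")
  expect_error(
    foraging_energetics(validate_events(tiny_trip()), tiny_meta("OTHER")),
    class = "beeforage_config")
})
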