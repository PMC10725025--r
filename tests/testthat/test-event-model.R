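test_that("event logs round-trip through the canonical CSV dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- validate_events(tiny_trip())
  write_event_log(ev, path)
  back <- read_event_log(path, check_phases = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(ev))

  # simulator-written two-bee log: identical structures after read
  cfg <- small_config(seed = 7)
  b1 <- simulate_bee(list(bee_id = "A", treatment = "control",
                          unladen_mass = 0.17), cfg)
  b2 <- simulate_bee(list(bee_id = "B", treatment = "high_difference",
                          unladen_mass = 0.19), cfg)
  ev2 <- validate_events(rbind(b1$events, b2$events))
  write_event_log(ev2, path)
  expect_equal(as.data.frame(read_event_log(path, check_phases = FALSE)),
               as.data.frame(ev2))
})

test_that("validation rejects malformed logs with informative errors", {
  ok <- tiny_trip()
  bad <- ok; bad$duration_ms[2] <- -5
  expect_error(validate_events(bad), class = "beeforage_validation")
  bad <- ok; bad$t_start_ms[4] <- 3500  # overlaps the drink event
  expect_error(validate_events(bad), "overlapping",
               class = "beeforage_validation")
  bad <- ok; bad$state[1] <- "landed"   # fly must be state na
  expect_error(validate_events(bad), class = "beeforage_validation")
  bad <- ok; bad$state[3] <- "hover"    # hover only on vertical flowers
  expect_error(validate_events(bad), class = "beeforage_validation")
  bad <- ok; bad$flower_id[2] <- "none"
  expect_error(validate_events(bad), class = "beeforage_validation")
  # missing column is a schema error naming the column
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ok[, -match("activity", names(ok))], path,
                   row.names = FALSE)
  expect_error(read_event_log(path), "activity", class = "beeforage_schema")
  expect_error(read_event_log("/nonexistent.csv"),
               class = "beeforage_schema")
})

test_that("a dialect mapper adapts foreign schemas", {
  ev <- validate_events(tiny_trip())
  foreign <- data.frame(Bee = ev$bee_id, Phase = ev$phase, Trip = ev$trip,
                        Start = ev$t_start_ms / 1000,
                        Dur = ev$duration_ms / 1000,
                        Behaviour = c("flying", "approach", "feeding",
                                      "flying"),
                        Wings = ev$state, Orient = ev$orientation,
                        Flower = ev$flower_id)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(foreign, path, row.names = FALSE)
  d <- event_log_dialect(
    columns = c(bee_id = "Bee", phase = "Phase", trip = "Trip",
                t_start_ms = "Start", duration_ms = "Dur",
                activity = "Behaviour", state = "Wings",
                orientation = "Orient", flower_id = "Flower"),
    activity_map = c(flying = "fly", approach = "visit", feeding = "drink"),
    time_unit = "s")
  expect_equal(as.data.frame(read_event_log(path, d, check_phases = FALSE)),
               as.data.frame(ev))
})

test_that("visit aggregation applies the 10 s return-merge and 2 s rules", {
  # two drink bouts (1.5 s + 1.0 s) on one flower, 4 s gap: one visit,
  # 2.5 s total, a choice
  ev <- bind_events(
    ev_row(t = 0, dur = 500, activity = "visit", state = "landed",
           orientation = "horizontal", flower = "F"),
    ev_row(t = 500, dur = 1500, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "F"),
    ev_row(t = 2000, dur = 4000),  # 4 s away, no other flower
    ev_row(t = 6000, dur = 1000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "F"))
  v <- aggregate_visits(validate_events(ev))
  expect_equal(nrow(v), 1)
  expect_equal(v$total_drink_time, 2.5)
  expect_true(v$is_choice)
  expect_equal(v$n_bouts, 2)

  # exactly 2.0 s of contact is tasting, not a choice
  v2 <- aggregate_visits(validate_events(tiny_trip(drink_ms = 2000)))
  expect_false(v2$is_choice)
  expect_true(aggregate_visits(
    validate_events(tiny_trip(drink_ms = 2001)))$is_choice)

  # return after 12 s: two separate visits
  ev3 <- bind_events(
    ev_row(t = 0, dur = 3000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "F"),
    ev_row(t = 3000, dur = 12000),
    ev_row(t = 15000, dur = 3000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "F"))
  expect_equal(nrow(aggregate_visits(validate_events(ev3))), 2)

  # an intervening flower interaction breaks the merge even under 10 s
  ev4 <- bind_events(
    ev_row(t = 0, dur = 3000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "F"),
    ev_row(t = 3000, dur = 1000, activity = "visit", state = "landed",
           orientation = "vertical", flower = "G"),
    ev_row(t = 4000, dur = 3000, activity = "drink", state = "landed",
           orientation = "horizontal", flower = "F"))
  expect_equal(nrow(aggregate_visits(validate_events(ev4))), 3)

  expect_equal(nrow(aggregate_visits(validate_events(
    ev_row(activity = "fly")))), 0)
})

test_that("drink time is conserved and choice ordinals increase", {
  cfg <- small_config(seed = 11)
  sim <- simulate_bee(list(bee_id = "A", treatment = "low_difference",
                           unladen_mass = 0.17), cfg)
  ev <- validate_events(sim$events)
  v <- aggregate_visits(ev)
  # count conservation per trip
  for (tr in unique(ev$trip)) {
    drink_ms <- sum(ev$duration_ms[ev$trip == tr & ev$activity == "drink"])
    expect_equal(sum(v$total_drink_time[v$trip == tr]) * 1000, drink_ms,
                 tolerance = 1e-9)
  }
  ords <- v$choice_ordinal[!is.na(v$choice_ordinal)]
  expect_equal(ords, seq_along(ords))
  expect_true(all(v$total_drink_time <= v$landed_time + v$hover_time + 1e-9))
})

test_that("per-trip vertical proportions and the cumulative predictor", {
  ev <- bind_events(
    tiny_trip("B1", 1, 3000, "vertical", "V1"),
    tiny_trip("B1", 2, 3000, "horizontal", "H1"))
  v <- aggregate_visits(validate_events(ev))
  pr <- proportion_vertical(v)
  expect_equal(pr$proportion, c(1, 0))
  expect_equal(pr$cum_drinks, c(1, 2))
  # arithmetic example: 4 vertical + 1 horizontal choices in one trip
  rows <- lapply(1:5, function(i)
    tiny_trip("B2", 1, 3000, if (i <= 4) "vertical" else "horizontal",
              paste0("F", i)))
  rows <- do.call(rbind, rows)
  rows$t_start_ms <- rows$t_start_ms + rep((0:4) * 20000, each = 4)
  pr2 <- proportion_vertical(aggregate_visits(validate_events(rows)))
  expect_equal(pr2$k_vertical, 4)
  expect_equal(pr2$n, 5)
  expect_equal(pr2$proportion, 0.8)
  expect_equal(nrow(proportion_vertical(
    aggregate_visits(validate_events(ev_row(activity = "fly"))))), 0)
})

test_that("phase boundaries are recomputed from the 60-drink rule", {
  cfg <- small_config(seed = 3)
  sim <- simulate_bee(list(bee_id = "A", treatment = "control",
                           unladen_mass = 0.17), cfg)
  ev <- validate_events(sim$events)
  ph <- recompute_phases(ev, fam_choices = cfg$familiarization_choices)
  expect_true(all(ph$phase_recorded == ph$phase_recomputed))
  # corrupt a phase label: the reader warns
  bad <- ev
  bad$phase[bad$trip == max(bad$trip)] <- "familiarization"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(bad)[order(bad$trip), ], path,
                   row.names = FALSE)
  expect_error(read_event_log(path, check_phases = FALSE),
               class = "beeforage_validation")  # test precedes fam now
})
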