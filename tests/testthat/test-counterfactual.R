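p <- physiology_params()

sim2 <- local({
  cfg <- small_config(seed = 21)
  simulate_experiment(cfg)
})

test_that("identity concentration map reproduces observed energetics", {
  meta <- sim2$metadata
  donors <- meta$bee_id[meta$treatment == "control"]
  obs <- foraging_energetics(
    sim2$events[sim2$events$bee_id %in% donors &
                  sim2$events$phase == "test", ],
    meta[meta$bee_id %in% donors, ])
  sp <- counterfactual_spec("control", "control",
                            c(vertical = 35, horizontal = 35))
  cf <- counterfactual_energetics(sim2$events, meta, sp)
  expect_equal(cf$energetics$trips$intake, obs$trips$intake,
               tolerance = 1e-12)
  expect_equal(cf$energetics$trips$rer, obs$trips$rer, tolerance = 1e-12)
  w_obs <- window_series(obs, "rer")
  w_cf <- cf$windows[cf$windows$metric == "rer",
                     setdiff(names(cf$windows),
                             c("target_treatment", "donor_treatment"))]
  expect_equal(w_cf$value, w_obs$value, tolerance = 1e-12)
})

test_that("35 -> 20 substitution scales intake by the sucrose-mass ratio", {
  meta <- sim2$metadata
  # control donors under the high-difference horizontal concentration;
  # vertical kept at 35 so only horizontal drinks change
  sp <- counterfactual_spec("high_difference", "control",
                            c(vertical = 35, horizontal = 20))
  cf <- counterfactual_energetics(sim2$events, meta, sp)
  donors <- meta$bee_id[meta$treatment == "control"]
  obs <- foraging_energetics(
    sim2$events[sim2$events$bee_id %in% donors &
                  sim2$events$phase == "test", ],
    meta[meta$bee_id %in% donors, ])
  # behavior unchanged: volumes identical (20% uses the 35% drink model)
  expect_equal(cf$energetics$visits$volume, obs$visits$volume,
               tolerance = 1e-12)
  # closed-form per-drink intake ratio (density x concentration)
  ratio <- (sucrose_density(20, p) * 20) / (sucrose_density(35, p) * 35)
  ov <- obs$visits; cv <- cf$energetics$visits
  hsel <- ov$orientation == "horizontal" & ov$volume > 0
  expect_equal(energy_intake(cv$volume[hsel], 20, p),
               energy_intake(ov$volume[hsel], 35, p) * ratio,
               tolerance = 1e-12)
  # trip intake decomposes accordingly
  for (i in seq_len(nrow(obs$trips))) {
    b <- obs$trips$bee_id[i]; tr <- obs$trips$trip[i]
    sel <- ov$bee_id == b & ov$trip == tr
    h <- sum(energy_intake(ov$volume[sel & ov$orientation == "horizontal"],
                           35, p))
    v <- sum(energy_intake(ov$volume[sel & ov$orientation == "vertical"],
                           35, p))
    expect_equal(cf$energetics$trips$intake[i], v + h * ratio,
                 tolerance = 1e-9)
  }
})

test_that("unchanged concentrations leave vertical drinks untouched", {
  meta <- sim2$metadata
  # high-difference donors mapped to low-difference: vertical stays at 50
  sp <- counterfactual_spec("low_difference", "high_difference",
                            c(vertical = 50, horizontal = 35))
  cf <- counterfactual_energetics(sim2$events, meta, sp)
  donors <- meta$bee_id[meta$treatment == "high_difference"]
  obs <- foraging_energetics(
    sim2$events[sim2$events$bee_id %in% donors &
                  sim2$events$phase == "test", ],
    meta[meta$bee_id %in% donors, ])
  ov <- obs$visits; cv <- cf$energetics$visits
  vsel <- ov$orientation == "vertical"
  expect_equal(cv$volume[vsel], ov$volume[vsel], tolerance = 1e-12)
  expect_error(counterfactual_energetics(
    sim2$events, meta,
    counterfactual_spec("x", "nosuch", c(vertical = 35, horizontal = 35))),
    class = "beeforage_config")
})

test_that("slippery-flower cost compares final-window handling medians", {
  meta <- sim2$metadata
  sub <- function(trt) {
    ids <- meta$bee_id[meta$treatment == trt]
    foraging_energetics(sim2$events[sim2$events$bee_id %in% ids, ],
                        meta[meta$bee_id %in% ids, ])
  }
  ctrl <- sub("control"); hd <- sub("high_difference")
  cs <- cost_of_slippery(ctrl, hd, window_index = 2)  # 20 test choices
  expect_true(cs$handling_energy$difference > 0)  # hovering is expensive
  expect_equal(cs$handling_time$difference,
               cs$handling_time$high_difference - cs$handling_time$control,
               tolerance = 1e-12)
  # identical inputs give zero cost
  cs0 <- cost_of_slippery(ctrl, ctrl, window_index = 2)
  expect_equal(cs0$handling_time$difference, 0)
  expect_equal(cs0$handling_energy$difference, 0)
  # a missing window errors, listing bees
  expect_error(cost_of_slippery(ctrl, hd, window_index = 9),
               class = "beeforage_missing_window")
})

test_that("hover-time inflation raises the time cost monotonically", {
  costs <- vapply(c(3, 8, 16), function(oh) {
    cfg <- small_config(seed = 31, hover_overhead_median = oh)
    s <- simulate_experiment(cfg)
    meta <- s$metadata
    sub <- function(trt) {
      ids <- meta$bee_id[meta$treatment == trt]
      foraging_energetics(s$events[s$events$bee_id %in% ids, ],
                          meta[meta$bee_id %in% ids, ])
    }
    cost_of_slippery(sub("control"), sub("high_difference"),
                     window_index = 2)$handling_time$difference
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
})
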