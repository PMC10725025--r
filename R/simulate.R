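# Agent-based generator of synthetic foraging experiments with known ground
# truth. Emulates the structure of the slippery-flower trade-off design: 36
# bees (3 colonies x 3 treatments x 4 bees), a familiarization phase on
# easy-grip flowers through the trip containing the 60th drinking visit and
# a test phase on slippery flowers through the trip containing the 90th, a
# 15+15 flower array with 15 uL rewards, hover-dominated visits to slippery
# vertical flowers with partial-volume drinks, and learning-driven switching
# of choice proportions. Drinking bout durations are generated by inverting
# the drinking-rate model, so the estimation pipeline recovers ground-truth
# consumption exactly (up to the taste-threshold and cap rules).

#' Simulation configuration
#'
#' @param n_colonies Number of colonies (3).
#' @param bees_per_treatment_per_colony Bees per treatment per colony (4).
#' @param treatments Named list of [treatment()] objects.
#' @param familiarization_choices,test_choices Drinking-visit quotas ending
#'   each phase (60 / 90); the running trip is always completed.
#' @param n_flowers_per_orientation Flowers per orientation (15).
#' @param crop_capacity Crop volume ending a trip, uL. Not reported by the
#'   study; 120 uL gives ~8 full rewards and 8--15 choices per trip,
#'   consistent with 90 choices over several trips. Must not exceed the
#'   total reward of one orientation (a bee can fill up on one orientation).
#' @param policy Choice policy: "learning_sigmoid" (default; treatment- and
#'   phase-specific sigmoid trajectories of p(vertical) against choice
#'   number), "constant_p", "greedy_rer" or "greedy_ee" (model-based
#'   prospective currency comparison; a data-generating device, not a claim
#'   about bee cognition).
#' @param policy_params Policy parameters: for "constant_p" a list with `p`;
#'   for "learning_sigmoid" a nested list
#'   `treatment -> phase -> c(p_start, p_end, midpoint, rate)` (defaults
#'   emulate the published choice trajectories); for the greedy policies a
#'   list with `explore` (probability of choosing the dispreferred
#'   orientation, default 0.05).
#' @param hover_prob_slippery_vertical Probability that a drinking attempt
#'   on a slippery vertical flower is hovered (0.98).
#' @param interruption_hazard Per-second hazard of a hover drinking bout
#'   being interrupted (slip/lose grip), default 0.12.
#' @param return_prob Probability an interrupted bee re-approaches the same
#'   flower within the visit (0.8).
#' @param flight_median,flight_sdlog Between-flower flight time lognormal
#'   (median 3 s).
#' @param landed_overhead_median,hover_overhead_median Approach/scrabbling
#'   overhead medians, s (1.5 landed, 6 hover -- calibrated so per-choice
#'   handling sits in the published 14--21 s range).
#' @param overhead_sdlog Lognormal sdlog for overheads.
#' @param rest_prob,rest_median Probability of a rest bout between flowers
#'   and its median duration (s).
#' @param taste_prob Probability a flower approach is a taste (<= 2 s
#'   glossa contact, no consumption) rather than a drinking attempt.
#' @param mass_meanlog,mass_sdlog Lognormal unladen-mass distribution in
#'   grams (median 171 mg, the study's mean forager mass).
#' @param seed RNG seed; per-bee substreams are derived from (seed, bee_id).
#' @return `sim_config` object.
#' @export
sim_config <- function(n_colonies = 3,
                       bees_per_treatment_per_colony = 4,
                       treatments = default_treatments(),
                       familiarization_choices = 60,
                       test_choices = 90,
                       n_flowers_per_orientation = 15,
                       crop_capacity = 120,
                       policy = c("learning_sigmoid", "constant_p",
                                  "greedy_rer", "greedy_ee"),
                       policy_params = NULL,
                       hover_prob_slippery_vertical = 0.98,
                       interruption_hazard = 0.12,
                       return_prob = 0.8,
                       flight_median = 3, flight_sdlog = 0.4,
                       landed_overhead_median = 1.5,
                       hover_overhead_median = 6,
                       overhead_sdlog = 0.35,
                       rest_prob = 0.04, rest_median = 10,
                       taste_prob = 0.08,
                       mass_meanlog = log(0.171), mass_sdlog = 0.12,
                       seed = 1L) {
  policy <- match.arg(policy)
  cfg <- list(n_colonies = n_colonies,
              bees_per_treatment_per_colony = bees_per_treatment_per_colony,
              treatments = treatments,
              familiarization_choices = familiarization_choices,
              test_choices = test_choices,
              n_flowers_per_orientation = n_flowers_per_orientation,
              crop_capacity = crop_capacity,
              policy = policy,
              policy_params = policy_params %||% default_policy_params(policy),
              hover_prob_slippery_vertical = hover_prob_slippery_vertical,
              interruption_hazard = interruption_hazard,
              return_prob = return_prob,
              flight_median = flight_median, flight_sdlog = flight_sdlog,
              landed_overhead_median = landed_overhead_median,
              hover_overhead_median = hover_overhead_median,
              overhead_sdlog = overhead_sdlog,
              rest_prob = rest_prob, rest_median = rest_median,
              taste_prob = taste_prob,
              mass_meanlog = mass_meanlog, mass_sdlog = mass_sdlog,
              seed = as.integer(seed))
  probs <- c(cfg$hover_prob_slippery_vertical, cfg$return_prob, cfg$rest_prob,
             cfg$taste_prob)
  if (any(probs < 0 | probs > 1))
    stop_beeforage("config", "probabilities must lie in [0, 1]")
  max_reward <- max(vapply(treatments, function(t) t$reward_volume, 1)) *
    n_flowers_per_orientation
  if (crop_capacity > max_reward)
    stop_beeforage("config", "crop_capacity exceeds one orientation's total ",
                   "reward (", max_reward, " uL)")
  if (interruption_hazard <= 0)
    stop_beeforage("config", "interruption_hazard must be > 0")
  structure(cfg, class = "sim_config")
}

default_policy_params <- function(policy) {
  switch(policy,
    constant_p = list(p = 0.5),
    greedy_rer = ,
    greedy_ee = list(explore = 0.05),
    learning_sigmoid = list(
      control = list(
        familiarization = c(p_start = 0.50, p_end = 0.47, midpoint = 20,
                            rate = 0.15),
        test = c(p_start = 0.47, p_end = 0.01, midpoint = 15, rate = 0.15)),
      low_difference = list(
        familiarization = c(p_start = 0.50, p_end = 0.95, midpoint = 15,
                            rate = 0.20),
        test = c(p_start = 0.65, p_end = 0.10, midpoint = 30, rate = 0.10)),
      high_difference = list(
        familiarization = c(p_start = 0.50, p_end = 0.995, midpoint = 10,
                            rate = 0.30),
        test = c(p_start = 0.99, p_end = 0.985, midpoint = 45,
                 rate = 0.10))))
}

# prospective per-choice currency value of an orientation under the
# model-based greedy policies (deterministic: timing medians plus the
# expected cost of slip interruptions while hovering)
greedy_orientation_value <- function(currency, orientation, trt, phase, cfg,
                                     params, mass) {
  conc <- concentration_map(trt)[[orientation]]
  rate <- drinking_rate(mass, conc, params)
  vol <- trt$reward_volume
  drink_s <- vol / rate
  hover <- phase == "test" && orientation == "vertical"
  overhead <- if (hover) cfg$hover_overhead_median else
    cfg$landed_overhead_median
  handle_class <- if (hover) "flight" else "probe"
  extra_s <- 0
  if (hover) {
    # interruptions arrive at the slip hazard over the drinking time; a
    # returning bee pays a short repositioning flight plus a re-approach
    n_int <- cfg$interruption_hazard * drink_s
    extra_s <- n_int * cfg$return_prob * (3 + 1)
  }
  time_s <- cfg$flight_median + overhead + drink_s + extra_s
  cost <- metabolic_power(mass, "flight", params) *
    (cfg$flight_median + extra_s) +
    metabolic_power(mass, handle_class, params) * (overhead + drink_s)
  gain <- energy_intake(vol, conc, params)
  if (currency == "rer") (gain - cost) / time_s else (gain - cost) / cost
}

policy_p_vertical <- function(cfg, trt, phase, choice_idx, params, mass) {
  pp <- cfg$policy_params
  switch(cfg$policy,
    constant_p = pp$p,
    learning_sigmoid = {
      par <- pp[[trt$name]][[phase]]
      if (is.null(par))
        stop_beeforage("config", "no learning_sigmoid parameters for ",
                       trt$name, "/", phase)
      par[["p_end"]] + (par[["p_start"]] - par[["p_end"]]) /
        (1 + exp(par[["rate"]] * (choice_idx - par[["midpoint"]])))
    },
    {
      currency <- if (cfg$policy == "greedy_rer") "rer" else "ee"
      vv <- greedy_orientation_value(currency, "vertical", trt, phase, cfg,
                                     params, mass)
      vh <- greedy_orientation_value(currency, "horizontal", trt, phase, cfg,
                                     params, mass)
      if (abs(vv - vh) < 1e-9) 0.5
      else if (vv > vh) 1 - pp$explore else pp$explore
    })
}

rlnorm_median <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# column accumulator for event streams: preallocated typed vectors grown by
# doubling, so large simulations stay linear
new_acc <- function() {
  a <- new.env(parent = emptyenv())
  a$n <- 0L
  a$cap <- 0L
  a
}
acc_add <- function(a, ...) {
  row <- list(...)
  i <- a$n + 1L
  if (a$cap == 0L) {
    a$cap <- 1024L
    for (nm in names(row))
      assign(nm, vector(typeof(row[[nm]]), 1024L), envir = a)
  } else if (i > a$cap) {
    for (nm in names(row))
      assign(nm, c(get(nm, envir = a), vector(typeof(row[[nm]]), a$cap)),
             envir = a)
    a$cap <- a$cap * 2L
  }
  for (nm in names(row)) a[[nm]][i] <- row[[nm]]
  a$n <- i
}
acc_df <- function(a, cols) {
  if (a$n == 0L) return(NULL)
  out <- lapply(cols, function(nm) a[[nm]][seq_len(a$n)])
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate one bee's complete experiment
#'
#' Generates the chronological behavioral event stream for a single bee
#' through both phases, plus the ground-truth consumption table. Events
#' satisfy every structural invariant of [validate_events()]; drinking
#' bout durations are target volume divided by the bee's drinking rate (at
#' unladen mass), so [estimate_volume()] inverts them exactly; per-flower
#' 15 uL depletion and the crop capacity are enforced within trips; a phase
#' ends at the end of the trip in which its drinking-visit quota is
#' completed.
#'
#' @param bee List/row with bee_id, treatment, unladen_mass (g).
#' @param config [sim_config()].
#' @param params [physiology_params()].
#' @param first_trip Index of the bee's first trip (trips are numbered
#'   consecutively across phases).
#' @return List: `events` (canonical event data.frame), `truth` (per
#'   drinking/tasting bout: bee_id, phase, trip, flower_id, orientation,
#'   concentration, volume (uL), duration_ms, is_taste).
#' @export
simulate_bee <- function(bee, config = sim_config(),
                         params = physiology_params(), first_trip = 1L) {
  cfg <- config
  trt <- cfg$treatments[[bee$treatment]]
  if (is.null(trt))
    stop_beeforage("config", "no treatment '", bee$treatment, "' in config")
  mass <- bee$unladen_mass
  cmap <- concentration_map(trt)
  rate_of <- c(vertical = drinking_rate(mass, cmap[["vertical"]], params),
               horizontal = drinking_rate(mass, cmap[["horizontal"]], params))
  nfl <- cfg$n_flowers_per_orientation
  flower_ids <- list(
    vertical = sprintf("V%02d", seq_len(nfl)),
    horizontal = sprintf("H%02d", seq_len(nfl)))

  ev <- new_acc(); truth <- new_acc()
  trip <- first_trip - 1L
  quotas <- c(familiarization = cfg$familiarization_choices,
              test = cfg$test_choices)
  for (phase in c("familiarization", "test")) {
    choices <- 0L
    slippery <- phase == "test"
    while (choices < quotas[[phase]]) {
      trip <- trip + 1L
      t <- 0  # ms since trip start
      crop <- 0
      remaining <- stats::setNames(
        rep(trt$reward_volume, 2 * nfl),
        c(flower_ids$vertical, flower_ids$horizontal))
      last_flower <- ""
      emit <- function(duration_s, activity, state, orientation, flower) {
        dur <- max(1, round(duration_s * 1000))
        acc_add(ev, bee_id = bee$bee_id, phase = phase, trip = trip,
                t_start_ms = t, duration_ms = dur, activity = activity,
                state = state, orientation = orientation, flower_id = flower)
        t <<- t + dur
        dur
      }
      while (cfg$crop_capacity - crop > 0.5) {
        emit(rlnorm_median(1, cfg$flight_median, cfg$flight_sdlog),
             "fly", "na", "none", "none")
        if (stats::runif(1) < cfg$rest_prob)
          emit(rlnorm_median(1, cfg$rest_median, 0.5),
               "rest", "na", "none", "none")
        taste <- stats::runif(1) < cfg$taste_prob
        if (taste) {
          orient <- if (stats::runif(1) < 0.5) "vertical" else "horizontal"
        } else {
          p_v <- policy_p_vertical(cfg, trt, phase, choices + 1L, params,
                                   mass)
          orient <- if (stats::runif(1) < p_v) "vertical" else "horizontal"
        }
        cand <- flower_ids[[orient]]
        cand <- cand[remaining[cand] > 0.5 & cand != last_flower]
        if (!length(cand)) next
        flower <- sample(cand, 1)
        conc <- cmap[[orient]]
        rate <- rate_of[[orient]]
        hover <- slippery && orient == "vertical" &&
          stats::runif(1) < cfg$hover_prob_slippery_vertical
        state <- if (hover) "hover" else "landed"
        ohead <- if (hover) cfg$hover_overhead_median else
          cfg$landed_overhead_median
        emit(rlnorm_median(1, ohead, cfg$overhead_sdlog),
             "visit", state, orient, flower)
        if (taste) {
          dur <- emit(stats::runif(1, 0.2, 1.8), "drink", state, orient,
                      flower)
          acc_add(truth, bee_id = bee$bee_id, phase = phase, trip = trip,
                  flower_id = flower, orientation = orient,
                  concentration = conc, volume = 0, duration_ms = dur,
                  is_taste = TRUE)
          last_flower <- flower
          next
        }
        target <- min(remaining[[flower]], cfg$crop_capacity - crop)
        total_drink_ms <- 0
        bouts <- 0L
        while (target > 1e-9 && bouts < 6L) {
          bouts <- bouts + 1L
          t_full <- target / rate
          t_int <- if (hover) stats::rexp(1, cfg$interruption_hazard) else Inf
          bout_s <- min(t_full, t_int)
          dur <- emit(bout_s, "drink", state, orient, flower)
          vol <- rate * dur / 1000  # from the emitted (rounded) duration
          total_drink_ms <- total_drink_ms + dur
          acc_add(truth, bee_id = bee$bee_id, phase = phase, trip = trip,
                  flower_id = flower, orientation = orient,
                  concentration = conc, volume = vol, duration_ms = dur,
                  is_taste = FALSE)
          crop <- crop + vol
          remaining[[flower]] <- remaining[[flower]] - vol
          target <- target - vol
          if (target <= 1e-9 || t_int >= t_full) break
          if (stats::runif(1) < cfg$return_prob) {
            # interrupted but re-approaches within the 10 s merge window
            emit(stats::runif(1, 1, 5), "fly", "na", "none", "none")
            emit(rlnorm_median(1, 1, 0.3), "visit", state, orient, flower)
          } else break  # abandons the flower for now
        }
        if (total_drink_ms / 1000 > params$taste_threshold)
          choices <- choices + 1L
        last_flower <- flower
      }
    }
  }
  cols <- c("bee_id", "phase", "trip", "t_start_ms", "duration_ms",
            "activity", "state", "orientation", "flower_id")
  list(events = acc_df(ev, cols),
       truth = acc_df(truth, c("bee_id", "phase", "trip", "flower_id",
                               "orientation", "concentration", "volume",
                               "duration_ms", "is_taste")))
}

bee_substream_seed <- function(seed, bee_id) {
  h <- 0
  for (b in utf8ToInt(bee_id)) h <- (h * 131 + b) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulate a complete experiment
#'
#' Builds the bee roster (colonies x treatments x replicates, unladen
#' masses drawn lognormally around the 171 mg forager median), simulates
#' every bee with its own RNG substream derived from (seed, bee_id), and
#' returns metadata, the pooled event log, and the ground-truth table.
#' Deterministic for a fixed seed.
#'
#' @param config [sim_config()].
#' @param params [physiology_params()].
#' @return Object of class `bee_simulation`: list with `metadata`, `events`
#'   (validated), `truth`, `config`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                params = physiology_params()) {
  cfg <- config
  trts <- names(cfg$treatments)
  roster <- list()
  for (col in seq_len(cfg$n_colonies))
    for (trt in trts)
      for (i in seq_len(cfg$bees_per_treatment_per_colony))
        roster[[length(roster) + 1]] <- list(
          bee_id = sprintf("C%d_%s_%02d", col, trt, i),
          colony_id = sprintf("C%d", col), treatment = trt)
  ev_list <- list(); truth_list <- list(); meta <- list()
  for (b in roster) {
    set.seed(bee_substream_seed(cfg$seed, b$bee_id))
    b$unladen_mass <- stats::rlnorm(1, cfg$mass_meanlog, cfg$mass_sdlog)
    sim <- simulate_bee(b, cfg, params)
    ev_list[[b$bee_id]] <- sim$events
    truth_list[[b$bee_id]] <- sim$truth
    meta[[b$bee_id]] <- data.frame(bee_id = b$bee_id,
                                   colony_id = b$colony_id,
                                   treatment = b$treatment,
                                   unladen_mass = b$unladen_mass,
                                   stringsAsFactors = FALSE)
  }
  events <- validate_events(
    do.call(rbind, c(ev_list, list(make.row.names = FALSE))))
  structure(list(
    metadata = validate_bee_metadata(
      do.call(rbind, c(meta, list(make.row.names = FALSE)))),
    events = events,
    truth = do.call(rbind, c(truth_list, list(make.row.names = FALSE))),
    config = cfg), class = "bee_simulation")
}

#' @export
print.bee_simulation <- function(x, ...) {
  cat("Simulated experiment:", nrow(x$metadata), "bees,",
      nrow(x$events), "events, policy", x$config$policy,
      "(seed", paste0(x$config$seed, ")\n"))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the canonical event-log CSV (`events.csv`), the bee-metadata CSV
#' (`bees.csv`, mass in mg) and the ground-truth CSV (`truth.csv`).
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_event_log(sim$events, file.path(dir, "events.csv"))
  write_bee_metadata(sim$metadata, file.path(dir, "bees.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
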