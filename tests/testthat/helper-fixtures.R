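# Builders for tiny hand-written event logs and scaled-down simulations.

ev_row <- function(bee = "B1", trip = 1L, t = 0, dur = 1000,
                   activity = "fly", state = "na", orientation = "none",
                   flower = "none", phase = "test") {
  data.frame(bee_id = bee, phase = phase, trip = as.integer(trip),
             t_start_ms = t, duration_ms = dur, activity = activity,
             state = state, orientation = orientation, flower_id = flower,
             stringsAsFactors = FALSE)
}

bind_events <- function(...) do.call(rbind, list(...))

# a minimal valid one-trip log: fly, landed visit+drink, fly
tiny_trip <- function(bee = "B1", trip = 1L, drink_ms = 5000,
                      orientation = "horizontal", flower = "H01",
                      state = "landed", phase = "test") {
  bind_events(
    ev_row(bee, trip, 0, 2000, phase = phase),
    ev_row(bee, trip, 2000, 1000, "visit", state, orientation, flower,
           phase),
    ev_row(bee, trip, 3000, drink_ms, "drink", state, orientation, flower,
           phase),
    ev_row(bee, trip, 3000 + drink_ms, 2000, phase = phase))
}

tiny_meta <- function(bee = "B1", treatment = "control", mass = 0.171) {
  bee_metadata(bee, "C1", treatment, mass)
}

# scaled-down simulation config for fast tests (defaults overridable)
small_config <- function(...) {
  args <- list(n_colonies = 1, bees_per_treatment_per_colony = 2,
               familiarization_choices = 10, test_choices = 20)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
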