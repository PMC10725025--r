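# Per-trip energy budgets: intake from estimated consumed volumes, event-by-
# event expenditure with in-trip mass updating, and the two currencies.

#' Rate of energy return
#'
#' RER = (energy intake - energy expenditure) / time, in J/s. May be
#' negative (net loss).
#'
#' @param intake,expenditure Energy, J.
#' @param time Trip time, s (> 0).
#' @return J/s.
#' @export
rer <- function(intake, expenditure, time) {
  if (any(time <= 0))
    stop_beeforage("undefined_currency", "rer: time must be > 0")
  (intake - expenditure) / time
}

#' Energetic efficiency
#'
#' EE = (energy intake - energy expenditure) / energy expenditure,
#' dimensionless; bounded below by -1.
#'
#' @inheritParams rer
#' @return Dimensionless efficiency.
#' @export
ee <- function(intake, expenditure) {
  if (any(expenditure <= 0))
    stop_beeforage("undefined_currency", "ee: expenditure must be > 0")
  (intake - expenditure) / expenditure
}

# Estimated consumed volume per visit for one bee-trip, with the per-flower
# per-trip cumulative cap. Returns per-visit volumes (uL) in visit order plus
# the visit id of every interaction event row.
trip_visit_volumes <- function(x, vid, unladen_mass, conc_of, params,
                               interpolate = FALSE) {
  n_vis <- if (length(vid)) max(vid) else 0L
  vols <- numeric(n_vis)
  consumed <- new.env(parent = emptyenv())
  for (v in seq_len(n_vis)) {
    g <- x[vid == v, , drop = FALSE]
    flower <- g$flower_id[1]
    conc <- conc_of(g$orientation[1])
    drink_s <- sum(g$duration_ms[g$activity == "drink"]) / 1000
    raw <- estimate_volume(drink_s, unladen_mass, conc, params, interpolate)
    already <- if (!is.null(consumed[[flower]])) consumed[[flower]] else 0
    vol <- min(raw, max(params$reward_cap - already, 0))
    consumed[[flower]] <- already + vol
    vols[v] <- vol
  }
  vols
}

#' Energetics of a single foraging trip
#'
#' Computes the full energy budget of one bee-trip from its validated
#' events:
#' \itemize{
#'   \item intake: for each flower visit, the consumed volume is estimated
#'     from summed drinking time and the concentration of the visited
#'     orientation (zero at or below the 2 s taste threshold), with the
#'     cumulative estimate per flower per trip capped at the reward volume;
#'     volumes are converted to sucrose mass and energy.
#'   \item expenditure: each logged arena event is integrated at the flight
#'     metabolic rate (flying, or any hovering flower interaction) or the
#'     probe rate (landed interaction, resting) using the bee's current
#'     mass. The bee starts at unladen mass; after each drinking bout the
#'     mass increases by the bout's consumed solution mass (volume x
#'     solution density), bout volumes being the visit volume split across
#'     bouts in proportion to bout duration. Nest time is modelled, not
#'     logged: offloading time from the collected volume (at the laden
#'     mass) plus a fixed other-nest time (at unladen mass), both at the
#'     probe rate. Any literal offload/nest_other rows in the log are
#'     ignored in favour of the model.
#'   \item trip time: arena span (first to last arena event) + offloading
#'     time + other nest time. Experimenter gate-holding between trips is
#'     never part of the log and is excluded by construction.
#' }
#'
#' @param events One bee-trip's validated events.
#' @param bee One row of [bee_metadata()] (or a list with `unladen_mass`).
#' @param treatment A [treatment()] or named concentration vector
#'   (vertical/horizontal, % w/w).
#' @param params [physiology_params()].
#' @param mass_updating Update mass with crop load during the trip? Setting
#'   `FALSE` fixes mass at unladen (robustness harness for load-independent
#'   metabolic rate).
#' @param interpolate Passed to [drinking_rate()].
#' @return List with `trip` (one-row data.frame: bee_id, trip, phase,
#'   intake, expenditure, trip_time, arena_time, offload_time, rer, ee),
#'   `events` (the arena events annotated with power class, mass and
#'   per-event expenditure), and `visit_volumes` (per-visit consumed uL).
#' @export
trip_energetics <- function(events, bee, treatment,
                            params = physiology_params(),
                            mass_updating = TRUE, interpolate = FALSE) {
  params <- as_physiology_params(params)
  ev <- if (inherits(events, "bee_events")) events else validate_events(events)
  if (length(unique(ev$bee_id)) != 1L || length(unique(ev$trip)) != 1L)
    stop_beeforage("config", "trip_energetics expects one bee-trip")
  cmap <- concentration_map(treatment)
  conc_of <- function(orientation) {
    if (!orientation %in% names(cmap))
      stop_beeforage("config", "no concentration for orientation '",
                     orientation, "'")
    cmap[[orientation]]
  }
  unladen <- bee$unladen_mass
  if (is.null(unladen) || !is.finite(unladen) || unladen <= 0)
    stop_beeforage("config", "bee$unladen_mass must be strictly positive")

  arena <- ev[ev$activity %in% c("fly", "visit", "drink", "rest"), ,
              drop = FALSE]
  if (!nrow(arena))
    stop_beeforage("validation", "trip has no arena events")
  span_s <- (max(arena$t_start_ms + arena$duration_ms) -
               min(arena$t_start_ms)) / 1000
  if (span_s <= 0)
    stop_beeforage("validation", "trip_time must be positive ",
                   "(zero-duration trip)")

  inter_idx <- which(arena$activity %in% c("visit", "drink"))
  x <- arena[inter_idx, , drop = FALSE]
  vid <- visit_groups(x)
  vols <- trip_visit_volumes(x, vid, unladen, conc_of, params, interpolate)

  # bout volumes: visit volume split across its drink bouts by duration
  bout_vol <- numeric(nrow(arena))
  for (v in seq_along(vols)) {
    rows <- inter_idx[vid == v]
    drink_rows <- rows[arena$activity[rows] == "drink"]
    if (!length(drink_rows) || vols[v] == 0) next
    w <- arena$duration_ms[drink_rows]
    bout_vol[drink_rows] <- vols[v] * w / sum(w)
  }

  # event walk with mass updating
  n <- nrow(arena)
  cls <- ifelse(arena$activity == "fly" | arena$state == "hover",
                "flight", "probe")
  mass_at <- numeric(n)
  m <- unladen
  exp_ev <- numeric(n)
  for (i in seq_len(n)) {
    mass_at[i] <- m
    exp_ev[i] <- metabolic_power(m, cls[i], params) *
      arena$duration_ms[i] / 1000
    if (mass_updating && bout_vol[i] > 0) {
      conc <- conc_of(arena$orientation[i])
      m <- m + bout_vol[i] / 1000 * sucrose_density(conc, params)
    }
  }

  # intake and nest terms per concentration actually consumed
  conc_by_visit <- vapply(seq_along(vols), function(v)
    conc_of(x$orientation[vid == v][1]), numeric(1))
  intake <- if (length(vols))
    sum(energy_intake(vols, conc_by_visit, params)) else 0
  offload_s <- 0
  for (cc in unique(conc_by_visit)) {
    vc <- sum(vols[conc_by_visit == cc])
    if (vc > 0) offload_s <- offload_s + offloading_time(vc, cc, params)
  }
  laden <- if (mass_updating) m else unladen
  nest_exp <- metabolic_power(laden, "probe", params) * offload_s +
    metabolic_power(unladen, "probe", params) * params$nest_other_time
  expenditure <- sum(exp_ev) + nest_exp
  trip_time <- span_s + offload_s + params$nest_other_time

  arena$power_class <- cls
  arena$mass <- mass_at
  arena$expenditure <- exp_ev
  arena$bout_volume <- bout_vol
  trip <- data.frame(bee_id = ev$bee_id[1], trip = ev$trip[1],
                     phase = ev$phase[1], intake = intake,
                     expenditure = expenditure, trip_time = trip_time,
                     arena_time = span_s, offload_time = offload_s,
                     rer = rer(intake, expenditure, trip_time),
                     ee = ee(intake, expenditure),
                     stringsAsFactors = FALSE)
  list(trip = trip, events = arena, visit_volumes = vols)
}

#' Full foraging-energetics pipeline
#'
#' Runs [trip_energetics()] over every bee-trip in an event log, resolving
#' each bee's treatment (hence orientation -> concentration map) from the
#' metadata, and assembles the tidy tables that downstream windowing,
#' counterfactual and cost analyses consume.
#'
#' @param events Validated `bee_events` for any number of bees.
#' @param metadata [bee_metadata()] covering every bee in `events`.
#' @param treatments Named list of [treatment()] objects keyed by the
#'   treatment names used in `metadata`.
#' @param params [physiology_params()].
#' @param conc_override Optional named concentration vector
#'   (vertical/horizontal) substituted for every bee's own treatment map --
#'   the counterfactual hook.
#' @inheritParams trip_energetics
#' @return Object of class `foraging_energetics`: list with `trips`
#'   (per-trip table incl. treatment), `events` (annotated arena events with
#'   trip rer/ee attached), `visits` (flower visits with consumed volume),
#'   `metadata`, `params`.
#' @export
foraging_energetics <- function(events, metadata,
                                treatments = default_treatments(),
                                params = physiology_params(),
                                conc_override = NULL,
                                mass_updating = TRUE, interpolate = FALSE) {
  params <- as_physiology_params(params)
  ev <- if (inherits(events, "bee_events")) events else validate_events(events)
  metadata <- validate_bee_metadata(as.data.frame(metadata))
  missing_bees <- setdiff(unique(ev$bee_id), metadata$bee_id)
  if (length(missing_bees))
    stop_beeforage("config", "bees missing from metadata: ",
                   paste(missing_bees, collapse = ", "))
  visits <- aggregate_visits(ev)
  trips <- list(); annotated <- list(); vol_rows <- list()
  for (b in unique(ev$bee_id)) {
    bee <- as.list(metadata[metadata$bee_id == b, ])
    trt <- if (!is.null(conc_override)) conc_override else {
      if (!bee$treatment %in% names(treatments))
        stop_beeforage("config", "no treatment definition for '",
                       bee$treatment, "'")
      treatments[[bee$treatment]]
    }
    evb <- ev[ev$bee_id == b, , drop = FALSE]
    for (tr in sort(unique(evb$trip))) {
      res <- trip_energetics(evb[evb$trip == tr, , drop = FALSE], bee, trt,
                             params, mass_updating, interpolate)
      res$trip$treatment <- bee$treatment
      trips[[length(trips) + 1]] <- res$trip
      annotated[[length(annotated) + 1]] <- res$events
      vv <- visits[visits$bee_id == b & visits$trip == tr, , drop = FALSE]
      if (nrow(vv) != length(res$visit_volumes))
        stop_beeforage("validation", "internal: visit count mismatch for bee ",
                       b, " trip ", tr)
      vv$volume <- res$visit_volumes
      vol_rows[[length(vol_rows) + 1]] <- vv
    }
  }
  trips <- do.call(rbind, c(trips, list(make.row.names = FALSE)))
  annotated <- do.call(rbind, c(annotated, list(make.row.names = FALSE)))
  visits <- do.call(rbind, c(vol_rows, list(make.row.names = FALSE)))
  key <- paste(annotated$bee_id, annotated$trip)
  tkey <- paste(trips$bee_id, trips$trip)
  annotated$trip_rer <- trips$rer[match(key, tkey)]
  annotated$trip_ee <- trips$ee[match(key, tkey)]
  structure(list(trips = trips, events = annotated, visits = visits,
                 metadata = metadata, params = params),
            class = "foraging_energetics")
}

#' @export
print.foraging_energetics <- function(x, ...) {
  cat("Foraging energetics:", length(unique(x$trips$bee_id)), "bees,",
      nrow(x$trips), "trips,", sum(x$visits$is_choice), "drinking visits\n")
  cat("  mean RER", signif(mean(x$trips$rer), 4), "J/s; mean EE",
      signif(mean(x$trips$ee), 4), "\n")
  invisible(x)
}
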