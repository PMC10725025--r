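# Event-weighted per-ten-choice summaries, counterfactual strategies, and
# the cost-of-slippery-flowers estimator.

# Assign every annotated arena event of one phase to a drinking visit
# (choice): an event belongs to choice k if it ends after the completion of
# choice k-1 and no later than the completion of choice k, ordering
# chronologically across trips. Completion time of a choice is the end of
# its (merged) visit. Events after a bee's final choice of the phase get NA.
assign_choice_events <- function(events_phase, visits_phase) {
  ev <- events_phase
  ch <- visits_phase[visits_phase$is_choice, , drop = FALSE]
  ev$choice <- NA_integer_
  if (!nrow(ch) || !nrow(ev)) return(ev)
  ch <- ch[order(ch$trip, ch$t_end_ms), , drop = FALSE]
  # lexicographic (trip, time) key; trips are small integers, times < 1e10 ms
  ev_key <- ev$trip * 1e12 + ev$t_start_ms + ev$duration_ms
  ch_key <- ch$trip * 1e12 + ch$t_end_ms
  idx <- findInterval(ev_key, ch_key, left.open = TRUE) + 1L
  idx[idx > nrow(ch)] <- NA_integer_
  ev$choice <- ch$choice_in_phase[idx]
  ev
}

#' Per-ten-choice window series of foraging metrics
#'
#' Summarises a foraging-energetics result in consecutive windows of ten
#' drinking visits per bee and phase, the unit used to compare bees that
#' took different numbers of trips. Each behavioral event carries the RER
#' (or EE) of the trip it occurred on; a choice's value is the mean over its
#' events, and a window's value the mean over all events of its ten choices
#' -- so windows spanning a trip transition are weighted between the two
#' trips by their event counts (set `weighting = "duration"` to weight by
#' event durations instead). Handling metrics divide the total
#' flower-interaction time (or its energetic cost) of the window by its
#' number of choices; `between_flight_time` does the same for time spent
#' flying between flowers, which by construction excludes hovering flower
#' interaction (that is interaction, not flying).
#'
#' @param energetics A [foraging_energetics()] result.
#' @param metric One of "rer", "ee", "handling_time", "handling_energy",
#'   "between_flight_time".
#' @param weighting Event-count ("events", default) or event-duration
#'   ("duration") weighting for the rer/ee means.
#' @param window_size Choices per window (10).
#' @return data.frame: bee_id, treatment, phase, metric, window_index,
#'   n_choices, complete, value. A final window with fewer than
#'   `window_size` choices is reported with `complete = FALSE` (flagged, not
#'   silently averaged into analyses).
#' @export
window_series <- function(energetics,
                          metric = c("rer", "ee", "handling_time",
                                     "handling_energy",
                                     "between_flight_time"),
                          weighting = c("events", "duration"),
                          window_size = 10) {
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  stopifnot(inherits(energetics, "foraging_energetics"))
  ev <- energetics$events
  vis <- energetics$visits
  meta <- energetics$metadata
  out <- list()
  for (b in unique(ev$bee_id)) {
    trt <- meta$treatment[meta$bee_id == b]
    for (ph in intersect(c("familiarization", "test"),
                         unique(ev$phase[ev$bee_id == b]))) {
      evp <- ev[ev$bee_id == b & ev$phase == ph, , drop = FALSE]
      visp <- vis[vis$bee_id == b & vis$phase == ph, , drop = FALSE]
      evp <- assign_choice_events(evp, visp)
      n_choices <- sum(visp$is_choice)
      if (!n_choices) next
      n_win <- ceiling(n_choices / window_size)
      for (w in seq_len(n_win)) {
        lo <- (w - 1) * window_size + 1
        hi <- min(w * window_size, n_choices)
        sel <- !is.na(evp$choice) & evp$choice >= lo & evp$choice <= hi
        g <- evp[sel, , drop = FALSE]
        nc <- hi - lo + 1
        value <- if (metric %in% c("rer", "ee")) {
          vals <- if (metric == "rer") g$trip_rer else g$trip_ee
          wts <- if (weighting == "events") rep(1, nrow(g)) else g$duration_ms
          if (nrow(g)) stats::weighted.mean(vals, wts) else NA_real_
        } else if (metric == "handling_time") {
          sum(g$duration_ms[g$activity %in% c("visit", "drink")]) / 1000 / nc
        } else if (metric == "handling_energy") {
          sum(g$expenditure[g$activity %in% c("visit", "drink")]) / nc
        } else {
          sum(g$duration_ms[g$activity == "fly"]) / 1000 / nc
        }
        out[[length(out) + 1]] <- data.frame(
          bee_id = b, treatment = trt, phase = ph, metric = metric,
          window_index = w, n_choices = nc,
          complete = nc == window_size, value = value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Counterfactual strategy specification
#'
#' Describes an alternative-strategy estimate: re-run the energetics of the
#' donor treatment's bees (their observed behavior: timings, choices,
#' flowers) under the target treatment's orientation -> concentration map.
#' Valid because drinking rate does not change with concentration below
#' roughly 35--40% w/w, so substituting concentrations leaves behavior
#' plausible while changing volumes, intake, offloading and mass updating.
#'
#' @param target_treatment Name of the treatment whose concentrations are
#'   imposed.
#' @param donor_treatment Name of the treatment whose bees supply behavior.
#' @param concentration_map Named vector: concentrations (% w/w) for
#'   "vertical" and "horizontal".
#' @return A `counterfactual_spec` object.
#' @examples
#' # energetics of high-difference bees had they faced control rewards
#' counterfactual_spec("control", "high_difference",
#'                     c(vertical = 35, horizontal = 35))
#' @export
counterfactual_spec <- function(target_treatment, donor_treatment,
                                concentration_map) {
  cm <- concentration_map
  if (!is.numeric(cm) || !all(c("vertical", "horizontal") %in% names(cm)))
    stop_beeforage("config",
                   "concentration_map must name vertical and horizontal")
  structure(list(target_treatment = target_treatment,
                 donor_treatment = donor_treatment,
                 concentration_map = cm[c("vertical", "horizontal")]),
            class = "counterfactual_spec")
}

#' Counterfactual (alternative-strategy) energetics
#'
#' Recomputes the complete energetics pipeline on the donor bees' event
#' streams with the target concentrations substituted, and returns the
#' per-ten-choice window series of both currencies. With an identity map
#' this reproduces the observed energetics exactly.
#'
#' @param events Validated `bee_events` (all bees; donors are selected by
#'   the spec's donor treatment).
#' @param metadata [bee_metadata()].
#' @param spec A [counterfactual_spec()].
#' @param params [physiology_params()].
#' @param phase Restrict to one phase (default "test"); use NULL for both.
#' @inheritParams foraging_energetics
#' @return List: `energetics` (the recomputed [foraging_energetics()]) and
#'   `windows` (rer + ee window series labelled with the spec).
#' @export
counterfactual_energetics <- function(events, metadata, spec,
                                      params = physiology_params(),
                                      phase = "test",
                                      mass_updating = TRUE,
                                      interpolate = FALSE) {
  stopifnot(inherits(spec, "counterfactual_spec"))
  metadata <- validate_bee_metadata(as.data.frame(metadata))
  donors <- metadata$bee_id[metadata$treatment == spec$donor_treatment]
  if (!length(donors))
    stop_beeforage("config", "no donor bees with treatment '",
                   spec$donor_treatment, "'")
  ev <- if (inherits(events, "bee_events")) events else validate_events(events)
  ev <- ev[ev$bee_id %in% donors, , drop = FALSE]
  if (!is.null(phase)) ev <- ev[ev$phase %in% phase, , drop = FALSE]
  en <- foraging_energetics(ev, metadata[metadata$bee_id %in% donors, ],
                            params = params,
                            conc_override = spec$concentration_map,
                            mass_updating = mass_updating,
                            interpolate = interpolate)
  win <- rbind(window_series(en, "rer"), window_series(en, "ee"))
  win$target_treatment <- spec$target_treatment
  win$donor_treatment <- spec$donor_treatment
  list(energetics = en, windows = win)
}

#' Cost of slippery vertical flowers
#'
#' Estimates the overall cost of foraging on slippery vertical flowers by
#' comparing, between two groups of bees (control: almost exclusively
#' horizontal by the end; high-difference: mostly vertical), the median
#' per-choice handling time and handling energy over the final complete
#' window of ten drinking visits of the test phase.
#'
#' @param control_energetics,highdiff_energetics [foraging_energetics()]
#'   results for the two groups (test phase present).
#' @param window_index Which window to compare (default 9, the final ten of
#'   a 90-choice test phase).
#' @return List with per-group medians and their differences:
#'   `handling_time` / `handling_energy` (each: control, high_difference,
#'   difference) and the per-bee window values used.
#' @export
cost_of_slippery <- function(control_energetics, highdiff_energetics,
                             window_index = 9) {
  pull <- function(en, metric) {
    w <- window_series(en, metric)
    w <- w[w$phase == "test" & w$window_index == window_index & w$complete, ,
           drop = FALSE]
    bees <- unique(en$metadata$bee_id)
    missing <- setdiff(bees, w$bee_id)
    if (length(missing))
      stop_beeforage("missing_window",
                     "no complete window ", window_index, " for bee(s): ",
                     paste(missing, collapse = ", "))
    w
  }
  res <- list()
  for (metric in c("handling_time", "handling_energy")) {
    wc <- pull(control_energetics, metric)
    wh <- pull(highdiff_energetics, metric)
    res[[metric]] <- list(control = stats::median(wc$value),
                          high_difference = stats::median(wh$value),
                          difference = stats::median(wh$value) -
                            stats::median(wc$value),
                          per_bee = rbind(wc, wh))
  }
  res
}
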