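# Behavioral event logs: canonical CSV dialect, structural validation, and
# readers/writers. One row per timestamped activity interval per bee per trip.
#
# Canonical columns (UTF-8 CSV, header required):
#   bee_id, phase, trip, t_start_ms, duration_ms, activity, state,
#   orientation, flower_id
# with activity in {fly, visit, drink, rest, nest_other, offload}, state in
# {landed, hover, na}, orientation in {vertical, horizontal, none}, times as
# integer milliseconds since the start of the trip.

EVENT_ACTIVITIES <- c("fly", "visit", "drink", "rest", "nest_other", "offload")
EVENT_STATES <- c("landed", "hover", "na")
EVENT_ORIENTATIONS <- c("vertical", "horizontal", "none")
EVENT_COLUMNS <- c("bee_id", "phase", "trip", "t_start_ms", "duration_ms",
                   "activity", "state", "orientation", "flower_id")

#' Event-log CSV dialect
#'
#' Maps an external CSV schema onto the canonical event columns, so a
#' differently-named deposit (e.g. an institutional-repository export whose
#' column schema is not documented) can be ingested without code changes.
#' `columns` maps canonical name -> file column name; the `*_map` arguments
#' recode file values to canonical vocabulary (file value -> canonical
#' value).
#'
#' @param columns Named character vector, canonical -> file column.
#' @param activity_map,state_map,orientation_map Optional named character
#'   vectors recoding file values.
#' @param time_unit Unit of the file's time columns: "ms" or "s".
#' @return An `event_log_dialect` object.
#' @examples
#' # a file with columns Bee, Phase, Trip, Start, Dur, Behaviour, ...
#' d <- event_log_dialect(columns = c(bee_id = "Bee", phase = "Phase",
#'   trip = "Trip", t_start_ms = "Start", duration_ms = "Dur",
#'   activity = "Behaviour", state = "Wings", orientation = "Orient",
#'   flower_id = "Flower"))
#' @export
event_log_dialect <- function(columns = stats::setNames(EVENT_COLUMNS,
                                                        EVENT_COLUMNS),
                              activity_map = NULL, state_map = NULL,
                              orientation_map = NULL, time_unit = "ms") {
  miss <- setdiff(EVENT_COLUMNS, names(columns))
  if (length(miss))
    stop_beeforage("config", "dialect must map canonical column(s): ",
                   paste(miss, collapse = ", "))
  if (!time_unit %in% c("ms", "s"))
    stop_beeforage("config", "time_unit must be 'ms' or 's'")
  structure(list(columns = columns, activity_map = activity_map,
                 state_map = state_map, orientation_map = orientation_map,
                 time_unit = time_unit),
            class = "event_log_dialect")
}

recode <- function(x, map) {
  if (is.null(map)) return(x)
  hit <- x %in% names(map)
  x[hit] <- map[x[hit]]
  x
}

#' Validate a behavioral event table
#'
#' Enforces the structural invariants of an event log: canonical columns
#' present; enumerations respected; durations non-negative; events of one
#' bee-trip time-ordered and non-overlapping; fly events carry no
#' flower/orientation/state; hover only on vertical flowers; flower
#' interactions (visit/drink) carry a flower and an orientation; a trip's
#' phase label is constant.
#'
#' @param events data.frame in canonical columns.
#' @return The validated events, ordered by bee, trip, start time, with class
#'   `bee_events` prepended.
#' @export
validate_events <- function(events) {
  miss <- setdiff(EVENT_COLUMNS, names(events))
  if (length(miss))
    stop_beeforage("schema", "event log missing column(s): ",
                   paste(miss, collapse = ", "))
  ev <- as.data.frame(events)[EVENT_COLUMNS]
  ev$bee_id <- as.character(ev$bee_id)
  ev$flower_id <- as.character(ev$flower_id)
  ev$trip <- as.integer(ev$trip)
  if (any(is.na(ev$trip)) || any(ev$trip < 1))
    stop_beeforage("validation", "trip must be a positive integer")
  if (any(!is.finite(ev$t_start_ms)) || any(!is.finite(ev$duration_ms)))
    stop_beeforage("validation", "non-finite timestamps")
  if (any(ev$duration_ms < 0))
    stop_beeforage("validation", "negative event duration")
  if (!all(ev$phase %in% c("familiarization", "test")))
    stop_beeforage("validation", "phase must be familiarization or test")
  if (!all(ev$activity %in% EVENT_ACTIVITIES))
    stop_beeforage("validation", "unknown activity value(s): ",
                   paste(setdiff(unique(ev$activity), EVENT_ACTIVITIES),
                         collapse = ", "))
  if (!all(ev$state %in% EVENT_STATES))
    stop_beeforage("validation", "unknown state value(s)")
  if (!all(ev$orientation %in% EVENT_ORIENTATIONS))
    stop_beeforage("validation", "unknown orientation value(s)")
  fly <- ev$activity == "fly"
  if (any(fly & (ev$state != "na" | ev$orientation != "none")))
    stop_beeforage("validation",
                   "fly events must have state 'na' and orientation 'none'")
  if (any(ev$state == "hover" & ev$orientation != "vertical"))
    stop_beeforage("validation", "hover only occurs on vertical flowers")
  inter <- ev$activity %in% c("visit", "drink")
  if (any(inter & (is.na(ev$flower_id) | ev$flower_id == "" |
                     ev$flower_id == "none")))
    stop_beeforage("validation", "visit/drink events must carry a flower_id")
  if (any(inter & ev$orientation == "none"))
    stop_beeforage("validation", "visit/drink events must carry an orientation")
  if (any(inter & ev$state == "na"))
    stop_beeforage("validation", "visit/drink events must be landed or hover")

  ord <- order(ev$bee_id, ev$trip, ev$t_start_ms)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  key <- paste(ev$bee_id, ev$trip)
  end <- ev$t_start_ms + ev$duration_ms
  prev_end <- c(-Inf, end[-nrow(ev)])
  same <- c(FALSE, key[-1] == key[-nrow(ev)])
  overlap <- same & ev$t_start_ms < prev_end - 1e-9
  if (any(overlap)) {
    i <- which(overlap)[1]
    stop_beeforage("validation", "overlapping events for bee ", ev$bee_id[i],
                   " trip ", ev$trip[i], " at t=", ev$t_start_ms[i], " ms")
  }
  ph <- tapply(ev$phase, key, function(p) length(unique(p)))
  if (any(ph > 1))
    stop_beeforage("validation",
                   "phase label must be constant within a trip: ",
                   paste(names(ph)[ph > 1], collapse = ", "))
  # trips of one bee must not go back in phase
  for (b in unique(ev$bee_id)) {
    sub <- ev[ev$bee_id == b, ]
    ph_by_trip <- tapply(sub$phase, sub$trip, `[`, 1)
    tr <- as.integer(names(ph_by_trip))
    ph_by_trip <- ph_by_trip[order(tr)]
    if (is.unsorted(match(ph_by_trip, c("familiarization", "test"))))
      stop_beeforage("validation", "bee ", b,
                     ": test trips precede familiarization trips")
  }
  class(ev) <- c("bee_events", "data.frame")
  ev
}

#' Read a behavioral event log CSV
#'
#' Reads, renames/recodes through the dialect, and validates. Optionally
#' checks the recorded phase labels against phase boundaries recomputed from
#' the drinking-visit counts (the familiarization phase ends with the trip
#' containing the 60th drinking visit; the test phase with the trip
#' containing the 90th test-phase drinking visit): the boundaries are
#' properties of the log, not trusted from the column.
#'
#' @param path CSV file path.
#' @param dialect An [event_log_dialect()].
#' @param check_phases Warn if the recorded familiarization/test labels
#'   disagree with labels recomputed from the 60-drink boundary.
#' @param fam_choices Drinking visits ending the familiarization phase.
#' @return Validated `bee_events` data.frame ordered by bee, trip, time.
#' @export
read_event_log <- function(path, dialect = event_log_dialect(),
                           check_phases = TRUE, fam_choices = 60) {
  if (!file.exists(path))
    stop_beeforage("schema", "event log file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cols <- dialect$columns
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss))
    stop_beeforage("schema", "event log missing column(s): ",
                   paste(miss, collapse = ", "))
  ev <- stats::setNames(raw[unname(cols)], names(cols))
  ev$activity <- recode(ev$activity, dialect$activity_map)
  ev$state <- recode(ev$state, dialect$state_map)
  ev$orientation <- recode(ev$orientation, dialect$orientation_map)
  scale <- if (dialect$time_unit == "s") 1000 else 1
  ev$t_start_ms <- as.numeric(ev$t_start_ms) * scale
  ev$duration_ms <- as.numeric(ev$duration_ms) * scale
  ev$trip <- as.integer(ev$trip)
  ev <- validate_events(ev)
  if (check_phases) check_phase_labels(ev, fam_choices = fam_choices)
  ev
}

#' Write a behavioral event log CSV (canonical dialect)
#'
#' @param events `bee_events` (validated on write).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_event_log <- function(events, path) {
  ev <- validate_events(events)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recompute phase labels from drinking-visit counts
#'
#' Returns per-bee trip labels derived from the rule that familiarization
#' runs through the trip in which the bee completes her `fam_choices`-th
#' drinking visit. Used to cross-check the phase column on ingest.
#'
#' @param events Validated `bee_events`.
#' @param fam_choices Familiarization drinking-visit quota (60).
#' @return data.frame: bee_id, trip, phase_recorded, phase_recomputed.
#' @export
recompute_phases <- function(events, fam_choices = 60) {
  visits <- aggregate_visits(events)
  out <- list()
  for (b in unique(events$bee_id)) {
    sub <- events[events$bee_id == b, ]
    trips <- sort(unique(sub$trip))
    rec <- vapply(trips, function(tr) sub$phase[sub$trip == tr][1], "")
    vb <- visits[visits$bee_id == b & visits$is_choice, ]
    drinks_by_trip <- vapply(trips, function(tr) sum(vb$trip <= tr), 0L)
    # first trip reaching the quota closes familiarization
    boundary <- match(TRUE, drinks_by_trip >= fam_choices)
    comp <- rep("familiarization", length(trips))
    if (!is.na(boundary) && boundary < length(trips))
      comp[(boundary + 1):length(trips)] <- "test"
    out[[b]] <- data.frame(bee_id = b, trip = trips, phase_recorded = rec,
                           phase_recomputed = comp, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

check_phase_labels <- function(events, fam_choices = 60) {
  ph <- recompute_phases(events, fam_choices)
  bad <- ph[ph$phase_recorded != ph$phase_recomputed, ]
  if (nrow(bad))
    warning("phase labels disagree with recomputed 60-drink boundary for ",
            nrow(bad), " trip(s), e.g. bee ", bad$bee_id[1], " trip ",
            bad$trip[1], call. = FALSE)
  invisible(nrow(bad) == 0)
}
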