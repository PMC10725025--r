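# The return-merge rule, shared by visit aggregation and energetics: given
# one bee-trip's flower-interaction events in time order, return a visit id
# per row. A new visit starts unless the row is on the same flower as the
# previous interaction and begins < merge_window_ms after that interaction
# ended (the 10 s clock runs from the end of the previous interaction with
# the flower; any interaction with another flower breaks the chain).
visit_groups <- function(x, merge_window_ms = 10000) {
  n <- nrow(x)
  if (!n) return(integer())
  end <- x$t_start_ms + x$duration_ms
  new_visit <- c(TRUE, x$flower_id[-1] != x$flower_id[-n] |
                   (x$t_start_ms[-1] - end[-n]) >= merge_window_ms)
  cumsum(new_visit)
}

#' Aggregate behavioral events into flower visits
#'
#' Walks each bee-trip's flower-interaction events (activities `visit` and
#' `drink`) in time order and groups them into visits. A return to the same
#' flower within 10 s of the end of the previous interaction with that
#' flower, with no intervening interaction with any other flower, is counted
#' as part of the original visit; gaps of 10 s or more, or an intervening
#' flower, start a new visit. Drinking durations within a visit are summed;
#' a visit is a drinking visit (a "choice") when its summed drinking time
#' exceeds the 2 s taste threshold. Merging never crosses a trip boundary.
#'
#' @param events Validated `bee_events` (any number of bees/trips; empty
#'   input gives an empty result).
#' @param merge_window_ms Return-merge window, milliseconds (default 10000).
#' @param taste_threshold Choice threshold on summed drinking time, seconds.
#' @return data.frame of class `flower_visits`: bee_id, phase, trip,
#'   flower_id, orientation, t_start_ms, t_end_ms, total_drink_time,
#'   landed_time, hover_time (seconds), n_bouts, is_choice, visit_ordinal
#'   (per bee, across the experiment), choice_ordinal (per bee, across the
#'   experiment; NA for non-choices), choice_in_phase (per bee within the
#'   visit's phase; NA for non-choices).
#' @export
aggregate_visits <- function(events, merge_window_ms = 10000,
                             taste_threshold = 2.0) {
  ev <- if (inherits(events, "bee_events")) events else validate_events(events)
  inter <- ev[ev$activity %in% c("visit", "drink"), , drop = FALSE]
  empty <- data.frame(bee_id = character(), phase = character(),
                      trip = integer(), flower_id = character(),
                      orientation = character(), t_start_ms = numeric(),
                      t_end_ms = numeric(), total_drink_time = numeric(),
                      landed_time = numeric(), hover_time = numeric(),
                      n_bouts = integer(), is_choice = logical(),
                      visit_ordinal = integer(), choice_ordinal = integer(),
                      choice_in_phase = integer(), stringsAsFactors = FALSE)
  if (!nrow(inter)) {
    class(empty) <- c("flower_visits", "data.frame")
    return(empty)
  }
  res <- list()
  for (b in unique(inter$bee_id)) {
    bi <- inter[inter$bee_id == b, , drop = FALSE]
    for (tr in sort(unique(bi$trip))) {
      x <- bi[bi$trip == tr, , drop = FALSE]
      vid <- visit_groups(x, merge_window_ms)
      for (v in unique(vid)) {
        g <- x[vid == v, , drop = FALSE]
        drink <- g$activity == "drink"
        res[[length(res) + 1]] <- data.frame(
          bee_id = b, phase = g$phase[1], trip = tr,
          flower_id = g$flower_id[1], orientation = g$orientation[1],
          t_start_ms = g$t_start_ms[1],
          t_end_ms = max(g$t_start_ms + g$duration_ms),
          total_drink_time = sum(g$duration_ms[drink]) / 1000,
          landed_time = sum(g$duration_ms[g$state == "landed"]) / 1000,
          hover_time = sum(g$duration_ms[g$state == "hover"]) / 1000,
          n_bouts = sum(drink), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out <- out[order(out$bee_id, out$trip, out$t_start_ms), , drop = FALSE]
  rownames(out) <- NULL
  out$is_choice <- out$total_drink_time > taste_threshold
  out$visit_ordinal <- stats::ave(seq_len(nrow(out)), out$bee_id,
                                  FUN = seq_along)
  out$choice_ordinal <- NA_integer_
  out$choice_in_phase <- NA_integer_
  for (b in unique(out$bee_id)) {
    sel <- out$bee_id == b & out$is_choice
    out$choice_ordinal[sel] <- seq_len(sum(sel))
    for (ph in c("familiarization", "test")) {
      sp <- sel & out$phase == ph
      out$choice_in_phase[sp] <- seq_len(sum(sp))
    }
  }
  class(out) <- c("flower_visits", "data.frame")
  out
}

#' Per-trip proportion of vertical choices (or visits)
#'
#' For each foraging trip, the number of qualifying events on vertical
#' flowers, the total, their ratio, and the cumulative number of completed
#' drinking visits by trip end (the model predictor used by
#' [fit_choice_curve()]; cumulative from the start of the experiment).
#'
#' @param visits `flower_visits` for one or more bees (typically one phase;
#'   the phase column is carried through).
#' @param unit Count drinking visits ("choices") or all visits ("visits").
#' @return data.frame: bee_id, phase, trip, k_vertical, n, proportion,
#'   cum_drinks. Trips with zero qualifying events are omitted (an empty
#'   input yields an empty result, not an error).
#' @export
proportion_vertical <- function(visits, unit = c("choices", "visits")) {
  unit <- match.arg(unit)
  v <- visits
  empty <- data.frame(bee_id = character(), phase = character(),
                      trip = integer(), k_vertical = integer(), n = integer(),
                      proportion = numeric(), cum_drinks = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(v)) return(empty)
  res <- list()
  for (b in unique(v$bee_id)) {
    vb <- v[v$bee_id == b, , drop = FALSE]
    for (tr in sort(unique(vb$trip))) {
      x <- vb[vb$trip == tr, , drop = FALSE]
      q <- if (unit == "choices") x[x$is_choice, , drop = FALSE] else x
      # predictor: completed drinks since experiment start, by trip end
      cum <- sum(vb$is_choice & vb$trip <= tr)
      if (!nrow(q)) next
      res[[length(res) + 1]] <- data.frame(
        bee_id = b, phase = x$phase[1], trip = tr,
        k_vertical = sum(q$orientation == "vertical"), n = nrow(q),
        proportion = mean(q$orientation == "vertical"),
        cum_drinks = cum, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
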