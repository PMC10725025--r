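# Independent brute-force oracles, deliberately naive: plain loops over flat
# lists, no reuse of the package's grouped/vectorised code paths.

# Flat-list event-weighted window mean: walk a bee-phase's arena events in
# (trip, time) order; each event inherits its trip's metric value and is
# assigned to the first drinking visit completing at-or-after the event's
# end; window value is the (weighted) mean over the events of its choices.
oracle_window_currency <- function(events, visits, trips, metric = "rer",
                                   window_size = 10, weighting = "events") {
  stopifnot(length(unique(events$bee_id)) == 1)
  out <- list()
  for (ph in unique(events$phase)) {
    ev <- events[events$phase == ph & events$activity %in%
                   c("fly", "visit", "drink", "rest"), ]
    ev <- ev[order(ev$trip, ev$t_start_ms), ]
    ch <- visits[visits$phase == ph & visits$is_choice, ]
    ch <- ch[order(ch$trip, ch$t_end_ms), ]
    if (!nrow(ch)) next
    vals <- c(); wts <- c(); idx <- c()
    for (i in seq_len(nrow(ev))) {
      e_end <- ev$t_start_ms[i] + ev$duration_ms[i]
      assigned <- NA
      for (k in seq_len(nrow(ch))) {
        if (ch$trip[k] > ev$trip[i] ||
            (ch$trip[k] == ev$trip[i] && ch$t_end_ms[k] >= e_end)) {
          assigned <- k
          break
        }
      }
      if (is.na(assigned)) next
      tr <- trips[trips$trip == ev$trip[i], ]
      vals <- c(vals, tr[[metric]])
      wts <- c(wts, if (weighting == "events") 1 else ev$duration_ms[i])
      idx <- c(idx, assigned)
    }
    n_win <- ceiling(nrow(ch) / window_size)
    for (w in seq_len(n_win)) {
      sel <- idx > (w - 1) * window_size & idx <= w * window_size
      out[[length(out) + 1]] <- data.frame(
        phase = ph, window_index = w,
        value = sum(vals[sel] * wts[sel]) / sum(wts[sel]))
    }
  }
  do.call(rbind, out)
}

# exhaustive two-sided permutation p-value (all re-splits), with the same
# add-one convention applied to the full enumeration
oracle_exhaustive_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(length(pool), na)
  stats <- apply(splits, 2, function(ix)
    mean(pool[ix]) - mean(pool[-ix]))
  mean(abs(stats) >= obs - 1e-12)
}
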