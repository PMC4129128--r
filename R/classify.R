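# The classifier: candidate-window segmentation from motion episodes,
# ambient value matrices, feature extraction, and the forward-chaining
# inference engine with priority-based conflict resolution.

#' Segment candidate activity windows from sorted streams
#'
#' A candidate is a maximal presence episode in one compartment: motion
#' samples (from any box in the compartment) are merged into one episode
#' while gaps stay within `gap_tolerance_s`; episodes shorter than
#' `min_duration_s` are discarded. Windows never overlap within a
#' compartment.
#'
#' @param sorted Named list of chronologically sorted per-compartment
#'   packet tibbles (from [sort_pipeline()]).
#' @param layout A `home_layout`.
#' @param start_date Calendar date mapped to absolute second 0; defaults
#'   to the earliest packet date.
#' @param gap_tolerance_s Largest motion gap kept inside one episode (s).
#' @param min_duration_s Minimum episode duration (s).
#' @return Tibble of candidate windows: `compartment`, `start`, `end`
#'   (absolute seconds).
#' @export
segment_candidates <- function(sorted, layout, start_date = NULL,
                               gap_tolerance_s = 120, min_duration_s = 60) {
  if (is.null(start_date)) {
    dates <- do.call(c, lapply(sorted, function(p) p$date))
    if (!length(dates)) {
      return(tibble::tibble(compartment = character(), start = numeric(), end = numeric()))
    }
    start_date <- min(dates)
  }
  out <- list()
  for (room in names(sorted)) {
    p <- sorted[[room]]
    if (!nrow(p)) next
    t_active <- sort(unique(datetod_to_abs(p$date[p$motion == 1L], p$timestamp[p$motion == 1L], start_date)))
    if (!length(t_active)) next
    brk <- which(diff(t_active) > gap_tolerance_s)
    starts <- t_active[c(1, brk + 1)]
    ends <- t_active[c(brk, length(t_active))] + sampling_period()
    keep <- (ends - starts) >= min_duration_s
    if (any(keep)) {
      out[[room]] <- tibble::tibble(
        compartment = room, start = starts[keep], end = ends[keep]
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(compartment = character(), start = numeric(), end = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Assemble the ambient value matrix for one candidate window
#'
#' Rows are (box, channel) pairs for every box of the window's
#' compartment — the wall box plus, in the kitchen and bathroom, the
#' appliance box — and columns are the 5 s samples of the window.
#' Samples missing from the sorted streams (packet loss) are masked as
#' `NA`, never interpolated.
#'
#' @param window One-row tibble or list with `compartment`, `start`, `end`.
#' @param sorted Named list of sorted per-compartment packet tibbles.
#' @param layout A `home_layout`.
#' @param start_date Calendar date mapped to absolute second 0.
#' @return An `ambient_matrix`: list with `values` (channels x samples
#'   matrix, rownames `node<id>.<channel>`), `times`, `window`,
#'   `compartment`, `boxes`.
#' @export
build_matrix <- function(window, sorted, layout, start_date = NULL) {
  room <- window$compartment
  p <- sorted[[room]]
  if (is.null(start_date)) {
    dates <- do.call(c, lapply(sorted, function(q) q$date))
    start_date <- min(dates)
  }
  grid <- seq(window$start, window$end - sampling_period(), by = sampling_period())
  boxes <- layout$boxes[layout$boxes$compartment == room, , drop = FALSE]
  channels <- sensor_channels()$channel
  values <- matrix(NA_real_,
    nrow = nrow(boxes) * length(channels), ncol = length(grid),
    dimnames = list(
      paste0(
        "node", rep(boxes$node_id, each = length(channels)), ".",
        rep(channels, nrow(boxes))
      ),
      NULL
    )
  )
  got_any <- FALSE
  if (!is.null(p) && nrow(p)) {
    t_abs <- datetod_to_abs(p$date, p$timestamp, start_date)
    for (b in seq_len(nrow(boxes))) {
      rows_b <- p$node_id == boxes$node_id[b]
      hit <- match(grid, t_abs[rows_b])
      if (all(is.na(hit))) next
      got_any <- TRUE
      pb <- p[rows_b, , drop = FALSE]
      for (ci in seq_along(channels)) {
        values[(b - 1) * length(channels) + ci, ] <- pb[[channels[ci]]][hit]
      }
    }
  }
  if (!got_any) {
    stop_adlsense(
      "empty ambient value matrix: no samples available in window [",
      window$start, ", ", window$end, ") of ", room,
      class = "adlsense_empty_matrix_error"
    )
  }
  structure(
    list(
      values = values, times = grid,
      window = c(start = window$start, end = window$end),
      compartment = room, boxes = boxes
    ),
    class = "ambient_matrix"
  )
}

#' @export
print.ambient_matrix <- function(x, ...) {
  cat(
    "<ambient_matrix>", x$compartment, "window [", x$window[1], ",", x$window[2],
    ") -", nrow(x$values), "channels x", ncol(x$values), "samples\n"
  )
  invisible(x)
}

#' Extract the feature vector of an ambient value matrix
#'
#' Deterministic summary used by the rules: window duration; robust
#' channel deltas (difference of the medians of the first and last
#' `endpoint_s` seconds) and their absolute values for temperature and
#' humidity; luminance range and mean; motion density (fraction of
#' samples with any box's PIR active, missing samples counting as
#' inactive); the number of acceleration transients on appliance boxes
#' (excursions above `transient_threshold` over the box's median,
#' separated by at least `transient_sep_s`); and time-of-day of the
#' window start and midpoint.
#'
#' @param matrix An `ambient_matrix`.
#' @param endpoint_s Endpoint width for robust deltas (s).
#' @param transient_threshold Acceleration excursion threshold (m/s²
#'   above the box baseline).
#' @param transient_sep_s Minimum separation between counted transients (s).
#' @return Named list of class `adl_features`.
#' @export
extract_features <- function(matrix, endpoint_s = 30,
                             transient_threshold = 1.5, transient_sep_s = 10) {
  stopifnot(inherits(matrix, "ambient_matrix"))
  v <- matrix$values
  nT <- ncol(v)
  k <- max(1L, min(nT, as.integer(endpoint_s / sampling_period())))
  wall <- matrix$boxes$node_id[matrix$boxes$placement == "wall"][1]
  row_of <- function(node, ch) v[paste0("node", node, ".", ch), ]
  robust_delta <- function(x) {
    stats::median(x[(nT - k + 1):nT], na.rm = TRUE) - stats::median(x[1:k], na.rm = TRUE)
  }
  temp <- row_of(wall, "temperature")
  hum <- row_of(wall, "humidity")
  lum <- row_of(wall, "luminance")

  motion_rows <- grepl("\\.motion$", rownames(v))
  any_motion <- apply(v[motion_rows, , drop = FALSE], 2, function(col) {
    any(col == 1, na.rm = TRUE)
  })

  appliance <- matrix$boxes$node_id[matrix$boxes$placement != "wall"]
  n_trans <- 0L
  sep <- max(1L, as.integer(transient_sep_s / sampling_period()))
  for (node in appliance) {
    acc <- row_of(node, "acceleration")
    base <- stats::median(acc, na.rm = TRUE)
    exc <- which(!is.na(acc) & acc > base + transient_threshold)
    if (length(exc)) {
      n_trans <- n_trans + 1L + sum(diff(exc) > sep)
    }
  }

  dt <- robust_delta(temp)
  dh <- robust_delta(hum)
  structure(
    list(
      duration_s = unname(matrix$window["end"] - matrix$window["start"]),
      compartment = matrix$compartment,
      motion_density = mean(any_motion),
      delta_temperature = dt,
      delta_humidity = dh,
      abs_delta_temperature = abs(dt),
      abs_delta_humidity = abs(dh),
      range_luminance = diff(range(lum, na.rm = TRUE)),
      mean_luminance = mean(lum, na.rm = TRUE),
      n_transients = n_trans,
      tod_start = unname(matrix$window["start"]) %% 86400,
      tod_mid = (unname(matrix$window["start"] + matrix$window["end"]) / 2) %% 86400
    ),
    class = "adl_features"
  )
}

# ---------------------------------------------------------------------------
# Inference engine
# ---------------------------------------------------------------------------

predicate_holds <- function(p, features) {
  x <- features[[p$feature]]
  if (is.null(x) || is.na(x)) {
    return(FALSE)
  }
  switch(p$op,
    "<" = x < p$value,
    "<=" = x <= p$value,
    ">" = x > p$value,
    ">=" = x >= p$value,
    "==" = x == p$value,
    "!=" = x != p$value,
    "in_range" = if (p$value[1] <= p$value[2]) {
      x >= p$value[1] && x <= p$value[2]
    } else {
      x >= p$value[1] || x <= p$value[2] # wraps midnight
    }
  )
}

fact_requirement_met <- function(req, window_start, window_end, facts) {
  if (is.null(req)) {
    return(TRUE)
  }
  f <- facts[facts$label == req$label, , drop = FALSE]
  if (!nrow(f)) {
    return(FALSE)
  }
  if (req$relation == "starts_within_after") {
    any(f$start - window_end >= -60 & f$start - window_end <= req$lag_s)
  } else {
    any(window_start - f$end >= -60 & window_start - f$end <= req$lag_s)
  }
}

rule_satisfied <- function(r, features, window_start, window_end, facts) {
  if (!identical(r$compartment, "any") && !(features$compartment %in% r$compartment)) {
    return(FALSE)
  }
  if (features$duration_s < r$duration_min_s || features$duration_s > r$duration_max_s) {
    return(FALSE)
  }
  if (!all(vapply(r$predicates, predicate_holds, logical(1), features = features))) {
    return(FALSE)
  }
  fact_requirement_met(r$requires_fact, window_start, window_end, facts)
}

#' Conflict resolution among satisfied rules
#'
#' When several rules are satisfied by one candidate, the rule defined
#' first — i.e. with the smallest priority number — wins. Deterministic by
#' the repository's unique-priority invariant.
#'
#' @param satisfied Non-empty list of satisfied [rule()] objects.
#' @return The winning rule.
#' @export
resolve_conflicts <- function(satisfied) {
  stopifnot(length(satisfied) >= 1)
  prios <- vapply(satisfied, function(r) r$priority, integer(1))
  satisfied[[which.min(prios)]]
}

#' Forward-chaining classification of candidate windows
#'
#' Data-driven inference over the fact database: in each pass, every
#' still-unlabelled candidate (in chronological order) is checked against
#' the rules; the first pass classifies all candidates whose rules need no
#' prior facts, and every new classification is appended to the fact
#' database so fact-dependent rules (getting ready for bed needs the
#' adjacent sleeping fact; eating may need the preceding cooking fact) can
#' fire in later passes. Iteration stops at a fixpoint — a pass that adds
#' no new fact — or after `max_iterations` passes (with a warning and the
#' partial result). The fact database is append-only: facts are never
#' retracted, so the run is monotone and terminates.
#'
#' @param candidates Candidate tibble (from [segment_candidates()]) with a
#'   `features` list-column (one [extract_features()] result per row).
#' @param repo A `rule_repository`.
#' @param db Prior fact database: an event tibble (possibly empty).
#' @param max_iterations Maximum number of passes.
#' @param verbose Print every rule evaluation (hand-trace auditing).
#' @return Classified event tibble (`source = "classified"`), one row per
#'   labelled candidate, with attributes `n_iterations` and
#'   `rule_id`.
#' @export
forward_chain <- function(candidates, repo, db = adl_events(),
                          max_iterations = 5, verbose = FALSE) {
  stopifnot(inherits(repo, "rule_repository"))
  n <- nrow(candidates)
  labels <- rep(NA_character_, n)
  rule_ids <- rep(NA_character_, n)
  facts <- db[, intersect(EVENT_COLUMNS, names(db)), drop = FALSE]
  ord <- order(candidates$start)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    added <- FALSE
    for (i in ord) {
      if (!is.na(labels[i])) next
      feats <- candidates$features[[i]]
      sat <- Filter(
        function(r) {
          ok <- rule_satisfied(r, feats, candidates$start[i], candidates$end[i], facts)
          if (verbose) {
            message(sprintf(
              "pass %d candidate %d [%s %g-%g]: rule %s %s",
              iter, i, feats$compartment, candidates$start[i], candidates$end[i],
              r$id, if (ok) "SATISFIED" else "failed"
            ))
          }
          ok
        },
        repo$rules
      )
      if (length(sat)) {
        win <- resolve_conflicts(sat)
        labels[i] <- win$target
        rule_ids[i] <- win$id
        facts <- rbind(facts, tibble::tibble(
          label = win$target,
          start = candidates$start[i], end = candidates$end[i],
          compartment = feats$compartment, source = "classified"
        ))
        facts <- facts[order(facts$start), , drop = FALSE]
        added <- TRUE
      }
    }
    if (!added) break
    if (iter >= max_iterations) {
      if (any(is.na(labels))) {
        warning("forward chaining stopped after ", max_iterations,
          " passes with unlabelled candidates remaining; returning partial result",
          call. = FALSE
        )
      }
      break
    }
  }
  hit <- !is.na(labels)
  out <- tibble::tibble(
    label = labels[hit],
    start = candidates$start[hit],
    end = candidates$end[hit],
    compartment = candidates$compartment[hit],
    source = "classified"
  )
  out <- out[order(out$start), , drop = FALSE]
  attr(out, "n_iterations") <- iter
  attr(out, "rule_id") <- rule_ids[hit][order(candidates$start[hit])]
  out
}

#' Classify sorted sensor streams into ADL events
#'
#' Convenience wrapper over the full classifier chain: candidate
#' segmentation, ambient-value-matrix assembly, feature extraction and
#' forward chaining.
#'
#' @param sorted Named list of sorted per-compartment packet tibbles.
#' @param layout A `home_layout`.
#' @param repo A `rule_repository` (default [default_rules()]).
#' @param start_date Calendar date mapped to absolute second 0.
#' @param db Prior fact database (event tibble).
#' @param ... Passed to [segment_candidates()], e.g. `gap_tolerance_s`.
#' @param verbose Print rule evaluations.
#' @return Classified event tibble.
#' @export
classify_events <- function(sorted, layout, repo = default_rules(),
                            start_date = NULL, db = adl_events(),
                            verbose = FALSE, ...) {
  cand <- segment_candidates(sorted, layout, start_date = start_date, ...)
  if (!nrow(cand)) {
    out <- adl_events(source = "classified")
    attr(out, "n_iterations") <- 0L
    return(out)
  }
  cand$features <- lapply(seq_len(nrow(cand)), function(i) {
    extract_features(build_matrix(cand[i, ], sorted, layout, start_date = start_date))
  })
  forward_chain(cand, repo, db = db, verbose = verbose)
}
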