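# Event-level evaluation: merge the protocol-device log with paper-logbook
# corrections, correlate classifier output with ground truth, and compute
# per-ADL and overall sensitivity/specificity.

#' Matching configuration
#'
#' @param mode `"event_overlap"` (greedy one-to-one event matching) or
#'   `"epoch"` (fixed-length epoch comparison).
#' @param overlap_threshold Required intersection as a fraction of the
#'   shorter event, in `(0, 1]`.
#' @param epoch_s Epoch length (s, multiple of 5) for epoch mode.
#' @return List of class `match_config`.
#' @export
match_config <- function(mode = c("event_overlap", "epoch"),
                         overlap_threshold = 0.5, epoch_s = 60) {
  mode <- match.arg(mode)
  stopifnot(
    overlap_threshold > 0, overlap_threshold <= 1,
    epoch_s %% sampling_period() == 0
  )
  structure(
    list(mode = mode, overlap_threshold = overlap_threshold, epoch_s = epoch_s),
    class = "match_config"
  )
}

#' Merge the protocol-device log with paper-logbook corrections
#'
#' Subjects recorded activities live with a switch device and noted
#' mistakes (wrongly flicked, forgotten or mistimed activities) in a paper
#' log book; the corrected ground truth superimposes the two. Corrections
#' are applied in file order. Operations: `add` (a forgotten event),
#' `delete` (a wrongly flicked switch), `relabel`, `retime`. `delete`,
#' `relabel` and `retime` reference the device event by exact
#' (`label`, `start`); referencing a non-existent event is a merge error,
#' and a correction that creates a same-label overlap violates the
#' ground-truth invariant and errors.
#'
#' @param device_log Event tibble (`source = "ground_truth"`).
#' @param corrections Tibble with columns `op`, `label`, `start` and,
#'   depending on the operation, `end`, `compartment`, `new_label`,
#'   `new_start`, `new_end`.
#' @return Merged, time-ordered ground-truth event tibble; corrected or
#'   added rows carry `provenance = "paper_logbook"`.
#' @export
merge_logs <- function(device_log, corrections = NULL) {
  log <- device_log
  if (!"provenance" %in% names(log)) log$provenance <- "device"
  if (is.null(corrections) || nrow(corrections) == 0) {
    validate_events(log, ground_truth = TRUE)
    return(log[order(log$start), , drop = FALSE])
  }
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    if (cr$op == "add") {
      log <- rbind(log, tibble::tibble(
        label = cr$label, start = cr$start, end = cr$end,
        compartment = cr$compartment, source = "ground_truth",
        provenance = "paper_logbook"
      ))
      next
    }
    hit <- which(log$label == cr$label & log$start == cr$start)
    if (!length(hit)) {
      stop_adlsense(
        "correction ", i, " (", cr$op, ") references a non-existent event: ",
        cr$label, " starting at ", cr$start,
        class = "adlsense_merge_error"
      )
    }
    hit <- hit[1]
    if (cr$op == "delete") {
      log <- log[-hit, , drop = FALSE]
    } else if (cr$op == "relabel") {
      log$label[hit] <- cr$new_label
      log$provenance[hit] <- "paper_logbook"
    } else if (cr$op == "retime") {
      log$start[hit] <- cr$new_start
      log$end[hit] <- cr$new_end
      log$provenance[hit] <- "paper_logbook"
    } else {
      stop_adlsense("unknown correction operation: ", cr$op,
        class = "adlsense_merge_error"
      )
    }
  }
  validate_events(log, ground_truth = TRUE)
  log[order(log$start), , drop = FALSE]
}

interval_intersection <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Correlate classifier output with the ground-truth protocol
#'
#' Event-overlap mode (default): greedy one-to-one matching in time
#' order. A truth event is a true positive for its label if an unmatched
#' same-label classified event overlaps it by at least the configured
#' fraction of the shorter event (earlier classified events are matched
#' first), otherwise a false negative; classified events left unmatched
#' are false positives. The one-vs-rest negative universe per label is
#' the set of truth events of other labels: those overlapped (at
#' threshold) by a classified event of this label are counted against the
#' true negatives. Epoch mode discretises the timeline into fixed epochs
#' labelled by majority coverage and compares per epoch.
#'
#' @param classified Classified event tibble.
#' @param truth Ground-truth event tibble.
#' @param config A [match_config()].
#' @return Confusion-count tibble: one row per ADL with `label`, `n`
#'   (performed), `tp`, `fn`, `fp`, `tn`.
#' @export
match_events <- function(classified, truth, config = match_config()) {
  validate_events(classified)
  validate_events(truth)
  if (config$mode == "epoch") {
    return(match_events_epoch(classified, truth, config))
  }
  thr <- config$overlap_threshold
  labels <- adl_labels()$label
  res <- lapply(labels, function(lab) {
    tr <- truth[truth$label == lab, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    cl <- classified[classified$label == lab, , drop = FALSE]
    cl <- cl[order(cl$start), , drop = FALSE]
    used <- rep(FALSE, nrow(cl))
    tp <- 0L
    for (i in seq_len(nrow(tr))) {
      inter <- interval_intersection(tr$start[i], tr$end[i], cl$start, cl$end)
      shorter <- pmin(tr$end[i] - tr$start[i], cl$end - cl$start)
      ok <- which(!used & inter >= thr * shorter & shorter > 0)
      if (length(ok)) {
        used[ok[1]] <- TRUE # greedy: earliest unmatched classified event
        tp <- tp + 1L
      }
    }
    fp <- sum(!used)
    # negatives: truth events of other labels; claimed if overlapped at
    # threshold by any classified event of this label
    other <- truth[truth$label != lab, , drop = FALSE]
    claimed <- 0L
    if (nrow(other) && nrow(cl)) {
      claimed <- sum(vapply(seq_len(nrow(other)), function(j) {
        inter <- interval_intersection(other$start[j], other$end[j], cl$start, cl$end)
        shorter <- pmin(other$end[j] - other$start[j], cl$end - cl$start)
        any(inter >= thr * shorter & shorter > 0)
      }, logical(1)))
    }
    tibble::tibble(
      label = lab, n = nrow(tr), tp = tp, fn = nrow(tr) - tp,
      fp = fp, tn = nrow(other) - claimed
    )
  })
  do.call(rbind, res)
}

match_events_epoch <- function(classified, truth, config) {
  ep <- config$epoch_s
  t_max <- max(c(truth$end, classified$end, 0))
  n_ep <- ceiling(t_max / ep)
  lab_of <- function(events) {
    out <- rep(NA_character_, n_ep)
    cover <- numeric(n_ep)
    for (i in order(events$start)) {
      lo <- floor(events$start[i] / ep) + 1
      hi <- min(n_ep, ceiling(events$end[i] / ep))
      if (lo > hi) next
      for (b in lo:hi) {
        cv <- interval_intersection(events$start[i], events$end[i], (b - 1) * ep, b * ep)
        if (cv > cover[b]) { # ties keep the earlier-starting event
          cover[b] <- cv
          out[b] <- events$label[i]
        }
      }
    }
    out
  }
  tl <- lab_of(truth)
  cl <- lab_of(classified)
  res <- lapply(adl_labels()$label, function(lab) {
    t_is <- !is.na(tl) & tl == lab
    c_is <- !is.na(cl) & cl == lab
    tibble::tibble(
      label = lab,
      n = sum(t_is), tp = sum(t_is & c_is), fn = sum(t_is & !c_is),
      fp = sum(!t_is & c_is), tn = sum(!t_is & !c_is)
    )
  })
  do.call(rbind, res)
}

#' Per-ADL sensitivity and specificity
#'
#' Sensitivity is the fraction of performed activities classified
#' correctly, `100 * TP / (TP + FN)`; specificity is the fraction of
#' non-instances correctly not attributed to the label,
#' `100 * TN / (TN + FP)`, one-vs-rest under the configured matching
#' mode. Both are rounded to two decimals. An empty denominator yields
#' `NA` (undefined), never zero.
#'
#' @param counts Confusion-count tibble from [match_events()].
#' @param label ADL label.
#' @return Percentage (2 dp) or `NA_real_`.
#' @export
sensitivity <- function(counts, label) {
  r <- counts[counts$label == label, , drop = FALSE]
  stopifnot(nrow(r) == 1)
  if (r$tp + r$fn == 0) {
    return(NA_real_)
  }
  round(100 * r$tp / (r$tp + r$fn), 2)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts, label) {
  r <- counts[counts$label == label, , drop = FALSE]
  stopifnot(nrow(r) == 1)
  if (r$tn + r$fp == 0) {
    return(NA_real_)
  }
  round(100 * r$tn / (r$tn + r$fp), 2)
}

#' Macro average of a per-ADL metric
#'
#' Unweighted arithmetic mean over the eight ADL, rounded to two
#' decimals — the aggregation that turns the per-ADL percentages into the
#' overall figures.
#'
#' @param values Numeric vector of 8 per-ADL percentages, named by label
#'   or in [adl_labels()] order.
#' @return Percentage (2 dp).
#' @export
#' @examples
#' macro_average(c(93.64, 94.07, 94.79, 92.38, 84.29, 87.78, 93.17, 90.06))
macro_average <- function(values) {
  labels <- adl_labels()$label
  if (!is.null(names(values))) {
    absent <- setdiff(labels, names(values))
    if (length(absent)) {
      stop_adlsense("missing per-ADL values for: ", paste(absent, collapse = ", "),
        class = "adlsense_validation_error"
      )
    }
    values <- values[labels]
  } else if (length(values) != length(labels)) {
    stop_adlsense("expected ", length(labels), " per-ADL values, got ", length(values),
      class = "adlsense_validation_error"
    )
  }
  if (anyNA(values)) {
    stop_adlsense("undefined per-ADL values for: ",
      paste(labels[is.na(values)], collapse = ", "),
      class = "adlsense_validation_error"
    )
  }
  unname(round(mean(values), 2))
}

#' Full per-ADL metrics table with grand totals
#'
#' One row per ADL (performed N, classified correctly, missed, false
#' positives, sensitivity %, specificity %) plus a `total` row with
#' summed counts and macro-averaged percentages.
#'
#' @param counts Confusion-count tibble from [match_events()].
#' @return Metrics tibble.
#' @export
metrics_table <- function(counts) {
  sens <- unname(vapply(counts$label, function(l) sensitivity(counts, l), numeric(1)))
  spec <- unname(vapply(counts$label, function(l) specificity(counts, l), numeric(1)))
  per <- tibble::tibble(
    label = counts$label,
    n = counts$n,
    classified_correctly = counts$tp,
    missed = counts$fn,
    false_positives = counts$fp,
    sensitivity = sens,
    specificity = spec
  )
  macro_or_na <- function(x) if (anyNA(x)) NA_real_ else macro_average(stats::setNames(x, counts$label))
  total <- tibble::tibble(
    label = "total",
    n = sum(per$n),
    classified_correctly = sum(per$classified_correctly),
    missed = sum(per$missed),
    false_positives = sum(per$false_positives),
    sensitivity = macro_or_na(sens),
    specificity = macro_or_na(spec)
  )
  rbind(per, total)
}
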