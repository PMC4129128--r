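# Labelled activity intervals. Events are tibbles with absolute times in
# seconds measured from 00:00 of day 1 of a recording, so intervals may
# cross midnight without special casing; helpers convert to calendar form.

EVENT_COLUMNS <- c("label", "start", "end", "compartment", "source")

#' Construct an event table
#'
#' An event is one labelled activity interval. Both ground-truth protocol
#' entries and classifier output use the same shape so they can be compared
#' directly.
#'
#' @param label ADL labels (see [adl_labels()]).
#' @param start,end Absolute times in seconds from day 1, 00:00; `start < end`.
#' @param compartment Room name.
#' @param source `"ground_truth"` or `"classified"`.
#' @param provenance Optional, for ground truth: `"device"` or
#'   `"paper_logbook"`.
#' @return Tibble with the event columns.
#' @export
adl_events <- function(label = character(), start = numeric(), end = numeric(),
                       compartment = character(), source = "ground_truth",
                       provenance = NULL) {
  ev <- tibble::tibble(
    label = as.character(label),
    start = as.numeric(start),
    end = as.numeric(end),
    compartment = as.character(compartment),
    source = rep_len(as.character(source), length(label))
  )
  if (!is.null(provenance)) ev$provenance <- rep_len(as.character(provenance), nrow(ev))
  validate_events(ev)
  ev
}

#' Validate event invariants
#'
#' Checks labels against the eight-ADL vocabulary, positive durations and —
#' for ground truth — that no two events of the same label overlap.
#'
#' @param events Event tibble.
#' @param ground_truth If `TRUE`, additionally enforce the same-label
#'   non-overlap invariant of a protocol log.
#' @return `events` invisibly, or an error describing the violation.
#' @export
validate_events <- function(events, ground_truth = FALSE) {
  if (nrow(events) == 0) {
    return(invisible(events))
  }
  bad <- !is_adl_label(events$label)
  if (any(bad)) {
    stop_adlsense("unknown ADL label: ", paste(unique(events$label[bad]), collapse = ", "),
      class = "adlsense_validation_error"
    )
  }
  if (any(events$start >= events$end)) {
    i <- which(events$start >= events$end)[1]
    stop_adlsense("event ", i, " (", events$label[i], ") has start >= end",
      class = "adlsense_validation_error"
    )
  }
  if (ground_truth) {
    ov <- same_label_overlaps(events)
    if (nrow(ov)) {
      stop_adlsense(
        "ground-truth log has overlapping events of the same label: ",
        ov$label[1], " at [", ov$start1[1], ", ", ov$end1[1], ") and [",
        ov$start2[1], ", ", ov$end2[1], ")",
        class = "adlsense_overlap_error"
      )
    }
  }
  invisible(events)
}

# all pairs of same-label events that overlap in time
same_label_overlaps <- function(events) {
  out <- list()
  for (lab in unique(events$label)) {
    e <- events[events$label == lab, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    hit <- which(e$start[-1] < e$end[-nrow(e)])
    if (length(hit)) {
      out[[lab]] <- tibble::tibble(
        label = lab,
        start1 = e$start[hit], end1 = e$end[hit],
        start2 = e$start[hit + 1], end2 = e$end[hit + 1]
      )
    }
  }
  if (length(out)) do.call(rbind, out) else tibble::tibble(
    label = character(), start1 = numeric(), end1 = numeric(),
    start2 = numeric(), end2 = numeric()
  )
}

#' Read or write event logs as CSV
#'
#' Column schema: `label,start,end,compartment,source` plus an optional
#' `provenance` column for ground-truth logs.
#'
#' @param events Event tibble.
#' @param path File path.
#' @param ground_truth Validate the same-label non-overlap invariant on read.
#' @return `read_events()` returns an event tibble.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, ground_truth = FALSE) {
  ev <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing)) {
    stop_adlsense("event file ", path, " lacks columns: ", paste(missing, collapse = ", "),
      class = "adlsense_validation_error"
    )
  }
  validate_events(ev, ground_truth = ground_truth)
  ev
}
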