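#' adlsense: ambient-sensor recognition of activities of daily living
#'
#' Tools for recognising eight activities of daily living (ADL) in a
#' single-occupant home instrumented with small wireless ambient sensor
#' boxes (temperature, humidity, luminance, passive-infrared motion,
#' acceleration), sampled at 0.2 Hz. The package covers the whole chain:
#' a packet codec with even-parity error handling, a compartment-wise
#' bucket sort followed by a chronological radix sort, a declarative
#' rulebase evaluated by a forward-chaining inference engine, event-level
#' sensitivity/specificity scoring, activity maps, and a synthetic
#' smart-home simulator used as a closed-loop benchmark.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# ADL vocabulary
# ---------------------------------------------------------------------------

#' The eight recognised activities of daily living
#'
#' Returns the fixed label set used throughout the package, together with
#' short include/exclude definitions. The labels are mutually exclusive:
#' grooming covers the whole personal-hygiene block (shower, toileting,
#' shaving, ...) performed as one activity, while toileting is the simple
#' visit with hand washing only; sleeping includes naps but excludes lying
#' down awake; eating covers proper meals (including delivered food) but not
#' snacking.
#'
#' @return A tibble with columns `label`, `includes`, `excludes`.
#' @export
#' @examples
#' adl_labels()$label
adl_labels <- function() {
  tibble::tibble(
    label = c(
      "sleeping", "grooming", "toileting", "getting_ready_for_bed",
      "cooking", "eating", "watching_tv", "seated_activity"
    ),
    includes = c(
      "night rest and naps, in bed or on the couch",
      "full personal hygiene block: shower, toileting, shaving, brushing teeth, styling",
      "simple toileting with hand washing",
      "personal hygiene immediately before bedtime",
      "preparing food in the kitchen",
      "having a meal, including delivered food",
      "watching TV with main focus on the TV",
      "sitting while reading, puzzling, crafting or listening to the radio"
    ),
    excludes = c(
      "lying down awake for recovery",
      "simple toileting and hand washing alone",
      "other or additional personal hygiene",
      "pre-bedtime rituals other than hygiene",
      "trivial preparation such as tea, coffee or cutting delivered pizza",
      "snacking or having just a drink",
      "other activities while the TV happens to be on",
      "taking a nap"
    )
  )
}

#' @rdname adl_labels
#' @export
is_adl_label <- function(x) x %in% adl_labels()$label

#' The five ambient sensor channels
#'
#' Every sensor box carries the same five sensors. Motion is a binary
#' passive-infrared (PIR) detector; acceleration is stored as a single
#' magnitude because the classifier only uses it for transient detection
#' (fridge door, flush handle).
#'
#' @return A tibble with columns `channel` and `unit`.
#' @export
sensor_channels <- function() {
  tibble::tibble(
    channel = c("temperature", "humidity", "luminance", "motion", "acceleration"),
    unit = c("°C", "g/m³", "lx", "binary", "m/s²")
  )
}

# ---------------------------------------------------------------------------
# Home layout
# ---------------------------------------------------------------------------

#' Describe an instrumented home
#'
#' A layout is the ordered list of compartments (rooms) plus the sensor
#' boxes installed in them. Wall boxes sit at about 2 m height facing the
#' room; two appliance boxes are special: one on the kitchen fridge door
#' and one on the bathroom flush handle.
#'
#' @param compartments Character vector of room names (must contain
#'   `"kitchen"` and `"bathroom"`).
#' @param boxes A data frame with columns `node_id` (integer), `compartment`
#'   and `placement` (one of `"wall"`, `"fridge_door"`, `"flush_handle"`).
#' @return An object of class `home_layout`.
#' @seealso [validate_layout()], [default_layout()]
#' @export
home_layout <- function(compartments, boxes) {
  boxes <- tibble::as_tibble(boxes)
  stopifnot(all(c("node_id", "compartment", "placement") %in% names(boxes)))
  boxes$node_id <- as.integer(boxes$node_id)
  layout <- structure(
    list(compartments = as.character(compartments), boxes = boxes),
    class = "home_layout"
  )
  layout
}

#' @export
print.home_layout <- function(x, ...) {
  cat("<home_layout> ", length(x$compartments), " compartments, ",
    nrow(x$boxes), " sensor boxes\n",
    sep = ""
  )
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  invisible(x)
}

#' Default two-bedroom apartment layout
#'
#' Five compartments, one wall box each, plus the fridge-door and
#' flush-handle appliance boxes (seven boxes in total).
#'
#' @return A `home_layout`.
#' @export
default_layout <- function() {
  home_layout(
    compartments = c("bedroom", "bedroom2", "living_room", "kitchen", "bathroom"),
    boxes = tibble::tibble(
      node_id = 1:7,
      compartment = c(
        "bedroom", "bedroom2", "living_room", "kitchen", "bathroom",
        "kitchen", "bathroom"
      ),
      placement = c(rep("wall", 5), "fridge_door", "flush_handle")
    )
  )
}

#' Check a home layout against its structural invariants
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the layout is valid. Checked invariants: node ids unique; kitchen
#' and bathroom present; at least one wall box per compartment; every box
#' placed in a declared compartment; fridge-door boxes only in the kitchen
#' and flush-handle boxes only in the bathroom.
#'
#' @param layout A `home_layout`.
#' @return Character vector of human-readable violations (empty if valid).
#' @export
#' @examples
#' validate_layout(default_layout())
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "home_layout"))
  v <- character()
  b <- layout$boxes
  if (anyDuplicated(b$node_id)) {
    dup <- unique(b$node_id[duplicated(b$node_id)])
    v <- c(v, paste0("duplicate node_id: ", paste(dup, collapse = ", ")))
  }
  for (room in c("kitchen", "bathroom")) {
    if (!room %in% layout$compartments) {
      v <- c(v, paste0("required compartment missing: ", room))
    }
  }
  unknown <- setdiff(unique(b$compartment), layout$compartments)
  if (length(unknown)) {
    v <- c(v, paste0("box placed in undeclared compartment: ", paste(unknown, collapse = ", ")))
  }
  bad_place <- setdiff(unique(b$placement), c("wall", "fridge_door", "flush_handle"))
  if (length(bad_place)) {
    v <- c(v, paste0("unknown placement: ", paste(bad_place, collapse = ", ")))
  }
  for (room in layout$compartments) {
    if (!any(b$compartment == room & b$placement == "wall")) {
      v <- c(v, paste0("compartment without wall box: ", room))
    }
  }
  off <- b$placement == "fridge_door" & b$compartment != "kitchen"
  if (any(off)) v <- c(v, "fridge_door box outside the kitchen")
  off <- b$placement == "flush_handle" & b$compartment != "bathroom"
  if (any(off)) v <- c(v, "flush_handle box outside the bathroom")
  v
}

#' Map node ids to compartments
#'
#' @param layout A `home_layout`.
#' @return Named character vector, names are node ids.
#' @keywords internal
node_compartment_map <- function(layout) {
  stats::setNames(layout$boxes$compartment, layout$boxes$node_id)
}

# ---------------------------------------------------------------------------
# Layout JSON round trip
# ---------------------------------------------------------------------------

#' Read or write a home layout as JSON
#'
#' The JSON form has two members: `compartments` (array of names) and
#' `boxes` (array of `{node_id, compartment, placement}` records).
#'
#' @param path File path.
#' @param layout A `home_layout`.
#' @return `read_layout()` returns a `home_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  x <- jsonlite::fromJSON(path)
  layout <- home_layout(x$compartments, x$boxes)
  v <- validate_layout(layout)
  if (length(v)) {
    stop_adlsense("invalid layout in ", path, ":\n  ", paste(v, collapse = "\n  "),
      class = "adlsense_validation_error"
    )
  }
  layout
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "home_layout"))
  jsonlite::write_json(
    list(compartments = layout$compartments, boxes = layout$boxes),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

# ---------------------------------------------------------------------------
# Shared error helper + time helpers
# ---------------------------------------------------------------------------

#' Signal a classed package error
#' @noRd
stop_adlsense <- function(..., class = "adlsense_error") {
  stop(structure(
    class = c(class, "adlsense_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Sampling period of the sensor boxes, in seconds (0.2 Hz)
#' @export
sampling_period <- function() 5L

#' Number of packets one box emits per full day at 0.2 Hz
#' @export
packets_per_day <- function() 86400L %/% sampling_period() # 17280

# Absolute seconds (since day 0, 00:00) <-> (date, seconds-of-day)
abs_to_date <- function(t, start_date) start_date + floor(t / 86400)
abs_to_tod <- function(t) as.integer(t %% 86400)
datetod_to_abs <- function(date, tod, start_date) {
  as.numeric(date - start_date) * 86400 + as.numeric(tod)
}
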