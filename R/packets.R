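# Data packets: one 0.2 Hz transmission from one sensor box.
#
# A packet carries a handshake word (timestamp as seconds-of-day on the 5 s
# grid, calendar date, node number, supply voltage, status word) plus the
# five ambient values. On the wire each record ends with an even-parity bit
# computed over the UTF-8 bytes of the serialised payload.

PACKET_COLUMNS <- c(
  "node_id", "date", "timestamp", "supply_voltage", "status_word",
  "temperature", "humidity", "luminance", "motion", "acceleration"
)

#' Construct a packet table
#'
#' Packets are plain tibbles with one row per transmission. `data_packets()`
#' validates the structural invariants: timestamps in `[0, 86400)` on the
#' 5 s sampling grid, binary motion, non-negative luminance and acceleration
#' magnitude.
#'
#' @param node_id,date,timestamp,supply_voltage,status_word Handshake fields
#'   (`date` a `Date`, `timestamp` integer seconds-of-day, multiple of 5).
#' @param temperature,humidity,luminance,motion,acceleration The five
#'   ambient values (°C, g/m³, lx, 0/1, m/s²).
#' @param parity_ok Logical; decode status. Defaults to `TRUE` for locally
#'   constructed packets.
#' @return Tibble with the packet columns plus `parity_ok`.
#' @export
data_packets <- function(node_id, date, timestamp, supply_voltage = 3.0,
                         status_word = 0L, temperature = 0, humidity = 0,
                         luminance = 0, motion = 0L, acceleration = 0,
                         parity_ok = TRUE) {
  p <- tibble::tibble(
    node_id = as.integer(node_id),
    date = as.Date(date),
    timestamp = as.integer(timestamp),
    supply_voltage = as.numeric(supply_voltage),
    status_word = as.integer(status_word),
    temperature = as.numeric(temperature),
    humidity = as.numeric(humidity),
    luminance = as.numeric(luminance),
    motion = as.integer(motion),
    acceleration = as.numeric(acceleration),
    parity_ok = as.logical(parity_ok)
  )
  validate_packets(p)
  p
}

#' Validate packet invariants
#'
#' @param packets A packet tibble.
#' @return `packets`, invisibly; errors name the offending field.
#' @export
validate_packets <- function(packets) {
  check <- function(ok, field, why) {
    if (!all(ok)) {
      stop_adlsense(
        "invalid packet field '", field, "': ", why,
        " (first offending row ", which(!ok)[1], ")",
        class = "adlsense_validation_error"
      )
    }
  }
  check(packets$timestamp >= 0 & packets$timestamp < 86400, "timestamp", "must lie in [0, 86400)")
  check(packets$timestamp %% sampling_period() == 0, "timestamp", "must sit on the 5 s sampling grid")
  check(packets$motion %in% c(0L, 1L), "motion", "PIR output is binary")
  check(packets$luminance >= 0, "luminance", "must be non-negative")
  check(packets$acceleration >= 0, "acceleration", "magnitude must be non-negative")
  check(!is.na(packets$node_id), "node_id", "must be present")
  invisible(packets)
}

# ---------------------------------------------------------------------------
# Even parity over serialised payload bytes
# ---------------------------------------------------------------------------

# popcount lookup for bytes 0..255
.bit_lut <- colSums(matrix(as.integer(sapply(0:255, function(b) intToBits(b)[1:8])), nrow = 8))

#' Even-parity bit of a string's UTF-8 bytes
#'
#' The parity bit is chosen so that the total number of 1-bits in payload
#' plus parity bit is even. Flipping any single payload bit is therefore
#' always detected; flipping two bits within the same parity scope is never
#' detected (the classic even-parity blind spot).
#'
#' @param payload Character vector.
#' @return Integer vector of 0/1 parity bits.
#' @export
parity_bit <- function(payload) {
  vapply(
    payload,
    function(s) as.integer(sum(.bit_lut[as.integer(charToRaw(s)) + 1L]) %% 2),
    integer(1),
    USE.NAMES = FALSE
  )
}

# Lossless numeric formatting: %.17g survives an as.numeric round trip.
fmt_num <- function(x) sprintf("%.17g", x)

packet_payload_csv <- function(packets) {
  paste(
    packets$node_id, format(packets$date, "%Y-%m-%d"), packets$timestamp,
    fmt_num(packets$supply_voltage), packets$status_word,
    fmt_num(packets$temperature), fmt_num(packets$humidity),
    fmt_num(packets$luminance), packets$motion, fmt_num(packets$acceleration),
    sep = ","
  )
}

packet_payload_jsonl <- function(packets) {
  sprintf(
    paste0(
      '{"node_id":%d,"date":"%s","timestamp":%d,"supply_voltage":%s,',
      '"status_word":%d,"temperature":%s,"humidity":%s,"luminance":%s,',
      '"motion":%d,"acceleration":%s}'
    ),
    packets$node_id, format(packets$date, "%Y-%m-%d"), packets$timestamp,
    fmt_num(packets$supply_voltage), packets$status_word,
    fmt_num(packets$temperature), fmt_num(packets$humidity),
    fmt_num(packets$luminance), packets$motion, fmt_num(packets$acceleration)
  )
}

#' Serialise packets to text records with an even-parity bit
#'
#' Two dialects are supported: `"csv"` (fixed column order, one record per
#' line, parity bit appended as the last column) and `"jsonl"` (one JSON
#' object per line with a `"parity"` member). Both round-trip losslessly
#' through [decode_packets()].
#'
#' @param packets Valid packet tibble (see [data_packets()]).
#' @param dialect `"csv"` or `"jsonl"`.
#' @return Character vector, one record per packet (no header).
#' @export
encode_packets <- function(packets, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  validate_packets(packets)
  if (dialect == "csv") {
    payload <- packet_payload_csv(packets)
    paste0(payload, ",", parity_bit(payload))
  } else {
    payload <- packet_payload_jsonl(packets)
    sprintf('{"payload":%s,"parity":%d}', payload, parity_bit(payload))
  }
}

#' Decode serialised packet records
#'
#' Records whose even-parity check fails are returned with
#' `parity_ok = FALSE`, never silently dropped: transmission-integrity
#' accounting downstream needs to see them. Structurally unparseable
#' records raise a decode error naming the line.
#'
#' @param records Character vector of records (as from [encode_packets()]).
#' @param dialect `"csv"` or `"jsonl"`.
#' @return Packet tibble with `parity_ok` set from the parity check.
#' @export
decode_packets <- function(records, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (length(records) == 0) {
    return(data_packets(
      integer(), as.Date(character()), integer(),
      numeric(), integer(), numeric(), numeric(), numeric(), integer(), numeric(),
      logical()
    ))
  }
  if (dialect == "csv") {
    parts <- strsplit(records, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 11L)
    if (length(bad)) {
      stop_adlsense("unparseable packet record at line ", bad[1],
        ": expected 11 comma-separated fields, got ", length(parts[[bad[1]]]),
        class = "adlsense_decode_error"
      )
    }
    m <- matrix(unlist(parts), nrow = 11L)
    payload <- vapply(parts, function(p) paste(p[1:10], collapse = ","), character(1))
    stored <- suppressWarnings(as.integer(m[11L, ]))
    fields <- list(
      node_id = m[1, ], date = m[2, ], timestamp = m[3, ],
      supply_voltage = m[4, ], status_word = m[5, ], temperature = m[6, ],
      humidity = m[7, ], luminance = m[8, ], motion = m[9, ],
      acceleration = m[10, ]
    )
  } else {
    parsed <- lapply(seq_along(records), function(i) {
      x <- tryCatch(jsonlite::fromJSON(records[i]), error = function(e) NULL)
      if (is.null(x) || is.null(x$payload) || is.null(x$parity)) {
        stop_adlsense("unparseable packet record at line ", i,
          class = "adlsense_decode_error"
        )
      }
      x
    })
    # parity is computed over the canonical payload serialisation
    payload <- vapply(
      parsed,
      function(x) {
        p <- x$payload
        sprintf(
          paste0(
            '{"node_id":%d,"date":"%s","timestamp":%d,"supply_voltage":%s,',
            '"status_word":%d,"temperature":%s,"humidity":%s,"luminance":%s,',
            '"motion":%d,"acceleration":%s}'
          ),
          as.integer(p$node_id), p$date, as.integer(p$timestamp),
          fmt_num(as.numeric(p$supply_voltage)), as.integer(p$status_word),
          fmt_num(as.numeric(p$temperature)), fmt_num(as.numeric(p$humidity)),
          fmt_num(as.numeric(p$luminance)), as.integer(p$motion),
          fmt_num(as.numeric(p$acceleration))
        )
      },
      character(1)
    )
    stored <- vapply(parsed, function(x) as.integer(x$parity), integer(1))
    get_field <- function(name) vapply(parsed, function(x) as.character(x$payload[[name]]), character(1))
    fields <- lapply(stats::setNames(nm = PACKET_COLUMNS), get_field)
  }
  ok <- !is.na(stored) & ((parity_bit(payload) + stored) %% 2L == 0L)
  tibble::tibble(
    node_id = as.integer(fields$node_id),
    date = as.Date(fields$date),
    timestamp = as.integer(fields$timestamp),
    supply_voltage = as.numeric(fields$supply_voltage),
    status_word = as.integer(fields$status_word),
    temperature = as.numeric(fields$temperature),
    humidity = as.numeric(fields$humidity),
    luminance = as.numeric(fields$luminance),
    motion = as.integer(fields$motion),
    acceleration = as.numeric(fields$acceleration),
    parity_ok = ok
  )
}

#' Read and write packet files
#'
#' `*.packets.csv` files carry a fixed documented header and one record per
#' packet including the trailing parity column; `*.packets.jsonl` files
#' carry one JSON record per line.
#'
#' @param packets Packet tibble.
#' @param path File path; the dialect is inferred from the extension
#'   (`.csv` vs `.jsonl`) unless given.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `write_packets()` returns `path` invisibly; `read_packets()`
#'   returns a packet tibble (with `parity_ok` from the parity check).
#' @export
write_packets <- function(packets, path, dialect = NULL) {
  dialect <- dialect %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  rec <- encode_packets(packets, dialect)
  if (dialect == "csv") {
    rec <- c(paste(c(PACKET_COLUMNS, "parity"), collapse = ","), rec)
  }
  writeLines(rec, path)
  invisible(path)
}

#' @rdname write_packets
#' @export
read_packets <- function(path, dialect = NULL) {
  dialect <- dialect %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  rec <- readLines(path)
  if (dialect == "csv" && length(rec) && startsWith(rec[1], "node_id,")) {
    rec <- rec[-1]
  }
  decode_packets(rec, dialect)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
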