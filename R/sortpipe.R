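# Preprocessing chain: packets are bijectively matched to their origin
# compartment by a one-pass bucket sort, then each bucket is lined up
# chronologically by a least-significant-digit radix sort over a
# five-component intra-day time key (second-of-minute, minute, hour,
# day-of-month, month). Both stages are stable and run in linear time;
# neither calls a comparison sort.

#' Partition packets into per-compartment buckets
#'
#' One stable pass: each packet is routed to the bucket of the compartment
#' its node belongs to, preserving relative arrival order within each
#' bucket. Every declared compartment gets a bucket, possibly empty.
#'
#' @param packets Packet tibble.
#' @param layout A `home_layout` (defines the node-to-compartment map).
#' @return Named list of packet tibbles, one per compartment, in layout
#'   order.
#' @export
bucket_sort <- function(packets, layout) {
  map <- node_compartment_map(layout)
  comp <- unname(map[as.character(packets$node_id)])
  if (anyNA(comp)) {
    i <- which(is.na(comp))[1]
    stop_adlsense(
      "cannot route packet ", i, ": node_id ", packets$node_id[i],
      " is not in the layout",
      class = "adlsense_routing_error"
    )
  }
  f <- factor(comp, levels = layout$compartments)
  idx <- split(seq_len(nrow(packets)), f) # stable hash partition
  lapply(idx, function(i) packets[i, , drop = FALSE])
}

# one stable counting pass: reorder `ord` by `digit[ord]` (values 0-based,
# < nbins), preserving relative order within equal digits
counting_pass <- function(ord, digit, nbins) {
  f <- factor(digit[ord], levels = 0:(nbins - 1))
  unlist(split(ord, f), use.names = FALSE)
}

#' Sort one bucket chronologically with an LSD radix sort
#'
#' Five stable counting passes over the time key, least significant digit
#' first: second-of-minute, minute, hour, day-of-month, month. The result
#' is ascending by (date, seconds-of-day) and stable (packets with equal
#' timestamps keep their relative order). Streams are assumed to lie
#' within one calendar year.
#'
#' @param bucket Packet tibble (typically one element of [bucket_sort()]).
#' @return The same packets, chronologically ordered.
#' @export
radix_sort_chronological <- function(bucket) {
  n <- nrow(bucket)
  if (n < 2) {
    return(bucket)
  }
  lt <- as.POSIXlt(bucket$date)
  ts <- bucket$timestamp
  digits <- list(
    list(d = ts %% 60L, k = 60L), # second of minute
    list(d = (ts %/% 60L) %% 60L, k = 60L), # minute
    list(d = ts %/% 3600L, k = 24L), # hour
    list(d = lt$mday - 1L, k = 31L), # day of month
    list(d = lt$mon, k = 12L) # month
  )
  ord <- seq_len(n)
  for (dg in digits) {
    ord <- counting_pass(ord, dg$d, dg$k)
  }
  bucket[ord, , drop = FALSE]
}

#' Run the full sorting pipeline
#'
#' Excludes packets whose parity check failed (they are accounted for in
#' the integrity report, not silently dropped into the analysis), bucket
#' sorts the remainder by compartment and radix sorts each bucket
#' chronologically.
#'
#' @param packets Packet tibble.
#' @param layout A `home_layout`.
#' @return List with `sorted` (named list of chronologically ordered
#'   per-compartment packet tibbles) and `n_corrupted` (count of excluded
#'   parity failures).
#' @export
sort_pipeline <- function(packets, layout) {
  corrupted <- !packets$parity_ok
  clean <- packets[!corrupted, , drop = FALSE]
  buckets <- bucket_sort(clean, layout)
  list(
    sorted = lapply(buckets, radix_sort_chronological),
    n_corrupted = sum(corrupted)
  )
}

#' Transmission-integrity accounting
#'
#' @param expected Number of packets sent (or expected from the sampling
#'   arithmetic: boxes x 17,280/day x days).
#' @param captured_packets Packet tibble of received packets; rows with
#'   `parity_ok = FALSE` count as corrupted. Alternatively a single count
#'   of correctly captured packets (then `corrupted` defaults to 0).
#' @return One-row tibble: `captured`, `lost`, `corrupted`,
#'   `reliability` (percent, 2 dp) and `lost_share` (percent, 2 dp), with
#'   `reliability = 100 * captured / (captured + lost)`.
#' @export
#' @examples
#' integrity_report(33939441 + 160269, 33939441)
integrity_report <- function(expected, captured_packets) {
  if (is.data.frame(captured_packets)) {
    corrupted <- sum(!captured_packets$parity_ok)
    captured <- nrow(captured_packets) - corrupted
  } else {
    corrupted <- 0L
    captured <- as.numeric(captured_packets)
  }
  if (expected < captured + corrupted) {
    stop_adlsense("accounting error: captured (", captured + corrupted,
      ") exceeds expected (", expected, ")",
      class = "adlsense_accounting_error"
    )
  }
  lost <- expected - captured - corrupted
  denom <- captured + lost
  tibble::tibble(
    captured = captured,
    lost = lost,
    corrupted = corrupted,
    reliability = if (denom > 0) round(100 * captured / denom, 2) else NA_real_,
    lost_share = if (denom > 0) round(100 * lost / denom, 2) else NA_real_
  )
}
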