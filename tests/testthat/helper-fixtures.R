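# Shared fixtures, built in code at test time.

# minimal valid home: three rooms, wall boxes + both appliance boxes
tiny_layout <- function() {
  home_layout(
    compartments = c("bedroom", "kitchen", "bathroom"),
    boxes = tibble::tibble(
      node_id = 1:5,
      compartment = c("bedroom", "kitchen", "bathroom", "kitchen", "bathroom"),
      placement = c("wall", "wall", "wall", "fridge_door", "flush_handle")
    )
  )
}

# n random valid packets (uniform nodes, dates, on-grid timestamps)
random_packets <- function(n, seed = 1, nodes = 1:7, n_dates = 3) {
  withr::with_seed(seed, data_packets(
    node_id = nodes[sample.int(length(nodes), n, replace = TRUE)],
    date = as.Date("2014-01-01") + sample.int(n_dates, n, replace = TRUE) - 1,
    timestamp = sample.int(17280, n, replace = TRUE) * 5L - 5L,
    supply_voltage = round(stats::runif(n, 2.4, 3.2), 3),
    status_word = sample.int(256, n, replace = TRUE) - 1L,
    temperature = round(stats::rnorm(n, 21, 2), 4),
    humidity = round(stats::runif(n, 5, 12), 4),
    luminance = round(stats::runif(n, 0, 500), 3),
    motion = sample(0:1, n, replace = TRUE),
    acceleration = round(stats::runif(n, 0, 4), 4)
  ))
}

# an ambient_matrix built directly from channel vectors for one wall box
# (node 1) and optionally one appliance box (node 2)
matrix_fixture <- function(start, end, compartment = "bathroom",
                           temperature = NULL, humidity = NULL,
                           luminance = NULL, motion = NULL,
                           acceleration2 = NULL) {
  times <- seq(start, end - 5, by = 5)
  nT <- length(times)
  dflt <- function(x, v) if (is.null(x)) rep(v, nT) else x
  boxes <- tibble::tibble(
    node_id = 1L, compartment = compartment, placement = "wall"
  )
  rows <- list(
    node1.temperature = dflt(temperature, 21),
    node1.humidity = dflt(humidity, 8),
    node1.luminance = dflt(luminance, 100),
    node1.motion = dflt(motion, 1),
    node1.acceleration = rep(0, nT)
  )
  if (!is.null(acceleration2)) {
    boxes <- rbind(boxes, tibble::tibble(
      node_id = 2L, compartment = compartment,
      placement = if (compartment == "kitchen") "fridge_door" else "flush_handle"
    ))
    rows <- c(rows, list(
      node2.temperature = dflt(temperature, 21),
      node2.humidity = dflt(humidity, 8),
      node2.luminance = dflt(luminance, 100),
      node2.motion = dflt(motion, 1),
      node2.acceleration = acceleration2
    ))
  }
  structure(
    list(
      values = do.call(rbind, rows), times = times,
      window = c(start = start, end = end),
      compartment = compartment, boxes = boxes
    ),
    class = "ambient_matrix"
  )
}

# a hand-built candidate row with injected features, for engine hand-traces
candidate_fixture <- function(start, end, compartment, ...) {
  feats <- structure(
    utils::modifyList(
      list(
        duration_s = end - start, compartment = compartment,
        motion_density = 1, delta_temperature = 0, delta_humidity = 0,
        abs_delta_temperature = 0, abs_delta_humidity = 0,
        range_luminance = 0, mean_luminance = 100, n_transients = 0,
        tod_start = start %% 86400, tod_mid = ((start + end) / 2) %% 86400
      ),
      list(...)
    ),
    class = "adl_features"
  )
  tibble::tibble(
    compartment = compartment, start = start, end = end,
    features = list(feats)
  )
}
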