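# Segmentation, matrices and features operate on small hand-built streams;
# engine behaviour is hand-traced on candidates with injected features.

# sorted-streams fixture: one bathroom wall box (node 3) + flush box (node 5)
# with motion active at the given absolute times
motion_stream <- function(active_times, node = 3L, compartment = "bathroom",
                          t_all = seq(0, 86400 - 5, by = 5)) {
  tibble::tibble(
    node_id = node,
    date = as.Date("2014-01-01") + t_all %/% 86400,
    timestamp = as.integer(t_all %% 86400),
    supply_voltage = 3, status_word = 0L,
    temperature = 21, humidity = 8, luminance = 100,
    motion = as.integer(t_all %in% active_times),
    acceleration = 0,
    parity_ok = TRUE
  )
}

test_that("no motion yields no candidates", {
  sorted <- list(bathroom = motion_stream(numeric(0)))
  cand <- segment_candidates(sorted, tiny_layout(), start_date = as.Date("2014-01-01"))
  expect_identical(nrow(cand), 0L)
})

test_that("a continuous motion block becomes exactly one covering candidate", {
  block <- seq(36000, 37195, by = 5) # 20 min
  sorted <- list(bathroom = motion_stream(block))
  cand <- segment_candidates(sorted, tiny_layout(), start_date = as.Date("2014-01-01"))
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$compartment, "bathroom")
  expect_equal(cand$start, 36000)
  expect_equal(cand$end, 37200)
})

test_that("gaps below the tolerance merge, larger gaps split, short episodes drop", {
  b1 <- seq(36000, 36295, by = 5)
  b2_near <- seq(36295 + 90, 36685, by = 5) # 90 s gap: merged
  sorted <- list(bathroom = motion_stream(c(b1, b2_near)))
  cand <- segment_candidates(sorted, tiny_layout(), start_date = as.Date("2014-01-01"))
  expect_identical(nrow(cand), 1L)

  b2_far <- seq(36300 + 150, 36800, by = 5) # 150 s gap: split
  sorted <- list(bathroom = motion_stream(c(b1, b2_far)))
  cand <- segment_candidates(sorted, tiny_layout(), start_date = as.Date("2014-01-01"))
  expect_identical(nrow(cand), 2L)

  blip <- c(40000, 40005) # 10 s episode: below the 60 s minimum
  sorted <- list(bathroom = motion_stream(blip))
  cand <- segment_candidates(sorted, tiny_layout(), start_date = as.Date("2014-01-01"))
  expect_identical(nrow(cand), 0L)
})

test_that("the ambient value matrix carries wall plus appliance channels", {
  lay <- tiny_layout()
  t_all <- seq(0, 86400 - 5, by = 5)
  sorted <- list(
    bathroom = rbind(
      motion_stream(seq(36000, 36595, by = 5), node = 3L),
      motion_stream(numeric(0), node = 5L)
    ),
    bedroom = motion_stream(numeric(0), node = 1L, compartment = "bedroom")
  )
  win <- tibble::tibble(compartment = "bathroom", start = 36000, end = 36600)
  m <- build_matrix(win, sorted, lay, start_date = as.Date("2014-01-01"))
  expect_identical(nrow(m$values), 10L) # 2 boxes x 5 channels
  expect_identical(ncol(m$values), 120L)
  expect_true("node5.acceleration" %in% rownames(m$values))

  win_bed <- tibble::tibble(compartment = "bedroom", start = 36000, end = 36600)
  m_bed <- build_matrix(win_bed, sorted, lay, start_date = as.Date("2014-01-01"))
  expect_identical(nrow(m_bed$values), 5L) # wall box only

  # a window lying entirely inside a packet-loss gap has no samples
  lost <- sorted
  lost$bathroom <- lost$bathroom[lost$bathroom$timestamp < 30000, ]
  expect_error(
    build_matrix(win, lost, lay, start_date = as.Date("2014-01-01")),
    class = "adlsense_empty_matrix_error"
  )
})

test_that("missing samples are masked, not interpolated", {
  lay <- tiny_layout()
  s <- motion_stream(seq(36000, 36595, by = 5), node = 3L)
  s <- s[!(s$timestamp >= 36100 & s$timestamp < 36200), ] # drop 20 samples
  win <- tibble::tibble(compartment = "bathroom", start = 36000, end = 36600)
  m <- build_matrix(win, list(bathroom = s), lay, start_date = as.Date("2014-01-01"))
  expect_identical(sum(is.na(m$values["node3.temperature", ])), 20L)
})

test_that("features of a constant matrix are all null", {
  m <- matrix_fixture(36000, 36600, motion = rep(0, 120))
  f <- extract_features(m)
  expect_identical(f$motion_density, 0)
  expect_identical(f$delta_temperature, 0)
  expect_identical(f$delta_humidity, 0)
  expect_identical(f$n_transients, 0L)
  expect_identical(f$duration_s, 600)
  expect_identical(f$range_luminance, 0)
})

test_that("robust deltas recover a linear pulse amplitude", {
  times <- seq(30000, 31495, by = 5)
  hum <- 8 + 6 * (times - 30000) / 1500 # the shower ramp
  m <- matrix_fixture(30000, 31500, humidity = hum)
  f <- extract_features(m)
  # expected value computed from the endpoint medians themselves
  expected <- stats::median(hum[295:300]) - stats::median(hum[1:6])
  expect_equal(f$delta_humidity, expected)
  expect_gte(f$delta_humidity, 5.5)
})

test_that("acceleration excursions separated by 10 s count as distinct transients", {
  acc <- rep(0, 120)
  acc[c(20, 21)] <- 3 # one flush
  acc[c(27, 28)] <- 3 # 30 s later: second flush
  m <- matrix_fixture(36000, 36600, acceleration2 = acc)
  f <- extract_features(m)
  expect_identical(f$n_transients, 2L)

  acc2 <- rep(0, 120)
  acc2[20:23] <- 3 # one sustained excursion
  expect_identical(extract_features(matrix_fixture(36000, 36600, acceleration2 = acc2))$n_transients, 1L)
})

test_that("conflict resolution picks the smallest priority number", {
  r2 <- rule("grooming_shower", "grooming", "bathroom", 2, 600, 3600,
    predicates = list(list(feature = "delta_humidity", op = ">=", value = 3))
  )
  r4 <- rule("toileting", "toileting", "bathroom", 4, 120, 900,
    predicates = list(list(feature = "n_transients", op = ">=", value = 1))
  )
  expect_identical(resolve_conflicts(list(r4, r2))$id, "grooming_shower")
  expect_identical(resolve_conflicts(list(r4))$id, "toileting")
})

test_that("the toileting hand-trace classifies as in the worked example", {
  # bathroom, 6 min, lit, one flush transient, humidity/temperature stable
  cand <- candidate_fixture(36000, 36360, "bathroom",
    n_transients = 1, mean_luminance = 180,
    delta_humidity = 0.2, abs_delta_humidity = 0.2,
    delta_temperature = 0.1, abs_delta_temperature = 0.1
  )
  out <- forward_chain(cand, default_rules())
  expect_identical(out$label, "toileting")

  # 25 min with a strong humidity rise: grooming wins despite the flush
  cand2 <- candidate_fixture(36000, 37500, "bathroom",
    n_transients = 1, mean_luminance = 180,
    delta_humidity = 5.6, abs_delta_humidity = 5.6
  )
  out2 <- forward_chain(cand2, default_rules())
  expect_identical(out2$label, "grooming")
})

test_that("no candidates leave the fact database unchanged", {
  db <- adl_events("sleeping", 0, 23400, "bedroom", source = "classified")
  out <- forward_chain(
    tibble::tibble(
      compartment = character(), start = numeric(), end = numeric(),
      features = list()
    ),
    default_rules(),
    db = db
  )
  expect_identical(nrow(out), 0L)
})

test_that("fact-dependent rules fire on the second pass", {
  # pre-bed hygiene needs the later sleeping block as a fact
  grfb <- candidate_fixture(80400, 80880, "bathroom", mean_luminance = 180)
  sleep <- candidate_fixture(81000, 81000 + 28800, "bedroom",
    mean_luminance = 2, motion_density = 0.2
  )
  out <- forward_chain(rbind(grfb, sleep), default_rules())
  expect_identical(attr(out, "n_iterations"), 3L) # 2 productive passes + fixpoint check
  expect_setequal(out$label, c("getting_ready_for_bed", "sleeping"))

  # without the sleeping candidate the bathroom visit stays unlabelled
  alone <- forward_chain(grfb, default_rules())
  expect_identical(nrow(alone), 0L)
})

test_that("chaining terminates within the iteration budget and warns when hit", {
  grfb <- candidate_fixture(80400, 80880, "bathroom", mean_luminance = 180)
  sleep <- candidate_fixture(81000, 81000 + 28800, "bedroom",
    mean_luminance = 2, motion_density = 0.2
  )
  expect_warning(
    out <- forward_chain(rbind(grfb, sleep), default_rules(), max_iterations = 1),
    "partial result"
  )
  expect_identical(out$label, "sleeping") # sleeping fired, the dependent rule could not
})

test_that("classification is deterministic and confined to candidate windows", {
  cfg <- sim_config(n_days = 2, packet_loss_rate = 0.0047, seed = 31)
  tr <- generate_routine(cfg$profile, cfg$layout, 2, seed = 31)
  st <- render_ambient(tr, cfg)
  pk <- packetize(st, cfg)
  sp <- sort_pipeline(pk$packets, cfg$layout)
  c1 <- classify_events(sp$sorted, cfg$layout, start_date = cfg$start_date)
  c2 <- classify_events(sp$sorted, cfg$layout, start_date = cfg$start_date)
  expect_identical(c1, c2)
  cand <- segment_candidates(sp$sorted, cfg$layout, start_date = cfg$start_date)
  # every classified event is exactly one candidate window
  for (i in seq_len(nrow(c1))) {
    hits <- sum(cand$start == c1$start[i] & cand$end == c1$end[i] &
      cand$compartment == c1$compartment[i])
    expect_identical(hits, 1L)
  }
  # no two classified events overlap within a compartment
  for (room in unique(c1$compartment)) {
    e <- c1[c1$compartment == room, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})
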