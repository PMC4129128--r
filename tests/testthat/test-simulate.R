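test_that("a perfectly regular resident repeats the same day shifted by 24 h", {
  prof <- resident_profile(structure_level = 1)
  tr <- generate_routine(prof, default_layout(), 2, seed = 5)
  d1 <- tr[tr$start >= 0 & tr$start < 86400 & tr$start > 0, ] # drop initial sleep tail
  d2 <- tr[tr$start >= 86400 & tr$start < 172800, ]
  expect_identical(d1$label, d2$label)
  expect_equal(d2$start, d1$start + 86400)
  expect_equal(d2$end, d1$end + 86400)
})

test_that("realised per-ADL daily counts track the profile rates", {
  prof <- resident_profile()
  n_days <- 20
  tr <- generate_routine(prof, default_layout(), n_days, seed = 202)
  rates <- expected_daily_rates(prof)
  counts <- table(factor(tr$label, levels = names(rates)))
  for (lab in names(rates)) {
    expected <- rates[[lab]] * n_days
    # Poisson-style 3 SD band, widened by 1 for boundary/placement effects
    tol <- 3 * sqrt(max(expected, 1)) + 1
    expect_lt(abs(counts[[lab]] - expected), tol + 1e-9, label = lab)
  }
  # grooming precedes any later bathroom visit by the humidity cooldown
  g <- tr[tr$label == "grooming", ]
  bath <- tr[tr$compartment == "bathroom" & tr$label != "grooming", ]
  for (i in seq_len(nrow(g))) {
    after <- bath$start[bath$start >= g$end[i]]
    if (length(after)) expect_gte(min(after) - g$end[i], prof$grooming_cooldown)
  }
})

test_that("most cooking events are followed by eating within the configured lag", {
  prof <- resident_profile()
  tr <- generate_routine(prof, default_layout(), 40, seed = 77)
  ck <- tr[tr$label == "cooking", ]
  expect_gte(nrow(ck), 5) # 40 days at 0.35/day
  eat <- tr[tr$label == "eating", ]
  followed <- vapply(seq_len(nrow(ck)), function(i) {
    any(eat$start - ck$end[i] >= 0 & eat$start - ck$end[i] <= 2700)
  }, logical(1))
  expect_gte(mean(followed), 0.6)
  # every night has a sleeping event
  nights <- unique(floor(tr$start[tr$label == "sleeping"] / 86400))
  expect_gte(length(nights), 40)
})

test_that("an infeasible profile raises a scheduling error", {
  dur <- default_durations()
  dur$dur_median[dur$label == "sleeping"] <- 30 * 3600
  dur$dur_max[dur$label == "sleeping"] <- 31 * 3600
  prof <- resident_profile(durations = dur)
  expect_error(
    generate_routine(prof, default_layout(), 2, seed = 1),
    "infeasible",
    class = "adlsense_scheduling_error"
  )
})

test_that("a profile needs every compartment it references", {
  lay <- tiny_layout() # no living room
  expect_error(
    generate_routine(resident_profile(), lay, 1, seed = 1),
    "living_room",
    class = "adlsense_validation_error"
  )
})

test_that("an empty house shows baselines only", {
  cfg <- sim_config(
    layout = tiny_layout(),
    profile = resident_profile(idle_move_rate = 0),
    emission = noise_free(), n_days = 1, packet_loss_rate = 0, seed = 3
  )
  st <- render_ambient(adl_events(), cfg)
  expect_true(all(st$motion == 0))
  expect_true(all(st$humidity == cfg$emission$hum_base))
  expect_true(all(st$acceleration == 0))
  # luminance follows the attenuated outdoor curve in every room
  bath <- st[st$node_id == 3, ]
  expect_equal(
    bath$luminance,
    outdoor_luminance(bath$t %% 86400, cfg$emission) * 0.02
  )
})

test_that("a toileting event maps to bathroom motion and a flush transient", {
  cfg <- sim_config(
    layout = tiny_layout(), profile = resident_profile(idle_move_rate = 0),
    emission = noise_free(), n_days = 1, packet_loss_rate = 0, seed = 3
  )
  ev <- adl_events("toileting", 36000, 36600, "bathroom")
  st <- render_ambient(ev, cfg)
  bath_nodes <- c(3L, 5L)
  on <- st$motion == 1
  expect_true(all(st$node_id[on] %in% bath_nodes))
  in_window <- st$t >= 36000 & st$t < 36600
  expect_true(any(on & in_window))
  expect_true(all(st$t[on] >= 36000 & st$t[on] < 36610)) # PIR hold tail only
  flush <- st[st$node_id == 5L, ]
  spike <- flush$acceleration > 1.5
  expect_true(any(spike))
  expect_true(all(flush$t[spike] >= 36000 & flush$t[spike] < 36600))
  # the fridge box stays quiet
  expect_true(all(st$acceleration[st$node_id == 4L] == 0))
})

test_that("a noise-free shower event reproduces the closed-form humidity pulse", {
  cfg <- sim_config(
    layout = tiny_layout(), profile = resident_profile(idle_move_rate = 0),
    emission = noise_free(), n_days = 1, packet_loss_rate = 0, seed = 3
  )
  s <- 30000
  e <- 31500
  ev <- adl_events("grooming", s, e, "bathroom")
  st <- render_ambient(ev, cfg)
  bath <- st[st$node_id == 3L, ]
  em <- cfg$emission
  # independent closed form: linear rise over the event, exponential decay
  expected <- em$hum_base + ifelse(
    bath$t >= s & bath$t < e,
    em$shower_hum_rise * (bath$t - s) / (e - s),
    ifelse(bath$t >= e & bath$t < e + 8 * em$decay_tau,
      em$shower_hum_rise * exp(-(bath$t - e) / em$decay_tau), 0
    )
  )
  expect_equal(bath$humidity, expected, tolerance = 1e-12)
})

test_that("packetisation conserves and loses packets as configured", {
  cfg0 <- sim_config(
    layout = tiny_layout(), n_days = 1,
    packet_loss_rate = 0, seed = 5
  )
  st <- render_ambient(adl_events(), cfg0)
  pk <- packetize(st, cfg0)
  expect_identical(nrow(pk$packets), nrow(st))
  expect_identical(pk$report$lost, 0L)
  expect_identical(nrow(st), 5L * packets_per_day()) # 17,280 per box per day

  cfg1 <- cfg0
  cfg1$packet_loss_rate <- 1
  pk1 <- packetize(st, cfg1)
  expect_identical(nrow(pk1$packets), 0L)
  expect_identical(pk1$report$lost, pk1$report$sent)
})

test_that("the empirical loss fraction converges to the configured rate", {
  n <- 1e6
  streams <- tibble::tibble(
    node_id = 1L, t = (seq_len(n) - 1) * 5,
    temperature = 21, humidity = 8, luminance = 0,
    motion = 0L, acceleration = 0
  )
  cfg <- sim_config(layout = tiny_layout(), packet_loss_rate = 0.0047, seed = 9)
  pk <- packetize(streams, cfg)
  lost <- pk$report$lost
  # 99% binomial CI around n * p
  half <- stats::qnorm(0.995) * sqrt(n * 0.0047 * (1 - 0.0047))
  expect_lt(abs(lost - n * 0.0047), half)
})

test_that("bit corruption surfaces as parity failures, counted not dropped", {
  cfg <- sim_config(
    layout = tiny_layout(), n_days = 1,
    packet_loss_rate = 0, bit_corruption_rate = 0.01, seed = 5
  )
  st <- render_ambient(adl_events(), cfg)
  pk <- packetize(st, cfg)
  expect_identical(nrow(pk$packets), nrow(st))
  expect_identical(sum(!pk$packets$parity_ok), pk$report$corrupted)
  expect_gt(pk$report$corrupted, 0)
})

test_that("a study re-run under the same seed is byte-identical", {
  cfg <- sim_config(
    layout = tiny_layout(),
    profile = resident_profile(
      slots = default_slots()[default_slots()$label %in% c("grooming", "cooking"), ],
      durations = default_durations()[default_durations()$label != "watching_tv" &
        default_durations()$label != "seated_activity", ]
    ),
    n_days = 1, seed = 1
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(1, 1, cfg, seed = 7, out_dir = d1)
  s2 <- simulate_study(1, 1, cfg, seed = 7, out_dir = d2)
  for (f in c("home01/packets.csv", "home01/truth.csv")) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = f
    )
  }
  expect_identical(
    s1$manifest$expected_packets_per_home,
    nrow(cfg$layout$boxes) * packets_per_day() * 1L
  )
})

test_that("different homes share statistics but not event times", {
  cfg <- sim_config(layout = default_layout(), n_days = 3, seed = 1)
  s <- simulate_study(2, 3, cfg, seed = 42)
  t1 <- s$homes[[1]]$truth
  t2 <- s$homes[[2]]$truth
  expect_false(identical(t1$start, t2$start))
  # both homes sleep nightly and visit the bathroom
  for (tr in list(t1, t2)) {
    expect_gte(sum(tr$label == "sleeping"), 3)
    expect_gt(sum(tr$compartment == "bathroom"), 0)
  }
})
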