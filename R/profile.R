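# Resident profiles and emission models: the behavioural and physical
# parameters behind the synthetic smart-home benchmark. Defaults emulate
# the study conditions: a single occupant, one wall box per room plus
# fridge-door and flush-handle boxes, about 6.6 protocolled ADL per day
# (per-ADL daily rates derived from 1317 events over 200 subject-days).

#' Describe a resident's daily routine
#'
#' A profile drives the agent-based routine generator: Bernoulli "slots"
#' at preferred times of day (meals, TV sessions, morning grooming),
#' Poisson-count activities placed uniformly in a daytime window
#' (toileting), a nightly sleeping block with optional pre-bed hygiene and
#' (for low-structure presets) sleep fragmentation with nocturnal
#' toileting. Event durations are truncated log-normal. `structure_level`
#' in `[0, 1]` scales day-to-day regularity: start-time jitter has
#' standard deviation `jitter_sd * (1 - structure_level)`, and at
#' `structure_level = 1` the generator is fully deterministic (identical
#' days).
#'
#' @param durations Tibble with one row per ADL: `label`, `compartment`,
#'   `dur_median`, `dur_sdlog`, `dur_min`, `dur_max` (seconds).
#' @param slots Tibble of Bernoulli slots: `label`, `tod` (preferred start,
#'   seconds-of-day), `prob`.
#' @param poisson Tibble of count-based activities: `label`, `lambda`
#'   (events/day), `max_count`, `window_lo`, `window_hi` (seconds-of-day).
#' @param sleep List: `start_tod`, `p_grfb` (probability of a
#'   getting-ready-for-bed event), `grfb_gap` (s between its end and sleep
#'   onset), `n_wake_lambda` (expected nocturnal awakenings),
#'   `wake_dur` (range, s), `p_noct_toilet` (probability an awakening
#'   includes a bathroom visit).
#' @param meal_link List: `prob` that a cooking event is followed by
#'   eating, and the lag range `lag_lo`/`lag_hi` (s).
#' @param structure_level Routine regularity in `[0, 1]`.
#' @param jitter_sd Base start-time jitter SD (s), scaled by
#'   `1 - structure_level`.
#' @param min_gap Minimum separation enforced between scheduled events (s).
#' @param grooming_cooldown Minimum delay between a grooming (shower) event
#'   and any later bathroom event (s), so residual humidity has decayed.
#' @param idle_move_rate Probability per 5 s sample of incidental movement
#'   in the currently occupied room between activities.
#' @return An object of class `resident_profile`.
#' @export
resident_profile <- function(durations = default_durations(),
                             slots = default_slots(),
                             poisson = default_poisson(),
                             sleep = list(
                               start_tod = 81000, p_grfb = 0.5, grfb_gap = 120,
                               n_wake_lambda = 0, wake_dur = c(600, 1500),
                               p_noct_toilet = 0.8
                             ),
                             meal_link = list(prob = 0.85, lag_lo = 240, lag_hi = 600),
                             structure_level = 0.8,
                             jitter_sd = 3600,
                             min_gap = 600,
                             grooming_cooldown = 1800,
                             idle_move_rate = 0.002) {
  stopifnot(
    structure_level >= 0, structure_level <= 1,
    all(durations$dur_median > 0), all(durations$dur_min > 0),
    all(durations$dur_min <= durations$dur_max),
    all(slots$prob >= 0), all(poisson$lambda >= 0)
  )
  structure(
    list(
      durations = tibble::as_tibble(durations),
      slots = tibble::as_tibble(slots),
      poisson = tibble::as_tibble(poisson),
      sleep = sleep, meal_link = meal_link,
      structure_level = structure_level, jitter_sd = jitter_sd,
      min_gap = min_gap, grooming_cooldown = grooming_cooldown,
      idle_move_rate = idle_move_rate
    ),
    class = "resident_profile"
  )
}

#' @export
print.resident_profile <- function(x, ...) {
  cat("<resident_profile> structure_level =", x$structure_level, "\n")
  cat("  expected events/day:", round(expected_daily_events(x), 2), "\n")
  invisible(x)
}

#' Default per-ADL duration parameters (seconds)
#' @return Tibble used by [resident_profile()].
#' @export
default_durations <- function() {
  tibble::tribble(
    ~label, ~compartment, ~dur_median, ~dur_sdlog, ~dur_min, ~dur_max,
    "sleeping", "bedroom", 28800, 0.08, 23400, 34200,
    "grooming", "bathroom", 1500, 0.25, 960, 2340,
    "toileting", "bathroom", 300, 0.30, 180, 600,
    "getting_ready_for_bed", "bathroom", 480, 0.20, 300, 720,
    "cooking", "kitchen", 1800, 0.25, 960, 2700,
    "eating", "kitchen", 1500, 0.20, 1080, 2400,
    "watching_tv", "living_room", 3600, 0.30, 1800, 5400,
    "seated_activity", "living_room", 2700, 0.30, 1500, 4500
  )
}

#' @rdname default_durations
#' @export
default_slots <- function() {
  tibble::tribble(
    ~label, ~tod, ~prob,
    "grooming", 27000, 0.70, # 07:30
    "cooking", 42300, 0.175, # 11:45
    "cooking", 65700, 0.175, # 18:15
    "watching_tv", 69300, 0.85, # 19:15
    "watching_tv", 75600, 0.75, # 21:00
    "seated_activity", 35100, 0.425, # 09:45
    "seated_activity", 55800, 0.425 # 15:30
  )
}

#' @rdname default_durations
#' @export
default_poisson <- function() {
  tibble::tribble(
    ~label, ~lambda, ~max_count, ~window_lo, ~window_hi,
    "toileting", 1.5, 4, 27000, 75600,
    "eating", 0.10, 1, 44100, 47700 # standalone (delivered) lunch
  )
}

# expected scheduled events per day (used for feasibility + count checks)
expected_daily_events <- function(profile) {
  1 + # nightly sleeping
    sum(profile$slots$prob) +
    sum(profile$slots$prob[profile$slots$label == "cooking"]) * profile$meal_link$prob +
    sum(pmin(profile$poisson$lambda, profile$poisson$max_count)) +
    profile$sleep$p_grfb
}

#' Expected per-ADL daily event rates implied by a profile
#'
#' @param profile A `resident_profile`.
#' @return Named numeric vector of events/day per ADL label.
#' @export
expected_daily_rates <- function(profile) {
  rates <- stats::setNames(numeric(length(adl_labels()$label)), adl_labels()$label)
  rates["sleeping"] <- 1
  rates["getting_ready_for_bed"] <- profile$sleep$p_grfb
  for (i in seq_len(nrow(profile$slots))) {
    rates[profile$slots$label[i]] <- rates[profile$slots$label[i]] + profile$slots$prob[i]
  }
  rates["eating"] <- rates["eating"] +
    sum(profile$slots$prob[profile$slots$label == "cooking"]) * profile$meal_link$prob
  for (i in seq_len(nrow(profile$poisson))) {
    rates[profile$poisson$label[i]] <- rates[profile$poisson$label[i]] + profile$poisson$lambda[i]
  }
  rates
}

#' Low-structure preset emulating an Alzheimer resident
#'
#' Qualitative preset: low routine regularity (`structure_level = 0.3`),
#' fragmented night sleep with nocturnal bathroom visits, and more
#' toileting events. Used to contrast activity-map regularity against the
#' default profile; no quantitative clinical claim is attached.
#'
#' @return A `resident_profile`.
#' @export
alzheimer_profile <- function() {
  pois <- default_poisson()
  pois$lambda[pois$label == "toileting"] <- 2.0
  resident_profile(
    poisson = pois,
    sleep = list(
      start_tod = 81000, p_grfb = 0.3, grfb_gap = 120,
      n_wake_lambda = 1.5, wake_dur = c(900, 1800), p_noct_toilet = 0.8
    ),
    structure_level = 0.3
  )
}

# ---------------------------------------------------------------------------
# Emission model
# ---------------------------------------------------------------------------

#' Per-channel emission physics of the simulated home
#'
#' Describes how activities imprint on the five ambient channels:
#' a diurnal outdoor luminance curve attenuated per room, lamps and the TV
#' luminance signature; shower and cooking pulses on humidity/temperature
#' (linear rise over the event, exponential decay with time constant
#' `decay_tau` afterwards); a passive-infrared motion model (trigger
#' probability per 5 s sample of movement, 10 s hold, rare false
#' triggers); and acceleration transients on the fridge-door and
#' flush-handle boxes. Gaussian noise SDs apply per channel.
#'
#' @param daylight Sunrise/sunset in seconds-of-day.
#' @param outdoor_peak_lx Outdoor midday luminance.
#' @param attenuation Named per-room daylight attenuation factors;
#'   `.default` applies to unlisted rooms.
#' @param lamp_lx Luminance added by the room lamp.
#' @param lamp_need_lx Daylight level below which an active resident
#'   switches the lamp on.
#' @param tv_lx Living-room luminance while the TV is on (the TV
#'   signature level).
#' @param temp_base,temp_diurnal_amp Baseline room temperature (°C) and
#'   diurnal amplitude.
#' @param hum_base Baseline absolute humidity (g/m³).
#' @param shower_hum_rise Humidity rise over a grooming (shower) event.
#' @param cook_temp_rise,cook_hum_rise Kitchen pulses during cooking.
#' @param decay_tau Exponential decay time constant of all pulses (s).
#' @param pir_p Trigger probability per 5 s sample in which the resident
#'   moves in the room.
#' @param pir_hold_s PIR hold time after a trigger (s).
#' @param pir_false_rate False-trigger probability per sample.
#' @param transient_amp Acceleration transient amplitude (m/s²) on
#'   appliance boxes.
#' @param flush_prob_grooming Probability a grooming event includes a
#'   flush (grooming subsumes toileting).
#' @param cook_extra_transients Expected extra fridge-door transients per
#'   cooking event beyond the guaranteed first one (Poisson).
#' @param movement Tibble (`label`, `interval_s`, `bout_len`): mean
#'   interval between movement bouts during each activity and bout length
#'   in samples. Intervals are jittered by ±20%.
#' @param noise_sd Named vector of Gaussian noise SDs for
#'   temperature, humidity, luminance, acceleration.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(daylight = c(25200, 68400),
                           outdoor_peak_lx = 1000,
                           attenuation = c(bathroom = 0.02, .default = 0.3),
                           lamp_lx = 200, lamp_need_lx = 120, tv_lx = 55,
                           temp_base = 21, temp_diurnal_amp = 0.5,
                           hum_base = 8,
                           shower_hum_rise = 6, cook_temp_rise = 2,
                           cook_hum_rise = 1.5, decay_tau = 1200,
                           pir_p = 0.95, pir_hold_s = 10, pir_false_rate = 1e-4,
                           transient_amp = 3, flush_prob_grooming = 0.7,
                           cook_extra_transients = 1,
                           movement = default_movement(),
                           noise_sd = c(
                             temperature = 0.08, humidity = 0.15,
                             luminance = 6, acceleration = 0.05
                           )) {
  stopifnot(
    all(noise_sd >= 0), pir_p >= 0, pir_p <= 1,
    pir_false_rate >= 0, pir_false_rate <= 1, decay_tau > 0
  )
  structure(
    list(
      daylight = daylight, outdoor_peak_lx = outdoor_peak_lx,
      attenuation = attenuation, lamp_lx = lamp_lx,
      lamp_need_lx = lamp_need_lx, tv_lx = tv_lx,
      temp_base = temp_base, temp_diurnal_amp = temp_diurnal_amp,
      hum_base = hum_base, shower_hum_rise = shower_hum_rise,
      cook_temp_rise = cook_temp_rise, cook_hum_rise = cook_hum_rise,
      decay_tau = decay_tau, pir_p = pir_p, pir_hold_s = pir_hold_s,
      pir_false_rate = pir_false_rate, transient_amp = transient_amp,
      flush_prob_grooming = flush_prob_grooming,
      cook_extra_transients = cook_extra_transients,
      movement = tibble::as_tibble(movement), noise_sd = noise_sd
    ),
    class = "emission_model"
  )
}

#' @rdname emission_model
#' @export
default_movement <- function() {
  tibble::tribble(
    ~label, ~interval_s, ~bout_len,
    "sleeping", 90, 2,
    "grooming", 10, 2,
    "toileting", 10, 2,
    "getting_ready_for_bed", 10, 2,
    "cooking", 10, 2,
    "eating", 30, 2,
    "watching_tv", 55, 2,
    "seated_activity", 40, 2
  )
}

#' Deterministic-sensing variant of an emission model
#'
#' Sets all channel noise SDs to zero, the PIR trigger probability to one
#' and the false-trigger rate to zero. This is the configuration of the
#' closed-loop oracle benchmark: with sensing made deterministic and the
#' default rulebase matched to the default emissions, every simulated
#' activity must be recovered exactly.
#'
#' @param emission An `emission_model`.
#' @return The modified `emission_model`.
#' @export
noise_free <- function(emission = emission_model()) {
  emission$noise_sd[] <- 0
  emission$pir_p <- 1
  emission$pir_false_rate <- 0
  emission
}

room_attenuation <- function(emission, room) {
  att <- emission$attenuation
  if (!is.null(names(att)) && room %in% names(att)) {
    unname(att[[room]])
  } else {
    unname(att[[".default"]] %||% 0.3)
  }
}

# outdoor luminance at seconds-of-day tod: half-sine between sunrise/sunset
outdoor_luminance <- function(tod, emission) {
  rise <- emission$daylight[1]
  set <- emission$daylight[2]
  frac <- (tod - rise) / (set - rise)
  ifelse(frac > 0 & frac < 1, emission$outdoor_peak_lx * sin(pi * frac), 0)
}

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Bundle a full simulation configuration
#'
#' @param layout A `home_layout`.
#' @param profile A `resident_profile`.
#' @param emission An `emission_model`.
#' @param n_days Number of simulated days (>= 1).
#' @param packet_loss_rate Per-packet transmission-loss probability
#'   (default 0.0047, the deployed system's observed loss share).
#' @param bit_corruption_rate Per-packet single-bit corruption probability
#'   (detected by the even-parity check).
#' @param seed Integer seed; every stochastic stage derives from it.
#' @param start_date Calendar date of simulation day 1.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(layout = default_layout(),
                       profile = resident_profile(),
                       emission = emission_model(),
                       n_days = 5L,
                       packet_loss_rate = 0.0047,
                       bit_corruption_rate = 0,
                       seed = 1L,
                       start_date = as.Date("2014-01-01")) {
  stopifnot(
    inherits(layout, "home_layout"), inherits(profile, "resident_profile"),
    inherits(emission, "emission_model"),
    n_days >= 1,
    packet_loss_rate >= 0, packet_loss_rate <= 1,
    bit_corruption_rate >= 0, bit_corruption_rate <= 1
  )
  v <- validate_layout(layout)
  if (length(v)) {
    stop_adlsense("invalid layout: ", paste(v, collapse = "; "),
      class = "adlsense_validation_error"
    )
  }
  structure(
    list(
      layout = layout, profile = profile, emission = emission,
      n_days = as.integer(n_days), packet_loss_rate = packet_loss_rate,
      bit_corruption_rate = bit_corruption_rate, seed = as.integer(seed),
      start_date = as.Date(start_date)
    ),
    class = "sim_config"
  )
}

# run code with a locally-set RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# deterministic per-home seed derivation, kept within 32-bit integer range
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}
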