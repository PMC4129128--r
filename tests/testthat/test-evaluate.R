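# helper: n same-label events spaced out on the timeline
event_train <- function(label, n, compartment = "bathroom",
                        dur = 600, gap = 1200, t0 = 0, source = "ground_truth") {
  starts <- t0 + (seq_len(n) - 1) * (dur + gap)
  adl_events(rep(label, n), starts, starts + dur, compartment, source = source)
}

test_that("log merging applies paper-logbook corrections in file order", {
  device <- adl_events(
    c("toileting", "cooking"), c(1000, 5000), c(1600, 6800),
    c("bathroom", "kitchen")
  )
  expect_identical(merge_logs(device, NULL)$label, device$label)

  # a wrongly flicked switch is deleted, a forgotten grooming added
  corr <- tibble::tibble(
    op = c("delete", "add"),
    label = c("cooking", "grooming"),
    start = c(5000, 9000), end = c(NA, 10500),
    compartment = c(NA, "bathroom"),
    new_label = NA_character_, new_start = NA_real_, new_end = NA_real_
  )
  merged <- merge_logs(device, corr)
  expect_setequal(merged$label, c("toileting", "grooming"))
  expect_identical(merged$provenance[merged$label == "grooming"], "paper_logbook")

  # relabel and retime
  corr2 <- tibble::tibble(
    op = c("relabel", "retime"),
    label = c("toileting", "cooking"),
    start = c(1000, 5000), end = NA_real_, compartment = NA_character_,
    new_label = c("grooming", NA),
    new_start = c(NA, 5200), new_end = c(NA, 7000)
  )
  merged2 <- merge_logs(device, corr2)
  expect_identical(merged2$label, c("grooming", "cooking"))
  expect_identical(merged2$start[2], 5200)
})

test_that("corrections referencing missing events are merge errors", {
  device <- adl_events("toileting", 1000, 1600, "bathroom")
  corr <- tibble::tibble(
    op = "delete", label = "cooking", start = 42, end = NA_real_,
    compartment = NA_character_, new_label = NA_character_,
    new_start = NA_real_, new_end = NA_real_
  )
  expect_error(merge_logs(device, corr), "non-existent", class = "adlsense_merge_error")
})

test_that("a relabel creating a same-label overlap is rejected", {
  device <- adl_events(
    c("toileting", "grooming"), c(1000, 1300), c(1600, 2500),
    "bathroom"
  )
  corr <- tibble::tibble(
    op = "relabel", label = "grooming", start = 1300, end = NA_real_,
    compartment = NA_character_, new_label = "toileting",
    new_start = NA_real_, new_end = NA_real_
  )
  expect_error(merge_logs(device, corr), class = "adlsense_overlap_error")
})

test_that("a perfect classifier scores TP = N with no errors", {
  truth <- rbind(
    event_train("toileting", 5),
    event_train("grooming", 3, t0 = 40000)
  )
  classified <- truth
  classified$source <- "classified"
  counts <- match_events(classified, truth)
  for (lab in c("toileting", "grooming")) {
    r <- counts[counts$label == lab, ]
    expect_identical(r$tp, r$n)
    expect_identical(r$fn, 0L)
    expect_identical(r$fp, 0L)
    expect_identical(sensitivity(counts, lab), 100)
    expect_identical(specificity(counts, lab), 100)
  }
})

test_that("per-label conservation TP + FN = N holds on random event sets", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      # per-label trains with random phase: cross-label overlaps allowed,
      # same-label events never overlap
      truth <- do.call(rbind, lapply(adl_labels()$label, function(l) {
        event_train(l, sample(3:8, 1),
          t0 = stats::runif(1, 0, 5000),
          dur = stats::runif(1, 200, 900), gap = stats::runif(1, 500, 2000)
        )
      }))
      keep <- stats::runif(nrow(truth)) < 0.7
      classified <- truth[keep, ]
      classified$source <- "classified"
      counts <- match_events(classified, truth)
      expect_identical(counts$tp + counts$fn, counts$n)
      expect_identical(sum(counts$n), nrow(truth))
    }
  })
})

test_that("the grooming row arithmetic matches the deployment protocol counts", {
  # 135 performed, 127 recovered
  truth <- event_train("grooming", 135, dur = 1500, gap = 3000)
  classified <- truth[1:127, ]
  classified$source <- "classified"
  counts <- match_events(classified, truth)
  r <- counts[counts$label == "grooming", ]
  expect_identical(c(r$n, r$tp, r$fn), c(135L, 127L, 8L))
  expect_identical(sensitivity(counts, "grooming"), 94.07)
})

test_that("one classified event matches at most one truth event, earlier first", {
  truth <- adl_events(
    c("eating", "eating"), c(1000, 2100), c(2000, 3100), "kitchen"
  )
  classified <- adl_events("eating", 1200, 2900, "kitchen", source = "classified")
  counts <- match_events(classified, truth)
  r <- counts[counts$label == "eating", ]
  expect_identical(r$tp, 1L) # greedy: the earlier truth event wins
  expect_identical(r$fn, 1L)
  expect_identical(r$fp, 0L)
})

test_that("events below the overlap threshold do not match", {
  truth <- adl_events("cooking", 1000, 2000, "kitchen")
  classified <- adl_events("cooking", 1900, 2900, "kitchen", source = "classified")
  counts <- match_events(classified, truth) # 100 s of 1000 s: under 50%
  r <- counts[counts$label == "cooking", ]
  expect_identical(r$tp, 0L)
  expect_identical(r$fp, 1L)
})

test_that("specificity counts one-vs-rest negatives", {
  # 100 negatives (other-label truth), 10 false positives placed elsewhere
  truth <- event_train("seated_activity", 100, dur = 1200, gap = 1800, compartment = "living_room")
  fp <- event_train("watching_tv", 10,
    dur = 600, gap = 400000,
    t0 = 1e6, compartment = "living_room", source = "classified"
  )
  counts <- match_events(fp, truth)
  r <- counts[counts$label == "watching_tv", ]
  expect_identical(r$fp, 10L)
  expect_identical(r$tn, 100L)
  expect_identical(specificity(counts, "watching_tv"), round(100 * 100 / 110, 2))

  # false positives that swallow the negatives drive specificity to zero
  fp_on_top <- truth
  fp_on_top$label <- "watching_tv"
  fp_on_top$source <- "classified"
  counts2 <- match_events(fp_on_top, truth)
  expect_identical(specificity(counts2, "watching_tv"), 0)
})

test_that("undefined metrics are NA markers, never zero", {
  counts <- match_events(adl_events(source = "classified"), adl_events())
  expect_true(is.na(sensitivity(counts, "cooking")))
  expect_true(is.na(specificity(counts, "cooking")))
})

test_that("macro averaging reproduces overall percentages from per-ADL rows", {
  sens <- c(93.64, 94.07, 94.79, 92.38, 84.29, 87.78, 93.17, 90.06)
  spec <- c(85.77, 96.98, 91.54, 94.48, 90.92, 94.83, 90.63, 94.98)
  expect_identical(macro_average(sens), 91.27)
  expect_identical(macro_average(spec), 92.52)
  expect_identical(macro_average(rep(77.7, 8)), 77.7)
  expect_error(
    macro_average(c(sleeping = 90)), "missing per-ADL",
    class = "adlsense_validation_error"
  )
})

test_that("metrics are invariant to global time shifts and room renames", {
  truth <- rbind(
    event_train("toileting", 8, t0 = 100),
    event_train("cooking", 6, t0 = 700, dur = 1500, gap = 2500, compartment = "kitchen"),
    event_train("watching_tv", 5, t0 = 1500, dur = 3000, gap = 4000, compartment = "living_room")
  )
  classified <- truth[seq(1, nrow(truth), by = 2), ]
  classified$source <- "classified"
  base <- match_events(classified, truth)

  shift <- function(e, dt) {
    e$start <- e$start + dt
    e$end <- e$end + dt
    e
  }
  expect_identical(match_events(shift(classified, 36000), shift(truth, 36000)), base)

  rename <- function(e) {
    e$compartment <- "bedroom2"
    e
  }
  expect_identical(match_events(rename(classified), rename(truth)), base)
})

test_that("epoch-mode matching agrees on a perfect classification", {
  truth <- event_train("sleeping", 3, dur = 7200, gap = 21600, compartment = "bedroom")
  classified <- truth
  classified$source <- "classified"
  counts <- match_events(classified, truth, match_config(mode = "epoch"))
  r <- counts[counts$label == "sleeping", ]
  expect_identical(r$fn, 0L)
  expect_identical(r$fp, 0L)
  expect_identical(sensitivity(counts, "sleeping"), 100)
  expect_gt(r$tn, 0)
})

test_that("a metrics table carries per-ADL rows plus macro totals", {
  truth <- do.call(rbind, lapply(adl_labels()$label, function(l) {
    event_train(l, 4, t0 = match(l, adl_labels()$label) * 40000, dur = 1200, gap = 2400)
  }))
  classified <- truth[seq_len(nrow(truth)) %% 4 != 0, ]
  classified$source <- "classified"
  m <- metrics_table(match_events(classified, truth))
  expect_identical(nrow(m), 9L)
  per <- m[m$label != "total", ]
  tot <- m[m$label == "total", ]
  expect_identical(tot$n, sum(per$n))
  expect_identical(tot$sensitivity, round(mean(per$sensitivity), 2))
  # macro lies between the per-ADL extremes
  expect_gte(tot$sensitivity, min(per$sensitivity))
  expect_lte(tot$sensitivity, max(per$sensitivity))
})

test_that("activity maps bin majority labels and score regularity", {
  # one event covering a whole day: uniform map
  one <- adl_events("sleeping", 0, 86400, "bedroom")
  m1 <- build_activity_map(one, 1)
  expect_true(all(m1$grid == "sleeping"))

  # a perfectly repeated 2-day schedule scores regularity 1
  day <- adl_events(
    c("sleeping", "grooming", "watching_tv"),
    c(0, 27000, 70200), c(23400, 28500, 75600),
    c("bedroom", "bathroom", "living_room")
  )
  two <- rbind(day, transform(day, start = start + 86400, end = end + 86400))
  m2 <- build_activity_map(adl_events(two$label, two$start, two$end, two$compartment), 2)
  expect_identical(m2$regularity, 1)

  # ties go to the earlier-starting event
  tie <- adl_events(
    c("eating", "seated_activity"), c(0, 150), c(150, 300),
    c("kitchen", "living_room")
  )
  mt <- build_activity_map(tie, 1)
  expect_identical(mt$grid[1, 1], "eating")
})
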