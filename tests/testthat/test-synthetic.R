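test_that("generated nights honor the event budget and are byte-reproducible", {
  nt <- generate_night(night_spec(duration_hours = 0.25, event_rate = 20,
                                  seed = 3), 4000)
  expect_equal(nrow(nt$events), 5L)                  # 20/h * 0.25 h
  expect_equal(nt$reference_ahi, 20)
  expect_length(nt$audio$samples, 0.25 * 3600 * 4000)
  again <- generate_night(night_spec(duration_hours = 0.25, event_rate = 20,
                                     seed = 3), 4000)
  expect_identical(nt$audio$samples, again$audio$samples)
  expect_identical(nt$events, again$events)

  quiet <- generate_night(night_spec(duration_hours = 0.1, event_rate = 0,
                                     seed = 1), 4000)
  expect_equal(nrow(quiet$events), 0L)
  expect_equal(quiet$reference_ahi, 0)
})

test_that("event durations and spacing respect the configured limits", {
  nt <- test_night(seed = 12, duration_hours = 0.5, event_rate = 30)
  expect_true(all(nt$events$duration >= 10 & nt$events$duration <= 60))
  ends <- nt$events$onset + nt$events$duration
  expect_true(all(nt$events$onset[-1] - head(ends, -1) >= 10 - 1e-9))
  expect_error(generate_night(night_spec(duration_hours = 0.1,
                                         event_rate = 200, seed = 1), 4000),
               "event rate too high")
})

test_that("apnea intervals are near-silent relative to normal breathing", {
  nt <- test_night(seed = 8, duration_hours = 0.25, event_rate = 16)
  ap <- nt$events[nt$events$event_type == "obstructive_apnea", ]
  skip_if(nrow(ap) == 0)
  sr <- nt$audio$rate
  in_event <- function(onset, dur) {
    idx <- (round(onset * sr) + 1):round((onset + dur) * sr)
    mean_power(nt$audio$samples[idx])
  }
  ev_pow <- mean(mapply(in_event, ap$onset, ap$duration))
  # normal breathing power over event-free epochs
  labs <- label_epochs(filter_obstructive(nt$events),
                       epoch_grid(duration(nt$audio)))
  free <- which(labs$label == "no_event")
  segs <- segment_epochs(nt$audio)
  base_pow <- mean(vapply(segs[free], mean_power, 0))
  expect_lt(ev_pow, 0.1 * base_pow)
})

test_that("the recovery gasp is louder than baseline breathing", {
  nt <- test_night(seed = 8, duration_hours = 0.25, event_rate = 16)
  ap <- nt$events[nt$events$event_type == "obstructive_apnea", ]
  skip_if(nrow(ap) == 0)
  sr <- nt$audio$rate
  g0 <- ap$onset[1] + ap$duration[1]
  gasp <- nt$audio$samples[round(g0 * sr):round((g0 + 1.8) * sr)]
  expect_gt(max(abs(gasp)), 2 * nt$spec$base_amplitude)
})

test_that("stationary clips are level-stable and event-driven clips are spiky", {
  frame_power <- function(a, frame_sec = 0.5) {
    n <- floor(duration(a) / frame_sec)
    vapply(seq_len(n), function(k) {
      idx <- ((k - 1) * frame_sec * a$rate + 1):(k * frame_sec * a$rate)
      mean_power(a$samples[idx])
    }, 0)
  }
  kurt <- function(x) mean((x - mean(x))^4) / (mean((x - mean(x))^2))^2
  stat <- generate_noise_clip(noise_spec("air_conditioner_fan", 60, seed = 2))
  ev <- generate_noise_clip(noise_spec("clock", 60, seed = 2))
  expect_equal(stat$kind, "stationary")
  expect_equal(ev$kind, "event_driven")
  fp_s <- frame_power(stat$audio); fp_e <- frame_power(ev$audio)
  expect_lt(sd(fp_s) / mean(fp_s), 0.2)
  expect_gt(kurt(fp_e), kurt(fp_s))
  expect_length(stat$audio$samples, 60 * 4000)
})

test_that("synthetic libraries split train and test clips disjointly", {
  lib <- test_noise_library()
  expect_setequal(unique(lib$category), noise_categories)
  tr <- which(lib$split == "train"); te <- which(lib$split == "test")
  expect_gt(length(tr), 0); expect_gt(length(te), 0)
  for (i in tr) for (j in te)
    expect_false(identical(lib$clips[[i]]$samples, lib$clips[[j]]$samples))
})

test_that("cohort plans hit the requested strata and realized AHIs match", {
  plan <- cohort_plan(8, strata_props = c(0, 0.5, 0.5, 0), seed = 3)
  expect_equal(sum(plan$target_ahi < 15), 4L)
  expect_equal(sum(plan$target_ahi >= 15), 4L)
  plan50 <- cohort_plan(50, seed = 4)
  expect_equal(as.vector(table(cut(plan50$target_ahi, c(-1, 5, 15, 30, 100),
                                   right = FALSE))),
               c(9, 16, 16, 9))
  expect_identical(cohort_plan(50, seed = 4), plan50)
})

test_that("written cohorts round-trip through WAV, annotations and manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(3, dir, duration_hours = 1 / 30, seed = 5,
                        strata_props = c(0, 1, 1, 0))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  mf <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), 3L)
  expect_equal(mf$reference_ahi, co$manifest$reference_ahi)
  a <- load_audio(mf$audio_path[1])
  expect_equal(duration(a), 120)
  ev <- read_events(mf$annotation_path[1])
  expect_equal(nrow(ev), nrow(co$nights[[1]]$events))
  # 16-bit quantization only
  expect_lt(max(abs(a$samples - co$nights[[1]]$audio$samples)), 1 / 32000)
})
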