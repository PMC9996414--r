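test_that("mean_power matches closed forms", {
  expect_equal(mean_power(rep(0.1, 1000)), 0.01)
  expect_equal(mean_power(rep(0, 100)), 0)
  # unit sinusoid over many whole periods -> 1/2
  x <- sin(2 * pi * 50 * (1:20000) / 1000)
  expect_equal(mean_power(x), 0.5, tolerance = 1e-3)
  expect_error(mean_power(numeric(0)), "empty")
})

test_that("snr_gain solves the power equation", {
  expect_equal(snr_gain(0.01, 0.04, 0), 0.5)
  expect_equal(snr_gain(0.3, 0.3, 0), 1)
  expect_equal(snr_gain(0.01, 0.04, -20), 5)
  expect_error(snr_gain(0.01, 0, 0), "noise_power")
})

test_that("noise covers have the exact requested length and are seed-reproducible", {
  lib <- test_noise_library()
  cover <- sample_noise_cover(lib, 420, seed = 5)
  expect_equal(length(cover$samples), 420 * lib$rate)
  expect_identical(cover$samples,
                   sample_noise_cover(lib, 420, seed = 5)$samples)
  # single clip exactly covering the need
  one <- sample_noise_cover(lib, 45, categories = "clock", seed = 2)
  expect_equal(length(one$samples), 45 * lib$rate)
  expect_error(sample_noise_cover(lib, 30, categories = "speech",
                                  split = "nope"), "eligible")
})

test_that("corrupt realizes the requested SNR exactly and is deterministic", {
  lib <- test_noise_library()
  set.seed(4)
  clean <- audio_signal(0.1 * rnorm(4000 * 60), 4000)
  for (snr in c(-30, -20, -5, 0, 10)) {
    noisy <- corrupt(clean, lib, snr, seed = 11)
    added <- noisy$samples - clean$samples
    expect_equal(10 * log10(mean_power(clean) / mean_power(added)), snr,
                 tolerance = 1e-9)
  }
  expect_identical(corrupt(clean, lib, 3, seed = 9)$samples,
                   corrupt(clean, lib, 3, seed = 9)$samples)
  # SNR 0 means equal measured powers
  zero <- corrupt(clean, lib, 0, seed = 1)
  expect_equal(mean_power(zero$samples - clean$samples), mean_power(clean),
               tolerance = 1e-12)
  # the no-noise limit returns the clean signal unchanged
  expect_identical(corrupt(clean, lib, Inf)$samples, clean$samples)
})

test_that("SNR round trip holds across the tested range for random draws", {
  lib <- test_noise_library()
  set.seed(8)
  for (i in 1:60) {
    clean <- audio_signal(runif(1, 0.01, 1) * rnorm(4000 * 5), 4000)
    target <- runif(1, -30, 10)
    noisy <- corrupt(clean, lib, target, seed = i)
    realized <- 10 * log10(mean_power(clean) /
                           mean_power(noisy$samples - clean$samples))
    expect_lt(abs(realized - target), 0.01)
  }
})

test_that("pitch shift preserves duration and scales a tone's dominant frequency", {
  sr <- 8000
  tone <- audio_signal(sin(2 * pi * 440 * (1:(sr * 3)) / sr), sr)
  dominant <- function(a) {
    s <- Mod(fft(a$samples))[1:(length(a$samples) %/% 2)]
    (which.max(s) - 1) * a$rate / length(a$samples)
  }
  for (s in c(12, -12, 3.5)) {
    shifted <- pitch_shift(tone, s)
    expect_length(shifted$samples, length(tone$samples))
    expect_equal(dominant(shifted), 440 * 2^(s / 12),
                 tolerance = 0.05 * 440 * 2^(s / 12))
  }
  expect_identical(pitch_shift(tone, 0), tone)
  expect_error(pitch_shift(tone, 13), "semitones")
})
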