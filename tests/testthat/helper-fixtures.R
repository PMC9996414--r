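# Shared fixtures, built in code. Feature configuration used throughout
# the tests: 4 kHz audio, 24 mel bands, 0.25 s hop (coarse but sufficient
# for breath-scale structure, and fast).

test_mel_config <- function() {
  mel_config(sample_rate = 4000, n_mels = 24,
             window_sec = 0.256, hop_sec = 0.25)
}

# A deterministic little night: clean breathing with a couple of events.
test_night <- function(seed = 3L, duration_hours = 0.25, event_rate = 16) {
  generate_night(night_spec(duration_hours = duration_hours,
                            event_rate = event_rate, seed = seed),
                 sample_rate = 4000)
}

# Cached prepared nights for the heavier pipeline tests (built once per
# test run).
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

test_noise_library <- function() {
  cached("noise_lib", synth_noise_library(clips_per_category = 2L,
                                          clip_sec = 45, seed = 31L))
}

# Brute-force rasterization oracle for epoch labeling: occupancy per type
# summed over a fine time grid (cell centres), then the same decision
# rule applied. Independent of the interval arithmetic in label_epochs.
raster_label_oracle <- function(events, grid, resolution = 0.01) {
  n <- grid$n_epochs
  if (n == 0L) return(character(0))
  centers <- seq(resolution / 2, n * grid$epoch_length, by = resolution)
  epoch_of <- floor(centers / grid$epoch_length) + 1
  occ_ap <- numeric(n); occ_hy <- numeric(n)
  for (i in seq_len(nrow(events))) {
    inside <- centers >= events$onset[i] &
      centers < events$onset[i] + events$duration[i]
    tab <- tabulate(epoch_of[inside], nbins = n)
    if (events$event_type[i] == "obstructive_apnea")
      occ_ap <- occ_ap + tab * resolution
    else occ_hy <- occ_hy + tab * resolution
  }
  out <- rep("no_event", n)
  has <- occ_ap > 1e-9 | occ_hy > 1e-9
  out[has & occ_ap >= occ_hy] <- "apnea"
  out[has & occ_hy > occ_ap] <- "hypopnea"
  out
}

# Random event layouts on a 0.1-s grid (so the raster oracle is exact).
random_events <- function(n_events, total_sec, seed) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); force(expr)
  }
  withr_seed(seed, {
    onset <- round(runif(n_events, 0, total_sec - 10) * 10) / 10
    duration <- round(runif(n_events, 1, 90) * 10) / 10
    type <- sample(c("obstructive_apnea", "hypopnea"), n_events, replace = TRUE)
    respiratory_events(type, onset, pmin(duration, pmax(total_sec - onset, 0.1)))
  })
}
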