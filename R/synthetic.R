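# Seeded synthetic nights and synthetic home-noise clips. The generator
# encodes the acoustic phenomenology of obstructive events: apnea is a
# cessation of breathing sound followed by a loud recovery gasp; hypopnea
# is attenuated, irregular breathing.

#' Specification of a synthetic night
#'
#' @param duration_hours Night length in hours.
#' @param event_rate Target apnea+hypopnea events per hour (the reference
#'   AHI equals the realized event count divided by the duration).
#' @param apnea_fraction Fraction of events that are obstructive apneas
#'   (the rest are hypopneas).
#' @param event_duration_range Event duration range in seconds (uniform).
#' @param gasp_gain Amplitude multiplier of the post-apnea recovery gasp
#'   relative to the baseline breath amplitude.
#' @param hypopnea_attenuation Amplitude fraction of breathing during a
#'   hypopnea (in (0,1)).
#' @param breath_rate Breaths per minute.
#' @param base_amplitude Baseline breath-burst amplitude.
#' @param jitter Fractional timing jitter of breath onsets.
#' @param breath_band Breath-noise band in Hz (must sit below Nyquist).
#' @param noise_floor Amplitude of the permanent microphone/room floor.
#' @param min_gap Minimum gap between events in seconds.
#' @param seed Integer seed; generation is byte-reproducible.
#' @return A list of class `night_spec`.
#' @export
night_spec <- function(duration_hours = 1, event_rate = 15,
                       apnea_fraction = 0.5,
                       event_duration_range = c(10, 60),
                       gasp_gain = 3, hypopnea_attenuation = 0.35,
                       breath_rate = 14, base_amplitude = 0.1,
                       jitter = 0.1, breath_band = c(300, 1800),
                       noise_floor = 3e-3, min_gap = 10, seed = 1L) {
  stopifnot(duration_hours > 0, event_rate >= 0,
            apnea_fraction >= 0, apnea_fraction <= 1,
            length(event_duration_range) == 2L,
            event_duration_range[1] >= 10, event_duration_range[2] <= 60,
            event_duration_range[1] <= event_duration_range[2],
            gasp_gain > 0, hypopnea_attenuation > 0, hypopnea_attenuation < 1,
            breath_rate > 0, base_amplitude >= 0, min_gap >= 0)
  structure(list(duration_hours = duration_hours, event_rate = event_rate,
                 apnea_fraction = apnea_fraction,
                 event_duration_range = event_duration_range,
                 gasp_gain = gasp_gain,
                 hypopnea_attenuation = hypopnea_attenuation,
                 breath_rate = breath_rate, base_amplitude = base_amplitude,
                 jitter = jitter, breath_band = breath_band,
                 noise_floor = noise_floor, min_gap = min_gap,
                 seed = as.integer(seed)),
            class = "night_spec")
}

# Band-limited Gaussian noise via FFT masking, unit variance. Long
# signals are synthesized in power-of-two blocks (the block seam is a
# phase discontinuity in an already random carrier, inaudible here).
bandlimited_noise <- function(n, rate, band, block = 2^18) {
  one_block <- function(m) {
    Z <- fft(rnorm(m))
    freqs <- (0:(m - 1)) / m * rate
    freqs <- pmin(freqs, rate - freqs)       # two-sided
    Z[freqs < band[1] | freqs > band[2]] <- 0
    Re(fft(Z, inverse = TRUE)) / m
  }
  x <- if (n <= block) one_block(n)
       else unlist(lapply(seq_len(ceiling(n / block)),
                          function(i) one_block(block)))[seq_len(n)]
  s <- sd(x)
  if (s > 0) x / s else x
}

hann_burst <- function(len) 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))

# Place n_events non-overlapping events with at least min_gap spacing by
# distributing the free slack uniformly between events (stick breaking),
# which succeeds whenever the layout is feasible at all.
place_events <- function(n_events, durations, total_sec, min_gap, margin = 15) {
  if (n_events == 0L) return(list(onset = numeric(0), duration = numeric(0)))
  slack <- total_sec - 2 * margin - sum(durations) - (n_events - 1) * min_gap
  if (slack < 0)
    stop("event rate too high: cannot place non-overlapping events")
  w <- runif(n_events + 1L)
  extra <- slack * w / sum(w)
  onsets <- margin + cumsum(extra[seq_len(n_events)]) +
    c(0, cumsum(durations[-n_events] + min_gap))
  list(onset = onsets, duration = durations)
}

#' Generate one synthetic night
#'
#' Breathing is realized as band-passed noise bursts under raised-cosine
#' envelopes at a quasi-periodic breath rate. Apnea events silence the
#' breathing for the event duration and append a louder, wider-band
#' recovery gasp; hypopnea events attenuate the breath amplitude and
#' increase its irregularity. Events are placed non-overlapping with a
#' minimum gap.
#'
#' @param spec A [night_spec()].
#' @param sample_rate Sample rate in Hz (default 4000; the breath band
#'   must fit below Nyquist).
#' @return A list of class `synthetic_night`: `audio` ([audio_signal()]),
#'   `events` ([respiratory_events()]), `reference_ahi`, `hours`, `spec`.
#' @export
generate_night <- function(spec = night_spec(), sample_rate = 4000) {
  stopifnot(inherits(spec, "night_spec"))
  if (spec$breath_band[2] >= sample_rate / 2)
    stop("breath_band must lie below the Nyquist frequency")
  total_sec <- spec$duration_hours * 3600
  n <- as.integer(round(total_sec * sample_rate))
  n_events <- as.integer(round(spec$event_rate * spec$duration_hours))

  with_seed(spec$seed, {
    durations <- runif(n_events, spec$event_duration_range[1],
                       spec$event_duration_range[2])
    pl <- place_events(n_events, durations, total_sec, spec$min_gap)
    types <- if (n_events > 0)
      ifelse(runif(n_events) < spec$apnea_fraction, "obstructive_apnea",
             "hypopnea") else character(0)
    events <- respiratory_events(types, pl$onset %||% numeric(0),
                                 pl$duration %||% numeric(0))

    # quasi-periodic breath onsets over the whole night
    period <- 60 / spec$breath_rate
    k <- ceiling(total_sec / period) + 8L
    gaps <- period * pmax(0.3, 1 + spec$jitter * rnorm(k))
    centers <- cumsum(gaps)
    centers <- centers[centers < total_sec - 2]
    amps <- spec$base_amplitude * pmax(0.2, 1 + 0.15 * rnorm(length(centers)))

    # event modulation of individual breaths
    is_ap <- events$event_type == "obstructive_apnea"
    for (i in seq_len(nrow(events))) {
      s <- events$onset[i]; e <- s + events$duration[i]
      sel <- centers >= s & centers < e
      if (events$event_type[i] == "obstructive_apnea") {
        amps[sel] <- 0
      } else {
        amps[sel] <- amps[sel] * spec$hypopnea_attenuation *
          pmax(0.3, 1 + 0.4 * rnorm(sum(sel)))
        centers[sel] <- centers[sel] + 0.3 * rnorm(sum(sel))
      }
    }

    breath_sec <- 1.0
    blen <- as.integer(round(breath_sec * sample_rate))
    burst <- hann_burst(blen)
    env <- numeric(n)
    starts <- as.integer(round((centers - breath_sec / 2) * sample_rate))
    for (j in seq_along(starts)) {
      if (amps[j] == 0) next
      i0 <- starts[j]
      idx <- (i0 + 1L):(i0 + blen)
      ok <- idx >= 1L & idx <= n
      env[idx[ok]] <- env[idx[ok]] + amps[j] * burst[ok]
    }

    # recovery gasps after each apnea
    gasp_len <- as.integer(round(1.4 * sample_rate))
    gasp_burst <- hann_burst(gasp_len)
    env_gasp <- numeric(n)
    for (i in which(is_ap)) {
      g0 <- as.integer(round((events$onset[i] + events$duration[i] + 0.2) *
                             sample_rate))
      idx <- (g0 + 1L):(g0 + gasp_len)
      ok <- idx >= 1L & idx <= n
      env_gasp[idx[ok]] <- env_gasp[idx[ok]] +
        spec$gasp_gain * spec$base_amplitude * gasp_burst[ok]
    }

    carrier <- bandlimited_noise(n, sample_rate, spec$breath_band)
    gasp_band <- c(max(50, spec$breath_band[1] / 2),
                   min(0.475 * sample_rate, spec$breath_band[2] * 1.25))
    gasp_carrier <- bandlimited_noise(n, sample_rate, gasp_band)
    x <- env * carrier + env_gasp * gasp_carrier +
      spec$noise_floor * rnorm(n)

    structure(list(audio = audio_signal(x, sample_rate),
                   events = events,
                   reference_ahi = n_events / spec$duration_hours,
                   hours = spec$duration_hours,
                   spec = spec),
              class = "synthetic_night")
  })
}

#' @export
print.synthetic_night <- function(x, ...) {
  cat(sprintf("<synthetic_night: %.2f h, %d events, reference AHI %.1f>\n",
              x$hours, nrow(x$events), x$reference_ahi))
  invisible(x)
}

# --- synthetic home noise ----------------------------------------------------

# Per-category synthesis parameters: spectral band, stationary vs
# event-driven, transient geometry. The mapping stands in for the nine
# home-noise groups with distinct spectral shapes and transient rates; it
# is not claimed acoustically faithful.
# The nine groups get distinct, mostly narrow spectral supports, the way
# domestic noise sources concentrate their energy (fans/cars/rooms in the
# low band, clicks and animal calls high, speech/media in the middle), so
# cross-group testing probes genuinely different spectra.
noise_category_params <- function(rate) {
  ny <- 0.475 * rate
  b <- function(lo, hi) c(lo, min(hi, ny))
  list(
    home_appliance      = list(kind = "stationary",   band = b(100, 700), am = 0.1),
    room_noise          = list(kind = "stationary",   band = b(30, 600), am = 0.05),
    contents            = list(kind = "event_driven", band = b(300, 1400),
                               rate_hz = 0.8, len = 0.6),
    clock               = list(kind = "event_driven", band = b(1200, 1900),
                               rate_hz = 1.0, len = 0.03),
    speech              = list(kind = "event_driven", band = b(200, 1000),
                               rate_hz = 3.0, len = 0.15, grouped = TRUE),
    animal              = list(kind = "event_driven", band = b(1400, 1900),
                               rate_hz = 0.5, len = 0.3),
    air_conditioner_fan = list(kind = "stationary",   band = b(40, 400), am = 0.08),
    rain_wind           = list(kind = "stationary",   band = b(200, 1200), am = 0.15),
    car_motorbike       = list(kind = "event_driven", band = b(50, 300),
                               rate_hz = 0.05, len = 5.0))
}

#' Specification of a synthetic noise clip
#'
#' @param category One of [noise_categories].
#' @param duration_sec Clip duration (>= 30 s by convention; shorter clips
#'   are allowed but flagged with a warning).
#' @param kind `"stationary"` or `"event_driven"`; default per category.
#' @param transient_rate Transients per second for event-driven clips
#'   (default per category).
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(category, duration_sec = 60, kind = NULL,
                       transient_rate = NULL, seed = 1L) {
  category <- match.arg(category, noise_categories)
  if (duration_sec < 30)
    warning("noise clip shorter than 30 s; flagged as synthetic short clip")
  if (!is.null(kind)) kind <- match.arg(kind, c("stationary", "event_driven"))
  structure(list(category = category, duration_sec = duration_sec,
                 kind = kind, transient_rate = transient_rate,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate one synthetic noise clip
#'
#' Stationary clips are band-shaped Gaussian noise with a mild slow
#' amplitude modulation (time-constant spectrum, low frame-power
#' variation); event-driven clips are sparse transients over a quiet
#' floor (high frame-power kurtosis).
#'
#' @param spec A [noise_spec()].
#' @param sample_rate Sample rate in Hz.
#' @return A list of class `noise_clip`: `audio`, `category`, `kind`.
#' @export
generate_noise_clip <- function(spec, sample_rate = 4000) {
  stopifnot(inherits(spec, "noise_spec"))
  pars <- noise_category_params(sample_rate)[[spec$category]]
  kind <- spec$kind %||% pars$kind
  n <- as.integer(round(spec$duration_sec * sample_rate))
  x <- with_seed(spec$seed, {
    if (kind == "stationary") {
      base <- bandlimited_noise(n, sample_rate, pars$band)
      t <- seq_len(n) / sample_rate
      am <- pars$am %||% 0.1
      base * (1 + am * sin(2 * pi * 0.08 * t + runif(1, 0, 2 * pi)))
    } else {
      rate_hz <- spec$transient_rate %||% pars$rate_hz
      len <- as.integer(round((pars$len %||% 0.1) * sample_rate))
      floor_amp <- 0.1    # ~20 dB below transient peaks, as in domestic recordings
      out <- floor_amp * bandlimited_noise(n, sample_rate, c(30, 0.475 * sample_rate))
      n_tr <- max(1L, stats::rpois(1, rate_hz * spec$duration_sec))
      pos <- sort(runif(n_tr, 0, spec$duration_sec - len / sample_rate))
      if (isTRUE(pars$grouped)) {       # syllable-like bursts come in groups
        keep <- (pos %% 3) < 2
        if (any(keep)) pos <- pos[keep]
      }
      carrier <- bandlimited_noise(n, sample_rate, pars$band)
      burst <- hann_burst(len)
      for (p in pos) {
        i0 <- as.integer(round(p * sample_rate))
        idx <- (i0 + 1L):min(i0 + len, n)
        out[idx] <- out[idx] + runif(1, 0.6, 1.4) * burst[seq_along(idx)] *
          carrier[idx]
      }
      out
    }
  })
  structure(list(audio = audio_signal(x, sample_rate),
                 category = spec$category, kind = kind),
            class = "noise_clip")
}

#' Synthesize a full noise library
#'
#' Generates `clips_per_category` train clips and `clips_per_category`
#' test clips for each requested category, with disjoint seeds so the
#' splits share no clip.
#'
#' @param categories Subset of [noise_categories].
#' @param clips_per_category Clips per category per split.
#' @param clip_sec Clip duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param seed Master seed.
#' @return A [noise_library()] object.
#' @export
synth_noise_library <- function(categories = noise_categories,
                                clips_per_category = 3L, clip_sec = 60,
                                sample_rate = 4000, seed = 1L) {
  categories <- match.arg(categories, noise_categories, several.ok = TRUE)
  n_total <- length(categories) * clips_per_category * 2L
  seeds <- derive_seeds(seed, n_total)
  clips <- vector("list", n_total)
  cat_v <- character(n_total); split_v <- character(n_total); kind_v <- character(n_total)
  i <- 0L
  for (split in c("train", "test")) {
    for (cg in categories) {
      for (k in seq_len(clips_per_category)) {
        i <- i + 1L
        cl <- generate_noise_clip(noise_spec(cg, clip_sec, seed = seeds[i]),
                                  sample_rate)
        clips[[i]] <- cl$audio
        cat_v[i] <- cg; split_v[i] <- split; kind_v[i] <- cl$kind
      }
    }
  }
  new_noise_library(clips, cat_v, split_v, sample_rate, kind = kind_v)
}

# --- cohorts -----------------------------------------------------------------

#' Plan a cohort: severity strata, target AHIs and per-night seeds
#'
#' Apportions subjects over the four severity strata (largest-remainder
#' rounding), draws a target AHI uniformly inside each subject's stratum,
#' and clamps the implied integer event count so that the realized
#' reference AHI (events / hours) stays inside the stratum.
#'
#' @param n_subjects Number of subjects.
#' @param strata_props Proportions for strata `<5`, `5-15`, `15-30`,
#'   `>=30` (normalized internally).
#' @param duration_hours Night duration.
#' @param seed Master seed.
#' @return Data frame: `subject_id`, `stratum`, `target_ahi`, `seed`.
#' @export
cohort_plan <- function(n_subjects, strata_props = c(0.18, 0.32, 0.32, 0.18),
                        duration_hours = 1, seed = 1L) {
  stopifnot(n_subjects >= 1, length(strata_props) == 4L, all(strata_props >= 0))
  props <- strata_props / sum(strata_props)
  counts <- floor(props * n_subjects)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {                      # largest-remainder apportionment
    frac <- props * n_subjects - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  lo <- c(0, 5, 15, 30); hi <- c(5, 15, 30, 60)
  seeds <- derive_seeds(seed, n_subjects + 1L)
  target_ahi <- with_seed(seeds[n_subjects + 1L], {
    unlist(lapply(1:4, function(s) {
      if (counts[s] == 0L) return(numeric(0))
      draw <- runif(counts[s], lo[s], hi[s])
      ev <- round(draw * duration_hours)
      ev_min <- if (s == 1L) 0 else ceiling(lo[s] * duration_hours)
      ev_max <- max(ev_min, ceiling(hi[s] * duration_hours) - 1)
      pmin(pmax(ev, ev_min), ev_max) / duration_hours
    }))
  })
  data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
             stratum = rep(c("normal", "mild", "moderate", "severe"), counts),
             target_ahi = target_ahi,
             seed = seeds[seq_len(n_subjects)],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of nights
#'
#' Draws per-subject reference AHIs across the four severity strata
#' (default proportions 18/32/32/18 percent for AHI < 5, 5-15, 15-30 and
#' >= 30), generates one night per subject, and (optionally) writes WAV
#' audio, annotation CSVs and a manifest CSV.
#'
#' @param n_subjects Number of subjects.
#' @param dir Output directory (required when `write = TRUE`).
#' @param strata_props Proportions over the strata `<5`, `5-15`, `15-30`,
#'   `>=30`; normalized internally.
#' @param duration_hours Night duration.
#' @param sample_rate Sample rate in Hz.
#' @param write Write WAVs + annotations + manifest (default TRUE); when
#'   FALSE the nights are returned in memory only.
#' @param seed Master seed; the manifest and audio are reproducible.
#' @param ... Further arguments passed to [night_spec()] (e.g.
#'   `apnea_fraction`).
#' @return A list of class `synthetic_cohort`: `manifest` (data frame
#'   `subject_id, audio_path, annotation_path, reference_ahi, hours`;
#'   paths NA when `write = FALSE`) and `nights` (list of
#'   `synthetic_night`).
#' @export
generate_cohort <- function(n_subjects, dir = NULL,
                            strata_props = c(0.18, 0.32, 0.32, 0.18),
                            duration_hours = 1, sample_rate = 4000,
                            write = TRUE, seed = 1L, ...) {
  stopifnot(n_subjects >= 1)
  if (write && is.null(dir)) stop("`dir` is required when write = TRUE")
  plan <- cohort_plan(n_subjects, strata_props, duration_hours, seed)
  nights <- vector("list", n_subjects)
  manifest <- data.frame(subject_id = plan$subject_id,
                         audio_path = NA_character_,
                         annotation_path = NA_character_,
                         reference_ahi = NA_real_,
                         hours = duration_hours,
                         stringsAsFactors = FALSE)
  if (write) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_subjects)) {
    sp <- night_spec(duration_hours = duration_hours,
                     event_rate = plan$target_ahi[i], seed = plan$seed[i], ...)
    nights[[i]] <- generate_night(sp, sample_rate)
    manifest$reference_ahi[i] <- nights[[i]]$reference_ahi
    if (write) {
      ap <- file.path(dir, paste0(manifest$subject_id[i], ".wav"))
      ep <- file.path(dir, paste0(manifest$subject_id[i], "_events.csv"))
      write_wav(nights[[i]]$audio, ap)
      write_events(nights[[i]]$events, ep)
      manifest$audio_path[i] <- ap
      manifest$annotation_path[i] <- ep
    }
  }
  if (write)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(list(manifest = manifest, nights = nights),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d nights, AHI %.1f-%.1f>\n",
              nrow(x$manifest), min(x$manifest$reference_ahi),
              max(x$manifest$reference_ahi)))
  invisible(x)
}
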