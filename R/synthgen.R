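# Seeded synthetic data: SEEG-like channels with rhythmic spike-wave ictal
# epochs over a drifting-noise background, video regularity traces with
# true-event drops and nuisance dips, and patient "families" with distinct
# spectral signatures for crossover experiments. Everything is a pure
# function of (parameters, seed). The event waveform is a Gaussian-windowed
# spike train convolved with a biphasic kernel — a statistical stand-in with
# the right rhythm and buildup, not a biophysical model.

#' Background specification
#'
#' @param fs sampling rate (default 256 Hz — half the clinical 512 Hz, for
#'   test speed; 512 available by configuration).
#' @param duration_s recording length in seconds.
#' @param bands matrix/data.frame with columns `freq` (Hz) and `amp`
#'   (oscillation amplitudes, arbitrary units).
#' @param noise_sd innovation sd of the AR(1) background noise.
#' @param ar_coef AR(1) coefficient of the background noise (default 0.9).
#' @param noise_floor_drift fractional slow modulation of the noise sd
#'   (default 0.5: the noise floor swings +/-50%).
#' @param drift_freq_hz frequency of the modulation (default 0.005 Hz).
#' @param band_mod_depth log-scale depth of the slow waxing/waning of each
#'   band's amplitude — the envelope is `exp(depth * m(t))` with `m` smooth
#'   unit-variance noise, i.e. log-normal band power (default 0.5).
#' @param band_mod_timescale_s timescale of the band modulation (default 20 s,
#'   the order of slow waxing/waning of band power).
#' @param artifact_rate_per_min rate of transient movement/electrode artifact
#'   bursts (default 2/min; monitored patients move, and the emulated
#'   pipeline applies no artifact rejection). Set 0 for a clean background.
#' @param artifact_duration_s artifact length range (default 1--5 s).
#' @param artifact_gain artifact amplitude range as multiples of background
#'   RMS (default 0.75--2; a continuum of magnitudes whose forecast errors
#'   stay below ictal ones).
#' @return a list of class `background_spec`.
#' @export
background_spec <- function(fs = 256, duration_s = 600,
                            bands = default_bands("A"), noise_sd = 0.4,
                            ar_coef = 0.9, noise_floor_drift = 0.5,
                            drift_freq_hz = 0.005, band_mod_depth = 0.5,
                            band_mod_timescale_s = 20,
                            artifact_rate_per_min = 2,
                            artifact_duration_s = c(1, 5),
                            artifact_gain = c(0.75, 2)) {
  bands <- as.data.frame(bands)
  if (!all(c("freq", "amp") %in% names(bands))) {
    stop_param("bands needs 'freq' and 'amp' columns")
  }
  if (fs <= 2 * max(bands$freq)) stop_param("fs must exceed twice the highest band")
  structure(list(fs = fs, duration_s = duration_s, bands = bands,
                 noise_sd = noise_sd, ar_coef = ar_coef,
                 noise_floor_drift = noise_floor_drift,
                 drift_freq_hz = drift_freq_hz,
                 band_mod_depth = band_mod_depth,
                 band_mod_timescale_s = band_mod_timescale_s,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_duration_s = sort(artifact_duration_s),
                 artifact_gain = sort(artifact_gain)),
            class = "background_spec")
}

# Smooth unit-variance modulation signal: low-pass filtered white noise with
# the requested correlation timescale.
smooth_modulator <- function(n, fs, timescale_s) {
  a <- exp(-1 / (fs * timescale_s))
  m <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive"))
  m / max(stats::sd(m), 1e-12)
}

default_bands <- function(family = c("A", "B")) {
  family <- match.arg(family)
  # per-band modulation: most bands wax/wane slowly; the family's alpha/
  # spindle-range band is bursty (short-timescale, deeper log-normal
  # envelope), which is what makes its residual signature patient-specific
  # families share their tonic (slowly modulated) bands and differ in the
  # centre frequency of the bursty band — the patient-specific signature a
  # matched forecaster notches out and a foreign one leaks
  burst_hz <- if (family == "A") 10 else 16
  data.frame(freq = c(2, 6, burst_hz, 20), amp = c(1.0, 0.6, 0.5, 0.2),
             mod_depth = c(0.5, 0.5, 1.2, 0.5),
             mod_timescale_s = c(20, 20, 3, 20))
}

#' Seizure specification
#'
#' Rhythmic spike-wave discharges: the clinical descriptions emulated here
#' are generalized spike-and-wave trains at 2--4 Hz that build up in
#' amplitude over the opening part of the event.
#'
#' @param n_events number of events (default 2).
#' @param event_duration_s `c(min, max)` seconds (default 5--15, the scale
#'   of short focal/absence electrographic events; anomalies must be rare
#'   relative to the record for any label-free threshold to be meaningful).
#' @param spike_rate_hz discharge rate (default 4 Hz).
#' @param amplitude_gain event RMS as a multiple of background RMS (default 5,
#'   must exceed 1).
#' @param buildup_fraction fraction of the event over which amplitude ramps up
#'   (default 0.25).
#' @param spike_sigma_s width (Gaussian sigma) of each spike transient
#'   (default 0.005 s, i.e. ~30 ms spikes).
#' @param amp_jitter per-discharge amplitude jitter as a fraction (default
#'   0.3: each spike is scaled by U(0.7, 1.3)).
#' @param broadband_fraction RMS of the desynchronised fast (broadband) ictal
#'   component relative to the rhythmic component (default 0.6; ictal onsets
#'   carry low-voltage fast beta/gamma activity that no forecaster can
#'   predict one step ahead).
#' @return a list of class `seizure_spec`.
#' @export
seizure_spec <- function(n_events = 2L, event_duration_s = c(5, 15),
                         spike_rate_hz = 4, amplitude_gain = 5,
                         buildup_fraction = 0.25, spike_sigma_s = 0.005,
                         amp_jitter = 0.3, broadband_fraction = 0.6) {
  assert_scalar_number(n_events, "n_events", lower = 0)
  if (amplitude_gain <= 1) stop_param("amplitude_gain must exceed 1")
  if (any(event_duration_s <= 0)) stop_param("durations must be positive")
  structure(list(n_events = as.integer(n_events),
                 event_duration_s = sort(event_duration_s),
                 spike_rate_hz = spike_rate_hz, amplitude_gain = amplitude_gain,
                 buildup_fraction = buildup_fraction,
                 spike_sigma_s = spike_sigma_s, amp_jitter = amp_jitter,
                 broadband_fraction = broadband_fraction),
            class = "seizure_spec")
}

#' Nuisance specification for video traces
#'
#' Non-ictal activity drops (a nurse visit, a repositioning) that depress the
#' regularity score less deeply than a true event; excluded from the truth set
#' by design so false-positive behaviour is measurable.
#'
#' @param n_dips number of nuisance dips (default 2).
#' @param dip_depth drop as a fraction of the regularity range, strictly
#'   inside (0, 1) (default 0.3).
#' @param dip_duration_s `c(min, max)` seconds (default 5--15).
#' @return a list of class `nuisance_spec`.
#' @export
nuisance_spec <- function(n_dips = 2L, dip_depth = 0.3,
                          dip_duration_s = c(5, 15)) {
  if (dip_depth <= 0 || dip_depth >= 1) stop_param("dip_depth must be in (0, 1)")
  structure(list(n_dips = as.integer(n_dips), dip_depth = dip_depth,
                 dip_duration_s = sort(dip_duration_s)),
            class = "nuisance_spec")
}

# Sample non-overlapping event supports (in samples, 0-based half-open) using
# the caller's RNG stream. Events land in [region] of the recording: training
# uses the opening minutes and, as in the monitored cohorts emulated here,
# most events occur later in the record.
sample_event_intervals <- function(n_events, duration_s, fs, dur_range_s,
                                   region = c(0.40, 0.98), min_gap_s = 10) {
  if (n_events == 0L) return(event_labels(fs = fs, source = "synthetic-truth"))
  n <- round(duration_s * fs)
  for (attempt in 1:200) {
    durs <- round(stats::runif(n_events, dur_range_s[1], dur_range_s[2]) * fs)
    lo <- round(region[1] * n); hi <- round(region[2] * n)
    starts <- sort(round(stats::runif(n_events, lo, hi - max(durs))))
    ends <- starts + durs
    gap <- round(min_gap_s * fs)
    ok <- all(ends <= hi) &&
      (n_events == 1L || all(starts[-1] - ends[-n_events] >= gap))
    if (ok) {
      return(event_labels(starts, ends, fs = fs, source = "synthetic-truth"))
    }
  }
  stop_param("could not place ", n_events, " non-overlapping events; recording too short")
}

# biphasic spike kernel: Gaussian derivative, unit peak
spike_kernel <- function(fs, sigma_s = 0.015) {
  tt <- seq(-4 * sigma_s, 4 * sigma_s, by = 1 / fs)
  k <- -tt * exp(-tt^2 / (2 * sigma_s^2))
  k / max(abs(k))
}

#' Generate one synthetic SEEG-like channel
#'
#' Background = band-limited oscillations (random phases) plus AR(1) noise
#' whose standard deviation is slowly modulated (the drifting noise floor).
#' Each event superimposes a rhythmic spike-wave train (biphasic kernel at
#' `spike_rate_hz`) whose amplitude ramps up over `buildup_fraction` of the
#' event and whose RMS is `amplitude_gain` times the background RMS. The
#' event effect is confined strictly to the labelled `[start, end)` support.
#'
#' @param background a [background_spec()].
#' @param seizures a [seizure_spec()].
#' @param seed integer seed (the generator is a pure function of spec + seed).
#' @param patient_id,channel_id provenance.
#' @param events optional pre-sampled [event_labels()] (shared across a
#'   patient's channels); sampled from `seizures` when `NULL`.
#' @param projection multiplier on the event amplitude for this channel
#'   (default 1). Ictal discharges are focal: they project at full amplitude
#'   onto onset-zone contacts and far more weakly elsewhere, so channels of
#'   one patient share the event support but not its local gain.
#' @return `list(series = channel_series, labels = event_labels)`.
#' @export
gen_seeg_channel <- function(background = background_spec(),
                             seizures = seizure_spec(), seed = 1L,
                             patient_id = "synthetic", channel_id = "ch1",
                             events = NULL, projection = 1) {
  with_seed(seed, {
    fs <- background$fs
    n <- round(background$duration_s * fs)
    tt <- (seq_len(n) - 1L) / fs
    sig <- numeric(n)
    for (j in seq_len(nrow(background$bands))) {
      depth <- background$bands$mod_depth[j] %||% background$band_mod_depth
      ts_j <- background$bands$mod_timescale_s[j] %||% background$band_mod_timescale_s
      bmod <- if (depth > 0) {
        # band power waxes and wanes; log-normal envelopes are the classic
        # description of EEG band-power distributions
        exp(depth * smooth_modulator(n, fs, ts_j))
      } else 1
      sig <- sig + background$bands$amp[j] * bmod *
        sin(2 * pi * background$bands$freq[j] * tt + stats::runif(1, 0, 2 * pi))
    }
    env <- 1 + background$noise_floor_drift *
      sin(2 * pi * background$drift_freq_hz * tt + stats::runif(1, 0, 2 * pi))
    noise <- as.numeric(stats::filter(stats::rnorm(n, 0, background$noise_sd),
                                      background$ar_coef, method = "recursive"))
    sig <- sig + env * noise
    bg_rms <- sqrt(mean(sig^2))
    # transient movement/electrode artifacts: short broadband bursts with a
    # continuum of magnitudes, not part of the labelled truth
    n_art <- stats::rpois(1, background$artifact_rate_per_min *
                            background$duration_s / 60)
    if (n_art > 0L) {
      for (a in seq_len(n_art)) {
        m <- round(stats::runif(1, background$artifact_duration_s[1],
                                background$artifact_duration_s[2]) * fs)
        st <- floor(stats::runif(1, 0, n - m))
        gain <- stats::runif(1, background$artifact_gain[1],
                             background$artifact_gain[2])
        w <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))   # Hann burst
        sig[(st + 1L):(st + m)] <- sig[(st + 1L):(st + m)] +
          gain * bg_rms * w * stats::rnorm(m)
      }
    }
    if (is.null(events)) {
      events <- sample_event_intervals(seizures$n_events, background$duration_s,
                                       fs, seizures$event_duration_s)
    }
    for (i in seq_len(nrow(events))) {
      idx <- (events$start[i] + 1L):events$end[i]
      m <- length(idx)
      train <- numeric(m)
      spike_at <- seq.int(1L, m, by = max(1L, round(fs / seizures$spike_rate_hz)))
      train[spike_at] <- stats::runif(length(spike_at),
                                      1 - seizures$amp_jitter,
                                      1 + seizures$amp_jitter)
      k <- spike_kernel(fs, sigma_s = seizures$spike_sigma_s)
      wave <- as.numeric(stats::convolve(train, rev(k), type = "open"))
      half <- (length(k) - 1L) %/% 2L
      wave <- wave[(half + 1L):(half + m)]
      # desynchronised fast (broadband) ictal activity rides on the rhythmic
      # discharge and is inherently unpredictable one step ahead
      wave <- wave / sqrt(mean(wave^2)) +
        seizures$broadband_fraction * stats::rnorm(m)
      u <- (seq_len(m) - 1L) / m
      ramp <- 0.2 + 0.8 * pmin(1, u / max(seizures$buildup_fraction, 1e-9))
      wave <- wave * ramp
      wave <- wave * projection * seizures$amplitude_gain * bg_rms /
        sqrt(mean(wave^2))
      sig[idx] <- sig[idx] + wave
    }
    list(series = channel_series(sig, fs, patient_id = patient_id,
                                 channel_id = channel_id),
         labels = events)
  })
}

#' Generate a synthetic video regularity trace
#'
#' Baseline regularity near 1 with small noise; true events depress the score
#' deeply (default depth 0.8) with raised-cosine edges, nuisance dips depress
#' it less (per `nuisance`). Truth labels contain the true events only, so
#' nuisance-driven detections count as false positives downstream.
#'
#' @param duration_s trace length in seconds.
#' @param fps frame rate (default 30).
#' @param events [event_labels()] in frame indices at `fps`, or `NULL` to
#'   sample `n_events` events.
#' @param nuisance a [nuisance_spec()].
#' @param seed integer seed.
#' @param n_events events sampled when `events` is `NULL` (default 1).
#' @param event_depth regularity drop of a true event (default 0.8).
#' @param event_duration_s duration range when sampling events.
#' @param noise_sd baseline noise level (default 0.02).
#' @return `list(trace = regularity_series, labels = event_labels)` (frame
#'   index time base).
#' @export
gen_regularity_trace <- function(duration_s, fps = 30, events = NULL,
                                 nuisance = nuisance_spec(), seed = 1L,
                                 n_events = 1L, event_depth = 0.8,
                                 event_duration_s = c(10, 30),
                                 noise_sd = 0.02) {
  if (event_depth <= nuisance$dip_depth) {
    stop_param("event_depth must exceed the nuisance dip depth")
  }
  with_seed(seed, {
    n <- round(duration_s * fps)
    if (is.null(events)) {
      events <- sample_event_intervals(n_events, duration_s, fps,
                                       event_duration_s)
    }
    if (nrow(events) > 0L && max(events$end) > n) {
      stop_param("events extend past the trace duration")
    }
    s <- 1 - abs(stats::rnorm(n, 0, noise_sd))
    dip_window <- function(m) {                # raised-cosine edges
      edge <- max(2L, round(0.15 * m))
      w <- rep(1, m)
      ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
      w[seq_len(edge)] <- ramp
      w[m + 1L - seq_len(edge)] <- ramp
      w
    }
    for (i in seq_len(nrow(events))) {
      idx <- (events$start[i] + 1L):events$end[i]
      s[idx] <- s[idx] - event_depth * dip_window(length(idx))
    }
    # nuisance dips, placed clear of true events
    occupied <- logical(n)
    for (i in seq_len(nrow(events))) {
      occupied[(events$start[i] + 1L):events$end[i]] <- TRUE
    }
    placed <- 0L; tries <- 0L
    while (placed < nuisance$n_dips && tries < 500L) {
      tries <- tries + 1L
      m <- round(stats::runif(1, nuisance$dip_duration_s[1],
                              nuisance$dip_duration_s[2]) * fps)
      st <- round(stats::runif(1, 0.35 * n, n - m - 1))
      idx <- (st + 1L):(st + m)
      if (any(occupied[idx])) next
      s[idx] <- s[idx] - nuisance$dip_depth * dip_window(m)
      occupied[idx] <- TRUE
      placed <- placed + 1L
    }
    s <- pmin(pmax(s, 0), 1)
    trace <- structure(list(e_t = 1 - s, a_t = 1 - s, s_t = s, fps = fps),
                       class = "regularity_series")
    list(trace = trace, labels = events)
  })
}

#' Family specification for crossover experiments
#'
#' A "family" is a spectral signature (band structure) shared, up to small
#' per-patient jitter, by its patients; two families differ in band
#' frequencies and powers by construction, standing in for two different
#' patients' electrophysiology.
#'
#' @param name family label.
#' @param bands band table as in [background_spec()].
#' @param ... further [background_spec()] arguments.
#' @return a list of class `family_spec`.
#' @export
family_spec <- function(name = "A", bands = default_bands(name), ...) {
  structure(list(name = name, bands = as.data.frame(bands),
                 bg_args = list(...)), class = "family_spec")
}

#' Generate a family of synthetic patients
#'
#' Each patient jitters the family's band frequencies (+/-1%) and amplitudes
#' (+/-10%), samples its own ictal events (shared across that patient's
#' channels), and generates `n_channels` channels.
#'
#' @param family a [family_spec()].
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @param n_channels channels per patient (default 2).
#' @param fs,duration_s recording geometry.
#' @param seizures a [seizure_spec()].
#' @return a list of patients, each
#'   `list(patient_id, channels = list(channel_series), labels)`.
#' @export
gen_patient_family <- function(family, n_patients, seed = 1L, n_channels = 2L,
                               fs = 256, duration_s = 600,
                               seizures = seizure_spec()) {
  if (!inherits(family, "family_spec")) stop_param("'family' must be a family_spec")
  with_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      bands <- family$bands
      bands$freq <- bands$freq * stats::runif(nrow(bands), 0.99, 1.01)
      bands$amp <- bands$amp * stats::runif(nrow(bands), 0.90, 1.10)
      bg <- do.call(background_spec,
                    c(list(fs = fs, duration_s = duration_s, bands = bands),
                      family$bg_args))
      pid <- sprintf("%s%d", family$name, p)
      n_ev <- if (seizures$n_events > 0L) sample(1:3, 1L) else 0L
      events <- sample_event_intervals(n_ev, duration_s, fs,
                                       seizures$event_duration_s)
      channels <- lapply(seq_len(n_channels), function(ch) {
        sub_seed <- sample.int(.Machine$integer.max, 1L)
        # channel 1 stands in for an onset-zone contact; the rest see the
        # focal discharge only as a weak projection
        proj <- if (ch == 1L) 1 else stats::runif(1, 0.15, 0.5)
        gen_seeg_channel(bg, seizures, seed = sub_seed, patient_id = pid,
                         channel_id = sprintf("ch%d", ch),
                         events = events, projection = proj)$series
      })
      list(patient_id = pid, channels = channels, labels = events)
    })
  })
}
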