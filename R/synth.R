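# Synthetic c-VEP EEG: single-target on/off flicker driven by the bundled
# 63-bit m-sequence, convolved with per-channel evoked impulse responses,
# plus broadband / 1-f noise, latency jitter and per-session gain drift.

#' Simulation configuration
#'
#' Defaults mirror the recording protocol the decoders target: 5 sessions of
#' 114 trials, 8 occipito-parietal channels at 512 Hz, six classes given by
#' circular code shifts.
#'
#' @param n_subjects Number of subjects (default 1).
#' @param n_sessions Sessions per subject (default 5).
#' @param n_trials_per_session Trials per session (default 114).
#' @param fs Sampling rate in Hz (default 512).
#' @param refresh_hz Stimulus refresh rate in Hz (default 60).
#' @param n_channels Channel count (default 8, layout
#'   O1, O2, Oz, Pz, P3, P4, PO7, PO8).
#' @param kernel_spec Per-channel evoked impulse response description; a data
#'   frame with columns `latency_ms`, `width_ms`, `amplitude`, `osc_hz` (one
#'   row per channel). `NULL` uses [default_kernel_spec()].
#' @param snr_db Per-trial signal-to-noise ratio in dB (clean evoked power
#'   over noise power, summed across channels). Default 10.
#' @param jitter_samples Maximum absolute circular latency jitter in samples
#'   (default 2).
#' @param session_gain_sd Standard deviation of the per-session log-normal
#'   multiplicative gain (default 0.1).
#' @param noise_model One of `"white"`, `"pink"`, `"mixture"` (default
#'   `"mixture"`: equal-power white + 1/f).
#' @param seed RNG seed (default 1).
#' @return A `cvep_simconfig` list.
#' @export
sim_config <- function(n_subjects = 1L, n_sessions = 5L,
                       n_trials_per_session = 114L, fs = 512, refresh_hz = 60,
                       n_channels = 8L, kernel_spec = NULL, snr_db = 10,
                       jitter_samples = 2L, session_gain_sd = 0.1,
                       noise_model = c("mixture", "white", "pink"),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(fs > 0, n_channels >= 2L, jitter_samples >= 0, is.finite(snr_db))
  if (is.null(kernel_spec)) kernel_spec <- default_kernel_spec(n_channels)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_trials_per_session = as.integer(n_trials_per_session),
                 fs = fs, refresh_hz = refresh_hz,
                 n_channels = as.integer(n_channels),
                 kernel_spec = kernel_spec, snr_db = snr_db,
                 jitter_samples = as.integer(jitter_samples),
                 session_gain_sd = session_gain_sd,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "cvep_simconfig")
}

#' Default evoked impulse-response specification
#'
#' One damped oscillation per channel: latency 90 ms, full width at half
#' maximum 60 ms, 10 Hz carrier; occipital sites (O1, O2, Oz, PO7, PO8) carry
#' 1.5x the amplitude of parietal sites (Pz, P3, P4).
#'
#' @param n_channels Channel count; the first 8 use the named layout,
#'   additional channels repeat the parietal profile.
#' @return Data frame with one row per channel.
#' @export
default_kernel_spec <- function(n_channels = 8L) {
  names8 <- c("O1", "O2", "Oz", "Pz", "P3", "P4", "PO7", "PO8")
  occ <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  nm <- if (n_channels <= 8L) names8[seq_len(n_channels)]
        else c(names8, paste0("ch", 9:n_channels))
  amp <- ifelse(rep_len(occ, n_channels), 1.5, 1.0)
  data.frame(channel = nm, latency_ms = 90, width_ms = 60,
             amplitude = amp, osc_hz = 10, stringsAsFactors = FALSE)
}

#' Build per-channel evoked impulse responses
#'
#' Each channel's kernel is a Gaussian-windowed cosine (damped oscillation)
#' `a * exp(-(t - t0)^2 / (2 s^2)) * cos(2 pi f (t - t0))` with peak at the
#' requested latency; `s` is derived from `width_ms` read as full width at
#' half maximum. Deterministic given the spec.
#'
#' @param kernel_spec Data frame as in [default_kernel_spec()].
#' @param fs Sampling rate in Hz.
#' @param duration_ms Kernel support in ms (default 250).
#' @return `channels x L` numeric matrix.
#' @export
make_vep_kernel <- function(kernel_spec, fs, duration_ms = 250) {
  stopifnot(is.data.frame(kernel_spec), fs > 0)
  if (any(kernel_spec$width_ms <= 0)) stop("kernel width must be positive")
  if (!all(is.finite(as.matrix(kernel_spec[c("latency_ms", "width_ms",
                                             "amplitude")]))))
    stop("kernel spec values must be finite")
  L <- as.integer(round(duration_ms / 1000 * fs))
  t <- (seq_len(L) - 1L) / fs
  ker <- t(apply(kernel_spec, 1, function(row) {
    t0 <- as.numeric(row[["latency_ms"]]) / 1000
    sig <- as.numeric(row[["width_ms"]]) / 1000 / (2 * sqrt(2 * log(2)))
    a <- as.numeric(row[["amplitude"]])
    f <- as.numeric(row[["osc_hz"]])
    a * exp(-(t - t0)^2 / (2 * sig^2)) * cos(2 * pi * f * (t - t0))
  }))
  rownames(ker) <- kernel_spec$channel
  ker
}

# 1/f-power ("pink") noise: white noise spectrally shaped with amplitude
# f^(-1/2), DC removed, rescaled to unit variance. n x m matrix of columns.
pink_noise <- function(n, m) {
  w <- matrix(stats::rnorm(n * m), n, m)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric freq index
  shape <- c(0, f[-1]^(-0.5))
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# Noise tensor (channels x nt) per trial according to the model, unit power.
draw_noise <- function(model, n_channels, nt) {
  switch(model,
    white = matrix(stats::rnorm(n_channels * nt), n_channels, nt),
    pink = t(pink_noise(nt, n_channels)),
    mixture = {
      w <- matrix(stats::rnorm(n_channels * nt), n_channels, nt)
      p <- t(pink_noise(nt, n_channels))
      sqrt(0.5) * w + sqrt(0.5) * p
    })
}

# Clean class templates: channels x nt x classes. The code waveform is
# mean-centered (the evoked response follows luminance modulation around its
# mean) and circularly convolved with each channel kernel; circular
# convolution is the faithful choice because the stimulus is periodic with
# the epoch.
clean_templates <- function(bank, kernel, fs, refresh_hz, nt) {
  n_ch <- nrow(kernel)
  kpad <- cbind(kernel, matrix(0, n_ch, nt - ncol(kernel)))
  kf <- t(stats::mvfft(t(kpad)))                      # channel-wise FFT
  out <- array(0, c(n_ch, nt, bank$n_classes))
  for (c in seq_len(bank$n_classes)) {
    w <- code_to_waveform(new_code(bank$codes[c, ]), refresh_hz, fs)
    wf <- stats::fft(w - mean(w))
    out[, , c] <- Re(t(stats::mvfft(t(kf * rep(wf, each = n_ch)),
                                    inverse = TRUE))) / nt
  }
  out
}

#' Simulate c-VEP epochs
#'
#' Per trial, the clean signal is the class code waveform circularly convolved
#' with the channel impulse responses, circularly delayed by an integer jitter
#' drawn uniformly from `[-jitter, +jitter]`; noise is added to reach
#' `snr_db` exactly (clean power over noise power, summed across channels);
#' a multiplicative log-normal gain is drawn once per session. Labels are
#' balanced across classes as evenly as the trial count allows. Fully
#' reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param bank A [build_code_bank()] whose bit length matches
#'   `config$fs / config$refresh_hz` timing.
#' @return A [new_epochs()] object with
#'   `n_subjects * n_sessions * n_trials_per_session` trials. The clean
#'   class templates are attached as attribute `"templates"`
#'   (`channels x time x classes`).
#' @export
simulate_epochs <- function(config, bank) {
  stopifnot(inherits(config, "cvep_simconfig"), inherits(bank, "cvep_codebank"))
  if (bank$n_classes < 1L) stop("empty code bank")
  nt <- samples_per_period(ncol(bank$codes), config$refresh_hz, config$fs)
  kernel <- make_vep_kernel(config$kernel_spec, config$fs)
  if (ncol(kernel) >= nt) stop("kernel support must be shorter than the epoch")
  tpl <- clean_templates(bank, kernel, config$fs, config$refresh_hz, nt)
  n_ch <- config$n_channels
  n_per <- config$n_trials_per_session
  n_all <- config$n_subjects * config$n_sessions * n_per
  snr_lin <- 10^(config$snr_db / 10)

  with_seed(config$seed, {
    data <- array(0, c(n_all, n_ch, nt))
    labels <- integer(n_all); session <- integer(n_all)
    subject <- integer(n_all)
    i <- 0L
    for (su in seq_len(config$n_subjects)) {
      for (se in seq_len(config$n_sessions)) {
        gain <- exp(stats::rnorm(1, 0, config$session_gain_sd))
        labs <- sample(rep_len(seq_len(bank$n_classes), n_per))
        for (k in seq_len(n_per)) {
          i <- i + 1L
          cl <- labs[k]
          jit <- if (config$jitter_samples > 0)
            sample(seq(-config$jitter_samples, config$jitter_samples), 1)
          else 0L
          clean <- tpl[, , cl]
          if (jit != 0L) clean <- clean[, ((seq_len(nt) - 1L - jit) %% nt) + 1L]
          noise <- draw_noise(config$noise_model, n_ch, nt)
          scale <- sqrt(sum(clean^2) / (sum(noise^2) * snr_lin))
          data[i, , ] <- gain * (clean + scale * noise)
          labels[i] <- cl; session[i] <- se; subject[i] <- su
        }
      }
    }
    ep <- new_epochs(data, labels, session, config$fs,
                     config$kernel_spec$channel, subject)
    attr(ep, "templates") <- tpl
    ep
  })
}
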