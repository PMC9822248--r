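# unit-peak biexponential PSC waveform sampled at fs; taus in ms
biexp_waveform <- function(tau_rise, tau_decay, fs, length_ms = NULL) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  if (is.null(length_ms)) length_ms <- tau_rise + 8 * tau_decay
  t <- seq(0, length_ms / 1000, by = 1 / fs)
  w <- exp(-t / (tau_decay / 1000)) - exp(-t / (tau_rise / 1000))
  w / max(w)
}

add_event <- function(samples, onset_idx, waveform, amplitude, sign) {
  n <- length(samples)
  k <- min(length(waveform), n - onset_idx + 1)
  if (k > 0) {
    idx <- onset_idx:(onset_idx + k - 1)
    samples[idx] <- samples[idx] + sign * amplitude * waveform[seq_len(k)]
  }
  samples
}

#' Simulate a current trace with known ground truth
#'
#' Generates the waveforms the metrics operate on: a paired-pulse sweep
#' (`"evoked_pair"`), a hypertonic-sucrose response (`"sucrose_step"`), a
#' spontaneous miniature-event recording (`"minis"`), or a stimulus train
#' (`"train"`). Every inserted event is reported in the `ground_truth`
#' attribute, so detection and measurement can be validated exactly.
#'
#' Evoked responses are biexponential PSCs starting `delay_ms` after each
#' stimulus; an optional brief biphasic stimulus artifact can be added at the
#' stimulus time itself. The sucrose response is a plateau of the stated
#' amplitude and duration beginning `app_delay` seconds after the recorded
#' application time; its injected charge (|amplitude| x duration, pA s = pC)
#' is part of the ground truth.
#'
#' @param kind one of `"evoked_pair"`, `"sucrose_step"`, `"minis"`, `"train"`.
#' @param sampling_rate Hz.
#' @param noise_sd additive Gaussian noise SD (pA).
#' @param polarity response sign convention, see [sweep_trace()].
#' @param seed integer seed (generator is deterministic given the seed).
#' @param amplitudes (`evoked_pair`) the two PSC amplitudes (pA).
#' @param interval_ms (`evoked_pair`) interstimulus interval.
#' @param stim_start first stimulus time (s).
#' @param delay_ms synaptic delay from stimulus to response onset.
#' @param tau_rise,tau_decay biexponential time constants (ms).
#' @param artifact_amplitude stimulus-artifact spike amplitude (pA, 0 = none).
#' @param amplitude (`sucrose_step`) plateau magnitude (pA).
#' @param app_time (`sucrose_step`) application time recorded as stimulus (s).
#' @param app_delay (`sucrose_step`) delay from application to response (s).
#' @param plateau_duration (`sucrose_step`) plateau length (s).
#' @param duration trace length (s); default depends on `kind`.
#' @param rate (`minis`) mean event rate (Hz); (`train`) stimulus rate (Hz).
#' @param amplitude_mean,amplitude_sd (`minis`) event amplitude distribution
#'   (normal, truncated at 0.1 pA).
#' @param min_interval (`minis`) minimum spacing between inserted events (s).
#' @param event_times (`minis`) explicit event times (s), overriding the
#'   Poisson draw.
#' @param n_stimuli (`train`) number of stimuli.
#' @param first_amplitude,depression_ratio (`train`) geometric amplitude
#'   sequence `first_amplitude * depression_ratio^(i-1)`.
#' @return a [sweep_trace()] with attribute `ground_truth`.
#' @examples
#' tr <- simulate_trace("evoked_pair", noise_sd = 0)
#' attr(tr, "ground_truth")$ppr
#' @export
simulate_trace <- function(kind = c("evoked_pair", "sucrose_step", "minis", "train"),
                           sampling_rate = 5000, noise_sd = 0,
                           polarity = "inward", seed = NULL,
                           amplitudes = c(100, 150), interval_ms = 50,
                           stim_start = 0.1, delay_ms = 4,
                           tau_rise = 0.3, tau_decay = 4,
                           artifact_amplitude = 0,
                           amplitude = 100, app_time = 2, app_delay = 0.2,
                           plateau_duration = 10,
                           duration = NULL, rate = NULL,
                           amplitude_mean = 30, amplitude_sd = 0,
                           min_interval = 0.1, event_times = NULL,
                           n_stimuli = 50, first_amplitude = 100,
                           depression_ratio = 1) {
  kind <- match.arg(kind)
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0", call. = FALSE)
  stop_if_negative(noise_sd, "noise_sd")
  fs <- sampling_rate
  sgn <- if (polarity == "inward") -1 else 1
  idx_of <- function(t) round(t * fs) + 1L

  with_seed_or_current(seed, {
    if (kind == "evoked_pair") {
      if (is.null(duration)) duration <- stim_start + interval_ms / 1000 + 0.15
      y <- numeric(round(duration * fs))
      stims <- stim_start + c(0, interval_ms / 1000)
      w <- biexp_waveform(tau_rise, tau_decay, fs)
      ev <- stims + delay_ms / 1000
      for (i in 1:2) y <- add_event(y, idx_of(ev[i]), w, amplitudes[i], sgn)
      gt <- list(stimulus_times = stims, event_times = ev,
                 amplitudes = amplitudes, ppr = amplitudes[2] / amplitudes[1])
    } else if (kind == "sucrose_step") {
      if (is.null(duration)) duration <- app_time + app_delay + plateau_duration + 2
      y <- numeric(round(duration * fs))
      on <- app_time + app_delay
      i0 <- idx_of(on); i1 <- min(idx_of(on + plateau_duration) - 1L, length(y))
      y[i0:i1] <- sgn * amplitude
      stims <- app_time
      gt <- list(onset_time = on, amplitude = amplitude,
                 plateau_duration = plateau_duration,
                 charge_pC = amplitude * plateau_duration)
    } else if (kind == "minis") {
      if (is.null(rate)) rate <- 0.1
      if (is.null(duration)) duration <- 110
      y <- numeric(round(duration * fs))
      if (is.null(event_times)) {
        n_ev <- rpois(1, rate * (duration - 2))
        times <- numeric(0)
        tries <- 0
        while (length(times) < n_ev && tries < 50 * max(n_ev, 1)) {
          cand <- runif(1, 1, duration - 1)
          if (!length(times) || min(abs(times - cand)) >= min_interval)
            times <- c(times, cand)
          tries <- tries + 1
        }
      } else {
        times <- event_times
      }
      times <- sort(times)
      amps <- pmax(rnorm(length(times), amplitude_mean, amplitude_sd), 0.1)
      w <- biexp_waveform(tau_rise, tau_decay, fs)
      for (i in seq_along(times)) y <- add_event(y, idx_of(times[i]), w, amps[i], sgn)
      stims <- numeric(0)
      gt <- list(event_times = times, amplitudes = amps,
                 rate = rate, analysis_window = duration)
    } else { # train
      if (is.null(rate)) rate <- 10
      if (is.null(duration)) duration <- 0.5 + n_stimuli / rate + 0.3
      y <- numeric(round(duration * fs))
      stims <- 0.5 + (seq_len(n_stimuli) - 1) / rate
      amps <- first_amplitude * depression_ratio^(seq_len(n_stimuli) - 1)
      w <- biexp_waveform(tau_rise, tau_decay, fs)
      for (i in seq_len(n_stimuli))
        y <- add_event(y, idx_of(stims[i] + delay_ms / 1000), w, amps[i], sgn)
      gt <- list(stimulus_times = stims, amplitudes = amps, rate = rate)
    }

    if (artifact_amplitude > 0 && length(stims)) {
      for (s in stims) {
        i <- idx_of(s)
        if (i + 3 <= length(y))
          y[i:(i + 3)] <- y[i:(i + 3)] + artifact_amplitude * c(1, 1, -1, -1)
      }
    }
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    tr <- sweep_trace(y, fs, stims, polarity)
    attr(tr, "ground_truth") <- gt
    tr
  })
}
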