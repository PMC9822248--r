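# index range helper: closed interval [t0, t1] in seconds -> sample indices
window_idx <- function(trace, t0, t1) {
  n <- length(trace$samples)
  i0 <- floor(t0 * trace$sampling_rate + 1e-9) + 1L
  i1 <- floor(t1 * trace$sampling_rate + 1e-9) + 1L
  if (i0 < 1 || i1 > n || i1 < i0)
    stop("analysis window [", t0, ", ", t1, ") s exceeds the trace", call. = FALSE)
  i0:i1
}

# baseline and peak-search windows for the response to stimulus_index.
# Baseline is taken immediately after the stimulus artifact: a short window
# starting when the artifact blanking ends. Peak search runs from there to the
# next stimulus (or `window_ms` for the last/single stimulus).
response_windows <- function(trace, stimulus_index, blank_ms, baseline_ms,
                             window_ms) {
  st <- trace$stimulus_times
  if (stimulus_index < 1 || stimulus_index > length(st))
    stop("`stimulus_index` out of range", call. = FALSE)
  t_stim <- st[stimulus_index]
  if (is.null(window_ms)) {
    window_ms <- if (stimulus_index < length(st))
      1000 * (st[stimulus_index + 1] - t_stim) else 50
  }
  b0 <- t_stim + blank_ms / 1000
  list(baseline = c(b0, b0 + baseline_ms / 1000),
       search = c(b0, t_stim + window_ms / 1000))
}

#' Evoked postsynaptic current amplitude
#'
#' Amplitude of the response to one stimulus: the polarity-signed extremum in
#' the post-stimulus search window minus a baseline measured immediately after
#' the stimulus artifact (a `baseline_ms` window starting once the
#' `blank_ms` artifact-blanking period has elapsed). Taking the baseline after
#' each artifact makes the measure robust to responses riding on the decay of
#' an earlier response, as in paired-pulse and train protocols. Returns a
#' non-negative magnitude in pA.
#'
#' @param trace a [sweep_trace()].
#' @param stimulus_index which stimulus (1-based).
#' @param blank_ms artifact blanking window after the stimulus (ms), excluded
#'   from baseline and peak search.
#' @param baseline_ms baseline window length (ms).
#' @param window_ms peak search window from the stimulus (ms); default is the
#'   interval to the next stimulus, or 50 ms for the last/single stimulus.
#' @return amplitude in pA (>= 0).
#' @export
psc_amplitude <- function(trace, stimulus_index = 1, blank_ms = 2,
                          baseline_ms = 1, window_ms = NULL) {
  stopifnot(inherits(trace, "sweep_trace"))
  w <- response_windows(trace, stimulus_index, blank_ms, baseline_ms, window_ms)
  baseline <- mean(trace$samples[window_idx(trace, w$baseline[1], w$baseline[2])])
  seg <- trace$samples[window_idx(trace, w$search[1], w$search[2])]
  sgn <- polarity_sign(trace)
  peak <- if (sgn < 0) min(seg) else max(seg)
  max(0, sgn * (peak - baseline))
}

#' 20-80% rise time of an evoked response
#'
#' Time between the first crossings of 20% and 80% of the peak amplitude on
#' the rising phase, with linear interpolation between samples.
#'
#' @inheritParams psc_amplitude
#' @return rise time in ms.
#' @export
rise_time_20_80 <- function(trace, stimulus_index = 1, blank_ms = 2,
                            baseline_ms = 1, window_ms = NULL) {
  stopifnot(inherits(trace, "sweep_trace"))
  w <- response_windows(trace, stimulus_index, blank_ms, baseline_ms, window_ms)
  baseline <- mean(trace$samples[window_idx(trace, w$baseline[1], w$baseline[2])])
  idx <- window_idx(trace, w$search[1], w$search[2])
  r <- polarity_sign(trace) * (trace$samples[idx] - baseline)  # response-positive
  amp <- max(r)
  if (amp <= 0) stop("zero response amplitude: rise time undefined", call. = FALSE)
  ipk <- which.max(r)
  cross <- function(level) {
    j <- which(r[seq_len(ipk)] >= level)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1 || r[j] == r[j - 1]) return(j - 1)
    (j - 1) - (r[j] - level) / (r[j] - r[j - 1])  # fractional sample, 0-based
  }
  t20 <- cross(0.2 * amp); t80 <- cross(0.8 * amp)
  1000 * (t80 - t20) / trace$sampling_rate
}

#' Paired-pulse ratio
#'
#' Sweeps are averaged sample-wise into one mean trace and the ratio is the
#' amplitude of the second response divided by the first, both measured with
#' [psc_amplitude()] (the second baselined immediately after the second
#' stimulus artifact). Set `method = "per_sweep"` to average per-sweep ratios
#' instead.
#'
#' @param sweeps a list of [sweep_trace()] objects (>= 1), all with the same
#'   two stimulus times, or a single trace.
#' @param method `"average_trace"` (default) or `"per_sweep"`.
#' @inheritParams psc_amplitude
#' @return the ratio (> 0).
#' @export
paired_pulse_ratio <- function(sweeps, method = c("average_trace", "per_sweep"),
                               blank_ms = 2, baseline_ms = 1) {
  method <- match.arg(method)
  if (inherits(sweeps, "sweep_trace")) sweeps <- list(sweeps)
  if (!length(sweeps)) stop("need at least one sweep", call. = FALSE)
  st <- sweeps[[1]]$stimulus_times
  if (length(st) != 2)
    stop("paired-pulse sweeps must have exactly two stimuli", call. = FALSE)
  for (s in sweeps) {
    if (length(s$stimulus_times) != 2 ||
        max(abs(s$stimulus_times - st)) > 1e-9 ||
        s$sampling_rate != sweeps[[1]]$sampling_rate)
      stop("all sweeps must share stimulus times and sampling rate", call. = FALSE)
  }
  one_ppr <- function(tr) {
    a1 <- psc_amplitude(tr, 1, blank_ms, baseline_ms)
    a2 <- psc_amplitude(tr, 2, blank_ms, baseline_ms)
    if (a1 == 0) stop("first-pulse amplitude is zero: ratio undefined", call. = FALSE)
    a2 / a1
  }
  if (method == "average_trace") {
    n <- min(vapply(sweeps, function(s) length(s$samples), integer(1)))
    m <- rowMeans(vapply(sweeps, function(s) s$samples[seq_len(n)], numeric(n)))
    one_ppr(sweep_trace(m, sweeps[[1]]$sampling_rate, st, sweeps[[1]]$polarity))
  } else {
    mean(vapply(sweeps, one_ppr, numeric(1)))
  }
}

#' Hypertonic-sucrose charge (readily releasable pool estimate)
#'
#' Trapezoidal integral of the absolute baseline-subtracted current over the
#' first `window` seconds from response onset; pA x s = pC. The baseline is
#' the mean of the pre-application segment (before the first stimulus/
#' application time, or the first second when no application time is
#' recorded). Onset is the first crossing of `onset_sd_mult` x baseline SD
#' that is sustained for `sustain_ms`, searched after the application time;
#' pass `onset` to override detection.
#'
#' @param trace a [sweep_trace()] at least `window` seconds long past onset.
#' @param window integration window (s); the paper's convention for pool
#'   estimates is the first 10 s of the response.
#' @param onset response onset time (s), or NULL to detect.
#' @param onset_sd_mult onset threshold in baseline-SD units.
#' @param sustain_ms the crossing must persist this long to count as onset.
#' @return charge in pC.
#' @export
sucrose_charge <- function(trace, window = 10, onset = NULL,
                           onset_sd_mult = 3, sustain_ms = 50) {
  stopifnot(inherits(trace, "sweep_trace"))
  app <- if (length(trace$stimulus_times)) trace$stimulus_times[1] else 1
  base_idx <- window_idx(trace, 0, app)
  baseline <- mean(trace$samples[base_idx])
  r <- polarity_sign(trace) * (trace$samples - baseline)  # response-positive
  if (is.null(onset)) {
    thr <- max(onset_sd_mult * sd(trace$samples[base_idx]), 1e-9)
    k <- max(1L, round(sustain_ms / 1000 * trace$sampling_rate))
    start <- floor(app * trace$sampling_rate) + 1L
    above <- r >= thr
    above[seq_len(start - 1L)] <- FALSE
    # first index from which `above` holds for k consecutive samples
    run <- cumsum(above); run <- c(run[k:length(run)]) - c(0, run[seq_len(length(run) - k)])
    j <- which(run == k)[1]
    if (is.na(j)) {
      if (max(r[start:length(r)]) < thr) return(0)  # flat trace: no response
      stop("no sustained response onset detected", call. = FALSE)
    }
    onset <- (j - 1) / trace$sampling_rate
  }
  idx <- window_idx(trace, onset, onset + window)
  tt <- (idx - 1) / trace$sampling_rate
  pracma::trapz(tt, abs(r[idx]))
}

#' Per-stimulus amplitudes of a stimulus train
#'
#' One [psc_amplitude()] per stimulus, each baselined immediately after its
#' own stimulus artifact, as required when responses summate during trains
#' (e.g. 50 stimuli at 10 Hz).
#'
#' @inheritParams psc_amplitude
#' @return numeric vector, one amplitude (pA) per stimulus.
#' @export
train_amplitudes <- function(trace, blank_ms = 2, baseline_ms = 1) {
  stopifnot(inherits(trace, "sweep_trace"))
  n <- length(trace$stimulus_times)
  if (!n) stop("trace has no stimulus times", call. = FALSE)
  vapply(seq_len(n), function(i) psc_amplitude(trace, i, blank_ms, baseline_ms),
         numeric(1))
}
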