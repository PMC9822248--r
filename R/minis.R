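#' Detect miniature synaptic events by scaled-template matching
#'
#' Slides an idealized biexponential PSC template along the trace and, at each
#' offset, finds the least-squares optimal scale and baseline offset of the
#' template. The detection criterion is the fitted scale divided by the
#' standard error of the fit (Clements & Bekkers style); samples where the
#' criterion exceeds `threshold` (in noise-SD units) with a positive scale are
#' candidate events, reduced to one event per local maximum of the criterion
#' and separated by at least `min_interval_ms`.
#'
#' @param trace a [sweep_trace()].
#' @param tau_rise,tau_decay template time constants (ms).
#' @param template_ms template length (ms).
#' @param threshold detection criterion threshold (default 4).
#' @param analysis_window seconds of trace analyzed from the start (the
#'   miniature-frequency convention is a 100 s window).
#' @param min_interval_ms minimum separation between detected events.
#' @return data frame of events (`time` s at template onset, `amplitude` pA,
#'   `rise_20_80` ms, `decay_time` ms, `criterion`), sorted by time, with
#'   attributes `frequency` (events / `analysis_window`, Hz) and
#'   `analysis_window`.
#' @export
detect_minis <- function(trace, tau_rise = 0.3, tau_decay = 4,
                         template_ms = 30, threshold = 4,
                         analysis_window = 100, min_interval_ms = 5) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (analysis_window > trace$duration + 1e-9)
    stop("`analysis_window` exceeds trace duration", call. = FALSE)
  fs <- trace$sampling_rate
  y <- polarity_sign(trace) * trace$samples[seq_len(round(analysis_window * fs))]
  tmpl <- biexp_waveform(tau_rise, tau_decay, fs, template_ms)
  K <- length(tmpl)
  if (K > length(y)) stop("template longer than the analyzed trace", call. = FALSE)

  # sliding sums via FFT correlation; s[i] refers to the window starting at i
  ones <- rep(1, K)
  se  <- convolve(y,   ones, type = "filter")
  see <- convolve(y^2, ones, type = "filter")
  ste <- convolve(y,   tmpl, type = "filter")
  st  <- sum(tmpl); stt <- sum(tmpl^2)

  scale  <- (ste - st * se / K) / (stt - st^2 / K)
  offset <- (se - scale * st) / K
  sse <- see + scale^2 * stt + K * offset^2 -
    2 * scale * ste - 2 * offset * se + 2 * scale * offset * st
  sse[sse < 0] <- 0
  std_err <- sqrt(sse / (K - 1))
  crit <- ifelse(std_err > 0, scale / std_err, 0)
  crit[scale <= 0] <- 0

  hit <- crit > threshold
  if (!any(hit)) {
    ev <- data.frame(time = numeric(0), amplitude = numeric(0),
                     rise_20_80 = numeric(0), decay_time = numeric(0),
                     criterion = numeric(0))
  } else {
    runs <- rle(hit)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    onsets <- integer(0); crits <- numeric(0)
    for (r in which(runs$values)) {
      i <- starts[r]:ends[r]
      onsets <- c(onsets, i[which.max(crit[i])])
      crits <- c(crits, max(crit[i]))
    }
    # enforce minimum separation, keeping the stronger detection
    min_gap <- round(min_interval_ms / 1000 * fs)
    keep <- order(-crits)
    taken <- logical(length(onsets))
    for (k in keep) {
      if (any(taken & abs(onsets - onsets[k]) < min_gap)) next
      taken[k] <- TRUE
    }
    onsets <- sort(onsets[taken])
    ev <- do.call(rbind, lapply(onsets, function(i) {
      s <- scale[i]; b <- offset[i]
      seg <- y[i:(i + K - 1)] - b
      ipk <- which.max(seg); pk <- seg[ipk]
      cr <- function(level) {
        j <- which(seg[seq_len(ipk)] >= level)[1]
        if (is.na(j) || j == 1) return(j - 1)
        (j - 1) - (seg[j] - level) / (seg[j] - seg[j - 1])
      }
      t20 <- cr(0.2 * pk); t80 <- cr(0.8 * pk)
      dec <- which(seg[ipk:length(seg)] <= pk * exp(-1))[1]
      data.frame(time = (i - 1) / fs, amplitude = s,
                 rise_20_80 = 1000 * (t80 - t20) / fs,
                 decay_time = if (is.na(dec)) NA_real_ else 1000 * (dec - 1) / fs,
                 criterion = crit[i])
    }))
  }
  attr(ev, "frequency") <- nrow(ev) / analysis_window
  attr(ev, "analysis_window") <- analysis_window
  ev
}
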