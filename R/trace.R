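#' Construct a sampled current trace
#'
#' A `sweep_trace` is a regularly sampled whole-cell current recording together
#' with the metadata the metrics need: sampling rate, stimulus times, and the
#' sign convention of the synaptic response.
#'
#' @param samples numeric vector of current samples (pA).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param stimulus_times stimulus (or application) onset times in seconds,
#'   ordered, within the trace.
#' @param polarity `"inward"` (negative-going responses, cells held below the
#'   reversal potential) or `"outward"`.
#' @return an object of class `sweep_trace`.
#' @export
sweep_trace <- function(samples, sampling_rate, stimulus_times = numeric(0),
                        polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  duration <- length(samples) / sampling_rate
  if (length(stimulus_times)) {
    if (is.unsorted(stimulus_times) || any(stimulus_times < 0) ||
        any(stimulus_times >= duration))
      stop("`stimulus_times` must be ordered and within [0, duration)", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 stimulus_times = as.numeric(stimulus_times),
                 polarity = polarity, duration = duration),
            class = "sweep_trace")
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("<sweep_trace> %.3f s at %g Hz (%d samples), %s, %d stimuli\n",
              x$duration, x$sampling_rate, length(x$samples), x$polarity,
              length(x$stimulus_times)))
  invisible(x)
}

# time axis in seconds (sample i at (i-1)/fs)
trace_time <- function(trace) (seq_along(trace$samples) - 1) / trace$sampling_rate

# +1 if responses go positive, -1 if negative
polarity_sign <- function(trace) if (trace$polarity == "inward") -1 else 1

#' Read / write a current trace as delimited text
#'
#' Two-column tab-separated table (`time`, `current`); sampling rate is taken
#' from the time column. Metadata (stimulus times, polarity) travels in the
#' arguments or in a JSON sidecar written next to the table.
#'
#' @param path file path of the table.
#' @param stimulus_times,polarity see [sweep_trace()]; ignored when a sidecar
#'   `<path>.json` exists, which takes precedence.
#' @return a `sweep_trace`.
#' @export
read_trace <- function(path, stimulus_times = numeric(0), polarity = "inward") {
  x <- utils::read.delim(path)
  if (!all(c("time", "current") %in% names(x)))
    stop("trace table must have columns `time` and `current`", call. = FALSE)
  dt <- diff(x$time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("time column must be regularly sampled", call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$stimulus_times)) stimulus_times <- meta$stimulus_times
    if (!is.null(meta$polarity)) polarity <- meta$polarity
  }
  sweep_trace(x$current, 1 / mean(dt), stimulus_times, polarity)
}

#' @rdname read_trace
#' @param trace a `sweep_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  utils::write.table(
    data.frame(time = trace_time(trace), current = trace$samples),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = trace$sampling_rate,
         stimulus_times = trace$stimulus_times, polarity = trace$polarity),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
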