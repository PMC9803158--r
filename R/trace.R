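#' Per-frame averaged color trace
#'
#' Container for the spatially averaged intensity of one color channel per
#' video frame, with its frame rate.  This is the raw input to the
#' preprocessing and denoising chain.
#'
#' @param values numeric vector of per-frame mean intensities (length >= 2).
#' @param fps frames per second (> 0).
#' @param t0 time of the first frame in seconds.
#' @param channel channel label, informational ("G" by default).
#' @return an object of class `color_trace`.
#' @export
color_trace <- function(values, fps, t0 = 0, channel = "G") {
  check_series(values, "values")
  check_scalar(fps, "fps", positive = TRUE)
  check_scalar(t0, "t0")
  structure(list(values = as.numeric(values), fps = fps, t0 = t0,
                 channel = channel),
            class = "color_trace")
}

#' @export
print.color_trace <- function(x, ...) {
  cat(sprintf("<color_trace> channel %s, %d frames @ %g fps (%.1f s)\n",
              x$channel, length(x$values), x$fps, length(x$values) / x$fps))
  invisible(x)
}

#' @export
length.color_trace <- function(x) length(x$values)

#' Frame timestamps of a trace
#' @param trace a [color_trace()].
#' @return numeric vector of per-frame times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$fps
}

#' Read / write a color trace as CSV
#'
#' The on-disk format is two columns, `t_seconds` and `value`; the frame
#' rate is recovered from the median time step on read.
#'
#' @param trace a [color_trace()].
#' @param path file path.
#' @return `read_trace_csv` returns a [color_trace()];
#'   `write_trace_csv` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "color_trace"))
  utils::write.csv(data.frame(t_seconds = trace_times(trace),
                              value = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fps optional frame rate override; inferred from timestamps when NULL.
#' @export
read_trace_csv <- function(path, fps = NULL) {
  d <- utils::read.csv(path)
  stop_if(!all(c("t_seconds", "value") %in% names(d)),
          "trace CSV needs columns 't_seconds' and 'value'")
  if (is.null(fps)) {
    dt <- stats::median(diff(d$t_seconds))
    stop_if(!is.finite(dt) || dt <= 0, "cannot infer fps from timestamps")
    fps <- 1 / dt
  }
  color_trace(d$value, fps = fps, t0 = d$t_seconds[1])
}
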