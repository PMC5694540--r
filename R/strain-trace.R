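#' Two-channel feeder strain trace
#'
#' Container for the amplified strain-gauge voltages recorded at the feeder:
#' a horizontal and a vertical channel sampled uniformly (1,000 Hz in the
#' instrumented-feeder rig), plus the dock/undock event intervals during which a bird was
#' present and feeding.
#'
#' @param time_s Sample times (s), uniformly spaced.
#' @param horizontal_V Horizontal-axis channel voltage.
#' @param vertical_V Vertical-axis channel voltage.
#' @param docks List of `c(start, end)` dock intervals (s), strictly inside
#'   the record, time-ordered and non-overlapping.
#' @return An object of class `strain_trace`: a data frame with columns
#'   `time_s`, `horizontal_V`, `vertical_V` and attributes `docks` (list)
#'   and `fs` (sampling rate, Hz).
#' @export
strain_trace <- function(time_s, horizontal_V, vertical_V, docks = list()) {
  n <- length(time_s)
  stopifnot(length(horizontal_V) == n, length(vertical_V) == n, n >= 2L)
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-9) stopf("time_s must be uniformly sampled")
  fs <- 1 / mean(dt)
  docks <- lapply(docks, function(d) {
    d <- as.numeric(d)
    if (length(d) != 2L || d[2L] <= d[1L]) stopf("each dock must be c(start, end) with end > start")
    d
  })
  if (length(docks) > 1L) {
    o <- order(vapply(docks, `[`, 0, 1L))
    docks <- docks[o]
    starts <- vapply(docks, `[`, 0, 1L)
    ends <- vapply(docks, `[`, 0, 2L)
    if (any(starts[-1L] < ends[-length(ends)])) stopf("dock intervals must not overlap")
  }
  for (d in docks) {
    if (d[1L] <= time_s[1L] || d[2L] >= time_s[n]) {
      stopf("dock intervals must lie strictly inside the record")
    }
  }
  out <- data.frame(time_s = time_s, horizontal_V = horizontal_V,
                    vertical_V = vertical_V)
  attr(out, "docks") <- docks
  attr(out, "fs") <- fs
  class(out) <- c("strain_trace", "data.frame")
  out
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf("<strain_trace> %.1f s at %.0f Hz, %d dock event(s)\n",
              max(x$time_s) - min(x$time_s), attr(x, "fs"),
              length(attr(x, "docks"))))
  invisible(x)
}

#' @rdname strain_trace
#' @param x An object.
#' @export
docks <- function(x) attr(x, "docks")

#' @rdname strain_trace
#' @export
sample_rate <- function(x) attr(x, "fs")
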