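LANDMARKS <- c("head", "tail", "l_shoulder", "r_shoulder",
               "l_wingtip", "r_wingtip", "l_p5", "r_p5")

new_landmark_set <- function(time_s, coords) {
  structure(list(time_s = time_s, coords = coords,
                 fs = 1 / mean(diff(time_s))),
            class = "landmark_set")
}

#' 3D landmark trajectory set
#'
#' Container for the time-indexed 3D positions of the eight digitized
#' anatomical landmarks. Accepts tidy long-format data (`time_s`,
#' `landmark`, `x_m`, `y_m`, `z_m`); sampling must be uniform, and gaps of
#' at most 5 ms are linearly interpolated while longer gaps are rejected.
#'
#' @param df Tidy data frame with columns `time_s`, `landmark` (one of
#'   head, tail, l_shoulder, r_shoulder, l_wingtip, r_wingtip, l_p5, r_p5),
#'   `x_m`, `y_m`, `z_m`.
#' @param max_gap_s Longest gap to interpolate (default 0.005 s).
#' @return An object of class `landmark_set`: list with `time_s`, `coords`
#'   (named list of n-by-3 matrices) and `fs`.
#' @export
landmark_set <- function(df, max_gap_s = 0.005) {
  df <- as.data.frame(df)
  missing_lm <- setdiff(LANDMARKS, unique(df$landmark))
  if (length(missing_lm)) stopf("missing landmarks: %s", paste(missing_lm, collapse = ", "))
  tt <- sort(unique(df$time_s))
  dt <- diff(tt)
  step <- stats::median(dt)
  if (any(dt > max_gap_s + step / 2)) {
    stopf("gaps longer than %.3f s cannot be interpolated", max_gap_s)
  }
  grid <- seq(min(tt), max(tt), by = step)
  coords <- lapply(LANDMARKS, function(lm) {
    d <- df[df$landmark == lm, ]
    d <- d[order(d$time_s), ]
    m <- vapply(c("x_m", "y_m", "z_m"), function(cc) {
      stats::approx(d$time_s, d[[cc]], xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    dimnames(m) <- NULL
    m
  })
  names(coords) <- LANDMARKS
  new_landmark_set(grid, coords)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d frames at %.0f fps (%.2f s), %d landmarks\n",
              length(x$time_s), x$fs, diff(range(x$time_s)),
              length(x$coords)))
  invisible(x)
}

#' Convert a landmark set to tidy long format
#'
#' @param x A `landmark_set`.
#' @param ... Unused.
#' @return Data frame with columns `time_s`, `landmark`, `x_m`, `y_m`, `z_m`.
#' @export
as.data.frame.landmark_set <- function(x, ...) {
  do.call(rbind, lapply(names(x$coords), function(lm) {
    m <- x$coords[[lm]]
    data.frame(time_s = x$time_s, landmark = lm,
               x_m = m[, 1L], y_m = m[, 2L], z_m = m[, 3L])
  }))
}

#' Zero-phase Butterworth filtering of landmark trajectories
#'
#' Each landmark class has its own low-pass cutoff, expressed as a multiple
#' of the wingbeat frequency: twice for the head, six times for the
#' shoulders and tail, and eight times for the wingtips and 5th primaries.
#' Filtering is forward-backward (zero phase) with a fourth-order
#' Butterworth design.
#'
#' @param lm A `landmark_set`.
#' @param wingbeat_freq_hz Wingbeat frequency (Hz) setting the cutoffs.
#' @param order Filter order (default 4).
#' @return A filtered `landmark_set` (attributes preserved).
#' @export
filter_trajectories <- function(lm, wingbeat_freq_hz, order = 4L) {
  stopifnot(inherits(lm, "landmark_set"))
  mult <- c(head = 2, tail = 6, l_shoulder = 6, r_shoulder = 6,
            l_wingtip = 8, r_wingtip = 8, l_p5 = 8, r_p5 = 8)
  nyq <- lm$fs / 2
  out <- lm
  for (nm in names(lm$coords)) {
    cutoff <- mult[[nm]] * wingbeat_freq_hz
    if (cutoff >= nyq) {
      stopf("cutoff %.1f Hz for %s is not below the Nyquist rate %.1f Hz",
            cutoff, nm, nyq)
    }
    bf <- signal::butter(order, cutoff / nyq, type = "low")
    out$coords[[nm]] <- apply(lm$coords[[nm]], 2L, function(col) {
      filtfilt_padded(bf, col)
    })
  }
  attributes(out) <- attributes(lm)
  out
}

# forward-backward filtering with odd-reflection end padding, which removes
# the start-up transients of a plain filtfilt and makes the filter exact on
# constant (DC) signals
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  npad <- min(n - 1L, 3L * (length(bf$b) + length(bf$a)) * 4L)
  left <- 2 * x[1L] - x[(npad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(npad + 1L):(npad + n)]
}

#' Estimate the wingbeat frequency from raw wingtip motion
#'
#' Periodogram peak of the mean-removed shoulder-relative wingtip
#' coordinates, searched above `min_freq`.
#'
#' @param lm A `landmark_set`.
#' @param min_freq Lowest admissible frequency (Hz, default 15).
#' @return Estimated frequency (Hz).
#' @export
estimate_wingbeat_frequency <- function(lm, min_freq = 15) {
  stopifnot(inherits(lm, "landmark_set"))
  rel <- lm$coords$l_wingtip - lm$coords$l_shoulder
  n <- nrow(rel)
  freqs <- (seq_len(n) - 1L) * lm$fs / n
  pw <- rowSums(vapply(1:3, function(j) {
    Mod(stats::fft(rel[, j] - mean(rel[, j])))^2
  }, numeric(n)))
  sel <- freqs >= min_freq & freqs <= lm$fs / 2
  freqs[sel][which.max(pw[sel])]
}
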