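# Stroke-plane fitting and in-plane excursion angle.
#
# The stroke plane is fitted by total least squares (principal components)
# to the shoulder-relative wingtip positions; the excursion angle is the
# in-plane polar angle of the projected wingtip about the shoulder, oriented
# so that positive excursion points toward the bird's front (supination, the
# maximum excursion, occurs at the front of the stroke).
stroke_plane_excursion <- function(rel, fwd_hint) {
  pc <- stats::prcomp(rel, center = TRUE, scale. = FALSE)
  e1 <- pc$rotation[, 1L]
  nrm <- pc$rotation[, 3L]
  mean_dir <- colMeans(rel)
  mean_dir <- mean_dir - sum(mean_dir * nrm) * nrm
  md <- sqrt(sum(mean_dir^2))
  if (md < 1e-12) {
    ref <- e1
  } else {
    ref <- mean_dir / md
  }
  e2 <- cross3(nrm, ref)
  e2 <- e2 / sqrt(sum(e2^2))
  if (sum(e2 * fwd_hint) < 0) e2 <- -e2
  ang <- rad2deg(atan2(rel %*% e2, rel %*% ref))
  list(angle = as.numeric(ang), normal = nrm, e1 = ref, e2 = e2)
}

# local extrema with a minimum separation; earliest sample wins ties
find_extrema <- function(x, min_dist, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (length(cand) == 0L) return(integer())
  keep <- integer()
  for (i in cand[order(-x[cand], cand)]) {
    if (all(abs(i - keep) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

# sub-sample extremum location by parabolic interpolation around index i
refine_extrema <- function(x, idx) {
  vapply(idx, function(i) {
    if (i <= 1L || i >= length(x)) return(as.numeric(i))
    denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (abs(denom) < 1e-12) return(as.numeric(i))
    i + 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  }, 0)
}

#' Segment wingstrokes from filtered landmark trajectories
#'
#' For each wing, fits a stroke plane to the shoulder-relative wingtip
#' positions, computes the in-plane excursion angle, and marks the
#' pronation (minimum excursion) and supination (maximum excursion) time of
#' every cycle. The wingbeat frequency is the reciprocal of the median
#' inter-pronation interval.
#'
#' @param lm A filtered `landmark_set`.
#' @param freq_band Plausibility band for the wingbeat frequency (Hz),
#'   default `c(20, 60)`.
#' @return An object of class `stroke_segmentation`: per-wing lists with
#'   `pronation_t`, `supination_t`, `excursion_deg` and
#'   `wingbeat_freq_hz`, plus an overall `wingbeat_freq_hz`.
#' @export
segment_strokes <- function(lm, freq_band = c(20, 60)) {
  stopifnot(inherits(lm, "landmark_set"))
  fwd <- colMeans(lm$coords$head - lm$coords$tail)
  fwd[3L] <- 0
  fwd <- fwd / sqrt(sum(fwd^2))
  f0 <- estimate_wingbeat_frequency(lm)
  min_dist <- max(2L, as.integer(round(0.6 * lm$fs / f0)))
  wings <- list()
  for (side in c("left", "right")) {
    tipnm <- paste0(substr(side, 1L, 1L), "_wingtip")
    shnm <- paste0(substr(side, 1L, 1L), "_shoulder")
    rel <- lm$coords[[tipnm]] - lm$coords[[shnm]]
    sp <- stroke_plane_excursion(rel, fwd)
    pron <- find_extrema(sp$angle, min_dist, "min")
    sup <- find_extrema(sp$angle, min_dist, "max")
    if (length(pron) < 4L) stopf("fewer than 3 full wingbeat cycles detected")
    dt <- 1 / lm$fs
    pron_t <- lm$time_s[1L] + (refine_extrema(sp$angle, pron) - 1) * dt
    sup_t <- lm$time_s[1L] + (refine_extrema(sp$angle, sup) - 1) * dt
    fw <- 1 / stats::median(diff(pron_t))
    if (fw < freq_band[1L] || fw > freq_band[2L]) {
      stopf("wingbeat frequency %.1f Hz outside the plausibility band", fw)
    }
    wings[[side]] <- list(pronation_i = pron, supination_i = sup,
                          pronation_t = pron_t,
                          supination_t = sup_t,
                          excursion_deg = sp$angle,
                          plane_normal = sp$normal,
                          wingbeat_freq_hz = fw)
  }
  structure(list(left = wings$left, right = wings$right,
                 wingbeat_freq_hz = stats::median(
                   c(wings$left$wingbeat_freq_hz,
                     wings$right$wingbeat_freq_hz))),
            class = "stroke_segmentation")
}

#' @export
print.stroke_segmentation <- function(x, ...) {
  cat(sprintf("<stroke_segmentation> %.1f Hz, %d left / %d right pronations\n",
              x$wingbeat_freq_hz, length(x$left$pronation_t),
              length(x$right$pronation_t)))
  invisible(x)
}

# For each left-wing cycle, the yaw (deg) of the wingtip-path dividing line:
# the line from the midpoint of the two wings' tip positions at pronation to
# the midpoint at supination, computed on head-centred positions.
dividing_line_yaw <- function(lm, seg) {
  ctr <- function(nm) lm$coords[[nm]] - lm$coords$head
  ltip <- ctr("l_wingtip"); rtip <- ctr("r_wingtip")
  lp <- seg$left$pronation_i
  yaw <- numeric(length(lp) - 1L)
  nearest <- function(cands, i) cands[which.min(abs(cands - i))]
  for (k in seq_len(length(lp) - 1L)) {
    i0 <- lp[k]; i1 <- lp[k + 1L]
    rs <- nearest(seg$right$pronation_i, i0)
    ls_sup <- seg$left$supination_i[seg$left$supination_i >= i0 &
                                      seg$left$supination_i <= i1]
    if (length(ls_sup) == 0L) ls_sup <- nearest(seg$left$supination_i, (i0 + i1) %/% 2)
    ls_sup <- ls_sup[1L]
    rs_sup <- nearest(seg$right$supination_i, ls_sup)
    p_pron <- (ltip[i0, ] + rtip[rs, ]) / 2
    p_sup <- (ltip[ls_sup, ] + rtip[rs_sup, ]) / 2
    v <- p_sup - p_pron
    if (sqrt(sum(v[1:2]^2)) < 1e-9) stopf("degenerate wingtip-path dividing line")
    yaw[k] <- rad2deg(atan2(v[2L], v[1L]))
  }
  yaw
}

#' Transform landmarks to the head-aligned gravitational frame
#'
#' Centres every frame on the head and yaws each wingbeat about the
#' vertical so that the wingtip-path dividing line (the line through the
#' midpoints of the two wings' tip positions at the stroke transitions)
#' points along +x. The vertical axis remains gravitational.
#'
#' @param lm A filtered `landmark_set`.
#' @param seg A [segment_strokes()] result.
#' @return A transformed `landmark_set` with attributes `yaw_deg` (per
#'   wingbeat) and `cycle_bounds_i` (left-wing pronation indices).
#' @export
transform_frame <- function(lm, seg) {
  stopifnot(inherits(lm, "landmark_set"), inherits(seg, "stroke_segmentation"))
  yaw <- dividing_line_yaw(lm, seg)
  lp <- seg$left$pronation_i
  n <- length(lm$time_s)
  # assign every frame the yaw of the cycle containing it (ends clamped)
  cyc_of <- pmin(pmax(findInterval(seq_len(n), lp), 1L), length(yaw))
  theta <- -deg2rad(yaw[cyc_of])
  ct <- cos(theta); st <- sin(theta)
  head <- lm$coords$head
  out <- lm
  for (nm in names(lm$coords)) {
    m <- lm$coords[[nm]] - head
    out$coords[[nm]] <- cbind(ct * m[, 1L] - st * m[, 2L],
                              st * m[, 1L] + ct * m[, 2L],
                              m[, 3L])
  }
  for (a in c("feeder_mouth_x", "culmen_length_m", "mode")) {
    attr(out, a) <- attr(lm, a)
  }
  attr(out, "yaw_deg") <- yaw
  attr(out, "cycle_bounds_i") <- lp
  out
}
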