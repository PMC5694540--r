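# shared fixtures, built in code at test time

# short strain recording: one feed, minimal pre/post windows
quick_strain_params <- function(..., seed = 1L) {
  strain_sim_params(pre_s = 3.2, post_s = 3.2,
                    dock_intervals = list(c(3.5, 7)), seed = seed, ...)
}

# reflect a landmark set through the sagittal (x-z) plane: negate y and swap
# the left/right landmark labels
reflect_landmarks <- function(lm) {
  df <- as.data.frame(lm)
  df$y_m <- -df$y_m
  swap <- c(head = "head", tail = "tail",
            l_shoulder = "r_shoulder", r_shoulder = "l_shoulder",
            l_wingtip = "r_wingtip", r_wingtip = "l_wingtip",
            l_p5 = "r_p5", r_p5 = "l_p5")
  df$landmark <- unname(swap[df$landmark])
  out <- landmark_set(df)
  for (a in c("feeder_mouth_x", "culmen_length_m")) attr(out, a) <- attr(lm, a)
  out
}

# translate every landmark by a constant vector
translate_landmarks <- function(lm, v) {
  df <- as.data.frame(lm)
  df$x_m <- df$x_m + v[1L]
  df$y_m <- df$y_m + v[2L]
  df$z_m <- df$z_m + v[3L]
  out <- landmark_set(df)
  for (a in c("feeder_mouth_x", "culmen_length_m")) attr(out, a) <- attr(lm, a)
  out
}

# raw periodogram peak frequency: independent FFT oracle
peak_frequency <- function(x, fs) {
  n <- length(x)
  pw <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs > 0 & freqs <= fs / 2
  freqs[sel][which.max(pw[sel])]
}
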