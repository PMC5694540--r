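#' Read and write strain traces
#'
#' The on-disk format is a CSV with columns `time_s`, `horizontal_V`,
#' `vertical_V`, `event` (`dock`/`undock` markers at the event samples,
#' empty elsewhere) plus a JSON side-car `{"docks": [[t0, t1], ...]}` with
#' the exact event times.
#'
#' @param trace A [strain_trace()].
#' @param csv_path CSV file path.
#' @param json_path Side-car JSON path (default `<csv>.docks.json`).
#' @return `write_strain_trace()` returns the CSV path invisibly;
#'   `read_strain_trace()` returns a [strain_trace()].
#' @export
write_strain_trace <- function(trace, csv_path,
                               json_path = paste0(csv_path, ".docks.json")) {
  stopifnot(inherits(trace, "strain_trace"))
  dk <- docks(trace)
  event <- character(nrow(trace))
  for (d in dk) {
    event[which.min(abs(trace$time_s - d[1L]))] <- "dock"
    event[which.min(abs(trace$time_s - d[2L]))] <- "undock"
  }
  out <- cbind(as.data.frame(trace), event = event)
  utils::write.csv(out, csv_path, row.names = FALSE)
  jsonlite::write_json(list(docks = dk), json_path, digits = NA)
  invisible(csv_path)
}

#' @rdname write_strain_trace
#' @export
read_strain_trace <- function(csv_path,
                              json_path = paste0(csv_path, ".docks.json")) {
  d <- utils::read.csv(csv_path)
  dk <- jsonlite::read_json(json_path, simplifyVector = TRUE)$docks
  if (is.matrix(dk)) dk <- lapply(seq_len(nrow(dk)), function(i) dk[i, ])
  strain_trace(d$time_s, d$horizontal_V, d$vertical_V, dk)
}

#' Read and write landmark sets
#'
#' Tidy CSV (`time_s`, `landmark`, `x_m`, `y_m`, `z_m`) plus a JSON
#' side-car with the feeder geometry and flight mode when available.
#'
#' @param lm A `landmark_set`.
#' @param csv_path CSV file path.
#' @param json_path Side-car JSON path (default `<csv>.meta.json`).
#' @return `write_landmarks()` returns the CSV path invisibly;
#'   `read_landmarks()` returns a `landmark_set`.
#' @export
write_landmarks <- function(lm, csv_path,
                            json_path = paste0(csv_path, ".meta.json")) {
  stopifnot(inherits(lm, "landmark_set"))
  utils::write.csv(as.data.frame(lm), csv_path, row.names = FALSE)
  meta <- list(feeder_mouth_x = attr(lm, "feeder_mouth_x"),
               culmen_length_m = attr(lm, "culmen_length_m"),
               mode = attr(lm, "mode"))
  meta <- meta[!vapply(meta, is.null, TRUE)]
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(csv_path,
                           json_path = paste0(csv_path, ".meta.json")) {
  lm <- landmark_set(utils::read.csv(csv_path))
  if (file.exists(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    for (a in names(meta)) attr(lm, a) <- meta[[a]]
  }
  lm
}

#' Read and write phase-normalized wingbeat cycles
#'
#' @param cyc A [wingbeat_cycle()].
#' @param path JSON file path.
#' @return `write_wingbeat_cycle()` returns `path` invisibly;
#'   `read_wingbeat_cycle()` returns a `wingbeat_cycle`.
#' @export
write_wingbeat_cycle <- function(cyc, path) {
  stopifnot(inherits(cyc, "wingbeat_cycle"))
  obj <- unclass(cyc)
  obj$stroke <- as.character(obj$stroke)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wingbeat_cycle
#' @export
read_wingbeat_cycle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$stroke <- factor(obj$stroke, levels = c("down", "up"))
  obj$phi <- as.list(obj$phi)
  obj$elev <- as.list(obj$elev)
  obj$alpha <- as.list(obj$alpha)
  class(obj) <- "wingbeat_cycle"
  validate_cycle(obj)
}

#' Read and write model configuration as YAML
#'
#' Serializes the wing morphology and coefficient-curve constants so model
#' runs can be configured from a file.
#'
#' @param morphology A [wing_morphology()].
#' @param coefficients An [aero_coefficients()].
#' @param path YAML file path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a list with `morphology` and
#'   `coefficients`.
#' @export
write_model_config <- function(path, morphology = wing_morphology(),
                               coefficients = aero_coefficients()) {
  yaml::write_yaml(list(morphology = unclass(morphology),
                        coefficients = unclass(coefficients)), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(morphology = do.call(wing_morphology, cfg$morphology),
       coefficients = do.call(aero_coefficients,
                              lapply(cfg$coefficients, as.numeric)))
}
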