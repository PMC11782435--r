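#' Construct an impact signal
#'
#' One force-versus-time trace for a single hammer blow on the osteotome.
#' Times are carried internally in milliseconds; file I/O uses seconds.
#'
#' @param force Numeric vector of force samples (newtons), all finite,
#'   at least 64 samples.
#' @param sampling_rate Sampling frequency in Hz (default 51200, i.e.
#'   51.2 kHz as delivered by the acquisition module).
#' @param time_ms Optional time grid in ms. If omitted it is built as
#'   `(0:(n-1)) / sampling_rate * 1000`. Must be strictly increasing and
#'   uniform with spacing `1/sampling_rate` (checked to 1e-9 s).
#' @param plate_id Character identifier of the bone plate / sample.
#' @param location_index Positive integer, osteotome position along the plate.
#' @param impact_index Positive integer, 1-based blow number within the plate
#'   (running across locations, in chronological order).
#' @param procedure `"osteotomy"` (impacts until plate rupture) or
#'   `"thickness_assessment"` (low-energy probing impacts).
#'
#' @return An object of class `impact_signal`: a list with elements
#'   `time_ms`, `force`, `sampling_rate`, `plate_id`, `location_index`,
#'   `impact_index`, `procedure`.
#' @export
#' @examples
#' t_ms <- (0:511) / 51.2
#' f <- 150 * exp(-(t_ms - 1)^2 / (2 * 0.15^2))
#' sig <- impact_signal(f, plate_id = "P01")
impact_signal <- function(force, sampling_rate = 51200, time_ms = NULL,
                          plate_id = "unknown", location_index = 1L,
                          impact_index = 1L,
                          procedure = c("osteotomy", "thickness_assessment")) {
  procedure <- match.arg(procedure)
  force <- as.numeric(force)
  n <- length(force)
  if (n < 64L)
    stop("impact_signal: need at least 64 samples, got ", n)
  if (!all(is.finite(force)))
    stop("impact_signal: force contains non-finite values")
  dt_ms <- 1000 / sampling_rate
  if (is.null(time_ms)) {
    time_ms <- (seq_len(n) - 1) * dt_ms
  } else {
    time_ms <- as.numeric(time_ms)
    if (length(time_ms) != n)
      stop("impact_signal: time and force lengths differ")
    d <- diff(time_ms)
    if (any(d <= 0))
      stop("impact_signal: time must be strictly increasing")
    # uniform grid at 1/sampling_rate, tolerance 1e-9 s = 1e-6 ms
    if (max(abs(d - dt_ms)) > 1e-6)
      stop("impact_signal: time grid is not uniform at 1/sampling_rate")
  }
  if (location_index < 1L || impact_index < 1L)
    stop("impact_signal: indices must be positive")
  structure(
    list(time_ms = time_ms, force = force, sampling_rate = sampling_rate,
         plate_id = as.character(plate_id),
         location_index = as.integer(location_index),
         impact_index = as.integer(impact_index),
         procedure = procedure),
    class = "impact_signal")
}

#' @export
print.impact_signal <- function(x, ...) {
  cat(sprintf(
    "<impact_signal> plate %s, location %d, impact %d (%s)\n",
    x$plate_id, x$location_index, x$impact_index, x$procedure))
  cat(sprintf("  %d samples at %.1f kHz (%.2f ms), peak force %.1f N\n",
              length(x$force), x$sampling_rate / 1000,
              max(x$time_ms), max(x$force)))
  invisible(x)
}

#' Read / write a single impact-signal CSV
#'
#' Signal files have two columns, `time_s` and `force_N`, one file per
#' impact; metadata travels in the manifest (see [read_manifest()]).
#'
#' @param path CSV file path.
#' @param sampling_rate Sampling frequency in Hz used to validate the grid.
#' @param plate_id,location_index,impact_index,procedure Metadata attached
#'   to the returned signal (typically taken from the manifest row).
#' @return `read_impact_signal()` returns an [impact_signal()];
#'   `write_impact_signal()` returns `path` invisibly.
#' @export
read_impact_signal <- function(path, sampling_rate = 51200,
                               plate_id = "unknown", location_index = 1L,
                               impact_index = 1L, procedure = "osteotomy") {
  if (!file.exists(path)) stop("signal file not found: ", path)
  df <- read.csv(path)
  if (!all(c("time_s", "force_N") %in% names(df)))
    stop("signal CSV must have columns time_s, force_N: ", path)
  impact_signal(df$force_N, sampling_rate = sampling_rate,
                time_ms = df$time_s * 1000, plate_id = plate_id,
                location_index = location_index, impact_index = impact_index,
                procedure = procedure)
}

#' @param signal An [impact_signal()].
#' @rdname read_impact_signal
#' @export
write_impact_signal <- function(signal, path) {
  stopifnot(inherits(signal, "impact_signal"))
  df <- data.frame(time_s = signal$time_ms / 1000, force_N = signal$force)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an experiment manifest CSV
#'
#' The manifest lists one row per impact with columns `plate_id`,
#' `location_index`, `impact_index`, `procedure`, `crossing`,
#' `flag_extra_post_rupture`, `path` (relative signal CSV path) and, for
#' synthetic experiments, the ground-truth columns `thickness_mm`,
#' `tau_true_ms`, `lambda_true`.
#'
#' @param path Manifest CSV path.
#' @return A `data.frame`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "location_index", "impact_index", "procedure",
            "crossing", "flag_extra_post_rupture")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  df$crossing <- as.logical(df$crossing)
  df$flag_extra_post_rupture <- as.logical(df$flag_extra_post_rupture)
  df
}

#' @param manifest Manifest `data.frame`.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
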