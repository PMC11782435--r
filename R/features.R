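#' Build the per-impact feature table
#'
#' Takes the per-impact indicator table (one row per impact with `tau` and
#' `lambda`) and derives the classification features: the first differences
#' `dtau(i) = tau(i) - tau(i-1)` and `dlambda(i) = lambda(i) - lambda(i-1)`
#' against the immediately preceding impact of the same plate — differences
#' run across osteotomy-location boundaries, since impacts are indexed
#' 1..N chronologically per plate. The first impact of each plate is
#' dropped (its differences are undefined). Labels are `"Crossing"` for the
#' impact at which the operator felt the blade cross the plate and for the
#' single additional post-rupture impact, `"Bone"` otherwise.
#'
#' @param indicators `data.frame` with columns `plate_id`, `location_index`,
#'   `impact_index`, `tau_ms`, `lambda` and a logical `crossing` column
#'   marking Crossing impacts. Rows must be ordered by
#'   (`plate_id`, `impact_index`) with no duplicate indices per plate.
#' @return `data.frame` with one row per impact with `impact_index > 1` per
#'   plate: `plate_id`, `location_index`, `impact_index`, `tau_ms`,
#'   `lambda`, `dtau_ms`, `dlambda`, `label` (factor Bone/Crossing).
#' @export
#' @examples
#' ind <- data.frame(plate_id = "P1", location_index = 1L, impact_index = 1:3,
#'                   tau_ms = c(1.0, 1.1, 1.6), lambda = c(0.6, 0.6, 0.2),
#'                   crossing = c(FALSE, FALSE, TRUE))
#' build_feature_table(ind)
build_feature_table <- function(indicators) {
  need <- c("plate_id", "location_index", "impact_index", "tau_ms",
            "lambda", "crossing")
  miss <- setdiff(need, names(indicators))
  if (length(miss))
    stop("indicator table missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(indicators, indicators$plate_id), function(d) {
    i <- d$impact_index
    if (anyDuplicated(i))
      stop("integrity error: duplicate impact indices in plate ", d$plate_id[1L])
    if (is.unsorted(i, strictly = TRUE))
      stop("integrity error: impacts not ordered by impact_index in plate ",
           d$plate_id[1L])
    if (nrow(d) < 2L) return(NULL)
    data.frame(
      plate_id = d$plate_id[-1L],
      location_index = d$location_index[-1L],
      impact_index = i[-1L],
      tau_ms = d$tau_ms[-1L],
      lambda = d$lambda[-1L],
      dtau_ms = diff(d$tau_ms),
      dlambda = diff(d$lambda),
      label = factor(ifelse(d$crossing[-1L], "Crossing", "Bone"),
                     levels = c("Bone", "Crossing")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract indicators from a collection of signals
#'
#' Runs [extract_indicators()] on each signal and assembles the per-impact
#' indicator table expected by [build_feature_table()]. Metadata (plate,
#' location, impact index, procedure) is taken from each signal; the
#' `crossing` flags are supplied separately (e.g. from the manifest), in
#' the same order as `signals`.
#'
#' @param signals List of [impact_signal()] objects.
#' @param crossing Logical vector, one element per signal.
#' @inheritParams extract_indicators
#' @return `data.frame` with columns `plate_id`, `location_index`,
#'   `impact_index`, `procedure`, `tau_ms`, `lambda`, `crossing`.
#' @export
extract_features <- function(signals, crossing = NULL,
                             min_prominence_fraction = 0.1,
                             window_halfwidth_ms = 0.3,
                             use_fit_centers = TRUE) {
  if (is.null(crossing)) crossing <- rep(FALSE, length(signals))
  if (length(crossing) != length(signals))
    stop("crossing flags and signals have different lengths")
  rows <- vector("list", length(signals))
  for (s in seq_along(signals)) {
    sig <- signals[[s]]
    ind <- extract_indicators(sig, min_prominence_fraction,
                              window_halfwidth_ms, use_fit_centers)
    rows[[s]] <- data.frame(
      plate_id = sig$plate_id, location_index = sig$location_index,
      impact_index = sig$impact_index, procedure = sig$procedure,
      tau_ms = ind$tau, lambda = ind$lambda, crossing = crossing[s],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df[order(df$plate_id, df$procedure, df$impact_index), , drop = FALSE]
}

#' Write / read a feature CSV
#'
#' Columns: `plate_id,location_index,impact_index,tau_ms,lambda,dtau_ms,`
#' `dlambda,label`.
#'
#' @param features Feature `data.frame` from [build_feature_table()].
#' @param path CSV path.
#' @export
write_feature_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$label <- factor(df$label, levels = c("Bone", "Crossing"))
  df
}
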