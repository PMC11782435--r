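#' Configuration of the synthetic experiment generator
#'
#' Defaults reproduce the structure of the ex vivo lamb-skull experiments:
#' per-plate osteotomy location counts drawn from the empirical distribution
#' \{2: 2, 3: 13, 4: 14, 5: 2\}/31 (mean 3.52), per-location impact counts
#' with rank-wise means 14.60, 10.32, 7.83, 7.94, 8.00, five low-energy
#' impacts per thickness-assessment location (location count mean 5.65), and
#' piecewise-linear `tau`-vs-thickness truths `tau0 = 0.95` ms,
#' `d_f = 1.2` mm, `k_f = -0.89` ms/mm. Each impact is synthesised as a
#' two-Gaussian force pulse; at plate crossing `tau` jumps by ~0.5 ms and
#' `lambda` is multiplied by a factor in [0.3, 0.7].
#'
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @param n_plates Number of osteotomy samples (plates).
#' @param location_count_prob Probabilities of 2, 3, 4, 5 osteotomy
#'   locations per plate.
#' @param impacts_per_location_mean,impacts_per_location_sd Rank-wise mean /
#'   sd of the per-location impact count (recycled beyond rank 5); draws are
#'   rounded and clipped to `impact_count_range`.
#' @param impact_count_range Admissible per-location impact counts.
#' @param tau0,d_f,k_f Piecewise-model truths: plateau delay (ms),
#'   breakpoint thickness (mm), slope below the breakpoint (ms/mm, < 0).
#' @param tau_noise_sd Per-impact Gaussian noise on `tau` (ms).
#' @param crossing_tau_jump_mean,crossing_tau_jump_sd Mean / sd of the `tau`
#'   jump at plate crossing (ms).
#' @param lambda_bone_mean,lambda_bone_sd `lambda` distribution for Bone
#'   impacts.
#' @param crossing_lambda_drop Range of the multiplicative `lambda` drop at
#'   crossing.
#' @param lambda_range `lambda` truths are clamped to this range so the
#'   second peak stays above the peak-detection prominence floor.
#' @param thickness_range Plate thickness at the first and last location
#'   (mm); intermediate locations interpolate linearly.
#' @param thickness_jitter_sd Per-location Gaussian jitter on thickness (mm).
#' @param thickness_min Lower clamp on location thickness (mm).
#' @param amplitude_osteotomy,amplitude_assessment First-peak amplitude
#'   ranges (N) for osteotomy and low-energy thickness-assessment impacts
#'   (sensor range 4450 N).
#' @param assess_locations_mean,assess_locations_sd Thickness-assessment
#'   location count per plate (draws clipped to 3..9).
#' @param assess_impacts Impacts per thickness-assessment location.
#' @param peak_width_ms Gaussian width of both force peaks (ms).
#' @param first_peak_time_ms Centre of the first peak (ms).
#' @param force_noise_sd Additive white noise on the force trace (N).
#' @param sampling_rate Hz. @param duration_ms Trace duration (ms).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_plates = 16L,
                             location_count_prob = c(`2` = 2, `3` = 13,
                                                     `4` = 14, `5` = 2) / 31,
                             impacts_per_location_mean = c(14.60, 10.32, 7.83,
                                                           7.94, 8.00),
                             impacts_per_location_sd = c(12.82, 4.66, 3.60,
                                                         3.32, 2.83),
                             impact_count_range = c(4L, 45L),
                             tau0 = 0.95, d_f = 1.2, k_f = -0.89,
                             tau_noise_sd = 0.03,
                             crossing_tau_jump_mean = 0.5,
                             crossing_tau_jump_sd = 0.1,
                             lambda_bone_mean = 0.6, lambda_bone_sd = 0.1,
                             crossing_lambda_drop = c(0.3, 0.7),
                             lambda_range = c(0.12, 0.95),
                             thickness_range = c(3.0, 0.5),
                             thickness_jitter_sd = 0.15,
                             thickness_min = 0.2,
                             amplitude_osteotomy = c(200, 400),
                             amplitude_assessment = c(100, 200),
                             assess_locations_mean = 5.65,
                             assess_locations_sd = 0.98,
                             assess_impacts = 5L,
                             peak_width_ms = 0.15,
                             first_peak_time_ms = 1.0,
                             force_noise_sd = 0,
                             sampling_rate = 51200, duration_ms = 20) {
  cfg <- as.list(environment())
  if (cfg$tau_noise_sd < 0 || cfg$crossing_tau_jump_sd < 0 ||
      cfg$lambda_bone_sd < 0 || cfg$force_noise_sd < 0)
    stop("generator_config: standard deviations must be >= 0")
  if (cfg$d_f <= 0) stop("generator_config: d_f must be > 0")
  if (cfg$k_f >= 0) stop("generator_config: k_f must be < 0")
  if (any(c(cfg$amplitude_osteotomy, cfg$amplitude_assessment) <= 0) ||
      any(c(cfg$amplitude_osteotomy, cfg$amplitude_assessment) > 4450))
    stop("generator_config: amplitudes must lie in (0, 4450] N")
  class(cfg) <- "generator_config"
  cfg
}

#' Synthesise one impact force trace
#'
#' The trace is the sum of two Gaussian pulses of equal width: the first
#' (hammer impact) centred at `first_peak_time_ms` with amplitude `a1`, the
#' second (osteotome rebound) at `tau_true` ms later with area
#' `lambda_true` times the first area, plus optional white noise.
#'
#' @param tau_true Inter-peak delay (ms), must exceed three pulse widths so
#'   the peaks are resolvable.
#' @param lambda_true Area ratio of the second to first pulse (>= 0).
#' @param a1 First-peak amplitude (N).
#' @param config A [generator_config()].
#' @param plate_id,location_index,impact_index,procedure Metadata.
#' @return An [impact_signal()]. Uses the current RNG stream (only when
#'   `config$force_noise_sd > 0`).
#' @export
generate_impact_signal <- function(tau_true, lambda_true, a1, config,
                                   plate_id = "SIM", location_index = 1L,
                                   impact_index = 1L,
                                   procedure = "osteotomy") {
  if (tau_true <= 0 || lambda_true < 0)
    stop("generate_impact_signal: need tau_true > 0 and lambda_true >= 0")
  w <- config$peak_width_ms
  if (tau_true < 3 * w)
    stop("peaks unresolvable: tau_true = ", signif(tau_true, 4),
         " ms is below 3 pulse widths (", 3 * w, " ms)")
  n <- round(config$duration_ms * config$sampling_rate / 1000)
  t <- (seq_len(n) - 1) * 1000 / config$sampling_rate
  t1 <- config$first_peak_time_ms
  a2 <- lambda_true * a1          # equal widths: area ratio = amplitude ratio
  f <- a1 * exp(-(t - t1)^2 / (2 * w^2)) +
       a2 * exp(-(t - t1 - tau_true)^2 / (2 * w^2))
  if (config$force_noise_sd > 0)
    f <- f + rnorm(n, 0, config$force_noise_sd)
  impact_signal(f, sampling_rate = config$sampling_rate, plate_id = plate_id,
                location_index = location_index, impact_index = impact_index,
                procedure = procedure)
}

# draw a bone-phase lambda, clamped to the detectable range
draw_lambda <- function(n, config) {
  pmin(pmax(rnorm(n, config$lambda_bone_mean, config$lambda_bone_sd),
            config$lambda_range[1L]), config$lambda_range[2L])
}

#' Simulate one osteotomy location
#'
#' Impacts are applied until the plate ruptures: cumulative damage grows
#' linearly over the bone-phase impacts, the effective thickness is
#' `thickness * (1 - damage)`, and the bone-phase `tau` follows the
#' piecewise model at the effective thickness plus Gaussian noise. The final
#' two impacts are the felt crossing and the single additional post-rupture
#' blow: both are labelled Crossing, with `tau` raised by the crossing jump
#' above the ruptured-plate level and `lambda` multiplied by the crossing
#' drop factor.
#'
#' @param thickness Plate thickness at this location (mm).
#' @param n_impacts Total impacts including the two Crossing ones (>= 3).
#' @param config A [generator_config()].
#' @param plate_id Plate identifier.
#' @param location_index Location rank within the plate.
#' @param first_impact_index Chronological index of this location's first
#'   impact within the plate.
#' @return List with `signals` (list of [impact_signal()]) and `truth`
#'   (`data.frame`: metadata, `crossing`, `flag_extra_post_rupture`,
#'   `thickness_mm`, `effective_thickness_mm`, `tau_true_ms`,
#'   `lambda_true`, `amplitude_N`). Uses the current RNG stream.
#' @export
generate_osteotomy_location <- function(thickness, n_impacts, config,
                                        plate_id = "SIM", location_index = 1L,
                                        first_impact_index = 1L) {
  if (n_impacts < 3L)
    stop("generate_osteotomy_location: need at least 3 impacts")
  n_bone <- n_impacts - 2L
  damage <- (seq_len(n_bone) - 1) / n_bone          # 0 -> (n_bone-1)/n_bone
  eff <- c(thickness * (1 - damage), 0, 0)
  tau <- piecewise_tau(eff, config$tau0, config$d_f, config$k_f) +
    rnorm(n_impacts, 0, config$tau_noise_sd)
  jump <- rnorm(2L, config$crossing_tau_jump_mean, config$crossing_tau_jump_sd)
  tau[n_bone + 1:2] <- tau[n_bone + 1:2] + pmax(jump, 0.1)
  lam <- draw_lambda(n_impacts, config)
  drop <- runif(2L, config$crossing_lambda_drop[1L],
                config$crossing_lambda_drop[2L])
  lam[n_bone + 1:2] <- pmax(lam[n_bone + 1:2] * drop, config$lambda_range[1L])
  tau <- pmax(tau, 3 * config$peak_width_ms + 0.01)
  a1 <- runif(n_impacts, config$amplitude_osteotomy[1L],
              config$amplitude_osteotomy[2L])
  idx <- first_impact_index + seq_len(n_impacts) - 1L
  signals <- lapply(seq_len(n_impacts), function(i)
    generate_impact_signal(tau[i], lam[i], a1[i], config, plate_id,
                           location_index, idx[i], "osteotomy"))
  truth <- data.frame(
    plate_id = plate_id, location_index = location_index, impact_index = idx,
    procedure = "osteotomy",
    crossing = seq_len(n_impacts) > n_bone,
    flag_extra_post_rupture = seq_len(n_impacts) == n_impacts,
    thickness_mm = thickness, effective_thickness_mm = eff,
    tau_true_ms = tau, lambda_true = lam, amplitude_N = a1,
    stringsAsFactors = FALSE)
  list(signals = signals, truth = truth)
}

#' Simulate a thickness-assessment pass over one plate
#'
#' At each probing location a fixed number of low-energy impacts
#' (first-peak amplitude in `config$amplitude_assessment`, 100--200 N by
#' default) is applied; `tau` is drawn from the piecewise model at the
#' location thickness plus noise, and no impact is a Crossing.
#'
#' @param thicknesses Per-location plate thickness (mm).
#' @param config A [generator_config()].
#' @param plate_id Plate identifier.
#' @return Same shape as [generate_osteotomy_location()].
#' @export
generate_thickness_assessment <- function(thicknesses, config,
                                          plate_id = "SIM") {
  k <- config$assess_impacts
  signals <- list(); rows <- list(); idx <- 0L
  for (loc in seq_along(thicknesses)) {
    th <- thicknesses[loc]
    tau <- piecewise_tau(rep(th, k), config$tau0, config$d_f, config$k_f) +
      rnorm(k, 0, config$tau_noise_sd)
    tau <- pmax(tau, 3 * config$peak_width_ms + 0.01)
    lam <- draw_lambda(k, config)
    a1 <- runif(k, config$amplitude_assessment[1L],
                config$amplitude_assessment[2L])
    for (i in seq_len(k)) {
      idx <- idx + 1L
      signals[[idx]] <- generate_impact_signal(
        tau[i], lam[i], a1[i], config, plate_id, loc, idx,
        "thickness_assessment")
    }
    rows[[loc]] <- data.frame(
      plate_id = plate_id, location_index = loc,
      impact_index = idx - k + seq_len(k), procedure = "thickness_assessment",
      crossing = FALSE, flag_extra_post_rupture = FALSE,
      thickness_mm = th, effective_thickness_mm = th,
      tau_true_ms = tau, lambda_true = lam, amplitude_N = a1,
      stringsAsFactors = FALSE)
  }
  list(signals = signals, truth = do.call(rbind, rows))
}

#' Generate a full synthetic experiment database
#'
#' Simulates `config$n_plates` plates, each with an osteotomy procedure
#' (locations drawn from the configured count distribution, decreasing
#' thickness along the plate, exactly one felt-crossing plus one
#' post-rupture impact per location) and a thickness-assessment procedure.
#' Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return Object of class `impact_experiment`: list with `signals` (list of
#'   [impact_signal()]) and `manifest` (`data.frame`, one row per signal,
#'   including ground-truth columns).
#' @export
#' @examples
#' exp <- generate_database(generator_config(seed = 42, n_plates = 2))
#' nrow(exp$manifest)
generate_database <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sig <- list(); man <- list()
  draw_thickness <- function(n) {
    th <- seq(config$thickness_range[1L], config$thickness_range[2L],
              length.out = max(n, 2L))[seq_len(n)] +
      rnorm(n, 0, config$thickness_jitter_sd)
    pmax(th, config$thickness_min)
  }
  for (p in seq_len(config$n_plates)) {
    pid <- sprintf("P%02d", p)
    n_loc <- sample(2:5, 1L, prob = config$location_count_prob)
    th <- draw_thickness(n_loc)
    next_idx <- 1L
    for (loc in seq_len(n_loc)) {
      mu <- config$impacts_per_location_mean[min(loc, length(config$impacts_per_location_mean))]
      s <- config$impacts_per_location_sd[min(loc, length(config$impacts_per_location_sd))]
      n_imp <- round(rnorm(1L, mu, s))
      n_imp <- min(max(n_imp, config$impact_count_range[1L]),
                   config$impact_count_range[2L])
      res <- generate_osteotomy_location(th[loc], n_imp, config, pid, loc,
                                         next_idx)
      next_idx <- next_idx + n_imp
      sig <- c(sig, res$signals); man[[length(man) + 1L]] <- res$truth
    }
    n_assess <- round(rnorm(1L, config$assess_locations_mean,
                            config$assess_locations_sd))
    n_assess <- min(max(n_assess, 3L), 9L)
    res <- generate_thickness_assessment(draw_thickness(n_assess), config, pid)
    sig <- c(sig, res$signals); man[[length(man) + 1L]] <- res$truth
  }
  manifest <- do.call(rbind, man)
  rownames(manifest) <- NULL
  structure(list(signals = sig, manifest = manifest, config = config),
            class = "impact_experiment")
}

#' @export
print.impact_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<impact_experiment> %d plates, %d impacts (%d osteotomy, %d assessment)\n",
              length(unique(m$plate_id)), nrow(m),
              sum(m$procedure == "osteotomy"),
              sum(m$procedure == "thickness_assessment")))
  cat(sprintf("  crossings: %d impacts at %d locations\n",
              sum(m$crossing),
              nrow(unique(m[m$crossing, c("plate_id", "location_index")]))))
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Emits one `time_s,force_N` CSV per impact under `dir/signals/` plus a
#' `manifest.csv` with a relative `path` column.
#'
#' @param experiment An `impact_experiment` from [generate_database()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "impact_experiment"))
  sigdir <- file.path(dir, "signals")
  dir.create(sigdir, recursive = TRUE, showWarnings = FALSE)
  m <- experiment$manifest
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- experiment$signals[[i]]
    paths[i] <- file.path("signals", sprintf("%s_%s_%03d.csv", s$plate_id,
                                             substr(s$procedure, 1, 3),
                                             s$impact_index))
    write_impact_signal(s, file.path(dir, paths[i]))
  }
  m$path <- paths
  write_manifest(m, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read an experiment directory written by [write_experiment()]
#'
#' @param dir Directory containing `manifest.csv` and the signal CSVs.
#' @return An `impact_experiment` (without generator config).
#' @export
read_experiment <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  manifest <- read_manifest(mpath)
  if (is.null(manifest$path))
    stop("manifest has no 'path' column: ", mpath)
  signals <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    read_impact_signal(file.path(dir, r$path), plate_id = r$plate_id,
                       location_index = r$location_index,
                       impact_index = r$impact_index, procedure = r$procedure)
  })
  structure(list(signals = signals, manifest = manifest),
            class = "impact_experiment")
}

#' Simulate location-level (thickness, tau) observations
#'
#' Draws location thicknesses uniformly over `thickness_range` and location
#' mean `tau` from the piecewise model plus Gaussian noise — the
#' location-level data on which the breakpoint regression operates. Uses
#' the current RNG stream.
#'
#' @param n Number of locations.
#' @param tau0,d_f,k_f Piecewise-model truths.
#' @param noise_sd Gaussian noise on `tau` (ms).
#' @param thickness_range Range of thickness draws (mm).
#' @return `data.frame` with `thickness_mm`, `tau_ms`.
#' @export
simulate_location_tau <- function(n = 60L, tau0 = 0.95, d_f = 1.2,
                                  k_f = -0.89, noise_sd = 0.03,
                                  thickness_range = c(0.3, 3.0)) {
  th <- runif(n, thickness_range[1L], thickness_range[2L])
  data.frame(thickness_mm = th,
             tau_ms = piecewise_tau(th, tau0, d_f, k_f) + rnorm(n, 0, noise_sd))
}

#' Simulate an imbalanced overlapping two-class test-bed
#'
#' Two bivariate Gaussian clouds with unit variance whose means are
#' `separation` apart along the first axis, with a configurable positive
#' (Crossing) fraction — a controlled stand-in for the projected impact
#' database used to study cost-sensitive classification. Uses the current
#' RNG stream.
#'
#' @param n Total number of records.
#' @param pos_frac Fraction of Crossing records (default 0.15, the order of
#'   the crossing fraction in an osteotomy database).
#' @param separation Distance between class means (in sd units).
#' @return List with `x` (n x 2 matrix) and `labels` (factor Bone/Crossing).
#' @export
simulate_overlapping_classes <- function(n = 800L, pos_frac = 0.15,
                                         separation = 1.5) {
  n_pos <- round(n * pos_frac)
  n_neg <- n - n_pos
  x <- rbind(cbind(rnorm(n_neg), rnorm(n_neg)),
             cbind(rnorm(n_pos, separation), rnorm(n_pos)))
  labels <- factor(rep(c("Bone", "Crossing"), c(n_neg, n_pos)),
                   levels = c("Bone", "Crossing"))
  ord <- sample.int(n)
  list(x = x[ord, , drop = FALSE], labels = labels[ord])
}
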