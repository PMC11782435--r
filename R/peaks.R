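#' Locate the first two peaks of a force trace
#'
#' Scans the signal for local maxima, computes the topographic prominence of
#' each, discards maxima whose prominence falls below a fraction of the
#' global maximum force (sensor ripple), merges maxima closer than
#' `min_separation_ms` (keeping the higher), and returns the first two
#' surviving maxima in time order. These correspond to the initial hammer
#' impact and the first rebound of the osteotome.
#'
#' @param signal An [impact_signal()].
#' @param min_prominence_fraction Minimum prominence as a fraction of the
#'   global maximum force, in (0, 1). Default 0.1.
#' @param min_separation_ms Minimum separation between retained peaks (ms).
#' @return Integer vector of length 2: sample indices of the two peaks,
#'   first index < second index.
#' @export
detect_first_two_peaks <- function(signal, min_prominence_fraction = 0.1,
                                   min_separation_ms = 0.1) {
  stopifnot(inherits(signal, "impact_signal"))
  if (min_prominence_fraction <= 0 || min_prominence_fraction >= 1)
    stop("min_prominence_fraction must be in (0, 1)")
  f <- signal$force
  cand <- local_maxima(f)
  prom <- vapply(cand, peak_prominence, numeric(1), force = f)
  keep <- cand[prom >= min_prominence_fraction * max(f)]
  # merge peaks closer than the separation floor, keeping the higher one
  if (length(keep) > 1L) {
    min_sep <- min_separation_ms * signal$sampling_rate / 1000
    merged <- keep[1L]
    for (i in keep[-1L]) {
      last <- merged[length(merged)]
      if (i - last < min_sep) {
        if (f[i] > f[last]) merged[length(merged)] <- i
      } else merged <- c(merged, i)
    }
    keep <- merged
  }
  if (length(keep) < 2L)
    stop(sprintf(
      "insufficient peaks: impact %s/%d has %d qualifying peak(s)",
      signal$plate_id, signal$impact_index, length(keep)))
  keep[1:2]
}

# indices of strict local maxima; a flat plateau counts once, at its first
# sample (sign of diff carried across zero runs)
local_maxima <- function(f) {
  n <- length(f)
  if (n < 3L) return(integer(0))
  d <- sign(diff(f))
  # carry the previous non-zero slope across plateaus
  for (i in seq_along(d)) if (d[i] == 0 && i > 1L) d[i] <- d[i - 1L]
  idx <- which(d[-length(d)] > 0 & d[-1L] < 0) + 1L
  # report the first sample of a plateau-topped peak
  vapply(idx, function(i) {
    while (i > 1L && f[i - 1L] == f[i]) i <- i - 1L
    i
  }, integer(1))
}

# topographic prominence: height minus the higher of the two bases, where a
# base is the minimum between the peak and the nearest higher ground (or the
# signal edge) on that side
peak_prominence <- function(i, force) {
  h <- force[i]
  # segments ordered walking outwards from the peak
  left <- if (i > 1L) force[(i - 1L):1L] else numeric(0)
  right <- if (i < length(force)) force[(i + 1L):length(force)] else numeric(0)
  base_of <- function(seg) {
    if (!length(seg)) return(min(force))
    higher <- which(seg > h)
    if (length(higher)) min(c(h, seg[seq_len(higher[1L] - 1L)])) else min(seg)
  }
  h - max(base_of(left), base_of(right))
}

#' Fit a Gaussian to one peak of a force trace
#'
#' Least-squares fit of `a * exp(-(t - c)^2 / (2 w^2))` on a window of
#' `window_halfwidth_ms` around a detected peak (truncated at the signal
#' edges). `w` is the Gaussian standard deviation; the peak integral is the
#' closed-form Gaussian area `L = sqrt(2*pi) * w * a`.
#'
#' Initial values come from the raw maximum (amplitude, centre) and from the
#' half-width at half-maximum divided by 1.177 (width). The fit errors with
#' "fit failed" on non-convergence or if the fitted width leaves
#' `(0, window span]`, and if the fitted amplitude strays outside the
#' window's force range by more than 50%.
#'
#' @param signal An [impact_signal()].
#' @param peak_index Sample index of the detected peak maximum.
#' @param window_halfwidth_ms Half-width of the fit window (ms), default 0.3.
#' @param rank Peak rank (1 or 2), recorded in the result.
#' @return An object of class `peak_fit`: list with `center_ms`, `amplitude`
#'   (N), `width_ms` (Gaussian sd), `integral` (N ms), `rank`.
#' @export
fit_gaussian_peak <- function(signal, peak_index, window_halfwidth_ms = 0.3,
                              rank = 1L) {
  stopifnot(inherits(signal, "impact_signal"))
  t <- signal$time_ms
  f <- signal$force
  half_n <- round(window_halfwidth_ms * signal$sampling_rate / 1000)
  win <- max(1L, peak_index - half_n):min(length(f), peak_index + half_n)
  if (length(win) < 5L)
    stop("fit failed: window around peak has fewer than 5 samples")
  tw <- t[win]; fw <- f[win]
  a0 <- f[peak_index]; c0 <- t[peak_index]
  w0 <- hwhm_ms(tw, fw, peak_index - win[1L] + 1L) / 1.177
  span <- diff(range(tw))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fw ~ a * exp(-(tw - cc)^2 / (2 * w^2)),
      start = list(a = a0, cc = c0, w = w0),
      lower = c(a = 1e-9, cc = min(tw), w = 1e-4),
      upper = c(a = Inf, cc = max(tw), w = span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("fit failed: Gaussian peak fit did not converge (impact ",
         signal$plate_id, "/", signal$impact_index, ")")
  p <- coef(fit)
  a <- unname(p["a"]); cc <- unname(p["cc"]); w <- unname(p["w"])
  if (!is.finite(w) || w <= 0 || w > span)
    stop("fit failed: fitted width outside (0, window span]")
  rng <- range(fw)
  if (a > rng[2] * 1.5 || a < -0.5 * rng[2])
    stop("fit failed: fitted amplitude outside window force range +/- 50%")
  structure(
    list(center_ms = cc, amplitude = a, width_ms = w,
         integral = sqrt(2 * pi) * w * a, rank = as.integer(rank)),
    class = "peak_fit")
}

# half width at half maximum (one-sided average, ms) for initialisation
hwhm_ms <- function(tw, fw, ip) {
  half <- fw[ip] / 2
  right <- which(fw[ip:length(fw)] <= half)
  left <- which(rev(fw[1:ip]) <= half)
  dr <- if (length(right)) tw[ip + right[1L] - 1L] - tw[ip] else tw[length(tw)] - tw[ip]
  dl <- if (length(left)) tw[ip] - tw[ip - left[1L] + 1L] else tw[ip] - tw[1L]
  max((dr + dl) / 2, diff(tw[1:2]))
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "<peak_fit #%d> center %.4f ms, amplitude %.1f N, width %.4f ms, area %.2f N.ms\n",
    x$rank, x$center_ms, x$amplitude, x$width_ms, x$integral))
  invisible(x)
}

#' Inter-peak delay tau
#'
#' `tau` is the time (ms) between the second and first peaks of the force
#' signal — the rebound delay of the osteotome, inversely related to the
#' rigidity of the material at the blade tip.
#'
#' @param first_peak,second_peak `peak_fit` objects in time order.
#' @return `tau` in ms (positive).
#' @export
compute_tau <- function(first_peak, second_peak) {
  tau <- second_peak$center_ms - first_peak$center_ms
  if (!is.finite(tau) || tau <= 0)
    stop("peak ordering error: second peak centre must follow the first")
  tau
}

#' Peak-area ratio lambda
#'
#' `lambda = L2 / L1`, the ratio of the Gaussian areas of the second to the
#' first peak; linked to the viscoelasticity of the impacted material and
#' observed to drop when the osteotome breaks through the plate.
#'
#' @param first_peak,second_peak `peak_fit` objects in time order.
#' @return Dimensionless `lambda >= 0`.
#' @export
compute_lambda <- function(first_peak, second_peak) {
  if (first_peak$integral <= 0)
    stop("division error: first peak integral L1 must be positive")
  second_peak$integral / first_peak$integral
}

#' Extract the (tau, lambda) indicator pair from one impact
#'
#' Runs peak detection and Gaussian fitting on both peaks and returns the
#' two indicators. By default `tau` is measured between the Gaussian-fit
#' centres; set `use_fit_centers = FALSE` to use the raw sample maxima.
#'
#' @inheritParams detect_first_two_peaks
#' @inheritParams fit_gaussian_peak
#' @param use_fit_centers Logical; measure `tau` between fitted centres
#'   (default) or raw maxima.
#' @return List with `tau` (ms), `lambda`, `peak1`, `peak2` (`peak_fit`).
#' @export
extract_indicators <- function(signal, min_prominence_fraction = 0.1,
                               window_halfwidth_ms = 0.3,
                               use_fit_centers = TRUE) {
  idx <- detect_first_two_peaks(signal, min_prominence_fraction)
  p1 <- fit_gaussian_peak(signal, idx[1L], window_halfwidth_ms, rank = 1L)
  p2 <- fit_gaussian_peak(signal, idx[2L], window_halfwidth_ms, rank = 2L)
  tau <- if (use_fit_centers) compute_tau(p1, p2)
         else {
           dt <- signal$time_ms[idx[2L]] - signal$time_ms[idx[1L]]
           if (dt <= 0) stop("peak ordering error") else dt
         }
  list(tau = tau, lambda = compute_lambda(p1, p2), peak1 = p1, peak2 = p2)
}
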