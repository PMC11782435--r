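# Independent brute-force oracles and small signal builders shared by the
# unit tests. These deliberately avoid the package's own peak machinery.

# sum-of-Gaussians impact signal on the standard 51.2 kHz grid
make_gauss_signal <- function(centers_ms, amps, widths_ms,
                              sampling_rate = 51200, duration_ms = 5,
                              noise_sd = 0, ...) {
  n <- round(duration_ms * sampling_rate / 1000)
  t <- (seq_len(n) - 1) * 1000 / sampling_rate
  f <- rep(0, n)
  for (i in seq_along(centers_ms))
    f <- f + amps[i] * exp(-(t - centers_ms[i])^2 / (2 * widths_ms[i]^2))
  if (noise_sd > 0) f <- f + rnorm(n, 0, noise_sd)
  impact_signal(f, sampling_rate = sampling_rate, ...)
}

# naive local-maxima scan with the prominence rule, walking the raw samples
oracle_prominent_peaks <- function(f, frac) {
  n <- length(f)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (!(f[i] > f[i - 1] && f[i] > f[i + 1])) next
    h <- f[i]
    lmin <- h; j <- i - 1
    while (j >= 1 && f[j] <= h) { lmin <- min(lmin, f[j]); j <- j - 1 }
    if (j < 1) lmin <- min(f[1:i])
    rmin <- h; j <- i + 1
    while (j <= n && f[j] <= h) { rmin <- min(rmin, f[j]); j <- j + 1 }
    if (j > n) rmin <- min(f[i:n])
    if (h - max(lmin, rmin) >= frac * max(f)) peaks <- c(peaks, i)
  }
  peaks
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# hand-made peak_fit for testing the pure indicator arithmetic
fake_peak <- function(center_ms, amplitude, width_ms, rank = 1L) {
  structure(list(center_ms = center_ms, amplitude = amplitude,
                 width_ms = width_ms,
                 integral = sqrt(2 * pi) * width_ms * amplitude,
                 rank = rank),
            class = "peak_fit")
}

# feature table straight from the generator's ground truth (no extraction)
truth_features <- function(experiment) {
  m <- experiment$manifest
  m <- m[m$procedure == "osteotomy", ]
  ind <- data.frame(plate_id = m$plate_id, location_index = m$location_index,
                    impact_index = m$impact_index, tau_ms = m$tau_true_ms,
                    lambda = m$lambda_true, crossing = m$crossing)
  build_feature_table(ind)
}
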