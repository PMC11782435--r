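# Peak detection, Gaussian peak fitting and the tau / lambda indicators.

test_that("two clean Gaussian pulses are detected at their centres", {
  sig <- make_gauss_signal(c(1.0, 2.5), c(150, 100), c(0.15, 0.15))
  idx <- detect_first_two_peaks(sig)
  expect_lt(abs(sig$time_ms[idx[1]] - 1.0), 1000 / sig$sampling_rate * 1.5)
  expect_lt(abs(sig$time_ms[idx[2]] - 2.5), 1000 / sig$sampling_rate * 1.5)
  expect_lt(idx[1], idx[2])
})

test_that("a single-maximum trace raises an insufficient-peaks error", {
  sig <- impact_signal(c(0, 150 * exp(-(0:254) / 30)), plate_id = "X")
  expect_error(detect_first_two_peaks(sig), "insufficient peaks")
})

test_that("a sub-prominence ripple is rejected, matching the brute-force scan", {
  sig <- make_gauss_signal(c(1.0, 2.5, 0.5), c(150, 150, 0.75),
                           c(0.15, 0.15, 0.05))
  idx <- detect_first_two_peaks(sig, min_prominence_fraction = 0.1)
  oracle <- oracle_prominent_peaks(sig$force, 0.1)
  expect_length(oracle, 2L)
  expect_equal(sort(idx), sort(oracle))
  expect_lt(abs(sig$time_ms[idx[1]] - 1.0), 0.02)
})

test_that("Gaussian fit recovers an exact Gaussian and its closed-form area", {
  sig <- make_gauss_signal(1.0, 150, 0.15)
  idx <- which.max(sig$force)
  fit <- fit_gaussian_peak(sig, idx)
  expect_lt(abs(fit$center_ms - 1.0) / 1.0, 0.01)
  expect_lt(abs(fit$amplitude - 150) / 150, 0.01)
  expect_lt(abs(fit$width_ms - 0.15) / 0.15, 0.01)
  # closed-form Gaussian integral, cross-checked by trapezoid integration
  expect_equal(fit$integral, sqrt(2 * pi) * 0.15 * 150, tolerance = 0.01)
  tt <- seq(fit$center_ms - 6 * fit$width_ms, fit$center_ms + 6 * fit$width_ms,
            length.out = 2000)
  num <- trapezoid(tt, fit$amplitude *
                     exp(-(tt - fit$center_ms)^2 / (2 * fit$width_ms^2)))
  expect_lt(abs(fit$integral - num) / num, 0.005)
})

test_that("Gaussian fit tolerates 2% white noise", {
  set.seed(7)
  sig <- make_gauss_signal(1.0, 150, 0.15, noise_sd = 3)
  fit <- fit_gaussian_peak(sig, which.max(sig$force))
  expect_lt(abs(fit$amplitude - 150) / 150, 0.05)
  expect_lt(abs(fit$width_ms - 0.15) / 0.15, 0.05)
})

test_that("tau is the centre difference and rejects misordered peaks", {
  expect_equal(compute_tau(fake_peak(1.0, 150, 0.15),
                           fake_peak(2.5, 80, 0.15)), 1.5)
  expect_error(compute_tau(fake_peak(1.0, 150, 0.15),
                           fake_peak(1.0, 80, 0.15)), "ordering")
})

test_that("raw-maximum tau reproduces sample-index arithmetic", {
  # peaks on grid samples 52 and 129 at 51.2 kHz: tau = 77 / 51.2 ms
  sr <- 51200
  c1 <- 51 / 51.2; c2 <- 128 / 51.2
  sig <- make_gauss_signal(c(c1, c2), c(150, 100), c(0.15, 0.15))
  ind <- extract_indicators(sig, use_fit_centers = FALSE)
  expect_equal(ind$tau, 77 / 51.2, tolerance = 1e-12)
  # fitted centres agree to within a sample period
  ind2 <- extract_indicators(sig, use_fit_centers = TRUE)
  expect_equal(ind2$tau, 77 / 51.2, tolerance = 1000 / sr)
})

test_that("lambda is the peak-area ratio", {
  p <- fake_peak(1.0, 150, 0.15)
  expect_equal(compute_lambda(p, fake_peak(2.5, 150, 0.15)), 1.0)
  # sqrt(2*pi) cancels: (50 * 0.2) / (200 * 0.1) = 0.5
  expect_equal(compute_lambda(fake_peak(1, 200, 0.1),
                              fake_peak(2, 50, 0.2)), 0.5)
  expect_equal(compute_lambda(p, fake_peak(2.5, 0, 0.15)), 0)
  expect_error(compute_lambda(fake_peak(1, 0, 0.1), p), "division")
})

test_that("indicators are invariant to uniform force rescaling", {
  base <- make_gauss_signal(c(1.0, 2.2), c(150, 90), c(0.15, 0.15))
  ref <- extract_indicators(base)
  for (s in c(0.5, 2, 10)) {
    scaled <- impact_signal(base$force * s, plate_id = "S")
    ind <- extract_indicators(scaled)
    expect_equal(ind$tau, ref$tau, tolerance = 1e-6)
    expect_equal(ind$lambda, ref$lambda, tolerance = 1e-6)
  }
})

test_that("feature table computes first differences and drops first impacts", {
  ind <- data.frame(plate_id = "P1", location_index = 1L, impact_index = 1:3,
                    tau_ms = c(1.0, 1.1, 1.6), lambda = c(0.6, 0.5, 0.2),
                    crossing = c(FALSE, FALSE, TRUE))
  ft <- build_feature_table(ind)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$dtau_ms, c(0.1, 0.5))
  expect_equal(ft$dlambda, c(-0.1, -0.3))
  expect_equal(as.character(ft$label), c("Bone", "Crossing"))
})

test_that("feature table spans location boundaries within a plate", {
  ind <- data.frame(plate_id = "P1", location_index = c(1L, 1L, 2L, 2L),
                    impact_index = 1:4, tau_ms = c(1, 2, 4, 7),
                    lambda = rep(0.5, 4), crossing = FALSE)
  ft <- build_feature_table(ind)
  # difference at the location boundary uses the previous location's impact
  expect_equal(ft$dtau_ms, c(1, 2, 3))
})

test_that("a plate with N impacts yields N - 1 feature records, 2 Crossing per location", {
  set.seed(11)
  cfg <- generator_config(seed = 11)
  loc <- generate_osteotomy_location(1.5, 9, cfg, plate_id = "P1")
  tr <- loc$truth
  ind <- data.frame(plate_id = tr$plate_id, location_index = tr$location_index,
                    impact_index = tr$impact_index, tau_ms = tr$tau_true_ms,
                    lambda = tr$lambda_true, crossing = tr$crossing)
  ft <- build_feature_table(ind)
  expect_equal(nrow(ft), 8L)
  expect_equal(sum(ft$label == "Crossing"), 2L)
})

test_that("unordered or duplicated impact indices are an integrity error", {
  ind <- data.frame(plate_id = "P1", location_index = 1L,
                    impact_index = c(1L, 3L, 2L), tau_ms = 1:3,
                    lambda = 0.5, crossing = FALSE)
  expect_error(build_feature_table(ind), "integrity")
  ind$impact_index <- c(1L, 2L, 2L)
  expect_error(build_feature_table(ind), "integrity")
})

test_that("signal validation rejects malformed traces", {
  expect_error(impact_signal(rep(1, 10)), "64 samples")
  f <- rep(1, 64); f[3] <- NA
  expect_error(impact_signal(f), "finite")
  expect_error(impact_signal(rep(1, 64), time_ms = seq(0, 10, length.out = 64)),
               "uniform")
})
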