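#' Piecewise-linear tau-thickness model
#'
#' The inter-peak delay `tau` is flat at `tau0` while the plate is thicker
#' than the breakpoint `d_f`, and rises linearly with slope `k_f` (< 0, in
#' ms/mm) as the plate thins below it:
#' \deqn{\tilde\tau(Th) = \tau_0 \; (Th > d_f); \quad
#'       \tau_0 + k_f (Th - d_f) \; (Th \le d_f).}
#' The two branches agree at `Th = d_f` (the model is continuous).
#'
#' @param Th Plate thickness (mm), vectorised, `>= 0`.
#' @param tau0 Plateau delay (ms).
#' @param d_f Breakpoint thickness (mm).
#' @param k_f Slope below the breakpoint (ms/mm).
#' @return Predicted `tau` (ms).
#' @export
#' @examples
#' piecewise_tau(2.0, 0.9507, 1.2, -0.8924)  # plateau: 0.9507
#' piecewise_tau(0.5, 0.9351, 0.93, -0.6423) # 1.2113
piecewise_tau <- function(Th, tau0, d_f, k_f) {
  ifelse(Th > d_f, tau0, tau0 + k_f * (Th - d_f))
}

#' Mean absolute deviation cost of the piecewise model
#'
#' \deqn{e_\tau(d_f, k_f, \tau_0) = \sum_{j=1}^P
#'       |\tau(j) - \tilde\tau(Th(j))| / P}
#' over the `P` locations.
#'
#' @param params Numeric vector `c(tau0, d_f, k_f)` (names optional).
#' @param tau_ms Observed location-mean `tau` (ms).
#' @param thickness_mm Location thickness (mm), same length.
#' @return Nonnegative scalar cost (ms).
#' @export
cost_e_tau <- function(params, tau_ms, thickness_mm) {
  if (!length(tau_ms)) stop("cost_e_tau: no locations supplied")
  if (length(tau_ms) != length(thickness_mm))
    stop("cost_e_tau: tau and thickness lengths differ")
  mean(abs(tau_ms - piecewise_tau(thickness_mm, params[1L], params[2L],
                                  params[3L])))
}

#' Fit the piecewise-linear tau-thickness model
#'
#' Minimises the mean absolute deviation cost [cost_e_tau()] by Nelder--Mead,
#' restarted from jittered initial values (multiplicative jitter of up to
#' 20% per component); the best run is kept, ties in cost going to the
#' smaller breakpoint `d_f`. The breakpoint is clamped to the observed
#' thickness range during optimisation. Initial values default to: `tau0`
#' from the median `tau` of the thickest tercile, `d_f` from the median
#' thickness, and `k_f` from a least-squares line through the thinnest
#' tercile.
#'
#' @param formula Model formula `tau ~ thickness` naming the two columns of
#'   `data` (response: location-mean `tau` in ms; covariate: thickness mm).
#' @param data `data.frame` with the variables of `formula`; one row per
#'   location.
#' @param init Optional initial `c(tau0, d_f, k_f)`.
#' @param restarts Number of Nelder--Mead runs (first from `init`, the rest
#'   jittered). Jitter draws use the current RNG stream.
#' @param maxit,reltol Nelder--Mead iteration cap and relative convergence
#'   tolerance on the cost.
#' @return Object of class `tau_piecewise` with components `coefficients`
#'   (`tau0`, `d_f`, `k_f`), `E_tau` (minimised mean absolute residual, ms),
#'   `P` (number of locations), `identifiable` (FALSE when no location lies
#'   below the fitted breakpoint, in which case `d_f` and `k_f` are not
#'   determined by the data), `data`, `restart_costs`.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_location_tau(60, noise_sd = 0)
#' fit <- fit_tau_thickness(tau_ms ~ thickness_mm, d)
#' coef(fit)
fit_tau_thickness <- function(formula, data, init = NULL, restarts = 10L,
                              maxit = 2000L, reltol = 1e-10) {
  mf <- stats::model.frame(formula, data)
  tau <- mf[[1L]]
  th <- mf[[2L]]
  if (length(tau) < 4L)
    stop("fit_tau_thickness: need at least 4 locations")
  th_range <- range(th)
  if (is.null(init)) init <- init_piecewise(tau, th)
  obj <- function(p) {
    d_f <- min(max(p[2L], th_range[1L]), th_range[2L])
    cost_e_tau(c(p[1L], d_f, p[3L]), tau, th)
  }
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    start <- if (r == 1L) init else init * runif(3L, 0.8, 1.2)
    opt <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    par <- opt$par
    par[2L] <- min(max(par[2L], th_range[1L]), th_range[2L])
    runs[[r]] <- list(par = par, value = obj(opt$par))
  }
  costs <- vapply(runs, `[[`, numeric(1), "value")
  best_cost <- min(costs)
  # tie-break equal-cost optima by the smallest breakpoint
  tied <- which(costs <= best_cost + 1e-9)
  best <- tied[which.min(vapply(runs[tied], function(r) r$par[2L], numeric(1)))]
  par <- runs[[best]]$par
  init_cost <- obj(init)
  if (costs[best] > init_cost + max(1e-8, 1e-6 * init_cost)) {
    warning("fit_tau_thickness: no restart improved on the initial values; ",
            "returning the initial parameters")
    par <- init
  }
  # the breakpoint is determined only if locations lie below it AND the
  # sloped segment moves tau by more than the residual scale
  slope_effect <- abs(par[3L]) * max(par[2L] - th_range[1L], 0)
  identifiable <- sum(th < par[2L] - 1e-8) >= 2L &&
    slope_effect > 2 * max(costs[best], 1e-8)
  if (!identifiable)
    warning("fit_tau_thickness: no location below the fitted breakpoint; ",
            "d_f and k_f are not identifiable from these data")
  structure(
    list(coefficients = setNames(par, c("tau0", "d_f", "k_f")),
         E_tau = costs[best], P = length(tau), identifiable = identifiable,
         data = data.frame(tau_ms = tau, thickness_mm = th),
         restart_costs = costs, formula = formula,
         call = match.call()),
    class = "tau_piecewise")
}

init_piecewise <- function(tau, th) {
  q <- quantile(th, c(1 / 3, 2 / 3), names = FALSE)
  thick <- th >= q[2L]
  thin <- th <= q[1L]
  tau0 <- median(tau[thick])
  k_f <- if (sum(thin) >= 2L && diff(range(th[thin])) > 0)
    unname(coef(stats::lm(tau[thin] ~ th[thin]))[2L]) else -0.5
  if (!is.finite(k_f) || k_f >= 0) k_f <- -0.5
  c(tau0 = tau0, d_f = median(th), k_f = k_f)
}

#' @export
print.tau_piecewise <- function(x, digits = 4, ...) {
  cat("Piecewise-linear tau-thickness fit (Nelder-Mead, mean |residual|)\n")
  cat(sprintf("  tau0 = %.*f ms, d_f = %.*f mm, k_f = %.*f ms/mm\n",
              digits, x$coefficients[1L], digits, x$coefficients[2L],
              digits, x$coefficients[3L]))
  cat(sprintf("  E_tau = %.*f ms over P = %d locations\n",
              digits, x$E_tau, x$P))
  if (!x$identifiable)
    cat("  note: all locations above the breakpoint; d_f, k_f unidentified\n")
  invisible(x)
}

#' @export
summary.tau_piecewise <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 residual_summary = summary(res),
                 thickness_range = range(object$data$thickness_mm)),
            class = "summary.tau_piecewise")
}

#' @export
print.summary.tau_piecewise <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  thickness range: %.2f - %.2f mm\n",
              x$thickness_range[1L], x$thickness_range[2L]))
  cat("  residuals (ms):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.tau_piecewise <- function(object, ...) object$coefficients

#' Predict tau from a fitted piecewise model
#'
#' @param object A `tau_piecewise` fit.
#' @param newdata Numeric vector of thicknesses (mm), or a `data.frame`
#'   containing the covariate named in the fit formula. Defaults to the
#'   training thicknesses.
#' @param ... Unused.
#' @return Predicted `tau` (ms).
#' @export
predict.tau_piecewise <- function(object, newdata = NULL, ...) {
  th <- if (is.null(newdata)) object$data$thickness_mm
        else if (is.data.frame(newdata)) {
          v <- all.vars(object$formula)[2L]
          if (!v %in% names(newdata))
            stop("newdata lacks column ", v)
          newdata[[v]]
        } else as.numeric(newdata)
  p <- object$coefficients
  piecewise_tau(th, p[1L], p[2L], p[3L])
}

#' @export
fitted.tau_piecewise <- function(object, ...) predict(object)

#' @export
residuals.tau_piecewise <- function(object, ...)
  object$data$tau_ms - fitted(object)

#' Plot a piecewise tau-thickness fit
#'
#' Scatter of location-mean `tau` against thickness with the fitted
#' piecewise line and the breakpoint marked.
#'
#' @param x A `tau_piecewise` fit.
#' @param ... Passed to [plot()].
#' @export
plot.tau_piecewise <- function(x, ...) {
  d <- x$data
  plot(d$thickness_mm, d$tau_ms, xlab = "Thickness (mm)",
       ylab = expression(tau ~ "(ms)"), ...)
  th <- seq(min(d$thickness_mm), max(d$thickness_mm), length.out = 200)
  lines(th, predict(x, th), lwd = 2)
  abline(v = x$coefficients["d_f"], lty = 3)
  invisible(x)
}

#' Pool calliper thickness measurements into location means
#'
#' The plate thickness is measured repeatedly on a regular grid along the
#' plate (5 repeats every 2.5 mm by default in the experiments); each
#' osteotome location covers an interval of that axis. All repeated
#' measures whose grid position falls inside a location's extent (closed
#' interval) are pooled into that location's mean and sd.
#'
#' @param measurements `data.frame` with columns `position_mm` and
#'   `thickness_mm` (one row per repeated measure).
#' @param extents `data.frame` with columns `location_index`, `x_min_mm`,
#'   `x_max_mm` (one row per location; extra id columns are carried through).
#' @return `extents` with added `mean_thickness_mm`, `sd_thickness_mm`,
#'   `n_measures`.
#' @export
#' @examples
#' m <- data.frame(position_mm = rep(c(0, 2.5), each = 5),
#'                 thickness_mm = c(rep(2, 5), rep(1, 5)))
#' e <- data.frame(location_index = 1, x_min_mm = 0, x_max_mm = 2.5)
#' aggregate_thickness(m, e)$mean_thickness_mm  # 1.5
aggregate_thickness <- function(measurements, extents) {
  stopifnot(all(c("position_mm", "thickness_mm") %in% names(measurements)),
            all(c("location_index", "x_min_mm", "x_max_mm") %in% names(extents)))
  out <- extents
  out$mean_thickness_mm <- NA_real_
  out$sd_thickness_mm <- NA_real_
  out$n_measures <- NA_integer_
  for (i in seq_len(nrow(extents))) {
    sel <- measurements$position_mm >= extents$x_min_mm[i] &
           measurements$position_mm <= extents$x_max_mm[i]
    if (!any(sel))
      stop("no thickness measurements overlap location ",
           extents$location_index[i])
    v <- measurements$thickness_mm[sel]
    out$mean_thickness_mm[i] <- mean(v)
    out$sd_thickness_mm[i] <- if (length(v) > 1L) sd(v) else 0
    out$n_measures[i] <- length(v)
  }
  out
}

#' Summarise impacts into per-location means
#'
#' Computes the per-location mean and sd of `tau` and of thickness, using
#' only the impacts labelled Bone (Crossing impacts reflect the ruptured
#' plate, not its thickness).
#'
#' @param impacts `data.frame` with columns `plate_id`, `location_index`,
#'   `procedure`, `tau_ms`, `thickness_mm` and either a logical `crossing`
#'   or a `label` column.
#' @return `data.frame` with one row per (plate, procedure, location):
#'   `plate_id`, `location_index`, `procedure`, `mean_tau_ms`, `sd_tau_ms`,
#'   `mean_thickness_mm`, `sd_thickness_mm`, `n_impacts`.
#' @export
summarize_locations <- function(impacts) {
  if (!is.null(impacts$label)) bone <- impacts$label == "Bone"
  else if (!is.null(impacts$crossing)) bone <- !impacts$crossing
  else bone <- rep(TRUE, nrow(impacts))
  d <- impacts[bone, , drop = FALSE]
  key <- interaction(d$plate_id, d$procedure, d$location_index, drop = TRUE)
  parts <- split(d, key)
  out <- do.call(rbind, lapply(parts, function(g) data.frame(
    plate_id = g$plate_id[1L], location_index = g$location_index[1L],
    procedure = g$procedure[1L],
    mean_tau_ms = mean(g$tau_ms),
    sd_tau_ms = if (nrow(g) > 1L) sd(g$tau_ms) else 0,
    mean_thickness_mm = mean(g$thickness_mm),
    sd_thickness_mm = if (nrow(g) > 1L) sd(g$thickness_mm) else 0,
    n_impacts = nrow(g), stringsAsFactors = FALSE)))
  out <- out[order(out$plate_id, out$procedure, out$location_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
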