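#' Preprocess an OD600 growth curve
#'
#' Blank subtraction and log transformation: the uninoculated-well signal
#' (if given) is subtracted pointwise, and the curve is transformed to
#' `y = ln(OD_t / OD_0)` with `OD_0` the (blank-corrected) reading at the
#' first time point, so `y[1] == 0` exactly.
#'
#' @param times hours, strictly increasing, `times[1] >= 0`.
#' @param od OD600 readings aligned to `times`.
#' @param blank optional uninoculated-well OD600 on the same time grid.
#' @return data.frame with columns `time` and `y`.
#' @export
preprocess_curve <- function(times, od, blank = NULL) {
  if (length(times) != length(od)) stop_bsa("times and od differ in length")
  if (any(diff(times) <= 0)) stop_bsa("times must be strictly increasing")
  if (times[1] < 0) stop_bsa("times must start at >= 0")
  if (!is.null(blank)) {
    if (length(blank) != length(od))
      stop_bsa("blank must be on the same time grid as od")
    od <- od - blank
  }
  if (any(od <= 0)) {
    bad <- times[od <= 0]
    stop_bsa("non-positive OD after blank subtraction at t = ",
             paste(format(bad), collapse = ", "))
  }
  data.frame(time = times, y = log(od / od[1]))
}

#' Reparameterized Gompertz growth model
#'
#' `y(t) = D * exp(-exp((mu_max * e / D) * (lam - t) + 1))` — the Zwietering
#' form whose parameters are directly interpretable: `D` is the asymptotic
#' maximum of `y = ln(OD_t/OD_0)`, `mu_max` the maximum specific growth
#' rate (h^-1, the slope at the inflection point), and `lam` the lag phase
#' (h, the time-axis intercept of the steepest tangent).
#'
#' @param t time in hours (vectorised).
#' @param D asymptote (> 0).
#' @param mu_max maximum specific growth rate (h^-1).
#' @param lam lag time (h).
#' @return y values.
#' @export
gompertz_y <- function(t, D, mu_max, lam) {
  if (D <= 0) stop_bsa("D must be > 0")
  D * exp(-exp((mu_max * exp(1) / D) * (lam - t) + 1))
}

# Jacobian of gompertz_y wrt (D, mu_max, lam); columns in that order.
gompertz_jacobian <- function(t, D, mu_max, lam) {
  e1 <- exp(1)
  u <- (mu_max * e1 / D) * (lam - t) + 1
  A <- exp(u)
  y <- D * exp(-A)
  dD <- exp(-A) + y * A * (mu_max * e1 / D^2) * (lam - t)
  dmu <- -y * A * (e1 / D) * (lam - t)
  dlam <- -y * A * (mu_max * e1 / D)
  cbind(D = dD, mu_max = dmu, lam = dlam)
}

#' Fit the reparameterized Gompertz model by damped Gauss-Newton
#'
#' Nonlinear least squares on a preprocessed `y` series. Initialisation:
#' `D0 = max(y)`, `mu0` = steepest finite-difference slope, `lam0` = the
#' time-axis intercept of the steepest tangent (floored at 0). Each
#' Gauss-Newton step is halved until the residual sum of squares decreases
#' (at most 50 halvings), guaranteeing descent; convergence is declared
#' when the relative SSE change drops below `tol` or after `max_iter`
#' iterations (the fit is then returned with `converged = FALSE`).
#'
#' @param y_series data.frame with columns `time`, `y` (see
#'   [preprocess_curve()]), at least 4 points, non-constant.
#' @param tol relative SSE convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `gompertz_fit`: list with `D`, `mu_max`, `lam`,
#'   `sse`, `converged`, `n_iter`.
#' @export
fit_gompertz <- function(y_series, tol = 1e-8, max_iter = 200L) {
  stopifnot(all(c("time", "y") %in% names(y_series)))
  t <- y_series$time; y <- y_series$y
  if (length(t) < 4L) stop_bsa("need at least 4 points to fit 3 parameters")
  if (max(y) - min(y) < .Machine$double.eps^0.5)
    stop_bsa("degenerate curve: y is constant")
  slopes <- diff(y) / diff(t)
  i <- which.max(slopes)
  D <- max(y)
  mu <- max(slopes[i], 1e-6)
  tm <- (t[i] + t[i + 1]) / 2; ym <- (y[i] + y[i + 1]) / 2
  lam <- max(tm - ym / mu, 0)
  theta <- c(D = max(D, 1e-6), mu_max = mu, lam = lam)
  sse <- sum((y - gompertz_y(t, theta[1], theta[2], theta[3]))^2)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - gompertz_y(t, theta[1], theta[2], theta[3])
    J <- gompertz_jacobian(t, theta[1], theta[2], theta[3])
    step <- tryCatch(solve(crossprod(J) + diag(1e-12, 3), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    step <- drop(step)
    # halve the step until SSE decreases and parameters stay admissible
    new_sse <- Inf; cand <- theta
    for (h in 0:50) {
      cand <- theta + step / 2^h
      if (cand[1] <= 0 || cand[2] <= 0) next
      s <- sum((y - gompertz_y(t, cand[1], cand[2], cand[3]))^2)
      if (is.finite(s) && s < sse) { new_sse <- s; break }
    }
    if (!is.finite(new_sse)) {
      # no descent left: converged if the normal-equations gradient is flat
      converged <- max(abs(crossprod(J, r))) < 1e-8 * (1 + sse)
      break
    }
    rel <- (sse - new_sse) / max(sse, .Machine$double.xmin)
    theta <- cand; sse <- new_sse
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(D = unname(theta[1]), mu_max = unname(theta[2]),
                 lam = unname(theta[3]), sse = sse,
                 converged = converged, n_iter = iter),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "gompertz_fit: D = %.4g, mu_max = %.4g h^-1, lam = %.4g h (sse %.3g, %s in %d iter)\n",
    x$D, x$mu_max, x$lam, x$sse,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Fit every well of a wide-format growth plate
#'
#' Reads the plate layout used by plate readers: first column time in
#' hours, one column per well. Blank wells (named in `blank_wells`) are
#' averaged and subtracted from every other well before fitting.
#'
#' @param plate data.frame, first column time, remaining columns OD600.
#' @param blank_wells character vector of blank column names (optional).
#' @return data.frame: well, D, mu_max, lam, sse, converged, n_iter.
#' @export
fit_growth_plate <- function(plate, blank_wells = NULL) {
  times <- plate[[1]]
  wells <- setdiff(names(plate)[-1], blank_wells)
  blank <- if (length(blank_wells))
    rowMeans(plate[, blank_wells, drop = FALSE]) else NULL
  do.call(rbind, lapply(wells, function(w) {
    fit <- fit_gompertz(preprocess_curve(times, plate[[w]], blank))
    data.frame(well = w, D = fit$D, mu_max = fit$mu_max, lam = fit$lam,
               sse = fit$sse, converged = fit$converged, n_iter = fit$n_iter)
  }))
}
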