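#' A single Cavitron vulnerability experiment
#'
#' Bundles the conductance measurements of one stem batch spun in the
#' centrifuge: a reference conductivity `K_max` measured at near-zero
#' xylem pressure, followed by conductivities at increasingly negative
#' pressures. PLC points for fitting are derived from the `points`
#' table against `K_max`.
#'
#' @param curve_id label identifying the experiment.
#' @param accession accession/genotype label.
#' @param pressure_MPa xylem pressures in MPa, all `<= 0`, strictly
#'   decreasing.
#' @param K conductivities at those pressures, non-negative.
#' @param K_max reference conductivity at near-zero pressure, positive.
#' @return an object of class `conductance_series`: a list with
#'   `curve_id`, `accession`, `points` (data.frame of `pressure_MPa`,
#'   `K`) and `K_max`.
#' @export
conductance_series <- function(curve_id, accession, pressure_MPa, K, K_max) {
  if (!is.numeric(K_max) || length(K_max) != 1L || !is.finite(K_max) || K_max <= 0) {
    stop("`K_max` must be a single positive conductivity", call. = FALSE)
  }
  if (length(pressure_MPa) != length(K)) {
    stop("`pressure_MPa` and `K` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(pressure_MPa)) || any(pressure_MPa > 0)) {
    stop("pressures must be finite and <= 0 MPa", call. = FALSE)
  }
  if (any(!is.finite(K)) || any(K < 0)) {
    stop("conductivities must be finite and >= 0", call. = FALSE)
  }
  if (length(pressure_MPa) > 1L && any(diff(pressure_MPa) >= 0)) {
    stop("pressures must be strictly decreasing along the spin schedule",
         call. = FALSE)
  }
  structure(
    list(
      curve_id = as.character(curve_id),
      accession = as.character(accession),
      points = data.frame(pressure_MPa = as.numeric(pressure_MPa),
                          K = as.numeric(K)),
      K_max = as.numeric(K_max)
    ),
    class = "conductance_series"
  )
}

#' @export
print.conductance_series <- function(x, ...) {
  cat(sprintf("<conductance_series> %s (%s): %d points, K_max = %.4g\n",
              x$curve_id, x$accession, nrow(x$points), x$K_max))
  invisible(x)
}

# PLC points of a series (pressure, plc) used by the fitter.
series_plc <- function(series) {
  data.frame(pressure_MPa = series$points$pressure_MPa,
             plc = plc(series$points$K, series$K_max))
}

#' Fit the sigmoid vulnerability model to one experiment
#'
#' Nonlinear least squares of the sigmoid model (see [sigmoid_plc()])
#' on the (pressure, PLC) points of a [conductance_series()].
#' The slope is fitted on the log scale, so `S > 0` is enforced
#' without hard bounds; `P50` is unconstrained. Starting values:
#' `P50` at the pressure of the point with PLC nearest 50 %, `S` from
#' the local finite-difference slope (floored at 5 % MPa^-1). On
#' non-convergence up to five jittered restarts are attempted; if all
#' fail the result carries `converged = FALSE` rather than erroring.
#'
#' @param series a [conductance_series()], or a data.frame with columns
#'   `pressure_MPa` and `plc` for pre-computed PLC points.
#' @param control list of optimiser settings: `maxiter` (default 500),
#'   `ftol` (relative RSS tolerance, default 1e-10), `restarts`
#'   (default 5).
#' @return an object of class `fitted_vc`: list with `P50_hat`,
#'   `S_hat`, `P12_hat`, `P88_hat`, `covariance` (2x2, for (P50, S),
#'   delta method on the log-S parameterisation), `rss`, `n_points`,
#'   `converged`, `curve_id`, `accession`, `residuals`.
#' @export
fit_curve <- function(series, control = list()) {
  ctl <- utils::modifyList(list(maxiter = 500L, ftol = 1e-10, restarts = 5L),
                           control)
  if (inherits(series, "conductance_series")) {
    pts <- series_plc(series)
    curve_id <- series$curve_id
    accession <- series$accession
  } else {
    pts <- as.data.frame(series)
    stopifnot(all(c("pressure_MPa", "plc") %in% names(pts)))
    curve_id <- attr(series, "curve_id") %||% NA_character_
    accession <- attr(series, "accession") %||% NA_character_
  }
  P <- pts$pressure_MPa
  y <- pts$plc
  if (length(P) < 4L) {
    warning("fewer than 4 PLC points: fit may be ill-posed", call. = FALSE)
  }
  if (diff(range(y)) < sqrt(.Machine$double.eps)) {
    stop("degenerate data: all PLC values equal; sigmoid parameters are not identifiable",
         call. = FALSE)
  }
  if (min(y) > 30 || max(y) < 70) {
    warning("PLC points do not span both the <30 % and >70 % regions; ",
            "fit may be poorly constrained", call. = FALSE)
  }

  # starting values from the point closest to 50 % loss
  i50 <- which.min(abs(y - 50))
  p50_init <- P[i50]
  ord <- order(P)
  fd <- abs(diff(y[ord]) / diff(P[ord]))
  fd <- fd[is.finite(fd)]  # duplicate pressures give 0/0 or Inf slopes
  slope_fd <- if (length(fd)) stats::median(fd) else 5
  s_init <- max(5, slope_fd)

  dat <- data.frame(P = P, y = y)
  fit1 <- function(p50_0, logS_0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ 100 / (1 + exp((exp(logS) / 25) * (P - P50))),
        data = dat,
        start = list(P50 = p50_0, logS = logS_0),
        control = minpack.lm::nls.lm.control(
          maxiter = ctl$maxiter, ftol = ctl$ftol, ptol = 1e-12)
      ),
      error = function(e) NULL)
  }

  fit <- fit1(p50_init, log(s_init))
  tries <- 0L
  while (is.null(fit) && tries < ctl$restarts) {
    tries <- tries + 1L
    jit_p <- p50_init + stats::runif(1, -0.5, 0.5) * max(1, diff(range(P)) / 2)
    jit_s <- log(s_init) + stats::runif(1, -1, 1)
    fit <- fit1(jit_p, jit_s)
  }

  if (is.null(fit)) {
    out <- list(P50_hat = NA_real_, S_hat = NA_real_,
                P12_hat = NA_real_, P88_hat = NA_real_,
                covariance = matrix(NA_real_, 2, 2,
                                    dimnames = list(c("P50", "S"), c("P50", "S"))),
                rss = NA_real_, n_points = length(P), converged = FALSE,
                curve_id = curve_id, accession = accession,
                residuals = rep(NA_real_, length(P)))
    return(structure(out, class = "fitted_vc"))
  }

  cf <- stats::coef(fit)
  P50_hat <- unname(cf["P50"])
  S_hat <- exp(unname(cf["logS"]))
  # delta method: var(S) = S^2 var(logS); cov(P50, S) = S cov(P50, logS)
  V <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(1, S_hat))
  covar <- J %*% V %*% t(J)
  dimnames(covar) <- list(c("P50", "S"), c("P50", "S"))
  res <- stats::residuals(fit)

  out <- list(
    P50_hat = P50_hat,
    S_hat = S_hat,
    P12_hat = pressure_at_loss(P50_hat, S_hat, 12),
    P88_hat = pressure_at_loss(P50_hat, S_hat, 88),
    covariance = covar,
    rss = sum(res^2),
    n_points = length(P),
    converged = TRUE,
    curve_id = curve_id,
    accession = accession,
    residuals = as.numeric(res)
  )
  structure(out, class = "fitted_vc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fitted_vc <- function(x, ...) {
  cat(sprintf(
    "<fitted_vc> %s (%s)\n  P50 = %.3f MPa  S = %.1f %% MPa^-1  [P12 = %.3f, P88 = %.3f]\n  rss = %.4g on %d points%s\n",
    x$curve_id, x$accession, x$P50_hat, x$S_hat, x$P12_hat, x$P88_hat,
    x$rss, x$n_points, if (x$converged) "" else "  (NOT CONVERGED)"))
  invisible(x)
}

#' Fit a set of vulnerability curves into one table
#'
#' @param series_list list of [conductance_series()] objects.
#' @param ... passed to [fit_curve()].
#' @return data.frame with one row per curve: `curve_id`, `accession`,
#'   `P50`, `S`, `P12`, `P88`, `rss`, `n_points`, `converged`.
#' @export
fit_curves <- function(series_list, ...) {
  fits <- lapply(series_list, fit_curve, ...)
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(curve_id = f$curve_id, accession = f$accession,
               P50 = f$P50_hat, S = f$S_hat, P12 = f$P12_hat,
               P88 = f$P88_hat, rss = f$rss, n_points = f$n_points,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Mean vulnerability curve with standard-error band
#'
#' Fits each input curve, evaluates every fitted sigmoid on a common
#' pressure grid, and returns the per-pressure mean PLC and its
#' standard error across curves (as in a mean curve +/- SE figure).
#'
#' @param curves list of [conductance_series()] objects (or of
#'   `fitted_vc` objects already produced by [fit_curve()]); at least 2.
#' @param grid pressures (MPa) at which to evaluate; non-empty.
#' @return object of class `mean_vc`: data.frame with `pressure_MPa`,
#'   `mean_plc`, `se_plc` and attribute `n_curves`.
#' @export
mean_curve <- function(curves, grid) {
  if (length(grid) == 0L || any(!is.finite(grid))) {
    stop("`grid` must be a non-empty vector of finite pressures", call. = FALSE)
  }
  if (length(curves) < 2L) {
    stop("need at least 2 curves for a mean curve", call. = FALSE)
  }
  fits <- lapply(curves, function(cv) {
    if (inherits(cv, "fitted_vc")) cv else fit_curve(cv)
  })
  bad <- !vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(bad)) {
    warning(sum(bad), " curve(s) did not converge and are excluded", call. = FALSE)
    fits <- fits[!bad]
  }
  mat <- vapply(fits, function(f) sigmoid_plc(grid, f$P50_hat, f$S_hat),
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n <- ncol(mat)
  mean_plc <- rowMeans(mat)
  se_plc <- apply(mat, 1, stats::sd) / sqrt(n)
  out <- data.frame(pressure_MPa = grid, mean_plc = mean_plc, se_plc = se_plc)
  attr(out, "n_curves") <- n
  class(out) <- c("mean_vc", "data.frame")
  out
}

#' Plot a mean vulnerability curve with its standard-error band
#'
#' @param x a `mean_vc` object from [mean_curve()].
#' @param ... further arguments passed to [plot()].
#' @export
plot.mean_vc <- function(x, ...) {
  op <- list(...)
  plot(x$pressure_MPa, x$mean_plc, type = "n",
       xlab = "Xylem pressure (MPa)", ylab = "PLC (%)",
       ylim = c(0, 100), ...)
  graphics::polygon(c(x$pressure_MPa, rev(x$pressure_MPa)),
                    c(x$mean_plc - x$se_plc, rev(x$mean_plc + x$se_plc)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$pressure_MPa, x$mean_plc, lwd = 2, col = "steelblue4")
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}
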