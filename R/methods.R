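#' @export
print.cbl_fit <- function(x, digits = 4, ...) {
  tr <- x$traits
  cat("Concentration boundary layer fit (", x$analyte, " profile)\n",
      sep = "")
  cat("  class:     ", x$profile_class, "\n")
  if (!is.na(tr$thickness_um))
    cat("  thickness: ", format(tr$thickness_um, digits = digits), "um\n")
  if (x$analyte == "O2") {
    cat("  surface:   ", format(tr$c_surface, digits = digits),
        "uM  (bulk ", format(tr$c_bulk, digits = digits), "uM)\n")
    cat("  delta O2:  ", format(tr$surface_delta, digits = digits), "uM\n")
    if (!is.na(tr$flux))
      cat("  flux:      ", format(tr$flux, digits = digits),
          "umol cm^-2 h^-1\n")
  } else {
    cat("  surface pH:", format(tr$ph_surface, digits = digits),
        " (bulk ", format(tr$ph_bulk, digits = digits), ")\n")
    cat("  delta pH:  ", format(tr$delta_ph, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
summary.cbl_fit <- function(object, ...) {
  segs <- object$segments
  seg_df <- if (length(segs)) {
    do.call(rbind, lapply(segs, function(s)
      data.frame(z_lo = s$z_lo, z_hi = s$z_hi, slope = s$slope_m,
                 intercept = s$intercept_c0, r2 = s$r2,
                 n = s$n_points)))
  } else data.frame()
  structure(list(fit = object, segments = seg_df,
                 sigma_noise = object$bulk$sigma_noise,
                 n_plateau = object$bulk$n_plateau),
            class = "summary.cbl_fit")
}

#' @export
print.summary.cbl_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  plateau:   ", x$n_plateau, "points, noise SD",
      format(x$sigma_noise, digits = digits), "\n")
  if (nrow(x$segments)) {
    cat("  segments (innermost first):\n")
    print(x$segments, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cbl_fit <- function(object, all = FALSE, ...) {
  if (all) {
    m <- t(vapply(object$segments, function(s)
      c(intercept = s$intercept_c0, slope = s$slope_m), c(0, 0)))
    return(m)
  }
  s <- object$chosen_segment
  if (is.null(s)) return(c(intercept = NA_real_, slope = NA_real_))
  c(intercept = s$intercept_c0, slope = s$slope_m)
}

#' Predicted profile values from a boundary layer fit
#'
#' Evaluates the fitted piecewise-linear model: segment lines over the
#' sub-bulk region, the bulk concentration beyond the plateau edge.
#' Predictions are in the working units of the fit ([H+] in mol L^-1 for
#' pH profiles, micromolar for O2).
#'
#' @param object a \code{"cbl_fit"}.
#' @param newdata optional numeric vector of positions (micrometres); the
#'   observed positions by default.
#' @param ... unused.
#' @export
predict.cbl_fit <- function(object, newdata = NULL, ...) {
  z <- if (is.null(newdata)) object$z else as.numeric(newdata)
  if (!length(object$segments))
    return(rep(object$bulk$c_bulk, length(z)))
  .piecewise_eval(object$segments, object$bulk, z)
}

#' @export
fitted.cbl_fit <- function(object, ...) predict(object)

#' @export
residuals.cbl_fit <- function(object, ...) object$y - fitted(object)

#' Simulate replicate profiles from a boundary layer fit
#'
#' Draws new profiles as the fitted piecewise-linear values plus Gaussian
#' noise with the plateau-estimated sensor SD, at the observed positions.
#'
#' @param object a \code{"cbl_fit"}.
#' @param nsim number of replicate profiles.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param ... unused.
#' @return List of numeric vectors of length \code{length(object$z)}.
#' @export
simulate.cbl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  f <- fitted(object)
  sig <- object$bulk$sigma_noise
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    f + stats::rnorm(length(f), 0, sig)))
}

#' Plot a boundary layer fit
#'
#' Base-graphics diagnostic plot: measured points, fitted segment lines,
#' the bulk concentration, plateau points, and the extrapolated thickness
#' marker.
#'
#' @param x a \code{"cbl_fit"}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.cbl_fit <- function(x, ...) {
  ylab <- if (x$analyte == "O2") "O2 (uM)" else "[H+] (mol L^-1)"
  graphics::plot(x$z, x$y, xlab = "height above surface (um)", ylab = ylab,
                 pch = 16, ...)
  graphics::abline(h = x$bulk$c_bulk, lty = 3)
  ip <- x$bulk$plateau_start_index:length(x$z)
  graphics::points(x$z[ip], x$y[ip], pch = 1, cex = 1.6, col = "grey40")
  for (s in x$segments)
    graphics::segments(s$z_lo, s$intercept_c0 + s$slope_m * s$z_lo,
                       s$z_hi, s$intercept_c0 + s$slope_m * s$z_hi,
                       col = "red3", lwd = 2)
  if (!is.na(x$traits$thickness_um))
    graphics::abline(v = x$traits$thickness_um, lty = 2, col = "blue3")
  invisible(x)
}

# run code with a temporary RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
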