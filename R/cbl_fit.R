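#' Detect the bulk-seawater plateau of a profile
#'
#' Identifies the free-flow region of a microsensor profile by growing a
#' plateau inward from the outermost point: starting from the three
#' outermost points, each next-inner point is accepted while it lies
#' within \code{k_sigma} running standard deviations (floored by
#' \code{noise_floor}) of the running plateau mean. The plateau mean is
#' the bulk concentration estimate and the plateau SD the sensor noise
#' estimate.
#'
#' @param profile a \code{\link{cbl_profile}} (or anything with numeric
#'   \code{z} and \code{value} elements).
#' @param k_sigma acceptance width in running SDs (default 3). With few
#'   plateau points the running SD is a poor noise estimate, so the
#'   acceptance band is the corresponding two-sided prediction interval
#'   (t quantile at n - 1 df, inflated by sqrt(1 + 1/n)); it converges to
#'   plain k_sigma running SDs as the plateau grows.
#' @param noise_floor lower bound on the running SD used in the
#'   acceptance test, in analyte units. Defaults to
#'   \code{1e-9 * max(|value|)} so that noiseless profiles terminate the
#'   plateau at the first genuinely off-plateau point whatever the
#'   analyte's magnitude.
#' @return List of class \code{"cbl_bulk"}: \code{c_bulk} (plateau mean),
#'   \code{sigma_noise} (plateau SD), \code{plateau_start_index} (index
#'   into the sorted profile of the innermost plateau point),
#'   \code{n_plateau}.
#' @export
detect_bulk <- function(profile, k_sigma = 3, noise_floor = NULL) {
  z <- profile$z; v <- profile$value
  n <- length(v)
  if (n < 3) stop("no free-flow region: fewer than 3 points")
  if (is.null(noise_floor)) noise_floor <- .default_noise_floor(v)
  alpha <- 2 * stats::pnorm(-k_sigma)
  idx <- n:(n - 2)                      # outermost three points
  repeat {
    cand <- min(idx) - 1
    if (cand < 1) break
    m <- mean(v[idx]); s <- max(stats::sd(v[idx]), noise_floor)
    np <- length(idx)
    band <- stats::qt(1 - alpha / 2, df = np - 1) * s * sqrt(1 + 1 / np)
    if (abs(v[cand] - m) <= band) idx <- c(idx, cand) else break
  }
  structure(list(c_bulk = mean(v[idx]),
                 sigma_noise = stats::sd(v[idx]),
                 plateau_start_index = min(idx),
                 n_plateau = length(idx)),
            class = "cbl_bulk")
}

# scale-relative floor so noiseless plateaus terminate at true gradient
# points for any analyte magnitude (O2 in uM, [H+] ~ 1e-8 mol/L)
.default_noise_floor <- function(v) 1e-9 * max(abs(v), 1e-300)

# Closed-form OLS of v ~ z on index set i; returns slope, intercept at
# z = 0, RSS, r2, and the z range.
.seg_ols <- function(z, v, i) {
  zi <- z[i]; vi <- v[i]
  zm <- mean(zi); vm <- mean(vi)
  szz <- sum((zi - zm)^2)
  slope <- if (szz > 0) sum((zi - zm) * (vi - vm)) / szz else 0
  c0 <- vm - slope * zm
  res <- vi - (c0 + slope * zi)
  rss <- sum(res^2)
  tss <- sum((vi - vm)^2)
  list(z_lo = min(zi), z_hi = max(zi), slope_m = slope, intercept_c0 = c0,
       rss = rss, r2 = if (tss > 0) max(0, 1 - rss / tss) else 1,
       n_points = length(i))
}

# all ways to split 1..n into k+1 contiguous blocks of >= min_pts points;
# returns list of integer vectors of block end indices (excluding n)
.breakpoint_sets <- function(n, k, min_pts) {
  if (k == 0) return(list(integer(0)))
  pos <- seq(min_pts, n - min_pts)     # candidate block ends
  if (length(pos) < k) return(list())
  combs <- utils::combn(pos, k, simplify = FALSE)
  Filter(function(b) all(diff(c(0, b, n)) >= min_pts), combs)
}

.fit_partition <- function(z, v, breaks, n) {
  bounds <- c(0, breaks, n)
  lapply(seq_len(length(bounds) - 1), function(j)
    .seg_ols(z, v, (bounds[j] + 1):bounds[j + 1]))
}

#' Fit piecewise-linear gradient segments below the bulk plateau
#'
#' The sub-bulk region of a profile (all points inside the plateau found
#' by \code{\link{detect_bulk}}) is fitted with 1 to \code{K_max + 1}
#' independent least-squares lines over contiguous blocks of at least
#' \code{min_pts} points. The number of breakpoints is chosen by BIC over
#' an exhaustive search of all breakpoint placements
#' (\code{n log(RSS/n) + p log(n)} with \code{p = 2(k+1) + k} parameters).
#' Ties are broken toward fewer segments, then toward the segmentation
#' whose outer segment extrapolates to the bulk concentration closest to
#' the outermost sub-bulk point. Adjacent segments whose slopes agree
#' within a factor \code{merge_ratio} are merged and refitted.
#'
#' @param profile a \code{\link{cbl_profile}}.
#' @param bulk result of \code{\link{detect_bulk}}.
#' @param K_max maximum number of breakpoints searched (default 2).
#' @param min_pts minimum points per segment (default 3).
#' @param merge_ratio slope-ratio threshold for merging adjacent segments
#'   (default 1.5).
#' @return List of segment lists, innermost first; each has
#'   \code{z_lo, z_hi, slope_m, intercept_c0, r2, n_points}.
#' @export
fit_segments <- function(profile, bulk, K_max = 2, min_pts = 3,
                         merge_ratio = 1.5) {
  z <- profile$z; v <- profile$value
  ns <- bulk$plateau_start_index - 1
  if (ns < min_pts)
    stop("CBL unresolved: fewer than ", min_pts, " sub-bulk points")
  zs <- z[1:ns]; vs <- v[1:ns]
  # RSS floor keeps BIC finite on noiseless data; the parameter penalty
  # then prefers fewer segments among exact fits
  floor_rss <- ns * (1e-10 * max(diff(range(v)), 1e-12))^2
  best <- NULL
  for (k in 0:K_max) {
    for (breaks in .breakpoint_sets(ns, k, min_pts)) {
      segs <- .fit_partition(zs, vs, breaks, ns)
      rss <- max(sum(vapply(segs, `[[`, 0, "rss")), floor_rss)
      p <- 2 * (k + 1) + k
      bic <- ns * log(rss / ns) + p * log(ns)
      cand <- list(bic = bic, segs = segs, k = k)
      if (is.null(best) || .seg_better(cand, best, bulk, zs)) best <- cand
    }
  }
  segs <- .merge_segments(best$segs, zs, vs, merge_ratio)
  lapply(segs, function(s) s[c("z_lo", "z_hi", "slope_m", "intercept_c0",
                               "r2", "n_points")])
}

# TRUE if candidate segmentation a beats incumbent b
.seg_better <- function(a, b, bulk, zs) {
  tol <- 1e-9 * max(1, abs(b$bic))
  if (a$bic < b$bic - tol) return(TRUE)
  if (a$bic > b$bic + tol) return(FALSE)
  if (a$k != b$k) return(a$k < b$k)            # fewer segments wins
  # outer segment reaching c_bulk closest to the outermost sub-bulk point;
  # distances equal to within numerical noise keep the incumbent, so the
  # earliest breakpoint placement wins among exact ties
  d <- function(x) {
    s <- x$segs[[length(x$segs)]]
    if (s$slope_m == 0) return(Inf)
    abs((bulk$c_bulk - s$intercept_c0) / s$slope_m - max(zs))
  }
  d(a) < d(b) - 1e-6 * max(zs)
}

.merge_segments <- function(segs, zs, vs, tau) {
  # map each segment back to its index block for refitting on merge
  blocks <- lapply(segs, function(s) which(zs >= s$z_lo & zs <= s$z_hi))
  repeat {
    if (length(segs) < 2) break
    merged <- FALSE
    for (j in seq_len(length(segs) - 1)) {
      s1 <- segs[[j]]$slope_m; s2 <- segs[[j + 1]]$slope_m
      tiny <- 1e-12 * max(abs(c(s1, s2, 1)))
      ok <- (abs(s1) < tiny && abs(s2) < tiny) ||
        (s1 * s2 > 0 && s1 / s2 >= 1 / tau && s1 / s2 <= tau)
      if (ok) {
        ii <- sort(union(blocks[[j]], blocks[[j + 1]]))
        segs[[j]] <- .seg_ols(zs, vs, ii)
        blocks[[j]] <- ii
        segs[[j + 1]] <- NULL; blocks[[j + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  segs
}

#' Classify a profile as simple, complex or undetectable
#'
#' A profile is \code{undetectable} when the surface value is within
#' \code{k_sigma} noise SDs of the bulk value; \code{simple} when a single
#' linear gradient spans the sub-bulk region; \code{complex} when two or
#' more gradient segments are retained (the multi-gradient shapes created
#' by ciliary vortices), with monotonic approach to bulk over the outer
#' half of the sub-bulk region checked on the fitted values.
#'
#' @param segments result of \code{\link{fit_segments}}.
#' @param bulk result of \code{\link{detect_bulk}}.
#' @param profile the \code{\link{cbl_profile}}.
#' @param k_sigma detection threshold in noise SDs (default 3).
#' @param noise_floor absolute floor on the noise SD (default as in
#'   \code{\link{detect_bulk}}).
#' @return One of \code{"simple"}, \code{"complex"}, \code{"undetectable"},
#'   with attribute \code{monotonic_outer} for multi-segment profiles.
#' @export
classify_profile <- function(segments, bulk, profile, k_sigma = 3,
                             noise_floor = NULL) {
  if (is.null(noise_floor))
    noise_floor <- .default_noise_floor(profile$value)
  sig <- max(bulk$sigma_noise, noise_floor)
  c_surface <- profile$value[1]
  if (abs(c_surface - bulk$c_bulk) <= k_sigma * sig)
    return("undetectable")
  if (length(segments) == 1) return("simple")
  mono <- .monotone_outer(segments, bulk, profile)
  structure("complex", monotonic_outer = mono)
}

# fitted values over the outer half of the sub-bulk region move toward
# bulk without sign reversal
.monotone_outer <- function(segments, bulk, profile) {
  z_hi <- max(vapply(segments, `[[`, 0, "z_hi"))
  zz <- profile$z[profile$z >= z_hi / 2 & profile$z <= z_hi]
  if (length(zz) < 2) return(TRUE)
  f <- .piecewise_eval(segments, bulk, zz)
  dir <- sign(bulk$c_bulk - profile$value[1])
  all(dir * diff(f) >= -1e-9 * max(1, abs(bulk$c_bulk)))
}

.piecewise_eval <- function(segments, bulk, z) {
  lo <- vapply(segments, `[[`, 0, "z_lo")
  hi <- vapply(segments, `[[`, 0, "z_hi")
  vapply(z, function(zi) {
    if (zi > max(hi)) return(bulk$c_bulk)
    j <- which(zi >= lo & zi <= hi)
    if (!length(j)) j <- which.min(pmin(abs(zi - lo), abs(zi - hi)))
    s <- segments[[j[1]]]
    s$intercept_c0 + s$slope_m * zi
  }, 0)
}

#' Boundary layer thickness by linear extrapolation
#'
#' The thickness delta is the distance from the surface to where the
#' chosen linear gradient, extrapolated, reaches the bulk concentration:
#' \code{delta = (c_bulk - intercept_c0) / slope_m}. For complex profiles
#' the segment passed must be the upper (bulk-adjacent) gradient.
#'
#' @param segment one segment from \code{\link{fit_segments}}.
#' @param bulk result of \code{\link{detect_bulk}}.
#' @return Thickness in micrometres (> 0).
#' @export
cbl_thickness <- function(segment, bulk) {
  if (segment$slope_m == 0)
    stop("inconsistent gradient: zero slope")
  delta <- (bulk$c_bulk - segment$intercept_c0) / segment$slope_m
  if (!is.finite(delta) || delta <= 0)
    stop("inconsistent gradient: extrapolation does not reach bulk above ",
         "the surface (delta = ", format(delta), ")")
  delta
}

#' Diffusive O2 flux through the boundary layer (Fick's first law)
#'
#' \code{J = -D * dC/dz}, converted so that with D in cm^2 s^-1 and the
#' gradient in micromolar per micrometre the flux is in
#' \eqn{\mu}mol cm^-2 h^-1 (factor 3.6e4). Efflux (surface
#' super-saturation, negative gradient toward bulk) is positive.
#'
#' @param segment the chosen gradient segment of an O2 profile (the upper
#'   gradient for complex profiles).
#' @param constants \code{\link{cbl_constants}}.
#' @param analyte analyte of the parent profile; anything other than
#'   \code{"O2"} is an error.
#' @return Signed flux, \eqn{\mu}mol cm^-2 h^-1.
#' @export
o2_flux <- function(segment, constants = cbl_constants(), analyte = "O2") {
  if (!identical(analyte, "O2"))
    stop("o2_flux is defined for O2 profiles only (got ", analyte, ")")
  -constants$D_O2 * segment$slope_m * 3.6e4
}
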