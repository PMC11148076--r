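#' Fit a concentration boundary layer model to a microsensor profile
#'
#' The central fitting function of the package. Orchestrates the full
#' trait-extraction pipeline on one profile: bulk-plateau detection
#' (\code{\link{detect_bulk}}), for pH profiles conversion of every point
#' to total-scale pH and then to hydrogen-ion concentration, exhaustive
#' BIC piecewise-linear segmentation (\code{\link{fit_segments}}), profile
#' classification (\code{\link{classify_profile}}), thickness by
#' extrapolation of the (upper, for complex profiles) gradient to the bulk
#' concentration (\code{\link{cbl_thickness}}), and, for O2 profiles,
#' diffusive flux via Fick's first law (\code{\link{o2_flux}}).
#'
#' For pH profiles the gradient fit and the thickness are computed on the
#' hydrogen-ion concentration (10^-pH), while the surface change is
#' reported both as \code{delta_ph} (total-scale pH units) and as
#' \code{delta_h} (mol L^-1). NBS-scale pH profiles (metadata
#' \code{ph_scale = "NBS"}) are converted to the total scale first, using
#' the salinity and temperature in \code{constants}.
#'
#' @param profile a \code{\link{cbl_profile}}.
#' @param constants a \code{\link{cbl_constants}} object.
#' @param k_sigma plateau/detectability threshold in noise SDs.
#' @param K_max,min_pts,merge_ratio segmentation settings, see
#'   \code{\link{fit_segments}}.
#' @param noise_floor floor on the noise SD, see \code{\link{detect_bulk}}.
#' @return Object of class \code{"cbl_fit"} with elements
#'   \describe{
#'     \item{profile}{the input profile (as measured).}
#'     \item{z, y}{working coordinates actually fitted (y is O2
#'       concentration, or [H+] for pH profiles).}
#'     \item{bulk}{the \code{cbl_bulk} plateau estimate (working units).}
#'     \item{segments}{fitted segments, innermost first (working units).}
#'     \item{chosen_segment}{the segment traits are derived from (the
#'       outermost retained segment).}
#'     \item{profile_class}{"simple", "complex" or "undetectable".}
#'     \item{traits}{named list: \code{thickness_um}, \code{c_surface},
#'       \code{c_bulk}, \code{surface_delta}, \code{flux} (O2 only, else
#'       NA), and for pH additionally \code{ph_surface}, \code{ph_bulk},
#'       \code{delta_ph}, \code{delta_h}.}
#'     \item{constants, settings}{inputs, for reproducibility.}
#'   }
#' @examples
#' p <- synth_profile(synth_spec(c_bulk = 240, delta_true = 104,
#'                               surface_offset = 73.8, noise_sigma = 0))
#' fit <- cbl_fit(p)
#' fit
#' coef(fit)
#' @export
cbl_fit <- function(profile, constants = cbl_constants(), k_sigma = 3,
                    K_max = 2, min_pts = 3, merge_ratio = 1.5,
                    noise_floor = NULL) {
  stopifnot(inherits(profile, "cbl_profile"))
  settings <- list(k_sigma = k_sigma, K_max = K_max, min_pts = min_pts,
                   merge_ratio = merge_ratio, noise_floor = noise_floor)
  z <- profile$z
  is_ph <- profile$analyte == "pH"
  if (is_ph) {
    ph <- profile$value
    scale <- profile$meta$ph_scale
    if (!is.null(scale) && scale == "NBS")
      ph <- ph_nbs_to_total(ph, S = constants$S, T = constants$T)
    y <- h_concentration(ph)          # fit on [H+]
  } else {
    y <- profile$value
  }
  work <- list(z = z, value = y)
  bulk <- detect_bulk(work, k_sigma = k_sigma, noise_floor = noise_floor)

  out <- list(profile = profile, z = z, y = y, bulk = bulk,
              constants = constants, settings = settings,
              analyte = profile$analyte)
  class(out) <- "cbl_fit"

  segments <- tryCatch(
    fit_segments(work, bulk, K_max = K_max, min_pts = min_pts,
                 merge_ratio = merge_ratio),
    error = function(e) e)
  if (inherits(segments, "error")) {
    out$segments <- list()
    out$profile_class <- "undetectable"
  } else {
    out$segments <- segments
    out$profile_class <- as.character(
      classify_profile(segments, bulk, work, k_sigma = k_sigma,
                       noise_floor = noise_floor))
  }

  c_surface <- y[1]
  traits <- list(thickness_um = NA_real_, c_surface = c_surface,
                 c_bulk = bulk$c_bulk,
                 surface_delta = c_surface - bulk$c_bulk,
                 flux = NA_real_)
  if (out$profile_class != "undetectable") {
    chosen <- out$segments[[length(out$segments)]]  # upper, bulk-adjacent
    out$chosen_segment <- chosen
    delta <- tryCatch(cbl_thickness(chosen, bulk), error = function(e) e)
    if (inherits(delta, "error")) {
      out$profile_class <- "undetectable"
      out$chosen_segment <- NULL
    } else {
      traits$thickness_um <- delta
      if (!is_ph)
        traits$flux <- o2_flux(chosen, constants, analyte = profile$analyte)
    }
  }
  if (is_ph) {
    ph_surface <- -log10(c_surface)
    ph_bulk <- -log10(bulk$c_bulk)
    traits$ph_surface <- ph_surface
    traits$ph_bulk <- ph_bulk
    traits$delta_ph <- ph_surface - ph_bulk
    traits$delta_h <- traits$surface_delta
  }
  out$traits <- traits
  out
}

#' Extract boundary layer traits from one or more profiles
#'
#' Convenience wrapper around \code{\link{cbl_fit}} that returns traits as
#' a data frame, one row per profile, with the condition metadata columns
#' alongside the derived traits.
#'
#' @param profiles a \code{\link{cbl_profile}} or a list of them.
#' @param constants a \code{\link{cbl_constants}} object.
#' @param ... further arguments passed to \code{\link{cbl_fit}}.
#' @return Data frame with metadata columns plus \code{analyte},
#'   \code{profile_class}, \code{thickness_um}, \code{c_surface},
#'   \code{c_bulk}, \code{surface_delta}, \code{flux}, \code{delta_ph},
#'   \code{delta_h}.
#' @export
extract_traits <- function(profiles, constants = cbl_constants(), ...) {
  if (inherits(profiles, "cbl_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    fit <- cbl_fit(p, constants = constants, ...)
    tr <- fit$traits
    meta_cols <- c("fragment_id", "species", "colony", "tank", "treatment",
                   "flow_cm_s", "light", "date")
    md <- lapply(meta_cols, function(nm)
      if (is.null(p$meta[[nm]])) NA else p$meta[[nm]])
    names(md) <- meta_cols
    data.frame(md, analyte = p$analyte, profile_class = fit$profile_class,
               thickness_um = tr$thickness_um, c_surface = tr$c_surface,
               c_bulk = tr$c_bulk, surface_delta = tr$surface_delta,
               flux = tr$flux,
               delta_ph = if (is.null(tr$delta_ph)) NA_real_ else tr$delta_ph,
               delta_h = if (is.null(tr$delta_h)) NA_real_ else tr$delta_h,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
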