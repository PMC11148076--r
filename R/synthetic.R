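#' Specification of a synthetic microsensor profile
#'
#' Ground-truth parameters for the profile generator. Simple profiles are
#' one linear ramp from the surface value to the bulk value at
#' \code{delta_true}, followed by a bulk plateau. Complex profiles are
#' two-slope monotonic ramps: the lower (surface-adjacent) gradient is
#' \code{lower_slope_ratio} times the upper gradient, the junction sits
#' at \code{upper_fraction * delta_true}, and \code{delta_true} is the
#' point where the \emph{upper} gradient extrapolates to the bulk value
#' (the multi-gradient shapes that ciliary vortices create in real
#' profiles). Flat profiles are constant at the bulk value.
#'
#' For pH profiles the ramp is constructed in hydrogen-ion concentration
#' space (values are then reported as pH), since gradient fitting for pH
#' operates on [H+]; \code{c_bulk} is the bulk pH and
#' \code{surface_offset} the surface-minus-bulk [H+] offset in mol L^-1.
#'
#' @param analyte \code{"O2"} or \code{"pH"}.
#' @param c_bulk bulk value (micromolar for O2; pH units for pH).
#' @param delta_true true boundary layer thickness, micrometres.
#' @param surface_offset surface minus bulk (analyte units for O2,
#'   mol L^-1 [H+] for pH); positive = light-like super-saturation.
#' @param profile_class \code{"simple"}, \code{"complex"} or \code{"flat"}.
#' @param upper_fraction junction position as a fraction of
#'   \code{delta_true} (complex only).
#' @param lower_slope_ratio lower-to-upper slope ratio, > 0 (complex
#'   only; > 1 makes the inner gradient steeper).
#' @param noise_sigma Gaussian sensor noise SD, analyte units.
#' @param seed integer seed recorded in the profile metadata.
#' @param schedule \code{"protocol"}, \code{"fine_small_cbl"} or
#'   \code{"uniform"} step schedule (see \code{\link{step_schedule}}).
#' @return Object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(analyte = "O2", c_bulk = 240, delta_true = 150,
                       surface_offset = 70, profile_class = "simple",
                       upper_fraction = 0.5, lower_slope_ratio = 3,
                       noise_sigma = 0, seed = 1,
                       schedule = "protocol") {
  stopifnot(analyte %in% c("O2", "pH"),
            profile_class %in% c("simple", "complex", "flat"),
            noise_sigma >= 0)
  if (profile_class != "flat" && delta_true <= 0)
    stop("delta_true must be > 0")
  if (profile_class == "complex") {
    if (!(upper_fraction > 0 && upper_fraction < 1))
      stop("upper_fraction must be in (0, 1)")
    if (lower_slope_ratio <= 0)
      stop("lower_slope_ratio must be > 0 (monotonic construction)")
  }
  structure(list(analyte = analyte, c_bulk = c_bulk,
                 delta_true = delta_true, surface_offset = surface_offset,
                 profile_class = profile_class,
                 upper_fraction = upper_fraction,
                 lower_slope_ratio = lower_slope_ratio,
                 noise_sigma = noise_sigma, seed = seed,
                 schedule = schedule),
            class = "synth_spec")
}

#' Sensor model for synthetic profiles
#'
#' @param spatial_resolution sensor spatial resolution, micrometres
#'   (25 for the O2 electrode, 75 for the pH electrode).
#' @param smoothing boxcar kernel width, micrometres; defaults to the
#'   spatial resolution. The true profile is averaged over this window
#'   before noise is added, emulating the signal integration of steps
#'   smaller than the sensor's resolution.
#' @return Object of class \code{"sensor_model"}.
#' @export
sensor_model <- function(spatial_resolution = 25,
                         smoothing = spatial_resolution) {
  stopifnot(spatial_resolution > 0)
  structure(list(spatial_resolution = spatial_resolution,
                 smoothing = smoothing),
            class = "sensor_model")
}

# even steps from `from` to `to`, spacing <= max_step, hitting both ends
.even_steps <- function(from, to, max_step) {
  if (to <= from) return(from)
  n <- max(1, ceiling((to - from) / max_step))
  seq(from, to, length.out = n + 1)
}

#' Measurement positions of the stepping protocol
#'
#' Returns the strictly increasing sensor positions of the profiling
#' protocol: fine steps (<= 15 um) from the surface to 100 um, coarser
#' steps (<= 35 um, or <= 50 um for boundary layers thicker than 300 um)
#' through the mid-gradient until about 75 percent of the estimated
#' thickness, fine steps again until the bulk level, then three 50-um
#' steps followed by coarse steps (<= 150 um) up to 500 um above the
#' surface (1000 um when the estimated thickness exceeds 300 um). The
#' \code{"fine_small_cbl"} variant starts with a first step at 5 um for
#' very thin boundary layers; \code{"uniform"} is a constant 20-um grid.
#'
#' @param kind \code{"protocol"}, \code{"fine_small_cbl"} or
#'   \code{"uniform"}.
#' @param estimated_delta estimated boundary layer thickness, um (> 0).
#' @return Numeric vector of positions, micrometres above the surface.
#' @export
step_schedule <- function(kind = c("protocol", "fine_small_cbl",
                                   "uniform"),
                          estimated_delta) {
  kind <- match.arg(kind)
  stopifnot(estimated_delta > 0)
  d <- estimated_delta
  extent <- if (d > 300) 1000 else 500
  if (kind == "uniform") return(seq(0, extent, by = 20))
  fine <- 15
  mid <- if (d > 300) 50 else 35
  z <- if (kind == "fine_small_cbl") c(0, 5) else 0
  z <- c(z, .even_steps(max(z), min(100, d), fine))
  if (d > 100) {
    mid_end <- max(0.75 * d, 100)
    z <- c(z, .even_steps(min(100, max(z)), mid_end, mid))
    z <- c(z, .even_steps(mid_end, d, fine))
  }
  top <- max(z)
  z <- c(z, top + c(50, 100, 150))
  z <- c(z, .even_steps(top + 150, extent, 150))
  sort(unique(round(z, 6)))
}

# true (noiseless, unsmoothed) profile value at height z
.synth_truth_fun <- function(spec) {
  cls <- spec$profile_class
  if (spec$analyte == "pH") {
    c_bulk <- h_concentration(spec$c_bulk)   # work in [H+]
  } else c_bulk <- spec$c_bulk
  off <- spec$surface_offset
  d <- spec$delta_true
  if (cls == "flat") return(function(z) rep(c_bulk, length(z)))
  if (cls == "simple") {
    return(function(z) ifelse(z >= d, c_bulk, c_bulk + off * (1 - z / d)))
  }
  # complex: upper slope from the closure condition
  f <- spec$upper_fraction; r <- spec$lower_slope_ratio
  zj <- f * d
  s_up <- off / (d * (f - 1 - r * f))
  s_lo <- r * s_up
  cj <- c_bulk + s_up * (zj - d)
  function(z) {
    ifelse(z >= d, c_bulk,
           ifelse(z >= zj, c_bulk + s_up * (z - d), cj + s_lo * (z - zj)))
  }
}

#' Generate a synthetic microsensor profile
#'
#' Evaluates the ground-truth profile of a \code{\link{synth_spec}} at
#' the positions of its step schedule, optionally applies sensor boxcar
#' smoothing, adds seeded Gaussian noise, and returns a validated
#' \code{\link{cbl_profile}} carrying the ground truth as attribute
#' \code{"truth"}.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param sensor optional \code{\link{sensor_model}}; when supplied, the
#'   true profile is boxcar-averaged over the smoothing window (clipped
#'   at the surface) before noise.
#' @param meta extra condition metadata merged into the profile.
#' @return A \code{\link{cbl_profile}} with attribute \code{"truth"}: a
#'   list with \code{delta_true}, \code{c_bulk}, \code{c_surface},
#'   \code{surface_offset}, \code{slope_upper}, \code{slope_lower},
#'   \code{flux_true} (O2), \code{profile_class}, \code{seed}.
#' @examples
#' p <- synth_profile(synth_spec(c_bulk = 240, delta_true = 104,
#'                               surface_offset = 73.8, noise_sigma = 0))
#' attr(p, "truth")$delta_true
#' @export
synth_profile <- function(spec, sensor = NULL, meta = list()) {
  stopifnot(inherits(spec, "synth_spec"))
  d_sched <- if (spec$profile_class == "flat") 150 else spec$delta_true
  z <- step_schedule(spec$schedule, d_sched)
  truth_fun <- .synth_truth_fun(spec)
  v <- truth_fun(z)
  if (!is.null(sensor) && sensor$smoothing > 0) {
    w <- sensor$smoothing / 2
    v <- vapply(z, function(zi) {
      grid <- seq(max(0, zi - w), zi + w, length.out = 51)
      mean(truth_fun(grid))
    }, 0)
  }
  if (spec$noise_sigma > 0) {
    noise <- .with_seed(spec$seed,
                        stats::rnorm(length(z), 0, spec$noise_sigma))
    if (spec$analyte == "pH") {
      # noise is in pH units for pH sensors
      v <- h_concentration(-log10(v) + noise)
    } else {
      v <- pmax(v + noise, 0)
    }
  }
  value <- if (spec$analyte == "pH") -log10(v) else v
  meta <- utils::modifyList(list(seed = spec$seed,
                                 ph_scale = if (spec$analyte == "pH")
                                   "total" else NULL), meta)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  p <- cbl_profile(z = z, value = value, analyte = spec$analyte,
                   meta = meta)
  # ground truth in working units ([H+] for pH)
  cls <- spec$profile_class
  if (cls == "complex") {
    f <- spec$upper_fraction; r <- spec$lower_slope_ratio
    s_up <- spec$surface_offset / (spec$delta_true * (f - 1 - r * f))
    s_lo <- r * s_up
  } else if (cls == "simple") {
    s_up <- -spec$surface_offset / spec$delta_true
    s_lo <- s_up
  } else s_up <- s_lo <- 0
  c_bulk_w <- if (spec$analyte == "pH")
    h_concentration(spec$c_bulk) else spec$c_bulk
  attr(p, "truth") <- list(
    delta_true = if (cls == "flat") NA_real_ else spec$delta_true,
    c_bulk = c_bulk_w,
    c_surface = c_bulk_w + if (cls == "flat") 0 else spec$surface_offset,
    surface_offset = if (cls == "flat") 0 else spec$surface_offset,
    slope_upper = s_up, slope_lower = s_lo,
    flux_true = if (spec$analyte == "O2") -cbl_constants()$D_O2 * s_up *
      3.6e4 else NA_real_,
    profile_class = cls, seed = spec$seed)
  p
}

#' Generate a diel seawater pH/temperature log
#'
#' Produces one day of seawater log entries following an asymmetric
#' sinusoid: pH rises from the daily mean to \code{daily_max}, falls
#' through the mean to \code{daily_min}, and returns, with the fraction
#' of the day spent on each half chosen so that the time average equals
#' \code{mean_ph}. With an even number of samples the extreme times fall
#' exactly on the sampling grid, so the generated minimum and maximum
#' equal the specified ones (at zero jitter). Optional seeded Gaussian
#' jitter is added to pH and temperature.
#'
#' @param mean_ph daily mean pH (total scale).
#' @param daily_min,daily_max daily extremes (min < mean < max).
#' @param TA total alkalinity, micromol kg^-1.
#' @param S salinity.
#' @param T_mean mean temperature, degrees C.
#' @param n_per_day samples per day (default 96 = 15-min logging).
#' @param seed integer seed for the jitter.
#' @param jitter_sd SD of the pH jitter (pH units; temperature jitter is
#'   10x this in degrees C). Default 0 (deterministic).
#' @return Data frame with columns \code{time_h}, \code{pH},
#'   \code{temp_C}, \code{TA}, \code{S}; attribute \code{"truth"} records
#'   the generator inputs.
#' @export
synth_diel_seawater <- function(mean_ph, daily_min, daily_max, TA, S,
                                T_mean, n_per_day = 96, seed = 1,
                                jitter_sd = 0) {
  if (!(daily_min < mean_ph && mean_ph < daily_max))
    stop("need daily_min < mean_ph < daily_max")
  stopifnot(n_per_day >= 1)
  n <- n_per_day
  amp_up <- daily_max - mean_ph
  amp_dn <- mean_ph - daily_min
  p <- amp_dn / (amp_up + amp_dn)   # fraction of day above the mean
  if (n >= 4 && n %% 2 == 0) {
    m <- 2 * max(1, min(round(n * p / 2), n / 2 - 1))
    p <- m / n                      # snap so extremes land on the grid
  }
  t <- (seq_len(n) - 1) / n
  ph <- ifelse(t < p,
               mean_ph + amp_up * sin(pi * t / p),
               mean_ph - amp_dn * sin(pi * (t - p) / (1 - p)))
  temp <- rep(T_mean, n)
  if (jitter_sd > 0) {
    jit <- .with_seed(seed, stats::rnorm(2 * n))
    ph <- ph + jitter_sd * jit[1:n]
    temp <- temp + 10 * jitter_sd * jit[(n + 1):(2 * n)]
  }
  out <- data.frame(time_h = t * 24, pH = ph, temp_C = temp,
                    TA = TA, S = S)
  attr(out, "truth") <- list(mean_ph = mean_ph, daily_min = daily_min,
                             daily_max = daily_max, TA = TA, S = S,
                             T_mean = T_mean, seed = seed,
                             jitter_sd = jitter_sd)
  out
}
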