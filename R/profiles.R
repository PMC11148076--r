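#' Construct and validate a microsensor profile
#'
#' A profile is a single depth series measured by a microsensor moving
#' upward from the coral surface: positions \code{z} in micrometres above
#' the surface (0 at the surface, increasing toward the free-flowing bulk
#' seawater) and the measured value at each position (\eqn{\mu}M for O2,
#' pH units for pH). Rows are sorted by \code{z}; duplicate positions are
#' averaged with a warning (repeated readings at one step are legitimate).
#'
#' @param z numeric vector of positions, micrometres above the surface.
#' @param value numeric vector of measurements, same length as \code{z}.
#' @param analyte \code{"O2"} or \code{"pH"}.
#' @param meta named list of condition metadata. Recognised fields:
#'   \code{species}, \code{fragment_id}, \code{colony}, \code{tank},
#'   \code{treatment} ("control"/"OA"), \code{flow_cm_s} (> 0),
#'   \code{light} ("light"/"dark"), \code{date}, and for pH profiles
#'   \code{ph_scale} ("NBS"/"total").
#' @return An object of class \code{"cbl_profile"}: list with elements
#'   \code{analyte}, \code{z}, \code{value}, \code{meta}.
#' @examples
#' p <- cbl_profile(z = seq(0, 500, by = 50),
#'                  value = c(300, 290, 280, 270, 260, 250, 240, 240, 240,
#'                            240, 240),
#'                  analyte = "O2",
#'                  meta = list(fragment_id = "F1", species = "A. cytherea",
#'                              treatment = "control", flow_cm_s = 2,
#'                              light = "light"))
#' @export
cbl_profile <- function(z, value, analyte = c("O2", "pH"), meta = list()) {
  analyte <- match.arg(analyte)
  if (length(z) != length(value))
    stop("z and value must have the same length")
  bad <- which(!is.finite(z) | !is.finite(value))
  if (length(bad))
    stop("non-finite z or value at row(s): ", paste(bad, collapse = ", "))
  o <- order(z)
  z <- z[o]; value <- value[o]
  if (anyDuplicated(z)) {
    warning("duplicate z positions averaged (",
            sum(duplicated(z)), " duplicate rows)")
    value <- as.numeric(tapply(value, z, mean))
    z <- sort(unique(z))
  }
  if (length(z) < 6)
    stop("profile needs >= 6 points (surface, gradient, 3-point plateau); got ",
         length(z))
  if (z[1] < 0) stop("z must be >= 0 (height above the coral surface)")
  if (any(diff(z) <= 0))
    stop("z not strictly increasing after sorting and de-duplication [",
         .profile_key(meta, analyte), "]")
  if (analyte == "O2" && any(value < 0))
    stop("O2 concentrations must be >= 0")
  .validate_meta(meta)
  structure(list(analyte = analyte, z = as.numeric(z),
                 value = as.numeric(value), meta = meta),
            class = "cbl_profile")
}

.validate_meta <- function(meta) {
  if (!is.null(meta$treatment) &&
      !meta$treatment %in% c("control", "OA"))
    stop("treatment must be 'control' or 'OA'")
  if (!is.null(meta$light) && !meta$light %in% c("light", "dark"))
    stop("light must be 'light' or 'dark'")
  if (!is.null(meta$flow_cm_s) && !(is.numeric(meta$flow_cm_s) &&
                                    meta$flow_cm_s > 0))
    stop("flow_cm_s must be a positive number")
  if (!is.null(meta$ph_scale) && !meta$ph_scale %in% c("NBS", "total"))
    stop("ph_scale must be 'NBS' or 'total'")
  invisible(TRUE)
}

.profile_key <- function(meta, analyte) {
  paste(c(meta$fragment_id, analyte, meta$flow_cm_s, meta$light,
          meta$treatment, meta$date), collapse = "/")
}

#' @export
print.cbl_profile <- function(x, ...) {
  cat("Microsensor profile:", x$analyte, "\n")
  cat("  ", length(x$z), "points, z ", min(x$z), "-", max(x$z), "um\n")
  m <- x$meta
  if (length(m))
    cat("  ", .profile_key(m, x$analyte), "\n")
  invisible(x)
}

# canonical long-format columns; ph_scale is optional
.profile_cols <- c("fragment_id", "species", "colony", "tank", "treatment",
                   "flow_cm_s", "light", "date", "analyte", "z_um", "value")
.group_cols <- c("fragment_id", "analyte", "flow_cm_s", "light",
                 "treatment", "date")

#' Read microsensor profiles from a long-format CSV/TSV file
#'
#' The canonical dialect is a long table with columns
#' \code{fragment_id, species, colony, tank, treatment, flow_cm_s, light,
#' date, analyte, z_um, value} (and optionally \code{ph_scale}). Rows are
#' grouped into profiles by (fragment_id, analyte, flow_cm_s, light,
#' treatment, date). Metadata that is constant across the file may instead
#' be supplied in a YAML sidecar (\code{<path>.yaml}) or via
#' \code{default_meta}; columns present in the file win.
#'
#' @param path path to a CSV (or TSV, see \code{sep}) file.
#' @param sep field separator; \code{","} by default.
#' @param default_meta named list of metadata applied to columns missing
#'   from the file.
#' @param sidecar path to a YAML file of default metadata; defaults to
#'   \code{<path>.yaml} if that file exists.
#' @return List of \code{\link{cbl_profile}} objects.
#' @seealso \code{\link{write_profiles}}
#' @export
read_profiles <- function(path, sep = ",", default_meta = list(),
                          sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sidecar)) {
    cand <- paste0(path, ".yaml")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    default_meta <- utils::modifyList(side, default_meta)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  # fill missing metadata columns from defaults
  for (nm in setdiff(.profile_cols, c("z_um", "value", "analyte"))) {
    if (!nm %in% names(df) && !is.null(default_meta[[nm]]))
      df[[nm]] <- default_meta[[nm]]
  }
  if (!"ph_scale" %in% names(df) && !is.null(default_meta$ph_scale))
    df$ph_scale <- default_meta$ph_scale
  need <- c("z_um", "value", "analyte")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$z_um) | !is.finite(df$value))
  if (length(bad))
    stop("non-finite z_um/value at data row(s): ",
         paste(bad, collapse = ", "))
  gcols <- intersect(.group_cols, names(df))
  key <- if (length(gcols))
    interaction(df[gcols], drop = TRUE, lex.order = TRUE) else factor(1)
  idx <- split(seq_len(nrow(df)), key)
  message("read_profiles: ", nrow(df), " rows -> ", length(idx),
          " profile(s) from ", path)
  lapply(idx, function(i) {
    sub <- df[i, , drop = FALSE]
    meta_cols <- setdiff(names(sub), c("z_um", "value", "analyte"))
    meta <- lapply(sub[1, meta_cols, drop = FALSE], identity)
    meta <- meta[!vapply(meta, function(v) is.na(v) || identical(v, ""),
                         logical(1))]
    cbl_profile(z = sub$z_um, value = sub$value,
                analyte = sub$analyte[1], meta = meta)
  })
}

#' Write microsensor profiles to the canonical long-format CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' \code{read_profiles(write_profiles(p))} reproduces \code{p} bit-exactly.
#'
#' @param profiles list of \code{\link{cbl_profile}} objects (may be empty:
#'   a header-only file is written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.list(profiles))
  cols <- c(.profile_cols, "ph_scale")
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "cbl_profile"))
    n <- length(p$z)
    out <- data.frame(matrix(NA_character_, n, length(cols)),
                      stringsAsFactors = FALSE)
    names(out) <- cols
    for (nm in setdiff(cols, c("analyte", "z_um", "value")))
      if (!is.null(p$meta[[nm]])) out[[nm]] <- as.character(p$meta[[nm]])
    out$analyte <- p$analyte
    out$z_um <- sprintf("%.17g", p$z)
    out$value <- sprintf("%.17g", p$value)
    out
  })
  df <- if (length(rows)) do.call(rbind, rows) else {
    df0 <- data.frame(matrix(character(0), 0, length(cols)),
                      stringsAsFactors = FALSE)
    names(df0) <- cols
    df0
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  message("write_profiles: ", nrow(df), " rows (", length(profiles),
          " profile(s)) -> ", path)
  invisible(path)
}
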