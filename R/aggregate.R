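#' Reference table of condition-level boundary layer trait means
#'
#' Condition-cell means (with SD and replication) of the five CBL traits
#' measured on three Indo-Pacific coral species (\emph{Acropora
#' cytherea}, \emph{Pocillopora verrucosa}, \emph{Porites cylindrica})
#' under two flow velocities (low = 2, moderate = 6 cm s^-1), two pH
#' treatments (control, OA) and light/darkness, shipped as a plain-text
#' fixture. Traits: \code{thickness_o2} (um), \code{thickness_h} (um),
#' \code{delta_o2} (uM), \code{delta_ph} (total-scale pH units),
#' \code{flux_o2} (umol cm^-2 h^-1).
#'
#' @param wide if \code{TRUE} (default) one row per condition cell with a
#'   column per trait mean; if \code{FALSE} the long (trait, mean, sd, n)
#'   form as stored.
#' @return Data frame of cell means.
#' @export
cbl_reference_traits <- function(wide = TRUE) {
  path <- system.file("extdata", "trait_cell_means.csv",
                      package = "coralCBL", mustWork = TRUE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!wide) return(long)
  keys <- c("species", "flow", "treatment", "light")
  w <- stats::reshape(long[c(keys, "trait", "mean")],
                      idvar = keys, timevar = "trait",
                      direction = "wide")
  names(w) <- sub("^mean\\.", "", names(w))
  rownames(w) <- NULL
  w
}

.check_factors <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("factor column(s) not in table: ", paste(miss, collapse = ", "))
}

#' Pooled means of a boundary layer trait
#'
#' Unweighted mean (with SD and n) of a trait over the rows of a trait
#' table, grouped by \code{group_by}. Pooling is the plain row mean:
#' with equal replication per condition cell, pooling raw profile rows
#' and pooling cell means give the same result. Groups implied by the
#' factor levels but empty in the data are flagged with a warning.
#'
#' @param table data frame (raw trait rows or cell means).
#' @param trait name of the trait column.
#' @param pool_over factor columns deliberately pooled over (checked to
#'   exist; pooling happens over any column not in \code{group_by}).
#' @param group_by factor columns to retain as groups; empty for a grand
#'   mean.
#' @return Data frame with the \code{group_by} columns plus \code{mean},
#'   \code{sd}, \code{n}.
#' @export
pooled_mean <- function(table, trait, pool_over = character(),
                        group_by = character()) {
  .check_factors(table, c(pool_over, group_by))
  if (!trait %in% names(table)) stop("no trait column: ", trait)
  x <- table[[trait]]
  keep <- !is.na(x)
  x <- x[keep]
  if (!length(group_by)) {
    return(data.frame(mean = mean(x), sd = stats::sd(x), n = length(x)))
  }
  g <- table[keep, group_by, drop = FALSE]
  key <- interaction(g, drop = FALSE, lex.order = TRUE)
  counts <- table(key)
  if (any(counts == 0))
    warning("empty group(s): ",
            paste(names(counts)[counts == 0], collapse = ", "))
  key <- droplevels(key)
  sp <- split(x, key)
  out <- do.call(rbind, lapply(names(sp), function(k) {
    row <- g[which(key == k)[1], , drop = FALSE]
    cbind(row, data.frame(mean = mean(sp[[k]]), sd = stats::sd(sp[[k]]),
                          n = length(sp[[k]])))
  }))
  rownames(out) <- NULL
  out
}

#' Low-to-moderate flow ratio of a trait
#'
#' Per-species ratio of the trait mean under low flow to the mean under
#' moderate flow, pooled over treatments and light conditions. Absolute
#' values are taken before pooling, so that traits with opposite signs in
#' light and darkness (flux, surface deltas) do not cancel.
#'
#' @param table trait table (rows or cell means) with columns
#'   \code{species}, \code{flow}, and the trait.
#' @param trait trait column name.
#' @param flow_col name of the flow factor column (levels \code{"low"}
#'   and \code{"moderate"}).
#' @return Data frame with \code{species}, \code{low}, \code{moderate}
#'   (pooled |mean|s) and \code{ratio}.
#' @export
flow_ratio <- function(table, trait, flow_col = "flow") {
  .check_factors(table, c("species", flow_col))
  tab <- table
  tab[[trait]] <- abs(tab[[trait]])
  pm <- pooled_mean(tab, trait, group_by = c("species", flow_col))
  out <- do.call(rbind, lapply(split(pm, pm$species), function(d) {
    lo <- d$mean[d[[flow_col]] == "low"]
    mo <- d$mean[d[[flow_col]] == "moderate"]
    if (!length(lo) || !length(mo))
      stop("missing flow level for species ", d$species[1])
    data.frame(species = d$species[1], low = lo, moderate = mo,
               ratio = lo / mo)
  }))
  rownames(out) <- NULL
  out
}

#' Percent increase of a trait from moderate to low flow
#'
#' \code{100 * (flow_ratio - 1)} per species.
#'
#' @inheritParams flow_ratio
#' @return Data frame with \code{species} and \code{percent}.
#' @export
percent_increase <- function(table, trait, flow_col = "flow") {
  fr <- flow_ratio(table, trait, flow_col)
  data.frame(species = fr$species, percent = 100 * (fr$ratio - 1))
}

#' Light-dark variation of a surface trait
#'
#' For each light/dark pairing (paired within every non-light factor
#' column present among species, flow, treatment and fragment_id), the
#' variation is \code{|delta_light| + |delta_dark|} - equal to
#' \code{|delta_light - delta_dark|} when the signs are opposite, as they
#' are for surface O2 and pH changes. Pair values are then averaged per
#' \code{group_by} group.
#'
#' @param table trait table with a \code{light} column (levels
#'   \code{"light"}, \code{"dark"}).
#' @param trait trait column (\code{delta_o2}, \code{delta_ph}, ...).
#' @param group_by factor columns retained in the output (default
#'   \code{"species"}).
#' @return Data frame with \code{group_by} columns plus \code{mean},
#'   \code{sd}, \code{n} (n = number of pairings).
#' @export
light_dark_variation <- function(table, trait, group_by = "species") {
  .check_factors(table, c("light", group_by))
  pair_cols <- intersect(c("species", "flow", "treatment", "fragment_id"),
                         names(table))
  li <- table[table$light == "light", , drop = FALSE]
  da <- table[table$light == "dark", , drop = FALSE]
  key <- function(d) interaction(d[pair_cols], drop = TRUE,
                                 lex.order = TRUE)
  kl <- key(li); kd <- key(da)
  if (!setequal(levels(kl), levels(kd)) || anyDuplicated(kl) ||
      anyDuplicated(kd))
    stop("unpaired light/dark cells")
  da <- da[match(kl, kd), , drop = FALSE]
  pairs <- li[pair_cols]
  pairs$variation <- abs(li[[trait]]) + abs(da[[trait]])
  pairs <- pairs[!is.na(pairs$variation), , drop = FALSE]
  pooled_mean(pairs, "variation", group_by = group_by)
}

#' Pearson correlation between O2 flux and surface pH change
#'
#' @param table trait table with columns for flux and surface delta pH
#'   (paired rows, e.g. by fragment).
#' @param flux_col,dph_col column names (defaults \code{"flux_o2"},
#'   \code{"delta_ph"}).
#' @return List with \code{r}, \code{p_value}, \code{n}.
#' @export
flux_ph_correlation <- function(table, flux_col = "flux_o2",
                                dph_col = "delta_ph") {
  .check_factors(table, c(flux_col, dph_col))
  ok <- stats::complete.cases(table[[flux_col]], table[[dph_col]])
  x <- table[[flux_col]][ok]; y <- table[[dph_col]][ok]
  if (length(x) < 3)
    stop("insufficient data: need >= 3 paired observations")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
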