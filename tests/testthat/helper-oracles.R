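# Independent oracles used by the tests. These deliberately re-derive the
# quantities by a different route (lm() fits, recursive partition
# enumeration, direct bisection) so that agreement with the package is a
# genuine cross-check, not a tautology.

# --- exhaustive piecewise-linear segmentation oracle -----------------------
# Enumerates every partition of points 1..n into 1..(kmax+1) contiguous
# blocks of >= min_pts points, fits each block with lm(), scores with
# BIC = n log(RSS/n) + (3k + 2) log(n), and returns the best partition
# (ties: fewer blocks).
oracle_segment <- function(z, v, kmax = 2, min_pts = 3) {
  n <- length(z)
  partitions <- list()
  recurse <- function(start, blocks) {
    if (length(blocks) > kmax + 1) return()
    if (start > n) {
      partitions[[length(partitions) + 1]] <<- blocks
      return()
    }
    for (end in seq(start + min_pts - 1, n)) {
      if (n - end != 0 && n - end < min_pts) next
      recurse(end + 1, c(blocks, list(start:end)))
    }
  }
  recurse(1, list())
  floor_rss <- n * (1e-10 * max(diff(range(v)), 1e-12))^2
  score <- function(blocks) {
    rss <- sum(vapply(blocks, function(i) {
      sum(stats::resid(stats::lm(v[i] ~ z[i]))^2)
    }, 0))
    k <- length(blocks) - 1
    n * log(max(rss, floor_rss) / n) + (3 * k + 2) * log(n)
  }
  scores <- vapply(partitions, score, 0)
  ord <- order(scores, vapply(partitions, length, 0L))
  blocks <- partitions[[ord[1]]]
  lapply(blocks, function(i) {
    fit <- stats::lm(v[i] ~ z[i])
    list(idx = i, slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]))
  })
}

# --- carbonate-system bisection oracle -------------------------------------
# Total alkalinity written via ionisation fractions (different algebra
# from the package's .ta_from_dic_h), all on the total scale.
oracle_ta <- function(dic, h, k) {
  a1 <- 1 / (h / k$K1 + 1 + k$K2 / h)
  a2 <- 1 / (h^2 / (k$K1 * k$K2) + h / k$K2 + 1)
  borate <- k$BT / (1 + h / k$KB)
  water <- k$KW / h
  hfree <- h / (1 + k$ST / k$KS)
  dic * (a1 + 2 * a2) + borate + water - hfree
}

# DIC (umol/kg) from (TA umol/kg, total-scale pH) by plain bisection
oracle_dic_from_ph_ta <- function(TA, ph_t, k, tol = 1e-10) {
  h <- 10^(-ph_t)
  f <- function(dic) oracle_ta(dic, h, k) - TA * 1e-6
  lo <- 1e-9; hi <- 1e-1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2 * 1e6
}

# total-scale pH from (DIC, TA) (umol/kg) by plain bisection
oracle_ph_from_dic_ta <- function(DIC, TA, k, tol = 1e-10) {
  f <- function(ph) oracle_ta(DIC * 1e-6, 10^(-ph), k) - TA * 1e-6
  lo <- 3; hi <- 12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# --- shared fixtures --------------------------------------------------------
# a small valid O2 profile with full canonical metadata
make_test_profile <- function(fragment_id = "F1", species = "A. cytherea",
                              flow = 2, light = "light",
                              treatment = "control", seed = 1,
                              noise = 0, delta = 120, offset = 60) {
  synth_profile(
    synth_spec(c_bulk = 240, delta_true = delta, surface_offset = offset,
               noise_sigma = noise, seed = seed),
    meta = list(fragment_id = fragment_id, species = species,
                colony = "C1", tank = "T1", treatment = treatment,
                flow_cm_s = flow, light = light, date = "2020-01-15"))
}

# synthetic raw trait table with equal replication per condition cell
make_synthetic_trait_table <- function(n_per_cell = 3, seed = 42) {
  set.seed(seed)
  grid <- expand.grid(species = c("sp1", "sp2"),
                      flow = c("low", "moderate"),
                      treatment = c("control", "OA"),
                      light = c("light", "dark"),
                      rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$flow == "low", 150, 100)
  sgn <- ifelse(grid$light == "light", 1, -1)
  grid$thickness_o2 <- base + rnorm(nrow(grid), 0, 5)
  grid$delta_o2 <- sgn * (60 + rnorm(nrow(grid), 0, 4))
  grid$flux_o2 <- sgn * (0.5 + rnorm(nrow(grid), 0, 0.05))
  grid
}
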