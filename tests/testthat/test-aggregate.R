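ref <- cbl_reference_traits()

test_that("pooled means reproduce the per-flow thickness means", {
  ac <- ref[ref$species == "Acropora cytherea", ]
  pm <- pooled_mean(ac, "thickness_o2", pool_over = c("light", "treatment"),
                    group_by = "flow")
  expect_equal(pm$mean[pm$flow == "low"], mean(c(104, 101, 202, 203)))
  expect_equal(pm$mean[pm$flow == "moderate"], mean(c(79, 81, 108, 111)))
  expect_equal(pm$mean[pm$flow == "low"], 152.5)
  expect_equal(pm$mean[pm$flow == "moderate"], 94.75)
  # pooling over nothing with full grouping is the identity on cells
  cells <- pooled_mean(ac, "thickness_o2",
                       group_by = c("flow", "treatment", "light"))
  expect_equal(sort(cells$mean), sort(ac$thickness_o2))
  expect_true(all(cells$n == 1))
})

test_that("grand mean of the light surface O2 elevations is reproduced", {
  li <- ref[ref$light == "light", ]
  gm <- pooled_mean(li, "delta_o2")
  expect_equal(gm$n, 12)
  expect_equal(gm$mean, 78.2, tolerance = 0.005 * 78.2 / 78.2)
  expect_equal(gm$mean, mean(li$delta_o2))
})

test_that("low-to-moderate flow ratios for thickness match the report", {
  fr <- flow_ratio(ref, "thickness_o2")
  r <- setNames(fr$ratio, fr$species)
  expect_equal(unname(r["Acropora cytherea"]), 1.61, tolerance = 0.005)
  expect_equal(unname(r["Pocillopora verrucosa"]), 1.55, tolerance = 0.005)
  expect_equal(unname(r["Porites cylindrica"]), 2.58, tolerance = 0.005)
  # identical low/moderate tables give ratio 1
  sym <- ref; sym$thickness_o2 <- 100
  expect_true(all(flow_ratio(sym, "thickness_o2")$ratio == 1))
})

test_that("flow ratios of surface delta O2 match the report", {
  fr <- flow_ratio(ref, "delta_o2")
  r <- setNames(fr$ratio, fr$species)
  expect_equal(unname(r["Acropora cytherea"]), 1.14, tolerance = 0.005)
  expect_equal(unname(r["Pocillopora verrucosa"]), 1.48, tolerance = 0.005)
  expect_equal(unname(r["Porites cylindrica"]), 1.22, tolerance = 0.005)
})

test_that("flow ratios of O2 flux match the report at printed precision", {
  # flux cell means are printed with two decimals; the reconstructed
  # ratios can differ from the printed ones by up to the propagated
  # rounding quantum (~0.01), so agreement is asserted at that precision
  fr <- flow_ratio(ref, "flux_o2")
  r <- setNames(fr$ratio, fr$species)
  expect_lte(abs(r[["Acropora cytherea"]] - 0.75), 0.01 + 1e-9)
  expect_lte(abs(r[["Pocillopora verrucosa"]] - 1.06), 0.01 + 1e-9)
  expect_lte(abs(r[["Porites cylindrica"]] - 0.56), 0.01 + 1e-9)
})

test_that("percent increase follows the flow ratio", {
  pc <- percent_increase(ref, "thickness_o2")
  p <- setNames(pc$percent, pc$species)
  expect_equal(unname(p["Acropora cytherea"]), 61, tolerance = 0.01)
  expect_equal(unname(p["Porites cylindrica"]), 158.3, tolerance = 0.01)
  # ratio 1 -> 0 %
  sym <- ref; sym$thickness_o2 <- 100
  expect_true(all(percent_increase(sym, "thickness_o2")$percent == 0))
})

test_that("light-dark variation of surface traits matches the report", {
  ld <- light_dark_variation(ref, "delta_o2")
  v <- setNames(ld$mean, ld$species)
  expect_equal(unname(v["Acropora cytherea"]), 112.26, tolerance = 0.005)
  expect_equal(unname(v["Pocillopora verrucosa"]), 155.31,
               tolerance = 0.005)
  expect_equal(unname(v["Porites cylindrica"]), 135.51, tolerance = 0.005)
  # A. cytherea surface pH, control, pooled over flow
  acc <- ref[ref$species == "Acropora cytherea" &
               ref$treatment == "control", ]
  ldp <- light_dark_variation(acc, "delta_ph")
  expect_equal(ldp$mean, 0.06, tolerance = 1e-9)
  # zero deltas give zero variation
  z <- ref; z$delta_o2 <- 0
  expect_true(all(light_dark_variation(z, "delta_o2")$mean == 0))
})

test_that("unpaired light/dark cells are an error", {
  broken <- ref[!(ref$light == "dark" & ref$species == "Porites cylindrica" &
                    ref$flow == "low" & ref$treatment == "OA"), ]
  expect_error(light_dark_variation(broken, "delta_o2"), "unpaired")
})

test_that("equal-n pooling over raw rows equals pooling over cell means", {
  raw <- make_synthetic_trait_table(n_per_cell = 4)
  cells <- pooled_mean(raw, "thickness_o2",
                       group_by = c("species", "flow", "treatment",
                                    "light"))
  names(cells)[names(cells) == "mean"] <- "thickness_o2"
  fr_raw <- flow_ratio(raw, "thickness_o2")
  fr_cells <- flow_ratio(cells, "thickness_o2")
  expect_equal(fr_raw$ratio, fr_cells$ratio, tolerance = 1e-12)
  pm_raw <- pooled_mean(raw, "thickness_o2", group_by = "species")
  pm_cells <- pooled_mean(cells, "thickness_o2", group_by = "species")
  expect_equal(pm_raw$mean, pm_cells$mean, tolerance = 1e-12)
})

test_that("swapping flow labels inverts the ratio exactly", {
  fr <- flow_ratio(ref, "thickness_o2")
  swapped <- ref
  swapped$flow <- ifelse(ref$flow == "low", "moderate", "low")
  fr2 <- flow_ratio(swapped, "thickness_o2")
  expect_equal(fr$ratio * fr2$ratio, rep(1, nrow(fr)))
})

test_that("missing flow levels and empty groups are reported", {
  lowonly <- ref[ref$flow == "low", ]
  expect_error(flow_ratio(lowonly, "thickness_o2"), "missing flow")
  gapped <- ref[!(ref$species == "Porites cylindrica" &
                    ref$treatment == "OA"), ]
  gapped$species <- factor(gapped$species)
  gapped$treatment <- factor(gapped$treatment)
  expect_warning(pooled_mean(gapped[gapped$species ==
                                      "Porites cylindrica", ],
                             "thickness_o2",
                             group_by = c("species", "treatment")),
                 "empty")
})

test_that("flux-pH correlation handles exact, null and tiny inputs", {
  lin <- data.frame(flux_o2 = 1:10, delta_ph = 0.01 * (1:10))
  expect_equal(flux_ph_correlation(lin)$r, 1)
  anti <- data.frame(flux_o2 = 1:10, delta_ph = -0.01 * (1:10))
  expect_equal(flux_ph_correlation(anti)$r, -1)
  expect_error(flux_ph_correlation(lin[1:2, ]), "insufficient")
  # Monte-Carlo under the null: |r| below the 5% critical value in at
  # least 90% of seeded replicates (n = 18 pairs)
  crit <- qt(0.975, 16) / sqrt(16 + qt(0.975, 16)^2)
  set.seed(2024)
  ok <- vapply(1:100, function(i) {
    d <- data.frame(flux_o2 = rnorm(18), delta_ph = rnorm(18))
    abs(flux_ph_correlation(d)$r) < crit
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
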