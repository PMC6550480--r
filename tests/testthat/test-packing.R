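test_that("pore-cap sweep endpoints and the commensurate linear law hold", {
  g <- thick_geom()
  curve <- sweep_capping(g, fractions = c(0, 0.3, 0.64, 1))
  expect_s3_class(curve, "packing_curve")
  expect_equal(curve$f[1], 0)
  expect_equal(curve$f[nrow(curve)], 1)

  de0 <- curve$de_ratio[1]
  dom0 <- voxelize(g)
  expect_equal(de0, discrete_pore_fraction(dom0), tolerance = 1e-10)
  expect_equal(curve$de_ratio[nrow(curve)], 0, tolerance = 1e-9)

  ## capped columns carry no flux: De(f) = (1 - f) De(0) within 2% relative
  mid <- curve$de_ratio > 0
  expect_equal(curve$de_ratio[mid],
               (1 - curve$f_realized[mid]) * de0,
               tolerance = 0.02)
  expect_true(all(diff(curve$de_ratio) <= 1e-9))
})

test_that("sweeps demand the 0 and 1 endpoints", {
  g <- tiny_geom()
  expect_error(sweep_capping(g, fractions = c(0, 0.5)), "endpoints",
               class = "aqpore_invalid")
  expect_error(sweep_capping(g, fractions = c(0.2, 1)), "endpoints",
               class = "aqpore_invalid")
  expect_error(sweep_capping(g, fractions = c(0, 2)), class = "aqpore_invalid")
})

test_that("packing inversion is exact at curve points and brackets correctly", {
  g <- thick_geom()
  curve <- sweep_capping(g, fractions = c(0, 0.25, 0.5, 0.64, 0.8, 1))
  ## round-trip: inverting De(f*) recovers f* for every swept point
  grid <- diff(range(curve$f_realized)) / (nrow(curve) - 1)
  for (i in seq_len(nrow(curve))) {
    est <- estimate_packing(curve, curve$de_ratio[i])
    expect_lte(abs(est$estimate$value - curve$f_realized[i]), grid + 1e-9)
    expect_gte(est$estimate$value, est$bracket["lo"] - 1e-12)
    expect_lte(est$estimate$value, est$bracket["hi"] + 1e-12)
  }
  ## measured = De(0) maps to zero packing
  expect_equal(estimate_packing(curve, curve$de_ratio[1])$estimate$value, 0)
  ## a 64% flux reduction inverts to ~64% capping on the linear curve
  est64 <- estimate_packing(curve, 0.36, measured = "flux_ratio")
  expect_equal(est64$estimate$value, 0.64, tolerance = 0.03)
})

test_that("out-of-range measurements are rejected with direction-specific errors", {
  g <- tiny_geom()
  curve <- sweep_capping(g, fractions = c(0, 0.5, 1))
  expect_error(estimate_packing(curve, max(curve$de_ratio) * 1.1),
               "above", class = "aqpore_above_range")
  expect_error(estimate_packing(curve, -0.01), class = "aqpore_invalid")
})

test_that("monomer and aggregate models cannot be discriminated from De alone", {
  g <- thick_geom()
  fr <- c(0, 0.2, 0.4, 0.64, 0.8, 1)
  agg <- sweep_capping(g, fractions = fr)
  mono <- monomer_curve(g, fractions = fr)
  expect_true(all(diff(mono$de_ratio) <= 1e-9))
  expect_equal(mono$de_ratio[1], agg$de_ratio[1], tolerance = 1e-10)
  expect_equal(mono$de_ratio[length(fr)], 0)

  ## compare at matched realized fractions (aggregate quantizes to pore counts)
  mono_at <- approx(mono$f_realized, mono$de_ratio,
                    xout = agg$f_realized)$y
  keep <- agg$de_ratio > 0.02
  rel <- abs(mono_at[keep] / agg$de_ratio[keep] - 1)
  expect_lt(max(rel), 0.10)
})

test_that("monomer patches larger than the pore opening are rejected", {
  g <- tiny_geom()
  expect_error(monomer_curve(g, fractions = c(0, 1), patch_side = 1.5),
               "larger than the pore", class = "aqpore_invalid")
})

test_that("flux reductions convert to tagged capping fractions", {
  pf <- flux_reduction_to_capping(64)
  expect_equal(pf$value, 0.64)
  expect_equal(pf$definition, "fraction_of_pores_capped")
  expect_equal(flux_reduction_to_capping(0)$value, 0)
  expect_equal(flux_reduction_to_capping(100)$value, 1)
  expect_error(flux_reduction_to_capping(101), class = "aqpore_invalid")
  expect_error(flux_reduction_to_capping(-2), class = "aqpore_invalid")
})

test_that("aggregate-disk sweeps occlude the requested pore-area fraction", {
  g <- thick_geom()
  curve <- sweep_capping(g, fractions = c(0, 0.36, 0.64, 1),
                         mode = "aggregate_disk")
  expect_true(all(diff(curve$de_ratio) <= 1e-9))
  expect_equal(curve$de_ratio[4], 0, tolerance = 1e-9)
  ## occluded-area proportionality; a 3x3 lattice gives the disk a coarse
  ## sample of the pore field, so the law holds only to ~10% here
  de0 <- curve$de_ratio[1]
  mid <- curve$de_ratio > 0
  expect_equal(curve$de_ratio[mid], (1 - curve$f_realized[mid]) * de0,
               tolerance = 0.10)
  ## the raw film-surface fraction is reported alongside and differs
  expect_true(all(curve$surface_fraction >= 0 & curve$surface_fraction <= 1))
})
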