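test_that("areal pore fraction matches closed-form values", {
  g28 <- film_geometry(pore_diameter = 1, coverage = 0.28)
  expect_equal(areal_pore_fraction(g28), 0.28, tolerance = 1e-12)
  expect_equal(g28$lattice_spacing, sqrt(pi * 0.25 / 0.28), tolerance = 1e-12)

  g <- film_geometry(pore_diameter = 1, lattice_spacing = 2)
  expect_equal(areal_pore_fraction(g), pi / 16, tolerance = 1e-12)

  ## vanishing pore diameter drives the fraction to zero
  gsmall <- film_geometry(pore_diameter = 1e-6, lattice_spacing = 2)
  expect_lt(areal_pore_fraction(gsmall), 1e-12)
})

test_that("geometry invariants are enforced with informative errors", {
  expect_error(film_geometry(pore_diameter = 3, lattice_spacing = 2),
               "pore_diameter", class = "aqpore_invalid")
  expect_error(film_geometry(film_thickness = -1), "strictly positive",
               class = "aqpore_invalid")
  expect_error(film_geometry(coverage = 1.2), class = "aqpore_invalid")
  expect_error(occlusion_spec("pore_cap", cap_fraction = 1.5),
               class = "aqpore_invalid")
  expect_error(packing_fraction(-0.1), class = "aqpore_invalid")
})

test_that("voxelization is deterministic and labels regions correctly", {
  g <- tiny_geom()
  occ <- occlusion_spec("pore_cap", cap_fraction = 0.5, placement_seed = 3L)
  d1 <- voxelize(g, occ)
  d2 <- voxelize(g, occ)
  expect_identical(d1$region, d2$region)
  expect_identical(d1$diffusivity, d2$diffusivity)

  ## x boundary faces are reservoirs
  expect_true(all(d1$region[1, , ] == 1L))
  expect_true(all(d1$region[d1$nx, , ] == 5L))
  ## diffusivity is zero exactly on solid and occluded voxels
  expect_true(all((d1$diffusivity == 0) == (d1$region %in% c(3L, 4L))))
})

test_that("occlusion endpoints behave: none at f = 0, sealed feed face at f = 1", {
  g <- tiny_geom()
  d0 <- voxelize(g, occlusion_spec("pore_cap", cap_fraction = 0))
  expect_false(any(d0$region == 4L))

  d1 <- voxelize(g, occlusion_spec("pore_cap", cap_fraction = 1))
  face <- d1$region[d1$film_x[1], , ]
  expect_false(any(face == 2L)) # every pore opening is occluded
  expect_true(any(face == 4L))
  expect_equal(discrete_pore_fraction(d1), 0)
})

test_that("voxelize rejects too-coarse resolution and oversized occlusions", {
  g <- tiny_geom()
  expect_error(voxelize(g, voxel_size = g$pore_diameter / 2),
               "too coarse", class = "aqpore_resolution")
  big <- occlusion_spec("aggregate_disk", disk_radius = 100)
  expect_error(voxelize(g, big), "exceeds", class = "aqpore_invalid")
  wide <- occlusion_spec("monomer_patch", patch_side = 10)
  expect_error(voxelize(g, wide), "exceeds", class = "aqpore_invalid")
})

test_that("realize_packing caps round(f * n) pores, seed-dependently", {
  g <- film_geometry(n_pores_x = 5L)
  o1 <- realize_packing(g, 0.64, seed = 1L)
  o2 <- realize_packing(g, 0.64, seed = 2L)
  expect_length(attr(o1, "capped_pores"), 16L)
  expect_length(attr(o2, "capped_pores"), 16L)
  expect_false(setequal(attr(o1, "capped_pores"), attr(o2, "capped_pores")))
  expect_equal(attr(o1, "realized"), 16 / 25)

  expect_identical(attr(realize_packing(g, 0), "capped_pores"), integer(0))
  expect_length(attr(realize_packing(g, 1), "capped_pores"), 25L)
})

test_that("realized packing matches the target within one quantization unit", {
  g <- film_geometry(n_pores_x = 4L, film_thickness = 10, reservoir_depth = 3)
  n <- g$n_pores_x * g$n_pores_y
  withr::with_seed(42, {
    for (i in 1:100) {
      target <- runif(1)
      seed <- sample.int(1e6, 1)
      occ <- realize_packing(g, target, seed = seed)
      expect_lte(abs(attr(occ, "realized") - target), 1 / (2 * n) + 1e-12)
      expect_length(attr(occ, "capped_pores"),
                    as.integer(round(attr(occ, "realized") * n)))
    }
  })
})

test_that("disk occlusions realize pore-area and surface-area targets", {
  g <- tiny_geom(n = 3L)
  rast_quantum <- 0.05 # generous bound on one voxel's share of pore area
  withr::with_seed(7, {
    for (target in runif(12)) {
      occ <- realize_packing(
        g, packing_fraction(target, "fraction_of_pore_area_occluded"))
      dom <- voxelize(g, occ)
      occluded <- 1 - discrete_pore_fraction(dom) /
        discrete_pore_fraction(voxelize(g))
      expect_equal(occluded, attr(occ, "realized"), tolerance = 1e-10)
      expect_lte(abs(attr(occ, "realized") - target), rast_quantum)
    }
  })
  ## continuous surface-fraction targets resolve exactly
  occ <- realize_packing(g, packing_fraction(0.37,
                                             "fraction_of_film_surface_occluded"))
  expect_equal(attr(occ, "realized"), 0.37, tolerance = 1e-8)
})

test_that("discrete pore fraction converges to the areal fraction under refinement", {
  g <- film_geometry(film_thickness = 1, reservoir_depth = 0.5, n_pores_x = 1L)
  target <- areal_pore_fraction(g)
  gap <- vapply(c(14, 28, 56), function(nsub) {
    dom <- voxelize(g, voxel_size = g$lattice_spacing / nsub)
    abs(discrete_pore_fraction(dom) - target)
  }, numeric(1))
  expect_lte(gap[2], gap[1] / 2 + 1e-12)
  expect_lte(gap[3], gap[2] / 2 + 1e-12)
  ## at the production resolution the gap is within two percentage points
  dom7 <- voxelize(g)
  expect_lt(abs(discrete_pore_fraction(dom7) - target), 0.02)
})
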