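test_that("uniform open domain reproduces the 1D linear profile", {
  dom <- layered_domain(data.frame(thickness = 2, diffusivity = 1),
                        voxel_size = 0.25, lateral = 3, reservoir_depth = 1)
  field <- solve_steady_state(dom)
  Lx <- dom$nx * dom$h
  xc <- (seq_len(dom$nx) - 0.5) * dom$h
  expected <- 1 - xc / Lx
  profile <- apply(field$c, 1, mean)
  expect_equal(profile, expected, tolerance = 1e-10)
  ## flux equals Fick's first law
  expect_equal(plane_flux(field, plane_x = dom$h * floor(dom$nx / 2)),
               1 / Lx, tolerance = 1e-10)
  expect_equal(effective_diffusivity(field, "domain")$ratio, 1,
               tolerance = 1e-10)
})

test_that("equal boundary concentrations give a constant field with zero flux", {
  dom <- voxelize(tiny_geom())
  field <- solve_steady_state(dom, boundary_conditions(0.5, 0.5))
  expect_equal(max(abs(field$c - 0.5), na.rm = TRUE), 0, tolerance = 1e-10)
  expect_lt(abs(plane_flux(field)), 1e-12)
  expect_error(effective_diffusivity(field), "difference",
               class = "aqpore_invalid")
})

test_that("two-layer domain matches the series-resistance closed form exactly", {
  layers <- data.frame(thickness = c(1, 1), diffusivity = c(1, 0.5))
  dom <- layered_domain(layers, voxel_size = 0.125, lateral = 2)
  field <- solve_steady_state(dom)
  oracle <- series_resistance_oracle(
    data.frame(thickness = c(1, 1), open_fraction = c(1, 0.5)))
  expect_equal(effective_diffusivity(field, "film")$ratio, oracle,
               tolerance = 1e-10)

  ## interface concentration from the resistance-in-series hand calculation:
  ## with unit drop across film faces, the drop splits as R1 : R2 = 1 : 2
  cl <- aqpore:::face_concentration(field, dom$film_x[1] - 1L)
  cr <- aqpore:::face_concentration(field, dom$film_x[2])
  kmid <- dom$film_x[1] - 1L + as.integer(round(1 / dom$h))
  cmid <- aqpore:::face_concentration(field, kmid)
  expect_equal((cl - cmid) / (cl - cr), 1 / 3, tolerance = 1e-10)
})

test_that("solver ratio matches the series-resistance oracle on random stacks", {
  withr::with_seed(11, {
    for (i in 1:5) {
      nl <- sample(2:4, 1)
      ## thicknesses on the voxel grid so the discrete stack is the nominal one
      layers <- data.frame(thickness = sample(2:8, nl, replace = TRUE) * 0.25,
                           diffusivity = round(runif(nl, 0.2, 1), 2))
      dom <- layered_domain(layers, voxel_size = 0.25, lateral = 2)
      field <- solve_steady_state(dom)
      oracle <- series_resistance_oracle(
        data.frame(thickness = layers$thickness,
                   open_fraction = layers$diffusivity))
      expect_equal(effective_diffusivity(field, "film")$ratio, oracle,
                   tolerance = 1e-8)
    }
  })
  ## oracle arithmetic spot checks
  expect_equal(series_resistance_oracle(
    data.frame(thickness = 1, open_fraction = 0.28)), 0.28)
  expect_equal(series_resistance_oracle(
    data.frame(thickness = c(1, 1), open_fraction = c(1, 0.5))), 2 / 3)
  expect_equal(series_resistance_oracle(
    data.frame(thickness = c(1, 1), open_fraction = c(1, 0))), 0)
})

test_that("flux is conserved across every interior plane", {
  g <- tiny_geom()
  occ <- realize_packing(g, 0.5)
  dom <- voxelize(g, occ)
  field <- solve_steady_state(dom)
  jmid <- plane_flux(field)
  for (k in c(1L, dom$n_reservoir, dom$film_x[1] + 2L, dom$nx - 1L)) {
    expect_equal(plane_flux(field, plane_x = k * dom$h), jmid,
                 tolerance = 1e-8)
  }
  expect_error(plane_flux(field, plane_x = -1), "inside",
               class = "aqpore_invalid")
  expect_error(plane_flux(field, plane_x = dom$nx * dom$h), "inside",
               class = "aqpore_invalid")
})

test_that("flux is linear in the imposed concentration difference", {
  dom <- voxelize(tiny_geom())
  j1 <- plane_flux(solve_steady_state(dom, boundary_conditions(1, 0)))
  j3 <- plane_flux(solve_steady_state(dom, boundary_conditions(3.5, 0.5)))
  expect_equal(j3 / j1, 3, tolerance = 1e-12)
})

test_that("maximum principle holds on random occluded geometries", {
  withr::with_seed(23, {
    for (i in 1:6) {
      g <- film_geometry(film_thickness = runif(1, 4, 10),
                         reservoir_depth = runif(1, 2, 4),
                         n_pores_x = sample(1:3, 1))
      occ <- switch(sample(3, 1),
        realize_packing(g, runif(1), seed = sample.int(1e6, 1)),
        realize_packing(g, packing_fraction(runif(1),
                                            "fraction_of_pore_area_occluded")),
        occlusion_spec("monomer_patch", patch_side = runif(1, 0.25, 0.9)))
      field <- solve_steady_state(voxelize(g, occ))
      expect_gte(min(field$c, na.rm = TRUE), -1e-9)
      expect_lte(max(field$c, na.rm = TRUE), 1 + 1e-9)
      expect_lt(field$residual, 1e-10)
    }
  })
})

test_that("De is invariant under mirroring the transport axis", {
  g <- tiny_geom()
  occ <- realize_packing(g, 0.5)
  dom <- voxelize(g, occ)
  ## swapping the Dirichlet values is the mirror experiment
  de_fwd <- effective_diffusivity(
    solve_steady_state(dom, boundary_conditions(1, 0)), "film")$ratio
  de_rev <- abs(effective_diffusivity(
    solve_steady_state(dom, boundary_conditions(0, 1)), "film")$ratio)
  expect_equal(de_fwd, de_rev, tolerance = 1e-9)
})

test_that("film-region De/D_bulk of straight uncapped channels equals the discrete pore fraction", {
  for (g in list(tiny_geom(), tiny_geom(n = 3L, film = 6))) {
    res <- solve_de(g)
    expect_equal(res$de$ratio, discrete_pore_fraction(res$dom),
                 tolerance = 0.01)
    ## in practice the identity is exact for the discrete system
    expect_equal(res$de$ratio, discrete_pore_fraction(res$dom),
                 tolerance = 1e-12)
  }
})

test_that("De ratio drifts by less than 1% when the voxel size is halved", {
  g <- tiny_geom()
  occ <- realize_packing(g, 0.5)
  h <- g$lattice_spacing / 7
  de_h <- solve_de(g, occ, voxel_size = h)$de$ratio
  de_h2 <- solve_de(g, occ, voxel_size = h / 2)$de$ratio
  expect_lt(abs(de_h2 / de_h - 1), 0.01)
})
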