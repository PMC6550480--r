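## Small geometries shared across tests.  `tiny_geom` keeps solves in the
## few-thousand-unknown range; `thick_geom` uses the study's 50 nm selective
## layer, needed wherever the commensurate-capping (column-decomposition)
## law is asserted quantitatively, since pore-entrance spreading resistance
## scales like pore_diameter/film_thickness.
tiny_geom <- function(n = 2L, film = 10, res = 3) {
  film_geometry(film_thickness = film, reservoir_depth = res, n_pores_x = n)
}

thick_geom <- function(n = 3L) {
  film_geometry(film_thickness = 50, reservoir_depth = 5, n_pores_x = n)
}

solve_de <- function(geom, occ = NULL, voxel_size = NULL, sep = "film",
                     bc = boundary_conditions()) {
  dom <- voxelize(geom, occ, voxel_size)
  field <- solve_steady_state(dom, bc)
  list(dom = dom, field = field,
       de = effective_diffusivity(field, sep))
}
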