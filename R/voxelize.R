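## region codes shared by voxelize() and the exporters
REGION_LEVELS <- c("left_reservoir", "film_pore", "film_solid",
                   "occlusion", "right_reservoir")

#' Voxelize a membrane geometry into a diffusivity field
#'
#' Rasterizes the reservoir-film-reservoir geometry onto a regular cubic
#' voxel grid.  Voxel membership is decided by a voxel-centre test (a centre
#' exactly on a surface counts as open).  Reservoirs are fully open; film
#' voxels are open only inside the pore cylinders; occlusions overwrite pore
#' voxels with solid starting at the feed-side film face.  Open voxels carry
#' the bulk diffusivity (1 by nondimensionalization), solid voxels carry 0.
#'
#' The transport axis is x; the feed (left) reservoir is at low x.  The
#' lateral voxel size snaps to an integer divisor of the lattice spacing so
#' identical inputs always produce bit-identical domains.
#'
#' @param geom A [film_geometry()].
#' @param occ An [occlusion_spec()], or `NULL` for an unoccluded film.
#' @param voxel_size Target voxel edge in nm; default `lattice_spacing / 7`.
#'   Must not exceed `pore_diameter / 4`.
#' @param d_bulk Bulk diffusivity assigned to open voxels (default 1).
#' @return An object of class `voxel_domain`: a list with the 3D
#'   `diffusivity` array, the 3D integer `region` array (levels
#'   left_reservoir, film_pore, film_solid, occlusion, right_reservoir),
#'   the voxel size `h`, grid extents and the film slice range.
#' @export
voxelize <- function(geom, occ = NULL, voxel_size = NULL, d_bulk = 1) {
  if (!inherits(geom, "film_geometry")) {
    abort("`geom` must be a film_geometry object", class = "aqpore_invalid")
  }
  if (!is.null(occ) && !inherits(occ, "occlusion_spec")) {
    abort("`occ` must be an occlusion_spec or NULL", class = "aqpore_invalid")
  }
  rast <- rasterize_face(geom, voxel_size)
  h <- rast$h
  nf <- as.integer(max(1, round_half_up(geom$film_thickness / h)))
  nr <- as.integer(max(1, round_half_up(geom$reservoir_depth / h)))
  nx <- nf + 2L * nr
  ny <- rast$ny
  nz <- rast$nz
  film_x <- (nr + 1L):(nr + nf)

  region <- array(0L, c(nx, ny, nz))
  region[seq_len(nr), , ] <- 1L                      # left reservoir
  region[(nr + nf + 1L):nx, , ] <- 5L                # right reservoir
  film2d <- ifelse(rast$open, 2L, 3L)                # pore / solid
  for (k in film_x) region[k, , ] <- film2d

  if (!is.null(occ)) {
    occ2d <- occlusion_footprint(geom, occ, rast)
    if (any(occ2d)) {
      t_occ <- occ$occlusion_thickness %||%
        (if (occ$mode == "pore_cap") h else geom$film_thickness)
      n_occ <- min(nf, max(1L, round_half_up(t_occ / h)))
      occ_lin <- which(occ2d & rast$open)
      for (k in nr + seq_len(n_occ)) {
        slice <- region[k, , ]
        slice[occ_lin] <- 4L
        region[k, , ] <- slice
      }
    }
  }

  diffusivity <- array(0, c(nx, ny, nz))
  diffusivity[region == 1L | region == 2L | region == 5L] <- d_bulk

  structure(
    list(diffusivity = diffusivity,
         region = region,
         region_levels = REGION_LEVELS,
         h = h,
         nx = nx, ny = ny, nz = nz,
         n_reservoir = nr, n_film = nf,
         film_x = c(nr + 1L, nr + nf),
         d_bulk = d_bulk,
         geom = geom, occ = occ),
    class = "voxel_domain")
}

## 2D lateral footprint (ny x nz logical) of an occlusion on the film face
occlusion_footprint <- function(geom, occ, rast) {
  if (occ$mode == "pore_cap") {
    if (occ$cap_fraction <= 0) {
      return(matrix(FALSE, rast$ny, rast$nz))
    }
    ids <- attr(occ, "capped_pores") %||%
      capped_pore_ids(geom, occ$cap_fraction, occ$placement_seed)
    rast$open & matrix(rast$pore_id %in% ids, rast$ny, rast$nz)
  } else if (occ$mode == "aggregate_disk") {
    W <- geom$n_pores_x * geom$lattice_spacing
    H <- geom$n_pores_y * geom$lattice_spacing
    rmax <- sqrt((W / 2)^2 + (H / 2)^2)
    if (occ$disk_radius > rmax + rast$h) {
      abort(sprintf("occlusion exceeds supercell: disk_radius %g nm > half-diagonal %g nm",
                    occ$disk_radius, rmax), class = "aqpore_invalid")
    }
    d2 <- outer((rast$yc - W / 2)^2, (rast$zc - H / 2)^2, "+")
    rast$open & (d2 <= occ$disk_radius^2 + 1e-12)
  } else { # monomer_patch
    if (occ$patch_side > geom$lattice_spacing) {
      abort(sprintf("occlusion exceeds supercell: patch_side %g nm > lattice spacing %g nm",
                    occ$patch_side, geom$lattice_spacing),
            class = "aqpore_invalid")
    }
    s <- geom$lattice_spacing
    pcx <- (pmin(pmax(ceiling(rast$yc / s), 1L), geom$n_pores_x) - 0.5) * s
    pcy <- (pmin(pmax(ceiling(rast$zc / s), 1L), geom$n_pores_y) - 0.5) * s
    half <- occ$patch_side / 2 + 1e-12
    iny <- abs(rast$yc - pcx) <= half
    inz <- abs(rast$zc - pcy) <= half
    rast$open & outer(iny, inz, "&")
  }
}

#' @export
print.voxel_domain <- function(x, ...) {
  cat("<voxel_domain>\n")
  cat(sprintf("  grid %d x %d x %d, voxel %.4g nm (x = transport axis)\n",
              x$nx, x$ny, x$nz, x$h))
  counts <- table(factor(x$region, levels = 1:5, labels = x$region_levels))
  for (nm in names(counts)) cat(sprintf("  %-15s %d\n", nm, counts[[nm]]))
  invisible(x)
}

#' Discrete pore fraction of the film face
#'
#' The fraction of film-face voxels that are open, counted on the feed-side
#' film face.  This is the rasterization audit for the effective-diffusivity
#' normalization: for straight uncapped channels the solver's film-region
#' De/D_bulk equals this discrete fraction (not the continuous areal
#' fraction, which it approaches as the voxel size shrinks).
#'
#' @param dom A [voxelize()]d domain.
#' @return Fraction of open voxels on the feed-side film face, in \[0, 1\].
#' @export
discrete_pore_fraction <- function(dom) {
  if (!inherits(dom, "voxel_domain")) {
    abort("`dom` must be a voxel_domain", class = "aqpore_invalid")
  }
  face <- dom$region[dom$film_x[1], , ]
  mean(face == 2L)
}

#' Export a voxel domain or concentration field as legacy VTK structured points
#'
#' Writes an ASCII legacy-VTK STRUCTURED_POINTS file with the diffusivity and
#' region-label arrays (and, for a concentration field, the concentration) as
#' point scalars, for inspection in ParaView or similar tools.
#'
#' @param x A `voxel_domain` or `concentration_field`.
#' @param path Output file path.
#' @param title Dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, path, title = "aqpore field") {
  if (inherits(x, "concentration_field")) {
    dom <- x$dom
    fields <- list(concentration = ifelse(is.na(x$c), 0, x$c),
                   diffusivity = dom$diffusivity,
                   region = dom$region)
  } else if (inherits(x, "voxel_domain")) {
    dom <- x
    fields <- list(diffusivity = dom$diffusivity, region = dom$region)
  } else {
    abort("`x` must be a voxel_domain or concentration_field",
          class = "aqpore_invalid")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  n <- dom$nx * dom$ny * dom$nz
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dom$nx, dom$ny, dom$nz),
               sprintf("ORIGIN %g %g %g", dom$h / 2, dom$h / 2, dom$h / 2),
               sprintf("SPACING %g %g %g", dom$h, dom$h, dom$h),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(fields)) {
    arr <- fields[[nm]]
    type <- if (is.integer(arr)) "int" else "double"
    writeLines(c(sprintf("SCALARS %s %s 1", nm, type),
                 "LOOKUP_TABLE default"), con)
    ## VTK expects x fastest, matching R array linearization
    vals <- as.vector(arr)
    writeLines(paste(format_num(as.double(vals))), con)
  }
  invisible(path)
}
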