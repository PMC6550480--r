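#' Parametric reservoir-film-reservoir membrane geometry
#'
#' Describes a slab of nanoporous polymer film ("the membrane selective
#' layer") sandwiched between two open reservoirs, with straight cylindrical
#' pores on a square lattice running along the transport (x) axis.  The
#' defaults reproduce the study membrane: 1 nm diameter pores whose lattice
#' spacing is set so that the pores cover 28% of the film face, and a 50 nm
#' selective layer.
#'
#' Exactly one of `lattice_spacing` or `coverage` should be given; when
#' `coverage` is given the spacing is solved from
#' \eqn{\pi (d/2)^2 / s^2 = \mathrm{coverage}}.
#'
#' @param pore_diameter Pore diameter in nm.
#' @param lattice_spacing Center-to-center pore spacing in nm (square lattice).
#' @param coverage Target areal pore fraction of the film face, in (0, 1).
#'   Used to derive `lattice_spacing` when that is not given.
#' @param film_thickness Film (selective layer) thickness in nm.
#' @param reservoir_depth Depth of each reservoir in nm.  A few lattice
#'   spacings suffice: the reservoir only needs to contain the pore-entrance
#'   spreading region, and any extra depth adds a uniform slab whose
#'   resistance cancels from every reported ratio.
#' @param n_pores_x,n_pores_y Number of pores along each lateral edge of the
#'   simulated supercell.
#' @return An object of class `film_geometry`.
#' @examples
#' geom <- film_geometry()
#' areal_pore_fraction(geom)
#' @export
film_geometry <- function(pore_diameter = 1.0,
                          lattice_spacing = NULL,
                          coverage = NULL,
                          film_thickness = 50,
                          reservoir_depth = 5,
                          n_pores_x = 5L,
                          n_pores_y = n_pores_x) {
  stopifnot_scalar(pore_diameter, "pore_diameter", positive = TRUE)
  stopifnot_scalar(film_thickness, "film_thickness", positive = TRUE)
  stopifnot_scalar(reservoir_depth, "reservoir_depth", positive = TRUE)
  if (is.null(lattice_spacing)) {
    coverage <- coverage %||% 0.28
    stopifnot_scalar(coverage, "coverage", positive = TRUE)
    if (coverage >= 1) {
      abort("invariant violated: areal pore fraction must be strictly in (0, 1)",
            class = "aqpore_invalid")
    }
    lattice_spacing <- sqrt(pi * (pore_diameter / 2)^2 / coverage)
  }
  stopifnot_scalar(lattice_spacing, "lattice_spacing", positive = TRUE)
  n_pores_x <- as.integer(n_pores_x)
  n_pores_y <- as.integer(n_pores_y)
  if (n_pores_x < 1L || n_pores_y < 1L) {
    abort("invariant violated: n_pores_x and n_pores_y must be >= 1",
          class = "aqpore_invalid")
  }
  if (pore_diameter >= lattice_spacing) {
    abort(sprintf(paste0("invariant violated: pore_diameter (%g nm) must be ",
                         "smaller than lattice_spacing (%g nm)"),
                  pore_diameter, lattice_spacing), class = "aqpore_invalid")
  }
  frac <- pi * (pore_diameter / 2)^2 / lattice_spacing^2
  if (frac <= 0 || frac >= 1) {
    abort("invariant violated: areal pore fraction must be strictly in (0, 1)",
          class = "aqpore_invalid")
  }
  structure(
    list(pore_diameter = pore_diameter,
         lattice_spacing = lattice_spacing,
         film_thickness = film_thickness,
         reservoir_depth = reservoir_depth,
         n_pores_x = n_pores_x,
         n_pores_y = n_pores_y),
    class = "film_geometry")
}

#' @export
print.film_geometry <- function(x, ...) {
  cat("<film_geometry>\n")
  cat(sprintf("  pores: %d x %d, diameter %.4g nm, lattice spacing %.4g nm\n",
              x$n_pores_x, x$n_pores_y, x$pore_diameter, x$lattice_spacing))
  cat(sprintf("  film %.4g nm thick, reservoirs %.4g nm each side\n",
              x$film_thickness, x$reservoir_depth))
  cat(sprintf("  areal pore fraction: %.4f\n", areal_pore_fraction(x)))
  invisible(x)
}

#' Continuous areal pore fraction of the film face
#'
#' The ratio of pore opening area to total film face area,
#' \eqn{\pi (d/2)^2 / s^2} for pore diameter d on a square lattice of spacing
#' s.  This is the accessible-to-total surface area ratio that normalizes the
#' effective diffusivity of a film of straight aligned channels.
#'
#' @param geom A [film_geometry()].
#' @return The areal pore fraction, a number in (0, 1).
#' @export
areal_pore_fraction <- function(geom) {
  if (!inherits(geom, "film_geometry")) {
    abort("`geom` must be a film_geometry object", class = "aqpore_invalid")
  }
  pi * (geom$pore_diameter / 2)^2 / geom$lattice_spacing^2
}

#' Aquaporin occlusion specification
#'
#' Describes how impermeable protein obstructions block the film pores.
#' Three modes are supported:
#' \describe{
#'   \item{`pore_cap`}{a fraction of pores, chosen pseudo-randomly from
#'     `placement_seed`, is fully capped by an impermeable layer at the
#'     feed-side film face (default thickness: one voxel layer; any
#'     thickness blocks a fully capped pore identically in steady state).}
#'   \item{`aggregate_disk`}{a single impermeable disk of radius
#'     `disk_radius`, centred on the supercell, occludes the pore area it
#'     covers.  Partial occlusions extend through the film depth by default
#'     so that blocked area carries no flux.}
#'   \item{`monomer_patch`}{a square patch of side `patch_side` (default the
#'     0.4 nm monomer footprint) centred on every pore opening, extending
#'     through the film depth by default.}
#' }
#'
#' @param mode One of `"pore_cap"`, `"aggregate_disk"`, `"monomer_patch"`.
#' @param cap_fraction Fraction of pores capped (pore_cap mode), in \[0, 1\].
#' @param disk_radius Aggregate disk radius in nm (aggregate_disk mode).
#' @param patch_side Monomer patch side in nm (monomer_patch mode).
#' @param occlusion_thickness Occlusion depth in nm measured from the
#'   feed-side film face.  `NULL` selects the mode default: one voxel layer
#'   for `pore_cap`, the full film depth for the partial occluders.
#' @param placement_seed Integer seed controlling which pores are capped.
#' @return An object of class `occlusion_spec`.
#' @export
occlusion_spec <- function(mode = c("pore_cap", "aggregate_disk", "monomer_patch"),
                           cap_fraction = 0,
                           disk_radius = 0,
                           patch_side = 0.4,
                           occlusion_thickness = NULL,
                           placement_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot_scalar(cap_fraction, "cap_fraction", nonneg = TRUE)
  if (cap_fraction > 1) {
    abort("invariant violated: cap_fraction must lie in [0, 1]",
          class = "aqpore_invalid")
  }
  stopifnot_scalar(disk_radius, "disk_radius", nonneg = TRUE)
  stopifnot_scalar(patch_side, "patch_side", nonneg = TRUE)
  if (!is.null(occlusion_thickness)) {
    stopifnot_scalar(occlusion_thickness, "occlusion_thickness", positive = TRUE)
  }
  structure(
    list(mode = mode,
         cap_fraction = cap_fraction,
         disk_radius = disk_radius,
         patch_side = patch_side,
         occlusion_thickness = occlusion_thickness,
         placement_seed = as.integer(placement_seed)),
    class = "occlusion_spec")
}

#' @export
print.occlusion_spec <- function(x, ...) {
  cat("<occlusion_spec>", x$mode, "\n")
  detail <- switch(x$mode,
    pore_cap = sprintf("  cap_fraction %.4g (placement seed %d)",
                       x$cap_fraction, x$placement_seed),
    aggregate_disk = sprintf("  disk_radius %.4g nm", x$disk_radius),
    monomer_patch = sprintf("  patch_side %.4g nm", x$patch_side))
  cat(detail, "\n")
  invisible(x)
}

#' Tagged packing fraction
#'
#' A packing/capping density is meaningless without its definition: the study
#' quotes both a fraction of pore openings capped and a fraction of surface
#' covered, which are numerically different.  This container keeps the two
#' from being confused.
#'
#' @param value Fraction in \[0, 1\].
#' @param definition One of `"fraction_of_pores_capped"`,
#'   `"fraction_of_pore_area_occluded"`, `"fraction_of_film_surface_occluded"`.
#' @return An object of class `packing_fraction`.
#' @export
packing_fraction <- function(value,
                             definition = c("fraction_of_pores_capped",
                                            "fraction_of_pore_area_occluded",
                                            "fraction_of_film_surface_occluded")) {
  definition <- match.arg(definition)
  stopifnot_scalar(value, "value", nonneg = TRUE)
  if (value > 1) {
    abort("invariant violated: packing fraction value must lie in [0, 1]",
          class = "aqpore_invalid")
  }
  structure(list(value = value, definition = definition),
            class = "packing_fraction")
}

#' @export
print.packing_fraction <- function(x, ...) {
  cat(sprintf("<packing_fraction> %.4g (%s)\n", x$value, x$definition))
  invisible(x)
}

#' Deterministic seeded choice of capped pores
#'
#' Pores are numbered 1..(n_pores_x * n_pores_y) in column-major order of the
#' lattice.  The subset of capped pores is a pure function of the geometry,
#' the cap fraction and the placement seed.
#'
#' @param geom A [film_geometry()].
#' @param cap_fraction Fraction of pores to cap.
#' @param seed Placement seed.
#' @return Integer vector of capped pore indices (possibly empty).
#' @export
capped_pore_ids <- function(geom, cap_fraction, seed = 1L) {
  n <- geom$n_pores_x * geom$n_pores_y
  k <- round_half_up(cap_fraction * n)
  if (k <= 0L) return(integer(0))
  if (k >= n) return(seq_len(n))
  with_rng(seed, sample.int(n, k))
}

## area of a disk of radius R centred in a W x H rectangle (R at most the
## half-diagonal, so adjacent edge segments never overlap)
disk_rect_overlap <- function(R, W, H) {
  a <- W / 2; b <- H / 2
  if (R <= 0) return(0)
  if (R >= sqrt(a^2 + b^2)) return(W * H)
  seg <- function(d) if (R > d) R^2 * acos(d / R) - d * sqrt(R^2 - d^2) else 0
  pi * R^2 - 2 * seg(a) - 2 * seg(b)
}

#' Realize a target packing fraction as an occlusion specification
#'
#' Solves for the occlusion whose realized packing density, under the
#' definition carried by `target`, is as close as quantization allows to the
#' requested value.
#'
#' \itemize{
#' \item `fraction_of_pores_capped`: `pore_cap` mode; caps
#'   `round(value * n_pores)` pores chosen pseudo-randomly from `seed`.
#' \item `fraction_of_pore_area_occluded`: `aggregate_disk` mode; searches
#'   the disk radius whose rasterized footprint (at `voxel_size`) occludes
#'   the requested fraction of pore-opening area.
#' \item `fraction_of_film_surface_occluded`: `aggregate_disk` mode; solves
#'   the continuous disk-square overlap for the requested fraction of total
#'   film face area.
#' }
#'
#' @param geom A [film_geometry()].
#' @param target A [packing_fraction()], or a bare number (interpreted as
#'   `fraction_of_pores_capped`).
#' @param seed Placement seed for pore_cap mode.
#' @param voxel_size Voxel size in nm used to quantize the disk footprint;
#'   default `lattice_spacing / 7`.
#' @return An `occlusion_spec` with attributes `target`, `realized` and
#'   `definition`.
#' @export
realize_packing <- function(geom, target, seed = 1L, voxel_size = NULL) {
  if (is.numeric(target)) target <- packing_fraction(target)
  if (!inherits(target, "packing_fraction")) {
    abort("`target` must be a packing_fraction or a number in [0, 1]",
          class = "aqpore_invalid")
  }
  f <- target$value
  if (target$definition == "fraction_of_pores_capped") {
    n <- geom$n_pores_x * geom$n_pores_y
    k <- round_half_up(f * n)
    realized <- k / n
    occ <- occlusion_spec("pore_cap", cap_fraction = realized,
                          placement_seed = seed)
    attr(occ, "capped_pores") <- capped_pore_ids(geom, realized, seed)
  } else if (target$definition == "fraction_of_pore_area_occluded") {
    occ <- realize_disk_pore_area(geom, f, voxel_size)
  } else {
    ## continuous film-surface fraction
    W <- geom$n_pores_x * geom$lattice_spacing
    H <- geom$n_pores_y * geom$lattice_spacing
    A <- W * H
    rmax <- sqrt((W / 2)^2 + (H / 2)^2)
    if (f <= 0) {
      occ <- occlusion_spec("aggregate_disk", disk_radius = 0)
      realized <- 0
    } else if (f >= 1) {
      occ <- occlusion_spec("aggregate_disk", disk_radius = rmax)
      realized <- 1
    } else {
      R <- stats::uniroot(function(r) disk_rect_overlap(r, W, H) / A - f,
                          lower = 0, upper = rmax, tol = 1e-12)$root
      occ <- occlusion_spec("aggregate_disk", disk_radius = R)
      realized <- disk_rect_overlap(R, W, H) / A
    }
    attr(occ, "realized") <- realized
  }
  attr(occ, "target") <- f
  attr(occ, "definition") <- target$definition
  if (is.null(attr(occ, "realized"))) {
    attr(occ, "realized") <- occ$cap_fraction
  }
  occ
}

## disk radius hitting a target fraction of rasterized pore-opening area
realize_disk_pore_area <- function(geom, f, voxel_size = NULL) {
  rast <- rasterize_face(geom, voxel_size)
  pore <- rast$open
  W <- geom$n_pores_x * geom$lattice_spacing
  H <- geom$n_pores_y * geom$lattice_spacing
  d2 <- outer((rast$yc - W / 2)^2, (rast$zc - H / 2)^2, "+")
  dists <- sqrt(d2[pore])
  n_pore <- length(dists)
  if (f <= 0) {
    occ <- occlusion_spec("aggregate_disk", disk_radius = 0)
    attr(occ, "realized") <- 0
    return(occ)
  }
  ## cluster distances that are equal up to roundoff (symmetry-degenerate
  ## voxel shells), so the radius never splits a shell
  ord <- sort(dists)
  brk <- which(diff(ord) > 1e-9)
  counts <- c(brk, length(ord))
  shell_max <- ord[counts]
  fracs <- counts / n_pore
  quantum <- max(diff(c(0, fracs)))
  j <- which.min(abs(fracs - f))
  realized <- fracs[j]
  if (abs(realized - f) > quantum + 1e-12) {
    abort(sprintf(paste0("target pore-area fraction %.4g unattainable under ",
                         "voxel quantization; nearest attainable is %.4g"),
                  f, realized), class = "aqpore_unattainable")
  }
  ## place the radius halfway to the next shell so the voxel set is robust
  R <- if (j < length(counts)) (shell_max[j] + ord[counts[j] + 1L]) / 2 else
    shell_max[j] + rast$h
  occ <- occlusion_spec("aggregate_disk", disk_radius = R)
  attr(occ, "realized") <- realized
  occ
}

## Shared lateral rasterization of the film face.  The lateral voxel size
## snaps to an integer divisor of the lattice spacing so that every unit cell
## is rasterized identically (and the voxelization is bitwise deterministic).
rasterize_face <- function(geom, voxel_size = NULL) {
  s <- geom$lattice_spacing
  voxel_size <- voxel_size %||% (s / 7)
  if (voxel_size > geom$pore_diameter / 4 + 1e-12) {
    abort(sprintf(paste0("resolution too coarse: voxel_size (%g nm) exceeds ",
                         "pore_diameter/4 (%g nm)"),
                  voxel_size, geom$pore_diameter / 4),
          class = "aqpore_resolution")
  }
  nsub <- max(1L, round_half_up(s / voxel_size))
  h <- s / nsub
  ny <- geom$n_pores_x * nsub
  nz <- geom$n_pores_y * nsub
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  pcx <- (seq_len(geom$n_pores_x) - 0.5) * s
  pcy <- (seq_len(geom$n_pores_y) - 0.5) * s
  ## nearest pore centre along each lateral axis
  iy <- pmin(pmax(ceiling(yc / s), 1L), geom$n_pores_x)
  iz <- pmin(pmax(ceiling(zc / s), 1L), geom$n_pores_y)
  dy <- yc - pcx[iy]
  dz <- zc - pcy[iz]
  r2 <- (geom$pore_diameter / 2)^2
  ## voxel-centre membership; centre exactly on the pore surface counts open
  open <- outer(dy^2, dz^2, "+") <= r2 + 1e-12
  pore_id <- matrix((iy[row(open)] - 1L) * geom$n_pores_y + iz[col(open)],
                    nrow(open), ncol(open))
  list(open = open, pore_id = pore_id, h = h, nsub = nsub,
       yc = yc, zc = zc, ny = ny, nz = nz)
}
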