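#' Dirichlet boundary conditions for the diffusion solve
#'
#' Fixed concentrations imposed on the two x-boundary faces of the domain
#' (the outer reservoir walls).  Concentrations are nondimensional; the
#' default unit difference, together with the unit bulk diffusivity, is the
#' normalization under which effective diffusivities are reported.
#'
#' @param c_left Concentration on the feed-side (low-x) boundary face.
#' @param c_right Concentration on the permeate-side (high-x) boundary face.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(c_left = 1, c_right = 0) {
  stopifnot_scalar(c_left, "c_left", nonneg = TRUE)
  stopifnot_scalar(c_right, "c_right", nonneg = TRUE)
  structure(list(c_left = c_left, c_right = c_right, axis = "x"),
            class = "boundary_conditions")
}

## Assemble the finite-volume Laplacian over voxels with positive diffusivity.
## Face conductances use the harmonic mean of the adjacent voxel
## diffusivities, which makes zero-diffusivity (solid) voxels exactly
## impermeable and is the scheme under which piecewise-constant layered
## profiles are solved exactly.
assemble_system <- function(dom, bc) {
  D <- dom$diffusivity
  h <- dom$h
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  open <- D > 0
  n <- sum(open)
  if (n == 0L) abort("domain has no open voxels", class = "aqpore_invalid")
  idx <- array(0L, dim(D)); idx[open] <- seq_len(n)

  pair_axis <- function(axis) {
    if (axis == 1L) {
      a <- open[-nx, , ] & open[-1, , ]
      list(i = idx[-nx, , ][a], j = idx[-1, , ][a],
           d1 = D[-nx, , ][a], d2 = D[-1, , ][a])
    } else if (axis == 2L) {
      a <- open[, -ny, ] & open[, -1, ]
      list(i = idx[, -ny, ][a], j = idx[, -1, ][a],
           d1 = D[, -ny, ][a], d2 = D[, -1, ][a])
    } else {
      a <- open[, , -nz] & open[, , -1]
      list(i = idx[, , -nz][a], j = idx[, , -1][a],
           d1 = D[, , -nz][a], d2 = D[, , -1][a])
    }
  }
  px <- pair_axis(1L); py <- pair_axis(2L); pz <- pair_axis(3L)
  pi_ <- c(px$i, py$i, pz$i)
  pj <- c(px$j, py$j, pz$j)
  ## conductance = D_face * face_area / distance = D_face * h
  g <- 2 * c(px$d1, py$d1, pz$d1) * c(px$d2, py$d2, pz$d2) /
    (c(px$d1, py$d1, pz$d1) + c(px$d2, py$d2, pz$d2)) * h

  ## Dirichlet half-cells on the two x faces
  bl <- idx[1, , ][open[1, , ]]
  br <- idx[nx, , ][open[nx, , ]]
  gl <- 2 * D[1, , ][open[1, , ]] * h
  gr <- 2 * D[nx, , ][open[nx, , ]] * h

  agg <- function(id, w) {
    out <- rep(0, n)
    if (length(id)) {
      sums <- rowsum(w, id, reorder = FALSE)
      out[as.integer(rownames(sums))] <- sums[, 1]
    }
    out
  }
  diag_val <- agg(c(pi_, pj), c(g, g))
  diag_val[bl] <- diag_val[bl] + gl
  diag_val[br] <- diag_val[br] + gr

  b <- rep(0, n)
  b[bl] <- b[bl] + gl * bc$c_left
  b[br] <- b[br] + gr * bc$c_right

  ## open voxels with no open neighbour and no boundary face are enclosed
  ## cavities: they carry no flux and take the mean boundary value
  isolated <- diag_val == 0
  list(i = pi_, j = pj, g = g, diag = diag_val, b = b, n = n,
       idx = idx, open = open, isolated = isolated)
}

#' Solve the steady-state diffusion equation on a voxel domain
#'
#' Solves div(D grad c) = 0 with Dirichlet concentrations on the two
#' x-boundary faces and no-flux lateral boundaries, using a conservative
#' finite-volume discretization (harmonic face diffusivities) and a direct
#' sparse Cholesky factorization.  The relative residual of the solved
#' linear system is checked against `tol`.
#'
#' @param dom A [voxelize()]d domain (or [layered_domain()]).
#' @param bc [boundary_conditions()].
#' @param tol Relative residual tolerance for the solved system.
#' @return An object of class `concentration_field`: the 3D concentration
#'   array (`NA` in solid voxels), the relative residual, the iteration
#'   count (1 for the direct factorization), `bc` and the domain.
#' @export
solve_steady_state <- function(dom, bc = boundary_conditions(), tol = 1e-10) {
  if (!inherits(dom, "voxel_domain")) {
    abort("`dom` must be a voxel_domain", class = "aqpore_invalid")
  }
  if (!inherits(bc, "boundary_conditions")) {
    abort("`bc` must be boundary_conditions", class = "aqpore_invalid")
  }
  stopifnot_scalar(tol, "tol", positive = TRUE)
  sys <- assemble_system(dom, bc)
  n <- sys$n
  x <- rep((bc$c_left + bc$c_right) / 2, n)
  live <- !sys$isolated
  if (any(live)) {
    map <- cumsum(live)
    A <- Matrix::sparseMatrix(
      i = c(map[sys$i], seq_len(sum(live))),
      j = c(map[sys$j], seq_len(sum(live))),
      x = c(-sys$g, sys$diag[live]),
      dims = c(sum(live), sum(live)),
      symmetric = TRUE)
    b <- sys$b[live]
    ch <- tryCatch(
      Matrix::Cholesky(A, LDL = FALSE, super = TRUE),
      error = function(e) {
        abort(paste0("steady-state solve failed: the open region contains a ",
                     "component with no boundary connection (",
                     conditionMessage(e), ")"),
              class = "aqpore_solver")
      })
    xs <- as.numeric(Matrix::solve(ch, b))
    res <- sqrt(sum((as.numeric(A %*% xs) - b)^2))
    bnorm <- sqrt(sum(b^2))
    rel <- if (bnorm > 0) res / bnorm else res
    if (!is.finite(rel) || rel > tol) {
      abort(sprintf("solver did not reach tolerance: relative residual %.3e > %.3e",
                    rel, tol), class = "aqpore_solver",
            residual = rel)
    }
    x[live] <- xs
  } else {
    rel <- 0
  }
  carr <- array(NA_real_, dim(dom$diffusivity))
  carr[sys$open] <- x
  structure(
    list(c = carr, residual = rel, iterations = 1L, tol = tol,
         bc = bc, dom = dom),
    class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("<concentration_field>\n")
  cat(sprintf("  grid %d x %d x %d, residual %.2e\n",
              x$dom$nx, x$dom$ny, x$dom$nz, x$residual))
  cat(sprintf("  c in [%.4g, %.4g] (boundaries %.4g / %.4g)\n",
              min(x$c, na.rm = TRUE), max(x$c, na.rm = TRUE),
              x$bc$c_left, x$bc$c_right))
  invisible(x)
}

## x-face index k (between slices k and k+1) nearest to plane_x; errors if
## the plane is not strictly inside the domain
plane_face_index <- function(dom, plane_x) {
  k <- round_half_up(plane_x / dom$h)
  if (k < 1 || k > dom$nx - 1) {
    abort(sprintf("plane_x = %g nm is not strictly inside the domain (0, %g)",
                  plane_x, dom$nx * dom$h), class = "aqpore_invalid")
  }
  as.integer(k)
}

#' Area-averaged flux through a lateral plane
#'
#' Sums the finite-volume face fluxes `D_face (c_i - c_j) / h * a_face`
#' across the voxel-face plane nearest `plane_x` and divides by the total
#' lateral area of the domain.  In a converged steady state this flux is the
#' same on every interior plane.
#'
#' @param field A [solve_steady_state()] result.
#' @param plane_x Plane position in nm along the transport axis (on a voxel
#'   face strictly inside the domain).  Default: the mid-film plane.
#' @return The mean flux (nondimensional).
#' @export
plane_flux <- function(field, plane_x = NULL) {
  if (!inherits(field, "concentration_field")) {
    abort("`field` must be a concentration_field", class = "aqpore_invalid")
  }
  dom <- field$dom
  if (is.null(plane_x)) {
    k <- dom$n_reservoir + floor(dom$n_film / 2)
    k <- max(1L, min(dom$nx - 1L, k))
  } else {
    k <- plane_face_index(dom, plane_x)
  }
  D <- dom$diffusivity
  d1 <- D[k, , ]; d2 <- D[k + 1, , ]
  a <- d1 > 0 & d2 > 0
  if (!any(a)) return(0)
  dface <- 2 * d1[a] * d2[a] / (d1[a] + d2[a])
  c1 <- field$c[k, , ][a]; c2 <- field$c[k + 1, , ][a]
  sum(dface * (c1 - c2) / dom$h * dom$h^2) / (dom$ny * dom$nz * dom$h^2)
}

## diffusivity-weighted mean concentration on the x-face plane k, averaged
## over open faces.  The weighting is the interface value implied by flux
## continuity across the face, so piecewise-constant layered profiles are
## rendered exactly.
face_concentration <- function(field, k) {
  dom <- field$dom
  d1 <- dom$diffusivity[k, , ]; d2 <- dom$diffusivity[k + 1, , ]
  a <- d1 > 0 & d2 > 0
  if (!any(a)) return(NA_real_)
  c1 <- field$c[k, , ][a]; c2 <- field$c[k + 1, , ][a]
  mean((d1[a] * c1 + d2[a] * c2) / (d1[a] + d2[a]))
}

#' Effective diffusivity of the film (or whole domain)
#'
#' Relates the area-averaged steady flux to the concentration difference and
#' separation: `De = <j> * (x_L - x_R) / (c_L - c_R)`.  With the default
#' `"film"` convention the separation is the film thickness and the boundary
#' concentrations are face-averaged over the open pore openings at the two
#' film faces, which makes De/D_bulk of a film of straight uncapped channels
#' equal its discrete pore fraction.  The `"domain"` convention uses the
#' imposed reservoir concentrations and the whole-domain separation.
#'
#' @param field A [solve_steady_state()] result.
#' @param separation `"film"` (default) or `"domain"`.
#' @return An object of class `effective_diffusivity` with fields
#'   `mean_flux`, `de`, `ratio` (De/D_bulk), `plane_position`,
#'   `separation_nm` and `separation` (the convention used).
#' @export
effective_diffusivity <- function(field, separation = c("film", "domain")) {
  separation <- match.arg(separation)
  if (!inherits(field, "concentration_field")) {
    abort("`field` must be a concentration_field", class = "aqpore_invalid")
  }
  bc <- field$bc
  if (bc$c_left == bc$c_right) {
    abort("effective diffusivity needs a nonzero concentration difference",
          class = "aqpore_invalid")
  }
  dom <- field$dom
  kmid <- max(1L, min(dom$nx - 1L, dom$n_reservoir + floor(dom$n_film / 2)))
  j <- plane_flux(field)
  if (separation == "film") {
    kL <- dom$n_reservoir
    kR <- dom$n_reservoir + dom$n_film
    cl <- if (kL >= 1) face_concentration(field, kL) else bc$c_left
    cr <- if (kR <= dom$nx - 1) face_concentration(field, kR) else bc$c_right
    sep <- dom$n_film * dom$h
    if (is.na(cl) || is.na(cr) || cl == cr) {
      ## film fully sealed: no open faces, no flux, De = 0 by convention
      de <- 0
    } else {
      de <- j * sep / (cl - cr)
    }
  } else {
    sep <- dom$nx * dom$h
    de <- j * sep / (bc$c_left - bc$c_right)
  }
  structure(
    list(mean_flux = j, de = de, ratio = de / dom$d_bulk,
         plane_position = kmid * dom$h,
         separation_nm = sep, separation = separation),
    class = "effective_diffusivity")
}

#' @export
print.effective_diffusivity <- function(x, ...) {
  cat(sprintf("<effective_diffusivity> De/D_bulk = %.6g (%s separation %.4g nm, <j> = %.6g)\n",
              x$ratio, x$separation, x$separation_nm, x$mean_flux))
  invisible(x)
}

#' Closed-form series-resistance composite for layered straight channels
#'
#' For a stack of planar layers, each of thickness `L_i` carrying straight
#' aligned channels of open fraction `phi_i` (with lateral mixing between
#' layers), the composite effective-to-bulk diffusivity ratio is the
#' harmonic series `L_total / sum(L_i / phi_i)`.  Used as the independent
#' oracle for the finite-volume solver on layered domains.
#'
#' @param layers A data frame with columns `thickness` and `open_fraction`
#'   (fractions in (0, 1\]; a zero open fraction short-circuits to 0).
#' @return The composite De/D_bulk ratio.
#' @export
series_resistance_oracle <- function(layers) {
  layers <- as.data.frame(layers)
  if (!all(c("thickness", "open_fraction") %in% names(layers))) {
    abort("`layers` needs columns `thickness` and `open_fraction`",
          class = "aqpore_invalid")
  }
  if (any(layers$thickness <= 0)) {
    abort("invariant violated: layer thicknesses must be positive",
          class = "aqpore_invalid")
  }
  if (any(layers$open_fraction < 0 | layers$open_fraction > 1)) {
    abort("invariant violated: open fractions must lie in [0, 1]",
          class = "aqpore_invalid")
  }
  if (any(layers$open_fraction == 0)) return(0)
  sum(layers$thickness) / sum(layers$thickness / layers$open_fraction)
}

#' Build a laterally uniform layered voxel domain
#'
#' Stacks planar layers of given thickness and diffusivity along the
#' transport axis, preceded and followed by open reservoirs.  Layers with
#' diffusivity equal to a layer's open channel fraction are the homogenized
#' representation of straight aligned channels, for which the finite-volume
#' solution reproduces [series_resistance_oracle()] exactly.
#'
#' @param layers Data frame with columns `thickness` (nm) and `diffusivity`.
#' @param voxel_size Voxel edge in nm.
#' @param lateral Number of voxels along each lateral edge.
#' @param reservoir_depth Reservoir depth in nm on each side.
#' @param d_bulk Bulk diffusivity of the reservoirs.
#' @return A `voxel_domain` whose film region spans the stacked layers.
#' @export
layered_domain <- function(layers, voxel_size = 0.5, lateral = 4L,
                           reservoir_depth = 2 * voxel_size, d_bulk = 1) {
  layers <- as.data.frame(layers)
  if (!all(c("thickness", "diffusivity") %in% names(layers))) {
    abort("`layers` needs columns `thickness` and `diffusivity`",
          class = "aqpore_invalid")
  }
  h <- voxel_size
  nlay <- vapply(layers$thickness,
                 function(t) as.integer(max(1, round_half_up(t / h))),
                 integer(1))
  nr <- max(1L, round_half_up(reservoir_depth / h))
  nf <- sum(nlay)
  nx <- nf + 2L * nr
  ny <- as.integer(lateral); nz <- as.integer(lateral)
  D <- array(d_bulk, c(nx, ny, nz))
  region <- array(1L, c(nx, ny, nz))
  region[(nr + nf + 1L):nx, , ] <- 5L
  k <- nr
  for (l in seq_len(nrow(layers))) {
    dl <- layers$diffusivity[l]
    for (s in seq_len(nlay[l])) {
      k <- k + 1L
      D[k, , ] <- dl
      region[k, , ] <- if (dl > 0) 2L else 3L
    }
  }
  structure(
    list(diffusivity = D, region = region, region_levels = REGION_LEVELS,
         h = h, nx = nx, ny = ny, nz = nz,
         n_reservoir = nr, n_film = nf,
         film_x = c(nr + 1L, nr + nf),
         d_bulk = d_bulk, geom = NULL, occ = NULL),
    class = "voxel_domain")
}
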