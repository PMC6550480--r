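new_packing_curve <- function(points, model, geom, voxel_size, extra = list()) {
  out <- tibble::new_tibble(points, nrow = nrow(points),
                            class = "packing_curve")
  attr(out, "model") <- model
  attr(out, "geometry_hash") <- digest::digest(geom)
  attr(out, "voxel_size") <- voxel_size
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

validate_curve_monotone <- function(de, f, tol = 1e-6) {
  if (any(diff(de) > tol * max(de[1], 1e-12))) {
    abort("packing curve invariant violated: De ratio must be non-increasing in f",
          class = "aqpore_invalid")
  }
  invisible(TRUE)
}

check_sweep_fractions <- function(fractions) {
  if (any(fractions < 0 | fractions > 1)) {
    abort("sweep fractions must lie in [0, 1]", class = "aqpore_invalid")
  }
  fractions <- sort(unique(fractions))
  if (fractions[1] != 0 || fractions[length(fractions)] != 1) {
    abort("sweep fractions must include the endpoints 0 and 1",
          class = "aqpore_invalid")
  }
  fractions
}

#' Sweep the occlusion packing density and record the De(f) curve
#'
#' Voxelizes and solves the steady-state diffusion problem once per packing
#' fraction, building the monotone effective-diffusivity-versus-packing
#' curve that is later inverted against measured flux ratios.
#'
#' In `pore_cap` mode the packing fraction is the fraction of pores capped
#' (capped pores chosen pseudo-randomly from `seed`); in `aggregate_disk`
#' mode it is the fraction of pore-opening area occluded by a centred
#' aggregate disk whose radius is solved per fraction.  The occluded
#' film-surface fraction is reported alongside in both modes.
#'
#' @param geom A [film_geometry()].
#' @param fractions Packing fractions to sweep; must include 0 and 1.
#'   Default: 0 to 1 in steps of 0.1 plus the 0.64 analysis point.
#' @param mode `"pore_cap"` or `"aggregate_disk"`.
#' @param seed Placement seed for capped-pore selection.
#' @param voxel_size Voxel edge in nm (default `lattice_spacing / 7`).
#' @param bc,tol Passed to [solve_steady_state()].
#' @return A `packing_curve` tibble with columns `model`, `f` (target),
#'   `f_realized`, `surface_fraction`, `de_ratio`.
#' @export
sweep_capping <- function(geom,
                          fractions = c(seq(0, 1, by = 0.1), 0.64),
                          mode = c("pore_cap", "aggregate_disk"),
                          seed = 1L,
                          voxel_size = NULL,
                          bc = boundary_conditions(),
                          tol = 1e-10) {
  mode <- match.arg(mode)
  fractions <- check_sweep_fractions(fractions)
  definition <- if (mode == "pore_cap") "fraction_of_pores_capped"
                else "fraction_of_pore_area_occluded"
  p_areal <- areal_pore_fraction(geom)
  rows <- purrr::map(fractions, function(f) {
    res <- tryCatch({
      occ <- if (f == 0) NULL else
        realize_packing(geom, packing_fraction(f, definition),
                        seed = seed, voxel_size = voxel_size)
      dom <- voxelize(geom, occ, voxel_size)
      field <- solve_steady_state(dom, bc, tol)
      de <- effective_diffusivity(field, "film")
      f_real <- if (is.null(occ)) 0 else attr(occ, "realized")
      surf <- if (mode == "pore_cap") {
        f_real * p_areal
      } else if (is.null(occ) || occ$disk_radius == 0) 0 else {
        W <- geom$n_pores_x * geom$lattice_spacing
        H <- geom$n_pores_y * geom$lattice_spacing
        disk_rect_overlap(min(occ$disk_radius, sqrt((W/2)^2 + (H/2)^2)), W, H) / (W * H)
      }
      tibble::tibble(f = f, f_realized = f_real, surface_fraction = surf,
                     de_ratio = max(0, de$ratio))
    }, error = function(e) {
      abort(sprintf("sweep failed at packing fraction %g: %s",
                    f, conditionMessage(e)), class = "aqpore_sweep")
    })
    res
  })
  points <- dplyr::bind_rows(rows)
  points <- dplyr::mutate(points, model = "aggregate", mode = mode,
                          .before = 1)
  validate_curve_monotone(points$de_ratio, points$f)
  new_packing_curve(points, model = "aggregate", geom = geom,
                    voxel_size = voxel_size,
                    extra = list(mode = mode, seed = seed,
                                 definition = definition))
}

#' Monomer-model De(f) curve from a single simulated patch configuration
#'
#' Models uniformly dispersed aquaporin monomers: a fixed square patch (the
#' 0.4 nm monomer footprint) is placed on every pore opening and the domain
#' solved once; together with the unoccluded and fully occluded limits, the
#' per-pore flux is scaled by occluded-area fraction, so the curve is the
#' monotone piecewise-linear interpolant through the simulated anchors
#' (0, De0), (f_patch, De_patch) and (1, 0), where f_patch is the rasterized
#' patch-to-pore-opening area fraction.
#'
#' @inheritParams sweep_capping
#' @param patch_side Monomer footprint side in nm.
#' @return A `packing_curve` tibble (model `"monomer"`).
#' @export
monomer_curve <- function(geom,
                          fractions = c(seq(0, 1, by = 0.1), 0.64),
                          patch_side = 0.4,
                          voxel_size = NULL,
                          bc = boundary_conditions(),
                          tol = 1e-10) {
  fractions <- check_sweep_fractions(fractions)
  if (patch_side > geom$pore_diameter) {
    abort(sprintf("monomer patch (%g nm) is larger than the pore opening (%g nm)",
                  patch_side, geom$pore_diameter), class = "aqpore_invalid")
  }
  dom0 <- voxelize(geom, NULL, voxel_size)
  de0 <- effective_diffusivity(solve_steady_state(dom0, bc, tol), "film")$ratio
  occ <- occlusion_spec("monomer_patch", patch_side = patch_side)
  domp <- voxelize(geom, occ, voxel_size)
  ## occluded fraction of the pore-opening area, on the raster
  face0 <- dom0$region[dom0$film_x[1], , ] == 2L
  facep <- domp$region[domp$film_x[1], , ] == 2L
  f_patch <- 1 - sum(facep) / sum(face0)
  if (f_patch <= 0) {
    abort("monomer patch rasterized to zero area; use a finer voxel_size",
          class = "aqpore_resolution")
  }
  dep <- effective_diffusivity(solve_steady_state(domp, bc, tol), "film")$ratio
  fa <- c(0, f_patch, 1)
  da <- c(de0, dep, 0)
  de <- stats::approx(fa, da, xout = fractions, method = "linear",
                      ties = "ordered")$y
  p_areal <- areal_pore_fraction(geom)
  points <- tibble::tibble(model = "monomer", mode = "monomer_patch",
                           f = fractions, f_realized = fractions,
                           surface_fraction = fractions * p_areal,
                           de_ratio = pmax(0, de))
  validate_curve_monotone(points$de_ratio, points$f)
  new_packing_curve(points, model = "monomer", geom = geom,
                    voxel_size = voxel_size,
                    extra = list(mode = "monomer_patch",
                                 definition = "fraction_of_pore_area_occluded",
                                 anchors = tibble::tibble(f = fa, de_ratio = da)))
}

#' Invert a packing curve at a measured diffusivity or flux ratio
#'
#' Monotone piecewise-linear inversion of a De(f) curve: finds the packing
#' fraction whose model effective diffusivity matches the measurement, with
#' the bracketing pair of adjacent curve points.  Because flux at fixed
#' concentration difference and geometry is proportional to De, a measured
#' flux ratio (occluded over unoccluded) may be supplied instead; it is
#' converted through the curve's own De(0).
#'
#' @param curve A `packing_curve`.
#' @param measured_ratio The measurement: a De/D_bulk ratio
#'   (`measured = "de_ratio"`) or a flux ratio relative to the unoccluded
#'   film (`measured = "flux_ratio"`).
#' @param measured Which quantity `measured_ratio` is.
#' @return An object of class `packing_estimate` with the estimate (a
#'   [packing_fraction()]), the bracketing interval and provenance.
#' @export
estimate_packing <- function(curve, measured_ratio,
                             measured = c("de_ratio", "flux_ratio")) {
  measured <- match.arg(measured)
  if (!inherits(curve, "packing_curve")) {
    abort("`curve` must be a packing_curve", class = "aqpore_invalid")
  }
  stopifnot_scalar(measured_ratio, "measured_ratio", nonneg = TRUE)
  f <- curve$f_realized
  de <- curve$de_ratio
  ord <- order(f)
  f <- f[ord]; de <- de[ord]
  r <- if (measured == "flux_ratio") measured_ratio * de[1] else measured_ratio
  if (r > max(de) + 1e-12) {
    abort(sprintf("measured ratio %.4g is above the curve maximum %.4g (packing below the swept range)",
                  r, max(de)), class = "aqpore_above_range")
  }
  if (r < min(de) - 1e-12) {
    abort(sprintf("measured ratio %.4g is below the curve minimum %.4g (packing above the swept range)",
                  r, min(de)), class = "aqpore_below_range")
  }
  r <- min(max(r, min(de)), max(de))
  ## first interval (in increasing f) with de[i] >= r >= de[i+1]
  i <- which(de[-length(de)] >= r - 1e-15 & de[-1] <= r + 1e-15)[1]
  if (is.na(i)) { # r equals a flat maximum region endpoint
    i <- max(which(de >= r)) - 1L
    i <- max(1L, i)
  }
  lo <- f[i]; hi <- f[i + 1]
  est <- if (de[i] == de[i + 1]) (lo + hi) / 2 else
    lo + (de[i] - r) / (de[i] - de[i + 1]) * (hi - lo)
  structure(
    list(estimate = packing_fraction(est, attr(curve, "definition") %||%
                                       "fraction_of_pores_capped"),
         measured_ratio = measured_ratio,
         measured = measured,
         de_ratio = r,
         bracket = c(lo = lo, hi = hi),
         model = attr(curve, "model"),
         geometry_hash = attr(curve, "geometry_hash")),
    class = "packing_estimate")
}

#' @export
print.packing_estimate <- function(x, ...) {
  cat(sprintf("<packing_estimate> %.4f (%s)\n", x$estimate$value,
              x$estimate$definition))
  cat(sprintf("  model %s, measured %s = %.4g, bracket [%.3f, %.3f]\n",
              x$model, x$measured, x$measured_ratio,
              x$bracket["lo"], x$bracket["hi"]))
  invisible(x)
}

#' Commensurate-capping identification of a flux reduction
#'
#' The study attributes a percentage reduction in steady-state flux, relative
#' to the unoccluded membrane, to capping the commensurate percentage of
#' available pores (exact for straight channels, where capped columns carry
#' no flux).  This converts a percent flux reduction into the tagged capped
#' fraction.
#'
#' @param reduction_pct Percent flux reduction in \[0, 100\].
#' @return A [packing_fraction()] with definition `fraction_of_pores_capped`.
#' @examples
#' flux_reduction_to_capping(64) # the study's PVA-alkyl vs Aqp-SH reduction
#' @export
flux_reduction_to_capping <- function(reduction_pct) {
  stopifnot_scalar(reduction_pct, "reduction_pct")
  if (reduction_pct < 0 || reduction_pct > 100) {
    abort("`reduction_pct` must lie in [0, 100]", class = "aqpore_invalid")
  }
  packing_fraction(reduction_pct / 100, "fraction_of_pores_capped")
}
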