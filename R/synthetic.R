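#' Specification of a synthetic filtration study
#'
#' Collects the ground truth and noise settings from which synthetic bench
#' tables (flux series per membrane variant, per-solute rejection profiles)
#' are generated.  The defaults are the study conditions the analysis
#' targets: a true capping fraction of 0.64, multiplicative measurement
#' noise of 5% relative standard deviation, and 10 replicate flux readings
#' per membrane variant.
#'
#' Variant mean fluxes follow the diffusion model: the occluded variant's
#' mean is `(1 - true_capping)` times the reference (aquaporin-modified)
#' variant's mean.  The unmodified support membrane sits above the reference
#' (no added surface layer) and the inactive-mutant control tracks the
#' occluded variant, reproducing the qualitative ordering of the bench flux
#' series.
#'
#' @param true_capping True capped-pore fraction, in \[0, 1\] (a
#'   [packing_fraction()] or bare number).
#' @param geometry The [film_geometry()] the simulated curve refers to.
#' @param flux_scale Mean flux of the reference variant, in arbitrary bench
#'   units (the analysis only uses ratios).
#' @param noise_sd_rel Relative standard deviation of the multiplicative
#'   Gaussian measurement noise on flux.
#' @param n_replicates Replicate flux readings per variant.
#' @param seed Integer seed; the generated dataset is a pure function of
#'   this spec including the seed.
#' @param rejection_midpoint_nm Stokes radius at 50% rejection of the
#'   sigmoid rejection profile.
#' @param rejection_steepness Width (nm) of the sigmoid transition; 0 gives
#'   a step profile.
#' @param rejection_noise_sd Additive noise on rejection, in percentage
#'   points (typical reported spreads are 1-5 points).
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(true_capping = 0.64,
                                 geometry = film_geometry(),
                                 flux_scale = 60,
                                 noise_sd_rel = 0.05,
                                 n_replicates = 10L,
                                 seed = 1L,
                                 rejection_midpoint_nm = 0.60,
                                 rejection_steepness = 0.05,
                                 rejection_noise_sd = 2.5) {
  if (is.numeric(true_capping)) {
    true_capping <- packing_fraction(true_capping)
  }
  if (!inherits(true_capping, "packing_fraction")) {
    abort("`true_capping` must be a packing_fraction or number in [0, 1]",
          class = "aqpore_invalid")
  }
  stopifnot_scalar(noise_sd_rel, "noise_sd_rel", nonneg = TRUE)
  stopifnot_scalar(flux_scale, "flux_scale", positive = TRUE)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) {
    abort("invariant violated: n_replicates must be >= 1",
          class = "aqpore_invalid")
  }
  stopifnot_scalar(rejection_midpoint_nm, "rejection_midpoint_nm", positive = TRUE)
  stopifnot_scalar(rejection_steepness, "rejection_steepness", nonneg = TRUE)
  stopifnot_scalar(rejection_noise_sd, "rejection_noise_sd", nonneg = TRUE)
  structure(
    list(true_capping = true_capping,
         geometry = geometry,
         flux_scale = flux_scale,
         noise_sd_rel = noise_sd_rel,
         n_replicates = n_replicates,
         seed = as.integer(seed),
         rejection_midpoint_nm = rejection_midpoint_nm,
         rejection_steepness = rejection_steepness,
         rejection_noise_sd = rejection_noise_sd),
    class = "synthetic_study_spec")
}

## the four bench membrane variants and their model-implied mean fluxes,
## in units of the reference (aqp_sh) mean
variant_means <- function(spec) {
  f <- spec$true_capping$value
  c(unmodified_pbi = 1 / 0.8,
    aqp_sh         = 1,
    aqp_sh_r189a   = 1 - f,
    pva_alkyl      = 1 - f) * spec$flux_scale
}

#' Generate synthetic flux measurements for the four membrane variants
#'
#' Draws `n_replicates` noisy flux readings per variant around the
#' model-implied means (multiplicative Gaussian noise of relative sd
#' `noise_sd_rel`), reproducibly from the spec's seed.  The inversion pair
#' is `pva_alkyl` (occluded) against `aqp_sh` (reference): the noiseless
#' ratio of their means is exactly `1 - true_capping`.
#'
#' @param spec A [synthetic_study_spec()].
#' @return An object of class `synthetic_dataset`: list with the `flux`
#'   tibble (`membrane_variant`, `replicate`, `flux`), a `truth` tibble
#'   (ground truth, kept separate from the "observed" tables), and the spec.
#' @export
generate_flux_measurements <- function(spec) {
  if (!inherits(spec, "synthetic_study_spec")) {
    abort("`spec` must be a synthetic_study_spec", class = "aqpore_invalid")
  }
  means <- variant_means(spec)
  flux <- with_rng(spec$seed, {
    purrr::map(names(means), function(v) {
      eps <- stats::rnorm(spec$n_replicates, 0, spec$noise_sd_rel)
      tibble::tibble(membrane_variant = v,
                     replicate = seq_len(spec$n_replicates),
                     flux = means[[v]] * (1 + eps))
    }) |> dplyr::bind_rows()
  })
  truth <- tibble::tibble(
    true_capping = spec$true_capping$value,
    definition = spec$true_capping$definition,
    seed = spec$seed)
  structure(list(flux = flux, rejection = NULL, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  if (!is.null(x$flux)) {
    cat(sprintf("  flux: %d readings, %d variants\n", nrow(x$flux),
                dplyr::n_distinct(x$flux$membrane_variant)))
  }
  if (!is.null(x$rejection)) {
    cat(sprintf("  rejection: %d solutes\n", nrow(x$rejection)))
  }
  cat(sprintf("  truth: capping %.3f (seed %d)\n",
              x$truth$true_capping, x$truth$seed))
  invisible(x)
}

#' Observed flux ratio between an occluded variant and its reference
#'
#' The mean flux of the occluded variant divided by the mean flux of the
#' reference variant — the quantity the packing inversion consumes.
#'
#' @param dataset A [generate_flux_measurements()] result, or its `flux`
#'   tibble.
#' @param occluded,reference Variant names.
#' @return A single flux ratio.
#' @export
flux_ratio <- function(dataset, occluded = "pva_alkyl", reference = "aqp_sh") {
  flux <- if (inherits(dataset, "synthetic_dataset")) dataset$flux else
    tibble::as_tibble(dataset)
  m <- dplyr::summarise(dplyr::group_by(flux, .data$membrane_variant),
                        mean_flux = mean(.data$flux), .groups = "drop")
  get <- function(v) {
    row <- m$mean_flux[m$membrane_variant == v]
    if (length(row) != 1L) {
      abort(sprintf("variant `%s` not found in flux table", v),
            class = "aqpore_invalid")
    }
    row
  }
  get(occluded) / get(reference)
}

#' Generate a synthetic per-solute rejection profile
#'
#' Rejection is a sigmoid in the solute Stokes radius,
#' `100 * plogis((r - midpoint) / steepness)`, with additive Gaussian noise
#' clamped to \[0, 100\].  A zero steepness yields a step profile.
#'
#' @param spec A [synthetic_study_spec()].
#' @param solutes Probe series: a data frame with columns `solute`,
#'   `molecular_weight`, `stokes_radius` (default [mwco_solutes()]).
#' @return A tibble with columns `solute`, `molecular_weight`,
#'   `stokes_radius`, `rejection_pct`.
#' @export
generate_rejection_profile <- function(spec, solutes = mwco_solutes()) {
  if (!inherits(spec, "synthetic_study_spec")) {
    abort("`spec` must be a synthetic_study_spec", class = "aqpore_invalid")
  }
  solutes <- tibble::as_tibble(solutes)
  if (nrow(solutes) == 0L) {
    abort("`solutes` must be non-empty", class = "aqpore_invalid")
  }
  z <- solutes$stokes_radius - spec$rejection_midpoint_nm
  base <- if (spec$rejection_steepness == 0) {
    100 * as.numeric(z >= 0)
  } else {
    100 * stats::plogis(z / spec$rejection_steepness)
  }
  noisy <- with_rng(spec$seed + 1L, {
    base + stats::rnorm(length(base), 0, spec$rejection_noise_sd)
  })
  dplyr::mutate(solutes, rejection_pct = pmin(pmax(noisy, 0), 100))
}

#' End-to-end parameter-recovery experiment
#'
#' Runs the full synthetic chain: generate noisy flux measurements, form the
#' occluded-to-reference flux ratio, and invert it on a simulated packing
#' curve.  Reports the true and estimated capping fraction, the bias, and a
#' percentile confidence interval from resampling the replicate readings.
#'
#' @param spec A [synthetic_study_spec()].
#' @param curve A precomputed `packing_curve` for the spec's geometry; when
#'   `NULL` one is computed with [sweep_capping()] (one PDE solve per sweep
#'   fraction).
#' @param sweep_fractions Sweep grid used when `curve` is `NULL`.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @param conf Confidence level.
#' @return An object of class `recovery_report`.
#' @export
recovery_experiment <- function(spec, curve = NULL,
                                sweep_fractions = c(seq(0, 1, by = 0.1), 0.64),
                                n_boot = 200L, conf = 0.95) {
  if (!inherits(spec, "synthetic_study_spec")) {
    abort("`spec` must be a synthetic_study_spec", class = "aqpore_invalid")
  }
  if (is.null(curve)) {
    curve <- sweep_capping(spec$geometry, fractions = sweep_fractions,
                           mode = "pore_cap", seed = spec$seed)
  }
  ds <- generate_flux_measurements(spec)
  r <- flux_ratio(ds)
  invert <- function(ratio) {
    ratio <- min(max(ratio, 0), 1)
    estimate_packing(curve, ratio, measured = "flux_ratio")$estimate$value
  }
  est <- invert(r)
  ci <- c(NA_real_, NA_real_)
  if (spec$n_replicates > 1L && n_boot > 0L) {
    boots <- with_rng(spec$seed + 2L, {
      occl <- ds$flux$flux[ds$flux$membrane_variant == "pva_alkyl"]
      ref <- ds$flux$flux[ds$flux$membrane_variant == "aqp_sh"]
      vapply(seq_len(n_boot), function(b) {
        ro <- mean(sample(occl, replace = TRUE)) /
          mean(sample(ref, replace = TRUE))
        invert(ro)
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }
  structure(
    list(true_capping = spec$true_capping$value,
         estimate = est,
         bias = est - spec$true_capping$value,
         flux_ratio = r,
         ci_lo = ci[1], ci_hi = ci[2], conf = conf,
         n_replicates = spec$n_replicates,
         noise_sd_rel = spec$noise_sd_rel,
         seed = spec$seed,
         curve = curve,
         dataset = ds),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> true %.3f, estimated %.3f (bias %+.4f)\n",
              x$true_capping, x$estimate, x$bias))
  if (is.finite(x$ci_lo)) {
    cat(sprintf("  %g%% CI [%.3f, %.3f] from replicate resampling\n",
                100 * x$conf, x$ci_lo, x$ci_hi))
  }
  invisible(x)
}

#' Repeat the recovery experiment over many seeds
#'
#' Reruns [recovery_experiment()] across seeds (reusing one packing curve)
#' and summarizes the estimator: mean bias and mean absolute error of the
#' recovered capping fraction against truth.
#'
#' @param spec A [synthetic_study_spec()]; its seed field is replaced by
#'   each element of `seeds`.
#' @param seeds Integer vector of seeds.
#' @param curve Optional precomputed `packing_curve` (computed once from the
#'   spec geometry when `NULL`).
#' @param sweep_fractions Sweep grid used when `curve` is `NULL`.
#' @return A tibble with one row per seed (`seed`, `true_capping`,
#'   `estimate`, `bias`) carrying `mae` and `mean_bias` attributes.
#' @export
recovery_study <- function(spec, seeds = 1:100, curve = NULL,
                           sweep_fractions = c(seq(0, 1, by = 0.1), 0.64)) {
  if (is.null(curve)) {
    curve <- sweep_capping(spec$geometry, fractions = sweep_fractions,
                           mode = "pore_cap", seed = spec$seed)
  }
  rows <- purrr::map(seeds, function(s) {
    sp <- spec; sp$seed <- as.integer(s)
    rep_ <- recovery_experiment(sp, curve = curve, n_boot = 0L)
    tibble::tibble(seed = s, true_capping = rep_$true_capping,
                   estimate = rep_$estimate, bias = rep_$bias)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mae") <- mean(abs(out$bias))
  attr(out, "mean_bias") <- mean(out$bias)
  out
}
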