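#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an effective-diffusivity result
#'
#' @param x An [effective_diffusivity()] object.
#' @param ... Unused.
#' @return A one-row tibble with `mean_flux`, `de`, `de_ratio`,
#'   `separation`, `separation_nm`, `plane_position`.
#' @method tidy effective_diffusivity
#' @export
tidy.effective_diffusivity <- function(x, ...) {
  tibble::tibble(mean_flux = x$mean_flux, de = x$de, de_ratio = x$ratio,
                 separation = x$separation, separation_nm = x$separation_nm,
                 plane_position = x$plane_position)
}

#' Tidy a packing estimate
#'
#' @param x A [estimate_packing()] result.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, its definition, the measured
#'   ratio and the bracketing interval.
#' @method tidy packing_estimate
#' @export
tidy.packing_estimate <- function(x, ...) {
  tibble::tibble(model = x$model,
                 estimate = x$estimate$value,
                 definition = x$estimate$definition,
                 measured = x$measured,
                 measured_ratio = x$measured_ratio,
                 de_ratio = x$de_ratio,
                 lo = unname(x$bracket["lo"]),
                 hi = unname(x$bracket["hi"]))
}

#' @rdname tidy.packing_estimate
#' @method glance packing_estimate
#' @export
glance.packing_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate$value,
                 bracket_width = unname(diff(x$bracket)),
                 model = x$model)
}

#' Tidy an MWCO determination
#'
#' `tidy()` returns the per-solute rejection table with a column marking
#' which solutes meet the threshold; `glance()` returns the one-row summary.
#'
#' @param x A [determine_mwco()] result.
#' @param ... Unused.
#' @method tidy mwco_result
#' @export
tidy.mwco_result <- function(x, ...) {
  dplyr::mutate(x$records, meets_threshold =
                  .data$rejection_pct >= x$threshold_pct)
}

#' @rdname tidy.mwco_result
#' @method glance mwco_result
#' @export
glance.mwco_result <- function(x, ...) {
  tibble::tibble(
    mwco = x$mwco,
    defining_solute = if (is.null(x$defining_solute)) NA_character_ else
      x$defining_solute$solute,
    threshold_pct = x$threshold_pct,
    status = x$status)
}

#' Tidy a parameter-recovery report
#'
#' @param x A [recovery_experiment()] result.
#' @param ... Unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  tibble::tibble(seed = x$seed,
                 true_capping = x$true_capping,
                 estimate = x$estimate,
                 bias = x$bias,
                 flux_ratio = x$flux_ratio,
                 ci_lo = x$ci_lo, ci_hi = x$ci_hi,
                 n_replicates = x$n_replicates,
                 noise_sd_rel = x$noise_sd_rel)
}
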