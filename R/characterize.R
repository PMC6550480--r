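#' Neutral-solute probe series for MWCO analysis
#'
#' The standard polyethylene-glycol and sucrose probe series used to bracket
#' a nanofiltration membrane's molecular weight cut-off, with their
#' Stokes-Einstein radii.
#'
#' @return A tibble with columns `solute`, `molecular_weight` (g/mol) and
#'   `stokes_radius` (nm).
#' @examples
#' mwco_solutes()
#' @export
mwco_solutes <- function() {
  tibble::tibble(
    solute = c("PEG 200", "Sucrose", "PEG 400", "PEG 600", "PEG 1000"),
    molecular_weight = c(200, 342.3, 400, 600, 1000),
    stokes_radius = c(0.41, 0.47, 0.57, 0.68, 0.94))
}

#' Apparent solute rejection
#'
#' `R = (1 - c_permeate / c_feed) * 100` percent.  Negative computed
#' rejections (permeate above feed, which measurement noise can produce) are
#' clamped to 0 with a warning.  Vectorized; feed and permeate must be in
#' the same concentration unit.
#'
#' @param c_feed Feed concentration(s), strictly positive.
#' @param c_permeate Permeate concentration(s), non-negative.
#' @return Rejection percent(s) in \[0, 100\].
#' @examples
#' rejection(100, 25) # 75
#' @export
rejection <- function(c_feed, c_permeate) {
  if (!is.numeric(c_feed) || !is.numeric(c_permeate)) {
    abort("concentrations must be numeric", class = "aqpore_invalid")
  }
  n <- max(length(c_feed), length(c_permeate))
  c_feed <- rep_len(c_feed, n); c_permeate <- rep_len(c_permeate, n)
  if (any(!is.finite(c_feed)) || any(c_feed <= 0)) {
    abort("invariant violated: c_feed must be strictly positive",
          class = "aqpore_invalid")
  }
  if (any(c_permeate < 0)) {
    abort("invariant violated: c_permeate must be non-negative",
          class = "aqpore_invalid")
  }
  r <- (1 - c_permeate / c_feed) * 100
  if (any(r < 0)) {
    warn(sprintf("%d rejection value(s) were negative (permeate above feed) and were clamped to 0",
                 sum(r < 0)))
    r <- pmax(r, 0)
  }
  r
}

#' Determine the molecular weight cut-off from a rejection profile
#'
#' Applies the standard 90%-rejection rule: the MWCO is the molecular weight
#' of the lightest tested solute rejected at or above the threshold.  If
#' every tested solute meets the threshold the cut-off lies at or below the
#' lightest tested solute and the result is flagged accordingly; if none
#' does, the result records that no MWCO lies within the tested range.
#'
#' @param records A data frame with columns `solute`, `molecular_weight` and
#'   either `rejection_pct` or both `c_feed` and `c_permeate` (from which
#'   rejection is computed).  Row order is irrelevant.
#' @param threshold Rejection threshold in percent (default 90; comparison
#'   is `>=`).
#' @return An object of class `mwco_result` with fields `mwco` (g/mol, `NA`
#'   when none), `defining_solute`, `threshold_pct`, `status` (one of
#'   `"determined"`, `"at_or_below_lightest"`, `"not_within_tested_range"`).
#' @examples
#' profile <- tibble::tibble(
#'   solute = c("PEG 200", "PEG 400", "PEG 600", "PEG 1000"),
#'   molecular_weight = c(200, 400, 600, 1000),
#'   rejection_pct = c(40, 65, 84, 94.2))
#' determine_mwco(profile)
#' @export
determine_mwco <- function(records, threshold = 90) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    abort("`records` must be non-empty", class = "aqpore_invalid")
  }
  if (!all(c("solute", "molecular_weight") %in% names(records))) {
    abort("`records` needs columns `solute` and `molecular_weight`",
          class = "aqpore_invalid")
  }
  if (!"rejection_pct" %in% names(records)) {
    if (!all(c("c_feed", "c_permeate") %in% names(records))) {
      abort("`records` needs `rejection_pct` or both `c_feed` and `c_permeate`",
            class = "aqpore_invalid")
    }
    records$rejection_pct <- rejection(records$c_feed, records$c_permeate)
  }
  if (any(records$rejection_pct < 0 | records$rejection_pct > 100)) {
    abort("invariant violated: rejection_pct must lie in [0, 100]",
          class = "aqpore_invalid")
  }
  records <- dplyr::arrange(records, .data$molecular_weight)
  meets <- records$rejection_pct >= threshold
  if (!any(meets)) {
    res <- list(mwco = NA_real_, defining_solute = NULL,
                threshold_pct = threshold,
                status = "not_within_tested_range", records = records)
    return(structure(res, class = "mwco_result"))
  }
  i <- which(meets)[1]
  status <- if (all(meets)) "at_or_below_lightest" else "determined"
  structure(
    list(mwco = records$molecular_weight[i],
         defining_solute = as.list(records[i, ]),
         threshold_pct = threshold,
         status = status,
         records = records),
    class = "mwco_result")
}

#' @export
print.mwco_result <- function(x, ...) {
  if (x$status == "not_within_tested_range") {
    cat(sprintf("<mwco_result> no MWCO within tested range (threshold %g%%)\n",
                x$threshold_pct))
  } else {
    flag <- if (x$status == "at_or_below_lightest") " (at or below lightest tested solute)" else ""
    cat(sprintf("<mwco_result> MWCO %g g/mol, defined by %s at %.1f%% rejection%s\n",
                x$mwco, x$defining_solute$solute,
                x$defining_solute$rejection_pct, flag))
  }
  invisible(x)
}

#' Stokes-Einstein radius of a neutral probe solute
#'
#' Exact lookup in the tabulated PEG/sucrose series; molecular weights
#' between tabulated entries are log-log interpolated between the
#' neighbouring probes (with a warning flagging the interpolation).  Weights
#' outside the tabulated range error unless `extrapolate = TRUE`, in which
#' case the outer log-log segment is extended.
#'
#' @param molecular_weight Molecular weight(s) in g/mol.
#' @param extrapolate Allow extrapolation beyond the tabulated series.
#' @return Stokes radius (nm), with attribute `interpolated` marking entries
#'   that were not exact table lookups.
#' @examples
#' stokes_radius(1000) # 0.94 nm
#' @export
stokes_radius <- function(molecular_weight, extrapolate = FALSE) {
  tab <- mwco_solutes()
  if (!is.numeric(molecular_weight) || any(molecular_weight <= 0)) {
    abort("`molecular_weight` must be positive", class = "aqpore_invalid")
  }
  lo <- min(tab$molecular_weight); hi <- max(tab$molecular_weight)
  out_of_range <- molecular_weight < lo | molecular_weight > hi
  if (any(out_of_range) && !extrapolate) {
    abort(sprintf(paste0("molecular weight(s) %s outside the tabulated series ",
                         "[%g, %g]; set extrapolate = TRUE to extend the ",
                         "outer log-log segment"),
                  paste(molecular_weight[out_of_range], collapse = ", "),
                  lo, hi), class = "aqpore_extrapolation")
  }
  exact <- match(molecular_weight, tab$molecular_weight)
  r <- tab$stokes_radius[exact]
  miss <- is.na(exact)
  if (any(miss)) {
    li <- stats::approx(log(tab$molecular_weight), log(tab$stokes_radius),
                        xout = log(molecular_weight[miss]), rule = 2)$y
    if (extrapolate && any(out_of_range)) {
      ## extend the outer segments instead of clamping
      extend <- function(mw) {
        x <- log(tab$molecular_weight); y <- log(tab$stokes_radius)
        if (mw < lo) y[1] + (log(mw) - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
        else y[length(y)] + (log(mw) - x[length(x)]) *
          (y[length(y)] - y[length(y) - 1]) / (x[length(x)] - x[length(x) - 1])
      }
      oor <- out_of_range[miss]
      li[oor] <- vapply(molecular_weight[miss][oor], extend, numeric(1))
    }
    r[miss] <- exp(li)
    warn(sprintf("Stokes radius log-log interpolated for %d molecular weight(s) not in the tabulated series",
                 sum(miss)))
  }
  attr(r, "interpolated") <- miss
  r
}
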