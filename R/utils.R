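#' @importFrom rlang abort warn inform %||%
NULL

## Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## round-half-up, so k = round_half_up(f * n) is independent of the platform's
## round-half-to-even convention
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "aqpore_invalid")
  }
  if (positive && x <= 0) {
    abort(sprintf("invariant violated: `%s` must be strictly positive (got %g)",
                  name, x), class = "aqpore_invalid")
  }
  if (nonneg && x < 0) {
    abort(sprintf("invariant violated: `%s` must be non-negative (got %g)",
                  name, x), class = "aqpore_invalid")
  }
  invisible(x)
}

## numeric formatting used by all CSV writers: 10 significant digits, '.' decimal
format_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
}

## write a data frame as UTF-8 CSV with numerics at 10 significant digits
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
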