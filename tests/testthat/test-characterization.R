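test_that("rejection formula reproduces its arithmetic identities", {
  expect_equal(rejection(100, 0), 100)
  expect_equal(rejection(50, 50), 0)
  expect_equal(rejection(100, 25), 75)
  expect_equal(rejection(c(100, 200), c(10, 30)), c(90, 85))
  expect_error(rejection(0, 1), class = "aqpore_invalid")
  expect_error(rejection(-5, 1), class = "aqpore_invalid")
  expect_error(rejection(10, -1), class = "aqpore_invalid")
})

test_that("negative rejections clamp to zero with a warning", {
  expect_warning(r <- rejection(100, 120), "clamped")
  expect_equal(r, 0)
})

test_that("rejection is antitone in permeate concentration", {
  cp <- sort(runif(20, 0, 100))
  r <- rejection(100, cp)
  expect_true(all(diff(r) <= 0))
})

test_that("the 90% rule assigns the printed cut-offs to the bench profiles", {
  ## unmodified PBI: PEG 1000 at 94.2% is the only solute above threshold
  unmodified <- tibble::tibble(
    solute = c("PEG 200", "Sucrose", "PEG 400", "PEG 600", "PEG 1000"),
    molecular_weight = c(200, 342.3, 400, 600, 1000),
    rejection_pct = c(35, 48, 62, 81, 94.2))
  res <- determine_mwco(unmodified)
  expect_equal(res$mwco, 1000)
  expect_equal(res$status, "determined")
  expect_equal(res$defining_solute$solute, "PEG 1000")

  ## PVA-alkyl modified: PEG 600 at 91.3% is the lightest above threshold
  pva <- tibble::tibble(
    solute = c("PEG 200", "Sucrose", "PEG 400", "PEG 600", "PEG 1000"),
    molecular_weight = c(200, 342.3, 400, 600, 1000),
    rejection_pct = c(42, 55, 74, 91.3, 96))
  res_pva <- determine_mwco(pva)
  expect_equal(res_pva$mwco, 600)
  expect_equal(glance(res_pva)$defining_solute, "PEG 600")

  ## threshold comparison is >=: a solute at exactly 90% defines the cut-off
  exactly <- dplyr::mutate(pva, rejection_pct =
                             replace(rejection_pct, 4, 90))
  expect_equal(determine_mwco(exactly)$mwco, 600)
})

test_that("MWCO determination is invariant to record ordering", {
  prof <- tibble::tibble(
    solute = c("PEG 1000", "PEG 200", "PEG 600", "PEG 400", "Sucrose"),
    molecular_weight = c(1000, 200, 600, 400, 342.3),
    rejection_pct = c(96, 42, 91.3, 74, 55))
  shuffled <- prof[c(3, 1, 5, 2, 4), ]
  expect_equal(glance(determine_mwco(prof)), glance(determine_mwco(shuffled)))
})

test_that("uniformly high and uniformly low profiles carry explicit flags", {
  ## aquaporin-modified membrane: every tested solute above 95%
  aqp <- tibble::tibble(
    solute = c("PEG 200", "Sucrose", "PEG 400", "PEG 600", "PEG 1000"),
    molecular_weight = c(200, 342.3, 400, 600, 1000),
    rejection_pct = c(95.2, 97.2, 98.4, 100, 100))
  res <- determine_mwco(aqp)
  expect_equal(res$status, "at_or_below_lightest")
  expect_equal(res$mwco, 200)

  low <- dplyr::mutate(aqp, rejection_pct = rejection_pct - 50)
  res_low <- determine_mwco(low)
  expect_equal(res_low$status, "not_within_tested_range")
  expect_true(is.na(res_low$mwco))
})

test_that("MWCO accepts feed/permeate pairs and computes rejection itself", {
  recs <- tibble::tibble(
    solute = c("PEG 400", "PEG 1000"),
    molecular_weight = c(400, 1000),
    c_feed = c(100, 100),
    c_permeate = c(40, 5))
  res <- determine_mwco(recs)
  expect_equal(res$mwco, 1000)
  expect_equal(res$records$rejection_pct, c(60, 95))
})

test_that("Stokes radii come from the tabulated probe series", {
  expect_equal(stokes_radius(1000), 0.94, ignore_attr = TRUE)
  expect_equal(stokes_radius(200), 0.41, ignore_attr = TRUE)
  expect_equal(stokes_radius(342.3), 0.47, ignore_attr = TRUE)
  expect_equal(stokes_radius(c(400, 600)), c(0.57, 0.68), ignore_attr = TRUE)
  ## the tabulated series is monotone in molecular weight
  tab <- mwco_solutes()
  expect_true(all(diff(tab$stokes_radius) >= 0))
  expect_true(all(diff(tab$molecular_weight) > 0))
})

test_that("untabulated weights interpolate log-log with a flag; extrapolation errs", {
  expect_warning(r <- stokes_radius(500), "interpolated")
  expect_true(attr(r, "interpolated"))
  expect_gt(r[1], 0.57)
  expect_lt(r[1], 0.68)
  expect_error(stokes_radius(5000), "extrapolate", class = "aqpore_extrapolation")
  expect_warning(r2 <- stokes_radius(5000, extrapolate = TRUE), "interpolated")
  expect_gt(r2[1], 0.94)
})
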