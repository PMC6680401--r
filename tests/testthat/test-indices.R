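test_that("index formulas are exact ratios of the defining measurements", {
  herd <- make_herd(1, BL = 71.20, CG = 84.07, BW = 21.88, CD = 30.31,
                    HW = 11.56, HL = 15.66, RW = 15.61, RL = 18.81,
                    WH = 70.12, CBP = 8.49)
  idx <- compute_indices(herd)
  expect_equal(idx$coi, 71.20 * 100 / 84.07)          # 84.69
  expect_equal(round(idx$coi, 2), 84.69)
  expect_equal(round(idx$mti, 2), 10.10)              # 8.49*100/84.07
  expect_equal(idx$thi, 21.88 * 100 / 30.31)
  expect_equal(idx$cei, 11.56 * 100 / 15.66)
  expect_equal(idx$pei, 15.61 * 100 / 18.81)
  expect_equal(idx$pri, 70.12 * 100 / 71.20)
  expect_equal(idx$rdi, 30.31 * 100 / 70.12)
  expect_equal(idx$tpi, 15.61 * 100 / 70.12)
  expect_equal(idx$lpi, 18.81 * 100 / 70.12)
})

test_that("identical measurements give identity ratios of 100", {
  herd <- make_herd(1)
  for (v in zoo_variables()) herd[[v]] <- 100
  idx <- compute_indices(herd)
  for (code in c("coi", "thi", "cei", "pei", "pri", "mti", "rdi",
                 "tpi", "lpi")) {
    expect_equal(idx[[code]], 100)
  }
})

test_that("indices are invariant to rescaling an animal's measurements", {
  herd <- simulate_herd(herd_sim_spec(n_animals = 20, seed = 12))
  scaled <- herd
  for (v in zoo_variables()) scaled[[v]] <- scaled[[v]] * 2.5
  expect_equal(compute_indices(scaled)[-(1:2)],
               compute_indices(herd)[-(1:2)], tolerance = 1e-12)
})

test_that("cephalic classification is consistent with HW vs HL", {
  herd <- simulate_herd(herd_sim_spec(n_animals = 100, seed = 13))
  idx <- classify_indices(compute_indices(herd))
  expect_identical(idx$cei < 100, herd$HW < herd$HL)
  expect_identical(idx$cei_class == "dolichocephalic", herd$HW < herd$HL)
})

test_that("classification reproduces the reference population calls", {
  prof <- tibble::tibble(coi = 85.11, thi = 71.98, cei = 74.29, pei = 83.75,
                         pri = 98.98, mti = 10.14, rdi = 43.27, tpi = 22.30,
                         lpi = 26.87)
  cl <- classify_indices(prof)
  expect_identical(cl$coi_class, "brevilinear")
  expect_true(cl$coi_gap)  # 85.11 sits in the published (85, 86) gap
  expect_identical(cl$thi_class, "elliptical_dairy")
  expect_identical(cl$cei_class, "dolichocephalic")
  expect_identical(cl$pei_class, "convexilinear")
  expect_identical(cl$pri_class, "square_dairy")
  expect_identical(cl$mti_class, "eumetric")
  expect_identical(cl$rdi_class, "dairy_type")
  expect_identical(cl$meat_indicator_count, 1L)  # LPI < 37 only
  expect_identical(cl$meat_tendency, "medium_tendency")
})

test_that("class boundaries and gaps behave as documented", {
  mk <- function(coi = 80, thi = 80, mti = 10.5, tpi = 22, lpi = 27) {
    tibble::tibble(coi = coi, thi = thi, cei = 90, pei = 90, pri = 98,
                   mti = mti, rdi = 45, tpi = tpi, lpi = lpi)
  }
  cl <- classify_indices(mk(coi = c(84, 85, 85.5, 86.5, 88, 89.5, 90)))
  expect_identical(cl$coi_class,
                   c("brevilinear", "brevilinear", "brevilinear",
                     "mesolinear", "mesolinear", "longilinear",
                     "longilinear"))
  expect_identical(cl$coi_gap, c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                                 FALSE))

  cl2 <- classify_indices(mk(thi = c(85, 87, 89)))
  expect_identical(cl2$thi_class, c("elliptical_dairy", "elliptical_dairy",
                                    "circular_meat"))
  expect_identical(cl2$thi_gap, c(FALSE, TRUE, FALSE))

  cl3 <- classify_indices(mk(mti = c(9.9, 10, 10.14, 11, 11.1)))
  expect_identical(cl3$mti_class, c("ellipometric", "eumetric", "eumetric",
                                    "eumetric", "hypermetric"))

  cl4 <- classify_indices(mk(tpi = c(34, 30, 34), lpi = c(30, 38, 38)))
  expect_identical(cl4$meat_indicator_count, c(2L, 0L, 1L))
  expect_identical(cl4$meat_tendency,
                   c("meat_leaning", "dairy_leaning", "medium_tendency"))
})

test_that("index table averages per-animal ratios, not ratios of means", {
  herd <- simulate_herd(herd_sim_spec(n_animals = 500, seed = 14))
  it <- index_table(herd)
  coi_mor <- it$mean[it$index == "coi"]
  expect_equal(coi_mor, mean(compute_indices(herd)$coi))
  coi_rom <- mean(herd$BL) * 100 / mean(herd$CG)
  expect_false(isTRUE(all.equal(coi_mor, coi_rom)))
  # Jensen direction for a ratio with positively correlated terms:
  # averaging per-animal ratios exceeds the ratio of the averages
  expect_gt(coi_mor, coi_rom)
})

test_that("degenerate herds are handled explicitly", {
  expect_error(index_table(make_herd(1)), "at least 2")
  herd <- make_herd(4)
  for (v in zoo_variables()) herd[[v]] <- rep(12, 4)
  it <- suppressWarnings(index_table(herd))
  expect_true(all(it$sd == 0))
})
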