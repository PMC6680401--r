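test_that("spearman matrix recovers monotone relationships exactly", {
  herd <- make_herd(10)
  herd$WH <- 1:10 + 50
  herd$RH <- (1:10)^2 + 50      # monotone increasing in WH
  herd$BL <- 60 - (1:10) / 2    # monotone decreasing
  sm <- spearman_matrix(herd)
  cell <- function(a, b) sm[sm$var1 == a & sm$var2 == b, ]
  expect_equal(cell("WH", "RH")$rho, 1)
  expect_equal(cell("WH", "BL")$rho, -1)
  expect_equal(cell("WH", "RH")$p_value, 0)
})

test_that("midranks agree with the hand-ranked oracle and stats::cor", {
  x <- c(1, 2, 2, 4, 5)
  y <- c(10, 9, 9, 2, 1)
  herd <- make_herd(5, HW = x, HL = y)
  sm <- spearman_matrix(herd)
  rho <- sm$rho[sm$var1 == "HW" & sm$var2 == "HL"]
  # midranks: x -> (1, 2.5, 2.5, 4, 5), y -> (5, 3.5, 3.5, 2, 1);
  # centred rank vectors are exact negatives, so Pearson on ranks = -1
  expect_equal(rho, -1)
  expect_equal(rho, cor(x, y, method = "spearman"))

  # no-ties case: classical d^2 formula as independent oracle
  set.seed(31)
  for (rep in 1:5) {
    a <- sample(100, 12)
    b <- sample(100, 12)
    herd2 <- make_herd(12, CG = a + 10, CD = b + 10)
    sm2 <- spearman_matrix(herd2)
    got <- sm2$rho[sm2$var1 == "CG" & sm2$var2 == "CD"]
    expect_equal(got, oracle_spearman_noties(a, b), tolerance = 1e-12)
    expect_equal(got, cor(a, b, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("rank correlations survive strictly monotone transforms", {
  herd <- simulate_herd(herd_sim_spec(n_animals = 80, seed = 21))
  warped <- herd
  warped$WH <- exp(warped$WH / 20)
  warped$CG <- sqrt(warped$CG)
  warped$HL <- warped$HL^3
  expect_equal(spearman_matrix(warped)$rho, spearman_matrix(herd)$rho,
               tolerance = 1e-12)
})

test_that("harmony score matches the brute-force pair count", {
  set.seed(41)
  for (rep in 1:10) {
    cells <- tibble::tibble(
      var1 = "a", var2 = "b",
      rho = round(runif(40, -1, 1), 2),
      p_value = runif(40)
    )
    rep_score <- harmony_score(cells)
    expect_identical(rep_score$n_positive_significant,
                     oracle_harmony_count(cells))
    expect_equal(rep_score$harmony_percent,
                 100 * oracle_harmony_count(cells) / nrow(cells))
  }
})

test_that("the reference correlation matrix scores 91.21% and high", {
  rep <- harmony_score(ref_correlation_matrix())
  expect_identical(rep$n_pairs, 91L)
  expect_identical(rep$n_positive_significant, 83L)
  expect_equal(round(rep$harmony_percent, 2), 91.21)
  expect_identical(rep$model, "high")

  # the starred negative cell is excluded despite its significance
  ref <- ref_correlation_matrix()
  neg <- ref[ref$rho < 0, ]
  expect_identical(nrow(neg), 1L)
  expect_identical(neg$stars, "***")
  only_neg <- harmony_score(neg)
  expect_identical(only_neg$n_positive_significant, 0L)
})

test_that("all-significant positive matrices score 100%", {
  cells <- tibble::tibble(var1 = "a", var2 = "b", rho = runif(20, 0.1, 0.9),
                          stars = "***")
  expect_equal(harmony_score(cells)$harmony_percent, 100)
})

test_that("undefined cells stay in the denominator only", {
  cells <- tibble::tibble(
    var1 = "a", var2 = "b",
    rho = c(0.5, NA, 0.7, -0.2),
    p_value = c(0.001, NA, 0.2, 0.001)
  )
  rep <- harmony_score(cells)
  expect_identical(rep$n_pairs, 4L)
  expect_identical(rep$n_positive_significant, 1L)
})

test_that("harmony model bands follow the adopted interpretation", {
  expect_identical(harmony_model(91.21), "high")
  expect_identical(harmony_model(50.1), "high")
  expect_identical(harmony_model(50), "medium")
  expect_identical(harmony_model(40), "medium")
  expect_identical(harmony_model(25.1), "medium")
  expect_identical(harmony_model(25), "low")
  expect_identical(harmony_model(0), "low")
})

test_that("normality screen accepts exact normal quantiles", {
  n <- 100
  herd <- make_herd(n)
  vs <- ref_variable_stats()
  for (i in seq_along(vs$variable)) {
    herd[[vs$variable[i]]] <-
      qnorm((1:n - 0.5) / n, vs$mean[i], vs$sd[i])
  }
  screen <- normality_screen(herd)
  expect_false(any(screen$reject))
  expect_identical(attr(screen, "recommended_method"), "pearson")
})

test_that("normality screen skips constant variables with a flag", {
  herd <- make_herd(20, SW = rep(15, 20))
  herd$WH <- herd$WH + runif(20)  # ensure others vary
  expect_warning(screen <- normality_screen(herd), "SW")
  expect_true(screen$skipped[screen$variable == "SW"])
  expect_true(is.na(screen$p_value[screen$variable == "SW"]))
})

test_that("tidy and glance expose the harmony report", {
  rep <- harmony_score(ref_correlation_matrix())
  td <- tidy(rep)
  expect_identical(td$n_positive_significant, 83L)
  expect_identical(glance(rep)$model, "high")
})
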