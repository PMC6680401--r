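# Morphological harmony: the share of variable pairs whose rank correlation
# is positive and significant. A population whose measurements rise and fall
# together ("harmonic") keeps its conformation proportional; above 50% of
# positive significant pairs the morphostructural model is called highly
# harmonic.

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of each measurement against a normal distribution with
#' that variable's sample mean and SD. If any variable rejects at `alpha`,
#' rank (Spearman) correlation is recommended; the pipeline default is
#' Spearman regardless, so the recommendation is advisory.
#'
#' @param herd A herd data frame (at least 8 records).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `variable`, `statistic`, `p_value`, `reject`,
#'   `skipped` (zero-variance variables are skipped and flagged); attribute
#'   `recommended_method` is `"spearman"` or `"pearson"`.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(seed = 1, noise_shape = "skewed"))
#' normality_screen(herd)
#' @export
normality_screen <- function(herd, alpha = 0.05) {
  herd <- validate_herd(herd, min_records = 8)
  stopifnot(alpha > 0, alpha < 1)
  rows <- purrr::map(zoo_variables(), function(v) {
    x <- herd[[v]]
    if (sd(x) == 0) {
      return(tibble::tibble(variable = v, statistic = NA_real_,
                            p_value = NA_real_, reject = NA, skipped = TRUE))
    }
    # measurement data are recorded to fixed precision, so ties are expected
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    tibble::tibble(variable = v, statistic = unname(kt$statistic),
                   p_value = kt$p.value, reject = kt$p.value < alpha,
                   skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$skipped)) {
    warn(paste0("Normality screen skipped for zero-variance variable(s): ",
                paste(out$variable[out$skipped], collapse = ", ")))
  }
  attr(out, "recommended_method") <-
    if (any(out$reject, na.rm = TRUE)) "spearman" else "pearson"
  out
}

stars_from_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# Spearman rho for two vectors via midranks; p from the t approximation
# with n - 2 degrees of freedom
spearman_pair <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(c(rho = NA_real_, p_value = NA_real_))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  c(rho = rho, p_value = p)
}

#' Spearman correlation matrix of a herd
#'
#' Rank correlation for all unordered pairs of the fourteen measurements:
#' midrank (average-rank) treatment of ties, rho as the linear correlation
#' of the ranks, two-sided p-value from the t approximation with n - 2
#' degrees of freedom. Pairs involving a zero-rank-variance variable are
#' returned with `NA` and flagged.
#'
#' @param herd A herd data frame (at least 5 records).
#' @return A tibble with `var1`, `var2`, `rho`, `p_value`, `stars`
#'   (91 rows for 14 variables); attribute `n` is the record count.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(seed = 1))
#' spearman_matrix(herd)
#' @export
spearman_matrix <- function(herd) {
  herd <- validate_herd(herd, min_records = 5)
  v <- zoo_variables()
  pairs <- utils::combn(v, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sp <- spearman_pair(herd[[a]], herd[[b]])
    tibble::tibble(var1 = a, var2 = b, rho = sp[["rho"]],
                   p_value = sp[["p_value"]])
  })
  out <- dplyr::bind_rows(rows)
  out$stars <- stars_from_p(out$p_value)
  if (anyNA(out$rho)) {
    warn("Some correlation cells are undefined (zero rank variance).")
  }
  attr(out, "n") <- nrow(herd)
  out
}

cell_significant <- function(cells, alpha) {
  if ("p_value" %in% names(cells) && !all(is.na(cells$p_value))) {
    cells$p_value < alpha
  } else {
    # printed matrices carry stars, not p-values: any star = significant
    !is.na(cells$stars) & cells$stars != ""
  }
}

#' Morphological harmony score
#'
#' Counts the variable pairs whose correlation is strictly positive and
#' significant, as a percentage of all pairs. Significance comes from the
#' `p_value` column when present (computed matrices) and from the
#' significance stars otherwise (printed matrices). Undefined cells stay in
#' the denominator, never the numerator. A negative or zero coefficient
#' never counts, whatever its p-value.
#'
#' @param cells A correlation tibble from [spearman_matrix()] or
#'   [ref_correlation_matrix()].
#' @param alpha Significance level for p-value-based matrices.
#' @return A `harmony_report`: list with `n_pairs`,
#'   `n_positive_significant`, `harmony_percent`, `model`.
#' @examples
#' harmony_score(ref_correlation_matrix()) # 83/91 = 91.21%, model "high"
#' @export
harmony_score <- function(cells, alpha = 0.05) {
  stopifnot(is.data.frame(cells),
            all(c("var1", "var2", "rho") %in% names(cells)))
  sig <- cell_significant(cells, alpha)
  pos_sig <- !is.na(cells$rho) & cells$rho > 0 & !is.na(sig) & sig
  pct <- 100 * sum(pos_sig) / nrow(cells)
  structure(
    list(
      n_pairs = nrow(cells),
      n_positive_significant = sum(pos_sig),
      harmony_percent = pct,
      model = harmony_model(pct),
      alpha = alpha
    ),
    class = "harmony_report"
  )
}

#' Harmony model classification
#'
#' Maps the percentage of positive significant correlations to the
#' morphostructural model: `high` above 50%, `low` at or below 25%,
#' `medium` between. The middle band is an interpretation: the published
#' rule calls a model medium when the share is "close to 50%" without
#' defining closeness, so the whole interval (25, 50\] is used.
#'
#' @param x A `harmony_report` or a percentage in \[0, 100\].
#' @return `"high"`, `"medium"` or `"low"`.
#' @examples
#' harmony_model(91.21) # "high"
#' harmony_model(40)    # "medium"
#' @export
harmony_model <- function(x) {
  if (inherits(x, "harmony_report")) x <- x$harmony_percent
  stopifnot(is.numeric(x), length(x) == 1, x >= 0, x <= 100)
  if (x > 50) "high" else if (x > 25) "medium" else "low"
}

#' @export
print.harmony_report <- function(x, ...) {
  cat("Morphological harmony report\n")
  cat(sprintf("  positive significant pairs: %d of %d (%.2f%%)\n",
              x$n_positive_significant, x$n_pairs, x$harmony_percent))
  cat(sprintf("  harmonic model: %s (alpha = %g)\n", x$model, x$alpha))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.harmony_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_positive_significant = x$n_positive_significant,
    harmony_percent = x$harmony_percent,
    model = x$model
  )
}

#' @exportS3Method generics::glance
glance.harmony_report <- function(x, ...) tidy(x)
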