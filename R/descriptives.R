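# Table-style descriptive statistics and the coefficient-of-variation
# homogeneity reading used in morphostructural characterization: CV below
# 10% marks a homogeneous trait, above 30% data too imprecise to keep.

#' Per-variable descriptive statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation (percent), minimum and maximum for each of the fourteen
#' measurements, pooled over all animals.
#'
#' @param herd A herd data frame (at least 2 records).
#' @return A tibble with columns `variable`, `mean`, `sd`, `cv`, `min`,
#'   `max`, `n`, one row per variable in canonical order. A zero-variance
#'   variable gets `cv = 0` and `zero_variance = TRUE`.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(seed = 1))
#' herd_summary(herd)
#' @export
herd_summary <- function(herd) {
  herd <- validate_herd(herd, min_records = 2)
  long <- tidyr::pivot_longer(herd, cols = dplyr::all_of(zoo_variables()),
                              names_to = "variable", values_to = "value")
  out <- long |>
    dplyr::group_by(variable = factor(.data$variable, levels = zoo_variables())) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$variable) |>
    dplyr::mutate(
      variable = as.character(.data$variable),
      zero_variance = .data$sd == 0,
      cv = dplyr::if_else(.data$sd == 0, 0, 100 * .data$sd / .data$mean)
    ) |>
    dplyr::select("variable", "mean", "sd", "cv", "min", "max", "n",
                  "zero_variance")
  if (any(out$zero_variance)) {
    warn(paste0("Zero-variance variable(s): ",
                paste(out$variable[out$zero_variance], collapse = ", "),
                "; cv reported as 0."))
  }
  out
}

#' Coefficient-of-variation homogeneity screen
#'
#' Labels each variable by its CV: `homogeneous` strictly below
#' `low_threshold`, `discard_candidate` strictly above `discard_threshold`,
#' `intermediate` otherwise.
#'
#' @param rows A summary tibble with columns `variable` and `cv`
#'   (e.g. from [herd_summary()] or [ref_variable_stats()]).
#' @param low_threshold CV percent below which a trait counts as
#'   homogeneous (default 10).
#' @param discard_threshold CV percent above which precision is considered
#'   too low to keep the variable (default 30).
#' @return The input with a `homogeneity` factor column added; attributes
#'   `n_homogeneous` and `n_discard` carry the label counts.
#' @examples
#' screen <- homogeneity_screen(ref_variable_stats())
#' attr(screen, "n_homogeneous") # 10 of 14 in the reference population
#' @export
homogeneity_screen <- function(rows, low_threshold = 10,
                               discard_threshold = 30) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0,
            all(c("variable", "cv") %in% names(rows)),
            low_threshold < discard_threshold)
  out <- dplyr::mutate(
    tibble::as_tibble(rows),
    homogeneity = factor(
      dplyr::case_when(
        .data$cv < low_threshold ~ "homogeneous",
        .data$cv > discard_threshold ~ "discard_candidate",
        TRUE ~ "intermediate"
      ),
      levels = c("homogeneous", "intermediate", "discard_candidate")
    )
  )
  attr(out, "n_homogeneous") <- sum(out$homogeneity == "homogeneous")
  attr(out, "n_discard") <- sum(out$homogeneity == "discard_candidate")
  out
}
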