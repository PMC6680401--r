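# Published reference tables for the Black Creole goat study population
# (n = 226 adults from eight localities in central Mexico), shipped as
# plain-text fixtures. They parameterize the synthetic-herd generator and
# let the headline analyses be reproduced without the raw field data, which
# were never deposited.

ref_path <- function(file) {
  system.file("extdata", file, package = "zoomorph", mustWork = TRUE)
}

read_ref_csv <- function(file) {
  readr::read_csv(ref_path(file), show_col_types = FALSE, progress = FALSE)
}

#' Reference descriptive statistics of the study population
#'
#' Per-variable mean, standard deviation, coefficient of variation (percent),
#' minimum and maximum (all lengths in cm) for the fourteen measurements of
#' the Black Creole goat reference population.
#'
#' @return A tibble with columns `variable`, `mean`, `sd`, `cv`, `min`, `max`.
#' @examples
#' ref_variable_stats()
#' @export
ref_variable_stats <- function() {
  out <- read_ref_csv("bcg_variable_stats.csv")
  out$variable <- factor(out$variable, levels = zoo_variables())
  dplyr::arrange(out, .data$variable) |>
    dplyr::mutate(variable = as.character(.data$variable))
}

#' Reference Spearman correlation matrix
#'
#' The pairwise Spearman rank correlations among the fourteen measurements of
#' the reference population, with their published significance stars
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001; `""` not significant).
#'
#' @param as_matrix If `TRUE`, return the 14 x 14 symmetric numeric matrix
#'   (unit diagonal) instead of the long tibble.
#' @return A tibble with columns `var1`, `var2`, `rho`, `stars` (one row per
#'   unordered pair, 91 rows), or a symmetric matrix when `as_matrix = TRUE`.
#' @examples
#' ref_correlation_matrix()
#' ref_correlation_matrix(as_matrix = TRUE)["HL", "FL"]
#' @export
ref_correlation_matrix <- function(as_matrix = FALSE) {
  long <- readr::read_csv(ref_path("bcg_spearman.csv"),
                          col_types = "ccdc", na = character(),
                          progress = FALSE)
  long$stars[is.na(long$stars)] <- ""
  if (!as_matrix) return(long)
  pairs_to_matrix(long, value = "rho")
}

# long (var1, var2, value) -> symmetric matrix in canonical variable order
pairs_to_matrix <- function(long, value, diag = 1) {
  v <- zoo_variables()
  m <- matrix(NA_real_, length(v), length(v), dimnames = list(v, v))
  diag(m) <- diag
  for (i in seq_len(nrow(long))) {
    m[long$var1[i], long$var2[i]] <- long[[value]][i]
    m[long$var2[i], long$var1[i]] <- long[[value]][i]
  }
  m
}

#' Reference principal-component loadings and eigenvalues
#'
#' Loadings of the fourteen measurements on the three retained principal
#' components of the reference population's correlation-matrix PCA, their
#' published communalities, and the component eigenvalues with percent
#' variance.
#'
#' @return A list with elements `loadings` (tibble: `variable`, `pc1`, `pc2`,
#'   `pc3`, `communality`) and `components` (tibble: `component`,
#'   `eigenvalue`, `pct_variance`).
#' @examples
#' ref_pca()$components
#' @export
ref_pca <- function() {
  list(
    loadings = read_ref_csv("bcg_pca_loadings.csv"),
    components = read_ref_csv("bcg_pca_components.csv")
  )
}

#' Reference Euclidean distance matrix among study localities
#'
#' Pairwise distances among the eight localities of the reference population,
#' computed from standardized locality mean profiles.
#'
#' @return A symmetric 8 x 8 numeric matrix with zero diagonal, locality
#'   names as dimnames.
#' @examples
#' ref_locality_distances()["Zapote Viejo", "Tlacote el Alto"]
#' @export
ref_locality_distances <- function() {
  df <- readr::read_csv(ref_path("bcg_locality_distances.csv"),
                        show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$locality
  storage.mode(m) <- "double"
  m
}

#' Reference locality sample sizes
#'
#' Number of animals sampled per locality in the reference study.
#'
#' @return A tibble with columns `locality` and `n` (8 rows, totalling 226).
#' @examples
#' sum(ref_locality_sizes()$n)
#' @export
ref_locality_sizes <- function() {
  read_ref_csv("bcg_locality_sizes.csv")
}
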