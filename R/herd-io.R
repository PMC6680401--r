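# A herd is a plain tibble: one row per animal, metadata columns
# (animal_id, locality, sex, age_class) plus the 14 measurement columns in
# centimetres. validate_herd() is the single gatekeeper every analysis
# entry point runs through.

#' Validate a herd table
#'
#' Checks that a data frame is a well-formed herd: all fourteen measurement
#' columns present, every measurement strictly positive and finite, metadata
#' columns present (missing ones are added with `"unknown"`), locality labels
#' non-empty.
#'
#' @param herd A data frame with one row per animal.
#' @param min_records Minimum number of rows required (default 1; statistical
#'   operations require at least 2).
#' @return The validated herd as a tibble, columns in canonical order.
#'   Extra columns trigger a warning and are dropped.
#' @examples
#' validate_herd(simulate_herd(herd_sim_spec(n_animals = 5, seed = 1)))
#' @export
validate_herd <- function(herd, min_records = 1) {
  if (!is.data.frame(herd)) {
    abort("`herd` must be a data frame.")
  }
  herd <- tibble::as_tibble(herd)
  missing_vars <- setdiff(zoo_variables(), names(herd))
  if (length(missing_vars) > 0) {
    abort(paste0("Missing measurement column(s): ",
                 paste(missing_vars, collapse = ", "), "."))
  }
  if (nrow(herd) < min_records) {
    abort(paste0("Herd has ", nrow(herd), " record(s); at least ",
                 min_records, " required."))
  }
  for (meta in herd_meta_cols()) {
    if (!meta %in% names(herd)) {
      herd[[meta]] <- if (meta == "animal_id") {
        sprintf("animal_%03d", seq_len(nrow(herd)))
      } else {
        "unknown"
      }
    }
    herd[[meta]] <- as.character(herd[[meta]])
  }
  bad_sex <- setdiff(unique(herd$sex), c("female", "male", "unknown"))
  if (length(bad_sex) > 0) {
    abort(paste0("Invalid sex value(s): ", paste(bad_sex, collapse = ", "),
                 " (expected female/male/unknown)."))
  }
  bad_age <- setdiff(unique(herd$age_class), c("adult", "unknown"))
  if (length(bad_age) > 0) {
    abort(paste0("Invalid age_class value(s): ",
                 paste(bad_age, collapse = ", "),
                 " (expected adult/unknown)."))
  }
  if (any(!nzchar(herd$locality) | is.na(herd$locality))) {
    abort("Locality labels must be non-empty.")
  }
  for (v in zoo_variables()) {
    x <- herd[[v]]
    if (!is.numeric(x)) {
      abort(paste0("Measurement column ", v, " is not numeric."))
    }
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) {
      abort(paste0("Non-positive or non-finite ", v, " in row(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   " (measurements are lengths in cm and must be > 0)."))
    }
  }
  extra <- setdiff(names(herd), herd_all_cols())
  if (length(extra) > 0) {
    warn(paste0("Ignoring unknown column(s): ",
                paste(extra, collapse = ", "), "."))
  }
  herd[herd_all_cols()]
}

#' Read a herd from delimited text
#'
#' Reads a per-animal measurement table (UTF-8, decimal point `"."`) and
#' validates it. The header must name the fourteen measurement codes; the
#' metadata columns `animal_id`, `locality`, `sex`, `age_class` are filled
#' with `"unknown"` defaults when absent. Values are parsed as-is: the file
#' is expected to be in centimetres and no unit conversion is applied.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default `","`).
#' @return A validated herd tibble, row order preserved.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(n_animals = 3, seed = 1))
#' tmp <- tempfile(fileext = ".csv")
#' write_herd(herd, tmp)
#' read_herd(tmp)
#' @export
read_herd <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (v in intersect(zoo_variables(), names(raw))) {
    if (!is.numeric(raw[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[v]]))))
      abort(paste0("Non-numeric ", v, " in row(s) ",
                   paste(head(bad, 5), collapse = ", "), " of ", path, "."))
    }
  }
  validate_herd(raw)
}

#' Write a herd to delimited text
#'
#' Inverse of [read_herd()]: values round-trip at full stored precision.
#'
#' @param herd A herd data frame.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_herd <- function(herd, path, delim = ",") {
  if (nrow(herd) == 0) {
    warn("Writing an empty herd (header only).")
    herd <- tibble::as_tibble(herd)[herd_all_cols()]
  } else {
    herd <- validate_herd(herd)
  }
  readr::write_delim(herd, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Sample size for estimating a proportion
#'
#' The classical precision-based sample size for a proportion,
#' \eqn{n = (z/m)^2 \, p(1-p)}, rounded up: `z` the standard-normal quantile
#' for the desired confidence, `m` the margin of error, `p` the anticipated
#' proportion. The reference study used z = 1.64 (90% confidence), m = 0.05
#' and p = 0.3, giving 226 animals.
#'
#' @param z Standard-normal quantile (> 0).
#' @param m Margin of error, a proportion in (0, 1).
#' @param p Anticipated proportion in \[0, 1\].
#' @return The smallest integer at or above the formula value. `p` of 0 or 1
#'   gives 0 with a warning (degenerate proportion).
#' @examples
#' required_sample_size(z = 1.64, m = 0.05, p = 0.3) # 226
#' @export
required_sample_size <- function(z, m, p) {
  stopifnot(is.numeric(z), is.numeric(m), is.numeric(p),
            length(z) == 1, length(m) == 1, length(p) == 1)
  if (!(z > 0)) abort("`z` must be > 0.")
  if (!(m > 0 && m < 1)) abort("`m` must be in (0, 1).")
  if (!(p >= 0 && p <= 1)) abort("`p` must be in [0, 1].")
  if (p * (1 - p) == 0) {
    warn("p(1 - p) is 0: degenerate anticipated proportion, returning 0.")
    return(0L)
  }
  as.integer(ceiling((z / m)^2 * p * (1 - p)))
}
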