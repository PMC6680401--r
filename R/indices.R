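# The nine classical zoometric indices and their zootechnical reading.
# Four ethnological (COI, THI, CEI, PEI) and five productive (PRI, MTI,
# RDI, TPI, LPI); each is a dimensionless ratio of two measurements x 100.
# Published class intervals contain gaps (e.g. corporal index: brevilinear
# <= 85 but mesolinear > 86); values falling in a gap are assigned the
# nearest class and flagged rather than silently reclassified.

#' Compute zoometric indices per animal
#'
#' The nine indices, exactly as defined ratios with no rounding:
#' \describe{
#'   \item{coi}{corporal index, BL x 100 / CG}
#'   \item{thi}{thoracic index, BW x 100 / CD}
#'   \item{cei}{cephalic index, HW x 100 / HL}
#'   \item{pei}{pelvic index, RW x 100 / RL}
#'   \item{pri}{proportionality index, WH x 100 / BL}
#'   \item{mti}{metacarpal-thoracic index, CBP x 100 / CG}
#'   \item{rdi}{relative depth of thorax, CD x 100 / WH}
#'   \item{tpi}{transversal pelvic index, RW x 100 / WH}
#'   \item{lpi}{longitudinal pelvic index, RL x 100 / WH}
#' }
#' All are scale-invariant: rescaling every measurement of an animal by the
#' same factor leaves its indices unchanged.
#'
#' @param herd A herd data frame (one row per animal).
#' @return A tibble with `animal_id`, `locality` and the nine index columns.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(n_animals = 5, seed = 1))
#' compute_indices(herd)
#' @export
compute_indices <- function(herd) {
  herd <- validate_herd(herd)
  dplyr::transmute(
    herd,
    animal_id = .data$animal_id,
    locality = .data$locality,
    coi = .data$BL * 100 / .data$CG,
    thi = .data$BW * 100 / .data$CD,
    cei = .data$HW * 100 / .data$HL,
    pei = .data$RW * 100 / .data$RL,
    pri = .data$WH * 100 / .data$BL,
    mti = .data$CBP * 100 / .data$CG,
    rdi = .data$CD * 100 / .data$WH,
    tpi = .data$RW * 100 / .data$WH,
    lpi = .data$RL * 100 / .data$WH
  )
}

index_codes <- function() {
  c("coi", "thi", "cei", "pei", "pri", "mti", "rdi", "tpi", "lpi")
}

# class intervals as (lo, hi, closed_lo, closed_hi); gaps between intervals
# get the nearest class plus a flag
classify_interval <- function(x, intervals) {
  labels <- names(intervals)
  label <- rep(NA_character_, length(x))
  gap <- rep(TRUE, length(x))
  dist_best <- rep(Inf, length(x))
  for (lab in labels) {
    iv <- intervals[[lab]]
    inside <- (if (iv$closed_lo) x >= iv$lo else x > iv$lo) &
      (if (iv$closed_hi) x <= iv$hi else x < iv$hi)
    label[inside] <- lab
    gap[inside] <- FALSE
    d <- pmax(iv$lo - x, x - iv$hi, 0)
    better <- gap & d < dist_best
    label[better] <- lab
    dist_best[better] <- d[better]
  }
  list(label = label, gap = gap)
}

iv <- function(lo, hi, closed_lo = TRUE, closed_hi = TRUE) {
  list(lo = lo, hi = hi, closed_lo = closed_lo, closed_hi = closed_hi)
}

#' Classify zoometric indices
#'
#' Applies the canonical zootechnical class intervals to per-animal index
#' values:
#' * COI: brevilinear (<= 85), mesolinear (> 86 and < 88), longilinear
#'   (>= 90); values in the published gaps take the nearest class with
#'   `coi_gap = TRUE`.
#' * THI: elliptical/dairy (<= 85), circular/meat (>= 89); gap flagged.
#' * CEI: dolichocephalic (< 100), mesocephalic (= 100), brachycephalic
#'   (> 100).
#' * PEI: convexilinear (< 100); `>= 100` is labelled width-dominant
#'   (non-canonical: only the convexilinear class is published).
#' * PRI: square/dairy-type when `>= pri_threshold` (default 95), else
#'   rectangular/meat-type; no published threshold exists, the default
#'   reflects the reading of 98.98 as a square, dairy-type conformation.
#' * MTI: ellipometric (< 10), eumetric (10 to 11, closed), hypermetric
#'   (> 11).
#' * RDI: meat-type short-legged (> 50), else dairy-type.
#' * TPI/LPI meat indicators: TPI > 33 and LPI < 37 each count one; 0 =
#'   dairy-leaning, 1 = medium tendency, 2 = meat-leaning.
#'
#' @param indices A tibble from [compute_indices()] (or any data frame with
#'   the nine index columns).
#' @param pri_threshold Threshold for the proportionality-index class.
#' @return The input with per-index class columns (`coi_class`, ...), gap
#'   flags for COI/THI, `meat_indicator_count` and `meat_tendency`.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(n_animals = 5, seed = 1))
#' classify_indices(compute_indices(herd))
#' @export
classify_indices <- function(indices, pri_threshold = 95) {
  stopifnot(all(index_codes() %in% names(indices)))
  out <- tibble::as_tibble(indices)

  coi <- classify_interval(out$coi, list(
    brevilinear = iv(-Inf, 85),
    mesolinear = iv(86, 88, closed_lo = FALSE, closed_hi = FALSE),
    longilinear = iv(90, Inf)
  ))
  thi <- classify_interval(out$thi, list(
    elliptical_dairy = iv(-Inf, 85),
    circular_meat = iv(89, Inf)
  ))
  out$coi_class <- coi$label
  out$coi_gap <- coi$gap
  out$thi_class <- thi$label
  out$thi_gap <- thi$gap
  out$cei_class <- dplyr::case_when(
    out$cei > 100 ~ "brachycephalic",
    out$cei == 100 ~ "mesocephalic",
    TRUE ~ "dolichocephalic"
  )
  out$pei_class <- dplyr::if_else(out$pei < 100, "convexilinear",
                                  "width_dominant_noncanonical")
  out$pri_class <- dplyr::if_else(out$pri >= pri_threshold,
                                  "square_dairy", "rectangular_meat")
  out$mti_class <- dplyr::case_when(
    out$mti < 10 ~ "ellipometric",
    out$mti <= 11 ~ "eumetric",
    TRUE ~ "hypermetric"
  )
  out$rdi_class <- dplyr::if_else(out$rdi > 50, "short_legged_meat",
                                  "dairy_type")
  out$meat_indicator_count <- (out$tpi > 33) + (out$lpi < 37)
  out$meat_tendency <- dplyr::case_when(
    out$meat_indicator_count == 2 ~ "meat_leaning",
    out$meat_indicator_count == 1 ~ "medium_tendency",
    TRUE ~ "dairy_leaning"
  )
  out
}

#' Population summary of zoometric indices
#'
#' Mean, sample SD, CV, min and max of the per-animal index values
#' (mean-of-ratios: each animal's index is computed first, then averaged —
#' not the ratio of population means).
#'
#' @param herd A herd data frame (at least 2 records).
#' @return A tibble with one row per index: `index`, `mean`, `sd`, `cv`,
#'   `min`, `max`, `n`.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(seed = 1))
#' index_table(herd)
#' @export
index_table <- function(herd) {
  herd <- validate_herd(herd, min_records = 2)
  compute_indices(herd) |>
    tidyr::pivot_longer(cols = dplyr::all_of(index_codes()),
                        names_to = "index", values_to = "value") |>
    dplyr::group_by(index = factor(.data$index, levels = index_codes())) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      cv = dplyr::if_else(sd(.data$value) == 0, 0,
                          100 * sd(.data$value) / mean(.data$value)),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$index) |>
    dplyr::mutate(index = as.character(.data$index))
}
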