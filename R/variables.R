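# Canonical measurement vocabulary. "HAW" (haunch width) is deliberately
# distinct from "HW" (head width): field protocols sometimes reuse "HW" for
# both, but all tabular interfaces here use HAW.

#' Canonical zoometric variable codes
#'
#' The fourteen linear body measurements, in centimetres, that define a
#' morphometric record, in the fixed order used by every table this package
#' produces.
#'
#' @return A character vector of 14 variable codes.
#' @examples
#' zoo_variables()
#' @export
zoo_variables <- function() {
  c("HW", "HL", "FL", "WH", "CG", "BL", "BW", "CD", "SW",
    "RL", "RW", "HAW", "RH", "CBP")
}

#' Zoometric variable descriptions
#'
#' @return A tibble with columns `variable` and `description`.
#' @examples
#' zoo_variable_info()
#' @export
zoo_variable_info <- function() {
  tibble::tibble(
    variable = zoo_variables(),
    description = c(
      "head width (between zygomatic arches)",
      "head length (occipital protuberance to upper lip)",
      "face length (midpoint of zygomatic arches to upper lip)",
      "wither height (ground to highest point of withers)",
      "chest girth (thorax circumference)",
      "body length (point of shoulder to point of buttock)",
      "bicostal width (side to side at the elbows)",
      "chest depth (withers to sternum)",
      "shoulder width (chest thickness at the front)",
      "rump length (point of haunch to point of buttock)",
      "rump width (between external iliac tuberosities)",
      "haunch width (between hip joints)",
      "rump height (ground to highest point of rump)",
      "cannon bone perimeter (mid-metacarpus circumference)"
    )
  )
}

# metadata columns expected alongside the measurements
herd_meta_cols <- function() c("animal_id", "locality", "sex", "age_class")

herd_all_cols <- function() c(herd_meta_cols(), zoo_variables())
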