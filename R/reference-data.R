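# Shipped reference tables on rabbit calf-muscle maturation.

#' Reference architecture of the maturing rabbit plantaris
#'
#' Architectural parameters of the rabbit M. plantaris for eight animals aged
#' 29 to 106 days (belly length, fascicle length and pennation statistics,
#' mass, PCSA, free tendon, mean aponeurosis dimensions). Useful as realistic
#' growth-parameter input for [grow_muscle()] and for worked examples of the
#' change/aggregation utilities.
#'
#' @return A tibble, one row per animal.
#' @export
#' @examples
#' ref <- reference_architecture()
#' with(ref, relative_change(belly_length_mm[animal_id == "R1"],
#'                           belly_length_mm[animal_id == "R8"], digits = 0))
reference_architecture <- function() {
  readr::read_csv(system.file("extdata", "rabbit_pla_architecture.csv",
                              package = "pennate"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reference growth-model prediction errors for rabbit calf muscles
#'
#' Per-age relative prediction errors (percent) of the four-parameter growth
#' model for plantaris (PLA), soleus (SOL) and medial gastrocnemius (GM), for
#' the derived metrics aponeurosis length, aponeurosis width, muscle height and
#' muscle mass. Input for the [summarize_errors()] aggregation convention.
#'
#' @return A tibble with columns `muscle`, `prediction_age_d`, `metric`,
#'   `error_pct`.
#' @export
reference_model_errors <- function() {
  readr::read_csv(system.file("extdata", "rabbit_calf_model_errors.csv",
                              package = "pennate"),
                  show_col_types = FALSE, progress = FALSE)
}
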