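# One-call analysis pipeline over a community dataset.

#' Run the full restoration analysis
#'
#' Computes, for every stratum (restoration age x canopy position), the
#' importance-value table, the alpha-diversity profile and the Godron
#' stability assessment, and, when the dataset carries soil samples, the
#' stratified soil summary with percent change versus the control age.
#'
#' @param dataset a [community_dataset()].
#' @param weight_mode proportion weighting for the diversity indices
#'   (see [diversity_profile()]).
#' @param degree polynomial degree of the stability fit.
#' @param paper_compat round stability coordinates/distances as
#'   published tables do (see [assess_stability()]).
#' @param control_years control age for soil percent change.
#' @return named list of data.frames: `importance`, `diversity`,
#'   `stability`, and `soil` (NULL when the dataset has no soil table).
#'   Suitable for [write_results()].
#' @export
restoration_analysis <- function(dataset,
                                 weight_mode = c("importance_value",
                                                 "abundance"),
                                 degree = 2, paper_compat = FALSE,
                                 control_years = 0) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(dataset, "community_dataset"))
  out <- list(
    importance = importance_table(dataset),
    diversity = diversity_table(dataset, weight_mode),
    stability = stability_table(dataset, degree = degree,
                                paper_compat = paper_compat))
  if (!is.null(dataset$soil))
    out$soil <- soil_change_table(dataset$soil,
                                  control_years = control_years)
  out
}
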