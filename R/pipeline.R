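# End-to-end convenience layer: current baseline + five scenarios, service
# scores per plot, and zone summaries, for one future period.

#' Run the full scenario and scoring pipeline
#'
#' Applies the five species-change scenarios for the chosen future period to
#' every plot, scores the current stand and each scenario stand for all
#' services, and aggregates zone summaries.
#'
#' @param plots Validated plot table (see [read_plots()]).
#' @param suitability Thresholded suitability table (see
#'   [build_suitability()]) covering the historical period and `period` for
#'   every plot.
#' @param period Future period id (default RCP 8.5, 2081-2100).
#' @param registry A `species_registry`.
#' @param scenarios Scenario labels to run.
#' @param redistribution Passed to [apply_scenario()].
#' @param weighted,native_wintergreen_only Passed to [score_services()].
#' @return List: `scores` (per-plot table stacked over `"current"` plus each
#'   scenario), `summaries` (zone summary tibble), `outcomes` (named list of
#'   outcome lists).
#' @examples
#' fx <- scenario_fixture("alpine_protect")
#' res <- run_pipeline(fx$plots, fx$suitability)
#' res$scores[, c("scenario", "production_value", "avalanche_risk")]
#' @export
run_pipeline <- function(plots, suitability, period = "rcp85_2081_2100",
                         registry = load_registry(),
                         scenarios = scenario_labels(),
                         redistribution = c("proportional", "drop"),
                         weighted = FALSE, native_wintergreen_only = FALSE) {
  redistribution <- match.arg(redistribution)
  current <- current_outcomes(plots)
  outcomes <- run_all_scenarios(plots, suitability, period, registry,
                                scenarios, redistribution)
  all_outcomes <- c(list(current = current), outcomes)
  scores <- dplyr::bind_rows(purrr::map(
    all_outcomes,
    score_services, plots = plots, registry = registry, weighted = weighted,
    native_wintergreen_only = native_wintergreen_only
  ))
  list(scores = scores,
       summaries = zone_summary(scores, plots),
       outcomes = all_outcomes)
}
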