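# Named micro-fixtures with hand-traceable expected outcomes, used in the
# documentation and the test suite.

fixture_plot <- function(plot_id, zone, altitude, slope, volume, rockfall,
                         shares) {
  row <- tibble::tibble(plot_id = plot_id, x = 0, y = 0, zone = zone,
                        altitude = altitude, slope = slope,
                        volume_m3_ha = volume, rockfall_zone = rockfall)
  for (code in load_registry()$code) {
    row[[paste0("share_", code)]] <-
      if (code %in% names(shares)) shares[[code]] else 0
  }
  row
}

fixture_suitability <- function(plot_id, probs_by_period) {
  reg <- load_registry()
  rows <- purrr::imap(probs_by_period, function(probs, period) {
    p <- setNames(rep(5, nrow(reg)), reg$code)
    if (length(probs) > 0) p[names(probs)] <- probs
    tibble::tibble(plot_id = plot_id, species = names(p), period = period,
                   probability = as.numeric(p))
  })
  build_suitability(dplyr::bind_rows(rows))
}

#' Hand-checkable scenario fixtures
#'
#' Tiny single-plot fixtures whose expected outcome per scenario can be
#' traced by hand against the replacement rules:
#'
#' * `"pannonian_spruce"`: a Pannonian spruce monoculture where no native
#'   species stays suitable but Douglas fir does. No-adaptation and both
#'   native scenarios leave the plot unstocked; both combi scenarios replant
#'   it with Douglas fir at unchanged volume.
#' * `"alpine_protect"`: an avalanche-eligible Alpine conifer stand
#'   (spruce 0.7, larch 0.3) where larch fails and spruce and silver fir
#'   stay suitable. Under no adaptation spruce absorbs the larch share and
#'   volume drops by 30%; under the adaptation scenarios silver fir (the
#'   most suitable candidate) receives the larch share at full volume.
#' * `"all_fail"`: a stand where no registry species is suitable in the
#'   future; every scenario leaves it unstocked.
#' * `"no_change"`: every occurring species remains suitable; every scenario
#'   returns the input composition.
#'
#' @param name Fixture name.
#' @return List with `plots` (one-row plot table) and `suitability`
#'   (thresholded records for all three periods).
#' @export
scenario_fixture <- function(name) {
  switch(
    name,
    pannonian_spruce = list(
      plots = fixture_plot("fx_pann", "pannonian", 200, 3, 300, FALSE,
                           c(pab = 1)),
      # Historically spruce is suitable (80 >= 56.5); in both future periods
      # every native drops below its cut-off while Douglas fir (70 >= 46.4)
      # and black walnut (65 >= 62.8) remain; Douglas fir has the higher
      # relative suitability (1.51 vs 1.04).
      suitability = fixture_suitability("fx_pann", list(
        historical_1961_1990 = c(pab = 80, que = 40),
        rcp45_2081_2100 = c(pab = 20, pme = 70, jni = 65),
        rcp85_2081_2100 = c(pab = 10, pme = 70, jni = 65)
      ))
    ),
    alpine_protect = list(
      plots = fixture_plot("fx_alp", "alpine_south", 1500, 35, 350, TRUE,
                           c(pab = 0.7, lde = 0.3)),
      # Future: larch fails (20 < 52.1); spruce stays (90 >= 56.5,
      # rel 1.59); silver fir becomes the best candidate (80/46.4 = 1.72).
      suitability = fixture_suitability("fx_alp", list(
        historical_1961_1990 = c(pab = 90, lde = 80, aal = 60),
        rcp45_2081_2100 = c(pab = 90, lde = 20, aal = 80),
        rcp85_2081_2100 = c(pab = 90, lde = 20, aal = 80)
      ))
    ),
    all_fail = list(
      plots = fixture_plot("fx_fail", "continental", 600, 10, 250, FALSE,
                           c(pab = 0.5, fsy = 0.5)),
      suitability = fixture_suitability("fx_fail", list(
        historical_1961_1990 = c(pab = 80, fsy = 70),
        rcp45_2081_2100 = c(),
        rcp85_2081_2100 = c()
      ))
    ),
    no_change = list(
      plots = fixture_plot("fx_same", "continental", 700, 12, 400, FALSE,
                           c(pab = 0.6, fsy = 0.4)),
      suitability = fixture_suitability("fx_same", list(
        historical_1961_1990 = c(pab = 80, fsy = 70),
        rcp45_2081_2100 = c(pab = 75, fsy = 65),
        rcp85_2081_2100 = c(pab = 70, fsy = 60)
      ))
    ),
    abort(paste0("unknown fixture: ", name))
  )
}
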