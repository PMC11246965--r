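# Shared builders for small in-code fixtures.

REG <- load_registry()

# One-row plot record in the wide plot-table format.
make_plot <- function(plot_id = "p1", shares = c(pab = 1), volume = 300,
                      zone = "continental", altitude = 600, slope = 10,
                      rockfall = FALSE) {
  row <- tibble::tibble(plot_id = plot_id, x = 0, y = 0, zone = zone,
                        altitude = altitude, slope = slope,
                        volume_m3_ha = volume, rockfall_zone = rockfall)
  for (code in REG$code) {
    row[[paste0("share_", code)]] <-
      if (code %in% names(shares)) shares[[code]] else 0
  }
  row
}

# Long suitability records for one plot and period from a named probability
# vector; species not named get probability 0 (unsuitable).
make_suit <- function(probs, plot_id = "p1", period = "rcp85_2081_2100") {
  p <- stats::setNames(rep(0, nrow(REG)), REG$code)
  if (length(probs) > 0) p[names(probs)] <- probs
  build_suitability(tibble::tibble(
    plot_id = plot_id, species = names(p), period = period,
    probability = as.numeric(p)
  ))
}

# A probability vector that makes exactly `suitable` suitable (just above
# the cut-off) and everything else just below; u in (0,1) scales position.
probs_with_suitable <- function(suitable, u = 0.5) {
  cut <- stats::setNames(REG$cutoff, REG$code)
  p <- cut * (u * 0.9)
  p[suitable] <- pmin(100, cut[suitable] * (1 + u))
  p
}
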