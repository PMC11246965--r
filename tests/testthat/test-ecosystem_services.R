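test_that("production value averages standardized increments of species present", {
  expect_equal(production_value(c(pab = 1)), 0.95)
  expect_equal(production_value(c(aal = .5, pab = .5)), (1.26 + 0.95) / 2)
  # unweighted by default: shares do not matter
  expect_equal(production_value(c(aal = .9, pab = .1)), (1.26 + 0.95) / 2)
  # weighted option
  expect_equal(production_value(c(aal = .9, pab = .1), weighted = TRUE),
               (1.26 * .9 + 0.95 * .1))
  expect_equal(production_value(stats::setNames(numeric(0), character(0))), 0)
  expect_error(production_value(c(zzz = 1)), "unknown species")
})

test_that("production categories partition values with the printed band edges", {
  expect_equal(classify_production(0.95), "high")
  expect_equal(classify_production(0.78), "moderate")
  expect_equal(classify_production(0.63), "moderate")
  expect_equal(classify_production(0.62), "low")
  # partition: exactly one category everywhere, monotone in the value
  v <- seq(0, 3, by = 0.005)
  cat <- classify_production(v)
  expect_true(all(cat %in% c("low", "moderate", "high")))
  rank <- match(cat, c("low", "moderate", "high"))
  expect_true(all(diff(rank) >= 0))
})

test_that("richness counts taxa present, with merged oaks as one", {
  expect_equal(richness(c(pab = .6, fsy = .4)), 2)
  expect_equal(richness(c(que = 1)), 1)
  expect_equal(richness(stats::setNames(numeric(0), character(0))), 0)
})

test_that("non-native share is normalised by the stocked fraction", {
  expect_equal(nnt_share(c(pab = .5, pme = .5)), 0.5)
  expect_equal(nnt_share(c(pab = .7, fsy = .3)), 0)
  expect_equal(nnt_share(c(pme = .3)), 1)  # partially stocked, all non-native
  expect_equal(nnt_share(stats::setNames(numeric(0), character(0))), 0)
})

test_that("frequency of occurrence is the percentage of plots with the species", {
  outs <- lapply(list(c(pab = 1), c(pab = .5, fsy = .5), c(fsy = 1),
                      c(que = 1)),
                 function(s) structure(list(shares = s, plot_id = "x",
                                            scenario = "current",
                                            volume = 1, unstocked = FALSE),
                                       class = "scenario_outcome"))
  expect_equal(frequency_of_occurrence(outs, "pab"), 50)
  expect_equal(frequency_of_occurrence(outs, "tpl"), 0)
  expect_equal(frequency_of_occurrence(outs, "fsy"), 50)
  expect_error(frequency_of_occurrence(list(), "pab"), "at least one plot")
})

test_that("avalanche eligibility needs altitude above 800 m and slope 25-60", {
  expect_true(avalanche_eligible(make_plot(altitude = 900, slope = 30)))
  expect_false(avalanche_eligible(make_plot(altitude = 800, slope = 30)))
  expect_false(avalanche_eligible(make_plot(altitude = 1200, slope = 61)))
  expect_true(avalanche_eligible(make_plot(altitude = 801, slope = 25)))
  expect_true(avalanche_eligible(make_plot(altitude = 2000, slope = 60)))
  expect_false(avalanche_eligible(make_plot(altitude = 2000, slope = 24.9)))
})

test_that("avalanche risk follows the wintergreen and stocking rules", {
  # 75% wintergreen, well stocked -> low
  expect_equal(avalanche_risk(c(pab = .75, fsy = .25), volume = 300), "low")
  # high wintergreen but under-stocked -> high (volume rule has precedence)
  expect_equal(avalanche_risk(c(pab = .85, fsy = .15), volume = 90), "high")
  expect_equal(avalanche_risk(c(pab = .40, fsy = .60), volume = 300), "high")
  expect_equal(avalanche_risk(c(pab = .55, fsy = .45), volume = 300),
               "moderate")
  # boundary closure: exactly 70% is low, volume exactly 100 is high
  expect_equal(avalanche_risk(c(pab = .70, fsy = .30), volume = 101), "low")
  expect_equal(avalanche_risk(c(pab = .70, fsy = .30), volume = 100), "high")
  # unstocked protects nothing
  expect_equal(avalanche_risk(stats::setNames(numeric(0), character(0)),
                              volume = 0), "high")
  # larch is deciduous: a pure larch stand has zero wintergreen share
  expect_equal(avalanche_risk(c(lde = 1), volume = 300), "high")
  # a planted non-native evergreen counts, unless restricted to the three
  # native wintergreens
  expect_equal(avalanche_risk(c(pme = 1), volume = 300), "low")
  expect_equal(avalanche_risk(c(pme = 1), volume = 300,
                              native_wintergreen_only = TRUE), "high")
})

test_that("rockfall risk is volume-banded with closed bounds", {
  expect_equal(rockfall_risk(400), "low")
  expect_equal(rockfall_risk(360), "low")
  expect_equal(rockfall_risk(359), "moderate")
  expect_equal(rockfall_risk(250), "moderate")
  expect_equal(rockfall_risk(181), "moderate")
  expect_equal(rockfall_risk(180), "high")
  expect_equal(rockfall_risk(0), "high")
  expect_error(rockfall_risk(-5), "volume")
})

test_that("risk rules are monotone in wintergreen share and volume", {
  vols <- c(50, 100, 150, 250, 360, 500)
  rk <- function(x) match(x, c("high", "moderate", "low"))
  for (v in vols) {
    cats <- vapply(seq(0, 1, by = 0.05), function(w) {
      avalanche_risk(c(pab = w, fsy = 1 - w), volume = v)
    }, character(1))
    expect_true(all(diff(rk(cats)) >= 0), info = paste("volume", v))
  }
  for (w in seq(0, 1, by = 0.25)) {
    cats <- vapply(vols, function(v) {
      avalanche_risk(c(pab = w, fsy = 1 - w), volume = v)
    }, character(1))
    expect_true(all(diff(rk(cats)) >= 0), info = paste("wintergreen", w))
  }
  expect_true(all(diff(rk(rockfall_risk(seq(0, 500, by = 1)))) >= 0))
})

test_that("change vs current is signed on the right scale", {
  expect_equal(change_vs_current(200, 150,
                                 current_volume = 200,
                                 scenario_volume = 150)$percent, -25)
  expect_equal(change_vs_current("moderate", "low", service = "risk")$change, 1)
  expect_equal(change_vs_current("moderate", "low",
                                 service = "production")$change, -1)
  expect_equal(change_vs_current("high", "high", service = "risk")$change, 0)
  r <- change_vs_current(2, 2, current_volume = 0, scenario_volume = 10)
  expect_true(is.na(r$percent))
  expect_equal(change_vs_current(1, 1, current_volume = 0,
                                 scenario_volume = 0)$percent, 0)
  expect_error(change_vs_current("low", "high"), "service")
})

test_that("score_services marks ineligible plots and scores the rest", {
  plots <- dplyr::bind_rows(
    make_plot("a", shares = c(pab = 1), volume = 300, altitude = 1200,
              slope = 35, rockfall = TRUE),
    make_plot("b", shares = c(fsy = 1), volume = 120, altitude = 400,
              slope = 5, rockfall = FALSE)
  )
  outs <- list(current_outcome(plots[1, ]), current_outcome(plots[2, ]))
  sc <- score_services(outs, plots)
  expect_equal(sc$avalanche_risk, c("low", "not_eligible"))
  expect_equal(sc$rockfall_risk, c("moderate", "not_eligible"))
  expect_equal(sc$production_category, c("high", "moderate"))
  expect_equal(sc$richness, c(1L, 1L))
})
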