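test_that("plot tables round-trip through CSV", {
  plots <- dplyr::bind_rows(
    make_plot("a", shares = c(pab = 0.123456, fsy = 0.654321), volume = 321.123456),
    make_plot("b", shares = c(que = 0.5), volume = 0),
    make_plot("c", shares = c(pme = 1), volume = 1700, rockfall = TRUE)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_plots(plots, f)
  back <- read_plots(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$share_pab, plots$share_pab, tolerance = 1e-7)
  expect_equal(back$volume_m3_ha, plots$volume_m3_ha, tolerance = 1e-7)
  expect_equal(back$rockfall_zone, plots$rockfall_zone)
})

test_that("plot validation names the offending row and field", {
  good <- make_plot("a", shares = c(pab = .5))

  bad <- good; bad$share_pab <- 1.2
  expect_error(validate_plots(bad), "share out of range, row 1")

  bad <- good; names(bad)[names(bad) == "share_pab"] <- "share_pinus_nigra"
  expect_error(validate_plots(bad), "unknown species")

  bad <- good; bad$zone <- "tundra"
  expect_error(validate_plots(bad), "zone, row 1")

  bad <- dplyr::bind_rows(good, good)
  expect_error(validate_plots(bad), "duplicate plot_id")

  bad <- good; bad$slope <- 90
  expect_error(validate_plots(bad), "slope out of range")

  two <- dplyr::bind_rows(good, make_plot("b", shares = c(pab = .6, fsy = .6)))
  expect_error(validate_plots(two), "share sum exceeds 1, row 2")
})

test_that("subplots aggregate with mean shares/volume and median terrain", {
  sub <- dplyr::bind_rows(lapply(1:4, function(i) {
    row <- make_plot("x", shares = c(pab = c(1, 0.5, 0, 0.5)[i]),
                     volume = c(100, 200, 300, 400)[i],
                     altitude = c(800, 900, 1000, 1100)[i],
                     slope = c(10, 20, 30, 40)[i])
    row$plot_id <- NULL
    row$site_id <- "s1"
    row
  }))
  agg <- aggregate_subplots(sub)
  expect_equal(agg$n_dropped, 0)
  p <- agg$plots
  expect_equal(p$share_pab, 0.5)
  expect_equal(p$volume_m3_ha, 250)
  expect_equal(p$altitude, 950)  # even count: midpoint of the two central
  expect_equal(p$slope, 25)

  # permutation invariance over subplot order
  agg2 <- aggregate_subplots(sub[c(3, 1, 4, 2), ])
  expect_equal(agg2$plots, p)
})

test_that("sites without any registry species are dropped and counted", {
  occupied <- make_plot("ignored", shares = c(fsy = .8))
  occupied$plot_id <- NULL
  empty <- make_plot("ignored2", shares = c())
  empty$plot_id <- NULL
  sub <- dplyr::bind_rows(
    dplyr::mutate(occupied, site_id = "s1"),
    dplyr::mutate(empty, site_id = "s2"),
    dplyr::mutate(empty, site_id = "s2")
  )
  agg <- aggregate_subplots(sub)
  expect_equal(agg$n_dropped, 1)
  expect_equal(agg$plots$plot_id, "s1")
  expect_error(aggregate_subplots(sub[0, ]), "zero subplots")
})

test_that("ascii-grid rasters are sampled nearest-cell with rescale detection", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "const73.asc")
  write_ascii_grid(matrix(73, nrow = 4, ncol = 4), f1, xll = 0, yll = 0,
                   cellsize = 10)
  f2 <- file.path(dir, "unit_scale.asc")
  write_ascii_grid(matrix(0.565, nrow = 4, ncol = 4), f2, xll = 0, yll = 0,
                   cellsize = 10)

  plots <- dplyr::bind_rows(
    make_plot("in1"), make_plot("in2"), make_plot("outside")
  )
  plots$x <- c(5, 35, 200); plots$y <- c(5, 35, 5)

  rasters <- tibble::tibble(
    species = c("pab", "pab"),
    period = c("historical_1961_1990", "rcp85_2081_2100"),
    path = c(f1, f2)
  )
  tab <- NULL
  ws <- testthat::capture_warnings(
    suppressMessages(tab <- sample_suitability_rasters(plots, rasters)))
  expect_length(ws, 2)  # one per raster: the third plot lies outside both
  expect_match(ws, "outside raster extent", all = TRUE)
  hist <- tab[tab$period == "historical_1961_1990", ]
  expect_equal(hist$probability[1:2], c(73, 73))
  expect_true(is.na(hist$probability[3]))
  fut <- tab[tab$period == "rcp85_2081_2100", ]
  expect_equal(fut$probability[1:2], c(56.5, 56.5))  # [0,1] auto-rescaled

  expect_error(read_ascii_grid(file.path(dir, "nope.asc")), "unreadable")
})

test_that("grid values land in the right cells, not just constant fields", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "grad.asc")
  m <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)  # north row first
  write_ascii_grid(m, f, xll = 0, yll = 0, cellsize = 1)
  g <- read_ascii_grid(f)
  # (0.5, 1.5) is in the north row, first column
  expect_equal(forestadapt:::grid_lookup(g, c(0.5, 1.5, 0.5, 1.5),
                                         c(1.5, 1.5, 0.5, 0.5)),
               c(1, 2, 3, 4))
})

test_that("zone summaries aggregate means, SDs and category counts per zone", {
  plots <- dplyr::bind_rows(
    make_plot("a", zone = "alpine_south", shares = c(pab = 1), volume = 400,
              altitude = 1200, slope = 35, rockfall = TRUE),
    make_plot("b", zone = "alpine_south", shares = c(pab = .5, fsy = .5),
              volume = 100, altitude = 1000, slope = 30),
    make_plot("c", zone = "pannonian", shares = c(que = 1), volume = 150,
              altitude = 250, slope = 3)
  )
  outs <- forestadapt:::current_outcomes(plots)
  sc <- score_services(outs, plots)
  zs <- zone_summary(sc, plots)
  expect_equal(nrow(zs), 2)
  alp <- zs[zs$zone == "alpine_south", ]
  expect_equal(alp$n_plots, 2L)
  expect_equal(alp$richness_mean, 1.5)
  expect_equal(alp$richness_sd, sd(c(1, 2)))
  # category counts sum to the eligible-plot count per service
  expect_equal(alp$production_low + alp$production_moderate +
                 alp$production_high, alp$n_plots)
  expect_equal(alp$avalanche_high + alp$avalanche_moderate +
                 alp$avalanche_low, alp$n_avalanche_eligible)
  expect_equal(alp$rockfall_high + alp$rockfall_moderate + alp$rockfall_low,
               alp$n_rockfall_eligible)
  expect_equal(alp$n_rockfall_eligible, 1L)
  pann <- zs[zs$zone == "pannonian", ]
  expect_equal(pann$n_plots, 1L)
  expect_equal(pann$richness_sd, NA_real_)
})

test_that("write_outputs produces per-plot, zone and change files", {
  fx <- scenario_fixture("alpine_protect")
  res <- run_pipeline(fx$plots, fx$suitability)
  dir <- withr::local_tempdir()
  files <- write_outputs(res$scores, fx$plots, dir, geojson = TRUE)
  expect_true(file.exists(file.path(dir, "per_plot_scores.csv")))
  expect_true(file.exists(file.path(dir, "zone_summary.csv")))
  per_plot <- read.csv(file.path(dir, "per_plot_scores.csv"))
  expect_equal(nrow(per_plot), 1)

  gj <- jsonlite::read_json(file.path(dir, "change_no_adaptation.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  props <- gj$features[[1]]$properties
  expect_true(props$production_change %in% c(-1, 0, 1))
  # losing 30% of the volume moves 350 -> 245, still moderate rockfall
  expect_equal(props$volume_change_percent, -30)
  expect_equal(props$rockfall_change, 0)
})

test_that("empty results still write header-only files", {
  plots <- make_plot("a")[0, ]
  sc <- score_services(list(), plots)
  dir <- withr::local_tempdir()
  expect_no_error(write_outputs(sc, plots, dir))
  expect_true(file.exists(file.path(dir, "per_plot_scores.csv")))
})
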