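# Seeded generator of inventory-like survey sites and suitability tables.
# The generator emulates the statistical structure the analysis assumes --
# zone-stratified terrain, 4-subplot sites aggregated to centroids,
# compositional species shares with zone-specific non-native targets,
# right-skewed stand volumes, and altitude-driven suitability bands that
# shift uphill under climate impact -- so every pipeline stage can be
# exercised without confidential inventory data.

#' Default generator configuration
#'
#' Returns the configuration of the synthetic inventory generator. Defaults
#' mirror the study region: 1423/1448/150 survey sites in the Alpine-South,
#' Continental and Pannonian zones, four subplots per site, Alpine terrain
#' high and steep versus Pannonian flat lowland, a small fraction of sites
#' carrying none of the registry species, right-skewed stand volumes
#' (lognormal, mean 360 m3/ha, truncated at 1700), zone-specific rockfall
#' hazard-zone membership, and current non-native share targets of about 1%
#' in the two mountain/upland zones and 16% in the Pannonian lowland.
#'
#' Suitability is generated mechanistically as an altitude band per species:
#' probability = amplitude x rising logistic at the lower band edge x
#' falling logistic at the upper edge, plus noise. Under climate impact
#' (0 = historical, `impact["rcp45"]` = 1, `impact["rcp85"]` = 2 by default)
#' the lower edge retreats uphill by `ret` metres per impact unit (the
#' decline knob: raising `ret` can only lower future probabilities) and the
#' upper edge advances by `adv` metres per impact unit (expansion). The two
#' white oaks are generated individually (`qpe`, `qro`) and merged
#' downstream.
#'
#' @param ... Named overrides of top-level config entries.
#' @return A `generator_config` list.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_sites = c(alpine_south = 1423, continental = 1448, pannonian = 150),
    subplots_per_site = 4,
    p_empty_site = 117 / 3141,
    terrain = list(
      alpine_south = list(altitude_mean = 1250, altitude_sd = 400,
                          slope_mean = 30, slope_sd = 10),
      continental  = list(altitude_mean = 600, altitude_sd = 250,
                          slope_mean = 15, slope_sd = 8),
      pannonian    = list(altitude_mean = 250, altitude_sd = 80,
                          slope_mean = 3, slope_sd = 2)
    ),
    subplot_jitter = list(altitude_sd = 15, slope_sd = 1.5),
    composition = list(
      alpine_south = list(
        native_weights = c(pab = .45, aal = .10, lde = .16, psy = .09,
                           fsy = .15, que = .05),
        nnt_presence_prob = 0.05, nnt_share_mean = 0.20,
        nnt_weights = c(pme = .6, jni = .1, rps = .05, qru = .1,
                        agr = .05, tpl = .05, fpe = .02, pco = .02, pra = .01)
      ),
      continental = list(
        native_weights = c(pab = .35, aal = .08, lde = .06, psy = .13,
                           fsy = .23, que = .15),
        nnt_presence_prob = 0.05, nnt_share_mean = 0.20,
        nnt_weights = c(pme = .5, jni = .2, rps = .1, qru = .1,
                        agr = .04, tpl = .02, fpe = .02, pco = .01, pra = .01)
      ),
      pannonian = list(
        native_weights = c(pab = .10, aal = .02, lde = .03, psy = .22,
                           fsy = .13, que = .50),
        nnt_presence_prob = 0.40, nnt_share_mean = 0.40,
        nnt_weights = c(pme = .2, jni = .3, rps = .3, qru = .1,
                        agr = .02, tpl = .02, fpe = .04, pco = .01, pra = .01)
      )
    ),
    richness_probs = c(.25, .40, .25, .10),  # P(1..4 native species per site)
    dirichlet_concentration = 2,
    stocking_beta = c(20, 1.5),
    volume = list(meanlog = log(360) - 0.7^2 / 2, sdlog = 0.7, max = 1700),
    rockfall_prob = c(alpine_south = 0.30, continental = 0.07, pannonian = 0),
    impact = c(rcp45 = 1, rcp85 = 2),
    suitability = default_suitability_params(),
    noise_sd = 5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown generator config field: ", paste(bad, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

# Altitude bands: amp = peak probability [%], lo/hi = band edges [m],
# width = logistic scale [m], ret = uphill retreat of the lower edge per
# impact unit [m] (decline), adv = uphill advance of the upper edge [m].
default_suitability_params <- function() {
  tibble::tribble(
    ~species, ~amp, ~lo,   ~hi,  ~width, ~ret, ~adv,
    "pab",    95,   450,  2000,  150,    500,  100,
    "aal",    90,   400,  1700,  150,    350,  150,
    "psy",    92,   150,  1500,  150,    450,  100,
    "lde",    90,   900,  2200,  150,    300,  150,
    "fsy",    90,   250,  1400,  150,    300,  150,
    "qpe",    88,  -600,   700,  150,      0,  350,
    "qro",    85,  -700,   600,  150,      0,  300,
    "pme",    88,   100,  1300,  150,    100,  250,
    "agr",    62,   300,  1200,  150,    150,  200,
    "fpe",    55,  -600,   500,  150,      0,  250,
    "jni",    80,  -700,   800,  150,      0,  300,
    "pco",    60,   900,  1800,  150,    200,  150,
    "pra",    60,  -500,   900,  150,      0,  400,
    "qru",    56,  -600,   800,  150,      0,  250,
    "rps",    68,  -500,   600,  150,      0,  300,
    "tpl",    53,   200,  1100,  150,    100,  200
  )
}

validate_generator_config <- function(cfg) {
  if (any(cfg$n_sites < 0)) abort("invalid config field: n_sites must be >= 0")
  if (cfg$p_empty_site < 0 || cfg$p_empty_site > 1) {
    abort("invalid config field: p_empty_site must be in [0,1]")
  }
  for (z in names(cfg$composition)) {
    comp <- cfg$composition[[z]]
    if (comp$nnt_presence_prob < 0 || comp$nnt_presence_prob > 1) {
      abort("invalid config field: nnt_presence_prob must be in [0,1]")
    }
    if (comp$nnt_share_mean <= 0 || comp$nnt_share_mean >= 1) {
      abort("invalid config field: nnt_share_mean must be in (0,1)")
    }
    if (any(comp$native_weights < 0) || any(comp$nnt_weights < 0)) {
      abort("invalid config field: negative species weight")
    }
  }
  if (any(cfg$suitability$ret < 0)) {
    abort("invalid config field: ret must be >= 0")
  }
  if (cfg$noise_sd < 0) abort("invalid config field: noise_sd must be >= 0")
  invisible(cfg)
}

#' Per-zone expected current non-native share of the generator
#'
#' The generator draws, per site, a non-native presence indicator and a
#' non-native total share, so the expected non-native share equals
#' presence probability x mean share given presence. Used by
#' parameter-recovery checks.
#'
#' @param config A `generator_config`.
#' @return Named numeric vector per zone.
#' @export
nnt_share_targets <- function(config = generator_config()) {
  vapply(config$composition,
         function(c) c$nnt_presence_prob * c$nnt_share_mean,
         numeric(1))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate synthetic survey sites and centroid plots
#'
#' Draws zone-stratified survey sites of four subplots each -- terrain from
#' zone-specific normals with small subplot jitter, compositional species
#' shares (natives from a zone-weighted Dirichlet, optionally one non-native
#' taxon), a stocked fraction below 1, lognormal stand volume, and a
#' rockfall hazard-zone flag -- and aggregates them to centroids via
#' [aggregate_subplots()]. Sites where no registry species occurs are
#' generated at the configured rate, then dropped and counted during
#' aggregation, as in inventory practice.
#'
#' @param config A `generator_config`.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return List: `subplots` (subplot-level tibble), `plots` (aggregated
#'   centroid tibble), `n_dropped` (empty sites removed).
#' @export
generate_plots <- function(config = generator_config(), seed = 1) {
  validate_generator_config(config)
  set.seed(seed)
  reg <- load_registry()
  all_codes <- reg$code
  zones_used <- names(config$n_sites)[config$n_sites > 0]

  site_rows <- list()
  k <- 0
  for (z in zones_used) {
    terr <- config$terrain[[z]]
    comp <- config$composition[[z]]
    n <- config$n_sites[[z]]
    for (s in seq_len(n)) {
      k <- k + 1
      alt <- max(0, rnorm(1, terr$altitude_mean, terr$altitude_sd))
      slp <- min(89, max(0, rnorm(1, terr$slope_mean, terr$slope_sd)))
      shares <- setNames(numeric(length(all_codes)), all_codes)
      empty <- runif(1) < config$p_empty_site
      if (!empty) {
        k_nat <- sample.int(4, 1, prob = config$richness_probs)
        k_nat <- min(k_nat, length(comp$native_weights))
        nats <- sample(names(comp$native_weights), k_nat,
                       prob = comp$native_weights)
        shares[nats] <- rdirichlet1(rep(config$dirichlet_concentration, k_nat))
        if (runif(1) < comp$nnt_presence_prob) {
          nnt <- sample(names(comp$nnt_weights), 1, prob = comp$nnt_weights)
          frac <- rbeta(1, 2, 2 * (1 - comp$nnt_share_mean) / comp$nnt_share_mean)
          shares <- shares * (1 - frac)
          shares[nnt] <- shares[nnt] + frac
        }
        stocked <- rbeta(1, config$stocking_beta[1], config$stocking_beta[2])
        shares <- shares * stocked
      }
      vol <- if (empty) 0 else min(config$volume$max,
                                   rlnorm(1, config$volume$meanlog,
                                          config$volume$sdlog))
      site_rows[[k]] <- list(zone = z, altitude = alt, slope = slp,
                             shares = shares, volume = vol,
                             rockfall = runif(1) < config$rockfall_prob[[z]],
                             x = runif(1, 0, 100), y = runif(1, 0, 100))
    }
  }

  nsub <- config$subplots_per_site
  sub_list <- purrr::map(seq_along(site_rows), function(i) {
    s <- site_rows[[i]]
    jit_alt <- rnorm(nsub, 0, config$subplot_jitter$altitude_sd)
    jit_slp <- rnorm(nsub, 0, config$subplot_jitter$slope_sd)
    tot <- sum(s$shares)
    u <- if (tot > 0) pmin(runif(nsub, 0.9, 1.1), 1 / tot) else rep(1, nsub)
    base <- tibble::tibble(
      site_id = sprintf("site_%04d", i),
      subplot = seq_len(nsub),
      x = s$x, y = s$y, zone = s$zone,
      altitude = pmax(0, s$altitude + jit_alt),
      slope = pmin(89, pmax(0, s$slope + jit_slp)),
      volume_m3_ha = pmin(config$volume$max,
                          pmax(0, s$volume * runif(nsub, 0.85, 1.15))),
      rockfall_zone = s$rockfall
    )
    for (code in names(s$shares)) {
      base[[paste0("share_", code)]] <- s$shares[[code]] * u
    }
    base
  })
  subplots <- dplyr::bind_rows(sub_list)

  agg <- aggregate_subplots(subplots, reg)
  list(subplots = subplots, plots = agg$plots, n_dropped = agg$n_dropped)
}

#' Generate suitability tables for the three periods
#'
#' Computes per plot x species x period probabilities of occurrence from the
#' configured altitude bands, plus seeded Gaussian noise, clamped to
#' \[0, 100\]. With all impact knobs at 0 the future tables equal the
#' historical one; increasing a species' `ret` (decline) parameter never
#' increases its future probability at any plot.
#'
#' @param plots Centroid plot table (needs `plot_id`, `altitude`).
#' @param config A `generator_config`.
#' @param seed Integer seed for the noise draw.
#' @return Long tibble `plot_id, species, period, probability` covering the
#'   individual oaks (`qpe`, `qro`); pass through [build_suitability()] to
#'   obtain merged, thresholded records.
#' @export
generate_suitability <- function(plots, config = generator_config(), seed = 1) {
  validate_generator_config(config)
  set.seed(seed + 1L)
  par <- config$suitability
  impact <- c(historical_1961_1990 = 0,
              rcp45_2081_2100 = config$impact[["rcp45"]],
              rcp85_2081_2100 = config$impact[["rcp85"]])

  grid <- tidyr::expand_grid(
    plot_id = plots$plot_id,
    species = par$species,
    period = names(impact)
  )
  grid$altitude <- plots$altitude[match(grid$plot_id, plots$plot_id)]
  i <- match(grid$species, par$species)
  imp <- impact[grid$period]
  lo <- par$lo[i] + imp * par$ret[i]
  hi <- par$hi[i] + imp * par$adv[i]
  base <- par$amp[i] *
    stats::plogis((grid$altitude - lo) / par$width[i]) *
    stats::plogis((hi - grid$altitude) / par$width[i])
  # One noise value per plot x species, shared across periods, so that a
  # species' fate at a plot changes over time only through the band shift.
  noise_key <- paste(grid$plot_id, grid$species)
  uniq <- unique(noise_key)
  eps <- setNames(rnorm(length(uniq), 0, config$noise_sd), uniq)
  grid$probability <- pmin(100, pmax(0, base + eps[noise_key]))
  grid$altitude <- NULL
  grid
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: plots plus thresholded suitability in one call.
#'
#' @inheritParams generate_plots
#' @return List `plots`, `suitability` (merged/thresholded), `probabilities`
#'   (raw, with individual oaks), `subplots`, `n_dropped`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  gp <- generate_plots(config, seed)
  prob <- generate_suitability(gp$plots, config, seed)
  list(plots = gp$plots,
       suitability = build_suitability(prob),
       probabilities = prob,
       subplots = gp$subplots,
       n_dropped = gp$n_dropped)
}
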