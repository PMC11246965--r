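# Ecosystem-service scoring of a stand (current or post-scenario):
# timber productivity, tree species richness, non-native share, and the two
# protective services (avalanche and rockfall risk categories).

PRODUCTION_HIGH <- 0.78  # production value strictly above -> high
PRODUCTION_LOW  <- 0.63  # production value strictly below -> low

AVALANCHE_WINTERGREEN_LOW  <- 70   # % wintergreen at or above -> low risk
AVALANCHE_WINTERGREEN_HIGH <- 40   # % wintergreen at or below -> high risk
AVALANCHE_VOLUME_HIGH      <- 100  # m3/ha at or below -> not fully stocked, high risk

ROCKFALL_VOLUME_LOW  <- 360  # m3/ha at or above -> low risk
ROCKFALL_VOLUME_HIGH <- 180  # m3/ha at or below -> high risk

RISK_LEVELS <- c("high", "moderate", "low")          # worst to best
PRODUCTION_LEVELS <- c("low", "moderate", "high")    # worst to best

outcome_shares <- function(outcome) {
  if (inherits(outcome, "scenario_outcome")) return(outcome$shares)
  if (is.numeric(outcome) && !is.null(names(outcome))) {
    return(outcome[outcome > 0])
  }
  abort("expected a scenario_outcome or a named share vector")
}

#' Production value of a stand
#'
#' The unweighted arithmetic mean of the standardized annual increments of
#' the species present (share > 0); a dimensionless productivity indicator
#' with 1 equal to the all-species mean increment. An unstocked stand scores
#' 0 by convention. Optionally the mean is share-weighted.
#'
#' @param outcome A `scenario_outcome` or named share vector.
#' @param registry A `species_registry`.
#' @param weighted If `TRUE`, weight increments by shares instead of the
#'   plain mean over species present.
#' @return Non-negative scalar.
#' @examples
#' production_value(c(pab = 1))           # Norway spruce monoculture: 0.95
#' production_value(c(aal = .5, pab = .5))
#' @export
production_value <- function(outcome, registry = load_registry(),
                             weighted = FALSE) {
  shares <- outcome_shares(outcome)
  if (length(shares) == 0) return(0)
  unknown <- setdiff(names(shares), registry$code)
  if (length(unknown) > 0) {
    abort(paste0("unknown species: ", paste(unknown, collapse = ", ")))
  }
  inc <- registry$increment_std[match(names(shares), registry$code)]
  if (weighted) {
    sum(inc * shares) / sum(shares)
  } else {
    mean(inc)
  }
}

#' Classify a production value into a category
#'
#' Categories are anchored on the native species with the highest
#' (silver fir, Norway spruce) and lowest (Scots pine, European larch)
#' standardized increments: high production above 0.78, low below 0.63,
#' moderate in the closed band between.
#'
#' @param value Non-negative production value(s). Vectorised.
#' @return Character vector in `c("low", "moderate", "high")`.
#' @examples
#' classify_production(c(0.62, 0.78, 0.95))
#' @export
classify_production <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("production value must be a non-negative number")
  }
  dplyr::case_when(
    value > PRODUCTION_HIGH ~ "high",
    value < PRODUCTION_LOW ~ "low",
    TRUE ~ "moderate"
  )
}

#' Tree species richness of a stand
#'
#' Number of registry taxa present with share > 0; the merged *Quercus* spp.
#' counts as one taxon. Unstocked stands have richness 0.
#'
#' @inheritParams production_value
#' @return Integer count.
#' @export
richness <- function(outcome) {
  length(outcome_shares(outcome))
}

#' Non-native share of a stand
#'
#' Sum of non-native species' shares divided by the sum of all shares, so a
#' partially stocked plot is normalised by its stocked fraction. 0 when
#' unstocked.
#'
#' @inheritParams production_value
#' @return Fraction in \[0, 1\].
#' @export
nnt_share <- function(outcome, registry = load_registry()) {
  shares <- outcome_shares(outcome)
  if (length(shares) == 0) return(0)
  native <- registry$native[match(names(shares), registry$code)]
  if (any(is.na(native))) {
    abort(paste0("unknown species: ",
                 paste(names(shares)[is.na(native)], collapse = ", ")))
  }
  sum(shares[!native]) / sum(shares)
}

#' Frequency of occurrence of a species across plots
#'
#' Percentage of plots on which the species is present (share > 0) in a set
#' of outcomes for one scenario.
#'
#' @param outcomes List of `scenario_outcome` (one scenario).
#' @param species Species code.
#' @return Percent in \[0, 100\].
#' @export
frequency_of_occurrence <- function(outcomes, species) {
  if (length(outcomes) == 0) abort("at least one plot required")
  present <- vapply(outcomes, function(o) species %in% names(outcome_shares(o)),
                    logical(1))
  100 * sum(present) / length(outcomes)
}

#' Avalanche-service eligibility of a plot
#'
#' The avalanche service is only assessed on terrain where avalanches can
#' release: centroids above 800 m altitude with slopes between 25 and 60
#' degrees.
#'
#' @param plot One-row plot record, or a plot table (vectorised).
#' @return Logical vector.
#' @export
avalanche_eligible <- function(plot) {
  plot$altitude > 800 & plot$slope >= 25 & plot$slope <= 60
}

#' Avalanche risk category of a stand
#'
#' Based on the share of wintergreen (evergreen) species, whose winter
#' canopy intercepts snow, and on stand volume as a stocking proxy: a stand
#' at or below 100 m3/ha is not fully stocked and is high risk regardless of
#' composition. Otherwise risk is low when the wintergreen share is at or
#' above 70%, high at or below 40%, moderate in between. Unstocked stands
#' are high risk: a bare slope protects nothing.
#'
#' @inheritParams production_value
#' @param volume Stand volume in m3 over bark per ha; defaults to the
#'   outcome's volume when a `scenario_outcome` is given.
#' @param native_wintergreen_only If `TRUE`, only the three native
#'   wintergreen conifers (Norway spruce, silver fir, Scots pine) count
#'   towards the wintergreen share; by default every evergreen registry
#'   species counts once planted.
#' @return One of `"high"`, `"moderate"`, `"low"`.
#' @export
avalanche_risk <- function(outcome, registry = load_registry(),
                           volume = NULL, native_wintergreen_only = FALSE) {
  shares <- outcome_shares(outcome)
  if (is.null(volume)) {
    if (!inherits(outcome, "scenario_outcome")) {
      abort("volume must be supplied when outcome is a share vector")
    }
    volume <- outcome$volume
  }
  if (length(shares) == 0) return("high")
  wg <- wintergreen_share(shares, registry, native_wintergreen_only) * 100
  if (volume <= AVALANCHE_VOLUME_HIGH || wg <= AVALANCHE_WINTERGREEN_HIGH) {
    "high"
  } else if (wg >= AVALANCHE_WINTERGREEN_LOW) {
    "low"
  } else {
    "moderate"
  }
}

wintergreen_share <- function(shares, registry, native_only = FALSE) {
  codes <- if (native_only) {
    intersect(names(shares), native_wintergreen_codes())
  } else {
    names(shares)[registry$evergreen[match(names(shares), registry$code)]]
  }
  sum(shares[codes]) / sum(shares)
}

#' Rockfall risk category of a stand
#'
#' Stand volume proxies the stand density that intercepts falling rocks:
#' low risk at or above 360 m3/ha, high risk at or below 180 m3/ha,
#' moderate in between. Only plots inside mapped rockfall hazard zones are
#' assessed (see `rockfall_zone` in the plot table); eligibility is the
#' caller's filter.
#'
#' @param volume Stand volume in m3 over bark per ha, or a
#'   `scenario_outcome`. Vectorised over numeric input.
#' @return Character vector in `c("high", "moderate", "low")`.
#' @examples
#' rockfall_risk(c(400, 250, 180))
#' @export
rockfall_risk <- function(volume) {
  if (inherits(volume, "scenario_outcome")) volume <- volume$volume
  if (any(!is.finite(volume)) || any(volume < 0)) {
    abort("volume must be a non-negative number")
  }
  dplyr::case_when(
    volume >= ROCKFALL_VOLUME_LOW ~ "low",
    volume <= ROCKFALL_VOLUME_HIGH ~ "high",
    TRUE ~ "moderate"
  )
}

#' Change of a service between the current stand and a scenario
#'
#' Returns the sign of the change on the service's scale: +1 improvement,
#' 0 no change, -1 deterioration. Risk categories are ordered
#' high < moderate < low (less risk is better), production categories
#' low < moderate < high. Numeric scores compare directly. For volume-based
#' services the percent change of volume relative to current is also
#' returned; it is `NA` (flagged) when the current volume is 0 and the
#' scenario volume is not.
#'
#' @param current,scenario Service scores on the same plot and service:
#'   both category labels, or both numeric.
#' @param service Scale of the scores: `"numeric"` (direct comparison, the
#'   default for numeric input), `"production"` (low < moderate < high) or
#'   `"risk"` (high < moderate < low; less risk is better). Required for
#'   character input because the two category scales share their labels with
#'   opposite ranking.
#' @param current_volume,scenario_volume Optional volumes for the percent
#'   change.
#' @return List with `change` in `c(-1, 0, 1)` and `percent` (possibly `NA`).
#' @export
change_vs_current <- function(current, scenario,
                              service = c("numeric", "production", "risk"),
                              current_volume = NULL, scenario_volume = NULL) {
  service <- match.arg(service)
  if (is.character(current) || is.character(scenario)) {
    if (service == "numeric") {
      abort("category scores need service = \"production\" or \"risk\"")
    }
    ord <- if (service == "risk") RISK_LEVELS else PRODUCTION_LEVELS
    bad <- setdiff(c(current, scenario), c(ord, "not_eligible"))
    if (length(bad) > 0) {
      abort(paste0("unknown category: ", paste(bad, collapse = ", ")))
    }
    delta <- match(scenario, ord) - match(current, ord)
  } else {
    delta <- scenario - current
  }
  percent <- NULL
  if (!is.null(current_volume) && !is.null(scenario_volume)) {
    percent <- if (current_volume == 0) {
      if (scenario_volume == 0) 0 else NA_real_
    } else {
      100 * (scenario_volume - current_volume) / current_volume
    }
  }
  list(change = sign(delta), percent = percent)
}

#' Score every service for a set of outcomes
#'
#' Convenience scorer producing a per-plot tibble of all services for one
#' scenario's outcomes, joined against the plot table for eligibility.
#' Protection categories are `"not_eligible"` outside the service's terrain
#' or hazard-zone filter.
#'
#' @param outcomes List of `scenario_outcome` in plot order.
#' @param plots Plot table matching `outcomes` (by `plot_id`).
#' @param registry A `species_registry`.
#' @param weighted,native_wintergreen_only Passed through to the individual
#'   scorers.
#' @return Tibble with one row per plot: `plot_id, scenario, volume,
#'   unstocked, production_value, production_category, richness, nnt_share,
#'   avalanche_risk, rockfall_risk`.
#' @export
score_services <- function(outcomes, plots, registry = load_registry(),
                           weighted = FALSE, native_wintergreen_only = FALSE) {
  ids <- vapply(outcomes, function(o) o$plot_id, character(1))
  idx <- match(ids, plots$plot_id)
  if (any(is.na(idx))) abort("outcome plot_id not present in plot table")
  elig_av <- avalanche_eligible(plots[idx, ])
  in_rockfall <- as.logical(plots$rockfall_zone[idx])

  pv <- vapply(outcomes, production_value, numeric(1),
               registry = registry, weighted = weighted)
  av <- character(length(outcomes))
  rf <- character(length(outcomes))
  for (i in seq_along(outcomes)) {
    av[i] <- if (elig_av[i]) {
      avalanche_risk(outcomes[[i]], registry,
                     native_wintergreen_only = native_wintergreen_only)
    } else {
      "not_eligible"
    }
    rf[i] <- if (in_rockfall[i]) rockfall_risk(outcomes[[i]]) else "not_eligible"
  }
  tibble::tibble(
    plot_id = ids,
    scenario = vapply(outcomes, function(o) o$scenario, character(1)),
    volume = vapply(outcomes, function(o) o$volume, numeric(1)),
    unstocked = vapply(outcomes, function(o) o$unstocked, logical(1)),
    production_value = pv,
    production_category = classify_production(pv),
    richness = vapply(outcomes, richness, integer(1)),
    nnt_share = vapply(outcomes, nnt_share, numeric(1), registry = registry),
    avalanche_risk = av,
    rockfall_risk = rf
  )
}
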