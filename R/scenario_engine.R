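# Scenario engine: the five species-change scenarios applied to a plot's
# composition under a future climate period. A failing (locally extinct)
# species vacates its growing space; depending on the scenario the space is
# recolonised by surviving residents, replanted with the most suitable
# species from a candidate pool, or left unstocked.
#
# The replacement rules operate on named share/suitability vectors in
# core_apply_scenario(); apply_scenario() wraps it for a single plot record
# and run_all_scenarios() drives it over a whole plot table without paying
# per-plot data-frame costs.

SCENARIO_TABLE <- tibble::tribble(
  ~label,          ~pool,      ~strategy,
  "no_adaptation", "resident", "none",
  "native_mss",    "native",   "mss",
  "combi_mss",     "combi",    "mss",
  "native_ccbb",   "native",   "ccbb",
  "combi_ccbb",    "combi",    "ccbb"
)

#' Define a species-change scenario
#'
#' The five scenarios differ in the candidate pool (natives only, or natives
#' plus non-natives) and the replacement strategy: none (no adaptation:
#' failing species can only be replaced by suitable species already present),
#' MSS (most suitable species: highest relative suitability wins), or CC/BB
#' (conifers preferably replaced by conifers and broadleaves by broadleaves,
#' falling back to the overall most suitable species when no same-form
#' candidate is suitable).
#'
#' @param label One of `"no_adaptation"`, `"native_mss"`, `"combi_mss"`,
#'   `"native_ccbb"`, `"combi_ccbb"`.
#' @param period Future period id, one of [periods()].
#' @return A `scenario_spec` list with fields `label`, `pool`, `strategy`,
#'   `period`.
#' @examples
#' scenario_spec("combi_mss", "rcp85_2081_2100")
#' @export
scenario_spec <- function(label, period = "rcp85_2081_2100") {
  i <- match(label, SCENARIO_TABLE$label)
  if (is.na(i)) {
    abort(paste0("unknown scenario label: ", label))
  }
  if (!period %in% PERIODS) {
    abort(paste0("unknown period: ", period))
  }
  structure(
    list(label = label, pool = SCENARIO_TABLE$pool[i],
         strategy = SCENARIO_TABLE$strategy[i], period = period),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$label, " (pool: ", x$pool,
      ", strategy: ", x$strategy, ", period: ", x$period, ")\n", sep = "")
  invisible(x)
}

# Deterministic argmax of relative suitability over candidate codes:
# ties broken by higher standardized increment, then by species code.
pick_best <- function(codes, relative, increment_std) {
  o <- order(-relative[codes], -increment_std[codes], codes)
  codes[o[1]]
}

#' Select the replacement species for a failing species
#'
#' Applies the scenario's replacement strategy over the suitable candidates:
#' MSS picks the candidate with the highest relative suitability; CC/BB first
#' restricts to candidates of the failing species' growth form (conifer or
#' broadleaf) and falls back to the unrestricted choice when no same-form
#' candidate is suitable. A species is never its own replacement. Ties in
#' relative suitability are broken by higher standardized increment, then by
#' species code, so the choice is deterministic.
#'
#' @param failing Code of the failing species.
#' @param candidates Suitability records for one plot and the scenario's
#'   period: tibble with columns `species`, `suitable`, `relative`, already
#'   restricted to the scenario pool by the caller ([apply_scenario()] does
#'   this; when calling directly, pass the pool you intend).
#' @param spec A `scenario_spec`.
#' @param registry A `species_registry` (growth form and tie-break lookup).
#' @return A species code, or `NA_character_` when no candidate is suitable.
#' @export
select_replacement <- function(failing, candidates, spec,
                               registry = load_registry()) {
  if (nrow(candidates) == 0) {
    abort("empty candidate set")
  }
  cand <- candidates$species[candidates$suitable & candidates$species != failing]
  if (length(cand) == 0) return(NA_character_)
  relative <- setNames(candidates$relative, candidates$species)
  inc <- setNames(registry$increment_std[match(candidates$species, registry$code)],
                  candidates$species)
  conifer <- setNames(registry$conifer[match(candidates$species, registry$code)],
                      candidates$species)
  if (spec$strategy == "ccbb") {
    failing_form <- registry$conifer[match(failing, registry$code)]
    same <- cand[conifer[cand] == failing_form]
    if (length(same) > 0) return(pick_best(same, relative, inc))
  }
  pick_best(cand, relative, inc)
}

# The rule core. All arguments are named vectors over species codes:
# shares (occurring species only, > 0), suitable (logical) and relative
# (numeric) must cover every occurring species; pool_codes is the candidate
# pool of the scenario (ignored for no_adaptation). Returns shares, volume,
# and the replacement log as plain vectors.
core_apply_scenario <- function(shares, volume, suitable, relative,
                                spec, pool_codes, conifer_flag, inc_std,
                                redistribution = "proportional") {
  occ <- names(shares)
  miss <- occ[!(occ %in% names(suitable))]
  if (length(miss) > 0) {
    abort(paste0("missing suitability record for occurring species: ",
                 paste(miss, collapse = ", ")))
  }
  failing <- occ[!suitable[occ]]
  surviving <- setdiff(occ, failing)
  log_failed <- character(0); log_receiver <- character(0); log_share <- numeric(0)

  if (length(failing) == 0) {
    return(list(shares = shares, volume = volume,
                failed = log_failed, receiver = log_receiver,
                share = log_share))
  }

  total_share <- sum(shares)
  failing_share <- sum(shares[failing])
  out_shares <- shares[surviving]

  if (spec$strategy == "none") {
    # Unadapted stands lose the failing timber in any case; the vacated
    # composition may be recolonised by surviving residents.
    out_volume <- volume * (1 - failing_share / total_share)
    if (length(surviving) > 0 && redistribution == "proportional") {
      weights <- out_shares / sum(out_shares)
      out_shares <- out_shares + failing_share * weights
      log_failed <- rep(failing, each = length(surviving))
      log_receiver <- rep(surviving, times = length(failing))
      log_share <- as.numeric(outer(weights, shares[failing]))
    } else {
      log_failed <- failing
      log_receiver <- rep(NA_character_, length(failing))
      log_share <- as.numeric(shares[failing])
    }
    return(list(shares = out_shares, volume = out_volume,
                failed = log_failed, receiver = log_receiver,
                share = log_share))
  }

  # Adaptation scenarios: candidates are the suitable pool species; a
  # failing species is unsuitable by definition and cannot receive.
  cand_all <- pool_codes[suitable[pool_codes]]
  cand_all <- cand_all[!is.na(cand_all)]
  lost_volume_fraction <- 0
  for (f in failing) {
    cand <- cand_all[cand_all != f]
    receiver <- NA_character_
    if (length(cand) > 0) {
      if (spec$strategy == "ccbb") {
        same <- cand[conifer_flag[cand] == conifer_flag[[f]]]
        receiver <- if (length(same) > 0) {
          pick_best(same, relative, inc_std)
        } else {
          pick_best(cand, relative, inc_std)
        }
      } else {
        receiver <- pick_best(cand, relative, inc_std)
      }
    }
    if (is.na(receiver)) {
      lost_volume_fraction <- lost_volume_fraction + shares[[f]] / total_share
    } else {
      if (receiver %in% names(out_shares)) {
        out_shares[[receiver]] <- out_shares[[receiver]] + shares[[f]]
      } else {
        out_shares[[receiver]] <- shares[[f]]
      }
    }
    log_failed <- c(log_failed, f)
    log_receiver <- c(log_receiver, receiver)
    log_share <- c(log_share, shares[[f]])
  }
  list(shares = out_shares, volume = volume * (1 - lost_volume_fraction),
       failed = log_failed, receiver = log_receiver, share = log_share)
}

registry_vectors <- function(registry) {
  list(
    conifer = setNames(registry$conifer, registry$code),
    inc_std = setNames(registry$increment_std, registry$code),
    native_codes = registry$code[registry$native],
    all_codes = registry$code
  )
}

pool_for <- function(spec, rv) {
  switch(spec$pool,
         resident = character(0),
         native = rv$native_codes,
         combi = rv$all_codes)
}

#' Apply one species-change scenario to one plot
#'
#' Identifies the locally failing species (occurring today, unsuitable in the
#' scenario's period), vacates their growing space and fills it according to
#' the scenario:
#'
#' * `no_adaptation`: each failing share is redistributed over the surviving
#'   suitable resident species proportionally to their current shares (or
#'   dropped when `redistribution = "drop"` or no resident survives). The
#'   stand volume is always reduced by the failing species' volume fraction:
#'   unadapted stands lose the failing timber.
#' * adaptation scenarios: each failing share is transferred whole to the
#'   species chosen by [select_replacement()] from the scenario pool
#'   (natives, or natives plus non-natives), merging with an existing share
#'   if the receiver is already present. Share and volume travel together,
#'   so volume is conserved whenever every failing species finds a receiver.
#'
#' A plot where no species remains is unstocked (zero shares, zero volume).
#'
#' @param plot One-row plot record (see [read_plots()]).
#' @param suitability Suitability table covering this plot and the scenario's
#'   period (other rows are ignored).
#' @param spec A `scenario_spec`.
#' @param registry A `species_registry`.
#' @param redistribution `no_adaptation` handling of vacated composition:
#'   `"proportional"` (default) or `"drop"` (leave the space vacant).
#' @return A `scenario_outcome` list: `plot_id`, `scenario`, `shares` (named
#'   vector over species with share > 0), `volume`, `unstocked`,
#'   `replacements` (tibble `failed, receiver, share`; `receiver` is `NA`
#'   for a dropped share).
#' @export
apply_scenario <- function(plot, suitability, spec,
                           registry = load_registry(),
                           redistribution = c("proportional", "drop")) {
  redistribution <- match.arg(redistribution)
  shares <- plot_shares(plot)
  shares <- shares[shares > 0]
  plot_id <- if (is.data.frame(plot) && "plot_id" %in% names(plot)) {
    plot$plot_id[[1]]
  } else {
    NA_character_
  }
  volume <- if (is.data.frame(plot) && "volume_m3_ha" %in% names(plot)) {
    plot$volume_m3_ha[[1]]
  } else {
    attr(plot, "volume") %||% 0
  }

  sub <- suitability[suitability$period == spec$period, ]
  if (nrow(sub) == 0) {
    abort(paste0("suitability table has no rows for period: ", spec$period))
  }
  if (!is.na(plot_id) && "plot_id" %in% names(sub)) {
    sub <- sub[sub$plot_id == plot_id, ]
  }
  suitable <- setNames(sub$suitable, sub$species)
  relative <- setNames(sub$relative, sub$species)

  rv <- registry_vectors(registry)
  pool <- intersect(pool_for(spec, rv), names(suitable))
  res <- core_apply_scenario(shares, volume, suitable, relative, spec, pool,
                             rv$conifer, rv$inc_std, redistribution)
  new_outcome(plot_id, spec$label, res$shares, res$volume,
              tibble::tibble(failed = res$failed, receiver = res$receiver,
                             share = res$share))
}

new_outcome <- function(plot_id, scenario, shares, volume, replacements) {
  shares <- shares[!is.na(shares) & shares > 0]
  shares <- shares[order(names(shares))]
  unstocked <- length(shares) == 0
  structure(
    list(plot_id = plot_id, scenario = scenario,
         shares = shares, volume = if (unstocked) 0 else volume,
         unstocked = unstocked, replacements = replacements),
    class = "scenario_outcome"
  )
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat("<scenario_outcome> ", x$plot_id, " [", x$scenario, "]\n", sep = "")
  if (x$unstocked) {
    cat("  unstocked\n")
  } else {
    cat("  shares:", paste0(names(x$shares), "=", signif(x$shares, 3),
                            collapse = " "), "\n")
    cat("  volume:", signif(x$volume, 5), "m3/ha\n")
  }
  invisible(x)
}

#' Outcome for the current (unmodified) stand
#'
#' Convenience wrapper producing a `scenario_outcome` labelled `"current"`
#' from a plot's present composition, so current and scenario stands can be
#' scored by the same service functions.
#'
#' @param plot One-row plot record.
#' @return A `scenario_outcome`.
#' @export
current_outcome <- function(plot) {
  shares <- plot_shares(plot)
  shares <- shares[shares > 0]
  new_outcome(plot$plot_id[[1]], "current", shares, plot$volume_m3_ha[[1]],
              tibble::tibble(failed = character(0), receiver = character(0),
                             share = numeric(0)))
}

# Current outcomes for every plot of a table, without per-row data-frame
# subsetting.
current_outcomes <- function(plots) {
  sh_cols <- grep("^share_", names(plots), value = TRUE)
  share_mat <- as.matrix(plots[sh_cols])
  colnames(share_mat) <- sub("^share_", "", sh_cols)
  empty_log <- tibble::tibble(failed = character(0), receiver = character(0),
                              share = numeric(0))
  lapply(seq_len(nrow(plots)), function(i) {
    shares <- share_mat[i, ]
    new_outcome(plots$plot_id[i], "current", shares[shares > 0],
                plots$volume_m3_ha[i], empty_log)
  })
}

#' Run all five scenarios over a plot table
#'
#' @param plots Plot table (one row per centroid, see [read_plots()]).
#' @param suitability Suitability table covering `period` for every plot.
#' @param period Future period id.
#' @param registry A `species_registry`.
#' @param scenarios Scenario labels to run (default all five).
#' @param redistribution Passed to [apply_scenario()].
#' @return Named list (by scenario label) of lists of `scenario_outcome`,
#'   each in plot order.
#' @export
run_all_scenarios <- function(plots, suitability, period,
                              registry = load_registry(),
                              scenarios = scenario_labels(),
                              redistribution = c("proportional", "drop")) {
  redistribution <- match.arg(redistribution)
  sub <- suitability[suitability$period == period, ]
  if (nrow(sub) == 0) {
    abort(paste0("suitability table has no rows for period: ", period))
  }

  # Dense plot x species matrices: one lookup per plot instead of repeated
  # data-frame filtering.
  sp_codes <- sort(unique(sub$species))
  sub <- sub[sub$plot_id %in% plots$plot_id, ]
  pi <- match(sub$plot_id, plots$plot_id)
  si <- match(sub$species, sp_codes)
  suit_mat <- matrix(NA, nrow = nrow(plots), ncol = length(sp_codes),
                     dimnames = list(plots$plot_id, sp_codes))
  rel_mat <- suit_mat
  suit_mat[cbind(pi, si)] <- sub$suitable
  rel_mat[cbind(pi, si)] <- sub$relative

  sh_cols <- grep("^share_", names(plots), value = TRUE)
  share_mat <- as.matrix(plots[sh_cols])
  colnames(share_mat) <- sub("^share_", "", sh_cols)
  volumes <- plots$volume_m3_ha
  ids <- plots$plot_id
  rv <- registry_vectors(registry)

  out <- vector("list", length(scenarios))
  names(out) <- scenarios
  for (lab in scenarios) {
    spec <- scenario_spec(lab, period)
    pool <- intersect(pool_for(spec, rv), sp_codes)
    out[[lab]] <- lapply(seq_len(nrow(plots)), function(i) {
      shares <- share_mat[i, ]
      shares <- shares[shares > 0]
      suitable <- suit_mat[i, ]
      suitable <- suitable[!is.na(suitable)]
      relative <- rel_mat[i, ]
      res <- core_apply_scenario(shares, volumes[i], suitable, relative,
                                 spec, pool[!is.na(suitable[pool])],
                                 rv$conifer, rv$inc_std, redistribution)
      new_outcome(ids[i], lab, res$shares, res$volume,
                  tibble::tibble(failed = res$failed, receiver = res$receiver,
                                 share = res$share))
    })
  }
  out
}

#' Flatten scenario outcomes to a long table
#'
#' @param outcomes A list of `scenario_outcome` (or a list of such lists, as
#'   returned by [run_all_scenarios()]).
#' @return Tibble `plot_id, scenario, species, share, volume, unstocked`;
#'   unstocked plots contribute one row with `species = NA`.
#' @export
outcomes_to_table <- function(outcomes) {
  if (length(outcomes) > 0 && inherits(outcomes[[1]], "scenario_outcome")) {
    outcomes <- list(outcomes)
  }
  rows <- purrr::map(outcomes, function(grp) {
    purrr::map(grp, function(o) {
      if (o$unstocked) {
        tibble::tibble(plot_id = o$plot_id, scenario = o$scenario,
                       species = NA_character_, share = 0,
                       volume = o$volume, unstocked = TRUE)
      } else {
        tibble::tibble(plot_id = o$plot_id, scenario = o$scenario,
                       species = names(o$shares), share = as.numeric(o$shares),
                       volume = o$volume, unstocked = FALSE)
      }
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
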