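# Suitability layer: thresholding continuous probabilities of occurrence
# into binary climatic suitability, relative suitability (the replacement
# ranking key), the white-oak merge, and the local-extinction rule.

#' Threshold a probability of occurrence into binary suitability
#'
#' A species is climatically suitable at a site when its modelled probability
#' of occurrence reaches its species-specific cut-off; probabilities below
#' the threshold are treated as absence. Equality at the cut-off counts as
#' suitable.
#'
#' @param probability Probability of occurrence in percent, in \[0, 100\].
#'   Vectorised.
#' @param cutoff Species cut-off in percent, in (0, 100\].
#' @return Logical vector.
#' @examples
#' binarize(c(56.4, 56.5), 56.5)
#' @export
binarize <- function(probability, cutoff) {
  check_prob_cutoff(probability, cutoff)
  probability >= cutoff
}

#' Relative climatic suitability
#'
#' Probability of occurrence divided by the species cut-off. Values of 1 or
#' more mean the species is suitable; the ratio is the ranking key used to
#' pick replacement species in the adaptation scenarios.
#'
#' @inheritParams binarize
#' @param mode `"ratio"` (default) returns probability/cutoff;
#'   `"difference"` returns (probability - cutoff)/cutoff + 1, i.e. an
#'   affine variant with the same unit point at the threshold. Both rank
#'   candidates identically for a fixed cut-off; ratio is the default
#'   reading of suitability "relative to" the threshold.
#' @return Numeric vector, \eqn{\ge 0} in ratio mode.
#' @examples
#' relative_suitability(92.8, 46.4)
#' @export
relative_suitability <- function(probability, cutoff, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  check_prob_cutoff(probability, cutoff)
  if (mode == "ratio") probability / cutoff else (probability - cutoff) / cutoff + 1
}

check_prob_cutoff <- function(probability, cutoff) {
  if (any(!is.finite(probability)) || any(probability < 0 | probability > 100)) {
    abort("probability out of [0,100]")
  }
  if (any(!is.finite(cutoff)) || any(cutoff <= 0 | cutoff > 100)) {
    abort("cutoff out of (0,100]")
  }
  invisible(NULL)
}

#' Merge the two white-oak suitabilities into Quercus spp.
#'
#' Inventory composition data does not discriminate *Q. petraea* from
#' *Q. robur*, so their modelled probabilities are merged by taking, per plot
#' and period, the species with the higher probability. The merged record is
#' judged against the *Quercus* spp. cut-off of the registry; the winning
#' species is kept as provenance.
#'
#' @param p_petraea,p_robur Probabilities in percent; `NA` is treated as 0.
#'   Vectorised (recycled to common length).
#' @param cutoff The merged-oak cut-off (default: registry value for "que").
#' @return Tibble with columns `probability`, `suitable`, `relative`,
#'   `source` ("petraea" or "robur"; ties go to petraea).
#' @examples
#' resolve_oaks(60, 50)
#' @export
resolve_oaks <- function(p_petraea, p_robur, cutoff = NULL) {
  if (is.null(cutoff)) {
    reg <- load_registry()
    cutoff <- reg$cutoff[reg$code == "que"]
  }
  p_petraea[is.na(p_petraea)] <- 0
  p_robur[is.na(p_robur)] <- 0
  n <- max(length(p_petraea), length(p_robur))
  p_petraea <- rep_len(p_petraea, n)
  p_robur <- rep_len(p_robur, n)
  prob <- pmax(p_petraea, p_robur)
  tibble::tibble(
    probability = prob,
    suitable = binarize(prob, cutoff),
    relative = relative_suitability(prob, cutoff),
    source = ifelse(p_petraea >= p_robur, "petraea", "robur")
  )
}

#' Build a suitability table from raw probabilities
#'
#' Takes long-format probabilities of occurrence (plot, species, period) and
#' derives the binary suitability and relative suitability columns from the
#' registry cut-offs. If the input carries the individual white oaks as
#' `"qpe"`/`"qro"` they are merged into `"que"` via [resolve_oaks()];
#' probabilities missing for a plot (e.g. outside a raster extent) may be
#' passed as `NA` and are treated as 0, i.e. unsuitable.
#'
#' @param probabilities Data frame with columns `plot_id`, `species`,
#'   `period`, `probability` (percent).
#' @param registry A `species_registry`.
#' @param mode Relative-suitability mode, see [relative_suitability()].
#' @return Tibble `plot_id, species, period, probability, suitable, relative`
#'   (plus `source` rows retained as an attribute `"oak_source"` when oaks
#'   were merged). Species codes are registry codes.
#' @export
build_suitability <- function(probabilities, registry = load_registry(),
                              mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  need <- c("plot_id", "species", "period", "probability")
  missing <- setdiff(need, names(probabilities))
  if (length(missing) > 0) {
    abort(paste0("probabilities table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(probabilities[need])
  tab$probability[is.na(tab$probability)] <- 0

  oak_source <- NULL
  if (any(tab$species %in% c("qpe", "qro"))) {
    oaks <- tab[tab$species %in% c("qpe", "qro"), ]
    rest <- tab[!tab$species %in% c("qpe", "qro"), ]
    wide <- tidyr::pivot_wider(oaks, id_cols = c("plot_id", "period"),
                               names_from = "species",
                               values_from = "probability",
                               values_fill = 0)
    if (!"qpe" %in% names(wide)) wide$qpe <- 0
    if (!"qro" %in% names(wide)) wide$qro <- 0
    que_cut <- registry$cutoff[registry$code == "que"]
    merged <- resolve_oaks(wide$qpe, wide$qro, cutoff = que_cut)
    oak_source <- tibble::tibble(plot_id = wide$plot_id, period = wide$period,
                                 source = merged$source)
    tab <- dplyr::bind_rows(
      rest,
      tibble::tibble(plot_id = wide$plot_id, species = "que",
                     period = wide$period, probability = merged$probability)
    )
  }

  unknown <- setdiff(unique(tab$species), registry$code)
  if (length(unknown) > 0) {
    abort(paste0("unknown species in probabilities: ",
                 paste(unknown, collapse = ", ")))
  }
  cut <- registry$cutoff[match(tab$species, registry$code)]
  out <- tab
  out$suitable <- binarize(out$probability, cut)
  out$relative <- relative_suitability(out$probability, cut, mode = mode)
  if (!is.null(oak_source)) attr(out, "oak_source") <- oak_source
  out
}

#' Species failing at a plot under a future period
#'
#' Species that occur today at the plot (share > 0) but are climatically
#' unsuitable in the given future period are considered unable to regenerate
#' and locally extinct in the long term.
#'
#' @param plot A single-plot record: either a one-row plot tibble with
#'   `share_*` columns (see [read_plots()]) or a named numeric vector of
#'   shares.
#' @param suitability Suitability table (from [build_suitability()]) filtered
#'   or filterable to the plot; rows for other plots/periods are ignored.
#' @param period Period id the failure is judged in.
#' @return Character vector of failing species codes (possibly empty).
#' @export
failing_species <- function(plot, suitability, period) {
  shares <- plot_shares(plot)
  occ <- names(shares)[shares > 0]
  if (length(occ) == 0) return(character(0))
  sub <- suitability[suitability$period == period, ]
  if ("plot_id" %in% names(sub) && is.data.frame(plot) && "plot_id" %in% names(plot)) {
    sub <- sub[sub$plot_id == plot$plot_id[[1]], ]
  }
  miss <- setdiff(occ, sub$species)
  if (length(miss) > 0) {
    abort(paste0("missing suitability record for occurring species: ",
                 paste(miss, collapse = ", ")))
  }
  suit <- setNames(sub$suitable, sub$species)
  occ[!suit[occ]]
}

# Accept either a named share vector or a one-row wide plot record.
plot_shares <- function(plot) {
  if (is.numeric(plot) && !is.null(names(plot))) {
    return(plot)
  }
  if (is.data.frame(plot)) {
    if (nrow(plot) != 1) abort("expected a single plot record")
    sh_cols <- grep("^share_", names(plot), value = TRUE)
    shares <- as.numeric(plot[1, sh_cols])
    names(shares) <- sub("^share_", "", sh_cols)
    return(shares)
  }
  abort("plot must be a named share vector or a one-row plot record")
}
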