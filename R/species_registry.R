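# Species registry: the 15 stand-forming taxa with their climatic cut-offs,
# mean annual increments and trait flags. The printed standardized increment
# values are canonical parameters for downstream scoring; the standardization
# helper exists for user-supplied increment sets.

# code, scientific name, native, conifer, evergreen, cutoff [%],
# increment [m3 over bark / ha / yr], standardized increment [-].
# Oaks are carried at the merged Quercus spp. level; the two white oak
# species exist only inside the suitability layer (see resolve_oaks).
REGISTRY_DEFAULTS <- tibble::tribble(
  ~code, ~scientific_name,          ~native, ~conifer, ~evergreen, ~cutoff, ~increment, ~increment_std,
  "aal", "Abies alba",              TRUE,    TRUE,     TRUE,       46.4,    15.59,      1.26,
  "fsy", "Fagus sylvatica",         TRUE,    FALSE,    FALSE,      50.2,     8.17,      0.66,
  "lde", "Larix decidua",           TRUE,    TRUE,     FALSE,      52.1,     7.76,      0.62,
  "pab", "Picea abies",             TRUE,    TRUE,     TRUE,       56.5,    11.77,      0.95,
  "psy", "Pinus sylvestris",        TRUE,    TRUE,     TRUE,       63.1,     7.47,      0.60,
  "que", "Quercus spp.",            TRUE,    FALSE,    FALSE,      48.3,     9.64,      0.78,
  "agr", "Abies grandis",           FALSE,   TRUE,     TRUE,       65.0,    31.85,      2.56,
  "fpe", "Fraxinus pennsylvanica",  FALSE,   FALSE,    FALSE,      56.7,     3.65,      0.29,
  "jni", "Juglans nigra",           FALSE,   FALSE,    FALSE,      62.8,     9.57,      0.77,
  "pco", "Pinus contorta",          FALSE,   TRUE,     TRUE,       69.1,     3.85,      0.31,
  "pra", "Pinus radiata",           FALSE,   TRUE,     TRUE,       53.2,    22.50,      1.81,
  "pme", "Pseudotsuga menziesii",   FALSE,   TRUE,     TRUE,       46.4,    19.08,      1.54,
  "qru", "Quercus rubra",           FALSE,   FALSE,    FALSE,      59.2,    11.15,      0.90,
  "rps", "Robinia pseudoacacia",    FALSE,   FALSE,    FALSE,      66.9,    10.68,      0.86,
  "tpl", "Thuja plicata",           FALSE,   TRUE,     TRUE,       55.5,    16.38,      1.32
)

# The three native wintergreen conifers named for avalanche interception.
NATIVE_WINTERGREEN <- c("pab", "aal", "psy")

REGISTRY_FIELDS <- c("code", "scientific_name", "native", "conifer",
                     "evergreen", "cutoff", "increment", "increment_std")

#' Load the species registry
#'
#' Returns the registry of stand-forming taxa used throughout the pipeline:
#' six native entries (the two white oaks merged as *Quercus* spp., since
#' inventory composition data does not discriminate them) and nine non-native
#' entries, each with its climatic cut-off threshold (percent probability of
#' occurrence below which a site is deemed unsuitable), its mean annual
#' volume increment and the standardized (dimensionless) increment used for
#' productivity scoring, plus trait flags (native, conifer, evergreen).
#'
#' The built-in standardized increments are used verbatim as canonical
#' scoring parameters rather than being recomputed from the increment column;
#' [standardize_increments()] is available for user-supplied increment sets.
#'
#' @param override_source Optional path to a delimited text file (CSV with a
#'   header) providing a full replacement registry. The file must contain one
#'   row per species with all of the columns `code`, `scientific_name`,
#'   `native`, `conifer`, `evergreen`, `cutoff`, `increment`,
#'   `increment_std`.
#' @return A `species_registry`: a tibble with one row per taxon.
#' @examples
#' reg <- load_registry()
#' reg[reg$code == "pab", c("cutoff", "increment_std")]
#' @export
load_registry <- function(override_source = NULL) {
  if (is.null(override_source)) {
    return(new_registry(REGISTRY_DEFAULTS))
  }
  if (!file.exists(override_source)) {
    abort(paste0("registry override file not found: ", override_source))
  }
  raw <- tibble::as_tibble(read.csv(override_source, stringsAsFactors = FALSE))
  missing <- setdiff(REGISTRY_FIELDS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("registry override missing required field(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- raw[REGISTRY_FIELDS]
  raw$native <- as.logical(raw$native)
  raw$conifer <- as.logical(raw$conifer)
  raw$evergreen <- as.logical(raw$evergreen)
  new_registry(raw)
}

new_registry <- function(df) {
  validate_registry(df)
  class(df) <- c("species_registry", class(df))
  df
}

validate_registry <- function(df) {
  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0) {
    abort(paste0("duplicate code in registry: ", paste(unique(dup), collapse = ", ")))
  }
  for (fld in c("cutoff", "increment", "increment_std")) {
    v <- df[[fld]]
    if (any(!is.finite(v))) {
      abort(paste0("missing or non-numeric value in field: ", fld))
    }
  }
  if (any(df$increment <= 0)) {
    abort("non-positive increment in field: increment")
  }
  if (any(df$increment_std <= 0)) {
    abort("non-positive value in field: increment_std")
  }
  if (any(df$cutoff <= 0 | df$cutoff > 100)) {
    abort("cutoff out of (0,100] in field: cutoff")
  }
  if (any(is.na(df$native) | is.na(df$conifer) | is.na(df$evergreen))) {
    abort("missing trait flag (native/conifer/evergreen)")
  }
  invisible(df)
}

#' Standardize annual increments
#'
#' Divides each species' mean annual volume increment by the arithmetic mean
#' increment over the supplied set, yielding a dimensionless productivity
#' contrast whose mean is 1.
#'
#' @param increments Named numeric vector of increments
#'   (m\eqn{^3} over bark ha\eqn{^{-1}} yr\eqn{^{-1}}), one per species; all
#'   values must be positive.
#' @return Named numeric vector of standardized increments, same names.
#' @examples
#' standardize_increments(c(a = 5, b = 15, c = 10))
#' @export
standardize_increments <- function(increments) {
  if (length(increments) == 0) {
    abort("empty increment map")
  }
  if (any(!is.finite(increments)) || any(increments <= 0)) {
    abort("non-positive value in field: increment")
  }
  increments / mean(increments)
}

#' Look up trait flags for a species
#'
#' @param code Species code present in `registry`.
#' @param registry A `species_registry`, default the built-in one.
#' @return Named logical vector `c(native=, conifer=, evergreen=)`.
#' @examples
#' traits("lde")  # deciduous conifer: native, conifer, not evergreen
#' @export
traits <- function(code, registry = load_registry()) {
  i <- match(code, registry$code)
  if (is.na(i)) {
    abort(paste0("unknown code: ", code))
  }
  c(native = registry$native[i],
    conifer = registry$conifer[i],
    evergreen = registry$evergreen[i])
}

#' Codes of the native wintergreen (evergreen) species
#'
#' The three native conifers that keep their needle canopy in winter and
#' therefore intercept snow: Norway spruce, silver fir and Scots pine.
#' European larch is the only deciduous conifer in the registry and is
#' excluded.
#'
#' @return Character vector of species codes.
#' @export
native_wintergreen_codes <- function() NATIVE_WINTERGREEN
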