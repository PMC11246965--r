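# Inventory I/O: plot tables, subplot-to-centroid aggregation, suitability
# raster sampling, zone-level summaries and result writing.
#
# Plot tables are delimited text (comma, UTF-8, header row) with one column
# per species share, prefixed "share_", and stand volume in "volume_m3_ha".

PLOT_BASE_COLS <- c("plot_id", "x", "y", "zone", "altitude", "slope",
                    "volume_m3_ha", "rockfall_zone")

#' Read a plot table
#'
#' Reads and validates a centroid-level plot table: one row per plot with
#' identifier, coordinates, environmental zone, terrain (altitude in m,
#' slope in degrees), per-species stand shares (`share_<code>` columns,
#' fractions summing to at most 1; sums below 1 are partially stocked
#' stands), stand volume over bark (m3/ha) and the rockfall hazard-zone
#' flag. Validation errors name the offending row and field.
#'
#' @param path Path to a CSV file.
#' @param registry A `species_registry`; share columns must use its codes.
#' @return Tibble of validated plot records.
#' @export
read_plots <- function(path, registry = load_registry()) {
  if (!file.exists(path)) abort(paste0("plot file not found: ", path))
  raw <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_plots(raw, registry)
}

#' Validate a plot table
#'
#' @param plots Data frame shaped like the [read_plots()] format.
#' @inheritParams read_plots
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_plots <- function(plots, registry = load_registry()) {
  plots <- tibble::as_tibble(plots)
  missing <- setdiff(PLOT_BASE_COLS, names(plots))
  if (length(missing) > 0) {
    abort(paste0("plot table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  sh_cols <- grep("^share_", names(plots), value = TRUE)
  codes <- sub("^share_", "", sh_cols)
  unknown <- setdiff(codes, registry$code)
  if (length(unknown) > 0) {
    abort(paste0("unknown species: ", paste(unknown, collapse = ", ")))
  }
  dup <- plots$plot_id[duplicated(plots$plot_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate plot_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_zone <- which(!plots$zone %in% ZONES | is.na(plots$zone))
  if (length(bad_zone) > 0) {
    abort(paste0("missing or unknown zone, row ", bad_zone[1]))
  }
  for (col in sh_cols) {
    v <- plots[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad) > 0) {
      abort(paste0("share out of range, row ", bad[1], " (", col, ")"))
    }
  }
  if (length(sh_cols) > 0) {
    tot <- rowSums(plots[sh_cols])
    bad <- which(tot > 1 + 1e-9)
    if (length(bad) > 0) {
      abort(paste0("share sum exceeds 1, row ", bad[1]))
    }
  }
  bad <- which(!is.finite(plots$altitude) | plots$altitude < 0)
  if (length(bad) > 0) abort(paste0("altitude out of range, row ", bad[1]))
  bad <- which(!is.finite(plots$slope) | plots$slope < 0 | plots$slope >= 90)
  if (length(bad) > 0) abort(paste0("slope out of range, row ", bad[1]))
  bad <- which(!is.finite(plots$volume_m3_ha) | plots$volume_m3_ha < 0)
  if (length(bad) > 0) abort(paste0("volume out of range, row ", bad[1]))
  plots$rockfall_zone <- as.logical(plots$rockfall_zone)
  plots
}

#' Write a plot table
#'
#' Inverse of [read_plots()]; shares and volume survive a round trip to at
#' least 6 decimals.
#'
#' @param plots Plot tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate subplot rows to centroids
#'
#' An inventory survey site consists of up to four subplots. Species shares
#' and stand volume are aggregated by the arithmetic mean, terrain (altitude
#' and slope) by the median (with the usual midpoint convention for an even
#' number of subplots). Sites where none of the registry species occurs are
#' dropped from the result and counted.
#'
#' @param subplots Data frame with a `site_id` column plus the plot-table
#'   columns (minus `plot_id`); 1-4 rows per site.
#' @inheritParams read_plots
#' @return List with `plots` (centroid tibble, `plot_id` = site id) and
#'   `n_dropped` (number of sites without any registry species).
#' @export
aggregate_subplots <- function(subplots, registry = load_registry()) {
  subplots <- tibble::as_tibble(subplots)
  if (!"site_id" %in% names(subplots)) abort("subplot table needs a site_id column")
  if (nrow(subplots) == 0) abort("zero subplots supplied")
  counts <- table(subplots$site_id)
  if (any(counts > 4)) {
    warn("site with more than 4 subplots; aggregating all rows")
  }
  sh_cols <- grep("^share_", names(subplots), value = TRUE)

  agg <- subplots |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      x = mean(.data$x),
      y = mean(.data$y),
      zone = .data$zone[1],
      altitude = stats::median(.data$altitude),
      slope = stats::median(.data$slope),
      volume_m3_ha = mean(.data$volume_m3_ha),
      rockfall_zone = any(as.logical(.data$rockfall_zone)),
      dplyr::across(dplyr::all_of(sh_cols), mean),
      .groups = "drop"
    ) |>
    dplyr::rename(plot_id = "site_id")

  stocked <- if (length(sh_cols) > 0) rowSums(agg[sh_cols]) > 0 else rep(FALSE, nrow(agg))
  list(
    plots = validate_plots(agg[stocked, ], registry),
    n_dropped = sum(!stocked)
  )
}

# --- plain-text rasters (ESRI ASCII grid) ---------------------------------

#' Read an ESRI ASCII grid raster
#'
#' Minimal reader for the plain-text `.asc` raster format (header lines
#' `ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value` followed by
#' rows of values, northmost row first).
#'
#' @param path Path to an `.asc` file.
#' @return List with `values` (matrix, rows = grid rows from north),
#'   `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(paste0("unreadable raster: ", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(paste0("unreadable raster (bad header): ", path))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(paste0("unreadable raster (cell count mismatch): ", path))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) m[m == nodata] <- NA
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid raster
#'
#' @param values Matrix of cell values (rows from north to south).
#' @param path Output path.
#' @param xll,yll Lower-left corner coordinates.
#' @param cellsize Cell size in coordinate units.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  values[is.na(values)] <- nodata
  hdr <- c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  body <- apply(values, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

grid_lookup <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row <- nrow(grid$values) - floor((y - grid$yll) / grid$cellsize)
  ok <- col >= 1 & col <= ncol(grid$values) & row >= 1 & row <= nrow(grid$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Sample suitability rasters at plot locations
#'
#' Nearest-cell lookup of per-species, per-period probability-of-occurrence
#' rasters at the plot coordinates. Rasters on a \[0, 1\] probability scale
#' (maximum finite value at most 1.5) are detected and rescaled to percent;
#' the applied scale is reported via a message. Plots outside a raster's
#' extent yield a missing probability and a warning; [build_suitability()]
#' treats missing as unsuitable.
#'
#' @param plots Plot table with `x`, `y` in the rasters' coordinate
#'   reference.
#' @param rasters Data frame with columns `species`, `period`, `path`
#'   (ESRI ASCII grid files), one row per raster.
#' @return Long tibble `plot_id, species, period, probability` suitable for
#'   [build_suitability()].
#' @export
sample_suitability_rasters <- function(plots, rasters) {
  need <- c("species", "period", "path")
  if (!all(need %in% names(rasters))) {
    abort("rasters table needs columns species, period, path")
  }
  rows <- purrr::map(seq_len(nrow(rasters)), function(i) {
    grid <- read_ascii_grid(rasters$path[i])
    p <- grid_lookup(grid, plots$x, plots$y)
    mx <- suppressWarnings(max(p, na.rm = TRUE))
    if (is.finite(mx) && mx <= 1.5) {
      message("raster ", rasters$path[i], ": values in [0,1], rescaled x100")
      p <- p * 100
    }
    if (any(is.na(p))) {
      warn(paste0("plot(s) outside raster extent or NODATA: ",
                  paste(plots$plot_id[is.na(p)], collapse = ", "),
                  " (", rasters$species[i], ", ", rasters$period[i], ")"))
    }
    tibble::tibble(plot_id = plots$plot_id, species = rasters$species[i],
                   period = rasters$period[i], probability = p)
  })
  dplyr::bind_rows(rows)
}

# --- reporting ------------------------------------------------------------

#' Zone-level summary of service scores
#'
#' Aggregates per-plot service scores to the environmental zones: unweighted
#' mean and standard deviation of richness, non-native share and production
#' value over all plots of the zone, and category counts for production
#' (all plots) and for the two protection services (eligible plots only).
#'
#' @param scores Per-plot score table from [score_services()] (any number of
#'   scenarios stacked).
#' @param plots Plot table supplying the zone assignment.
#' @return Tibble with one row per zone x scenario: means/SDs, category
#'   counts (`production_low`, ..., `avalanche_high`, ..., `rockfall_low`),
#'   `n_plots`, `n_avalanche_eligible`, `n_rockfall_eligible`,
#'   `n_unstocked`.
#' @export
zone_summary <- function(scores, plots) {
  zone <- plots$zone[match(scores$plot_id, plots$plot_id)]
  if (any(is.na(zone))) abort("score rows without a zone assignment")
  scores$zone <- zone
  count_cat <- function(x, lvl) sum(x == lvl)
  scores |>
    dplyr::group_by(.data$zone, .data$scenario) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      n_unstocked = sum(.data$unstocked),
      richness_mean = mean(.data$richness),
      richness_sd = stats::sd(.data$richness),
      nnt_share_mean = mean(.data$nnt_share),
      nnt_share_sd = stats::sd(.data$nnt_share),
      production_mean = mean(.data$production_value),
      production_sd = stats::sd(.data$production_value),
      production_low = count_cat(.data$production_category, "low"),
      production_moderate = count_cat(.data$production_category, "moderate"),
      production_high = count_cat(.data$production_category, "high"),
      n_avalanche_eligible = sum(.data$avalanche_risk != "not_eligible"),
      avalanche_high = count_cat(.data$avalanche_risk, "high"),
      avalanche_moderate = count_cat(.data$avalanche_risk, "moderate"),
      avalanche_low = count_cat(.data$avalanche_risk, "low"),
      n_rockfall_eligible = sum(.data$rockfall_risk != "not_eligible"),
      rockfall_high = count_cat(.data$rockfall_risk, "high"),
      rockfall_moderate = count_cat(.data$rockfall_risk, "moderate"),
      rockfall_low = count_cat(.data$rockfall_risk, "low"),
      .groups = "drop"
    )
}

#' Write pipeline outputs
#'
#' Writes the per-plot score table (one row per plot x scenario), the zone
#' summary in wide layout, and optionally a GeoJSON point collection whose
#' features carry the signed change of each service versus the current
#' stand (attribute values in -1/0/+1), mirroring the negative/positive
#' change encoding of change maps as data rather than styling.
#'
#' @param scores Stacked per-plot score table (all scenarios, including the
#'   `"current"` baseline if change output is wanted).
#' @param plots Plot table (zone, coordinates).
#' @param out_dir Output directory, created if needed.
#' @param geojson Also write `change_<scenario>.geojson` per non-current
#'   scenario with per-service change attributes.
#' @return Invisible character vector of files written.
#' @export
write_outputs <- function(scores, plots, out_dir, geojson = FALSE) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) abort(paste0("unwritable directory: ", out_dir))
  files <- character(0)

  per_plot <- tidyr::pivot_wider(
    scores,
    id_cols = "plot_id",
    names_from = "scenario",
    values_from = c("production_value", "production_category", "richness",
                    "nnt_share", "avalanche_risk", "rockfall_risk", "volume",
                    "unstocked")
  )
  f <- file.path(out_dir, "per_plot_scores.csv")
  write.csv(per_plot, f, row.names = FALSE)
  files <- c(files, f)

  zs <- zone_summary(scores, plots)
  f <- file.path(out_dir, "zone_summary.csv")
  write.csv(zs, f, row.names = FALSE)
  files <- c(files, f)

  if (geojson && "current" %in% scores$scenario) {
    cur <- scores[scores$scenario == "current", ]
    for (lab in setdiff(unique(scores$scenario), "current")) {
      sc <- scores[scores$scenario == lab, ]
      m <- match(sc$plot_id, cur$plot_id)
      pm <- match(sc$plot_id, plots$plot_id)
      feats <- purrr::map(seq_len(nrow(sc)), function(i) {
        j <- m[i]
        list(
          type = "Feature",
          geometry = list(type = "Point",
                          coordinates = c(plots$x[pm[i]], plots$y[pm[i]])),
          properties = list(
            plot_id = sc$plot_id[i],
            scenario = lab,
            production_change = change_vs_current(
              cur$production_category[j], sc$production_category[i],
              service = "production")$change,
            richness_change = sign(sc$richness[i] - cur$richness[j]),
            avalanche_change = change_vs_current(
              cur$avalanche_risk[j], sc$avalanche_risk[i],
              service = "risk")$change,
            rockfall_change = change_vs_current(
              cur$rockfall_risk[j], sc$rockfall_risk[i],
              service = "risk")$change,
            volume_change_percent = change_vs_current(
              0, 0, current_volume = cur$volume[j],
              scenario_volume = sc$volume[i])$percent
          )
        )
      })
      gj <- list(type = "FeatureCollection", features = feats)
      f <- file.path(out_dir, paste0("change_", lab, ".geojson"))
      jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
      files <- c(files, f)
    }
  }
  invisible(files)
}
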