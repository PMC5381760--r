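PHENOTYPE_LEVELS <- c("melanistic", "non_melanistic", "unconfirmed_melanistic")
SOURCE_LEVELS <- c("museum", "field_capture", "camera_trap", "communication")

#' Read and validate a location-record table
#'
#' Expects a CSV (or data.frame) with columns `id, lon, lat, phenotype,
#' source, year` (an optional `individual_id` column marks camera-trap
#' records identified as unique individuals). Coordinates must be decimal
#' degrees WGS84; phenotype one of `melanistic`, `non_melanistic`,
#' `unconfirmed_melanistic`.
#'
#' Records whose melanism is reported but not directly documented
#' (`unconfirmed_melanistic`) are flagged ineligible for phenotype
#' modelling (`eligible = FALSE`), conservatively treating melanism as
#' absent there; they remain in the table for mapping.
#'
#' @param path CSV file path, or a data.frame.
#' @return data.frame of validated records with an `eligible` column.
#' @export
read_records <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) {
    warning("record table is empty")
    df$eligible <- logical(0)
    return(df)
  }
  req <- c("id", "lon", "lat", "phenotype")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  bad <- which(is.na(df$lon) | is.na(df$lat) |
                 df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)
  if (length(bad))
    stop("malformed coordinates at row(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(df$phenotype), PHENOTYPE_LEVELS)
  if (length(unknown))
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "),
         " (expected ", paste(PHENOTYPE_LEVELS, collapse = "/"), ")")
  if (!is.null(df$source)) {
    unk <- setdiff(unique(df$source), SOURCE_LEVELS)
    if (length(unk))
      stop("unknown source label(s): ", paste(unk, collapse = ", "))
  }
  if (is.null(df$year)) df$year <- NA_integer_
  df$year <- suppressWarnings(as.integer(df$year))
  df$eligible <- df$phenotype != "unconfirmed_melanistic"
  df
}

#' Records eligible for phenotype modelling (confirmed phenotypes only)
#' @param records validated record table.
#' @export
modelling_records <- function(records) {
  records[records$eligible %in% TRUE, , drop = FALSE]
}

#' Collapse repeat camera-trap detections of the same animal
#'
#' Camera-trap records of the same phenotype lying within a buffer (default
#' diameter 25 km, the species' maximum reported home-range extent) are
#' assumed to be repeat detections of one individual unless explicitly
#' identified as unique (`individual_id` set); within each such cluster only
#' the first record is retained. Other source types are untouched.
#'
#' @param records validated record table.
#' @param diameter_km buffer diameter in km (default 25).
#' @return deduplicated record table.
#' @export
dedup_camera_traps <- function(records, diameter_km = 25) {
  if (nrow(records) < 2) return(records)
  identified <- if (is.null(records$individual_id)) rep(FALSE, nrow(records)) else
    !is.na(records$individual_id) & records$individual_id != ""
  cand <- which(records$source == "camera_trap" & !identified)
  keep <- rep(TRUE, nrow(records))
  kept <- integer(0)
  for (i in cand) {
    if (length(kept)) {
      same <- kept[records$phenotype[kept] == records$phenotype[i]]
      if (length(same)) {
        d <- haversine_km(records$lon[i], records$lat[i],
                          records$lon[same], records$lat[same])
        if (any(d < diameter_km)) { keep[i] <- FALSE; next }
      }
    }
    kept <- c(kept, i)
  }
  records[keep, , drop = FALSE]
}

#' Filter records for recency, exact duplicates and landscape modification
#'
#' Applies, in order: (1) age — drop records collected `max_age` or more
#' years before `reference_year`; (2) exact duplicates — among records at
#' bitwise-identical coordinates keep one (preferring a melanistic record
#' when phenotypes conflict, the rarer class); (3) landscape change — drop
#' records whose absolute NDVI change meets or exceeds `ndvi_cutoff`.
#' A record failing several rules is attributed to the first. Records that
#' fall outside the NDVI raster cannot be assessed and are kept with a
#' warning.
#'
#' @param records validated record table.
#' @param reference_year year against which age is measured.
#' @param ndvi_change optional list with `values` matrix and `grid`
#'   (e.g. from [read_esri_ascii()]) or a `synthetic_truth`'s layer + grid.
#' @param ndvi_grid grid for `ndvi_change` when given as a bare matrix.
#' @param ndvi_cutoff absolute NDVI-change threshold (default 0.7).
#' @param max_age age cutoff in years (default 20, applied as `>=`).
#' @return list with `records` (filtered) and `report` (a `filter_report`).
#' @export
filter_records <- function(records, reference_year, ndvi_change = NULL,
                           ndvi_grid = NULL, ndvi_cutoff = 0.7, max_age = 20) {
  n_input <- nrow(records)
  removed <- character(0)

  age <- reference_year - records$year
  old <- !is.na(age) & age >= max_age
  n_age <- sum(old)
  removed <- c(removed, records$id[old])
  rec <- records[!old, , drop = FALSE]

  key <- paste(sprintf("%.12f", rec$lon), sprintf("%.12f", rec$lat))
  dup_drop <- rep(FALSE, nrow(rec))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    mel <- idx[rec$phenotype[idx] == "melanistic"]
    keep_one <- if (length(mel)) mel[1] else idx[1]
    if (length(mel) && length(mel) < length(idx))
      warning("duplicate coordinates with conflicting phenotypes at ",
              k, "; keeping melanistic record ", rec$id[keep_one])
    dup_drop[setdiff(idx, keep_one)] <- TRUE
  }
  n_dup <- sum(dup_drop)
  removed <- c(removed, rec$id[dup_drop])
  rec <- rec[!dup_drop, , drop = FALSE]

  n_ndvi <- 0L
  if (!is.null(ndvi_change)) {
    if (is.list(ndvi_change) && !is.null(ndvi_change$values)) {
      ndvi_grid <- ndvi_change$grid
      ndvi_change <- ndvi_change$values
    }
    if (is.null(ndvi_grid)) stop("ndvi_grid required with a bare ndvi matrix")
    idx <- cell_from_xy(ndvi_grid, rec$lon, rec$lat)
    dv <- rep(NA_real_, nrow(rec))
    dv[!is.na(idx)] <- ndvi_change[idx[!is.na(idx)]]
    unfilterable <- is.na(dv)
    if (any(unfilterable))
      warning(sum(unfilterable),
              " record(s) outside the NDVI raster kept unassessed")
    drop_ndvi <- !is.na(dv) & abs(dv) >= ndvi_cutoff
    n_ndvi <- sum(drop_ndvi)
    removed <- c(removed, rec$id[drop_ndvi])
    rec <- rec[!drop_ndvi, , drop = FALSE]
  }

  report <- structure(
    list(n_input = n_input, n_removed_age = n_age, n_removed_duplicate = n_dup,
         n_removed_ndvi = n_ndvi, n_output = nrow(rec), removed_ids = removed),
    class = "filter_report")
  stopifnot(report$n_output ==
              report$n_input - n_age - n_dup - n_ndvi)
  list(records = rec, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d in -> %d out ",
                     "(age %d, duplicate %d, ndvi %d)\n"),
              x$n_input, x$n_output, x$n_removed_age, x$n_removed_duplicate,
              x$n_removed_ndvi))
  invisible(x)
}

#' Serialise a filter report to JSON
#' @param report a `filter_report`.
#' @param path optional output file.
#' @export
filter_report_json <- function(report, path = NULL) {
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(j, path)
  invisible(j)
}

#' Attach biome labels from a categorical raster
#'
#' @param records validated record table.
#' @param biomes integer matrix of biome class codes.
#' @param grid the `env_grid` of the biome raster.
#' @param levels optional character labels indexed by class code.
#' @return records with a `biome` column (`NA`, with a warning, for records
#'   off-grid or on nodata).
#' @export
assign_biomes <- function(records, biomes, grid, levels = NULL) {
  idx <- cell_from_xy(grid, records$lon, records$lat)
  code <- rep(NA_integer_, nrow(records))
  code[!is.na(idx)] <- biomes[idx[!is.na(idx)]]
  if (any(is.na(code)))
    warning(sum(is.na(code)), " record(s) have no biome (off-grid or nodata)")
  records$biome <- if (is.null(levels)) code else levels[code]
  records
}
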