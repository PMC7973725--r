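# CSV and GeoJSON interchange.

#' Write / read a tract table as CSV
#'
#' Plain-CSV round trip of a `tract_table`.  Columns are written as-is with
#' a header; the referral-centre attribute is not persisted (it is
#' recomputable as the population-weighted centroid, and `dist_centre` is a
#' column).
#'
#' @param tracts a `tract_table`.
#' @param path file path.
#' @return `write_tract_table`: the path, invisibly. `read_tract_table`:
#'   a `tract_table`.
#' @export
write_tract_table <- function(tracts, path) {
  utils::write.csv(as.data.frame(tracts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tract_table
#' @export
read_tract_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("tract_table", "data.frame")
  out
}

#' Write / read patient records as CSV
#'
#' @param patients patient records data frame.
#' @param path file path.
#' @return The path (write) or the records (read).
#' @export
write_patient_records <- function(patients, path) {
  utils::write.csv(as.data.frame(patients), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_records
#' @export
read_patient_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export tracts as GeoJSON square tiles
#'
#' Writes a GeoJSON FeatureCollection with one square tile per tract,
#' centred on the tract centroid, carrying the tract attributes (and any
#' extra per-tract values) as feature properties.  Coordinates are the
#' synthetic planar km coordinates; any GIS tool can render the result as a
#' choropleth.
#'
#' @param tracts a `tract_table`.
#' @param path output file path.
#' @param values optional named list of extra per-tract property vectors
#'   (e.g. estimated rates).
#' @param tile_km tile side length in km.
#' @return The path, invisibly.
#' @export
tracts_geojson <- function(tracts, path, values = NULL, tile_km = 1) {
  h <- tile_km / 2
  keep <- setdiff(names(tracts), c("x", "y"))
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    x <- tracts$x[i]; y <- tracts$y[i]
    props <- as.list(tracts[i, keep, drop = FALSE])
    for (nm in names(values)) props[[nm]] <- values[[nm]][i]
    list(type = "Feature",
         geometry = list(
           type = "Polygon",
           coordinates = list(list(c(x - h, y - h), c(x + h, y - h),
                                   c(x + h, y + h), c(x - h, y + h),
                                   c(x - h, y - h)))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write rate estimates as CSV
#'
#' Rates are rounded to 3 decimals, the convention for rates per 100,000.
#'
#' @param estimates a `rate_estimate` data frame (rows may be concatenated
#'   with `rbind`).
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_rate_estimates <- function(estimates, path) {
  df <- as.data.frame(estimates)
  for (col in c("point", "lower", "upper"))
    if (col %in% names(df)) df[[col]] <- round(df[[col]], 3)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
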