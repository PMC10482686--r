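# Domain containers and occurrence-table I/O shared by every analysis stage.

.guild_levels <- c("suspension", "deposit", "scavenger_predator", "unknown")
.occ_required <- c("specimen_id", "image_id", "site", "latitude", "longitude", "depth")
.occ_optional <- c("morphotype", "higher_taxon", "phylum", "guild", "area")

# Fixed metadata column set written before taxon columns in sample matrices.
.sample_meta_cols <- c(
  "sample_id", "location_id", "site", "mode",
  "depth_bin_low", "depth_bin_high", "mean_depth",
  "mean_latitude", "mean_longitude", "n_specimens", "area", "poc_flux"
)

#' Construct a validated occurrence table
#'
#' An occurrence table pairs one row per detected specimen with the set of
#' image frames the specimens were annotated on. Frames carry the seabed area
#' (m^2) needed for density work; video-derived frames have no area and are
#' excluded from standing-stock analyses by [filter_subset()].
#'
#' @param records data frame with columns `specimen_id`, `image_id`, `site`,
#'   `latitude`, `longitude`, `depth`, and optionally `morphotype`,
#'   `higher_taxon`, `phylum`, `guild`. An `id_level` column
#'   (`"morphotype"`/`"higher_only"`) is derived from `morphotype` presence.
#' @param frames data frame with columns `image_id`, `site`, `latitude`,
#'   `longitude`, `depth` and optional `area` (m^2, `NA` for video).
#' @param provenance free-text origin note.
#' @return An object of class `occurrence_table`: a list with elements
#'   `records`, `frames`, `provenance`.
#' @export
occurrence_table <- function(records, frames, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  frames <- as.data.frame(frames, stringsAsFactors = FALSE)
  for (col in .occ_required) {
    if (!col %in% names(records)) {
      stop("records missing mandatory column: ", col, call. = FALSE)
    }
  }
  for (col in c("morphotype", "higher_taxon", "phylum", "guild")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  if (!"area" %in% names(frames)) frames$area <- NA_real_

  if (anyDuplicated(records$specimen_id)) {
    stop("duplicate specimen_id values", call. = FALSE)
  }
  if (anyDuplicated(frames$image_id)) {
    stop("duplicate image_id values in frames", call. = FALSE)
  }
  missing_frames <- setdiff(records$image_id, frames$image_id)
  if (length(missing_frames)) {
    stop("records reference unknown image_id: ",
         paste(utils::head(missing_frames, 5), collapse = ", "), call. = FALSE)
  }

  .check_coords(records, what = "record")
  if (nrow(frames)) {
    bad_area <- !is.na(frames$area) & frames$area <= 0
    if (any(bad_area)) stop("frame area must be positive when present", call. = FALSE)
  }

  mt <- records$morphotype
  mt[!is.na(mt) & !nzchar(trimws(mt))] <- NA_character_
  records$morphotype <- mt
  records$id_level <- ifelse(is.na(mt), "higher_only", "morphotype")

  g <- records$guild
  g[is.na(g) | !nzchar(trimws(g))] <- "unknown"
  bad_g <- !g %in% .guild_levels
  if (any(bad_g)) {
    stop("unknown guild value(s): ",
         paste(unique(g[bad_g]), collapse = ", "), call. = FALSE)
  }
  records$guild <- g

  structure(
    list(records = records, frames = frames, provenance = provenance),
    class = "occurrence_table"
  )
}

.check_coords <- function(df, what) {
  for (col in c("latitude", "longitude", "depth")) {
    if (anyNA(df[[col]])) {
      stop(what, "s with missing ", col, " are rejected (rows ",
           paste(utils::head(which(is.na(df[[col]])), 5), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  if (any(df$depth <= 0 | df$depth >= 11000)) {
    stop("depth out of range (0, 11000) m", call. = FALSE)
  }
  if (any(abs(df$latitude) > 90)) stop("|latitude| > 90", call. = FALSE)
  if (any(df$longitude < -180 | df$longitude > 180)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("<occurrence_table> ", nrow(x$records), " specimens on ",
      nrow(x$frames), " frames, ",
      sum(x$records$id_level == "morphotype"), " identified to morphotype\n",
      sep = "")
  invisible(x)
}

#' Read a specimen occurrence table from CSV
#'
#' Expects one row per detected specimen with a header naming at least
#' `specimen_id`, `image_id`, `site`, `latitude`, `longitude`, `depth`
#' (canonical lower-snake-case names; deviating dialects are absorbed with
#' `aliases`). Optional columns: `morphotype`, `higher_taxon`, `phylum`,
#' `guild`, `area` (frame seabed area in m^2, repeated per specimen).
#' Rows lacking a morphotype are kept with `id_level = "higher_only"`.
#'
#' @param path CSV file path.
#' @param catalogue optional morphotype catalogue (see [read_catalogue()]);
#'   when given, morphotype labels absent from it are reported via a warning
#'   and recorded in the `unmatched_morphotypes` attribute, and missing
#'   phylum/higher-taxon/guild fields are filled from the catalogue.
#' @param aliases named character vector mapping canonical column names to the
#'   file's column names, e.g. `c(depth = "Depth_m")`.
#' @return An [occurrence_table()].
#' @export
read_occurrences <- function(path, catalogue = NULL, aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!is.null(aliases)) {
    for (canon in names(aliases)) {
      j <- match(aliases[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  missing <- setdiff(.occ_required, names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("latitude", "longitude", "depth", "area")) {
    if (!col %in% names(raw)) next
    txt <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) & nzchar(txt) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("unparsable ", col, " on line ", bad[1] + 1L, ": '",
           raw[[col]][bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- num
  }

  records <- raw[intersect(c(.occ_required, .occ_optional), names(raw))]
  records$area <- NULL

  # one frame per image; coordinates/area taken from its first record
  first <- !duplicated(raw$image_id)
  frames <- data.frame(
    image_id = raw$image_id[first],
    site = raw$site[first],
    latitude = raw$latitude[first],
    longitude = raw$longitude[first],
    depth = raw$depth[first],
    area = if ("area" %in% names(raw)) raw$area[first] else NA_real_,
    stringsAsFactors = FALSE
  )

  if (!is.null(catalogue)) {
    records <- .apply_catalogue(records, catalogue)
  }
  tab <- occurrence_table(records, frames, provenance = path)
  if (!is.null(catalogue)) {
    attr(tab, "unmatched_morphotypes") <- attr(records, "unmatched_morphotypes")
  }
  tab
}

.apply_catalogue <- function(records, catalogue) {
  catalogue <- as.data.frame(catalogue, stringsAsFactors = FALSE)
  mt <- records$morphotype
  known <- !is.na(mt) & nzchar(trimws(ifelse(is.na(mt), "", mt)))
  unmatched <- setdiff(unique(mt[known]), catalogue$morphotype)
  if (length(unmatched)) {
    warning("morphotype label(s) absent from catalogue: ",
            paste(utils::head(unmatched, 10), collapse = ", "), call. = FALSE)
  }
  j <- match(mt, catalogue$morphotype)
  for (col in c("phylum", "higher_taxon", "guild")) {
    if (!col %in% names(catalogue)) next
    if (!col %in% names(records)) records[[col]] <- NA_character_
    fill <- is.na(records[[col]]) & !is.na(j)
    records[[col]][fill] <- catalogue[[col]][j[fill]]
  }
  attr(records, "unmatched_morphotypes") <- unmatched
  records
}

#' Read a morphotype catalogue
#'
#' CSV with columns `morphotype`, `qualifier` (open-nomenclature qualifier,
#' carried as metadata only), `phylum`, `higher_taxon`, `guild`. Every
#' catalogue morphotype is treated as a distinct species-level unit.
#'
#' @param path CSV file path.
#' @return data frame, one row per morphotype.
#' @export
read_catalogue <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"morphotype" %in% names(cat)) {
    stop("catalogue must have a 'morphotype' column", call. = FALSE)
  }
  if (anyDuplicated(cat$morphotype)) {
    stop("duplicate morphotype in catalogue", call. = FALSE)
  }
  cat
}

#' Subset an occurrence table for biodiversity or standing-stock analyses
#'
#' `mode = "BD"` (biodiversity) keeps only specimens identified to morphotype
#' level, from any frame type. `mode = "SS"` (standing stock) keeps specimens
#' at all identification levels but only from frames with a measured seabed
#' area (scalable stills), so that densities are well defined.
#'
#' @param table an [occurrence_table()].
#' @param mode `"BD"` or `"SS"`.
#' @return A filtered [occurrence_table()].
#' @export
filter_subset <- function(table, mode = c("BD", "SS")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "occurrence_table"))
  rec <- table$records
  if (mode == "BD") {
    keep <- rec$id_level == "morphotype"
  } else {
    has_area <- table$frames$image_id[!is.na(table$frames$area)]
    keep <- rec$image_id %in% has_area
  }
  rec <- rec[keep, , drop = FALSE]
  frames <- table$frames[table$frames$image_id %in% rec$image_id, , drop = FALSE]
  if (mode == "SS") {
    # retain all measured frames at surveyed positions, including empty ones:
    # they contribute area to density denominators
    frames <- table$frames[!is.na(table$frames$area), , drop = FALSE]
  }
  out <- table
  out$records <- rec
  out$frames <- frames
  attr(out, "subset_mode") <- mode
  out
}

#' Construct a set of community samples
#'
#' A community sample is an equally sized, location- and depth-bin-constrained
#' set of specimens summarised as an abundance vector over taxa. Created by
#' [make_samples()]; this constructor validates an assembled set.
#'
#' @param meta data frame with the metadata columns
#'   `sample_id, location_id, site, mode, depth_bin_low, depth_bin_high,
#'   mean_depth, mean_latitude, mean_longitude, n_specimens, area, poc_flux`.
#' @param abundance numeric matrix, samples x taxa, with `rownames` equal to
#'   `meta$sample_id`.
#' @return An object of class `community_samples`.
#' @export
community_samples <- function(meta, abundance) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing <- setdiff(.sample_meta_cols, names(meta))
  if (length(missing)) {
    stop("sample metadata missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- meta[.sample_meta_cols]
  abundance <- as.matrix(abundance)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (nrow(abundance) != nrow(meta) ||
      (nrow(meta) > 0 &&
       !identical(rownames(abundance), as.character(meta$sample_id)))) {
    stop("abundance rows must match meta$sample_id", call. = FALSE)
  }
  if (any(abundance < 0)) stop("negative abundance", call. = FALSE)
  tot <- rowSums(abundance)
  if (nrow(meta) && any(abs(tot - meta$n_specimens) > 1e-8)) {
    stop("n_specimens must equal the abundance row sum", call. = FALSE)
  }
  bad_bin <- meta$mean_depth < meta$depth_bin_low |
    meta$mean_depth >= meta$depth_bin_high
  if (nrow(meta) && any(bad_bin)) {
    stop("mean_depth outside depth bin for sample(s): ",
         paste(meta$sample_id[bad_bin], collapse = ", "), call. = FALSE)
  }
  structure(list(meta = meta, abundance = abundance),
            class = "community_samples")
}

#' @export
print.community_samples <- function(x, ...) {
  cat("<community_samples> ", nrow(x$meta), " samples x ",
      ncol(x$abundance), " taxa (mode: ",
      paste(unique(x$meta$mode), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Number of samples in a community-sample set
#' @param x a `community_samples` object.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$meta)

#' Write community samples to a wide CSV
#'
#' One row per sample: the metadata columns first, then one column per taxon.
#' Round-trips losslessly through [read_samples()].
#'
#' @param samples a `community_samples` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "community_samples"))
  clash <- intersect(colnames(samples$abundance), .sample_meta_cols)
  if (length(clash)) {
    stop("taxon label collides with metadata column: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  wide <- cbind(samples$meta,
                as.data.frame(samples$abundance, check.names = FALSE))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read community samples written by [write_samples()]
#' @param path CSV path.
#' @return A `community_samples` object.
#' @export
read_samples <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.sample_meta_cols, names(wide))
  if (length(missing)) {
    stop("not a sample table; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- wide[.sample_meta_cols]
  for (col in c("depth_bin_low", "depth_bin_high", "mean_depth",
                "mean_latitude", "mean_longitude", "n_specimens",
                "area", "poc_flux")) {
    meta[[col]] <- as.numeric(meta[[col]])  # all-NA columns read as logical
  }
  taxa <- setdiff(names(wide), .sample_meta_cols)
  ab <- as.matrix(wide[taxa])
  rownames(ab) <- as.character(meta$sample_id)
  community_samples(meta, ab)
}

#' Write an occurrence table to CSV (one row per specimen)
#'
#' The inverse of [read_occurrences()]: frame area is repeated on each
#' specimen row of its image.
#'
#' @param table an [occurrence_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(table, path) {
  stopifnot(inherits(table, "occurrence_table"))
  rec <- table$records
  j <- match(rec$image_id, table$frames$image_id)
  rec$area <- table$frames$area[j]
  rec$id_level <- NULL
  utils::write.csv(rec, path, row.names = FALSE, na = "")
  invisible(path)
}
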