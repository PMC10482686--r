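# Gridded survey design: geographic locations and specimen-rarefied
# replicate community samples (the BD / SS sampling scheme).

.earth_radius_km <- 6371

#' Sampling plan for replicate community-sample generation
#'
#' @param cell_size_km grid-cell edge (km); occurrences are constrained to
#'   geographic locations of `cell_size_km^2` km^2.
#' @param depth_bin_width_m depth-bin width (m); samples never mix specimens
#'   across bins.
#' @param bd_size exact specimen count of a biodiversity (BD) sample.
#' @param ss_min,ss_max specimen-count window of a standing-stock (SS) sample.
#' @param seed integer seed driving every random choice in [make_samples()].
#' @return list of class `sampling_plan`.
#' @export
sampling_plan <- function(cell_size_km = 10, depth_bin_width_m = 200,
                          bd_size = 200, ss_min = 450, ss_max = 500,
                          seed = 1L) {
  stopifnot(cell_size_km > 0, depth_bin_width_m > 0, bd_size > 0,
            ss_min > 0, ss_min <= ss_max)
  structure(list(cell_size_km = cell_size_km,
                 depth_bin_width_m = depth_bin_width_m,
                 bd_size = as.integer(bd_size),
                 ss_min = as.integer(ss_min), ss_max = as.integer(ss_max),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# local equirectangular projection about (lat0, lon0), in km
project_local <- function(latitude, longitude, lat0, lon0) {
  if (any(abs(latitude) > 85)) {
    stop("record latitude outside projection validity (|lat| > 85)",
         call. = FALSE)
  }
  rad <- pi / 180
  list(x = .earth_radius_km * cos(lat0 * rad) * (longitude - lon0) * rad,
       y = .earth_radius_km * (latitude - lat0) * rad)
}

#' Assign occurrence records to gridded geographic locations
#'
#' Specimens are projected with a local equirectangular projection about the
#' dataset centroid and partitioned by floor division of the projected
#' coordinates into `cell_size_km` cells; a location is one site x cell
#' combination (locations never merge across sites). At abyssal-plain working
#' latitudes the projection distortion over a 10-km cell is negligible.
#'
#' @param table an [occurrence_table()].
#' @param plan a [sampling_plan()].
#' @return list of class `grid_locations`: `locations` (one row per location:
#'   `location_id, site, cell_x, cell_y, mean_latitude, mean_longitude,
#'   n_records`) and `records` (the table's records with a `location_id`
#'   column appended).
#' @export
assign_grid_locations <- function(table, plan = sampling_plan()) {
  stopifnot(inherits(table, "occurrence_table"))
  rec <- table$records
  if (!nrow(rec)) {
    return(structure(list(
      locations = data.frame(location_id = character(), site = character(),
                             cell_x = integer(), cell_y = integer(),
                             mean_latitude = numeric(),
                             mean_longitude = numeric(),
                             n_records = integer()),
      records = cbind(rec, location_id = character(0))),
      class = "grid_locations"))
  }
  lat0 <- mean(rec$latitude)
  lon0 <- mean(rec$longitude)
  xy <- project_local(rec$latitude, rec$longitude, lat0, lon0)
  cx <- floor(xy$x / plan$cell_size_km)
  cy <- floor(xy$y / plan$cell_size_km)
  loc_id <- sprintf("%s_c%d_%d", rec$site, cx, cy)
  rec$location_id <- loc_id
  agg <- data.frame(location_id = loc_id, site = rec$site,
                    cell_x = cx, cell_y = cy,
                    latitude = rec$latitude, longitude = rec$longitude)
  locs <- do.call(rbind, lapply(split(agg, agg$location_id), function(d) {
    data.frame(location_id = d$location_id[1], site = d$site[1],
               cell_x = d$cell_x[1], cell_y = d$cell_y[1],
               mean_latitude = mean(d$latitude),
               mean_longitude = mean(d$longitude),
               n_records = nrow(d), stringsAsFactors = FALSE)
  }))
  locs <- locs[order(locs$location_id), , drop = FALSE]
  rownames(locs) <- NULL
  structure(list(locations = locs, records = rec), class = "grid_locations")
}

#' Split a record set into aligned half-open depth bins
#'
#' Bins are `[k*w, (k+1)*w)` metres, aligned to multiples of the bin width
#' `w`; empty bins are omitted.
#'
#' @param records data frame with a `depth` column.
#' @param plan a [sampling_plan()] (uses `depth_bin_width_m`).
#' @return named list of record subsets; names are `"<low>-<high>"`, ordered
#'   by increasing depth.
#' @export
bin_by_depth <- function(records, plan = sampling_plan()) {
  w <- plan$depth_bin_width_m
  low <- floor(records$depth / w) * w
  out <- split(records, low)
  lows <- as.numeric(names(out))
  names(out) <- sprintf("%g-%g", lows, lows + w)
  out[order(lows)]
}

#' Generate equally sized replicate community samples
#'
#' Within each geographic location x 200-m depth bin, specimens are shuffled
#' with the plan's seeded generator and rarefied without replacement:
#'
#' * `mode = "BD"`: partitioned into `floor(n / bd_size)` samples of exactly
#'   `bd_size` morphotype-identified specimens; the remainder is discarded
#'   (never pooled across bins or locations).
#' * `mode = "SS"`: whole images are accumulated in shuffled order until the
#'   running specimen count falls in `[ss_min, ss_max]`; an image whose
#'   inclusion would overshoot `ss_max` is set aside and accumulation
#'   continues; groups that never reach `ss_min` are discarded. Images are
#'   never split, so the sample's summed seabed area is well defined.
#'
#' Each specimen appears in at most one sample. Sample metadata (mean depth,
#' mean position; SS: summed area) is computed from the sample's own members.
#'
#' @param table an [occurrence_table()] already passed through
#'   [filter_subset()] with the same `mode`.
#' @param mode `"BD"` or `"SS"`.
#' @param plan a [sampling_plan()].
#' @return A `community_samples` object. Taxon columns are morphotypes (BD)
#'   or morphotype-or-higher-taxon labels (SS, higher-only records labelled
#'   `higher:<taxon>`).
#' @export
make_samples <- function(table, mode = c("BD", "SS"), plan = sampling_plan()) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "occurrence_table"))
  gl <- assign_grid_locations(table, plan)
  rec <- gl$records
  if (mode == "BD") {
    if (any(rec$id_level != "morphotype")) {
      stop("BD sampling requires filter_subset(table, 'BD') first",
           call. = FALSE)
    }
    rec$taxon <- rec$morphotype
  } else {
    j <- match(rec$image_id, table$frames$image_id)
    if (anyNA(table$frames$area[j])) {
      stop("SS sampling requires frames with measured area; ",
           "apply filter_subset(table, 'SS') first", call. = FALSE)
    }
    rec$taxon <- ifelse(rec$id_level == "morphotype", rec$morphotype,
                        paste0("higher:", rec$higher_taxon))
  }

  pieces <- with_seed(plan$seed, {
    out <- list()
    for (loc in sort(unique(rec$location_id))) {
      loc_rec <- rec[rec$location_id == loc, , drop = FALSE]
      bins <- bin_by_depth(loc_rec, plan)
      for (bn in names(bins)) {
        groups <- if (mode == "BD") {
          .partition_bd(bins[[bn]], plan)
        } else {
          .partition_ss(bins[[bn]], table$frames, plan)
        }
        for (g in groups) {
          g$location_id <- loc
          g$bin_name <- bn
          out[[length(out) + 1L]] <- g
        }
      }
    }
    out
  })

  .assemble_samples(pieces, mode, table$frames, plan)
}

.partition_bd <- function(recs, plan) {
  n <- nrow(recs)
  k <- n %/% plan$bd_size
  if (k == 0) return(list())
  shuffled <- recs[sample.int(n), , drop = FALSE]
  lapply(seq_len(k), function(i) {
    shuffled[((i - 1) * plan$bd_size + 1):(i * plan$bd_size), , drop = FALSE]
  })
}

.partition_ss <- function(recs, frames, plan) {
  imgs <- unique(recs$image_id)
  imgs <- imgs[sample.int(length(imgs))]
  counts <- table(recs$image_id)[imgs]
  groups <- list()
  current <- character()
  total <- 0L
  for (i in seq_along(imgs)) {
    n_i <- as.integer(counts[[i]])
    if (total + n_i > plan$ss_max) next  # set aside; never split an image
    current <- c(current, imgs[i])
    total <- total + n_i
    if (total >= plan$ss_min) {
      groups[[length(groups) + 1L]] <-
        recs[recs$image_id %in% current, , drop = FALSE]
      current <- character()
      total <- 0L
    }
  }
  groups  # a trailing partial group (< ss_min) is discarded
}

.assemble_samples <- function(pieces, mode, frames, plan) {
  taxa <- sort(unique(unlist(lapply(pieces, function(p) p$taxon))))
  w <- plan$depth_bin_width_m
  meta_rows <- vector("list", length(pieces))
  ab <- matrix(0, nrow = length(pieces), ncol = length(taxa),
               dimnames = list(NULL, taxa))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    lims <- as.numeric(strsplit(p$bin_name[1], "-", fixed = TRUE)[[1]])
    area <- NA_real_
    if (mode == "SS") {
      area <- sum(frames$area[match(unique(p$image_id), frames$image_id)])
    }
    sid <- sprintf("%s_%g_%s%03d", p$location_id[1], lims[1], mode, i)
    meta_rows[[i]] <- data.frame(
      sample_id = sid, location_id = p$location_id[1], site = p$site[1],
      mode = mode, depth_bin_low = lims[1], depth_bin_high = lims[2],
      mean_depth = mean(p$depth), mean_latitude = mean(p$latitude),
      mean_longitude = mean(p$longitude), n_specimens = nrow(p),
      area = area, poc_flux = NA_real_, stringsAsFactors = FALSE)
    tab <- table(p$taxon)
    ab[i, names(tab)] <- as.numeric(tab)
  }
  if (!length(pieces)) {
    meta <- data.frame(sample_id = character(), location_id = character(),
                       site = character(), mode = character(),
                       depth_bin_low = numeric(), depth_bin_high = numeric(),
                       mean_depth = numeric(), mean_latitude = numeric(),
                       mean_longitude = numeric(), n_specimens = numeric(),
                       area = numeric(), poc_flux = numeric(),
                       stringsAsFactors = FALSE)
    return(community_samples(meta, matrix(0, 0, 0)))
  }
  meta <- do.call(rbind, meta_rows)
  # number samples within each location-bin for stable readable ids
  rownames(ab) <- meta$sample_id
  community_samples(meta, ab)
}

#' Attach environmental covariates (POC flux) to samples
#'
#' Evaluates a POC-flux model at each sample's mean position and mean depth
#' and stores the result in the `poc_flux` metadata column. Idempotent.
#'
#' @param samples a `community_samples` object.
#' @param poc_model a function `f(latitude, longitude, depth)` returning flux
#'   in gC m^-2 yr^-1, e.g. from [poc_flux_model()].
#' @return `samples` with `poc_flux` filled.
#' @export
attach_environment <- function(samples, poc_model) {
  stopifnot(inherits(samples, "community_samples"), is.function(poc_model))
  m <- samples$meta
  flux <- poc_model(m$mean_latitude, m$mean_longitude, m$mean_depth)
  if (anyNA(flux) || any(!is.finite(flux))) {
    bad <- m$sample_id[!is.finite(flux) | is.na(flux)]
    stop("POC model undefined at sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  samples$meta$poc_flux <- as.numeric(flux)
  samples
}
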