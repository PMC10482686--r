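# Synthetic occurrence generator: an abyssal-plain survey region with a
# depth/latitude site lattice, a Martin-attenuated POC-flux field, a hard
# carbonate-compensation-depth (CCD) cut-off for calcifying taxa, and a
# long-tailed (log-series) morphotype abundance distribution. Ground truth is
# returned alongside the data for recovery tests.

#' Configuration of the synthetic survey region
#'
#' Defaults emulate a 14-site, 28-location abyssal nodule-province survey
#' spanning 3,900-5,300 m with depth shoaling (and POC flux rising) from the
#' northwest to the southeast, a CCD at 4,600 m (the midpoint of the regional
#' 4,400-4,800 m CCD band), and ~400 morphotypes most of which are rare.
#'
#' @param n_sites number of survey sites.
#' @param locations_per_site integer vector (length `n_sites`) of geographic
#'   locations per site; the default allocation totals 28.
#' @param depth_range survey depth span (m).
#' @param ccd_depth hard cut-off depth (m) below which calcifying
#'   (`ccd_restricted`) taxa cannot occur; configurable within the regional
#'   4,400-4,800 m band.
#' @param province_boundaries depth-province boundaries (m) used by recovery
#'   tests.
#' @param export_flux_range export POC flux (gC m^-2 yr^-1) at the 100-m
#'   reference depth, `c(north, south)`: a linear latitude ramp rising toward
#'   the productive southern edge.
#' @param lat_range,lon_range site latitude/longitude spans (deg N / deg E);
#'   sites run from the deep northwest corner to the shallow southeast.
#' @param martin_b Martin-curve attenuation exponent.
#' @param n_morphotypes size of the regional morphotype pool.
#' @param sad_x log-series parameter in (0, 1) governing the abundance
#'   distribution; values near 1 give a long rare tail.
#' @param response_mix named proportions of taxon depth-response classes
#'   (`ccd_restricted`, `declining`, `increasing`, `ubiquitous`).
#' @param images_per_location,area_per_image survey effort: still frames per
#'   location and seabed area (m^2) per frame.
#' @param depth_jitter_m half-width of uniform image-depth scatter around the
#'   location depth (m).
#' @param density_scale expected total faunal density (ind m^-2) at the
#'   reference flux (region-centre latitude, 4,600 m).
#' @param site_occupancy_scale occupancy-abundance coupling: a morphotype of
#'   regional weight `w` is present at a given site with probability
#'   `1 - exp(-w / site_occupancy_scale)`, making rare taxa locally patchy
#'   (regionally long-tailed abundance with realistic local richness).
#' @param site_abundance_sigma standard deviation of the lognormal
#'   multiplicative perturbation applied to morphotype weights per site,
#'   producing site-scale dominance shifts and compositional turnover.
#' @param depth_response_scale_m logistic scale (m) of the declining /
#'   increasing depth responses; smaller values sharpen the community
#'   replacement around the CCD.
#' @param higher_only_rate fraction of specimens relabelled as identifiable
#'   only to a higher taxonomic level (morphotype withheld).
#' @param seed default integer seed for [generate_community()] /
#'   [generate_occurrences()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 14,
                             locations_per_site =
                               c(1, 1, 1, 2, 2, 2, 1, 3, 1, 3, 6, 3, 1, 1),
                             depth_range = c(3900, 5300),
                             ccd_depth = 4600,
                             province_boundaries = c(4300, 4800),
                             export_flux_range = c(north = 15, south = 40),
                             lat_range = c(8, 18),
                             lon_range = c(-155, -117),
                             martin_b = 0.858,
                             n_morphotypes = 400,
                             sad_x = 0.995,
                             response_mix = c(ccd_restricted = 0.10,
                                              declining = 0.25,
                                              increasing = 0.25,
                                              ubiquitous = 0.40),
                             images_per_location = 80,
                             area_per_image = 20,
                             depth_jitter_m = 40,
                             density_scale = 0.7,
                             site_occupancy_scale = 5,
                             site_abundance_sigma = 1.0,
                             depth_response_scale_m = 80,
                             higher_only_rate = 0.30,
                             seed = 1L) {
  stopifnot(length(locations_per_site) == n_sites,
            all(locations_per_site >= 1),
            depth_range[1] < depth_range[2],
            ccd_depth > depth_range[1], ccd_depth < depth_range[2],
            martin_b > 0, sad_x > 0, sad_x < 1,
            n_morphotypes > 0, images_per_location > 0, area_per_image > 0,
            density_scale > 0, site_occupancy_scale > 0,
            site_abundance_sigma >= 0, depth_response_scale_m > 0,
            higher_only_rate >= 0, higher_only_rate < 1,
            abs(sum(response_mix) - 1) < 1e-8)
  structure(as.list(environment()), class = "synthetic_config")
}

#' POC flux model (Martin-curve attenuation of a latitudinal export ramp)
#'
#' `F(lat, z) = F_export(lat) * (z / z_ref)^(-b)` with `z_ref = 100` m.
#' Export flux ramps linearly from the northern to the southern edge of the
#' configured latitude range (clamped outside it); flux is monotone
#' decreasing in depth and increasing toward the productive edge.
#'
#' @param config a [synthetic_config()].
#' @return function `f(latitude, longitude, depth)` returning gC m^-2 yr^-1
#'   (longitude is accepted for interface compatibility and ignored).
#' @export
poc_flux_model <- function(config = synthetic_config()) {
  fr <- config$export_flux_range
  lr <- config$lat_range
  b <- config$martin_b
  function(latitude, longitude = NULL, depth) {
    if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
    frac_south <- pmin(pmax((lr[2] - latitude) / (lr[2] - lr[1]), 0), 1)
    f_export <- fr[["north"]] + (fr[["south"]] - fr[["north"]]) * frac_south
    unname(f_export * (depth / 100)^(-b))
  }
}

# reference flux anchoring density_scale: region-centre latitude, 4,600 m
.reference_flux <- function(config) {
  poc_flux_model(config)(mean(config$lat_range), NULL, 4600)
}

# log-series abundance-class sampler: P(n) proportional to x^n / n
.rlogseries <- function(n, x, nmax = 10000) {
  support <- seq_len(nmax)
  p <- x^support / support
  sample(support, n, replace = TRUE, prob = p)
}

.response_pools <- list(
  ccd_restricted = data.frame(
    higher_taxon = c("Bivalvia", "Gastropoda", "Polyplacophora", "Bryozoa"),
    phylum = c("Mollusca", "Mollusca", "Mollusca", "Bryozoa"),
    guild = c("suspension", "deposit", "deposit", "suspension"),
    stringsAsFactors = FALSE),
  declining = data.frame(
    higher_taxon = c("Alcyonacea", "Ophiuroidea"),
    phylum = c("Cnidaria", "Echinodermata"),
    guild = c("suspension", "deposit"),
    stringsAsFactors = FALSE),
  increasing = data.frame(
    higher_taxon = c("Actiniaria", "Holothuroidea"),
    phylum = c("Cnidaria", "Echinodermata"),
    guild = c("scavenger_predator", "deposit"),
    stringsAsFactors = FALSE),
  ubiquitous = data.frame(
    higher_taxon = c("Hexactinellida", "Demospongiae", "Antipatharia",
                     "Decapoda"),
    phylum = c("Porifera", "Porifera", "Cnidaria", "Arthropoda"),
    guild = c("suspension", "suspension", "suspension",
              "scavenger_predator"),
    stringsAsFactors = FALSE)
)

#' Generate a synthetic regional morphotype pool
#'
#' Draws `n_morphotypes` morphotypes with log-series base abundance weights
#' (yielding many rare taxa), assigns each a depth-response class with the
#' configured mix, and gives each class taxonomically plausible higher-taxon,
#' phylum and guild labels. Depth responses are monotone logistic profiles
#' (`declining` / `increasing`), flat (`ubiquitous`) or flat with a hard zero
#' below the CCD (`ccd_restricted`) — by construction no morphotype prefers
#' the transition band exclusively.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to the config's).
#' @return data frame, one row per morphotype: `morphotype`, `phylum`,
#'   `higher_taxon`, `guild`, `response`, `weight`, `depth_mid`,
#'   `depth_scale`.
#' @export
generate_community <- function(config = synthetic_config(),
                               seed = config$seed) {
  with_seed(seed, {
    n <- config$n_morphotypes
    response <- sample(names(config$response_mix), n, replace = TRUE,
                       prob = config$response_mix)
    weight <- .rlogseries(n, config$sad_x)
    pool_row <- vapply(response, function(r) {
      sample.int(nrow(.response_pools[[r]]), 1)
    }, integer(1))
    info <- do.call(rbind, lapply(seq_len(n), function(i) {
      .response_pools[[response[i]]][pool_row[i], , drop = FALSE]
    }))
    # replacement programmed at the CCD: logistic midpoints centred there
    depth_mid <- ifelse(response %in% c("declining", "increasing"),
                        stats::runif(n, config$ccd_depth - 150,
                                     config$ccd_depth + 150), NA_real_)
    data.frame(morphotype = sprintf("MTP_%03d", seq_len(n)),
               phylum = info$phylum, higher_taxon = info$higher_taxon,
               guild = info$guild, response = response,
               weight = weight, depth_mid = depth_mid,
               depth_scale = config$depth_response_scale_m,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# per-morphotype relative occurrence weight at depth z
.depth_profile <- function(community, z, ccd_depth) {
  w <- community$weight
  prof <- numeric(nrow(community))
  r <- community$response
  prof[r == "ubiquitous"] <- 1
  prof[r == "ccd_restricted"] <- as.numeric(z < ccd_depth)
  dec <- r == "declining"
  prof[dec] <- stats::plogis((community$depth_mid[dec] - z) /
                               community$depth_scale[dec])
  inc <- r == "increasing"
  prof[inc] <- stats::plogis((z - community$depth_mid[inc]) /
                               community$depth_scale[inc])
  w * prof
}

#' Generate a synthetic occurrence table with ground truth
#'
#' Sites sit on a joint depth/latitude/longitude lattice (deep northwest to
#' shallow southeast); each site holds its configured number of geographic
#' locations, spaced ~30 km apart so they resolve to distinct 10-km grid
#' cells. Every location is surveyed by `images_per_location` still frames of
#' fixed area; per-image specimen counts are Poisson with mean
#' `area * density_scale * F(lat, z) / F_ref`, so expected density scales
#' linearly with the POC flux field. Specimens are assigned to morphotypes
#' with probability proportional to the depth-modulated community weights
#' (hard zero below the CCD for `ccd_restricted` taxa), and a fraction
#' `higher_only_rate` are relabelled as identifiable only to their higher
#' taxon.
#'
#' @param config a [synthetic_config()].
#' @param community optional morphotype pool from [generate_community()]
#'   (regenerated from `seed` when `NULL`).
#' @param seed integer seed (defaults to the config's).
#' @return list with elements `table` (an [occurrence_table()]) and `truth`
#'   (class `synthetic_truth`): programmed `ccd_depth`, `martin_b`,
#'   `density_scale`, `f_ref`, `density_flux_slope` (expected ind m^-2 per
#'   unit flux), `density_depth_sign`, per-location expected densities
#'   (`locations`), and the `community` pool.
#' @export
generate_occurrences <- function(config = synthetic_config(),
                                 community = NULL, seed = config$seed) {
  if (is.null(community)) community <- generate_community(config, seed)
  flux <- poc_flux_model(config)
  f_ref <- .reference_flux(config)

  n_sites <- config$n_sites
  site_depth <- seq(config$depth_range[2] - 50, config$depth_range[1] + 50,
                    length.out = n_sites)
  site_lat <- seq(config$lat_range[2], config$lat_range[1],
                  length.out = n_sites)
  site_lon <- seq(config$lon_range[1], config$lon_range[2],
                  length.out = n_sites)
  site_name <- sprintf("S%02d", seq_len(n_sites))

  out <- with_seed(seed + 1L, {
    rows <- list(); frame_rows <- list(); loc_rows <- list()
    spec_counter <- 0L
    # occupancy-abundance thinning: rare morphotypes are locally patchy
    p_occ <- 1 - exp(-community$weight / config$site_occupancy_scale)
    site_presence <- matrix(
      stats::runif(nrow(community) * n_sites) < rep(p_occ, n_sites),
      nrow = nrow(community), ncol = n_sites)
    # site-scale dominance shifts: lognormal perturbation of the weights
    site_weight <- matrix(
      exp(stats::rnorm(nrow(community) * n_sites, 0,
                       config$site_abundance_sigma)),
      nrow = nrow(community), ncol = n_sites) * site_presence
    for (s in seq_len(n_sites)) {
      for (l in seq_len(config$locations_per_site[s])) {
        # ~30 km northward steps keep sibling locations in distinct cells
        lat <- site_lat[s] + (l - 1) * 0.27
        lon <- site_lon[s]
        ldep <- min(max(site_depth[s] + stats::runif(1, -80, 80),
                        config$depth_range[1] + config$depth_jitter_m),
                    config$depth_range[2] - config$depth_jitter_m)
        loc_id <- sprintf("%s_L%02d", site_name[s], l)
        img_depth <- ldep + stats::runif(config$images_per_location,
                                         -config$depth_jitter_m,
                                         config$depth_jitter_m)
        lambda <- config$area_per_image * config$density_scale *
          flux(lat, lon, img_depth) / f_ref
        counts <- stats::rpois(config$images_per_location, lambda)
        loc_rows[[loc_id]] <- data.frame(
          location = loc_id, site = site_name[s], latitude = lat,
          longitude = lon, depth = ldep,
          poc_flux = flux(lat, lon, ldep),
          expected_density = config$density_scale * flux(lat, lon, ldep) / f_ref,
          observed_density = sum(counts) /
            (config$images_per_location * config$area_per_image),
          stringsAsFactors = FALSE)
        for (i in seq_len(config$images_per_location)) {
          img_id <- sprintf("%s_I%03d", loc_id, i)
          frame_rows[[img_id]] <- data.frame(
            image_id = img_id, site = site_name[s], latitude = lat,
            longitude = lon, depth = img_depth[i],
            area = config$area_per_image, stringsAsFactors = FALSE)
          if (counts[i] == 0) next
          wz <- .depth_profile(community, img_depth[i], config$ccd_depth) *
            site_weight[, s]
          if (!any(wz > 0)) next
          idx <- sample.int(nrow(community), counts[i], replace = TRUE,
                            prob = wz)
          rows[[img_id]] <- data.frame(
            specimen_id = sprintf("SP%07d", spec_counter + seq_len(counts[i])),
            image_id = img_id, site = site_name[s], latitude = lat,
            longitude = lon, depth = img_depth[i],
            morphotype = community$morphotype[idx],
            higher_taxon = community$higher_taxon[idx],
            phylum = community$phylum[idx],
            guild = community$guild[idx], stringsAsFactors = FALSE)
          spec_counter <- spec_counter + counts[i]
        }
      }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    # a fraction of records only identifiable to a higher taxonomic level
    hide <- stats::runif(nrow(records)) < config$higher_only_rate
    records$morphotype[hide] <- NA_character_
    list(records = records,
         frames = do.call(rbind, frame_rows),
         locations = do.call(rbind, loc_rows))
  })
  rownames(out$frames) <- NULL
  rownames(out$locations) <- NULL

  table <- occurrence_table(out$records, out$frames,
                            provenance = sprintf("synthetic (seed %d)", seed))
  truth <- structure(list(
    ccd_depth = config$ccd_depth,
    martin_b = config$martin_b,
    density_scale = config$density_scale,
    f_ref = f_ref,
    density_flux_slope = config$density_scale / f_ref,
    density_depth_sign = -1,
    locations = out$locations,
    community = community,
    config = config), class = "synthetic_truth")
  list(table = table, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> CCD ", x$ccd_depth, " m; density-flux slope ",
      signif(x$density_flux_slope, 4), " ind m^-2 per gC m^-2 yr^-1; ",
      nrow(x$locations), " locations\n", sep = "")
  invisible(x)
}
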