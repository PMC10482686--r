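# Fixtures are built in code; the synthetic default run is generated once per
# session and cached, since several files exercise it.

.fixture_cache <- new.env(parent = emptyenv())

# default-condition synthetic region (the study conditions), memoised by seed
synth_fixture <- function(seed = 1L) {
  key <- paste0("synth_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_occurrences(synthetic_config(),
                                                  seed = seed)
  }
  .fixture_cache[[key]]
}

bd_fixture <- function(seed = 1L) {
  key <- paste0("bd_", seed)
  if (is.null(.fixture_cache[[key]])) {
    gen <- synth_fixture(seed)
    .fixture_cache[[key]] <- make_samples(filter_subset(gen$table, "BD"),
                                          "BD", sampling_plan(seed = seed))
  }
  .fixture_cache[[key]]
}

ss_fixture <- function(seed = 1L) {
  key <- paste0("ss_", seed)
  if (is.null(.fixture_cache[[key]])) {
    gen <- synth_fixture(seed)
    .fixture_cache[[key]] <- make_samples(filter_subset(gen$table, "SS"),
                                          "SS", sampling_plan(seed = seed))
  }
  .fixture_cache[[key]]
}

# a tiny hand-built occurrence table: n specimens on one frame per specimen
# unless images is given; morphotype NA for indices in `higher_only`
toy_table <- function(n = 5, higher_only = integer(), site = "A",
                      lat = 10, lon = -140, depth = 4100,
                      area = 10, images = NULL) {
  if (is.null(images)) images <- seq_len(n)
  depth <- rep_len(depth, n)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)
  site <- rep_len(site, n)
  img_id <- sprintf("IMG%03d", images)
  records <- data.frame(
    specimen_id = sprintf("SP%03d", seq_len(n)),
    image_id = img_id, site = site, latitude = lat, longitude = lon,
    depth = depth,
    morphotype = ifelse(seq_len(n) %in% higher_only, NA_character_,
                        sprintf("MT%02d", seq_len(n) %% 3 + 1)),
    higher_taxon = rep_len("Actiniaria", n),
    phylum = rep_len("Cnidaria", n),
    guild = rep_len("suspension", n), stringsAsFactors = FALSE)
  first <- !duplicated(img_id)
  frames <- data.frame(image_id = img_id[first], site = site[first],
                       latitude = lat[first], longitude = lon[first],
                       depth = depth[first],
                       area = rep_len(area, sum(first)),
                       stringsAsFactors = FALSE)
  occurrence_table(records, frames, provenance = "toy")
}

# abundance-vector community_samples builder (BD mode)
samples_from_counts <- function(counts_list, depths = NULL, mode = "BD",
                                areas = NULL, sites = NULL) {
  taxa <- sort(unique(unlist(lapply(counts_list, names))))
  n <- length(counts_list)
  if (is.null(depths)) depths <- rep(4100, n)
  if (is.null(sites)) sites <- rep("A", n)
  ab <- matrix(0, n, length(taxa), dimnames = list(NULL, taxa))
  for (i in seq_len(n)) ab[i, names(counts_list[[i]])] <- counts_list[[i]]
  ids <- sprintf("S%02d", seq_len(n))
  rownames(ab) <- ids
  meta <- data.frame(
    sample_id = ids, location_id = "L1", site = sites, mode = mode,
    depth_bin_low = floor(depths / 200) * 200,
    depth_bin_high = floor(depths / 200) * 200 + 200,
    mean_depth = depths, mean_latitude = 10, mean_longitude = -140,
    n_specimens = rowSums(ab),
    area = if (is.null(areas)) NA_real_ else areas,
    poc_flux = NA_real_, stringsAsFactors = FALSE)
  community_samples(meta, ab)
}

write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
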