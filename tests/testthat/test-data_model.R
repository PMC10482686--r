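test_that("read_occurrences parses valid files and flags missing morphotypes", {
  path <- write_toy_csv(c(
    "specimen_id,image_id,site,latitude,longitude,depth,morphotype,area",
    "s1,i1,A,10.1,-140.2,4100,MT01,12.5",
    "s2,i1,A,10.1,-140.2,4100,MT02,12.5",
    "s3,i2,A,10.2,-140.3,4150,MT01,9.0"))
  tab <- read_occurrences(path)
  expect_s3_class(tab, "occurrence_table")
  expect_equal(nrow(tab$records), 3)
  expect_equal(nrow(tab$frames), 2)
  expect_equal(tab$frames$area, c(12.5, 9.0))

  # 2 of 5 rows lack a morphotype: kept, flagged higher_only
  path5 <- write_toy_csv(c(
    "specimen_id,image_id,site,latitude,longitude,depth,morphotype,higher_taxon",
    "s1,i1,A,10,-140,4100,MT01,Actiniaria",
    "s2,i2,A,10,-140,4100,,Actiniaria",
    "s3,i3,A,10,-140,4100,MT02,Actiniaria",
    "s4,i4,A,10,-140,4100,,Ophiuroidea",
    "s5,i5,A,10,-140,4100,MT01,Actiniaria"))
  tab5 <- read_occurrences(path5)
  expect_equal(nrow(tab5$records), 5)
  expect_equal(sum(tab5$records$id_level == "higher_only"), 2)
})

test_that("read_occurrences reports format and row-level errors precisely", {
  bad_depth <- write_toy_csv(c(
    "specimen_id,image_id,site,latitude,longitude,depth",
    "s1,i1,A,10,-140,abc",
    "s2,i2,A,10,-140,4100"))
  expect_error(read_occurrences(bad_depth), "line 2")

  no_site <- write_toy_csv(c(
    "specimen_id,image_id,latitude,longitude,depth",
    "s1,i1,10,-140,4100"))
  expect_error(read_occurrences(no_site), "site")

  # aliases absorb a foreign header dialect
  alias <- write_toy_csv(c(
    "id,frame,Station,lat,lon,Depth_m",
    "s1,i1,A,10,-140,4100"))
  tab <- read_occurrences(alias, aliases = c(
    specimen_id = "id", image_id = "frame", site = "Station",
    latitude = "lat", longitude = "lon", depth = "Depth_m"))
  expect_equal(nrow(tab$records), 1)
})

test_that("records with missing or out-of-range coordinates are rejected", {
  rec <- data.frame(specimen_id = "s1", image_id = "i1", site = "A",
                    latitude = NA_real_, longitude = -140, depth = 4100)
  frm <- data.frame(image_id = "i1", site = "A", latitude = 10,
                    longitude = -140, depth = 4100, area = 1)
  expect_error(occurrence_table(rec, frm), "missing latitude")
  rec$latitude <- 95
  expect_error(occurrence_table(rec, frm), "latitude")
  rec$latitude <- 10; rec$depth <- -5
  expect_error(occurrence_table(rec, frm), "depth")
})

test_that("catalogue lookup fills taxonomy and reports unknown labels", {
  path <- write_toy_csv(c(
    "specimen_id,image_id,site,latitude,longitude,depth,morphotype",
    "s1,i1,A,10,-140,4100,MT01",
    "s2,i2,A,10,-140,4100,MT99"))
  catalogue <- data.frame(morphotype = "MT01", qualifier = "sp. indet.",
                          phylum = "Cnidaria", higher_taxon = "Actiniaria",
                          guild = "suspension", stringsAsFactors = FALSE)
  expect_warning(tab <- read_occurrences(path, catalogue = catalogue), "MT99")
  expect_equal(attr(tab, "unmatched_morphotypes"), "MT99")
  expect_equal(tab$records$phylum[1], "Cnidaria")
})

test_that("filter_subset implements the BD/SS rules and is idempotent", {
  tab <- toy_table(10, higher_only = c(1, 2, 3))
  bd <- filter_subset(tab, "BD")
  ss <- filter_subset(tab, "SS")
  expect_equal(nrow(bd$records), 7)
  expect_equal(nrow(ss$records), 10)
  # idempotence
  expect_identical(filter_subset(bd, "BD")$records, bd$records)

  # video-only data (no frame area): SS drops everything
  video <- toy_table(4, area = NA_real_)
  expect_equal(nrow(filter_subset(video, "SS")$records), 0)
  expect_equal(nrow(filter_subset(video, "BD")$records), 4)

  # empty table stays empty
  empty <- toy_table(0)
  expect_equal(nrow(filter_subset(empty, "BD")$records), 0)
})

test_that("sample matrices round-trip losslessly through CSV", {
  bd <- bd_fixture()
  sub <- community_samples(bd$meta[1:4, ], bd$abundance[1:4, , drop = FALSE])
  path <- tempfile(fileext = ".csv")
  write_samples(sub, path)
  back <- read_samples(path)
  expect_equal(back$meta, sub$meta, tolerance = 1e-12)
  expect_equal(back$abundance, sub$abundance)

  # zero samples: header-only file that still round-trips
  none <- community_samples(sub$meta[0, ], sub$abundance[0, , drop = FALSE])
  p0 <- tempfile(fileext = ".csv")
  write_samples(none, p0)
  expect_equal(length(readLines(p0)), 1L)
  expect_equal(n_samples(read_samples(p0)), 0L)
})

test_that("duplicate sample ids are rejected", {
  meta <- data.frame(sample_id = c("a", "a"), location_id = "L", site = "A",
                     mode = "BD", depth_bin_low = 4000, depth_bin_high = 4200,
                     mean_depth = 4100, mean_latitude = 10,
                     mean_longitude = -140, n_specimens = 1, area = NA,
                     poc_flux = NA)
  ab <- matrix(1, 2, 1, dimnames = list(c("a", "a"), "m"))
  expect_error(community_samples(meta, ab), "duplicate")
})
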