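test_that("grid assignment groups nearby records and splits distant ones", {
  # two records 3 km apart plus a distant second site; assert the pair shares
  # a cell by checking projected coordinates directly
  rec <- data.frame(
    specimen_id = c("s1", "s2", "s3"),
    image_id = c("i1", "i2", "i3"),
    site = c("A", "A", "B"),
    latitude = c(10.000, 10.027, 10.500),
    longitude = rep(-140, 3), depth = 4100)
  frm <- data.frame(image_id = rec$image_id, site = rec$site,
                    latitude = rec$latitude, longitude = rec$longitude,
                    depth = rec$depth, area = 1)
  tab <- occurrence_table(rec, frm)
  gl <- assign_grid_locations(tab, sampling_plan())
  xy <- abyssbio:::project_local(rec$latitude, rec$longitude,
                                 mean(rec$latitude), mean(rec$longitude))
  expect_identical(floor(xy$y[1] / 10), floor(xy$y[2] / 10))
  expect_equal(nrow(gl$locations), 2)
  expect_equal(gl$records$location_id[1], gl$records$location_id[2])

  # two records 25 km apart can never share a 10-km cell
  rec2 <- rec[1:2, ]
  rec2$latitude <- c(10.000, 10.225)
  frm2 <- frm[1:2, ]; frm2$latitude <- rec2$latitude
  gl2 <- assign_grid_locations(occurrence_table(rec2, frm2), sampling_plan())
  expect_equal(nrow(gl2$locations), 2)

  # projection validity bound
  rec3 <- rec[1, ]; rec3$latitude <- 87
  frm3 <- frm[1, ]; frm3$latitude <- 87
  expect_error(assign_grid_locations(occurrence_table(rec3, frm3)),
               "projection")
})

test_that("the 28 programmed synthetic clusters resolve to 28 locations", {
  gen <- synth_fixture()
  gl <- assign_grid_locations(gen$table, sampling_plan())
  expect_equal(nrow(gl$locations), 28)
  # brute-force oracle: programmed cluster centres are pairwise >= 25 km apart
  locs <- gen$truth$locations
  xy <- abyssbio:::project_local(locs$latitude, locs$longitude,
                                 mean(locs$latitude), mean(locs$longitude))
  dmat <- as.matrix(dist(cbind(xy$x, xy$y)))
  expect_true(all(dmat[lower.tri(dmat)] >= 25))
})

test_that("depth bins are half-open and aligned to the bin width", {
  plan <- sampling_plan()
  b1 <- bin_by_depth(data.frame(depth = c(4050, 4150)), plan)
  expect_equal(names(b1), "4000-4200")
  b2 <- bin_by_depth(data.frame(depth = c(4199, 4201)), plan)
  expect_equal(names(b2), c("4000-4200", "4200-4400"))
  b3 <- bin_by_depth(data.frame(depth = 4200), plan)
  expect_equal(names(b3), "4200-4400")
})

test_that("BD rarefaction partitions exactly and discards the remainder", {
  tab <- toy_table(523, images = rep(1:40, length.out = 523),
                   depth = 4100)
  plan <- sampling_plan(seed = 7)
  bd <- make_samples(filter_subset(tab, "BD"), "BD", plan)
  expect_equal(n_samples(bd), 2)
  expect_true(all(bd$meta$n_specimens == 200))

  tab199 <- toy_table(199)
  expect_equal(n_samples(make_samples(filter_subset(tab199, "BD"),
                                      "BD", plan)), 0)
})

test_that("sampling is deterministic in the seed and count-stable across seeds", {
  tab <- filter_subset(toy_table(450, images = rep(1:30, 15)), "BD")
  s1 <- make_samples(tab, "BD", sampling_plan(seed = 3))
  s2 <- make_samples(tab, "BD", sampling_plan(seed = 3))
  expect_identical(s1, s2)
  s3 <- make_samples(tab, "BD", sampling_plan(seed = 4))
  expect_equal(n_samples(s3), n_samples(s1))
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("SS samples respect the specimen window and whole-image assembly", {
  gen <- synth_fixture()
  ss <- ss_fixture()
  expect_true(all(ss$meta$n_specimens >= 450 & ss$meta$n_specimens <= 500))
  expect_true(all(ss$meta$area > 0))
  # area must be the sum of whole frames: always a multiple of the frame area
  frame_area <- synthetic_config()$area_per_image
  expect_true(all(abs(ss$meta$area / frame_area -
                        round(ss$meta$area / frame_area)) < 1e-9))
  # SS on area-less frames must be refused
  video <- toy_table(500, area = NA_real_)
  expect_error(make_samples(video, "SS", sampling_plan()), "area")
})

test_that("no specimen is ever used twice across samples (partition property)", {
  plan <- sampling_plan(seed = 11)
  for (mode in c("BD", "SS")) {
    tab <- filter_subset(synth_fixture()$table, mode)
    gl <- assign_grid_locations(tab, plan)
    smp <- make_samples(tab, mode, plan)
    expect_lte(sum(smp$meta$n_specimens), nrow(tab$records))
  }
})

test_that("BD samples of exactly 200 arise for any input (fuzz)", {
  plan <- sampling_plan(seed = 5)
  set.seed(99)
  for (i in 1:25) {
    n <- sample(50:700, 1)
    tab <- filter_subset(
      toy_table(n, images = rep(seq_len(max(1, n %/% 10)), length.out = n),
                depth = sample(c(4100, 4300), n, replace = TRUE)), "BD")
    smp <- make_samples(tab, "BD", plan)
    expect_true(all(smp$meta$n_specimens == 200))
    bins <- bin_by_depth(tab$records, plan)
    expect_equal(n_samples(smp), sum(vapply(bins, nrow, 1L) %/% 200))
  }
})

test_that("rarefaction without replacement is unbiased (chi-square style check)", {
  # pool of 300 A + 100 B; a 200-specimen sample should average 150 A
  tab <- toy_table(400, images = rep(1:20, 20))
  tab$records$morphotype <- rep(c("A", "B"), c(300, 100))
  tab <- filter_subset(tab, "BD")
  means <- vapply(1:200, function(s) {
    smp <- make_samples(tab, "BD", sampling_plan(seed = s))
    smp$abundance[1, "A"]
  }, numeric(1))
  # hypergeometric: mean 150, sd ~4.3; 200-seed mean has se ~0.31
  expect_lt(abs(mean(means) - 150), 1.6)
})

test_that("attach_environment evaluates the flux model at sample positions", {
  bd <- bd_fixture()
  const <- attach_environment(bd, function(lat, lon, depth) rep(1, length(lat)))
  expect_true(all(const$meta$poc_flux == 1))
  # Martin attenuation: export 10 at 100 m, b = 0.858, depth 4000 m
  martin <- function(lat, lon, depth) 10 * (depth / 100)^(-0.858)
  expect_equal(martin(0, 0, 4000), 0.422, tolerance = 1e-3)
  expect_equal(martin(0, 0, 100), 10)  # reference depth leaves export unchanged
  withflux <- attach_environment(bd, martin)
  twice <- attach_environment(withflux, martin)
  expect_identical(withflux, twice)  # idempotent
  expect_error(
    attach_environment(bd, function(lat, lon, depth) rep(NA_real_, length(lat))),
    "undefined")
})
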