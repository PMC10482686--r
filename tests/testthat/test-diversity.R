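test_that("Hill numbers match direct formula evaluation", {
  smp <- samples_from_counts(list(
    c(a = 200), c(a = 100, b = 100), c(a = 150, b = 50)))
  expect_equal(unname(hill_richness(smp)), c(1L, 2L, 2L))
  sh <- unname(hill_shannon(smp))
  expect_equal(sh[1], 1.0)
  expect_equal(sh[2], 2.0)
  expect_equal(sh[3], exp(-(0.75 * log(0.75) + 0.25 * log(0.25))))
  expect_equal(sh[3], 1.7547, tolerance = 1e-4)
})

test_that("Hill ordering and the replication principle hold", {
  bd <- bd_fixture()
  s <- hill_richness(bd)
  h <- hill_shannon(bd)
  expect_true(all(h <= s + 1e-9))
  expect_true(all(h >= 1))
  # doubling every abundance leaves both Hill numbers unchanged
  dbl <- bd
  dbl$abundance <- bd$abundance * 2
  dbl$meta$n_specimens <- bd$meta$n_specimens * 2
  expect_equal(hill_richness(dbl), s)
  expect_equal(hill_shannon(dbl), h)
  # equality iff perfectly even
  even <- samples_from_counts(list(c(a = 50, b = 50, c = 50, d = 50)))
  expect_equal(unname(hill_shannon(even)), 4)
})

test_that("diversity refuses SS-mode samples and empty samples", {
  ss <- samples_from_counts(list(c(a = 450, "higher:x" = 50)), mode = "SS",
                            areas = 100)
  expect_error(hill_richness(ss), "BD")
  expect_error(hill_shannon(ss), "BD")
})

test_that("density divides counts by surveyed area with unit conversion", {
  smp <- samples_from_counts(list(c(a = 400, b = 68)), mode = "SS",
                             areas = 1170)
  expect_equal(unname(density_per_m2(smp)), 468 / 1170)
  expect_equal(unname(density_per_m2(smp)), 0.40, tolerance = 1e-2)
  expect_equal(unname(density_per_m2(smp, taxa = "a")), 400 / 1170)
  expect_equal(unname(density_per_m2(smp, taxa = "absent_group")), 0)
  expect_equal(per_m2_to_per_ha(0.25), 2500)
  bd <- samples_from_counts(list(c(a = 200)))
  expect_error(density_per_m2(bd), "area")
})

test_that("province summaries use t-based 95% confidence intervals", {
  s <- province_summary(c(1, 1, 1, 1), rep("shallow", 4))
  expect_equal(s$mean, 1)
  expect_equal(s$ci_high - s$ci_low, 0)

  s2 <- province_summary(c(0, 2), c("deep", "deep"))
  expect_equal(s2$mean, 1)
  # brute check against the t quantile: half-width = qt(.975, 1) * sd/sqrt(2)
  half <- qt(0.975, df = 1) * sd(c(0, 2)) / sqrt(2)
  expect_equal(s2$ci_high, 1 + half)
  expect_equal(s2$ci_low, 1 - half)
  expect_equal(half, 12.706, tolerance = 1e-3)

  # identical value sets in two provinces must overlap
  s3 <- province_summary(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_true(s3$ci_low[1] <= s3$ci_high[2] && s3$ci_low[2] <= s3$ci_high[1])

  # a single-sample province has no interval
  s4 <- province_summary(c(1, 2, 3), c("a", "a", "b"))
  expect_true(is.na(s4$ci_low[s4$province == "b"]))
})

test_that("accumulation curves accumulate pooled richness correctly", {
  # three samples with disjoint 5-morphotype sets: exact (5, 10, 15), no spread
  disjoint <- samples_from_counts(list(
    setNames(rep(1, 5), paste0("a", 1:5)),
    setNames(rep(1, 5), paste0("b", 1:5)),
    setNames(rep(1, 5), paste0("c", 1:5))))
  cur <- accumulation_curve(disjoint, n_randomizations = 50, seed = 1)
  expect_equal(cur$mean_richness, c(5, 10, 15))
  expect_equal(cur$ci_high - cur$ci_low, rep(0, 3))

  # identical samples: flat curve at S
  same <- samples_from_counts(list(c(a = 1, b = 1), c(a = 2, b = 2),
                                   c(a = 5, b = 1)))
  cur2 <- accumulation_curve(same, n_randomizations = 20, seed = 1)
  expect_equal(cur2$mean_richness, c(2, 2, 2))
})

test_that("the accumulation final point equals the set-union oracle", {
  bd <- bd_fixture()
  sub <- community_samples(bd$meta[1:8, ], bd$abundance[1:8, , drop = FALSE])
  cur <- accumulation_curve(sub, n_randomizations = 30, seed = 2)
  union_richness <- sum(colSums(sub$abundance > 0) > 0)
  expect_equal(cur$mean_richness[8], union_richness)
  expect_equal(cur$sd[8], 0)
  expect_true(all(diff(cur$mean_richness) >= 0))
})

test_that("Monte-Carlo accumulation agrees with the analytic expectation", {
  bd <- bd_fixture()
  sub <- community_samples(bd$meta[1:10, ], bd$abundance[1:10, , drop = FALSE])
  cur <- accumulation_curve(sub, n_randomizations = 200, seed = 3)
  exact <- suppressWarnings(vegan::specaccum(sub$abundance, method = "exact"))
  expect_equal(cur$mean_richness, as.numeric(exact$richness), tolerance = 0.02)
})

test_that("density increases with programmed POC flux on synthetic data", {
  ss <- ss_fixture()
  ss <- attach_environment(ss, poc_flux_model(synthetic_config()))
  dens <- density_per_m2(ss)
  expect_gt(cor(dens, ss$meta$poc_flux, method = "spearman"), 0)
})
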