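bc_manual <- function(x, y, sqrt_transform = TRUE) {
  if (sqrt_transform) { x <- sqrt(x); y <- sqrt(y) }
  sum(abs(x - y)) / sum(x + y)
}

test_that("Bray-Curtis matches the hand formula, including the sqrt case", {
  smp <- samples_from_counts(list(c(a = 4, b = 1), c(a = 1, b = 4),
                                  c(a = 4, b = 1)))
  d <- bray_curtis(smp, transform = "sqrt")
  dm <- as.matrix(d)
  expect_equal(dm["S01", "S02"], 1 / 3, tolerance = 1e-12)
  expect_equal(dm["S01", "S03"], 0)         # identical samples
  expect_equal(attr(d, "transform"), "sqrt")

  disj <- samples_from_counts(list(c(a = 3), c(b = 7)))
  expect_equal(as.numeric(bray_curtis(disj)), 1)  # disjoint samples

  zero <- samples_from_counts(list(c(a = 1), c(a = 0, b = 0)))
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("Bray-Curtis axioms hold on random abundance fixtures", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1); k <- sample(4:12, 1)
    ab <- matrix(rpois(n * k, 3) + 1, n, k,
                 dimnames = list(sprintf("s%d", 1:n), sprintf("t%d", 1:k)))
    d <- as.matrix(bray_curtis(ab, transform = "sqrt"))
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    # independent oracle: direct formula evaluation per pair
    i1 <- sample(n, 1); i2 <- sample(n, 1)
    expect_equal(d[i1, i2], bc_manual(ab[i1, ], ab[i2, ]), tolerance = 1e-12)
  }
})

test_that("pool-adjacent-violators matches the base isotonic oracle", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    y <- rnorm(n)
    expect_equal(pava_isotonic(y), as.numeric(isoreg(y)$yf), tolerance = 1e-12)
  }
  # weighted case: merging two points equals their weighted mean
  expect_equal(pava_isotonic(c(2, 0), w = c(1, 3)), c(0.5, 0.5))
  expect_equal(pava_isotonic(1:5), 1:5 + 0)
})

test_that("NMDS recovers a planted planar configuration", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))  # unit-square corners
  d <- dist(pts)
  ord <- nmds(d, k = 2, n_restarts = 5, seed = 1)
  expect_lt(ord$stress, 0.01)
  # recovered distance order matches the input order: every side pair
  # (distance 1) shorter than every diagonal pair (distance sqrt(2))
  dd <- as.vector(dist(ord$points))
  sides <- abs(as.vector(d) - 1) < 1e-9
  expect_lt(max(dd[sides]), min(dd[!sides]))
  # coordinates centred
  expect_equal(colMeans(ord$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
})

test_that("stress decreases monotonically and restarts are deterministic", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 2))
  d <- dist(pts)
  o1 <- nmds(d, k = 2, n_restarts = 4, seed = 9)
  o2 <- nmds(d, k = 2, n_restarts = 4, seed = 9)
  expect_identical(o1$points, o2$points)
  expect_true(all(diff(o1$trace) <= 1e-12))
  o3 <- nmds(d, k = 2, n_restarts = 4, seed = 10)
  expect_lt(abs(o3$stress - o1$stress), 1e-4)
})

test_that("k + 1 points embed perfectly and degenerate input warns", {
  d3 <- dist(rbind(c(0, 0), c(3, 1), c(1, 4)))
  ord <- nmds(d3, k = 2, n_restarts = 3, seed = 1)
  expect_lt(ord$stress, 1e-3)
  dunif <- as.dist(matrix(1, 4, 4) - diag(4))
  expect_warning(ord2 <- nmds(dunif, k = 2, seed = 1), "degenerate")
  expect_equal(colMeans(ord2$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
})

test_that("NMDS stress agrees with an independent implementation", {
  bd <- bd_fixture()
  sub <- community_samples(bd$meta[1:20, ], bd$abundance[1:20, , drop = FALSE])
  d <- bray_curtis(sub)
  ours <- nmds(d, k = 2, n_restarts = 8, seed = 2)
  ref <- vegan::monoMDS(d, k = 2, model = "global")
  expect_lt(abs(ours$stress - ref$stress), 0.02)
})

test_that("ordination_report joins coordinates with sample context", {
  smp <- samples_from_counts(list(c(a = 5, b = 1), c(a = 1, b = 5),
                                  c(a = 3, c = 3)),
                             depths = c(4100, 4500, 4900))
  ord <- nmds(bray_curtis(smp), k = 2, n_restarts = 3, seed = 1)
  rep_tab <- ordination_report(ord, smp)
  expect_equal(nrow(rep_tab), 3)
  expect_equal(as.character(rep_tab$province),
               c("shallow", "transition", "deep"))
  # coordinates round-trip through CSV
  path <- tempfile(fileext = ".csv")
  write.csv(rep_tab, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$NMDS1, rep_tab$NMDS1, tolerance = 1e-12)
})

test_that("between-province dissimilarity exceeds within-province (synthetic)", {
  bd <- bd_fixture()
  d <- bray_curtis(bd)
  prov <- as.character(classify_province(bd$meta$mean_depth))
  gs <- group_separation(d, prov)
  expect_gt(gs$between, gs$within)
})
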