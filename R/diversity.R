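# Standing stocks, Hill diversity numbers, province summaries with
# confidence intervals, and sample-based accumulation curves.

.assert_bd <- function(samples) {
  stopifnot(inherits(samples, "community_samples"))
  if (any(samples$meta$mode != "BD")) {
    stop("Hill diversity requires BD-mode samples ",
         "(SS samples mix identification levels)", call. = FALSE)
  }
  invisible(samples)
}

#' Morphotype richness (Hill number of order 0)
#'
#' Number of morphotypes with abundance > 0 per sample.
#'
#' @param samples a BD-mode `community_samples` object.
#' @return named integer vector (one value per sample).
#' @export
hill_richness <- function(samples) {
  .assert_bd(samples)
  out <- rowSums(samples$abundance > 0)
  storage.mode(out) <- "integer"
  out
}

#' Exponential Shannon diversity (Hill number of order 1)
#'
#' `exp(H')` with `H' = -sum(p_i * log(p_i))` in nats, `p_i` the relative
#' abundance of morphotype `i`; zero-abundance morphotypes contribute 0.
#' Ranges from 1 (single morphotype) to the richness (perfectly even sample).
#'
#' @param samples a BD-mode `community_samples` object.
#' @return named numeric vector.
#' @export
hill_shannon <- function(samples) {
  .assert_bd(samples)
  if (nrow(samples$meta) && any(rowSums(samples$abundance) == 0)) {
    stop("empty sample(s): Shannon diversity undefined", call. = FALSE)
  }
  apply(samples$abundance, 1, function(x) {
    p <- x[x > 0] / sum(x)
    exp(-sum(p * log(p)))
  })
}

#' Per-sample diversity estimates
#'
#' @param samples a BD-mode `community_samples` object.
#' @return data frame: `sample_id`, `richness`, `exp_shannon`, plus sample
#'   metadata (`mean_depth`, `poc_flux`, `site`, `location_id`).
#' @export
diversity_estimates <- function(samples) {
  .assert_bd(samples)
  m <- samples$meta
  data.frame(sample_id = m$sample_id,
             richness = as.numeric(hill_richness(samples)),
             exp_shannon = as.numeric(hill_shannon(samples)),
             mean_depth = m$mean_depth, poc_flux = m$poc_flux,
             site = m$site, location_id = m$location_id,
             stringsAsFactors = FALSE)
}

#' Faunal density per sample (individuals per square metre)
#'
#' Total (or group-restricted) specimen count divided by the summed seabed
#' area the sample's images cover.
#'
#' @param samples an SS-mode `community_samples` object with areas.
#' @param taxa optional character vector restricting the count to a subset of
#'   taxon columns (e.g. one higher taxon's labels); taxa absent from the
#'   matrix contribute zero.
#' @return named numeric vector, ind m^-2.
#' @export
density_per_m2 <- function(samples, taxa = NULL) {
  stopifnot(inherits(samples, "community_samples"))
  area <- samples$meta$area
  if (anyNA(area) || any(area <= 0)) {
    stop("density requires SS samples with positive area", call. = FALSE)
  }
  if (is.null(taxa)) {
    cnt <- rowSums(samples$abundance)
  } else {
    keep <- intersect(taxa, colnames(samples$abundance))
    cnt <- if (length(keep)) {
      rowSums(samples$abundance[, keep, drop = FALSE])
    } else {
      rep(0, nrow(samples$meta))
    }
  }
  out <- cnt / area
  names(out) <- samples$meta$sample_id
  out
}

#' Convert a density from ind m^-2 to ind ha^-1
#' @param x density in individuals per square metre.
#' @return density in individuals per hectare (`x * 1e4`).
#' @export
per_m2_to_per_ha <- function(x) x * 1e4

#' Per-province mean and 95% confidence interval of a metric
#'
#' Arithmetic mean with a two-sided t confidence interval
#' (`mean +/- t(0.975, n-1) * s / sqrt(n)`) per province. Provinces with
#' fewer than 2 samples get `NA` interval bounds. A bootstrap percentile
#' interval is available as an alternative.
#'
#' @param values numeric metric, one per sample.
#' @param provinces province label per sample (same length).
#' @param conf confidence level.
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param n_boot,seed bootstrap replicates and seed (bootstrap method only).
#' @return data frame: `province`, `metric_n`, `mean`, `ci_low`, `ci_high`.
#' @export
province_summary <- function(values, provinces, conf = 0.95,
                             method = c("t", "bootstrap"),
                             n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(values) == length(provinces))
  alpha <- 1 - conf
  res <- lapply(split(values, provinces), function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    m <- mean(v)
    if (n < 2) return(c(n = n, mean = m, lo = NA_real_, hi = NA_real_))
    if (method == "t") {
      half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(v) / sqrt(n)
      c(n = n, mean = m, lo = m - half, hi = m + half)
    } else {
      boots <- with_seed(seed, replicate(n_boot, mean(sample(v, n, TRUE))))
      q <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      c(n = n, mean = m, lo = q[1], hi = q[2])
    }
  })
  out <- data.frame(province = names(res),
                    metric_n = vapply(res, `[[`, 0, "n"),
                    mean = vapply(res, `[[`, 0, "mean"),
                    ci_low = vapply(res, `[[`, 0, "lo"),
                    ci_high = vapply(res, `[[`, 0, "hi"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sample-based morphotype accumulation curve
#'
#' Monte-Carlo (sample-order permutation) accumulation: for each of
#' `n_randomizations` seeded permutations of the samples, the cumulative
#' pooled richness is recorded at every step; the curve reports the per-step
#' mean with a t-based 95% confidence envelope across permutations. The last
#' point equals the pooled richness of all samples for every permutation.
#'
#' @param samples a BD-mode `community_samples` object (>= 1 sample).
#' @param n_randomizations number of random sample orders.
#' @param seed integer seed.
#' @param conf confidence level of the envelope.
#' @return data frame of class `accumulation_curve`: `n_samples`,
#'   `mean_richness`, `ci_low`, `ci_high`, `sd`.
#' @export
accumulation_curve <- function(samples, n_randomizations = 100, seed = 1L,
                               conf = 0.95) {
  .assert_bd(samples)
  inc <- samples$abundance > 0
  n <- nrow(inc)
  stopifnot(n >= 1)
  rich <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(r) {
      ord <- sample.int(n)
      seen <- rep(FALSE, ncol(inc))
      cum <- numeric(n)
      for (i in seq_len(n)) {
        seen <- seen | inc[ord[i], ]
        cum[i] <- sum(seen)
      }
      cum
    }, numeric(n))
  })
  rich <- matrix(rich, nrow = n)  # steps x randomizations
  mu <- rowMeans(rich)
  sdev <- apply(rich, 1, stats::sd)
  half <- stats::qt(1 - (1 - conf) / 2, df = n_randomizations - 1) *
    sdev / sqrt(n_randomizations)
  out <- data.frame(n_samples = seq_len(n), mean_richness = mu,
                    ci_low = mu - half, ci_high = mu + half, sd = sdev)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}
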