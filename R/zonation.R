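# Depth-structured community description: province classification, ridgeline
# depth distributions, morphotype overlap/exclusivity, dominance tables and
# the province-boundary sweep diagnostic.

#' Depth-province scheme
#'
#' Three half-open depth bands: shallow `[0, b1)`, transition `[b1, b2)`,
#' deep `[b2, Inf)`. Defaults follow the northeast-Pacific zonation
#' (shallow < 4,300 m, transition 4,300-4,800 m, deep > 4,800 m), bracketing
#' the regional carbonate compensation depth band.
#'
#' @param b1,b2 boundary depths in metres, `0 < b1 < b2`.
#' @return list of class `province_scheme`.
#' @export
province_scheme <- function(b1 = 4300, b2 = 4800) {
  stopifnot(0 < b1, b1 < b2)
  structure(list(b1 = b1, b2 = b2,
                 labels = c("shallow", "transition", "deep")),
            class = "province_scheme")
}

#' Classify depths into provinces
#'
#' @param depth numeric depths (m, positive down).
#' @param scheme a [province_scheme()].
#' @return factor with levels `shallow`, `transition`, `deep`.
#' @export
classify_province <- function(depth, scheme = province_scheme()) {
  stopifnot(all(depth > 0))
  cut(depth, breaks = c(0, scheme$b1, scheme$b2, Inf),
      labels = scheme$labels, right = FALSE)
}

#' Ridgeline depth distributions of dominant taxonomic groups
#'
#' For each higher taxonomic group with more than `min_occurrences` specimen
#' occurrences, the normalized depth histogram of its occurrences (relative
#' to all occurrences of that group). The histogram is the canonical output;
#' any kernel smoothing is a display concern only.
#'
#' @param table an [occurrence_table()].
#' @param min_occurrences strict inclusion threshold (group kept iff
#'   occurrences > threshold).
#' @param bin_width_m depth-bin width of the histogram (m), bins aligned to
#'   multiples of the width, half-open.
#' @param group_col records column holding the group label.
#' @return data frame: `group`, `n_occurrences`, `bin_low`, `bin_high`,
#'   `frequency` (sums to 1 within each group).
#' @export
ridgeline <- function(table, min_occurrences = 50, bin_width_m = 100,
                      group_col = "higher_taxon") {
  stopifnot(inherits(table, "occurrence_table"))
  rec <- table$records
  rec <- rec[!is.na(rec[[group_col]]), , drop = FALSE]
  counts <- base::table(rec[[group_col]])  # `table` is the data argument here
  keep <- names(counts)[counts > min_occurrences]
  rows <- lapply(keep, function(g) {
    depths <- rec$depth[rec[[group_col]] == g]
    low <- floor(depths / bin_width_m) * bin_width_m
    tab <- base::table(low)
    data.frame(group = g, n_occurrences = length(depths),
               bin_low = as.numeric(names(tab)),
               bin_high = as.numeric(names(tab)) + bin_width_m,
               frequency = as.numeric(tab) / length(depths),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = character(), n_occurrences = integer(),
               bin_low = numeric(), bin_high = numeric(),
               frequency = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Morphotype overlap and exclusivity between provinces
#'
#' Working from rarefied BD samples (each labelled by the province of its
#' mean depth): a morphotype's province set is the set of provinces holding a
#' sample where it occurs; it is *exclusive* when that set is a singleton and
#' *rare* when its total specimen count across all samples is below
#' `rare_threshold`. Shallow-deep sharing is counted irrespective of
#' transition-zone presence.
#'
#' @param samples a BD-mode `community_samples` object.
#' @param scheme a [province_scheme()].
#' @param rare_threshold strict rare cut-off on total occurrences (default:
#'   rare means fewer than 5).
#' @return list of class `overlap_counts`: `per_province` (data frame
#'   `province`, `total`, `exclusive`, `rare_exclusive`),
#'   `shared_shallow_deep`, `shared_shallow_deep_rare`,
#'   `total_morphotypes`, `total_rare`.
#' @export
overlap_counts <- function(samples, scheme = province_scheme(),
                           rare_threshold = 5) {
  .assert_bd(samples)
  prov <- classify_province(samples$meta$mean_depth, scheme)
  ab <- samples$abundance
  present <- ab > 0
  totals <- colSums(ab)
  rare <- totals < rare_threshold
  in_prov <- sapply(scheme$labels, function(p) {
    if (!any(prov == p)) return(rep(FALSE, ncol(ab)))
    colSums(present[prov == p, , drop = FALSE]) > 0
  })  # taxa x 3 logical
  n_prov <- rowSums(in_prov)
  per_province <- data.frame(
    province = scheme$labels,
    total = colSums(in_prov),
    exclusive = sapply(scheme$labels, function(p) {
      sum(in_prov[, p] & n_prov == 1)
    }),
    rare_exclusive = sapply(scheme$labels, function(p) {
      sum(in_prov[, p] & n_prov == 1 & rare)
    }),
    stringsAsFactors = FALSE, row.names = NULL)
  shared <- in_prov[, "shallow"] & in_prov[, "deep"]
  structure(list(per_province = per_province,
                 shared_shallow_deep = sum(shared),
                 shared_shallow_deep_rare = sum(shared & rare),
                 total_morphotypes = sum(n_prov > 0),
                 total_rare = sum(rare & n_prov > 0)),
            class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("<overlap_counts> ", x$total_morphotypes, " morphotypes (",
      x$total_rare, " rare)\n", sep = "")
  print(x$per_province)
  cat("shared shallow-deep: ", x$shared_shallow_deep, " (",
      x$shared_shallow_deep_rare, " rare)\n", sep = "")
  invisible(x)
}

#' Dominance ranking and dominance concentration per province
#'
#' Ranks taxa within each province by summed abundance (BD samples) or mean
#' density (SS samples) and reports the top `k` together with the cumulative
#' share of total abundance they encompass. Ties are broken by taxon label,
#' so output is deterministic.
#'
#' @param samples a `community_samples` object.
#' @param k number of top taxa (conventionally 10 for morphotypes, 4 for
#'   higher taxonomic groups).
#' @param scheme a [province_scheme()].
#' @param group_map optional named character vector morphotype -> group; when
#'   given, abundances are aggregated to groups before ranking.
#' @return list of class `dominance_table`: `table` (data frame `province`,
#'   `rank`, `taxon`, `value`, `share`), `top_k_share` (named numeric, the
#'   cumulative top-`k` abundance share per province), `k`.
#' @export
dominance <- function(samples, k = 10, scheme = province_scheme(),
                      group_map = NULL) {
  stopifnot(inherits(samples, "community_samples"))
  prov <- classify_province(samples$meta$mean_depth, scheme)
  ab <- samples$abundance
  if (!is.null(group_map)) {
    grp <- group_map[colnames(ab)]
    grp[is.na(grp)] <- colnames(ab)[is.na(grp)]
    ab <- t(rowsum(t(ab), group = grp))
  }
  is_ss <- all(samples$meta$mode == "SS") && !anyNA(samples$meta$area)
  rows <- list(); shares <- numeric()
  for (p in levels(prov)) {
    sel <- prov == p
    if (!any(sel)) next
    if (is_ss) {
      dens <- sweep(ab[sel, , drop = FALSE], 1,
                    samples$meta$area[sel], "/")
      val <- colMeans(dens)
    } else {
      val <- colSums(ab[sel, , drop = FALSE])
    }
    total_ab <- sum(ab[sel, , drop = FALSE])
    ord <- order(-val, names(val))
    topk <- ord[seq_len(min(k, sum(val > 0)))]
    share_ab <- colSums(ab[sel, , drop = FALSE]) / total_ab
    rows[[p]] <- data.frame(province = p, rank = seq_along(topk),
                            taxon = names(val)[topk],
                            value = unname(val[topk]),
                            share = unname(share_ab[topk]),
                            stringsAsFactors = FALSE)
    shares[p] <- sum(share_ab[topk])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, top_k_share = shares, k = k),
            class = "dominance_table")
}

#' @export
print.dominance_table <- function(x, ...) {
  cat("<dominance_table> top-", x$k, " cumulative abundance share:\n",
      sep = "")
  print(round(x$top_k_share, 3))
  invisible(x)
}

#' Boundary-sweep zonation diagnostic
#'
#' Slides a single candidate boundary depth over a grid, splits the samples
#' into above/below groups and records the mean between-group minus mean
#' within-group Bray-Curtis dissimilarity. The boundary maximising this
#' separation estimates the depth of the strongest community replacement.
#'
#' @param samples a BD-mode `community_samples` object.
#' @param d optional precomputed [bray_curtis()] distance for `samples`.
#' @param boundaries candidate boundary depths (m).
#' @param min_group minimum samples required on each side for a candidate to
#'   be evaluated.
#' @return list of class `boundary_sweep`: `sweep` (data frame `boundary`,
#'   `within`, `between`, `separation`), `best_boundary`.
#' @export
boundary_sweep <- function(samples, d = NULL,
                           boundaries = seq(4000, 5200, by = 100),
                           min_group = 2) {
  .assert_bd(samples)
  if (is.null(d)) d <- bray_curtis(samples)
  depth <- samples$meta$mean_depth
  rows <- lapply(boundaries, function(b) {
    grp <- depth >= b
    if (sum(grp) < min_group || sum(!grp) < min_group) {
      return(data.frame(boundary = b, within = NA_real_,
                        between = NA_real_, separation = NA_real_))
    }
    gs <- group_separation(d, grp)
    data.frame(boundary = b, within = gs$within, between = gs$between,
               separation = gs$separation)
  })
  sweep_df <- do.call(rbind, rows)
  best <- sweep_df$boundary[which.max(sweep_df$separation)]
  structure(list(sweep = sweep_df, best_boundary = best),
            class = "boundary_sweep")
}

#' @export
print.boundary_sweep <- function(x, ...) {
  cat("<boundary_sweep> best boundary: ", x$best_boundary, " m\n", sep = "")
  invisible(x)
}
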