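# Bray-Curtis dissimilarity on square-root-transformed abundances and
# non-metric multidimensional scaling (Kruskal stress-1), implemented with
# pool-adjacent-violators isotonic regression and steepest-descent updates.

#' Bray-Curtis dissimilarity between community samples
#'
#' `BC(x, y) = sum(|x' - y'|) / sum(x' + y')` with `x' = sqrt(x)` under the
#' (default) square-root transform, which down-weights dominant taxa.
#'
#' @param samples a `community_samples` object (>= 2 samples over a shared
#'   taxon universe) or a samples x taxa abundance matrix.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return a [stats::dist] object labelled with sample ids; attribute
#'   `transform` records the transform applied.
#' @export
bray_curtis <- function(samples, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  ab <- if (inherits(samples, "community_samples")) samples$abundance
        else as.matrix(samples)
  if (nrow(ab) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(ab) == 0)) {
    stop("all-zero abundance sample(s): Bray-Curtis undefined", call. = FALSE)
  }
  if (transform == "sqrt") ab <- sqrt(ab)
  d <- vegan::vegdist(ab, method = "bray")
  attr(d, "transform") <- transform
  d
}

#' Pool-adjacent-violators isotonic least squares
#'
#' Fits the non-decreasing sequence minimising the weighted sum of squares to
#' `y` (in its given order).
#'
#' @param y numeric vector.
#' @param w positive weights, same length.
#' @return fitted non-decreasing numeric vector.
#' @export
pava_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      # merge the two top blocks (weighted mean)
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = sz[seq_len(top)])
}

# stress-1 and its gradient for configuration X against dissimilarities dvec
# (lower-triangle order). Ties in dvec are handled by Kruskal's primary
# approach: within a tied block, fitted distances follow the configuration
# distances (sort dhat ascending inside ties before PAVA).
.stress1 <- function(X, dvec, gradient = FALSE) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  dhat <- D[lower.tri(D)]
  ord <- order(dvec, dhat)
  dstar <- numeric(length(dvec))
  dstar[ord] <- pava_isotonic(dhat[ord])
  sstar <- sum((dhat - dstar)^2)
  tstar <- sum(dhat^2)
  s <- sqrt(sstar / tstar)
  if (!gradient) return(list(stress = s))
  # dS/d dhat_ij = S * ((dhat - dstar)/S* - dhat/T*)
  coef_vec <- if (s > 0) s * ((dhat - dstar) / sstar - dhat / tstar)
              else numeric(length(dhat))
  Cm <- matrix(0, n, n)
  Cm[lower.tri(Cm)] <- coef_vec
  Cm <- Cm + t(Cm)
  Dsafe <- D; Dsafe[Dsafe == 0] <- Inf
  W <- Cm / Dsafe
  G <- X * rowSums(W) - W %*% X
  list(stress = s, gradient = G)
}

# one NMDS run from a given start configuration
.nmds_run <- function(X, dvec, max_iter, tol) {
  st <- .stress1(X, dvec, gradient = TRUE)
  trace <- st$stress
  converged <- FALSE
  step <- 0.1 * sqrt(sum(X^2)) / max(sqrt(sum(st$gradient^2)), 1e-12)
  for (iter in seq_len(max_iter)) {
    gnorm <- sqrt(sum(st$gradient^2))
    if (gnorm < 1e-12) { converged <- TRUE; break }
    improved <- FALSE
    for (h in seq_len(25)) {       # step halving
      Xn <- X - step * st$gradient
      sn <- .stress1(Xn, dvec, gradient = FALSE)$stress
      if (sn < st$stress) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    delta <- st$stress - sn
    X <- Xn
    st <- .stress1(X, dvec, gradient = TRUE)
    trace <- c(trace, st$stress)
    step <- step * 1.5              # allow the step to grow again
    if (delta < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = st$stress, trace = trace, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimises `stress-1 = sqrt(sum((dhat - d*)^2) / sum(dhat^2))`, where
#' `dhat` are configuration distances and `d*` their monotone (isotonic,
#' pool-adjacent-violators) regression on the rank order of the input
#' dissimilarities. Steepest-descent updates with step halving run until the
#' stress improvement falls below `tol` or `max_iter` is reached; the best of
#' `n_restarts` starts is kept (start 1: classical metric scaling; the rest:
#' seeded random configurations). The returned configuration is centred and
#' rotated to its principal axes.
#'
#' @param d a [stats::dist] of dissimilarities (e.g. from [bray_curtis()]).
#' @param k target dimension (default 2); needs `n >= k + 1` points.
#' @param n_restarts number of starts.
#' @param max_iter iteration cap per start.
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param tol stress-improvement convergence tolerance.
#' @return list of class `nmds_ordination`: `points` (n x k, centred,
#'   principal-axis rotated, row names = labels of `d`), `stress`, `trace`
#'   (per-iteration stress of the best start), `converged`, `n_restarts`,
#'   `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 200, seed = 1L,
                 tol = 1e-6) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 points", call. = FALSE)
  dvec <- as.vector(d)
  labs <- attr(d, "Labels")
  if (length(unique(dvec)) == 1L) {
    warning("all dissimilarities equal: degenerate ordination", call. = FALSE)
    X <- .centre_rotate(stats::cmdscale(d, k = k))
    st <- .stress1(X, dvec)$stress
    return(structure(list(points = .label(X, labs), stress = st,
                          trace = st, converged = FALSE,
                          n_restarts = 0L, seed = seed),
                     class = "nmds_ordination"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1L) {
      X0 <- stats::cmdscale(d, k = k)
      if (ncol(X0) < k) cbind(X0, matrix(0, n, k - ncol(X0))) else X0
    } else {
      with_seed(seed + r - 1L, matrix(stats::rnorm(n * k), n, k))
    }
    run <- .nmds_run(X0, dvec, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  X <- .centre_rotate(best$X)
  structure(list(points = .label(X, labs), stress = best$stress,
                 trace = best$trace, converged = best$converged,
                 n_restarts = n_restarts, seed = seed),
            class = "nmds_ordination")
}

.centre_rotate <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  s <- svd(X)
  X <- s$u %*% diag(s$d, nrow = length(s$d))
  # deterministic sign: largest-magnitude loading positive per axis
  for (j in seq_len(ncol(X))) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  X
}

.label <- function(X, labs) {
  if (!is.null(labs)) rownames(X) <- labs
  colnames(X) <- paste0("NMDS", seq_len(ncol(X)))
  X
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("<nmds_ordination> ", nrow(x$points), " points, k = ", ncol(x$points),
      ", stress-1 = ", signif(x$stress, 4),
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Ordination export table
#'
#' Joins NMDS coordinates with sample metadata and a depth-province label —
#' the payload for ordination plots coloured by site or depth.
#'
#' @param ordination an `nmds_ordination` from [nmds()].
#' @param samples the `community_samples` the ordination was computed from.
#' @param scheme a [province_scheme()].
#' @return data frame: `sample_id`, `NMDS1..k`, `site`, `mean_depth`,
#'   `province`.
#' @export
ordination_report <- function(ordination, samples,
                              scheme = province_scheme()) {
  stopifnot(inherits(ordination, "nmds_ordination"),
            inherits(samples, "community_samples"))
  pts <- ordination$points
  m <- samples$meta
  if (!identical(rownames(pts), as.character(m$sample_id))) {
    stop("ordination points and sample metadata are not aligned",
         call. = FALSE)
  }
  out <- data.frame(sample_id = m$sample_id, pts, site = m$site,
                    mean_depth = m$mean_depth,
                    province = classify_province(m$mean_depth, scheme),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Mean within- versus between-group dissimilarity
#'
#' Summarises a dissimilarity matrix by group membership: the mean of all
#' pairs within the same group and the mean of all pairs straddling groups.
#' A positive `separation` (between minus within) indicates compositional
#' structure along the grouping.
#'
#' @param d a [stats::dist].
#' @param groups group label per point (in the order of `d`'s labels).
#' @return list: `within`, `between`, `separation`.
#' @export
group_separation <- function(d, groups) {
  n <- attr(d, "Size")
  stopifnot(length(groups) == n)
  dm <- as.matrix(d)
  same <- outer(groups, groups, "==")
  lt <- lower.tri(dm)
  within <- mean(dm[lt & same])
  between <- mean(dm[lt & !same])
  list(within = within, between = between, separation = between - within)
}
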