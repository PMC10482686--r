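# Metric-versus-environment regressions under named transformation families,
# AICc model selection, and the environmental-factor correlation screen.

.gradient_families <- c("linear", "log", "exp")

#' Fit a metric ~ predictor regression under a transformation family
#'
#' Ordinary least squares on transformed variables:
#' * `linear`: `y ~ x`
#' * `log`:    `y ~ log(x)` (predictor transform; requires `x > 0`)
#' * `exp`:    `log(y) ~ x` (exponential response; requires `y > 0`)
#'
#' F (with 1 and n-2 df), p and R^2 are reported on the transformed scale.
#' AICc is computed on a common response scale: for the `exp` family the
#' Gaussian log-likelihood of `log(y)` is adjusted by the log-Jacobian
#' `-sum(log(y))` so that families with different response transforms are
#' comparable.
#'
#' @param y response metric per sample (e.g. density, richness).
#' @param x predictor per sample (`depth` or `poc_flux`).
#' @param family one of `"linear"`, `"log"`, `"exp"`.
#' @param metric,predictor optional names carried into the result.
#' @return one-row data frame of class `gradient_fit`: `metric`, `predictor`,
#'   `family`, `intercept`, `slope`, `F`, `df1`, `df2`, `p_value`,
#'   `r_squared`, `aicc`, `n`. The underlying [stats::lm] fit is attached as
#'   attribute `"model"`.
#' @export
fit_gradient <- function(y, x, family = c("linear", "log", "exp"),
                         metric = deparse1(substitute(y)),
                         predictor = deparse1(substitute(x))) {
  family <- match.arg(family)
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (family == "exp" && any(y <= 0)) {
    stop("exp family requires y > 0 (offending index ",
         which(y <= 0)[1], ")", call. = FALSE)
  }
  if (family == "log" && any(x <= 0)) {
    stop("log family requires x > 0 (offending index ",
         which(x <= 0)[1], ")", call. = FALSE)
  }
  yt <- if (family == "exp") log(y) else y
  xt <- if (family == "log") log(x) else x
  fit <- stats::lm(yt ~ xt)
  sm <- summary(fit)
  r2 <- sm$r.squared
  # a constant response has no slope signal; report a null fit exactly
  if (stats::sd(yt) == 0) r2 <- 0
  if (is.null(sm$fstatistic) || stats::sd(yt) == 0) {
    fstat <- 0; pval <- 1
  } else {
    fstat <- unname(sm$fstatistic[1])
    pval <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))          # MLE sigma
  if (family == "exp") ll <- ll - sum(log(y))   # Jacobian of log response
  kpar <- 3  # intercept, slope, sigma
  aicc <- -2 * ll + 2 * kpar + 2 * kpar * (kpar + 1) / (n - kpar - 1)
  out <- data.frame(metric = metric, predictor = predictor, family = family,
                    intercept = unname(stats::coef(fit)[1]),
                    slope = unname(stats::coef(fit)[2]),
                    F = fstat, df1 = 1L, df2 = n - 2L, p_value = pval,
                    r_squared = r2, aicc = aicc, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("gradient_fit", "data.frame")
  attr(out, "model") <- fit
  out
}

#' Select the best transformation family by AICc
#'
#' Fits every requested family whose domain preconditions hold (skipped
#' families are noted), ranks by AICc and returns the best fit together with
#' the full ranking.
#'
#' @inheritParams fit_gradient
#' @param families character subset of `c("linear", "log", "exp")`.
#' @return list of class `model_selection`: `best` (a `gradient_fit`),
#'   `ranking` (data frame of all fitted families with `delta_aicc`),
#'   `skipped` (named character vector of skip reasons, possibly empty).
#' @export
select_model <- function(y, x, families = .gradient_families,
                         metric = deparse1(substitute(y)),
                         predictor = deparse1(substitute(x))) {
  families <- match.arg(families, .gradient_families, several.ok = TRUE)
  fits <- list(); skipped <- character()
  for (fam in families) {
    f <- tryCatch(
      fit_gradient(y, x, fam, metric = metric, predictor = predictor),
      error = function(e) conditionMessage(e))
    if (is.character(f)) skipped[fam] <- f else fits[[fam]] <- f
  }
  if (!length(fits)) {
    stop("no family could be fitted: ",
         paste(names(skipped), skipped, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  ranking <- do.call(rbind, fits)
  ranking <- ranking[order(ranking$aicc), , drop = FALSE]
  ranking$delta_aicc <- ranking$aicc - ranking$aicc[1]
  rownames(ranking) <- NULL
  best <- fits[[ranking$family[1]]]
  structure(list(best = best, ranking = ranking, skipped = skipped),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> best family: ", x$best$family,
      " (AICc ", signif(x$best$aicc, 5), ")\n", sep = "")
  print(x$ranking[c("family", "slope", "F", "p_value", "r_squared",
                    "aicc", "delta_aicc")])
  invisible(x)
}

#' Environmental-factor collinearity screen
#'
#' Pairwise Pearson correlations among the candidate predictors (depth,
#' latitude, longitude, POC flux); pairs with `|r|` above the threshold are
#' flagged as unusable together in a regression. Zero-variance variables get
#' `NA` correlations and their pairs are flagged as undefined.
#'
#' @param env data frame holding (a subset of) the columns `depth`,
#'   `latitude`, `longitude`, `poc_flux` — e.g. built from sample metadata.
#' @param threshold absolute-correlation flag threshold (default 0.7).
#' @return list of class `correlation_screen`: `r` (correlation matrix),
#'   `flagged` (data frame `var1`, `var2`, `r`, `reason`), `threshold`.
#' @export
correlation_screen <- function(env, threshold = 0.7) {
  vars <- intersect(c("depth", "latitude", "longitude", "poc_flux"),
                    names(env))
  if (length(vars) < 2) stop("need at least 2 screen variables", call. = FALSE)
  m <- as.matrix(env[vars])
  if (nrow(m) < 3) stop("need at least 3 units", call. = FALSE)
  const <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- ifelse(const, NA, 1)
  flagged <- data.frame(var1 = character(), var2 = character(),
                        r = numeric(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_along(vars)[-length(vars)]) {
    for (j in (i + 1):length(vars)) {
      rij <- r[i, j]
      if (is.na(rij)) {
        flagged[nrow(flagged) + 1L, ] <-
          list(vars[i], vars[j], NA_real_, "undefined (zero variance)")
      } else if (abs(rij) >= threshold) {
        flagged[nrow(flagged) + 1L, ] <-
          list(vars[i], vars[j], rij, "collinear")
      }
    }
  }
  structure(list(r = r, flagged = flagged, threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("<correlation_screen> |r| threshold ", x$threshold, "\n", sep = "")
  print(round(x$r, 3))
  if (nrow(x$flagged)) {
    cat("flagged pairs:\n"); print(x$flagged)
  } else cat("no flagged pairs\n")
  invisible(x)
}
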