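# Environmental predictors and metric ~ predictor regressions.

#' Exponential Shannon diversity of arthropod dry mass
#'
#' Hill number of order 1: `exp(H')` with `H' = -sum p_i log p_i`, where
#' `p_i` is the share of total dry mass in arthropod order i. Equals the
#' effective number of equally abundant orders; zero-mass orders are
#' dropped.
#'
#' @param mass_by_order numeric vector of dry masses in grams (>= 0, at
#'   least one positive).
#' @return `exp(H')`, in `[1, number of orders]`.
#' @examples
#' shannon_exp_diversity(c(Coleoptera = 1, Araneae = 1, Orthoptera = 2))
#' @export
shannon_exp_diversity <- function(mass_by_order) {
  w <- as.numeric(mass_by_order)
  if (any(w < 0)) stop("negative mass")
  w <- w[w > 0]
  if (length(w) == 0L) stop("all masses are zero")
  p <- w / sum(w)
  exp(-sum(p * log(p)))
}

#' Log-transformed fruit availability
#'
#' `log10(count + 1)` by default; the +1 offset keeps zero counts defined.
#' Set `base = exp(1)` for natural-log reporting.
#'
#' @param count non-negative fruit count.
#' @param base logarithm base (default 10).
#' @return Transformed availability.
#' @export
fruit_predictor <- function(count, base = 10) {
  if (any(count < 0)) stop("negative fruit count")
  log(count + 1, base = base)
}

#' PCA summary of habitat structure
#'
#' One principal component analysis over all stations pooled across sites
#' and seasons. Each structural variable is Z-scored first (so the PCA is on
#' the correlation structure); axis signs are fixed so the largest-magnitude
#' loading of each axis is positive, making score gradients reproducible in
#' direction. Site-by-season predictors are the mean station scores on the
#' first two axes.
#'
#' @param samples data.frame with columns `site`, `season`, `station` and
#'   one numeric column per structural variable (all remaining columns).
#' @return A list with `loadings` (variables x axes), `variance_fraction`
#'   (per axis, sums to 1), `scores` (per station, with site/season kept)
#'   and `predictors` (one row per site x season: `pc1_score`, `pc2_score`).
#' @export
habitat_pca <- function(samples) {
  meta <- c("site", "season", "station")
  vars <- setdiff(names(samples), meta)
  if (length(vars) < 2L) stop("need >= 2 structural variables")
  X <- as.matrix(samples[vars])
  if (!is.numeric(X)) stop("structural variables must be numeric")
  if (nrow(X) <= length(vars))
    stop("need more stations than variables for a stable PCA")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("constant structural variable: ",
                          vars[which(sds == 0)[1L]])
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (a in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, a]))
    if (pc$rotation[j, a] < 0) {
      pc$rotation[, a] <- -pc$rotation[, a]
      pc$x[, a] <- -pc$x[, a]
    }
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(samples[intersect(meta, names(samples))],
                       pc$x[, 1:2, drop = FALSE])
  agg <- stats::aggregate(scores[c("PC1", "PC2")],
                          by = scores[c("site", "season")], FUN = mean)
  names(agg)[names(agg) == "PC1"] <- "pc1_score"
  names(agg)[names(agg) == "PC2"] <- "pc2_score"
  list(loadings = pc$rotation, variance_fraction = varfrac,
       scores = scores, predictors = agg)
}

#' Simple linear regression of a network metric on a predictor
#'
#' Ordinary least squares `y = a + b x` across site-by-season points, with
#' the two-sided p-value for the slope. With the study design's eight
#' points, power is limited; `n` is carried in the result so readers see it.
#'
#' @param x predictor values (one per site x season).
#' @param y metric values, same length, `n >= 3`.
#' @param predictor,response labels carried into the result.
#' @return A list with `predictor`, `response`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `significant` (p < 0.05).
#' @export
fit_metric_regression <- function(x, y, predictor = "x", response = "y") {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 points")
  if (stats::sd(x) == 0) stop("zero variance in predictor ", predictor)
  fit <- stats::lm(y ~ x)
  # a perfect fit trips summary.lm's reliability warning; handled below
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) < 2L || sm$sigma == 0) {
    # perfect fit: slope exactly determined
    0
  } else sm$coefficients["x", "Pr(>|t|)"]
  list(predictor = predictor, response = response,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared, p_value = p, n = length(x),
       significant = is.finite(p) && p < 0.05)
}

#' Spearman collinearity screen among predictors
#'
#' Pairwise Spearman rank correlations with p-values across the predictor
#' table, flagging pairs with p <= 0.1 (the screen used before regressing
#' metrics on resource-availability variables).
#'
#' @param predictors data.frame of numeric predictor columns (>= 4 rows).
#' @return A data.frame with one row per unordered pair: `var1`, `var2`,
#'   `rho`, `p_value`, `flagged`.
#' @export
collinearity_screen <- function(predictors) {
  predictors <- predictors[vapply(predictors, is.numeric, logical(1))]
  if (nrow(predictors) < 4L) stop("need >= 4 rows")
  nm <- names(predictors)
  pairs <- utils::combn(nm, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- predictors[[pairs[1L, k]]]
    b <- predictors[[pairs[2L, k]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(var1 = pairs[1L, k], var2 = pairs[2L, k], rho = rho,
               p_value = p, flagged = is.finite(p) && p <= 0.1)
  }))
  out
}
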