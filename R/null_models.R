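# Erdos-Renyi null ensembles, Monte Carlo significance and SES.

#' Random bipartite incidence matrix (Erdos-Renyi null)
#'
#' Two null flavors, matching the two readings of a size-matched random
#' network: `bernoulli_half` sets every cell to 1 independently with
#' probability 0.5 (every item equally likely to be selected or not);
#' `match_connectance` places exactly `round(c_obs * n_rows * n_cols)` links
#' uniformly at random, preserving the observed connectance.
#'
#' @param n_rows,n_cols matrix dimensions (>= 1).
#' @param mode `"bernoulli_half"` or `"match_connectance"`.
#' @param c_obs observed connectance, required for `match_connectance`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return A plain 0/1 integer matrix with generic dimnames. All-zero rows
#'   or columns may occur; downstream metrics prune or redraw as
#'   appropriate.
#' @export
er_random_matrix <- function(n_rows, n_cols,
                             mode = c("bernoulli_half", "match_connectance"),
                             c_obs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  m <- with_seed(seed, {
    if (mode == "bernoulli_half") {
      matrix(stats::rbinom(n_rows * n_cols, 1L, 0.5), n_rows, n_cols)
    } else {
      if (is.null(c_obs)) stop("c_obs required for match_connectance")
      L <- round(c_obs * n_rows * n_cols)
      if (L < 1L || L >= n_rows * n_cols)
        stop("impossible fill under match_connectance: L = ", L)
      out <- matrix(0L, n_rows, n_cols)
      out[sample.int(n_rows * n_cols, L)] <- 1L
      out
    }
  })
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("i", seq_len(n_rows)),
                      paste0("r", seq_len(n_cols)))
  m
}

#' Monte Carlo significance test against an Erdos-Renyi null
#'
#' Evaluates `metric_fn` on `n_sim` random matrices of the same shape as
#' `template` and computes a two-sided Monte Carlo p-value with the plus-one
#' correction: `p_high = (#{sim >= obs} + 1) / (n_sim + 1)`, `p_low`
#' analogously, `p = min(1, 2 * min(p_low, p_high))`. Draws on which the
#' metric is undefined (e.g. an edgeless graph) are redrawn, up to
#' `redraw_limit` per replicate, and the redraw count is reported.
#'
#' @param observed observed metric value.
#' @param metric_fn function taking a 0/1 matrix and returning a scalar.
#' @param template the observed [incidence_matrix()] (supplies the shape and,
#'   under `match_connectance`, the fill).
#' @param n_sim ensemble size (default 1000).
#' @param mode null flavor, see [er_random_matrix()].
#' @param seed integer seed for the whole ensemble.
#' @param alpha nominal significance level for the `significant` flag.
#' @param metric_name label carried into the result.
#' @param redraw_limit max redraws per replicate before failing.
#' @return An object of class `null_test` with fields `metric_name`,
#'   `observed`, `null_values`, `n_sim`, `p_value`, `ses`, `significant`,
#'   `mode`, `seed` and `n_redraws`.
#' @export
monte_carlo_test <- function(observed, metric_fn, template, n_sim = 1000L,
                             mode = c("bernoulli_half", "match_connectance"),
                             seed = 1L, alpha = 0.05,
                             metric_name = "metric", redraw_limit = 100L) {
  mode <- match.arg(mode)
  stopifnot(n_sim >= 1L)
  c_obs <- if (mode == "match_connectance") connectance(template) else NULL
  n_redraws <- 0L
  null_values <- with_seed(seed, {
    vapply(seq_len(n_sim), function(k) {
      for (attempt in seq_len(redraw_limit + 1L)) {
        mat <- er_random_matrix(nrow(template), ncol(template),
                                mode = mode, c_obs = c_obs, seed = NULL)
        val <- tryCatch(metric_fn(mat), error = function(e) NA_real_)
        if (is.finite(val)) return(val)
        n_redraws <<- n_redraws + 1L
      }
      stop("metric failed on ", redraw_limit, " consecutive null draws")
    }, numeric(1))
  })
  p_high <- (sum(null_values >= observed) + 1) / (n_sim + 1)
  p_low <- (sum(null_values <= observed) + 1) / (n_sim + 1)
  p <- min(1, 2 * min(p_low, p_high))
  ses <- if (stats::sd(null_values) > 0)
    standardized_effect_size(observed, null_values) else NA_real_
  structure(list(metric_name = metric_name, observed = observed,
                 null_values = null_values, n_sim = n_sim,
                 p_value = p, ses = ses, significant = p <= alpha,
                 mode = mode, seed = seed, n_redraws = n_redraws),
            class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("Monte Carlo null test (%s, %s, %d draws)\n",
              x$metric_name, x$mode, x$n_sim))
  cat(sprintf("  observed = %.4f; null mean = %.4f (sd %.4f)\n",
              x$observed, mean(x$null_values), stats::sd(x$null_values)))
  cat(sprintf("  p = %.4g%s; SES = %.3f\n", x$p_value,
              if (x$significant) " *" else "", x$ses))
  invisible(x)
}

#' Standardized effect size
#'
#' `SES = (observed - mean(null)) / sd(null)` with the sample (n - 1)
#' standard deviation. Under an approximately normal null, values outside
#' `[-2, 2]` indicate a metric significantly higher (above 2) or lower
#' (below -2) than expected by chance.
#'
#' @param observed observed metric value.
#' @param null_values at least two simulated metric values.
#' @return A scalar.
#' @export
standardized_effect_size <- function(observed, null_values) {
  if (length(null_values) < 2L) stop("need >= 2 null values")
  s <- stats::sd(null_values)
  if (s == 0) stop("degenerate null ensemble: zero variance")
  (observed - mean(null_values)) / s
}
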