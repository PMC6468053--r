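# Scalar network descriptors of an incidence matrix.

#' Connectance
#'
#' Fraction of realized links: `L / (I * R)` where `L` is the number of 1s,
#' `I` the number of individuals (rows) and `R` the number of food items
#' (columns).
#'
#' @param m an [incidence_matrix()] or plain 0/1 matrix.
#' @return A fraction in `[0, 1]`.
#' @export
connectance <- function(m) sum(m == 1L) / length(m)

#' Degree distribution of individuals
#'
#' Proportion of individuals (rows) interacting with each observed number of
#' food items.
#'
#' @param m an [incidence_matrix()].
#' @return A named numeric vector: names are observed degrees, values are
#'   proportions summing to 1.
#' @export
degree_distribution <- function(m) {
  deg <- rowSums(unclass(m) == 1L)
  tab <- table(deg)
  stats::setNames(as.numeric(tab) / nrow(m), names(tab))
}

#' Chao1 richness estimate and sampling coverage
#'
#' Estimates the number of food-item categories in the population's diet
#' from the frequencies with which items were detected across individuals,
#' and reports coverage = observed / estimated richness. With doubletons
#' present the classic estimator `S_obs + f1^2 / (2 f2)` is used; with
#' `f2 = 0` the bias-corrected additive term `f1 (f1 - 1) / 2` replaces it.
#'
#' @param item_frequencies named vector: per item, the number of individuals
#'   that consumed it (all counts >= 1). Column sums of an incidence matrix.
#' @return A list with `s_obs`, `f1`, `f2`, `s_est` and `coverage`.
#' @examples
#' chao1(c(a = 1, b = 1, c = 2, d = 2, e = 5))
#' @export
chao1 <- function(item_frequencies) {
  f <- as.numeric(item_frequencies)
  if (length(f) == 0L) stop("empty item frequencies")
  if (any(f < 1)) stop("item frequencies must be >= 1")
  s_obs <- length(f)
  f1 <- sum(f == 1)
  f2 <- sum(f == 2)
  s_est <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  list(s_obs = s_obs, f1 = f1, f2 = f2, s_est = s_est,
       coverage = s_obs / s_est)
}

#' All network descriptors of one incidence matrix
#'
#' Convenience wrapper computing connectance, degree distribution, Chao1
#' coverage, matrix temperature / nestedness and fast-greedy modularity.
#'
#' @inheritParams matrix_temperature
#' @return A list with elements `n_individuals`, `n_items`, `links`,
#'   `connectance`, `degree_distribution`, `chao1`, `temperature`,
#'   `nestedness`, `modularity` and `module_assignment`.
#' @export
network_metrics <- function(m, seed = 1L, effort = "fast") {
  stopifnot(inherits(m, "incidence_matrix"))
  tp <- matrix_temperature(m, seed = seed, effort = effort)
  md <- fast_greedy_modularity(m)
  list(n_individuals = nrow(m), n_items = ncol(m), links = sum(m),
       connectance = connectance(m),
       degree_distribution = degree_distribution(m),
       chao1 = chao1(colSums(unclass(m))),
       temperature = tp$temperature, nestedness = tp$nestedness,
       modularity = md$modularity, module_assignment = md$membership)
}
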