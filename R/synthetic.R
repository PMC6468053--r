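# Generators for the three individual diet-specialization models and for
# matched environmental covariates. The three models are verbal hypotheses
# in the individual-specialization literature (shared preference, distinct
# preference, competitive refuge); the parameterization here is this
# package's own explicit formalization: a breadth law on ranked preferences,
# symmetric bit-flip noise, and an abstract forager-density control in
# [0, 1]. Every choice is recorded in the generation manifest.

#' Parameters of an individual diet-specialization generator
#'
#' @param model `"shared_preference"`, `"distinct_preference"` or
#'   `"competitive_refuge"`.
#' @param n_individuals number of consumers (rows).
#' @param n_resources number of food-item categories (columns).
#' @param density abstract forager-density control in `[0, 1]`; drives diet
#'   expansion (distinct preference) or use of alternative resources
#'   (competitive refuge).
#' @param core_size number of shared top-ranked resources (competitive
#'   refuge only).
#' @param n_groups number of alternative-resource groups (competitive refuge
#'   only).
#' @param breadth_distribution integer `c(min, max)` niche breadths.
#' @param noise symmetric bit-flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return A validated list of class `diet_model_params`.
#' @export
diet_model_params <- function(model = c("shared_preference",
                                        "distinct_preference",
                                        "competitive_refuge"),
                              n_individuals = 40L, n_resources = 20L,
                              density = 0.5, core_size = 5L, n_groups = 3L,
                              breadth_distribution = c(2L, 10L),
                              noise = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_individuals >= 1L, n_resources >= 1L,
            density >= 0, density <= 1,
            core_size >= 0L, core_size <= n_resources, n_groups >= 1L,
            length(breadth_distribution) == 2L,
            breadth_distribution[1L] >= 1L,
            breadth_distribution[1L] <= breadth_distribution[2L],
            breadth_distribution[2L] <= n_resources,
            noise >= 0, noise < 0.5)
  if (model == "competitive_refuge" &&
      n_groups > n_resources - core_size)
    stop("n_groups exceeds the number of alternative resources")
  structure(list(model = model, n_individuals = as.integer(n_individuals),
                 n_resources = as.integer(n_resources), density = density,
                 core_size = as.integer(core_size),
                 n_groups = as.integer(n_groups),
                 breadth_distribution = as.integer(breadth_distribution),
                 noise = noise, seed = as.integer(seed)),
            class = "diet_model_params")
}

.flip_noise <- function(m, noise) {
  if (noise > 0) {
    flips <- matrix(stats::runif(length(m)) < noise, nrow(m), ncol(m))
    m <- (m + flips) %% 2L
  }
  m
}

.finish_sim <- function(m) {
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("ind%02d", seq_len(nrow(m))),
                      sprintf("item%02d", seq_len(ncol(m))))
  incidence_matrix(m, prune = TRUE)
}

#' Shared-preference diet model
#'
#' All individuals share one resource ranking; individual i draws a niche
#' breadth uniformly from `breadth_distribution` and consumes the top
#' resources of the shared ranking, so diets are nested prefixes (perfectly
#' nested, T = 0, when `noise = 0`). Independent bit-flip noise follows.
#'
#' @param p a [diet_model_params()].
#' @return An [incidence_matrix()] (pruned of empty rows/columns).
#' @export
simulate_shared_preference <- function(p) {
  stopifnot(inherits(p, "diet_model_params"))
  with_seed(p$seed, {
    ranking <- sample.int(p$n_resources)
    b <- resample(seq(p$breadth_distribution[1L], p$breadth_distribution[2L]),
                  p$n_individuals, replace = TRUE)
    m <- matrix(0L, p$n_individuals, p$n_resources)
    for (i in seq_len(p$n_individuals)) m[i, ranking[seq_len(b[i])]] <- 1L
    .finish_sim(.flip_noise(m, p$noise))
  })
}

#' Distinct-preference diet model
#'
#' Every individual has its own independent resource ranking; competition at
#' high forager density expands diets, so realized breadth is
#' `round(b_min + density * (b_max - b_min))` for all individuals. Strong
#' individual specialization therefore occurs at low density and declines as
#' density grows. Bit-flip noise follows.
#'
#' @inheritParams simulate_shared_preference
#' @return An [incidence_matrix()].
#' @export
simulate_distinct_preference <- function(p) {
  stopifnot(inherits(p, "diet_model_params"))
  b <- round(p$breadth_distribution[1L] +
               p$density * diff(as.numeric(p$breadth_distribution)))
  with_seed(p$seed, {
    m <- matrix(0L, p$n_individuals, p$n_resources)
    for (i in seq_len(p$n_individuals)) {
      m[i, sample.int(p$n_resources, b)] <- 1L
    }
    .finish_sim(.flip_noise(m, p$noise))
  })
}

#' Competitive-refuge diet model
#'
#' Individuals share the `core_size` top-ranked resources but differ in
#' their alternative resources: the remaining items are partitioned into
#' `n_groups` disjoint groups, each individual is assigned one group
#' (round-robin over a seeded shuffle, so every group is used), and consumes
#' a random fraction `density` of its group. At `density = 0` everyone eats
#' only the shared core (no individual specialization); as density grows the
#' alternative blocks fill in and the network becomes modular. Bit-flip
#' noise follows.
#'
#' @inheritParams simulate_shared_preference
#' @return An [incidence_matrix()].
#' @export
simulate_competitive_refuge <- function(p) {
  stopifnot(inherits(p, "diet_model_params"))
  n_alt <- p$n_resources - p$core_size
  if (p$n_groups > n_alt) stop("n_groups exceeds alternative resources")
  groups <- split(p$core_size + seq_len(n_alt),
                  rep_len(seq_len(p$n_groups), n_alt))
  with_seed(p$seed, {
    assign <- rep_len(seq_len(p$n_groups), p$n_individuals)[
      sample.int(p$n_individuals)]
    m <- matrix(0L, p$n_individuals, p$n_resources)
    if (p$core_size > 0L) m[, seq_len(p$core_size)] <- 1L
    for (i in seq_len(p$n_individuals)) {
      g <- groups[[assign[i]]]
      k <- round(p$density * length(g))
      if (k > 0L) m[i, resample(g, k)] <- 1L
    }
    .finish_sim(.flip_noise(m, p$noise))
  })
}

#' Simulate one incidence matrix under a named diet model
#'
#' @param p a [diet_model_params()]; dispatches on `p$model`.
#' @return An [incidence_matrix()].
#' @export
simulate_diet_model <- function(p) {
  switch(p$model,
         shared_preference = simulate_shared_preference(p),
         distinct_preference = simulate_distinct_preference(p),
         competitive_refuge = simulate_competitive_refuge(p))
}

#' Default environmental effect sizes for the synthetic study
#'
#' Seasonal contrasts emulating a strongly seasonal savanna: the warm-wet
#' season has more even arthropod order masses (higher exp(H')), more total
#' arthropod biomass, and more fruit; habitat variables load on two latent
#' factors (vegetation density and tree structure) whose means shift with
#' season.
#'
#' @param season_evenness reduction of the log-normal spread of order
#'   masses in the warm-wet season (0 = no seasonal evenness effect).
#' @param season_biomass log-scale increase of total arthropod mass in the
#'   warm-wet season.
#' @param fruit_ratio multiplicative increase of mean fruit count in the
#'   warm-wet season (>= 1).
#' @param habitat_shift shift of the vegetation-density factor mean in the
#'   warm-wet season, in factor SD units.
#' @return A validated list.
#' @export
env_effects <- function(season_evenness = 0.6, season_biomass = 0.5,
                        fruit_ratio = 4, habitat_shift = 1) {
  out <- list(season_evenness = season_evenness,
              season_biomass = season_biomass,
              fruit_ratio = fruit_ratio, habitat_shift = habitat_shift)
  if (!all(vapply(out, function(v) is.numeric(v) && is.finite(v),
                  logical(1))))
    stop("invalid effect sizes")
  if (fruit_ratio < 1) stop("fruit_ratio must be >= 1")
  if (season_evenness < 0 || season_evenness > 1)
    stop("season_evenness must lie in [0, 1]")
  out
}

# 8 structural variables built from 2 latent habitat factors. Rows are
# variables, columns the factor loadings used by simulate_environment().
.habitat_loadings <- function() {
  vars <- c("understory_obstruction", "herbaceous_obstruction",
            "canopy_openness", "canopy_connectivity", "litter_depth",
            "tree_dbh", "tree_distance", "tree_height")
  L <- rbind(c(0.8, 0.0), c(0.7, 0.1), c(-0.6, -0.2), c(0.6, 0.3),
             c(0.2, 0.5), c(0.0, 0.8), c(-0.1, 0.7), c(0.1, 0.8))
  dimnames(L) <- list(vars, c("vegetation", "trees"))
  L
}

#' Simulate environmental covariates for a multi-site seasonal study
#'
#' Per site and season: arthropod order dry masses (log-normal order
#' effects, more even and heavier in the warm-wet season), a fruit count
#' (negative binomial, larger warm-wet mean), and a table of habitat
#' stations whose 8 structural variables arise from a fixed 2-factor
#' loading matrix plus independent noise.
#'
#' @param sites character vector of site labels.
#' @param seasons season labels (default the two study seasons).
#' @param n_orders number of arthropod orders.
#' @param n_stations_range integer range of habitat stations per
#'   site x season.
#' @param effects an [env_effects()] list.
#' @param seed integer seed.
#' @return A list with `arthropods` (long data.frame: site, season, order,
#'   dry_mass_g), `fruits` (site, season, fruit_count) and `habitat`
#'   (stations x variables with site/season/station columns).
#' @export
simulate_environment <- function(sites = c("S1", "S2", "S3", "S4"),
                                 seasons = c("cool_dry", "warm_wet"),
                                 n_orders = 10L,
                                 n_stations_range = c(57L, 78L),
                                 effects = env_effects(), seed = 1L) {
  stopifnot(length(sites) >= 1L, length(seasons) == 2L)
  if (!is.list(effects)) stop("invalid effect sizes")
  orders <- sprintf("order%02d", seq_len(n_orders))
  L <- .habitat_loadings()
  with_seed(seed, {
    arth <- list(); fru <- list(); hab <- list()
    for (s in sites) {
      site_habitat <- stats::rnorm(2L, 0, 0.5)  # site-level factor means
      for (se in seasons) {
        wet <- se == "warm_wet"
        spread <- if (wet) 1 - effects$season_evenness else 1
        lmu <- if (wet) effects$season_biomass else 0
        mass <- stats::rlnorm(n_orders,
                              meanlog = lmu + stats::rnorm(n_orders, 0, spread),
                              sdlog = 0.3)
        arth[[paste(s, se)]] <- data.frame(site = s, season = se,
                                           order = orders,
                                           dry_mass_g = round(mass, 4))
        mu_fruit <- 120 * if (wet) effects$fruit_ratio else 1
        fru[[paste(s, se)]] <- data.frame(
          site = s, season = se,
          fruit_count = stats::rnbinom(1L, size = 5, mu = mu_fruit))
        n_st <- resample(seq(n_stations_range[1L], n_stations_range[2L]), 1L)
        f1 <- stats::rnorm(n_st, site_habitat[1L] +
                             if (wet) effects$habitat_shift else 0, 1)
        f2 <- stats::rnorm(n_st, site_habitat[2L], 1)
        X <- cbind(f1, f2) %*% t(L) +
          matrix(stats::rnorm(n_st * nrow(L), 0, 0.4), n_st)
        hab[[paste(s, se)]] <- data.frame(
          site = s, season = se,
          station = sprintf("st%03d", seq_len(n_st)),
          as.data.frame(X))
      }
    }
    list(arthropods = do.call(rbind, c(arth, make.row.names = FALSE)),
         fruits = do.call(rbind, c(fru, make.row.names = FALSE)),
         habitat = do.call(rbind, c(hab, make.row.names = FALSE)))
  })
}

#' Simulate a complete synthetic study
#'
#' A full multi-site, two-season study: one incidence matrix per
#' site x season drawn from a diet-specialization model whose density
#' control is tied to season (higher in the warm-wet season, when the
#' population is larger and resources richer), plus matched environmental
#' covariates. The returned manifest is sufficient to regenerate the study
#' bit-identically.
#'
#' @param sites site labels.
#' @param model diet model family for all site x season networks.
#' @param density_by_season named numeric: density per season.
#' @param n_individuals_range range of consumers per site x season.
#' @param n_resources number of food-item categories.
#' @param noise bit-flip probability.
#' @param effects an [env_effects()] list.
#' @param seed master seed (all child seeds derive from it).
#' @param manifest instead of the above, regenerate from a manifest.
#' @return A list of class `synthetic_study`: `networks` (named list of
#'   incidence matrices, names `site:season`), `environment` (see
#'   [simulate_environment()]) and `manifest`.
#' @export
simulate_study <- function(sites = c("S1", "S2", "S3", "S4"),
                           model = "competitive_refuge",
                           density_by_season = c(cool_dry = 0.3,
                                                 warm_wet = 0.9),
                           n_individuals_range = c(27L, 72L),
                           n_resources = 20L, noise = 0.02,
                           effects = env_effects(), seed = 1L,
                           manifest = NULL) {
  if (!is.null(manifest)) {
    return(do.call(simulate_study, manifest))
  }
  seasons <- c("cool_dry", "warm_wet")
  man <- list(sites = sites, model = model,
              density_by_season = density_by_season,
              n_individuals_range = as.integer(n_individuals_range),
              n_resources = as.integer(n_resources), noise = noise,
              effects = effects, seed = as.integer(seed))
  cells <- expand.grid(site = sites, season = seasons,
                       stringsAsFactors = FALSE)
  child <- derive_seeds(seed, nrow(cells) * 2L + 1L)
  networks <- list()
  for (k in seq_len(nrow(cells))) {
    n_ind <- with_seed(child[2L * k - 1L],
                       resample(seq(n_individuals_range[1L],
                                    n_individuals_range[2L]), 1L))
    p <- diet_model_params(model = model, n_individuals = n_ind,
                           n_resources = n_resources,
                           density = density_by_season[[cells$season[k]]],
                           noise = noise, seed = child[2L * k])
    networks[[paste(cells$site[k], cells$season[k], sep = ":")]] <-
      simulate_diet_model(p)
  }
  env <- simulate_environment(sites = sites, seasons = seasons,
                              effects = effects,
                              seed = child[length(child)])
  structure(list(networks = networks, environment = env, manifest = man),
            class = "synthetic_study")
}
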