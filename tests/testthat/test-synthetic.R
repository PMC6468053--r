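jaccard_overlap <- function(m) {
  m <- unclass(m)
  n <- nrow(m)
  pairs <- utils::combn(n, 2L)
  mean(vapply(seq_len(ncol(pairs)), function(k) {
    a <- m[pairs[1L, k], ] == 1L
    b <- m[pairs[2L, k], ] == 1L
    sum(a & b) / sum(a | b)
  }, numeric(1)))
}

test_that("parameter validation catches inconsistent diet models", {
  expect_error(diet_model_params(noise = 0.5), "noise")
  expect_error(diet_model_params(breadth_distribution = c(5L, 30L),
                                 n_resources = 20L), "breadth")
  expect_error(diet_model_params("competitive_refuge", n_resources = 6L,
                                 core_size = 4L, n_groups = 3L,
                                 breadth_distribution = c(1L, 6L)),
               "n_groups")
})

test_that("shared-preference diets are perfectly nested at zero noise", {
  # Diets are prefixes of one shared ranking, so every pair of rows is
  # subset-ordered. With all breadths distinct the packed matrix is a strict
  # staircase and T is exactly 0; tied breadths flatten the staircase into
  # steps that deviate slightly from the smooth isocline, so T stays near
  # (but not exactly) 0 -- far below the ~50 of an Erdos-Renyi matrix.
  for (seed in 1:12) {
    p <- diet_model_params("shared_preference", n_individuals = 15L,
                           n_resources = 12L,
                           breadth_distribution = c(1L, 12L),
                           noise = 0, seed = seed)
    m <- simulate_shared_preference(p)
    if (nrow(m) < 2L || ncol(m) < 2L) next
    # subset-ordering: perfect nestedness by construction
    rows <- unclass(m)[order(-rowSums(m)), , drop = FALSE]
    for (i in seq_len(nrow(rows) - 1L))
      expect_true(all(rows[i + 1L, ] <= rows[i, ] |
                        rows[i + 1L, ] == 0L))
    tt <- matrix_temperature(m, seed = 1)$temperature
    expect_lt(tt, 5)
  }
  # strict staircase through the generator's construction: T exactly 0
  expect_equal(matrix_temperature(staircase_matrix(8))$temperature, 0,
               tolerance = 1e-8)
  # equal breadths degenerate to identical rows (fill = 1 after pruning)
  p <- diet_model_params("shared_preference", n_individuals = 6L,
                         n_resources = 10L,
                         breadth_distribution = c(4L, 4L), noise = 0)
  m <- simulate_shared_preference(p)
  expect_equal(ncol(m), 4L)
  expect_true(all(m == 1L))
})

test_that("shared-preference networks are more nested than the ER null", {
  hits <- 0L
  n_seeds <- 12L
  for (seed in seq_len(n_seeds)) {
    p <- diet_model_params("shared_preference", n_individuals = 20L,
                           n_resources = 15L,
                           breadth_distribution = c(2L, 14L),
                           noise = 0, seed = 100L + seed)
    m <- simulate_shared_preference(p)
    obs <- matrix_temperature(m, seed = 1,
                              effort = list(restarts = 2L, iter = 1500L))
    nt <- monte_carlo_test(
      obs$nestedness,
      function(mat) {
        mat <- indivnet:::prune_incidence(mat)
        if (nrow(mat) < 2L || ncol(mat) < 2L) return(NA_real_)
        matrix_temperature(mat, seed = 1,
                           effort = list(restarts = 1L,
                                         iter = 1000L))$nestedness
      },
      m, n_sim = 30L, seed = 200L + seed)
    if (nt$ses > 2) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("distinct-preference overlap grows monotonically with density", {
  overlap_at <- function(density) {
    mean(vapply(1:25, function(seed) {
      p <- diet_model_params("distinct_preference", n_individuals = 20L,
                             n_resources = 15L, density = density,
                             breadth_distribution = c(1L, 15L),
                             noise = 0, seed = 300L + seed)
      jaccard_overlap(simulate_distinct_preference(p))
    }, numeric(1)))
  }
  o <- vapply(c(0, 0.5, 1), overlap_at, numeric(1))
  expect_lt(o[1], o[2])
  expect_lt(o[2], o[3])
  expect_equal(o[3], 1)   # full generalization: all-ones matrix

  # density 0 with b_min = 1: every individual eats exactly one resource
  p0 <- diet_model_params("distinct_preference", n_individuals = 10L,
                          n_resources = 8L, density = 0,
                          breadth_distribution = c(1L, 8L), noise = 0)
  expect_true(all(rowSums(simulate_distinct_preference(p0)) == 1L))
})

test_that("competitive-refuge builds core + group blocks as density grows", {
  p0 <- diet_model_params("competitive_refuge", n_individuals = 12L,
                          n_resources = 20L, density = 0, core_size = 5L,
                          n_groups = 3L, noise = 0)
  m0 <- simulate_competitive_refuge(p0)
  expect_equal(ncol(m0), 5L)          # only the shared core survives pruning
  expect_true(all(m0 == 1L))

  p1 <- diet_model_params("competitive_refuge", n_individuals = 12L,
                          n_resources = 20L, density = 1, core_size = 5L,
                          n_groups = 3L, noise = 0)
  m1 <- simulate_competitive_refuge(p1)
  expect_equal(ncol(m1), 20L)
  expect_true(all(m1[, 1:5] == 1L))
  # each alternative column is used by exactly one group of individuals:
  # individuals sharing an alternative column share their whole alternative set
  alt <- unclass(m1)[, -(1:5), drop = FALSE]
  patterns <- apply(alt, 1L, paste, collapse = "")
  expect_equal(length(unique(patterns)), 3L)
  # deterministic block structure: Q increases with density at zero noise
  q0 <- fast_greedy_modularity(m0)$modularity
  q1 <- fast_greedy_modularity(m1)$modularity
  expect_gt(q1, q0)
})

test_that("competitive-refuge modularity SES rises with forager density", {
  ses_at <- function(density, seed) {
    p <- diet_model_params("competitive_refuge", n_individuals = 30L,
                           n_resources = 20L, density = density,
                           core_size = 5L, n_groups = 3L, noise = 0.02,
                           seed = seed)
    m <- simulate_competitive_refuge(p)
    monte_carlo_test(fast_greedy_modularity(m)$modularity,
                     indivnet:::.null_modularity, m, n_sim = 100L,
                     seed = seed + 5000L)$ses
  }
  n_seeds <- 50L
  wins <- sum(vapply(seq_len(n_seeds), function(s)
    ses_at(1, 400L + s) > ses_at(0.1, 400L + s), logical(1)))
  # sign test: density = 1 should beat density = 0.1 nearly always
  expect_gte(wins / n_seeds, 0.9)
  expect_lt(stats::binom.test(wins, n_seeds, 0.5,
                              alternative = "greater")$p.value, 1e-6)
})

test_that("generators are bit-reproducible from their parameters", {
  for (model in c("shared_preference", "distinct_preference",
                  "competitive_refuge")) {
    p <- diet_model_params(model, n_individuals = 25L, n_resources = 18L,
                           density = 0.7, noise = 0.05, seed = 11L)
    expect_identical(unclass(simulate_diet_model(p)),
                     unclass(simulate_diet_model(p)))
  }
  s1 <- simulate_study(seed = 21L)
  s2 <- simulate_study(manifest = s1$manifest)
  expect_identical(lapply(s1$networks, unclass),
                   lapply(s2$networks, unclass))
  expect_identical(s1$environment, s2$environment)
})

test_that("synthetic environment shows the constructed seasonal contrasts", {
  div_gap <- vapply(1:30, function(seed) {
    env <- simulate_environment(sites = "A", seed = seed)
    d <- vapply(split(env$arthropods$dry_mass_g, env$arthropods$season),
                shannon_exp_diversity, numeric(1))
    d[["warm_wet"]] - d[["cool_dry"]]
  }, numeric(1))
  # sign test for higher warm-wet arthropod diversity
  expect_lt(binom.test(sum(div_gap > 0), length(div_gap),
                       alternative = "greater")$p.value, 0.01)

  # zero seasonal effects: gaps center on zero
  flat <- env_effects(season_evenness = 0, season_biomass = 0,
                      fruit_ratio = 1, habitat_shift = 0)
  gap0 <- vapply(1:30, function(seed) {
    env <- simulate_environment(sites = "A", effects = flat,
                                seed = 600L + seed)
    d <- vapply(split(env$arthropods$dry_mass_g, env$arthropods$season),
                shannon_exp_diversity, numeric(1))
    d[["warm_wet"]] - d[["cool_dry"]]
  }, numeric(1))
  expect_gt(binom.test(sum(gap0 > 0), length(gap0))$p.value, 0.01)

  env <- simulate_environment(seed = 5)
  expect_identical(env, simulate_environment(seed = 5))
  expect_error(simulate_environment(effects = env_effects(fruit_ratio = 0.5)),
               "fruit_ratio")
})

test_that("study networks respect the emulated study dimensions", {
  s <- simulate_study(seed = 31L)
  expect_length(s$networks, 8L)
  for (m in s$networks) {
    expect_lte(nrow(m), 72L)
    expect_lte(ncol(m), 20L)
    expect_true(all(rowSums(m) > 0) && all(colSums(m) > 0))
  }
})
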