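# Study orchestration: networks -> metrics -> null tests -> predictors ->
# regressions, from a config list or YAML file.

#' Trapping-effort arithmetic
#'
#' Total trap-nights of a live-trapping design: the product of the number of
#' grids, traps set per night, consecutive nights per session, sessions per
#' season and seasons.
#'
#' @param grids,traps_per_night,nights_per_session,sessions_per_season,seasons
#'   positive integers.
#' @return Total trap-nights.
#' @examples
#' sampling_effort(4, 160, 6, 3, 2)  # 23040
#' @export
sampling_effort <- function(grids, traps_per_night, nights_per_session,
                            sessions_per_season, seasons) {
  args <- c(grids, traps_per_night, nights_per_session,
            sessions_per_season, seasons)
  stopifnot(all(args >= 1), all(args == round(args)))
  prod(args)
}

# Nestedness of a (possibly degenerate) null draw; NA -> redraw upstream.
.null_nestedness <- function(effort, seed) {
  force(effort); force(seed)
  function(mat) {
    mat <- prune_incidence(mat)
    if (nrow(mat) < 2L || ncol(mat) < 2L) return(NA_real_)
    matrix_temperature(mat, seed = seed, effort = effort)$nestedness
  }
}

.null_modularity <- function(mat) {
  mat <- prune_incidence(mat)
  if (sum(mat) < 1L) return(NA_real_)
  fast_greedy_modularity(mat)$modularity
}

#' Run a full site-by-season network study
#'
#' Orchestrates the whole analysis over every site x season network:
#' descriptors (connectance, degree distribution, temperature/nestedness,
#' modularity), Monte Carlo null tests and SES for nestedness and
#' modularity, environmental predictors (exp(H') arthropod diversity, total
#' arthropod dry mass, log fruit count, habitat PC1/PC2), and simple linear
#' regressions of both metrics on each predictor. Connectance is reported
#' but, being strongly (negatively) collinear with modularity, excluded from
#' the regression table unless `regress_connectance` is set in the config.
#'
#' @param config a list, or path to a YAML file, with sections:
#'   \describe{
#'     \item{simulate}{arguments passed to [simulate_study()] (synthetic
#'       studies); otherwise}
#'     \item{data}{paths: `records` (TSV diet records), `arthropods`,
#'       `fruits`, `habitat` (CSV tables as written by
#'       [write_study_inputs()]).}
#'     \item{null}{`mode` (default `"bernoulli_half"`), `n_sim` (default
#'       1000), `seed` (default 1).}
#'     \item{metrics}{`effort` (default `"fast"`).}
#'     \item{report}{optional output directory; writes `report.csv`,
#'       `regressions.csv`, `report.json` and `run.log`.}
#'   }
#' @return A list of class `study_report`: `rows` (one data.frame row per
#'   site x season), `regressions`, `collinearity`, `pca`, `manifest`,
#'   `log`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  null_cfg <- utils::modifyList(list(mode = "bernoulli_half", n_sim = 1000L,
                                     seed = 1L), config$null %||% list())
  effort <- (config$metrics %||% list())$effort %||% "fast"
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  if (!is.null(config$simulate)) {
    study <- do.call(simulate_study, config$simulate)
    networks <- study$networks
    env <- study$environment
    manifest <- c(study$manifest, null = list(null_cfg),
                  effort = list(effort))
    say("simulated study: %d networks, seed %d", length(networks),
        study$manifest$seed)
  } else if (!is.null(config$data)) {
    d <- config$data
    records <- dedupe_one_per_season(read_diet_records(d$records))
    counts <- count_samples(records)
    networks <- list()
    for (k in seq_len(nrow(counts))) {
      key <- paste(counts$site[k], counts$season[k], sep = ":")
      networks[[key]] <- build_incidence(records, counts$site[k],
                                         as.character(counts$season[k]))
    }
    env <- list(arthropods = utils::read.csv(d$arthropods),
                fruits = utils::read.csv(d$fruits),
                habitat = utils::read.csv(d$habitat))
    manifest <- list(data = d, null = null_cfg, effort = effort)
    say("loaded study: %d networks from %s", length(networks), d$records)
  } else stop("config needs a `simulate` or `data` section")

  seeds <- derive_seeds(null_cfg$seed, 3L * length(networks))
  rows <- list()
  for (k in seq_along(networks)) {
    key <- strsplit(names(networks)[k], ":", fixed = TRUE)[[1L]]
    m <- networks[[k]]
    if (nrow(m) < 2L || ncol(m) < 2L) {
      say("%s: insufficient data (%dx%d), flagged", names(networks)[k],
          nrow(m), ncol(m))
      rows[[k]] <- data.frame(site = key[1L], season = key[2L],
                              insufficient_data = TRUE)
      next
    }
    met <- network_metrics(m, seed = seeds[3L * k - 2L], effort = effort)
    nt_nest <- monte_carlo_test(
      met$nestedness, .null_nestedness(effort, seeds[3L * k - 2L]), m,
      n_sim = null_cfg$n_sim, mode = null_cfg$mode,
      seed = seeds[3L * k - 1L], metric_name = "nestedness")
    nt_mod <- monte_carlo_test(
      met$modularity, .null_modularity, m,
      n_sim = null_cfg$n_sim, mode = null_cfg$mode,
      seed = seeds[3L * k], metric_name = "modularity")
    say("%s: %d ind x %d items, L=%d, C=%.3f, T=%.2f, Q=%.3f, redraws=%d/%d",
        names(networks)[k], met$n_individuals, met$n_items, met$links,
        met$connectance, met$temperature, met$modularity,
        nt_nest$n_redraws, nt_mod$n_redraws)
    rows[[k]] <- data.frame(
      site = key[1L], season = key[2L], insufficient_data = FALSE,
      n_individuals = met$n_individuals, n_items = met$n_items,
      links = met$links, connectance = met$connectance,
      chao1_coverage = met$chao1$coverage,
      temperature = met$temperature, nestedness = met$nestedness,
      modularity = met$modularity,
      nestedness_p = nt_nest$p_value, nestedness_ses = nt_nest$ses,
      modularity_p = nt_mod$p_value, modularity_ses = nt_mod$ses)
  }
  rows <- do.call(rbind, c(rows, make.row.names = FALSE))

  # environmental predictors per site x season
  arth <- env$arthropods
  akey <- paste(arth$site, arth$season)
  div <- vapply(split(arth$dry_mass_g, akey), shannon_exp_diversity,
                numeric(1))
  tot <- vapply(split(arth$dry_mass_g, akey), sum, numeric(1))
  pred <- data.frame(site = sub(" .*", "", names(div)),
                     season = sub(".* ", "", names(div)),
                     arthropod_diversity = unname(div),
                     arthropod_total_mass = unname(tot))
  pred <- merge(pred, env$fruits, by = c("site", "season"))
  pred$log_fruit <- fruit_predictor(pred$fruit_count)
  pca <- habitat_pca(env$habitat)
  pred <- merge(pred, pca$predictors, by = c("site", "season"))
  say("habitat PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
      100 * pca$variance_fraction[1L], 100 * pca$variance_fraction[2L])

  tab <- merge(rows[!rows$insufficient_data, , drop = FALSE], pred,
               by = c("site", "season"))
  predictors <- c("arthropod_diversity", "arthropod_total_mass", "log_fruit",
                  "pc1_score", "pc2_score")
  responses <- c("nestedness", "modularity")
  if (isTRUE(config$regress_connectance)) responses <- c(responses,
                                                         "connectance")
  regressions <- do.call(rbind, lapply(responses, function(y)
    do.call(rbind, lapply(predictors, function(x) {
      as.data.frame(fit_metric_regression(tab[[x]], tab[[y]],
                                          predictor = x, response = y))
    }))))
  coll <- collinearity_screen(pred[c("arthropod_diversity",
                                     "arthropod_total_mass", "log_fruit")])

  report <- structure(list(rows = merge(rows, pred, by = c("site", "season"),
                                        all.x = TRUE),
                           regressions = regressions, collinearity = coll,
                           pca = pca[c("loadings", "variance_fraction")],
                           manifest = manifest, log = log_lines),
                      class = "study_report")
  out_dir <- (config$report %||% list())$dir
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d site x season networks\n", nrow(x$rows)))
  print(x$rows, digits = 3)
  cat("\nregressions (significant only):\n")
  sig <- x$regressions[x$regressions$significant, , drop = FALSE]
  if (nrow(sig)) print(sig, digits = 3) else cat("  none at p < 0.05\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.csv` (site x season rows), `regressions.csv`,
#' `report.json` (rows, regressions, collinearity, PCA summary, manifest)
#' and `run.log`.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rows, file.path(dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$regressions, file.path(dir, "regressions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(rows = report$rows, regressions = report$regressions,
         collinearity = report$collinearity,
         pca_variance_fraction = report$pca$variance_fraction,
         manifest = report$manifest),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Write synthetic study inputs as the package's on-disk formats
#'
#' Serializes a [simulate_study()] result to the delimited-text formats
#' consumed by the `data` section of [run_study()]: per-network incidence
#' CSVs plus `arthropods.csv`, `fruits.csv`, `habitat.csv`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(study$networks)) {
    f <- file.path(dir, paste0("matrix_", gsub(":", "_", nm), ".csv"))
    write_incidence(study$networks[[nm]], f)
    paths[[nm]] <- f
  }
  for (tb in c("arthropods", "fruits", "habitat")) {
    f <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(study$environment[[tb]], f, row.names = FALSE)
    paths[[tb]] <- f
  }
  invisible(paths)
}
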