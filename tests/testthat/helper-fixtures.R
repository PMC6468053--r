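# Fixtures are generated in code; nothing binary is stored.

# A small labeled 0/1 matrix with no empty rows/columns.
random_incidence <- function(n, m, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- matrix(rbinom(n * m, 1L, p), n, m)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) break
  }
  dimnames(x) <- list(paste0("i", seq_len(n)), paste0("r", seq_len(m)))
  incidence_matrix(x)
}

# Perfect staircase: row i consumes items 1..i.
staircase_matrix <- function(n) {
  x <- (lower.tri(matrix(0, n, n), diag = TRUE)) + 0L
  dimnames(x) <- list(paste0("i", seq_len(n)), paste0("r", seq_len(n)))
  incidence_matrix(x)
}

# Long-format diet records emulating the study design. `per_site_season` is
# a data.frame (site, season, n_samples) giving the retained samples per
# cell; `shared_by_site` (named int) individuals per site are recaptured
# across seasons (same id in both seasons), so
#   total individuals = total samples - sum(shared_by_site).
# `n_dup_within` adds later same-season recapture events per site that
# dedupe_one_per_season() must discard.
make_records_fixture <- function(per_site_season, shared_by_site = NULL,
                                 n_dup_within = 0L, items_per_sample = 3L,
                                 n_items = 20L, seed = 1L) {
  set.seed(seed)
  items <- sprintf("item%02d", seq_len(n_items))
  rows <- list()
  add <- function(id, site, season, date, its) {
    rows[[length(rows) + 1L]] <<- data.frame(
      individual_id = id, site = site, season = season,
      capture_date = as.character(date), item = its)
  }
  for (s in unique(per_site_season$site)) {
    sub <- per_site_season[per_site_season$site == s, ]
    counts <- stats::setNames(sub$n_samples, sub$season)
    shared <- min(shared_by_site[s] %||% 0L, min(counts))
    made <- 0L
    for (season in names(counts)) {
      base_date <- if (season == "cool_dry") as.Date("2009-06-01")
                   else as.Date("2009-11-01")
      for (k in seq_len(counts[[season]])) {
        id <- if (k <= shared) sprintf("%s_shared%03d", s, k)
              else sprintf("%s_ind%03d", s, made + k)
        add(id, s, season, base_date + k, sample(items, items_per_sample))
      }
      made <- made + counts[[season]] - shared
    }
    # later cool-dry recaptures of an existing cool-dry individual
    for (d in seq_len(n_dup_within)) {
      add(sprintf("%s_ind%03d", s, shared + 1L), s, "cool_dry",
          as.Date("2009-08-20") + d, sample(items, items_per_sample))
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

write_records_tsv <- function(records, path = tempfile(fileext = ".tsv")) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# The study's per-site/per-season retained-sample design (374 samples).
study_sample_design <- function() {
  data.frame(
    site = rep(c("FAL", "EEJBB1", "EEJBB2", "EEJBB3"), each = 2L),
    season = rep(c("cool_dry", "warm_wet"), 4L),
    n_samples = c(44L, 72L, 36L, 52L, 48L, 58L, 37L, 27L))
}
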