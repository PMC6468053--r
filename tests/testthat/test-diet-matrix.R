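test_that("diet records are parsed, validated and season-aliased", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tsite\tseason\tcapture_date\titem",
               "A\tFAL\tcool_dry\t2009-06-03\tColeoptera",
               "A\tFAL\tcool_dry\t2009-06-03\tfruit_pulp",
               "B\tFAL\twet\t2009-11-10\tColeoptera",
               "B\tFAL\twarm_wet\t2009-11-10\tAraneae",
               "C\tEEJBB1\tdry\t\tOrthoptera",
               "C\tEEJBB1\tcool_dry\t\tseeds",
               "D\tEEJBB1\twarm_wet\t2010-01-20\tbird_remains"),
             tsv)
  rec <- read_diet_records(tsv)
  expect_equal(nrow(rec), 7L)                       # header excluded
  expect_s3_class(rec$season, "factor")
  expect_equal(as.character(rec$season[3]), "warm_wet")  # "wet" alias
  expect_equal(as.character(rec$season[5]), "cool_dry")  # "dry" alias
  expect_true(is.na(rec$capture_date[5]))

  empty <- tempfile(fileext = ".tsv")
  writeLines("individual_id\tsite\tseason\titem", empty)
  expect_error(read_diet_records(empty), "no records")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tsite\tseason\titem",
               "A\tFAL\tmonsoon\tseeds"), bad)
  expect_error(read_diet_records(bad), "unknown season")

  nocol <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tsite\titem", "A\tFAL\tseeds"), nocol)
  expect_error(read_diet_records(nocol), "season")
})

test_that("dedupe keeps the earliest capture per individual-season", {
  rec <- data.frame(
    individual_id = c("A", "A", "A", "A", "B"),
    site = "FAL",
    season = factor(c("warm_wet", "warm_wet", "warm_wet", "cool_dry",
                      "warm_wet"),
                    levels = c("cool_dry", "warm_wet")),
    capture_date = as.Date(c("2009-11-02", "2009-11-02", "2009-12-05",
                             "2009-06-01", "2009-11-09")),
    item = c("x", "y", "z", "x", "y"))
  out <- dedupe_one_per_season(rec)
  a_wet <- out[out$individual_id == "A" & out$season == "warm_wet", ]
  expect_setequal(a_wet$item, c("x", "y"))          # d1's items, not d2's
  expect_equal(sum(out$individual_id == "A" & out$season == "cool_dry"), 1L)
  # idempotence
  expect_identical(dedupe_one_per_season(out), out)
  # union rule pools all events
  uni <- dedupe_one_per_season(rec, rule = "union")
  expect_setequal(uni$item[uni$individual_id == "A" &
                             uni$season == "warm_wet"], c("x", "y", "z"))
})

test_that("the study design's per-cell counts sum to 374 retained samples", {
  design <- study_sample_design()
  shared <- c(FAL = 15L, EEJBB1 = 14L, EEJBB2 = 14L, EEJBB3 = 12L)  # 55
  rec <- make_records_fixture(design, shared_by_site = shared,
                              n_dup_within = 5L, seed = 7)
  parsed <- read_diet_records(write_records_tsv(rec))
  dd <- dedupe_one_per_season(parsed)
  counts <- count_samples(dd)
  merged <- merge(design, counts, by = c("site", "season"),
                  suffixes = c("_design", "_observed"))
  expect_equal(merged$n_samples_observed, merged$n_samples_design)
  expect_equal(sum(counts$n_samples), 374L)
  expect_equal(length(unique(dd$individual_id)), 319L)
})

test_that("incidence construction is binary, pruned and occurrence-based", {
  rec <- data.frame(
    individual_id = c("A", "A", "B", "A"),
    site = "FAL",
    season = factor("warm_wet", levels = c("cool_dry", "warm_wet")),
    capture_date = as.Date("2009-11-01"),
    item = c("x", "y", "y", "x"))   # duplicate (A, x)
  m <- build_incidence(rec, "FAL", "warm_wet")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(sum(m), 3L)                           # occurrence, not count
  expect_true(all(m %in% 0:1))
  expect_true(all(rowSums(m) > 0) && all(colSums(m) > 0))
  expect_error(build_incidence(rec, "FAL", "cool_dry"), "cool_dry")

  one <- rec[3, ]
  m1 <- build_incidence(one, "FAL", "warm_wet")
  expect_equal(unname(unclass(m1)), matrix(1L, 1, 1))
})

test_that("incidence CSV round-trip is the identity and validates cells", {
  m <- random_incidence(5, 4, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_incidence(m, f)
  expect_identical(unclass(read_incidence(f)), unclass(m))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("individual,x,y", "A,1,2", "B,0,1"), bad)
  expect_error(read_incidence(bad), "non-binary cell \"2\"")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("individual,x,x", "A,1,0", "B,0,1"), dup)
  expect_error(read_incidence(dup), "duplicated column")

  expect_error(incidence_matrix(matrix(c(0, 1, 1, 0.5), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("x", "y")))),
               "non-binary")
})
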