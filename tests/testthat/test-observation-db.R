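test_that("ingest validates rows, logs drops, and back-fills isotope fields", {
  obs <- ingest_observations(fixture_path("observations_synthetic.csv"))
  meta <- obs_meta(obs)
  expect_equal(meta$n_input, 16)
  expect_equal(meta$n_kept, 13)
  expect_setequal(meta$dropped$reason,
                  c("compound not one of DIC/CO2/CH4",
                    "year outside 1950-present", "non-positive f14c"))
  # conservation: every input row is accounted for
  expect_equal(meta$n_kept + meta$n_dropped, meta$n_input)
  # the Delta14C-only row gets F14C back-filled by the decay-corrected
  # inverse conversion
  taiw <- obs[obs$site_id == "TAIW-3", ]
  expect_equal(taiw$f14c, delta14c_to_f14c(-112.4, 2016), tolerance = 1e-12)
  # F14C-only rows get Delta14C and the conventional age derived
  amz <- obs[obs$site_id == "AMZ-01" & obs$compound == "DIC", ]
  expect_equal(amz$delta14c, f14c_to_delta14c(0.914, 2005), tolerance = 1e-12)
  expect_equal(round(amz$age_14c), 722)
})

test_that("ingest fails on unreadable files and missing mandatory columns", {
  expect_error(ingest_observations("no-such-file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site_id = "A", year = 2000), path, row.names = FALSE)
  expect_error(ingest_observations(path), "mandatory")
})

test_that("column mapping renames file headers to the canonical schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(Site = "A", yr = 2005, gas = "DIC", Fm = 0.9),
            path, row.names = FALSE)
  obs <- ingest_observations(path, column_map = c(
    Site = "site_id", yr = "year", gas = "compound", Fm = "f14c"))
  expect_equal(nrow(obs), 1)
  expect_equal(obs$f14c, 0.9)
})

test_that("conflicting date and year drops the row with a log entry", {
  obs <- obs_set(obs_row(year = 2010, date = "2011-05-01"),
                 obs_row(year = 2010, date = "2010-05-01"))
  expect_equal(nrow(obs), 1)
  expect_equal(obs_meta(obs)$dropped$reason, "date/year conflict")
})

test_that("repeat-sample collapsing averages groups of five or more", {
  mk <- function(f, cmpd = "DIC") {
    obs_row(site_id = "R", year = 2015, compound = cmpd, f14c = f,
            sigma_f14c = 0.005)
  }
  obs <- do.call(obs_set, c(lapply(c(0.90, 0.92, 0.94, 0.96, 0.98), mk),
                            list(obs_row(site_id = "Q", year = 2015,
                                         f14c = 0.7))))
  out <- collapse_repeats(obs)
  expect_equal(nrow(out), 2)
  r <- out[out$site_id == "R", ]
  expect_equal(r$f14c, 0.94)
  # age and Delta14C recomputed from the mean
  expect_equal(round(r$age_14c), round(-8033 * log(0.94)))
  # uncertainty: max(sd/sqrt(n), quadrature mean of analytical sigmas)
  expect_equal(r$sigma_f14c,
               max(sd(c(0.90, 0.92, 0.94, 0.96, 0.98)) / sqrt(5),
                   sqrt(5 * 0.005^2) / 5))
  expect_equal(obs_meta(out)$rows_removed_by_collapse, 4)
})

test_that("exactly four repeats pass through unchanged", {
  obs <- do.call(obs_set, lapply(c(0.90, 0.92, 0.94, 0.96), function(f) {
    obs_row(site_id = "R", year = 2015, f14c = f)
  }))
  out <- collapse_repeats(obs)
  expect_equal(nrow(out), 4)
  expect_equal(sort(out$f14c), c(0.90, 0.92, 0.94, 0.96))
})

test_that("collapsing is per compound, conservative and idempotent", {
  rows <- c(
    lapply(seq(0.90, 0.98, by = 0.02), function(f) {
      obs_row(site_id = "R", year = 2015, compound = "DIC", f14c = f)
    }),
    lapply(seq(0.80, 0.88, by = 0.02), function(f) {
      obs_row(site_id = "R", year = 2015, compound = "CO2", f14c = f)
    })
  )
  obs <- do.call(obs_set, rows)
  out <- collapse_repeats(obs)
  # one collapsed record per compound
  expect_equal(nrow(out), 2)
  expect_setequal(out$compound, c("DIC", "CO2"))
  expect_equal(sort(out$f14c), c(0.84, 0.94))
  # row count never increases; conservation holds; idempotent
  expect_lte(nrow(out), nrow(obs))
  m <- obs_meta(out)
  expect_equal(nrow(out) + m$rows_removed_by_collapse, nrow(obs))
  again <- collapse_repeats(out)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
})

test_that("size classification matches the published bin edges", {
  cl <- classify_size(c(10, 10.1, 99, 100, 101, 250000, 5))
  expect_equal(as.character(cl$binary),
               c("small", "large", "large", "large", "large", "large",
                 "small"))
  expect_equal(as.character(cl$exponential),
               c("0-10", "100", "100", "100", "1,000", "1,000,000", "0-10"))
  expect_error(classify_size(0), "classification")
  expect_error(classify_size(-5), "classification")
})

test_that("size classes partition the positive axis and stay consistent", {
  set.seed(5)
  area <- 10^runif(2000, -2, 7)
  cl <- classify_size(area)
  expect_false(anyNA(cl$exponential))
  # binary 'small' if and only if exponential class is the 0-10 bin
  expect_identical(cl$binary == "small", cl$exponential == "0-10")
})

test_that("lithology mapping is total and exact on the HydroATLAS codes", {
  expected <- c(
    MT = "metamorphic",
    VB = "igneous", PB = "igneous", VA = "igneous", PA = "igneous",
    VI = "igneous", PY = "igneous", PI = "igneous",
    SU = "sedimentary", SS = "sedimentary", SM = "sedimentary",
    SC = "sedimentary",
    ND = "excluded", IG = "excluded"
  )
  got <- simplify_lithology(names(expected))
  expect_equal(as.character(got), unname(expected))
  # surjective onto the three target classes given the full code list
  expect_setequal(setdiff(unique(as.character(got)), "excluded"),
                  c("sedimentary", "igneous", "metamorphic"))
  expect_warning(out <- simplify_lithology("XX"), "unknown")
  expect_equal(as.character(out), "excluded")
})

test_that("biome mapping reproduces the eight-class simplification", {
  expected <- c(
    "1" = "tropical broadleaf and conifer forests",
    "2" = "tropical broadleaf and conifer forests",
    "3" = "tropical broadleaf and conifer forests",
    "4" = "temperate and Mediterranean broadleaf mixed forest",
    "5" = "temperate conifer and boreal forests",
    "6" = "temperate conifer and boreal forests",
    "7" = "tropical grasslands and shrublands",
    "8" = "temperate grasslands and shrublands",
    "9" = "tropical grasslands and shrublands",
    "10" = "montane grass and shrubs",
    "11" = "tundra",
    "12" = "temperate and Mediterranean broadleaf mixed forest",
    "13" = "deserts",
    "15" = "deserts"
  )
  got <- simplify_biome(as.integer(names(expected)))
  expect_equal(as.character(got), unname(expected))
  # surjective onto all eight classes
  expect_length(unique(as.character(got)), 8)
  expect_warning(out <- simplify_biome(14), "unknown")
  expect_equal(as.character(out), "unclassified")
})

test_that("summaries report n, mean, sd, median and the modern fraction", {
  one <- obs_set(obs_row(f14c = 0.9))
  s1 <- summarize_observations(one)
  expect_equal(s1$mean, 0.9)
  expect_equal(s1$median, 0.9)
  expect_equal(s1$sd, 0)
  expect_true(s1$n1_flag)

  two <- obs_set(obs_row(site_id = "A", f14c = 0.8),
                 obs_row(site_id = "B", f14c = 1.2))
  s2 <- summarize_observations(two)
  expect_equal(s2$mean, 1.0)
  expect_equal(s2$frac_gt_1, 0.5)

  # grouping by compound keeps groups separate and deterministic
  mix <- obs_set(obs_row(site_id = "A", compound = "DIC", f14c = 0.9),
                 obs_row(site_id = "B", compound = "CH4", f14c = 0.7))
  sc <- summarize_observations(mix, group_by = "compound")
  expect_equal(sc$group, sort(sc$group))
})

test_that("summary statistics converge on a large synthetic sample", {
  set.seed(9)
  n <- 5000
  f <- rnorm(n, 0.92, 0.18)
  f <- f[f > 0]
  d <- data.frame(site_id = sprintf("S%d", seq_along(f)), year = 2010,
                  compound = "DIC", f14c = f)
  s <- summarize_observations(harmonize_observations(d))
  expect_equal(s$mean, 0.92, tolerance = 0.01 / 0.92)
  expect_equal(s$sd, 0.18, tolerance = 0.01 / 0.18)
})

test_that("normalized summaries divide by the collection-year atmosphere", {
  r <- flat_record(2000:2020, 1.25)
  obs <- obs_set(obs_row(site_id = "A", year = 2005, f14c = 1.0),
                 obs_row(site_id = "B", year = 2010, f14c = 1.25))
  s <- summarize_observations(obs, normalized = TRUE, record = r)
  expect_equal(s$mean, mean(c(0.8, 1.0)))
  expect_error(summarize_observations(obs, normalized = TRUE), "record")
})

test_that("paired DIC-CO2 offsets match the worked example", {
  obs <- ingest_observations(fixture_path("observations_synthetic.csv"))
  po <- paired_offset(obs)
  expect_equal(po$n_pairs, 2)
  expect_equal(po$pairs$abs_offset, c(0.02, 0.02), tolerance = 1e-12)
  moor <- po$pairs[po$pairs$site_id == "MOOR-1", ]
  expect_equal(round(moor$age_offset_yr), 162)

  # three constructed pairs: mean and max are plain arithmetic
  obs3 <- obs_set(
    obs_row(site_id = "P1", date = "2010-01-01", compound = "DIC", f14c = 1.00),
    obs_row(site_id = "P1", date = "2010-01-01", compound = "CO2", f14c = 0.99),
    obs_row(site_id = "P2", date = "2010-01-01", compound = "DIC", f14c = 1.00),
    obs_row(site_id = "P2", date = "2010-01-01", compound = "CO2", f14c = 0.98),
    obs_row(site_id = "P3", date = "2010-01-01", compound = "DIC", f14c = 1.00),
    obs_row(site_id = "P3", date = "2010-01-01", compound = "CO2", f14c = 0.97)
  )
  po3 <- paired_offset(obs3)
  expect_equal(po3$mean_offset, 0.02, tolerance = 1e-12)
  expect_equal(po3$max_offset, 0.03, tolerance = 1e-12)

  # identical pair and the no-pair marker
  same <- obs_set(
    obs_row(site_id = "Z", date = "2010-01-01", compound = "DIC", f14c = 0.9),
    obs_row(site_id = "Z", date = "2010-01-01", compound = "CO2", f14c = 0.9))
  expect_equal(paired_offset(same)$mean_offset, 0)
  none <- obs_set(obs_row(site_id = "A", compound = "DIC", f14c = 0.9))
  expect_equal(paired_offset(none)$n_pairs, 0)
})

test_that("group tests wrap the standard nonparametric machinery", {
  set.seed(13)
  value <- c(rnorm(40, 0.85, 0.05), rnorm(40, 0.95, 0.05))
  group <- rep(c("sedimentary", "metamorphic"), each = 40)
  gt <- group_tests(value, group)
  expect_lt(gt$kruskal$p_value, 0.01)
  expect_equal(nrow(gt$pairwise), 1)
  expect_lt(gt$pairwise$p_value, 0.01)
})
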