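# Ingest/validate/harmonize the river 14C observation database: repeat-sample
# collapsing, catchment-size, lithology and biome classification, grouped
# summaries and the paired DIC-CO2 offset check.

.compounds <- c("DIC", "CO2", "CH4")

.obs_columns <- c(
  "site_id", "year", "date", "compound", "f14c", "sigma_f14c", "delta14c",
  "age_14c", "latitude", "longitude", "coord_flag", "uncertainty_flag",
  "catchment_area_km2", "area_is_estimated", "water_type", "ph",
  "temperature_c", "lithology_raw", "biome_raw"
)

.new_observation_set <- function(df, meta) {
  rownames(df) <- NULL
  structure(df, meta = meta, class = c("observation_set", "data.frame"))
}

#' Ingest metadata of an observation set
#'
#' Returns the provenance record attached at ingest (or by
#' [collapse_repeats()]): source file, input/kept/dropped row counts, the
#' per-row drop log, and collapse bookkeeping. The conservation identity
#' `n_input = n_kept + n_dropped (+ rows_removed_by_collapse)` always holds.
#'
#' @param obs An `observation_set`.
#' @return A list of provenance fields.
#' @export
obs_meta <- function(obs) {
  attr(obs, "meta")
}

#' Ingest a river radiocarbon observation CSV
#'
#' Reads a comma-separated observation table (UTF-8, header required, empty
#' fields as missing), validates every row against the database invariants,
#' and back-fills derived isotope fields: rows reporting only Delta14C get
#' F14C recomputed from it (and vice versa), and the conventional age is
#' recomputed from F14C. Rows that fail validation are dropped and logged
#' with a reason, never silently discarded.
#'
#' Mandatory columns (after applying `column_map`): `site_id`, `year`,
#' `compound`, and at least one of `f14c` / `delta14c`. Recognised optional
#' columns: `date` (ISO-8601), `sigma_f14c`, `latitude`, `longitude`,
#' `coord_flag` (1 exact, 2 general, 3 map-estimated), `uncertainty_flag`
#' (1 reported, 2 facility-average), `catchment_area_km2`,
#' `area_is_estimated`, `water_type`, `ph`, `temperature_c`,
#' `lithology_raw`, `biome_raw`.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping file column
#'   names to canonical names, e.g. `c(Fm = "f14c", Site = "site_id")`.
#' @return An `observation_set`: a data frame with one row per valid
#'   observation and provenance metadata retrievable via [obs_meta()].
#' @export
ingest_observations <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("ingest error: file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(column_map)) {
    hit <- match(names(column_map), names(raw))
    names(raw)[hit[!is.na(hit)]] <- column_map[!is.na(hit)]
  }
  mandatory <- c("site_id", "year", "compound")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0 ||
      !any(c("f14c", "delta14c") %in% names(raw))) {
    stop("ingest error: missing mandatory column(s): ",
         paste(c(missing_cols,
                 if (!any(c("f14c", "delta14c") %in% names(raw)))
                   "f14c|delta14c"), collapse = ", "))
  }
  harmonize_observations(raw, source = path)
}

#' Harmonize an in-memory observation data frame
#'
#' The validation/back-fill core of [ingest_observations()], usable directly
#' on a data frame (e.g. one produced by [simulate_observations()]).
#'
#' @param raw A data frame with at least `site_id`, `year`, `compound` and
#'   one of `f14c` / `delta14c`.
#' @param source Provenance label stored in the metadata.
#' @return An `observation_set`.
#' @export
harmonize_observations <- function(raw, source = "in-memory") {
  n_input <- nrow(raw)
  for (col in .obs_columns) if (is.null(raw[[col]])) raw[[col]] <- NA
  raw <- raw[, .obs_columns]
  this_year <- as.integer(format(Sys.Date(), "%Y"))

  num <- function(x) suppressWarnings(as.numeric(x))
  raw$year <- num(raw$year)
  for (col in c("f14c", "sigma_f14c", "delta14c", "age_14c", "latitude",
                "longitude", "catchment_area_km2", "ph", "temperature_c")) {
    raw[[col]] <- num(raw[[col]])
  }

  reasons <- character(n_input)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond & reasons == ""] <<- why
  }

  flag(is.na(raw$site_id) | raw$site_id == "", "missing site_id")
  flag(is.na(raw$year), "missing/invalid year")
  flag(!is.na(raw$year) & (raw$year < 1950 | raw$year > this_year),
       "year outside 1950-present")
  flag(is.na(raw$compound) | !(raw$compound %in% .compounds),
       "compound not one of DIC/CO2/CH4")
  # year derived from date must agree when both present
  if (any(!is.na(raw$date))) {
    date_year <- suppressWarnings(
      as.integer(format(as.Date(raw$date, format = "%Y-%m-%d"), "%Y")))
    flag(!is.na(raw$date) & is.na(date_year), "unparseable date")
    flag(!is.na(date_year) & !is.na(raw$year) & date_year != raw$year,
         "date/year conflict")
  }
  flag(is.na(raw$f14c) & is.na(raw$delta14c), "no f14c or delta14c")
  flag(!is.na(raw$f14c) & raw$f14c <= 0, "non-positive f14c")
  flag(!is.na(raw$delta14c) & raw$delta14c <= -1000, "delta14c <= -1000")
  flag(!is.na(raw$sigma_f14c) & raw$sigma_f14c < 0, "negative sigma_f14c")
  flag(!is.na(raw$latitude) & abs(raw$latitude) > 90, "latitude out of range")
  flag(!is.na(raw$longitude) & abs(raw$longitude) > 180,
       "longitude out of range")
  flag(!is.na(raw$coord_flag) & !(raw$coord_flag %in% 1:3),
       "coord_flag not in 1-3")
  flag(!is.na(raw$uncertainty_flag) & !(raw$uncertainty_flag %in% 1:2),
       "uncertainty_flag not in 1-2")
  flag(!is.na(raw$catchment_area_km2) & raw$catchment_area_km2 <= 0,
       "non-positive catchment area")

  keep <- reasons == ""
  dropped <- data.frame(row = which(!keep), reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  d <- raw[keep, , drop = FALSE]

  # back-fill derived isotope fields (decay-corrected inter-conversion)
  fill_f <- is.na(d$f14c) & !is.na(d$delta14c)
  d$f14c[fill_f] <- delta14c_to_f14c(d$delta14c[fill_f], d$year[fill_f])
  fill_d <- is.na(d$delta14c)
  d$delta14c[fill_d] <- suppressWarnings(
    f14c_to_delta14c(d$f14c[fill_d], d$year[fill_d]))
  age <- f14c_to_age(d$f14c)
  d$age_14c <- as.numeric(age)
  d$modern <- attr(age, "modern")

  .new_observation_set(d, meta = list(
    source = source,
    n_input = n_input,
    n_kept = nrow(d),
    n_dropped = nrow(dropped),
    dropped = dropped
  ))
}

#' Collapse locations repeat-sampled more than four times in a year
#'
#' Repeat sampling (time series, method development) over-weights a handful
#' of locations. For each (site, calendar year, compound) group observed
#' more than four times, the group is replaced by a single record whose F14C
#' is the arithmetic mean of the replicates; groups of four or fewer pass
#' through unchanged. The compound is part of the grouping key because DIC,
#' CO2 and CH4 are analysed separately throughout.
#'
#' The collapsed record's uncertainty is the larger of the standard error of
#' the replicate F14C values (sd/sqrt(n)) and the quadrature-propagated mean
#' of the replicate analytical sigmas (sqrt(sum(sigma^2))/n) - a
#' conservative convention. Delta14C and the conventional age are
#' recomputed from the mean F14C.
#'
#' @param obs An `observation_set`.
#' @return An `observation_set` with metadata fields `groups_collapsed` and
#'   `rows_removed_by_collapse` added; `n_input = n_kept +
#'   rows_removed_by_collapse` relative to the input set.
#' @export
collapse_repeats <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  d <- as.data.frame(obs)
  if (nrow(d) == 0) return(obs)
  key <- interaction(d$site_id, floor(d$year), d$compound, drop = TRUE)
  counts <- table(key)
  big <- names(counts)[counts > 4]
  if (length(big) == 0) {
    meta <- obs_meta(obs)
    meta$groups_collapsed <- 0L
    meta$rows_removed_by_collapse <- 0L
    return(.new_observation_set(d, meta))
  }
  keep_rows <- d[!(key %in% big), , drop = FALSE]
  collapsed <- lapply(big, function(g) {
    grp <- d[key == g, , drop = FALSE]
    rec <- grp[1, , drop = FALSE]
    n <- nrow(grp)
    m <- mean(grp$f14c)
    se_spread <- stats::sd(grp$f14c) / sqrt(n)
    sig <- grp$sigma_f14c
    se_analytical <- if (all(is.na(sig))) NA_real_
                     else sqrt(sum(sig^2, na.rm = TRUE)) / n
    rec$f14c <- m
    rec$sigma_f14c <- max(se_spread, se_analytical, na.rm = TRUE)
    rec$date <- NA_character_
    rec$delta14c <- suppressWarnings(f14c_to_delta14c(m, rec$year))
    a <- f14c_to_age(m)
    rec$age_14c <- as.numeric(a)
    rec$modern <- attr(a, "modern")
    rec
  })
  out <- rbind(keep_rows, do.call(rbind, collapsed))
  out <- out[order(out$site_id, out$year, out$compound), , drop = FALSE]
  meta <- obs_meta(obs)
  meta$groups_collapsed <- length(big)
  meta$rows_removed_by_collapse <- nrow(d) - nrow(out)
  .new_observation_set(out, meta)
}

#' Classify catchment area into size classes
#'
#' Two parallel classifications of catchment area: a binary split at
#' 10 km2 ("small" <= 10, "large" > 10; 10 km2 is the lower basin-size
#' limit of HydroATLAS), and an exponential decade classification labelled
#' by the upper bound of each bin: "0-10", "100" (10 to 100), "1,000"
#' (100 to 1,000), "10,000", "100,000" and "1,000,000" (> 100,000). Decade
#' bins are left-open, right-closed; every positive area falls in exactly
#' one bin.
#'
#' @param area_km2 Numeric vector of catchment areas in km2 (> 0).
#' @return A data frame with factor columns `binary` and `exponential`.
#' @examples
#' classify_size(c(10, 10.1, 250000))
#' @export
classify_size <- function(area_km2) {
  stopifnot(is.numeric(area_km2))
  if (any(!is.na(area_km2) & area_km2 <= 0)) {
    stop("classification error: catchment area must be > 0")
  }
  breaks <- c(0, 10, 100, 1000, 10000, 100000, Inf)
  labels <- c("0-10", "100", "1,000", "10,000", "100,000", "1,000,000")
  expo <- cut(area_km2, breaks = breaks, labels = labels, right = TRUE)
  binary <- factor(ifelse(area_km2 <= 10, "small", "large"),
                   levels = c("small", "large"))
  data.frame(binary = binary, exponential = expo)
}

.lithology_map <- c(
  MT = "metamorphic",
  VB = "igneous", PB = "igneous", VA = "igneous", PA = "igneous",
  VI = "igneous", PY = "igneous", PI = "igneous",
  SU = "sedimentary", SS = "sedimentary", SM = "sedimentary",
  SC = "sedimentary",
  ND = "excluded", IG = "excluded"
)

#' Simplify HydroATLAS lithology codes to three classes
#'
#' Maps the HydroATLAS lithology classes to `sedimentary` (SU, SS, SM, SC),
#' `igneous` (VB, PB, VA, PA, VI, PY, PI) or `metamorphic` (MT). No-data
#' (ND) and ice/glacier (IG) codes - the latter covering the Antarctic
#' samples - are `excluded` from lithology analyses; unknown codes are
#' excluded with a warning.
#'
#' @param code Character vector of HydroATLAS lithology codes.
#' @return Factor with levels sedimentary, igneous, metamorphic, excluded.
#' @examples
#' simplify_lithology(c("SC", "PY", "IG"))
#' @export
simplify_lithology <- function(code) {
  code <- toupper(as.character(code))
  out <- unname(.lithology_map[code])
  unknown <- !is.na(code) & is.na(out)
  if (any(unknown)) {
    warning("unknown lithology code(s) excluded: ",
            paste(unique(code[unknown]), collapse = ", "))
    out[unknown] <- "excluded"
  }
  factor(out, levels = c("sedimentary", "igneous", "metamorphic", "excluded"))
}

.biome_map <- c(
  "1" = "tropical broadleaf and conifer forests",
  "2" = "tropical broadleaf and conifer forests",
  "3" = "tropical broadleaf and conifer forests",
  "4" = "temperate and Mediterranean broadleaf mixed forest",
  "12" = "temperate and Mediterranean broadleaf mixed forest",
  "5" = "temperate conifer and boreal forests",
  "6" = "temperate conifer and boreal forests",
  "7" = "tropical grasslands and shrublands",
  "9" = "tropical grasslands and shrublands",
  "8" = "temperate grasslands and shrublands",
  "10" = "montane grass and shrubs",
  "11" = "tundra",
  "13" = "deserts",
  "15" = "deserts"
)

#' Simplify HydroATLAS biome codes to eight classes
#'
#' Collapses the 14 HydroATLAS biomes (1-13, plus 15 = polar desert, used
#' for Antarctic samples) into eight classes: tropical broadleaf and
#' conifer forests (1-3), temperate and Mediterranean broadleaf mixed
#' forest (4, 12), temperate conifer and boreal forests (5, 6), tropical
#' grasslands and shrublands (7, 9), temperate grasslands and shrublands
#' (8), montane grass and shrubs (10), tundra (11) and deserts (13, 15).
#' Unknown codes map to `unclassified` with a warning.
#'
#' @param code Integer (or character) vector of HydroATLAS biome codes.
#' @return Factor with the eight class labels plus `unclassified`.
#' @examples
#' simplify_biome(c(9, 11, 15))
#' @export
simplify_biome <- function(code) {
  code <- as.character(as.integer(as.numeric(code)))
  out <- unname(.biome_map[code])
  unknown <- !is.na(code) & is.na(out)
  if (any(unknown)) {
    warning("unknown biome code(s) unclassified: ",
            paste(unique(code[unknown]), collapse = ", "))
    out[unknown] <- "unclassified"
  }
  factor(out, levels = c(sort(unique(unname(.biome_map))), "unclassified"))
}

#' Grouped summaries of an observation set
#'
#' Per-group sample size, mean, standard deviation (1 sigma, n-1
#' denominator), median of F14C - or of bomb-curve-normalized F14C_atm when
#' `normalized = TRUE` - and the fraction of values above 1.0. Groups are
#' ordered deterministically by label. For lithology summaries the
#' `excluded` class (no-data and ice/glacier reaches, i.e. Antarctica) is
#' omitted.
#'
#' @param obs An `observation_set`.
#' @param group_by One of `"none"`, `"compound"`, `"lithology"`, `"biome"`,
#'   `"size_class"`.
#' @param normalized Summarize F14C_atm instead of raw F14C.
#' @param record An `atm_record`; required when `normalized = TRUE`.
#' @return A data frame with columns `group`, `n`, `mean`, `sd`, `median`,
#'   `frac_gt_1`, `n1_flag` (TRUE where sd is reported as 0 because n = 1).
#' @export
summarize_observations <- function(obs,
                                   group_by = c("none", "compound",
                                                "lithology", "biome",
                                                "size_class"),
                                   normalized = FALSE, record = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  group_by <- match.arg(group_by)
  d <- as.data.frame(obs)
  if (nrow(d) == 0) {
    return(data.frame(group = character(), n = integer(), mean = numeric(),
                      sd = numeric(), median = numeric(),
                      frac_gt_1 = numeric(), n1_flag = logical()))
  }
  value <- if (normalized) {
    if (is.null(record)) stop("record is required when normalized = TRUE")
    d$f14c / atm_value_at(record, d$year)
  } else d$f14c

  g <- switch(group_by,
    none = factor(rep("all", nrow(d))),
    compound = factor(d$compound, levels = .compounds),
    lithology = simplify_lithology(d$lithology_raw),
    biome = simplify_biome(d$biome_raw),
    size_class = classify_size(d$catchment_area_km2)$binary
  )
  if (group_by == "lithology") {
    keep <- !is.na(g) & g != "excluded"
    g <- droplevels(g[keep]); value <- value[keep]
  } else {
    keep <- !is.na(g)
    g <- droplevels(g[keep]); value <- value[keep]
  }
  labs <- levels(g)
  rows <- lapply(labs, function(lab) {
    v <- value[g == lab]
    if (length(v) == 0) return(NULL)
    data.frame(
      group = lab, n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0,
      median = stats::median(v),
      frac_gt_1 = mean(v > 1.0),
      n1_flag = length(v) == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$group), , drop = FALSE]
}

#' Paired DIC-CO2 offset check
#'
#' Finds site-dates where both DIC and CO2 were measured and summarizes the
#' absolute F14C offset between the two compounds - the empirical check
#' that DIC is a usable surrogate for emitted CO2. Multiple measurements of
#' one compound at a site-date are averaged before pairing. Each pair also
#' carries its age-equivalent offset in conventional 14C years.
#'
#' @param obs An `observation_set`.
#' @return A list with `pairs` (data frame: site_id, date, f14c_dic,
#'   f14c_co2, abs_offset, age_offset_yr), `n_pairs`, `mean_offset`,
#'   `max_offset`. With no pairs, `n_pairs = 0` and the summaries are `NA`.
#' @export
paired_offset <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  d <- as.data.frame(obs)
  d <- d[d$compound %in% c("DIC", "CO2") & !is.na(d$date), , drop = FALSE]
  if (nrow(d) > 0) {
    agg <- stats::aggregate(f14c ~ site_id + date + compound, data = d,
                            FUN = mean)
    wide <- stats::reshape(agg, idvar = c("site_id", "date"),
                           timevar = "compound", direction = "wide")
    names(wide) <- sub("^f14c\\.", "f14c_", tolower(names(wide)))
    have_both <- !is.na(wide$f14c_dic) & !is.na(wide$f14c_co2)
    wide <- wide[have_both, , drop = FALSE]
  } else {
    wide <- data.frame(site_id = character(), date = character(),
                       f14c_dic = numeric(), f14c_co2 = numeric())
  }
  if (nrow(wide) == 0) {
    return(list(pairs = wide, n_pairs = 0L,
                mean_offset = NA_real_, max_offset = NA_real_))
  }
  wide$abs_offset <- abs(wide$f14c_dic - wide$f14c_co2)
  wide$age_offset_yr <- age_equivalent_offset(wide$f14c_dic, wide$f14c_co2)
  rownames(wide) <- NULL
  list(pairs = wide, n_pairs = nrow(wide),
       mean_offset = mean(wide$abs_offset),
       max_offset = max(wide$abs_offset))
}

#' Nonparametric group comparison of F14C values
#'
#' Thin convenience wrappers around [stats::kruskal.test()] and pairwise
#' [stats::wilcox.test()] for comparing F14C (or F14C_atm) across the
#' classification groups. Returns statistics and p-values only.
#'
#' @param value Numeric vector of F14C (or normalized) values.
#' @param group Factor of group labels.
#' @return A list with `kruskal` (statistic, df, p_value) and `pairwise`
#'   (data frame of group pairs and Wilcoxon p-values, unadjusted).
#' @export
group_tests <- function(value, group) {
  group <- droplevels(as.factor(group))
  kw <- stats::kruskal.test(value, group)
  labs <- levels(group)
  pw <- if (length(labs) >= 2) {
    combs <- utils::combn(labs, 2)
    data.frame(
      group_a = combs[1, ], group_b = combs[2, ],
      p_value = apply(combs, 2, function(p) {
        stats::wilcox.test(value[group == p[1]],
                           value[group == p[2]])$p.value
      }),
      stringsAsFactors = FALSE
    )
  } else data.frame(group_a = character(), group_b = character(),
                    p_value = numeric())
  list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value),
    pairwise = pw
  )
}
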