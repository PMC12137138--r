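# Shared fixtures built in code.

# flat atmospheric record, handy when the normalization should be the
# identity up to a constant
flat_record <- function(years = 2000:2010, level = 1.25) {
  atmospheric_record(years, rep(level, length(years)))
}

# minimal in-memory observation set
obs_set <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  harmonize_observations(d, source = "test")
}

obs_row <- function(site_id = "S1", year = 2010, compound = "DIC",
                    f14c = 0.95, date = NA_character_,
                    sigma_f14c = NA_real_, ...) {
  c(list(site_id = site_id, year = year, compound = compound, f14c = f14c,
         date = date, sigma_f14c = sigma_f14c), list(...))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "riverc14", mustWork = TRUE)
}
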