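#' Generate covariate and population context tables
#'
#' Produces smooth maternal-education trajectories (average years of
#' schooling among women of reproductive age) per country-year, and female
#' population counts per (country, year, five-year age group) for ages
#' 20--44. Education rises linearly from a country-specific base; population
#' grows geometrically from a country-specific base with mild age tapering.
#' A bookkeeping ledger with the global population total is attached so
#' downstream aggregation can be checked against it.
#'
#' @param hierarchy a `hierarchy`
#' @param seed integer seed
#' @param years calendar years to cover
#' @param edu_base_range range of baseline (first-year) schooling, years
#' @param edu_slope_range range of total schooling gain over the window
#' @param pop_base_range range of per-age-group female population at the
#'   first year
#' @param pop_growth annual population growth rate
#' @return a `context_tables` list with elements `education`, `population`
#'   and a `ledger` of generator bookkeeping totals
#' @export
generate_context <- function(hierarchy, seed = 1L, years = 1990:2010,
                             edu_base_range = c(4, 10),
                             edu_slope_range = c(0.5, 2.5),
                             pop_base_range = c(5e4, 5e5),
                             pop_growth = 0.01) {
  validate_hierarchy(hierarchy)
  withr_seed(seed)
  countries <- hierarchy$country_id
  n <- length(countries)
  base <- runif(n, edu_base_range[1], edu_base_range[2])
  gain <- runif(n, edu_slope_range[1], edu_slope_range[2])
  span <- diff(range(years))
  frac <- if (span == 0) rep(0, length(years)) else (years - min(years)) / span
  education <- data.frame(
    country_id = rep(countries, each = length(years)),
    year = rep(years, times = n),
    years_schooling = rep(base, each = length(years)) +
      rep(gain, each = length(years)) * rep(frac, times = n)
  )

  pop_base <- runif(n, pop_base_range[1], pop_base_range[2])
  # younger groups slightly larger, as in growing populations
  age_taper <- c(1.05, 1.0, 0.95, 0.9, 0.85)
  grid <- expand.grid(country_id = countries, year = years,
                      age_group = age_group_labels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ci <- match(grid$country_id, countries)
  ai <- match(grid$age_group, age_group_labels())
  grid$women <- pop_base[ci] * age_taper[ai] *
    (1 + pop_growth)^(grid$year - min(years))
  grid$women <- round(grid$women)

  structure(list(education = education, population = grid,
                 ledger = list(total_women = sum(grid$women),
                               n_countries = n, years = range(years))),
            class = "context_tables")
}

#' @export
print.context_tables <- function(x, ...) {
  cat(sprintf("<context_tables> %d countries, years %d-%d, %.1fM women total\n",
              x$ledger$n_countries, x$ledger$years[1], x$ledger$years[2],
              x$ledger$total_women / 1e6))
  invisible(x)
}

#' Write context tables as CSV
#' @param context a `context_tables`
#' @param dir output directory (created if needed)
#' @export
write_context_csv <- function(context, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(context$education, file.path(dir, "education.csv"), row.names = FALSE)
  write.csv(context$population, file.path(dir, "population.csv"), row.names = FALSE)
  invisible(dir)
}
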