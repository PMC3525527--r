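#' Infertility as a percent of all women: product of draws
#'
#' The all-women percent is child-seeking prevalence multiplied by the
#' proportion exposed to the risk of pregnancy, combined draw by draw so
#' the product's uncertainty propagates exactly.
#'
#' @param prev_draws,exposure_draws matched draw vectors
#' @return draw vector of products
#' @export
all_women_percent <- function(prev_draws, exposure_draws) {
  if (length(prev_draws) != length(exposure_draws))
    stop("draw vectors must have equal length")
  prev_draws * exposure_draws
}

#' Population-weighted aggregate of cell draws
#'
#' Aggregation happens within each draw: the result's draw j is the
#' weighted mean of the cells' draws j. Used for all-age, regional and
#' global estimates, weighting (country, age) cells by the female
#' population of the age group.
#'
#' @param draws matrix of draws (rows) by cells (columns), or a list of
#'   equal-length draw vectors
#' @param weights nonnegative cell weights, not all zero
#' @return draw vector of weighted means
#' @export
aggregate_weighted <- function(draws, weights) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (length(weights) != ncol(draws))
    stop("one weight per cell required")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  as.numeric(draws %*% weights) / sum(weights)
}

#' Summarize draws into a central estimate and 95% uncertainty interval
#'
#' The central estimate is the mean of the draws; the interval runs from
#' the 2.5th to the 97.5th percentile, computed with linear interpolation
#' between order statistics (R's default type-7 convention).
#'
#' @param draws numeric draw vector (>= 2 draws)
#' @param quantity optional label
#' @param scope optional scope label (country/region/global, year, ...)
#' @return an `aggregate_estimate` (one-row data.frame: `quantity`,
#'   `scope`, `mean`, `lower_95`, `upper_95`)
#' @export
summarize_draws <- function(draws, quantity = NA_character_,
                            scope = NA_character_) {
  if (length(draws) < 2) stop("need at least two draws")
  q <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  structure(data.frame(quantity = quantity, scope = scope,
                       mean = mean(draws), lower_95 = q[1], upper_95 = q[2],
                       stringsAsFactors = FALSE),
            class = c("aggregate_estimate", "data.frame"))
}

#' 1990 to 2010 change with its posterior probability of increase
#'
#' Subtracts the 1990 draw from the 2010 draw, draw by draw, and summarizes
#' the differences. `pp_increase` is the share of draws in which the
#' difference is strictly positive (ties count as non-increase); a trend is
#' flagged statistically significant when the pp of the observed direction
#' exceeds 0.975.
#'
#' @param draws_1990,draws_2010 matched draw vectors
#' @param quantity,scope optional labels
#' @return an `aggregate_estimate` with `pp_increase` and `significant`
#' @export
compute_trend <- function(draws_1990, draws_2010,
                          quantity = NA_character_, scope = NA_character_) {
  if (length(draws_1990) != length(draws_2010))
    stop("draw vectors must have equal length")
  diff <- draws_2010 - draws_1990
  out <- summarize_draws(diff, quantity, scope)
  out$pp_increase <- mean(diff > 0)
  pp_dir <- max(out$pp_increase, mean(diff < 0))
  out$significant <- pp_dir > 0.975
  out
}

#' Couples affected by infertility
#'
#' Per draw, sums percent-affected times female population over
#' (country, age) cells. Populations are women aged 20--44 from the
#' context tables; cells of countries flagged `china_rule` must be removed
#' by the caller for secondary infertility (see
#' [couples_affected_from_posterior()], which does this).
#'
#' @param all_women_draws draws-by-cells matrix of all-women proportions
#'   (not percent), or a list of draw vectors
#' @param population female population per cell, matching the columns
#' @param quantity,scope optional labels
#' @return an `aggregate_estimate` in numbers of couples, with the full
#'   draw vector attached as attribute `draws`
#' @export
couples_affected <- function(all_women_draws, population,
                             quantity = NA_character_, scope = NA_character_) {
  if (is.list(all_women_draws)) all_women_draws <- do.call(cbind, all_women_draws)
  if (is.null(dim(all_women_draws)))
    all_women_draws <- matrix(all_women_draws, ncol = 1)
  if (length(population) != ncol(all_women_draws))
    stop("one population per cell required")
  if (anyNA(population)) stop("missing population cells")
  if (any(population < 0)) stop("populations must be nonnegative")
  counts <- as.numeric(all_women_draws %*% population)
  out <- summarize_draws(counts, quantity, scope)
  attr(out, "draws") <- counts
  out
}

#' Combine primary and secondary couples counts draw by draw
#'
#' @param primary_draws,secondary_draws matched draw vectors of couples
#'   counts
#' @param quantity,scope optional labels
#' @return an `aggregate_estimate` of the total, with draws attached
#' @export
combine_couples <- function(primary_draws, secondary_draws,
                            quantity = "couples_total",
                            scope = NA_character_) {
  if (length(primary_draws) != length(secondary_draws))
    stop("draw vectors must have equal length")
  total <- primary_draws + secondary_draws
  out <- summarize_draws(total, quantity, scope)
  attr(out, "draws") <- total
  out
}

# Draw matrix for a set of cells (country x age) at one year.
cell_draw_matrix <- function(posterior, indicator, countries, year) {
  cells <- expand.grid(country_id = countries, age_group = age_group_labels(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(cells$country_id, year, cells$age_group),
               paste(posterior$cells$country_id, posterior$cells$year,
                     posterior$cells$age_group))
  if (anyNA(idx)) stop("cells outside the fitted window")
  list(cells = cells, draws = posterior$fits[[indicator]]$pred[, idx, drop = FALSE])
}

cell_population <- function(context, cells, year) {
  pop <- context$population
  w <- pop$women[match(paste(cells$country_id, year, cells$age_group),
                       paste(pop$country_id, pop$year, pop$age_group))]
  if (anyNA(w)) stop("missing population cells")
  w
}

#' Population-weighted prevalence aggregate from a posterior
#'
#' Convenience wrapper: all-age prevalence of an indicator over a set of
#' countries at one year, weighting each (country, age) cell by its female
#' population. For secondary infertility, countries flagged `china_rule`
#' are excluded.
#'
#' @param posterior a `posterior`
#' @param indicator indicator name
#' @param context a `context_tables` (for populations)
#' @param year calendar year
#' @param countries country ids (default: all in the hierarchy)
#' @return draw vector of the aggregate prevalence
#' @export
aggregate_prevalence_draws <- function(posterior, indicator, context, year,
                                       countries = NULL) {
  h <- posterior$spec$hierarchy
  countries <- countries %||% h$country_id
  if (indicator %in% c("secondary_prev", "secondary_exposure"))
    countries <- setdiff(countries, h$country_id[h$china_rule])
  cm <- cell_draw_matrix(posterior, indicator, countries, year)
  w <- cell_population(context, cm$cells, year)
  aggregate_weighted(cm$draws, w)
}

#' Couples affected, computed from a posterior
#'
#' All-women percent per cell (prevalence times exposure, draw by draw)
#' multiplied by the cell's female population and summed over cells.
#' Secondary infertility excludes `china_rule` countries.
#'
#' @param posterior a `posterior` with both the prevalence and exposure
#'   indicator fitted
#' @param type `"primary"` or `"secondary"`
#' @param context a `context_tables`
#' @param year calendar year
#' @param countries country ids (default: all)
#' @return an `aggregate_estimate` with draws attached
#' @export
couples_affected_from_posterior <- function(posterior, type = c("primary", "secondary"),
                                            context, year, countries = NULL) {
  type <- match.arg(type)
  h <- posterior$spec$hierarchy
  countries <- countries %||% h$country_id
  if (type == "secondary")
    countries <- setdiff(countries, h$country_id[h$china_rule])
  prev_ind <- paste0(type, "_prev"); exp_ind <- paste0(type, "_exposure")
  cm_p <- cell_draw_matrix(posterior, prev_ind, countries, year)
  cm_e <- cell_draw_matrix(posterior, exp_ind, countries, year)
  aw <- cm_p$draws * cm_e$draws
  pop <- cell_population(context, cm_p$cells, year)
  couples_affected(aw, pop, quantity = paste0("couples_", type),
                   scope = as.character(year))
}

#' Tabulate regional and global estimates across years
#'
#' Produces a long table mirroring the region/global-by-indicator-by-year
#' layout of the study's summary datasets.
#'
#' @param posterior a `posterior`
#' @param context a `context_tables`
#' @param years years to tabulate
#' @param indicators indicators to tabulate
#' @return data.frame with columns `quantity`, `scope`, `year`, `mean`,
#'   `lower_95`, `upper_95`
#' @export
report_levels <- function(posterior, context, years = c(1990, 2010),
                          indicators = names(posterior$fits)) {
  h <- posterior$spec$hierarchy
  scopes <- c(list(global = h$country_id),
              split(h$country_id, h$region_id))
  rows <- list()
  for (ind in indicators) for (yr in years) for (sc in names(scopes)) {
    dr <- aggregate_prevalence_draws(posterior, ind, context, yr,
                                     countries = scopes[[sc]])
    s <- summarize_draws(dr, quantity = ind, scope = sc)
    s$year <- yr
    rows[[length(rows) + 1L]] <- s
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out
}
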