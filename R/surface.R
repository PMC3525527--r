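#' Generative settings for a true prevalence surface
#'
#' The synthetic world mirrors the structure of the estimation model:
#' on the logit scale each indicator has a global intercept, nested
#' region/subregion/country intercept deviations, a global linear time
#' trend (per decade, centered at 2000) with region-level slope deviations,
#' a maternal-education covariate effect, and fixed age-group offsets.
#' The High-Income region gets its own age-offset set for exposure to
#' primary infertility.
#'
#' Default levels are chosen to resemble the field's reported magnitudes:
#' primary infertility around 2% (elevated at ages 20--24), secondary
#' around 5% at 20--24 rising steeply with age, roughly two-thirds of
#' women exposed to primary risk and a quarter to secondary risk.
#'
#' @param ... overrides of any default element
#' @return a list of generative settings
#' @export
surface_params <- function(...) {
  p <- list(
    years = 1990:2010,
    # logit-scale intercepts at age [20,25), year 2000, education at center
    # NB: the survey generator's composition implies exposure-to-secondary
    # can never fall below the secondary-denominator share (a secondary
    # fertile or infertile union is exposed by definition), about
    # prev_denominator_share * exposure-to-primary; defaults keep a margin.
    intercept = c(primary_prev = logit(0.025), secondary_prev = logit(0.05),
                  primary_exposure = logit(0.65), secondary_exposure = logit(0.42)),
    # additive logit age offsets, first age group is the reference
    age_offsets = list(
      primary_prev = c(0, -0.35, -0.5, -0.55, -0.55),
      secondary_prev = c(0, 0.5, 1.0, 1.4, 1.8),
      primary_exposure = c(0, 0.1, 0.1, 0.0, -0.2),
      secondary_exposure = c(0, 0.15, 0.15, 0.0, -0.15)
    ),
    # High-Income deviation from the age_offsets of primary_exposure
    hi_age_offsets = c(0, 0.3, 0.5, 0.4, 0.2),
    sd_region = 0.25, sd_subregion = 0.15, sd_country = 0.15,
    # per-decade logit slopes
    slope_global = c(primary_prev = -0.10, secondary_prev = 0.05,
                     primary_exposure = -0.10, secondary_exposure = -0.15),
    sd_region_slope = 0.05,
    # effect of one year of schooling (education centered at edu_center)
    edu_coef = c(primary_prev = -0.03, secondary_prev = -0.03,
                 primary_exposure = -0.02, secondary_exposure = -0.02),
    edu_center = 7
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Generate a true prevalence/exposure surface with known ground truth
#'
#' Draws nested random effects and builds, for each of the four indicators,
#' a probability for every (country, year, age-group) cell by applying the
#' inverse-logit link to the linear predictor described in
#' [surface_params()]. The surface is the ground truth that synthetic
#' surveys are sampled from and that recovery tests compare against.
#'
#' @param hierarchy a `hierarchy` from [generate_hierarchy()]
#' @param params generative settings, see [surface_params()]
#' @param seed integer seed; the surface is exactly reproducible from
#'   (params, seed)
#' @param context optional `context_tables` from [generate_context()]; if
#'   missing one is generated from `seed`
#' @return a `true_surface` object: data.frame with columns `indicator`,
#'   `country_id`, `year`, `age_group`, `true_value`, with the generating
#'   effects, params, hierarchy and context attached as attributes
#' @export
generate_true_surface <- function(hierarchy, params = surface_params(),
                                  seed = 1L, context = NULL) {
  validate_hierarchy(hierarchy)
  sds <- c(params$sd_region, params$sd_subregion, params$sd_country,
           params$sd_region_slope)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("variance (sd) parameters must be nonnegative")
  if (is.null(context)) context <- generate_context(hierarchy, seed = seed)
  withr_seed(seed)

  regions <- unique(hierarchy$region_id)
  subregions <- unique(hierarchy$subregion_id)
  countries <- hierarchy$country_id
  eff <- list(
    region = setNames(rnorm(length(regions), 0, params$sd_region), regions),
    subregion = setNames(rnorm(length(subregions), 0, params$sd_subregion), subregions),
    country = setNames(rnorm(length(countries), 0, params$sd_country), countries),
    region_slope = setNames(rnorm(length(regions), 0, params$sd_region_slope), regions)
  )

  edu <- context$education
  edu_key <- setNames(edu$years_schooling, paste(edu$country_id, edu$year))

  grid <- expand.grid(indicator = INDICATORS, country_id = countries,
                      year = params$years, age_group = age_group_labels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  h_idx <- match(grid$country_id, hierarchy$country_id)
  reg <- hierarchy$region_id[h_idx]
  sub <- hierarchy$subregion_id[h_idx]
  hi <- hierarchy$is_high_income[h_idx]
  t_dec <- (grid$year - 2000) / 10
  a_idx <- match(grid$age_group, age_group_labels())
  age_off <- mapply(function(ind, a) params$age_offsets[[ind]][a],
                    grid$indicator, a_idx)
  hi_off <- ifelse(grid$indicator == "primary_exposure" & hi,
                   params$hi_age_offsets[a_idx], 0)
  edu_x <- edu_key[paste(grid$country_id, grid$year)] - params$edu_center
  lp <- params$intercept[grid$indicator] +
    eff$region[reg] + eff$subregion[sub] + eff$country[grid$country_id] +
    (params$slope_global[grid$indicator] + eff$region_slope[reg]) * t_dec +
    params$edu_coef[grid$indicator] * edu_x +
    age_off + hi_off
  grid$true_value <- inv_logit(unname(lp))

  structure(grid, class = c("true_surface", "data.frame"),
            params = params, effects = eff,
            hierarchy = hierarchy, context = context, seed = seed)
}

#' @export
print.true_surface <- function(x, ...) {
  cat(sprintf("<true_surface> %d countries x %d years x %d age groups x 4 indicators\n",
              length(unique(x$country_id)), length(unique(x$year)),
              length(unique(x$age_group))))
  invisible(x)
}

# Lookup of true values for one (country, year) across indicators/ages.
surface_cell <- function(surface, country_id, year, indicator) {
  sel <- surface$country_id == country_id & surface$year == year &
    surface$indicator == indicator
  v <- surface$true_value[sel]
  names(v) <- surface$age_group[sel]
  v[age_group_labels()]
}

#' Write generative parameters as YAML
#' @param surface a `true_surface`
#' @param path file path
#' @export
write_surface_params_yaml <- function(surface, path) {
  p <- attr(surface, "params")
  p$age_offsets <- lapply(p$age_offsets, as.numeric)
  yaml::write_yaml(lapply(p, function(x) if (is.numeric(x)) as.list(x) else x),
                   path)
  invisible(path)
}
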