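#' Specify the hierarchical space-time-age model
#'
#' On the logit scale, each indicator's expected prevalence for a
#' (country, year, age-group) cell is
#'
#'   global intercept + region + subregion + country intercept deviations
#'   + (global slope + region slope deviation) * (year - 2000)/10
#'   + education coefficient * (years of schooling - center)
#'   + age-group offset (+ High-Income age offset, exposure-to-primary only)
#'
#' Intercept deviations are nested: country ~ N(0, tau_c^2) around its
#' subregion, subregion ~ N(0, tau_s^2) around its region, region ~
#' N(0, tau_r^2) around the global level; region slopes are nested in the
#' global slope. Observations are normal around the cell's logit with known
#' sampling-plus-correction variance plus an estimated extra variance, with
#' separate components for national and subnational sources so national
#' data weigh more.
#'
#' @param hierarchy a `hierarchy`
#' @param education data.frame `country_id, year, years_schooling` (e.g.
#'   `generate_context(...)$education`)
#' @param years prediction window (calendar years)
#' @param edu_center schooling level at which the covariate is centered
#' @param priors list: `fixed_sd` (normal sd of fixed effects, logit scale),
#'   `sd_scale`, `sd_scale_slope` (half-normal scales of the level and
#'   slope sd components), `sd_scale_extra_national`,
#'   `sd_scale_extra_subnational` (half-normal scales of the extra
#'   observation sds; larger for subnational sources)
#' @return a `model_spec`
#' @export
model_spec <- function(hierarchy, education, years = 1990:2010,
                       edu_center = 7,
                       priors = list()) {
  validate_hierarchy(hierarchy)
  defaults <- list(fixed_sd = 2, sd_scale = 1, sd_scale_slope = 1,
                   sd_scale_extra_national = 0.5,
                   sd_scale_extra_subnational = 1)
  defaults[names(priors)] <- priors
  structure(list(hierarchy = hierarchy, education = education,
                 years = years, edu_center = edu_center, priors = defaults),
            class = "model_spec")
}

edu_lookup <- function(spec, country_id, year) {
  edu <- spec$education
  # surveys may predate the covariate window: clamp to the nearest year
  yr <- pmin(pmax(year, min(edu$year)), max(edu$year))
  key <- paste(edu$country_id, edu$year)
  vals <- setNames(edu$years_schooling, key)
  x <- vals[paste(country_id, yr)]
  if (anyNA(x)) stop("education covariate missing for some country-years")
  unname(x) - spec$edu_center
}

#' Assemble model inputs from (corrected) observations
#'
#' Transforms observation values to the analysis (logit) scale and
#' attaches each observation's total variance: the delta-method sampling
#' variance 1/(n * p * (1-p)) plus any correction variance carried in
#' `corr_var_logit`. The continuity correction of half a count is applied
#' to every observation, not only to zeros and ones — i.e. the transform
#' is the empirical logit, log((x+0.5)/(D-x+0.5)), whose variance is the
#' delta formula at the shifted proportion. With the small infertile
#' counts of low-prevalence cells the plain logit of a binomial proportion
#' is biased downward by Jensen's inequality; the empirical logit removes
#' that bias to second order while reducing to the plain logit for large
#' cells. The design effect enters as the ratio of the raw to the
#' effective denominator, multiplying the variance.
#'
#' The variance is evaluated at the pooled proportion of the observation's
#' (indicator, age group) stratum, not at the observation's own value:
#' with small counts, a variance of the form 1/(x + 0.5) makes precision
#' weights correlate with the observed count and biases every
#' precision-weighted summary upward; evaluating it at the pooled
#' proportion removes the correlation while keeping the counts' scale.
#'
#' @param observations observation data.frame ([extract_observations()],
#'   optionally through [apply_correction()])
#' @param link analysis link; only `"logit"` is implemented
#' @return data.frame with columns `indicator`, `country_id`, `year`,
#'   `age_group`, `y`, `variance`, `is_national`
#' @export
assemble_inputs <- function(observations, link = c("logit")) {
  link <- match.arg(link)
  if (any(observations$effective_n <= 0))
    stop("effective_n must be positive")
  D <- observations$raw_denominator
  x <- observations$value * D        # works for corrected values too
  deff <- D / observations$effective_n
  p <- (x + 0.5) / (D + 1)
  stratum <- paste(observations$indicator, observations$age_group)
  p_pool <- (ave(x, stratum, FUN = sum) + 0.5) /
    (ave(D, stratum, FUN = sum) + 1)
  samp_var <- deff / ((D + 1) * p_pool * (1 - p_pool))
  corr_var <- if (is.null(observations$corr_var_logit)) 0 else
    observations$corr_var_logit
  data.frame(indicator = observations$indicator,
             country_id = observations$country_id,
             year = observations$survey_year,
             age_group = observations$age_group,
             y = logit(p),
             variance = samp_var + corr_var,
             is_national = observations$is_national,
             stringsAsFactors = FALSE)
}

# Column layout of the location-parameter vector for one indicator.
param_layout <- function(spec, indicator) {
  h <- spec$hierarchy
  regions <- unique(h$region_id)
  subregions <- unique(h$subregion_id)
  countries <- h$country_id
  nm <- c("alpha0",
          paste0("a_r[", regions, "]"),
          paste0("a_s[", subregions, "]"),
          paste0("a_c[", countries, "]"),
          "beta0",
          paste0("b_r[", regions, "]"),
          "gamma",
          paste0("age[", age_group_labels()[-1], "]"))
  hi_cols <- character(0)
  if (indicator == "primary_exposure" && any(h$is_high_income)) {
    hi_cols <- paste0("age_hi[", age_group_labels()[-1], "]")
    nm <- c(nm, hi_cols)
  }
  idx <- function(prefix) which(startsWith(nm, prefix))
  list(names = nm, regions = regions, subregions = subregions,
       countries = countries,
       region = idx("a_r["), subregion = idx("a_s["), country = idx("a_c["),
       region_slope = idx("b_r["), has_hi = length(hi_cols) > 0)
}

# Dense design matrix rows for arbitrary (country, year, age) cells.
design_rows <- function(spec, layout, indicator, country_id, year, age_group) {
  h <- spec$hierarchy
  n <- length(country_id)
  p <- length(layout$names)
  X <- matrix(0, n, p, dimnames = list(NULL, layout$names))
  hrow <- match(country_id, h$country_id)
  X[, "alpha0"] <- 1
  X[cbind(seq_len(n), layout$region[match(h$region_id[hrow], layout$regions)])] <- 1
  X[cbind(seq_len(n),
          layout$subregion[match(h$subregion_id[hrow], layout$subregions)])] <- 1
  X[cbind(seq_len(n), layout$country[match(country_id, layout$countries)])] <- 1
  t_dec <- (year - 2000) / 10
  X[, "beta0"] <- t_dec
  X[cbind(seq_len(n),
          layout$region_slope[match(h$region_id[hrow], layout$regions)])] <- t_dec
  X[, "gamma"] <- edu_lookup(spec, country_id, year)
  a_idx <- match(age_group, age_group_labels())
  for (a in 2:5) {
    col <- paste0("age[", age_group_labels()[a], "]")
    X[a_idx == a, col] <- 1
  }
  if (layout$has_hi) {
    hi <- h$is_high_income[hrow]
    for (a in 2:5) {
      col <- paste0("age_hi[", age_group_labels()[a], "]")
      X[hi & a_idx == a, col] <- 1
    }
  }
  X
}

#' Fit the hierarchical model by Markov chain Monte Carlo
#'
#' Each indicator present in the inputs is fitted independently. The
#' sampler is a blocked Gibbs scheme: all location parameters are drawn
#' jointly from their exact multivariate-normal full conditional, and the
#' six standard-deviation components by slice sampling under half-normal
#' priors. Convergence is assessed by split potential-scale-reduction
#' (threshold 1.05) on every scalar parameter; failure is reported in the
#' returned diagnostics and as a warning, never silently.
#'
#' @param inputs data.frame from [assemble_inputs()]
#' @param spec a [model_spec()]
#' @param seed integer seed; retained draws are reproducible from it
#' @param n_retained total retained posterior draws (split across chains)
#' @param n_chains number of chains (>= 2 for convergence diagnostics)
#' @param n_warmup discarded warmup iterations per chain
#' @return a `posterior` object with retained parameter draws, predicted
#'   prevalence draws for every (country, year in `spec$years`, age group),
#'   and convergence diagnostics
#' @export
fit_model <- function(inputs, spec, seed = 1L, n_retained = 1600,
                      n_chains = 4, n_warmup = 500) {
  stopifnot(inherits(spec, "model_spec"), n_chains >= 2)
  indicators <- intersect(INDICATORS, unique(inputs$indicator))
  if (!length(indicators)) stop("no observations for any indicator")
  if (any(inputs$variance <= 0)) stop("observation variances must be positive")
  withr_seed(seed)
  n_keep <- ceiling(n_retained / n_chains)

  h <- spec$hierarchy
  grid <- expand.grid(country_id = h$country_id, year = spec$years,
                      age_group = age_group_labels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  fits <- list(); diag_rows <- list()
  for (ind in indicators) {
    d <- inputs[inputs$indicator == ind, , drop = FALSE]
    unknown <- setdiff(d$country_id, h$country_id)
    if (length(unknown))
      stop("observations for countries outside the hierarchy: ",
           paste(unique(unknown), collapse = ", "))
    layout <- param_layout(spec, ind)
    X <- design_rows(spec, layout, ind, d$country_id, d$year, d$age_group)
    chains <- lapply(seq_len(n_chains), function(ch)
      run_chain(X, d$y, d$variance, d$is_national, layout, spec$priors,
                n_warmup, n_keep))

    theta <- do.call(rbind, lapply(chains, `[[`, "theta"))[seq_len(n_retained), , drop = FALSE]
    colnames(theta) <- layout$names
    sds <- do.call(rbind, lapply(chains, `[[`, "sds"))[seq_len(n_retained), , drop = FALSE]

    par_mat <- cbind(theta, sds)
    rhats <- vapply(seq_len(ncol(par_mat)), function(j) {
      per_chain <- vapply(chains, function(ch)
        cbind(ch$theta, ch$sds)[, j], numeric(n_keep))
      split_rhat(per_chain)
    }, numeric(1))
    names(rhats) <- colnames(par_mat)
    diag_rows[[ind]] <- data.frame(indicator = ind, parameter = names(rhats),
                                   rhat = unname(rhats), stringsAsFactors = FALSE)

    Xp <- design_rows(spec, layout, ind, grid$country_id, grid$year, grid$age_group)
    pred <- inv_logit(theta %*% t(Xp))   # draws x cells
    fits[[ind]] <- list(theta = theta, sds = sds, pred = pred,
                        rhat = rhats, layout = layout)
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  max_rhat <- max(diagnostics$rhat, na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat < 1.05
  if (!converged)
    warning(sprintf("convergence not reached: max split-Rhat %.3f (threshold 1.05); inspect $diagnostics", max_rhat))
  structure(list(fits = fits, cells = grid, spec = spec, seed = seed,
                 n_retained = n_retained, diagnostics = diagnostics,
                 converged = converged),
            class = "posterior")
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf("<posterior> %s; %d draws x %d cells; converged: %s (max Rhat %.3f)\n",
              paste(names(x$fits), collapse = ", "), x$n_retained,
              nrow(x$cells), x$converged, max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Extract predicted prevalence draws for one cell
#'
#' @param posterior a `posterior` from [fit_model()]
#' @param indicator indicator name
#' @param country_id,year,age_group the cell; must lie inside the fitted
#'   window (years in `spec$years`, age groups 20--44)
#' @return numeric vector of retained draws, all in (0, 1)
#' @export
predict_prevalence <- function(posterior, indicator, country_id, year,
                               age_group) {
  stopifnot(inherits(posterior, "posterior"))
  fit <- posterior$fits[[indicator]]
  if (is.null(fit)) stop("indicator not fitted: ", indicator)
  cell <- which(posterior$cells$country_id == country_id &
                  posterior$cells$year == year &
                  posterior$cells$age_group == age_group)
  if (length(cell) != 1)
    stop(sprintf("query outside the fitted window: %s %s %s",
                 country_id, year, age_group))
  unname(fit$pred[, cell])
}

#' Write convergence diagnostics as CSV
#' @param posterior a `posterior`
#' @param path CSV path
#' @export
write_diagnostics_csv <- function(posterior, path) {
  write.csv(posterior$diagnostics, path, row.names = FALSE)
  invisible(path)
}

#' Persist a posterior as CSV arrays with an index manifest
#'
#' Writes, per indicator, the parameter draws (`<indicator>_params.csv`,
#' draws by parameters) and predicted prevalence draws
#' (`<indicator>_pred.csv`, draws by cells), plus `cells.csv` (the cell
#' index matching the prediction columns), `diagnostics.csv`, and
#' `manifest.yaml` describing the layout. Mind the size: predictions are
#' draws x (countries x years x ages).
#'
#' @param posterior a `posterior`
#' @param dir output directory (created if needed)
#' @export
write_posterior_csv <- function(posterior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ind in names(posterior$fits)) {
    f <- posterior$fits[[ind]]
    write.csv(cbind(as.data.frame(f$theta), as.data.frame(f$sds)),
              file.path(dir, paste0(ind, "_params.csv")), row.names = FALSE)
    pred <- as.data.frame(f$pred)
    names(pred) <- paste(posterior$cells$country_id, posterior$cells$year,
                         posterior$cells$age_group, sep = "|")
    write.csv(pred, file.path(dir, paste0(ind, "_pred.csv")),
              row.names = FALSE)
  }
  write.csv(posterior$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(posterior$diagnostics, file.path(dir, "diagnostics.csv"),
            row.names = FALSE)
  yaml::write_yaml(list(
    indicators = names(posterior$fits),
    n_retained = posterior$n_retained,
    n_cells = nrow(posterior$cells),
    converged = posterior$converged,
    layout = "rows are retained draws; prediction columns follow cells.csv",
    seed = posterior$seed), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
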