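obs_row <- function(value, n, country = "R01.S01.C01", year = 2000,
                    age = "[25,30)", indicator = "primary_prev",
                    national = TRUE, deff = 1) {
  data.frame(indicator = indicator, country_id = country, survey_year = year,
             age_group = age, value = value, effective_n = n / deff,
             is_national = national, is_biased = FALSE,
             raw_numerator = round(value * n), raw_denominator = n,
             contra_prev = 0.3, stringsAsFactors = FALSE)
}

test_that("assemble_inputs transforms to the logit scale correctly", {
  # p = 0.5 maps to 0 (the half-count shift is symmetric there)
  a <- assemble_inputs(obs_row(0.5, 1000))
  expect_equal(a$y, 0, tolerance = 1e-12)

  # delta variance at p = 0.02, n_eff = 1000 ~ 1/(1000 * 0.02 * 0.98);
  # frozen oracle: empirical variance of the transform over 2e5 binomial
  # draws at D = 1000, p = 0.02 (seed 7) is 0.0523
  a <- assemble_inputs(obs_row(0.02, 1000))
  expect_equal(a$variance, 1 / (1000 * 0.02 * 0.98), tolerance = 0.07)
  expect_equal(a$variance, 0.0523, tolerance = 0.08)

  # p = 0 with denominator 50: continuity-corrected by half a count
  a <- assemble_inputs(obs_row(0, 50))
  expect_equal(a$y, qlogis(0.5 / 51), tolerance = 1e-12)
  expect_true(is.finite(a$variance))

  # design effect scales the variance, not the transformed value
  a1 <- assemble_inputs(obs_row(0.1, 400, deff = 1))
  a2 <- assemble_inputs(obs_row(0.1, 400, deff = 2))
  expect_equal(a2$y, a1$y)
  expect_equal(a2$variance, 2 * a1$variance)

  expect_error(assemble_inputs(obs_row(0.1, -5)), "positive")
})

test_that("assemble_inputs variance matches a simulation oracle", {
  # empirical check of the delta formula at moderate counts
  set.seed(7)
  D <- 1000; p <- 0.02
  x <- rbinom(2e5, D, p)
  y <- log((x + 0.5) / (D - x + 0.5))
  emp <- var(y)
  a <- assemble_inputs(obs_row(0.02, 1000))
  expect_equal(a$variance, emp, tolerance = 0.1)
})

test_that("a data-rich single cell shrinks the posterior onto the data", {
  h <- generate_hierarchy(1, 1, 1, seed = 1)
  ctx <- generate_context(h, seed = 2)
  spec <- model_spec(h, ctx$education)
  val <- 0.12
  obs <- do.call(rbind, lapply(1:12, function(i)
    obs_row(val, 8000, country = h$country_id[1], year = 2000)))
  post <- suppressWarnings(
    fit_model(assemble_inputs(obs), spec, seed = 5,
              n_retained = fast_mcmc$n_retained, n_chains = fast_mcmc$n_chains,
              n_warmup = fast_mcmc$n_warmup))
  dr <- predict_prevalence(post, "primary_prev", h$country_id[1], 2000,
                           "[25,30)")
  expect_equal(mean(dr), val, tolerance = 0.01)
})

test_that("a country with no data is centered on its subregion", {
  h <- generate_hierarchy(1, 1, 3, seed = 1)
  ctx <- generate_context(h, seed = 2)
  spec <- model_spec(h, ctx$education)
  # two data-rich countries at logit(0.2); third has no data
  obs <- do.call(rbind, lapply(h$country_id[1:2], function(cid)
    do.call(rbind, lapply(c(1995, 2000, 2005), function(yr)
      obs_row(0.2, 5000, country = cid, year = yr)))))
  post <- suppressWarnings(
    fit_model(assemble_inputs(obs), spec, seed = 6,
              n_retained = 800, n_chains = 2, n_warmup = 300))
  with_data <- predict_prevalence(post, "primary_prev", h$country_id[1],
                                  2000, "[25,30)")
  no_data <- predict_prevalence(post, "primary_prev", h$country_id[3],
                                2000, "[25,30)")
  # posterior mean of the empty country sits near the subregion level,
  # within the shrinkage tolerance implied by the country-level variance
  tau_c <- mean(post$fits$primary_prev$sds[, "tau_country"])
  gap <- abs(mean(qlogis(no_data)) - mean(qlogis(with_data)))
  expect_lt(gap, 2 * tau_c + 0.1)
  # and its interval is wider than the data-rich country's
  expect_gt(diff(quantile(no_data, c(0.025, 0.975))),
            diff(quantile(with_data, c(0.025, 0.975))))
})

test_that("noisier data shrink a country toward its subregion, conjugate-style", {
  # six tight sibling countries pin the subregion at 0.10; a seventh
  # country observes 0.25 with varying information; an eighth, empty
  # country reads out the subregion level. Education is held constant so
  # the covariate cannot soak up level differences.
  h <- generate_hierarchy(1, 1, 8, seed = 1)
  ctx <- generate_context(h, seed = 2, edu_base_range = c(7, 7),
                          edu_slope_range = c(0, 0))
  spec <- model_spec(h, ctx$education)
  country_block <- function(value, n, country) do.call(rbind, lapply(
    age_labels, function(ag) obs_row(value, n, country = country, age = ag)))
  mk <- function(n_b) rbind(
    do.call(rbind, lapply(1:6, function(i)
      country_block(0.10, 20000, h$country_id[i]))),
    country_block(0.25, n_b, h$country_id[7]))
  shrink_frac <- function(post) {
    c7 <- mean(qlogis(predict_prevalence(post, "primary_prev",
                                         h$country_id[7], 2000, "[25,30)")))
    sub <- mean(qlogis(predict_prevalence(post, "primary_prev",
                                          h$country_id[8], 2000, "[25,30)")))
    (qlogis(0.25) - c7) / (qlogis(0.25) - sub)
  }
  post_loose <- suppressWarnings(fit_model(assemble_inputs(mk(100)), spec,
    seed = 7, n_retained = 800, n_chains = 2, n_warmup = 300))
  post_tight <- suppressWarnings(fit_model(assemble_inputs(mk(20000)), spec,
    seed = 7, n_retained = 800, n_chains = 2, n_warmup = 300))
  f_loose <- shrink_frac(post_loose)
  f_tight <- shrink_frac(post_tight)
  expect_gt(f_loose, f_tight)
  expect_lt(f_tight, 0.05)
  # agreement with the exact conjugate normal-normal weight, evaluated at
  # the posterior median country-level variance
  inp <- assemble_inputs(mk(100))
  v <- inp$variance[inp$country_id == h$country_id[7]][1]
  tau2 <- median(post_loose$fits$primary_prev$sds[, "tau_country"])^2
  conj <- (1 / tau2) / (1 / tau2 + 5 / v)
  expect_equal(f_loose, conj, tolerance = 0.5)
})

test_that("fits are reproducible and predictions well-formed", {
  h <- tiny_hierarchy()
  ctx <- tiny_context()
  spec <- model_spec(h, ctx$education)
  obs <- rbind(obs_row(0.1, 500, country = h$country_id[1]),
               obs_row(0.2, 500, country = h$country_id[3], year = 1994),
               obs_row(0.15, 500, country = h$country_id[6], year = 2007))
  fit1 <- suppressWarnings(fit_model(assemble_inputs(obs), spec, seed = 9,
    n_retained = 400, n_chains = 2, n_warmup = 150))
  fit2 <- suppressWarnings(fit_model(assemble_inputs(obs), spec, seed = 9,
    n_retained = 400, n_chains = 2, n_warmup = 150))
  expect_identical(fit1$fits$primary_prev$theta, fit2$fits$primary_prev$theta)

  dr <- predict_prevalence(fit1, "primary_prev", h$country_id[2], 1990,
                           "[40,45)")
  expect_length(dr, 400)
  expect_true(all(dr > 0 & dr < 1))
  expect_identical(dr, predict_prevalence(fit1, "primary_prev",
                                          h$country_id[2], 1990, "[40,45)"))
  expect_error(predict_prevalence(fit1, "primary_prev", h$country_id[2],
                                  1985, "[40,45)"), "window")
  expect_error(predict_prevalence(fit1, "primary_prev", h$country_id[2],
                                  2000, "[15,20)"), "window")
  expect_error(predict_prevalence(fit1, "secondary_prev", h$country_id[2],
                                  2000, "[25,30)"), "not fitted")
})

test_that("fit_model validates its inputs", {
  h <- tiny_hierarchy()
  spec <- model_spec(h, tiny_context()$education)
  expect_error(fit_model(data.frame(indicator = character(0)), spec),
               "no observations")
  bad <- assemble_inputs(obs_row(0.1, 500, country = "ELSEWHERE"))
  expect_error(suppressWarnings(fit_model(bad, spec, n_retained = 100,
                                          n_chains = 2, n_warmup = 50)),
               "outside the hierarchy")
})

test_that("convergence diagnostics are reported, not silent", {
  h <- tiny_hierarchy()
  spec <- model_spec(h, tiny_context()$education)
  obs <- obs_row(0.1, 500, country = h$country_id[1])
  # absurdly short chains cannot pass split-Rhat on every parameter
  expect_warning(
    post <- fit_model(assemble_inputs(obs), spec, seed = 10,
                      n_retained = 16, n_chains = 2, n_warmup = 2),
    "convergence")
  expect_false(post$converged)
  expect_true(all(c("indicator", "parameter", "rhat") %in%
                    names(post$diagnostics)))
})
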