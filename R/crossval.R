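# Posterior-predictive draws for arbitrary observation rows (any year,
# including pre-window survey years): cell prevalence draws plus the
# observation's own noise (known variance + the fitted extra component).
predict_obs_draws <- function(posterior, indicator, df, include_noise = TRUE) {
  fit <- posterior$fits[[indicator]]
  if (is.null(fit)) stop("indicator not fitted: ", indicator)
  X <- design_rows(posterior$spec, fit$layout, indicator,
                   df$country_id, df$year, df$age_group)
  mu <- fit$theta %*% t(X)                      # draws x obs
  if (include_noise) {
    extra <- vapply(seq_len(nrow(df)), function(j)
      fit$sds[, if (df$is_national[j]) "sigma_national" else
        "sigma_subnational"]^2, numeric(nrow(fit$theta)))
    noise_sd <- sqrt(extra + rep(df$variance, each = nrow(fit$theta)))
    mu <- mu + rnorm(length(mu)) * noise_sd
  }
  inv_logit(mu)
}

#' Country-withholding cross-validation of predictive validity
#'
#' Runs each indicator's model several times, each time withholding all
#' data from an independent random sample of a fraction of the countries
#' that have data, then compares the withheld observations to the refitted
#' model's predictions. Reported per indicator and pooled: root mean
#' square error on the percentage-point scale, median relative error
#' (prediction minus observation, over observation), and the share of
#' withheld observations inside the 95% posterior-predictive interval.
#'
#' @param observations observation table (post-correction); assembled
#'   internally with [assemble_inputs()]
#' @param spec a [model_spec()]
#' @param n_folds number of independent holdout replicates
#' @param holdout_fraction fraction of data-bearing countries withheld per
#'   fold (each fold samples independently; not a rotating partition)
#' @param seed integer seed controlling fold membership and fitting
#' @param n_retained,n_chains,n_warmup MCMC settings per refit
#' @return a `cv_report`: `summary` (metrics per indicator plus `pooled`),
#'   `detail` (one row per withheld observation), `folds` (country
#'   membership)
#' @export
run_cv <- function(observations, spec, n_folds = 5, holdout_fraction = 0.2,
                   seed = 1L, n_retained = 800, n_chains = 2, n_warmup = 300) {
  withr_seed(seed)
  inputs <- assemble_inputs(observations)
  countries <- unique(inputs$country_id)
  n_hold <- max(1L, round(holdout_fraction * length(countries)))
  if (n_hold >= length(countries))
    stop("holdout would remove every country with data")
  h <- spec$hierarchy

  detail <- list(); folds <- list()
  for (f in seq_len(n_folds)) {
    held <- sort(sample(countries, n_hold))
    folds[[f]] <- data.frame(fold = f, country_id = held,
                             stringsAsFactors = FALSE)
    regions_left <- unique(h$region_id[match(setdiff(countries, held),
                                             h$country_id)])
    gone <- setdiff(unique(h$region_id), regions_left)
    if (length(gone))
      warning(sprintf("fold %d empties region(s) %s of data; the hierarchy covers the gap",
                      f, paste(gone, collapse = ", ")))
    train <- inputs[!inputs$country_id %in% held, , drop = FALSE]
    test <- inputs[inputs$country_id %in% held, , drop = FALSE]
    fold_seed <- (seed * 1000L + f) %% .Machine$integer.max
    post <- suppressWarnings(
      fit_model(train, spec, seed = fold_seed, n_retained = n_retained,
                n_chains = n_chains, n_warmup = n_warmup))
    for (ind in names(post$fits)) {
      te <- test[test$indicator == ind, , drop = FALSE]
      if (!nrow(te)) next
      pp <- predict_obs_draws(post, ind, te, include_noise = TRUE)
      point <- colMeans(inv_logit(post$fits[[ind]]$theta %*%
                                    t(design_rows(spec, post$fits[[ind]]$layout,
                                                  ind, te$country_id, te$year,
                                                  te$age_group))))
      qs <- apply(pp, 2, quantile, c(0.025, 0.975))
      obs_p <- inv_logit(te$y)
      detail[[length(detail) + 1L]] <- data.frame(
        fold = f, indicator = ind, country_id = te$country_id,
        year = te$year, age_group = te$age_group,
        observed = obs_p, predicted = point,
        lower_95 = qs[1, ], upper_95 = qs[2, ],
        covered = obs_p >= qs[1, ] & obs_p <= qs[2, ],
        stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  rownames(detail) <- NULL

  metric <- function(d) data.frame(
    n = nrow(d),
    rmse_pp = sqrt(mean((d$predicted - d$observed)^2)) * 100,
    median_rel_error = median((d$predicted - d$observed) / d$observed),
    coverage = mean(d$covered))
  summary <- do.call(rbind, lapply(split(detail, detail$indicator), metric))
  summary <- cbind(indicator = rownames(summary), summary)
  pooled <- cbind(indicator = "pooled", metric(detail))
  summary <- rbind(summary, pooled)
  rownames(summary) <- NULL

  structure(list(summary = summary, detail = detail,
                 folds = do.call(rbind, folds), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write cross-validation outputs as CSV
#' @param report a `cv_report`
#' @param path summary CSV path; per-fold predictions go to
#'   `<path>.predictions.csv`
#' @export
write_cv_csv <- function(report, path) {
  write.csv(report$summary, path, row.names = FALSE)
  write.csv(report$detail, paste0(path, ".predictions.csv"), row.names = FALSE)
  invisible(path)
}
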