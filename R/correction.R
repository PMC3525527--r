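#' Fit a measurement-bias correction regression
#'
#' Ordinary least squares of the natural log of the less-biased prevalence
#' estimate on the biased estimate (proportion scale), the age-group
#' midpoint, and — for secondary infertility only — the prevalence of
#' contraceptive use. Training pairs come from surveys with complete
#' contraception history and union duration, classified twice: once with
#' the full information and once with the current-status fallback (see
#' [build_correction_pairs()]).
#'
#' @param pairs data.frame with columns `biased`, `unbiased`, `age_mid`,
#'   and for secondary infertility `contra_prev`; an optional `denominator`
#'   column allows continuity correction of zero unbiased values
#'   (0.5/denominator)
#' @param indicator `"primary_prev"` or `"secondary_prev"`
#' @return a `correction_model`: coefficients, residual variance (log
#'   scale), coefficient covariance, pair count
#' @export
fit_correction <- function(pairs, indicator) {
  indicator <- match.arg(indicator, c("primary_prev", "secondary_prev"))
  vars <- c("biased", "age_mid")
  if (indicator == "secondary_prev") vars <- c(vars, "contra_prev")
  missing_cols <- setdiff(c(vars, "unbiased"), names(pairs))
  if (length(missing_cols))
    stop("pairs lack required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(pairs) < length(vars) + 2)
    stop("need at least ", length(vars) + 2, " pairs")

  u <- pairs$unbiased
  zero <- !is.na(u) & u <= 0
  if (any(zero)) {
    if (is.null(pairs$denominator))
      stop("zero unbiased values need a denominator column for continuity correction")
    u[zero] <- 0.5 / pairs$denominator[zero]
  }
  X <- as.matrix(cbind(1, pairs[, vars, drop = FALSE]))
  colnames(X) <- c("(Intercept)", vars)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient correction design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  y <- log(u)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  dfree <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / max(dfree, 1)
  XtXinv <- chol2inv(qr.R(qrX))
  structure(list(indicator = indicator,
                 coefficients = beta,
                 residual_variance = sigma2,
                 coefficient_covariance = sigma2 * XtXinv,
                 n_pairs = nrow(pairs),
                 regressors = vars),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %s: ln(unbiased) ~ %s (n=%d, sigma2=%.4g)\n",
              x$indicator, paste(x$regressors, collapse = " + "),
              x$n_pairs, x$residual_variance))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Apply a correction model to biased observations
#'
#' Rows flagged `is_biased` are replaced by the model's predicted
#' (exponentiated) prevalence; rows not flagged pass through unchanged. A
#' `corr_var_logit` column carries the correction's prediction variance
#' (coefficient term plus residual variance, delta-mapped from the log to
#' the logit scale); it is zero for unbiased rows, so total observation
#' variance never decreases under correction.
#'
#' @param obs observation data.frame from [extract_observations()]
#' @param model a `correction_model` for the matching indicator
#' @return `obs` with corrected `value`, original values in `value_biased`,
#'   and a `corr_var_logit` column
#' @export
apply_correction <- function(obs, model) {
  stopifnot(inherits(model, "correction_model"))
  rows <- obs$indicator == model$indicator
  if (is.null(obs$corr_var_logit)) obs$corr_var_logit <- 0
  if (is.null(obs$value_biased)) obs$value_biased <- obs$value
  target <- rows & obs$is_biased
  if (!any(target)) return(obs)

  Xcols <- lapply(model$regressors, function(v) switch(
    v,
    biased = obs$value[target],
    age_mid = age_midpoint(obs$age_group[target]),
    contra_prev = obs$contra_prev[target]
  ))
  X <- cbind(1, do.call(cbind, Xcols))
  pred_log <- as.numeric(X %*% model$coefficients)
  v_log <- rowSums((X %*% model$coefficient_covariance) * X) +
    model$residual_variance
  p <- exp(pred_log)
  over <- p >= 1
  if (any(over)) {
    warning(sum(over), " corrected value(s) at or above 1 clipped to 0.99")
    p[over] <- 0.99
  }
  obs$value[target] <- p
  # delta method: var ln p -> var logit p multiplies by 1/(1-p)^2
  obs$corr_var_logit[target] <- v_log / (1 - p)^2
  obs
}

#' Build correction training pairs from full-information surveys
#'
#' For every (survey, age-group) cell of surveys that recorded both
#' contraception history and current-union duration, computes the indicator
#' twice — once with the full information (the less-biased estimate) and
#' once forcing the current-status/first-union fallback (the biased
#' estimate).
#'
#' @param datasets list of `survey_dataset` objects with full history
#' @param indicator `"primary_prev"` or `"secondary_prev"`
#' @return data.frame of pairs suitable for [fit_correction()]
#' @export
build_correction_pairs <- function(datasets, indicator) {
  if (inherits(datasets, "survey_dataset")) datasets <- list(datasets)
  out <- list()
  for (ds in datasets) {
    if (!isTRUE(ds$has_contraceptive_history) ||
        !isTRUE(ds$has_current_union_duration)) {
      warning("skipping survey without full history: ", ds$country_id)
      next
    }
    for (ag in age_group_labels()) {
      full <- compute_observation(ds, indicator, ag, has_full_history = TRUE)
      biased <- compute_observation(ds, indicator, ag, has_full_history = FALSE)
      if (is.null(full) || is.null(biased)) next
      out[[length(out) + 1L]] <- data.frame(
        biased = biased$value, unbiased = full$value,
        age_mid = age_midpoint(ag), contra_prev = full$contra_prev,
        denominator = full$raw_denominator)
    }
  }
  do.call(rbind, out)
}

#' Serialize / load a correction model as YAML
#' @param model a `correction_model`
#' @param path file path
#' @export
write_correction_yaml <- function(model, path) {
  yaml::write_yaml(list(
    indicator = model$indicator,
    regressors = model$regressors,
    coefficients = as.list(setNames(as.numeric(model$coefficients),
                                    names(model$coefficients))),
    residual_variance = model$residual_variance,
    coefficient_covariance = apply(model$coefficient_covariance, 1, as.numeric,
                                   simplify = FALSE),
    n_pairs = model$n_pairs), path, precision = 12)
  invisible(path)
}

#' @rdname write_correction_yaml
#' @export
read_correction_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cov <- do.call(rbind, y$coefficient_covariance)
  structure(list(indicator = y$indicator,
                 coefficients = unlist(y$coefficients),
                 residual_variance = y$residual_variance,
                 coefficient_covariance = cov,
                 n_pairs = y$n_pairs,
                 regressors = y$regressors),
            class = "correction_model")
}
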