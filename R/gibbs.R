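# Sampler internals for the hierarchical space-time-age model.
#
# Given the variance components the model is linear-Gaussian on the logit
# scale, so the full conditional of the complete location-parameter vector
# is multivariate normal and is drawn exactly by Cholesky factorization
# (blocked Gibbs). Standard-deviation components have half-Normal priors
# and are updated by univariate slice sampling on the log scale.

# One exact draw of theta ~ N((X'WX+P)^-1 X'Wy, (X'WX+P)^-1).
draw_locations <- function(XtW, X, y, prior_prec) {
  A <- XtW %*% X
  diag(A) <- diag(A) + prior_prec
  b <- XtW %*% y
  R <- chol(A)
  mu <- backsolve(R, forwardsolve(t(R), b))
  as.numeric(mu + backsolve(R, rnorm(length(b))))
}

# Slice sampler (Neal 2003, stepping out + shrinkage) for a scalar.
slice_draw <- function(x0, log_f, w = 1, max_steps = 30L) {
  f0 <- log_f(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  z <- f0 - rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  Rr <- L + w
  k <- max_steps
  while (k > 0 && log_f(L) > z) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0 && log_f(Rr) > z) { Rr <- Rr + w; k <- k - 1L }
  repeat {
    x1 <- runif(1, L, Rr)
    if (log_f(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else Rr <- x1
  }
}

# log half-Normal(scale) density of sd, plus Jacobian for sampling log(sd)
log_halfnormal_logsd <- function(log_sd, scale) {
  sd <- exp(log_sd)
  -sd^2 / (2 * scale^2) + log_sd   # log prior + log|d sd/d log sd|
}

# Update one hierarchical sd given its effects vector.
update_level_sd <- function(sd0, effects, scale) {
  k <- length(effects)
  if (k == 0) return(abs(rnorm(1, 0, scale)))
  ss <- sum(effects^2)
  lf <- function(ls) {
    s <- exp(ls)
    -k * ls - ss / (2 * s^2) + log_halfnormal_logsd(ls, scale)
  }
  exp(slice_draw(log(max(sd0, 1e-4)), lf, w = 0.5))
}

# Update an extra (national or subnational) observation sd given residuals.
update_extra_sd <- function(sd0, resid, base_var, scale) {
  if (length(resid) == 0) return(abs(rnorm(1, 0, scale)))
  lf <- function(ls) {
    s2 <- exp(2 * ls)
    v <- base_var + s2
    -0.5 * sum(log(v) + resid^2 / v) + log_halfnormal_logsd(ls, scale)
  }
  exp(slice_draw(log(max(sd0, 1e-4)), lf, w = 0.5))
}

# Truncated-normal draw on (0, Inf).
rtruncnorm_pos <- function(mean, sd) {
  lo <- pnorm(0, mean, sd)
  if (lo > 1 - 1e-12) return(1e-8)
  qnorm(runif(1, lo, 1), mean, sd)
}

# Ancillarity-sufficiency interweaving for one hierarchical level: with
# eta = effects/sd held fixed, the sd's conditional given the data is
# normal (truncated to sd > 0), which decouples the sd from its effects
# and repairs the slow mixing of the centered parameterization.
interweave_level <- function(theta, sds, name, idx, X, y, w, scale) {
  tau <- sds[name]
  a <- theta[idx]
  if (tau < 1e-8 || !length(idx)) return(list(theta = theta, sds = sds))
  eta <- a / tau
  contrib <- as.numeric(X[, idx, drop = FALSE] %*% a)
  s <- contrib / tau                       # = X[, idx] %*% eta
  r <- y - as.numeric(X %*% theta) + contrib
  prec <- sum(w * s^2) + 1 / scale^2
  m <- sum(w * r * s) / prec
  tau_new <- rtruncnorm_pos(m, 1 / sqrt(prec))
  theta[idx] <- tau_new * eta
  sds[name] <- tau_new
  list(theta = theta, sds = sds)
}

# split-Rhat (Gelman et al.): draws is iterations x chains.
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < 1e-12) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Run one chain; returns draws of theta (kept x p), sds (kept x n_sd).
run_chain <- function(X, y, v_base, is_national, layout, priors,
                      n_warmup, n_keep) {
  p <- ncol(X)
  sd_names <- c("tau_region", "tau_subregion", "tau_country", "tau_slope",
                "sigma_national", "sigma_subnational")
  sds <- setNames(rep(0.3, 6), sd_names)
  theta <- rep(0, p)
  keep_theta <- matrix(NA_real_, n_keep, p)
  keep_sds <- matrix(NA_real_, n_keep, 6, dimnames = list(NULL, sd_names))
  nat <- which(is_national); sub <- which(!is_national)
  Xt <- t(X)

  for (it in seq_len(n_warmup + n_keep)) {
    extra <- ifelse(is_national, sds["sigma_national"]^2,
                    sds["sigma_subnational"]^2)
    w <- 1 / (v_base + extra)
    prior_prec <- rep(1 / priors$fixed_sd^2, p)
    prior_prec[layout$region] <- 1 / sds["tau_region"]^2
    prior_prec[layout$subregion] <- 1 / sds["tau_subregion"]^2
    prior_prec[layout$country] <- 1 / sds["tau_country"]^2
    prior_prec[layout$region_slope] <- 1 / sds["tau_slope"]^2
    theta <- draw_locations(Xt * rep(w, each = p), X, y, prior_prec)

    sds["tau_region"] <- update_level_sd(sds["tau_region"],
                                         theta[layout$region], priors$sd_scale)
    sds["tau_subregion"] <- update_level_sd(sds["tau_subregion"],
                                            theta[layout$subregion], priors$sd_scale)
    sds["tau_country"] <- update_level_sd(sds["tau_country"],
                                          theta[layout$country], priors$sd_scale)
    sds["tau_slope"] <- update_level_sd(sds["tau_slope"],
                                        theta[layout$region_slope],
                                        priors$sd_scale_slope)
    for (lv in list(list("tau_region", layout$region, priors$sd_scale),
                    list("tau_subregion", layout$subregion, priors$sd_scale),
                    list("tau_country", layout$country, priors$sd_scale),
                    list("tau_slope", layout$region_slope, priors$sd_scale_slope))) {
      iw <- interweave_level(theta, sds, lv[[1]], lv[[2]], X, y, w, lv[[3]])
      theta <- iw$theta; sds <- iw$sds
    }
    resid <- y - as.numeric(X %*% theta)
    sds["sigma_national"] <- update_extra_sd(sds["sigma_national"],
                                             resid[nat], v_base[nat],
                                             priors$sd_scale_extra_national)
    sds["sigma_subnational"] <- update_extra_sd(sds["sigma_subnational"],
                                                resid[sub], v_base[sub],
                                                priors$sd_scale_extra_subnational)
    if (it > n_warmup) {
      keep_theta[it - n_warmup, ] <- theta
      keep_sds[it - n_warmup, ] <- sds
    }
  }
  list(theta = keep_theta, sds = keep_sds)
}
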