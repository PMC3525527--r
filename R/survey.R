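#' Survey design flags and bias-structure settings
#'
#' @param is_national nationally representative sample?
#' @param ever_married_only interview only women who have ever been in a
#'   union (some high-fertility-country surveys do); all records then carry
#'   a time-since-first-union
#' @param has_contraceptive_history is contraceptive use over the last five
#'   years recorded (vs current status only)?
#' @param has_current_union_duration is the duration of the current union
#'   recorded (vs time since first union only)?
#' @param design_effect variance-inflation factor of the sampling design;
#'   1.0 for simple random samples, conventionally ~1.5 for clustered
#'   national surveys
#' @param prev_denominator_share share of primary-exposed women who belong
#'   to the long-union prevalence denominator (the "core" child-seeking or
#'   child-having population)
#' @param bias_primary,bias_secondary magnitude of the planted
#'   current-status contraception bias: mass of recent contraception
#'   quitters who mimic infertile unions, relative to the true infertile
#'   mass, before age weighting
#' @param bias_union magnitude of the planted union-duration bias: mass of
#'   remarried women (first union over five years back, current union
#'   short) who mimic infertile unions under the first-union clock,
#'   relative to the true infertile mass
#' @param bias_age_weights age-group multipliers of the planted biases;
#'   decreasing with age (the biases hit younger couples hardest)
#' @param contra_user_frac share of secondary-fertile and of
#'   out-of-union women who currently use contraception (varies the
#'   contraceptive-use-prevalence regressor of the secondary correction)
#' @param outside_age_frac share of respondents aged 15--19 or 45--49, who
#'   never enter observations
#' @return a list of design settings
#' @export
survey_design <- function(is_national = TRUE, ever_married_only = FALSE,
                          has_contraceptive_history = TRUE,
                          has_current_union_duration = TRUE,
                          design_effect = 1.0,
                          prev_denominator_share = 0.4,
                          bias_primary = 0.5, bias_secondary = 0.5,
                          bias_union = 0.3,
                          bias_age_weights = c(1.6, 1.3, 1.0, 0.7, 0.4),
                          contra_user_frac = 0.35,
                          outside_age_frac = 0.08) {
  stopifnot(design_effect > 0, prev_denominator_share > 0,
            prev_denominator_share <= 1)
  as.list(environment())
}

# Role masses for one age group, given that group's four true values.
# Solved so that full-history classification recovers (p1, p2, e1, e2)
# exactly in expectation; the pseudo_* (contraception-quitter) and gap_*
# (remarriage-gap) masses only distort classification when contraceptive
# history, respectively current-union duration, is unavailable. Bias
# masses are proportional to the true infertile masses and decline with
# age, so the planted bias is multiplicative and worst for young couples.
role_masses <- function(p1, p2, e1, e2, design, age_idx) {
  w <- design$bias_age_weights[age_idx]
  b1 <- design$bias_primary * w
  b2 <- design$bias_secondary * w
  g <- design$bias_union * w
  f_pd <- design$prev_denominator_share * e1
  B <- f_pd * (1 - p1) / (1 + b2 * p2)     # secondary-denominator mass
  pi2 <- p2 * B                            # secondary infertile
  pi7 <- b2 * pi2                          # pseudo secondary infertile
  pi1 <- p1 * f_pd                         # primary infertile
  pi34 <- B * (1 - p2)                     # secondary fertile
  pi6 <- b1 * pi1                          # pseudo primary infertile
  gp1 <- g * pi1                           # remarriage-gap, nulliparous
  gp2 <- g * pi2                           # remarriage-gap, parous
  x2_raw <- e2 - (B + pi7 + gp2)           # parous short-union child-seekers
  pi_x2 <- min(max(x2_raw, 0), 1)
  x5_raw <- e1 - f_pd - pi6 - gp1 - gp2 - pi_x2  # nulliparous short-union seekers
  pi5 <- min(max(x5_raw, 0), 1)
  clamped <- x2_raw < -1e-9 || x5_raw < -1e-9
  m <- c(prim_inf = pi1, sec_inf = pi2, sec_fert = pi34,
         pseudo_prim = pi6, pseudo_sec = pi7,
         gap_prim = gp1, gap_sec = gp2,
         extra_parous = pi_x2, extra_nullip = pi5)
  m <- c(m, not_union = max(1 - sum(m), 0))
  list(mass = m / sum(m), clamped = clamped)
}

#' Generate a woman-level survey dataset from a true surface
#'
#' Draws `n_women` respondent records whose classification by the
#' extraction module recovers, in expectation, the surface's true values of
#' all four indicators for the given country and year. Depending on the
#' design flags, the dataset omits contraceptive history and/or
#' current-union duration, in which case the planted bias structures
#' (recent contraception quitters who mimic infertile unions; remarried
#' women whose first union predates the current one) inflate apparent
#' infertility under the fallback classification.
#'
#' @param surface a `true_surface`
#' @param country_id,survey_year the cell to sample from (must be inside
#'   the surface's support)
#' @param n_women number of respondents (> 0)
#' @param design a [survey_design()] list
#' @param seed integer seed
#' @return a `survey_dataset`: list with `records` (one row per woman) and
#'   the design metadata
#' @export
generate_survey <- function(surface, country_id, survey_year, n_women,
                            design = survey_design(), seed = 1L) {
  stopifnot(inherits(surface, "true_surface"))
  if (!is.numeric(n_women) || n_women <= 0)
    stop("n_women must be positive")
  n_women <- as.integer(n_women)
  if (!country_id %in% surface$country_id)
    stop("country_id not in surface support")
  if (!survey_year %in% surface$year)
    stop("survey_year not in surface support")
  withr_seed(seed)

  truths <- vapply(INDICATORS, function(ind)
    surface_cell(surface, country_id, survey_year, ind), numeric(5))
  masses <- lapply(seq_len(5), function(a)
    role_masses(truths[a, "primary_prev"], truths[a, "secondary_prev"],
                truths[a, "primary_exposure"], truths[a, "secondary_exposure"],
                design, a))
  if (any(vapply(masses, `[[`, logical(1), "clamped")))
    warning(sprintf(
      "exposure targets infeasible for %s/%d given the design; role masses clamped",
      country_id, survey_year))

  n_out <- rbinom(1, n_women, design$outside_age_frac)
  n_in <- n_women - n_out
  age <- c(sample(20:44, n_in, replace = TRUE),
           sample(c(15:19, 45:49), n_out, replace = TRUE))
  grp <- findInterval(age, c(AGE_STARTS, 45L))
  in_window <- age >= 20 & age <= 44

  roles <- rep("not_union", n_women)
  role_names <- names(masses[[1]]$mass)
  for (a in seq_len(5)) {
    idx <- which(in_window & grp == a)
    if (length(idx))
      roles[idx] <- sample(role_names, length(idx), replace = TRUE,
                           prob = masses[[a]]$mass)
  }

  n <- n_women
  rec <- data.frame(
    age_years = age,
    in_union = FALSE,
    years_since_first_union = NA_real_,
    years_in_current_union = NA_real_,
    n_live_births = 0L,
    years_since_first_birth = NA_real_,
    years_since_last_birth = NA_real_,
    current_contraception = FALSE,
    contraception_last_5y = FALSE,
    desire = NA_character_,
    survey_weight = 1.0
  )
  desiring <- function(k) sample(c("wants_child", "undecided", "declared_unable"),
                                 k, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  set_union <- function(i, dur) {
    rec$in_union[i] <<- TRUE
    rec$years_in_current_union[i] <<- dur
    rec$years_since_first_union[i] <<- dur
  }

  i <- which(roles == "prim_inf")
  set_union(i, sample(5:15, length(i), replace = TRUE))
  rec$desire[i] <- desiring(length(i))

  i <- which(roles == "pseudo_prim")          # quit contraception recently
  set_union(i, sample(5:15, length(i), replace = TRUE))
  rec$desire[i] <- desiring(length(i))
  rec$contraception_last_5y[i] <- TRUE

  i <- which(roles == "sec_inf")
  if (length(i)) {
    last <- sample(5:9, length(i), replace = TRUE)
    nb <- sample(1:3, length(i), replace = TRUE)
    first <- last + ifelse(nb > 1, sample(1:6, length(i), replace = TRUE), 0)
    set_union(i, first + sample(0:5, length(i), replace = TRUE))
    rec$n_live_births[i] <- nb
    rec$years_since_last_birth[i] <- last
    rec$years_since_first_birth[i] <- first
    rec$desire[i] <- desiring(length(i))
  }

  i <- which(roles == "pseudo_sec")           # as sec_inf, but past contraception
  if (length(i)) {
    last <- sample(5:9, length(i), replace = TRUE)
    nb <- sample(1:3, length(i), replace = TRUE)
    first <- last + ifelse(nb > 1, sample(1:6, length(i), replace = TRUE), 0)
    set_union(i, first + sample(0:5, length(i), replace = TRUE))
    rec$n_live_births[i] <- nb
    rec$years_since_last_birth[i] <- last
    rec$years_since_first_birth[i] <- first
    rec$desire[i] <- desiring(length(i))
    rec$contraception_last_5y[i] <- TRUE
  }

  i <- which(roles == "sec_fert")             # birth within 5y, first birth >= 5y ago
  if (length(i)) {
    last <- sample(0:4, length(i), replace = TRUE)
    first <- sample(5:12, length(i), replace = TRUE)
    set_union(i, first + sample(0:5, length(i), replace = TRUE))
    rec$n_live_births[i] <- sample(2:4, length(i), replace = TRUE)
    rec$years_since_last_birth[i] <- last
    rec$years_since_first_birth[i] <- first
    rec$desire[i] <- sample(c("wants_no_more", "wants_child"), length(i),
                            replace = TRUE)
    # current users; exposed regardless via the recent-additional-child rule
    user <- runif(length(i)) < design$contra_user_frac
    rec$current_contraception[i[user]] <- TRUE
    rec$contraception_last_5y[i[user]] <- TRUE
  }

  i <- which(roles == "gap_prim")             # remarried, short current union
  if (length(i)) {
    dur <- sample(2:4, length(i), replace = TRUE)
    rec$in_union[i] <- TRUE
    rec$years_in_current_union[i] <- dur
    rec$years_since_first_union[i] <- dur + sample(4:8, length(i), replace = TRUE)
    rec$desire[i] <- desiring(length(i))
  }

  i <- which(roles == "gap_sec")              # remarried, parous, last birth 5+y back
  if (length(i)) {
    dur <- sample(2:4, length(i), replace = TRUE)
    rec$in_union[i] <- TRUE
    rec$years_in_current_union[i] <- dur
    rec$years_since_first_union[i] <- dur + sample(4:8, length(i), replace = TRUE)
    last <- sample(5:9, length(i), replace = TRUE)
    nb <- sample(1:3, length(i), replace = TRUE)
    first <- last + ifelse(nb > 1, sample(1:6, length(i), replace = TRUE), 0)
    rec$n_live_births[i] <- nb
    rec$years_since_last_birth[i] <- last
    rec$years_since_first_birth[i] <- first
    rec$desire[i] <- desiring(length(i))
  }

  i <- which(roles == "extra_parous")         # one child, union too short
  if (length(i)) {
    set_union(i, sample(2:4, length(i), replace = TRUE))
    rec$n_live_births[i] <- 1L
    b <- sample(0:4, length(i), replace = TRUE)
    rec$years_since_last_birth[i] <- b
    rec$years_since_first_birth[i] <- b
    rec$desire[i] <- desiring(length(i))
  }

  i <- which(roles == "extra_nullip")         # no child, union too short
  if (length(i)) {
    set_union(i, sample(1:4, length(i), replace = TRUE))
    rec$desire[i] <- desiring(length(i))
  }

  i <- which(roles == "not_union")
  rec$desire[i] <- sample(c("wants_child", "wants_no_more"), length(i),
                          replace = TRUE)
  if (length(i)) {
    user <- runif(length(i)) < design$contra_user_frac
    rec$current_contraception[i[user]] <- TRUE
    rec$contraception_last_5y[i[user]] <- TRUE
  }
  if (design$ever_married_only && length(i)) {
    # formerly-in-union women: union history present, currently not in union
    rec$years_since_first_union[i] <- sample(1:10, length(i), replace = TRUE)
  }

  if (!design$has_contraceptive_history)
    rec$contraception_last_5y <- NA
  if (!design$has_current_union_duration)
    rec$years_in_current_union <- NA_real_

  structure(list(records = rec,
                 country_id = country_id, survey_year = survey_year,
                 is_national = design$is_national,
                 ever_married_only = design$ever_married_only,
                 has_contraceptive_history = design$has_contraceptive_history,
                 has_current_union_duration = design$has_current_union_duration,
                 design_effect = design$design_effect,
                 truths = truths),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %s %d: %d women (national=%s, full history=%s)\n",
              x$country_id, x$survey_year, nrow(x$records),
              x$is_national, x$has_contraceptive_history))
  invisible(x)
}

#' Write / read a survey dataset as CSV
#'
#' The CSV holds one row per woman; survey-level metadata travel in a
#' sidecar YAML file `<path>.meta.yaml`.
#'
#' @param dataset a `survey_dataset`
#' @param path CSV path
#' @export
write_survey_csv <- function(dataset, path) {
  write.csv(dataset$records, path, row.names = FALSE)
  meta <- dataset[setdiff(names(dataset), c("records", "truths"))]
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  structure(c(list(records = rec), meta), class = "survey_dataset")
}
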