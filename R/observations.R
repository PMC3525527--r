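#' Build one (survey, indicator, age-group) prevalence observation
#'
#' Restricts the survey to the requested five-year age group, classifies
#' the records, and forms the indicator's ratio: infertile unions over
#' infertile plus fertile unions for prevalence indicators, exposed women
#' over women with a determinable status for exposure indicators. The
#' effective sample size is the classified denominator count divided by the
#' survey's design effect.
#'
#' @param dataset a `survey_dataset`
#' @param indicator indicator name
#' @param age_group one of `"[20,25)"` ... `"[40,45)"`
#' @param weighted use survey weights in the ratio (counts stay unweighted)?
#' @param has_full_history use contraception history / current-union
#'   duration when present (`FALSE` forces the biased fallback classifier;
#'   used when building correction training pairs)
#' @return a one-row data.frame observation, or `NULL` (with a message)
#'   when the denominator is empty
#' @export
compute_observation <- function(dataset, indicator, age_group,
                                weighted = FALSE, has_full_history = TRUE) {
  indicator <- match.arg(indicator, INDICATORS)
  stopifnot(age_group %in% age_group_labels())
  rec <- dataset$records
  rec <- rec[!is.na(rec$age_years) &
               age_group_of(rec$age_years) %in% age_group, , drop = FALSE]
  cls <- classify_records(rec, indicator, has_full_history = has_full_history)
  if (indicator %in% c("primary_prev", "secondary_prev")) {
    num_mask <- cls$status == "infertile_union"
    den_mask <- num_mask | cls$status == "fertile_union"
  } else {
    num_mask <- cls$status == "exposed"
    den_mask <- num_mask | cls$status == "not_exposed"
  }
  raw_num <- sum(num_mask)
  raw_den <- sum(den_mask)
  if (raw_den == 0) {
    message(sprintf("empty denominator: %s %s %s %s -- observation omitted",
                    dataset$country_id, dataset$survey_year, indicator, age_group))
    return(NULL)
  }
  value <- if (weighted) {
    sum(rec$survey_weight[num_mask]) / sum(rec$survey_weight[den_mask])
  } else raw_num / raw_den
  is_biased <- indicator %in% c("primary_prev", "secondary_prev") &&
    (!has_full_history ||
       !isTRUE(dataset$has_contraceptive_history) ||
       !isTRUE(dataset$has_current_union_duration))
  data.frame(
    indicator = indicator,
    country_id = dataset$country_id,
    survey_year = dataset$survey_year,
    age_group = age_group,
    value = value,
    effective_n = raw_den / dataset$design_effect,
    is_national = isTRUE(dataset$is_national),
    is_biased = is_biased,
    raw_numerator = raw_num,
    raw_denominator = raw_den,
    # contraceptive-use prevalence in the age group: a regressor of the
    # secondary-infertility correction model
    contra_prev = mean(rec$current_contraception, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Screen a survey for use with an indicator
#'
#' A survey is excluded for an indicator when the share of its respondents
#' aged 20--44 with missing information on the indicator's decision path
#' strictly exceeds 15%. Ever-married-only samples contribute exposure
#' observations only for ages 30 and over (younger never-married women are
#' unobserved in such samples). Surveys from countries carrying the
#' `china_rule` flag yield no secondary-infertility observations.
#'
#' @param dataset a `survey_dataset`
#' @param indicator indicator name
#' @param hierarchy optional `hierarchy` supplying the `china_rule` flag
#' @param missing_threshold exclusion threshold on the missingness share
#' @return list with `decision` (`"included"`/`"excluded"`), `reason`, and
#'   `age_mask`, a named logical vector over the five age groups
#' @export
screen_survey <- function(dataset, indicator, hierarchy = NULL,
                          missing_threshold = 0.15) {
  indicator <- match.arg(indicator, INDICATORS)
  age_mask <- setNames(rep(TRUE, 5L), age_group_labels())
  if (!is.null(hierarchy) && indicator == "secondary_prev") {
    row <- match(dataset$country_id, hierarchy$country_id)
    if (!is.na(row) && isTRUE(hierarchy$china_rule[row]))
      return(list(decision = "excluded", reason = "china_rule",
                  age_mask = age_mask & FALSE))
  }
  rec <- dataset$records
  rec <- rec[!is.na(age_group_of(rec$age_years)), , drop = FALSE]
  if (nrow(rec) > 0) {
    cls <- classify_records(rec, indicator, has_full_history = TRUE)
    miss_share <- mean(cls$status == "excluded" &
                         cls$reason == "missing_data", na.rm = TRUE)
    if (miss_share > missing_threshold)
      return(list(decision = "excluded", reason = "missingness_over_15pct",
                  age_mask = age_mask & FALSE))
  }
  if (isTRUE(dataset$ever_married_only) &&
      indicator %in% c("primary_exposure", "secondary_exposure")) {
    age_mask[AGE_STARTS < 30] <- FALSE
  }
  list(decision = "included", reason = NA_character_, age_mask = age_mask)
}

#' Extract all usable observations from a collection of surveys
#'
#' Applies [screen_survey()] and [compute_observation()] over every
#' (survey, indicator, age group) combination.
#'
#' @param datasets a list of `survey_dataset` objects
#' @param hierarchy optional `hierarchy` (for the china rule)
#' @param indicators indicators to extract
#' @param weighted passed to [compute_observation()]
#' @return a data.frame of observations with a `screening_log` attribute
#' @export
extract_observations <- function(datasets, hierarchy = NULL,
                                 indicators = INDICATORS, weighted = FALSE) {
  if (inherits(datasets, "survey_dataset")) datasets <- list(datasets)
  obs <- list(); log <- list()
  for (ds in datasets) {
    for (ind in indicators) {
      scr <- screen_survey(ds, ind, hierarchy)
      log[[length(log) + 1L]] <- data.frame(
        country_id = ds$country_id, survey_year = ds$survey_year,
        indicator = ind, decision = scr$decision,
        reason = scr$reason, stringsAsFactors = FALSE)
      if (scr$decision == "excluded") next
      for (ag in names(scr$age_mask)[scr$age_mask]) {
        o <- compute_observation(ds, ind, ag, weighted = weighted)
        if (!is.null(o)) obs[[length(obs) + 1L]] <- o
      }
    }
  }
  out <- if (length(obs)) do.call(rbind, obs) else NULL
  attr(out, "screening_log") <- do.call(rbind, log)
  out
}

#' Write an observation table (and its screening log) as CSV
#' @param observations observation data.frame from [extract_observations()]
#' @param path CSV path; the screening log goes to `<path>.screening.csv`
#'   when present
#' @export
write_observations_csv <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE)
  log <- attr(observations, "screening_log")
  if (!is.null(log))
    write.csv(log, paste0(path, ".screening.csv"), row.names = FALSE)
  invisible(path)
}
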