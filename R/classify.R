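#' Classify survey respondents for an indicator
#'
#' Deterministic, vectorized implementation of the woman-level decision
#' algorithms. For the two prevalence indicators each record is assigned
#' exactly one of `infertile_union` / `fertile_union` / `excluded` (with a
#' reason); for the two exposure indicators, `exposed` / `not_exposed` /
#' `excluded(missing_data)`.
#'
#' Definitions (women undecided about, or declaring themselves unable to
#' have, a(nother) child count as desiring one):
#' * primary infertile union: no live birth, desires a child, in a union of
#'   at least five years during which no contraceptives were used;
#' * primary fertile union: at least one live birth and at least five years
#'   in the union;
#' * secondary infertile union: at least one live birth, desires another
#'   child, at least five contraception-free years in union since the last
#'   live birth;
#' * secondary fertile union: a live birth within the past five years and at
#'   least five years in union following the first birth;
#' * exposed to primary: in a union and either (not currently contracepting
#'   and desiring a child) or having had at least one live birth;
#' * exposed to secondary: in a union and either (at least one live birth,
#'   not currently contracepting, desiring another child) or (a second or
#'   later child born within the past five years).
#'
#' When `has_full_history` is `FALSE`, contraceptive use over the last five
#' years is proxied by current use and the union clock by time since first
#' union, regardless of whether the richer fields are present — the biased
#' estimator that the correction module adjusts. When `TRUE`, the richer
#' fields are used where present, with the same fallbacks where absent.
#'
#' @param records data.frame of woman records (see [generate_survey()] for
#'   the column dictionary)
#' @param indicator one of `"primary_prev"`, `"secondary_prev"`,
#'   `"primary_exposure"`, `"secondary_exposure"`
#' @param has_full_history use five-year contraception history and
#'   current-union duration when available?
#' @return data.frame with columns `status` and `reason` (`NA` unless
#'   excluded), one row per record
#' @export
classify_records <- function(records, indicator, has_full_history = TRUE) {
  indicator <- match.arg(indicator, INDICATORS)
  n <- nrow(records)
  desires <- records$desire %in% c("wants_child", "undecided", "declared_unable")
  desires[is.na(records$desire)] <- NA

  if (has_full_history) {
    dur <- ifelse(!is.na(records$years_in_current_union),
                  records$years_in_current_union,
                  records$years_since_first_union)
    contra5 <- ifelse(!is.na(records$contraception_last_5y),
                      records$contraception_last_5y,
                      records$current_contraception)
  } else {
    dur <- records$years_since_first_union
    contra5 <- records$current_contraception
  }
  parous <- records$n_live_births >= 1L
  yslb <- records$years_since_last_birth
  ysfb <- records$years_since_first_birth

  status <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  exclude <- function(cond, why) {
    hit <- is.na(status) & cond & !is.na(cond)
    status[hit] <<- "excluded"; reason[hit] <<- why
  }
  assign_left <- function(cond, what) {
    hit <- is.na(status) & cond & !is.na(cond)
    status[hit] <<- what
  }

  if (indicator == "primary_prev") {
    exclude(is.na(records$in_union), "missing_data")
    exclude(!records$in_union, "not_in_union")
    exclude(is.na(dur), "missing_data")
    assign_left(parous & dur >= 5, "fertile_union")
    exclude(parous, "insufficient_exposure")     # parous, short union
    exclude(dur < 5, "insufficient_exposure")
    exclude(is.na(desires), "missing_data")
    exclude(!desires, "no_desire")
    exclude(is.na(contra5), "missing_data")
    exclude(contra5, "used_contraception")
    assign_left(TRUE, "infertile_union")
  } else if (indicator == "secondary_prev") {
    exclude(is.na(records$in_union), "missing_data")
    exclude(!records$in_union, "not_in_union")
    exclude(!parous, "nulliparous")
    exclude(is.na(dur) | is.na(yslb), "missing_data")
    assign_left(yslb < 5 & ysfb >= 5 & dur >= 5, "fertile_union")
    exclude(yslb < 5 & dur >= 5 & is.na(ysfb), "missing_data")
    exclude(yslb < 5 | dur < 5, "insufficient_exposure")
    # remaining: yslb >= 5 and dur >= 5 -- the infertile-union path
    exclude(is.na(desires), "missing_data")
    exclude(!desires, "no_desire")
    exclude(is.na(contra5), "missing_data")
    exclude(contra5, "used_contraception")
    assign_left(TRUE, "infertile_union")
  } else if (indicator == "primary_exposure") {
    exclude(is.na(records$in_union), "missing_data")
    assign_left(!records$in_union, "not_exposed")
    assign_left(parous, "exposed")               # in union, has a child
    exclude(is.na(records$current_contraception), "missing_data")
    assign_left(records$current_contraception, "not_exposed")
    exclude(is.na(desires), "missing_data")
    assign_left(desires, "exposed")
    assign_left(TRUE, "not_exposed")
  } else {                                       # secondary_exposure
    exclude(is.na(records$in_union), "missing_data")
    assign_left(!records$in_union, "not_exposed")
    assign_left(!parous, "not_exposed")
    assign_left(records$n_live_births >= 2L & !is.na(yslb) & yslb < 5,
                "exposed")                       # an additional child in past 5y
    exclude(is.na(records$current_contraception), "missing_data")
    assign_left(records$current_contraception, "not_exposed")
    exclude(is.na(desires), "missing_data")
    assign_left(desires, "exposed")
    assign_left(TRUE, "not_exposed")
  }
  data.frame(status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Classify a single woman record
#'
#' Scalar wrapper around [classify_records()].
#'
#' @param record a one-row data.frame or a named list of woman fields
#' @inheritParams classify_records
#' @return a list with `status` and `exclusion_reason`
#' @export
classify_woman <- function(record, indicator, has_full_history = TRUE) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  out <- classify_records(record, indicator, has_full_history)
  list(status = out$status[1], exclusion_reason = out$reason[1])
}
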