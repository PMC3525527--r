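# Independent brute-force classification oracle: a literal, one-record
# transcription of the indicator definitions, written without reference to
# the package's vectorized decision waterfall. Returns only the status;
# exclusion reasons are not part of the contract it checks.

oracle_classify <- function(r, indicator, full = TRUE) {
  getv <- function(x) if (is.null(x) || length(x) == 0) NA else x
  in_union <- getv(r$in_union)
  desire <- getv(r$desire)
  wants <- if (is.na(desire)) NA else
    desire %in% c("wants_child", "undecided", "declared_unable")
  births <- getv(r$n_live_births)
  cur_dur <- getv(r$years_in_current_union)
  first_dur <- getv(r$years_since_first_union)
  union_years <- if (full && !is.na(cur_dur)) cur_dur else first_dur
  c5 <- getv(r$contraception_last_5y)
  cnow <- getv(r$current_contraception)
  contra5 <- if (full && !is.na(c5)) c5 else cnow
  yslb <- getv(r$years_since_last_birth)
  ysfb <- getv(r$years_since_first_birth)

  known <- function(...) all(!is.na(c(...)))

  if (indicator == "primary_prev") {
    if (is.na(in_union)) return("excluded")
    # infertile: no live birth, desires a child, union >= 5y, no contraception
    if (known(in_union, union_years, births, wants, contra5) &&
        in_union && union_years >= 5 && births == 0 && wants && !contra5)
      return("infertile_union")
    # fertile: >= 1 live birth and >= 5y in the union
    if (known(in_union, union_years, births) &&
        in_union && union_years >= 5 && births >= 1)
      return("fertile_union")
    return("excluded")
  }
  if (indicator == "secondary_prev") {
    if (is.na(in_union)) return("excluded")
    # infertile: a birth, desires another, >= 5 contraception-free union
    # years since the last live birth
    if (known(in_union, births, yslb, union_years, wants, contra5) &&
        in_union && births >= 1 && yslb >= 5 && union_years >= 5 &&
        wants && !contra5)
      return("infertile_union")
    # fertile: a birth within 5y and >= 5 union years after the first birth
    if (known(in_union, births, yslb, ysfb, union_years) &&
        in_union && births >= 1 && yslb < 5 && ysfb >= 5 && union_years >= 5)
      return("fertile_union")
    return("excluded")
  }
  if (indicator == "primary_exposure") {
    if (is.na(in_union)) return("excluded")
    if (!in_union) return("not_exposed")
    if (!is.na(births) && births >= 1) return("exposed")
    if (is.na(cnow)) return("excluded")
    if (!cnow) {
      if (is.na(wants)) return("excluded")
      if (wants) return("exposed")
    }
    return("not_exposed")
  }
  if (indicator == "secondary_exposure") {
    if (is.na(in_union)) return("excluded")
    if (!in_union) return("not_exposed")
    if (is.na(births) || births == 0) return("not_exposed")
    if (births >= 2 && !is.na(yslb) && yslb < 5) return("exposed")
    if (is.na(cnow)) return("excluded")
    if (!cnow) {
      if (is.na(wants)) return("excluded")
      if (wants) return("exposed")
    }
    return("not_exposed")
  }
  stop("unknown indicator")
}

# Random woman records exercising every missing-data pattern.
random_records <- function(n, seed) {
  set.seed(seed)
  maybe <- function(x, p_na = 0.1) ifelse(runif(n) < p_na, NA, x)
  births <- sample(0:4, n, replace = TRUE)
  first_union <- maybe(sample(0:20, n, replace = TRUE), 0.15)
  cur <- pmin(sample(0:20, n, replace = TRUE), first_union)
  yslb <- ifelse(births >= 1, sample(0:12, n, replace = TRUE), NA)
  ysfb <- ifelse(births >= 1, yslb + ifelse(births > 1,
                                            sample(0:6, n, replace = TRUE), 0), NA)
  data.frame(
    age_years = sample(20:44, n, replace = TRUE),
    in_union = maybe(runif(n) < 0.7, 0.05),
    years_since_first_union = first_union,
    years_in_current_union = maybe(cur, 0.3),
    n_live_births = births,
    years_since_first_birth = ysfb,
    years_since_last_birth = yslb,
    current_contraception = maybe(runif(n) < 0.3, 0.05),
    contraception_last_5y = maybe(runif(n) < 0.4, 0.3),
    desire = maybe(sample(c("wants_child", "undecided", "declared_unable",
                            "wants_no_more"), n, replace = TRUE), 0.1),
    survey_weight = 1,
    stringsAsFactors = FALSE
  )
}
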