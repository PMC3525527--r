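woman <- function(...) {
  base <- list(age_years = 30L, in_union = TRUE,
               years_since_first_union = NA_real_,
               years_in_current_union = NA_real_,
               n_live_births = 0L,
               years_since_first_birth = NA_real_,
               years_since_last_birth = NA_real_,
               current_contraception = FALSE,
               contraception_last_5y = FALSE,
               desire = "wants_child", survey_weight = 1)
  mod <- list(...)
  base[names(mod)] <- mod
  as.data.frame(base, stringsAsFactors = FALSE)
}

test_that("classify_woman applies the printed definitions", {
  # primary: 6y union, no contraception, desires, no birth -> infertile
  r <- woman(years_in_current_union = 6, years_since_first_union = 6)
  expect_equal(classify_woman(r, "primary_prev")$status, "infertile_union")
  # one birth in a >= 5y union -> fertile
  r <- woman(years_in_current_union = 6, years_since_first_union = 6,
             n_live_births = 1L, years_since_first_birth = 4,
             years_since_last_birth = 4)
  expect_equal(classify_woman(r, "primary_prev")$status, "fertile_union")
  # 3y union, no birth -> excluded (insufficient exposure)
  r <- woman(years_in_current_union = 3, years_since_first_union = 3)
  out <- classify_woman(r, "primary_prev")
  expect_equal(out$status, "excluded")
  expect_equal(out$exclusion_reason, "insufficient_exposure")
  # undecided counts as desiring; wants_no_more does not
  r <- woman(years_in_current_union = 7, years_since_first_union = 7,
             desire = "undecided")
  expect_equal(classify_woman(r, "primary_prev")$status, "infertile_union")
  r$desire <- "wants_no_more"
  expect_equal(classify_woman(r, "primary_prev")$exclusion_reason, "no_desire")
  # contraception within the window excludes from the infertile numerator
  r <- woman(years_in_current_union = 7, years_since_first_union = 7,
             contraception_last_5y = TRUE)
  expect_equal(classify_woman(r, "primary_prev")$exclusion_reason,
               "used_contraception")
  # missing decision-path field -> missing_data
  r <- woman(years_in_current_union = 7, years_since_first_union = 7,
             desire = NA_character_)
  expect_equal(classify_woman(r, "primary_prev")$exclusion_reason,
               "missing_data")

  # secondary: infertile clock anchored on the last birth
  r <- woman(years_in_current_union = 9, years_since_first_union = 9,
             n_live_births = 1L, years_since_first_birth = 6,
             years_since_last_birth = 6)
  expect_equal(classify_woman(r, "secondary_prev")$status, "infertile_union")
  # fertile: birth in past 5y and >= 5y union after the first birth
  r <- woman(years_in_current_union = 9, years_since_first_union = 9,
             n_live_births = 2L, years_since_first_birth = 7,
             years_since_last_birth = 2)
  expect_equal(classify_woman(r, "secondary_prev")$status, "fertile_union")
  # nulliparous women never enter secondary prevalence
  r <- woman(years_in_current_union = 9, years_since_first_union = 9)
  expect_equal(classify_woman(r, "secondary_prev")$exclusion_reason,
               "nulliparous")

  # exposure to primary: parous in-union women count regardless of desire
  r <- woman(n_live_births = 1L, years_since_first_birth = 2,
             years_since_last_birth = 2, desire = "wants_no_more",
             current_contraception = TRUE)
  expect_equal(classify_woman(r, "primary_exposure")$status, "exposed")
  r <- woman(in_union = FALSE)
  expect_equal(classify_woman(r, "primary_exposure")$status, "not_exposed")

  # exposure to secondary: second child within 5y counts even when
  # contracepting now
  r <- woman(n_live_births = 2L, years_since_first_birth = 6,
             years_since_last_birth = 3, current_contraception = TRUE,
             desire = "wants_no_more")
  expect_equal(classify_woman(r, "secondary_exposure")$status, "exposed")
  r <- woman(desire = "wants_child")   # nulliparous
  expect_equal(classify_woman(r, "secondary_exposure")$status, "not_exposed")

  expect_error(classify_woman(woman(), "nonsense"))
})

test_that("the biased fallback ignores history fields", {
  # quit contraception recently: full history excludes, current status
  # calls her infertile
  r <- woman(years_in_current_union = 8, years_since_first_union = 8,
             contraception_last_5y = TRUE, current_contraception = FALSE)
  expect_equal(classify_woman(r, "primary_prev", TRUE)$status, "excluded")
  expect_equal(classify_woman(r, "primary_prev", FALSE)$status,
               "infertile_union")
  # remarriage gap: first-union clock reaches 5y, current union does not
  r <- woman(years_in_current_union = 3, years_since_first_union = 9)
  expect_equal(classify_woman(r, "primary_prev", TRUE)$status, "excluded")
  expect_equal(classify_woman(r, "primary_prev", FALSE)$status,
               "infertile_union")
})

test_that("classification agrees exactly with the brute-force oracle", {
  for (ind in c("primary_prev", "secondary_prev",
                "primary_exposure", "secondary_exposure")) {
    rec <- random_records(1000, seed = match(ind, c(
      "primary_prev", "secondary_prev", "primary_exposure",
      "secondary_exposure")))
    for (full in c(TRUE, FALSE)) {
      got <- classify_records(rec, ind, has_full_history = full)$status
      want <- vapply(seq_len(nrow(rec)), function(i)
        oracle_classify(as.list(rec[i, ]), ind, full), character(1))
      expect_identical(got, want, label = paste(ind, "full =", full))
    }
  }
})

test_that("classification is a partition and order-invariant", {
  rec <- random_records(500, seed = 42)
  for (ind in c("primary_prev", "secondary_prev")) {
    cls <- classify_records(rec, ind)
    expect_true(all(cls$status %in%
                      c("infertile_union", "fertile_union", "excluded")))
    expect_false(anyNA(cls$status))
    expect_true(all(is.na(cls$reason) == (cls$status != "excluded")))
    # permutation invariance
    perm <- sample(nrow(rec))
    cls_p <- classify_records(rec[perm, ], ind)
    expect_identical(cls_p$status, cls$status[perm])
  }
})

test_that("compute_observation forms the printed ratio", {
  inf <- woman(years_in_current_union = 7, years_since_first_union = 7)
  fert <- woman(years_in_current_union = 7, years_since_first_union = 7,
                n_live_births = 1L, years_since_first_birth = 3,
                years_since_last_birth = 3)
  mk <- function(records, design_effect = 1) {
    structure(list(records = records, country_id = "X", survey_year = 2000,
                   is_national = TRUE, ever_married_only = FALSE,
                   has_contraceptive_history = TRUE,
                   has_current_union_duration = TRUE,
                   design_effect = design_effect),
              class = "survey_dataset")
  }
  rec <- do.call(rbind, c(replicate(2, inf, simplify = FALSE),
                          replicate(98, fert, simplify = FALSE)))
  o <- compute_observation(mk(rec), "primary_prev", "[30,35)")
  expect_equal(o$value, 0.02)
  expect_equal(o$raw_denominator, 100L)
  expect_equal(o$raw_numerator, 2L)

  rec0 <- do.call(rbind, replicate(50, fert, simplify = FALSE))
  o0 <- compute_observation(mk(rec0), "primary_prev", "[30,35)")
  expect_equal(o0$value, 0)

  # effective sample size divides by the design effect
  ode <- compute_observation(mk(rec, design_effect = 2), "primary_prev",
                             "[30,35)")
  expect_equal(ode$effective_n, 50)

  # empty denominator -> omitted, never 0/0
  none <- woman(in_union = FALSE)
  expect_message(
    out <- compute_observation(mk(none), "primary_prev", "[30,35)"),
    "omitted")
  expect_null(out)

  # monotonicity: an extra infertile union never lowers the value,
  # an extra fertile union never raises it
  o_plus_inf <- compute_observation(mk(rbind(rec, inf)), "primary_prev",
                                    "[30,35)")
  o_plus_fert <- compute_observation(mk(rbind(rec, fert)), "primary_prev",
                                     "[30,35)")
  expect_gte(o_plus_inf$value, o$value)
  expect_lte(o_plus_fert$value, o$value)
})

test_that("effective sample size matches clustered-sample information", {
  # a design effect of 2 halves the information: the binomial variance at
  # n/deff matches the variance of a cluster-correlated sample (oracle:
  # simulate clusters sized m with intra-cluster correlation chosen so
  # deff = 1 + (m-1)*icc = 2)
  set.seed(99)
  m <- 5; icc <- 0.25; p <- 0.3; n_clusters <- 60
  reps <- 4000
  phat <- replicate(reps, {
    cluster_p <- ifelse(runif(n_clusters) < icc, NA, p)  # shared vs indep
    draws <- vapply(cluster_p, function(cp) {
      if (is.na(cp)) { shared <- runif(1) < p; rep(shared, m) }
      else runif(m) < cp
    }, logical(m))
    mean(draws)
  })
  n <- n_clusters * m
  expect_equal(var(phat), p * (1 - p) / (n / 2), tolerance = 0.15)
})

test_that("screen_survey enforces the missingness and design rules", {
  surf <- tiny_surface()
  h <- tiny_hierarchy()
  ok <- generate_survey(surf, h$country_id[1], 2000, 800, seed = 20)
  expect_equal(screen_survey(ok, "primary_prev")$decision, "included")

  # plant missingness: desire NA for a controlled share of in-window women
  poke_missing <- function(ds, share) {
    rec <- ds$records
    idx <- which(!is.na(age_group_of(rec$age_years)))
    cls <- classify_records(rec[idx, ], "primary_exposure")
    determ <- idx[cls$status != "excluded"]
    k <- ceiling(share * length(idx))
    rec$in_union[determ[seq_len(k)]] <- NA
    ds$records <- rec
    ds
  }
  high <- poke_missing(ok, 0.17)
  expect_equal(screen_survey(high, "primary_exposure")$decision, "excluded")
  expect_equal(screen_survey(high, "primary_exposure")$reason,
               "missingness_over_15pct")

  # ever-married-only surveys: exposure usable only at 30+
  em <- generate_survey(surf, h$country_id[2], 2000, 800,
                        design = survey_design(ever_married_only = TRUE),
                        seed = 21)
  mask <- screen_survey(em, "primary_exposure")$age_mask
  expect_equal(unname(mask), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # prevalence indicators keep all ages
  expect_true(all(screen_survey(em, "primary_prev")$age_mask))

  # china rule: no secondary-infertility observations
  hc <- generate_hierarchy(2, 2, 2, seed = 1, china_country = "R01.S01.C01")
  sc <- generate_true_surface(hc, seed = 3)
  cn <- generate_survey(sc, "R01.S01.C01", 2000, 400, seed = 22)
  expect_equal(screen_survey(cn, "secondary_prev", hc)$decision, "excluded")
  expect_equal(screen_survey(cn, "secondary_prev", hc)$reason, "china_rule")
  expect_equal(screen_survey(cn, "primary_prev", hc)$decision, "included")
})

test_that("the 15% screen uses a strict inequality", {
  # exactly 15% missing stays in; just over drops out
  base <- woman(years_in_current_union = 7, years_since_first_union = 7)
  rec <- do.call(rbind, replicate(100, base, simplify = FALSE))
  rec$in_union[1:15] <- NA
  ds <- structure(list(records = rec, country_id = "X", survey_year = 2000,
                       is_national = TRUE, ever_married_only = FALSE,
                       has_contraceptive_history = TRUE,
                       has_current_union_duration = TRUE, design_effect = 1),
                  class = "survey_dataset")
  expect_equal(screen_survey(ds, "primary_prev")$decision, "included")
  rec$in_union[16] <- NA
  ds$records <- rec
  expect_equal(screen_survey(ds, "primary_prev")$decision, "excluded")
})
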