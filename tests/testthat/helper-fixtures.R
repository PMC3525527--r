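# Shared fixtures, built once per test run.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, envir = cache)) assign(name, build(), envir = cache)
    get(name, envir = cache)
  }
})

tiny_hierarchy <- function() fx("tiny_h", function()
  generate_hierarchy(2, 2, 2, seed = 1))

tiny_context <- function() fx("tiny_ctx", function()
  generate_context(tiny_hierarchy(), seed = 2))

tiny_surface <- function() fx("tiny_surf", function()
  generate_true_surface(tiny_hierarchy(), seed = 3, context = tiny_context()))

# fast MCMC settings for structural tests (not for calibration claims)
fast_mcmc <- list(n_retained = 400, n_chains = 2, n_warmup = 200)

age_labels <- c("[20,25)", "[25,30)", "[30,35)", "[35,40)", "[40,45)")

# Direct observation rows at the truth with enormous denominators:
# effectively noise-free data for degenerate model/CV cases.
noise_free_obs <- function(surface, countries, years,
                           indicators = "primary_prev") {
  rows <- list()
  for (cid in countries) for (yr in years) for (ind in indicators) {
    sel <- surface$indicator == ind & surface$country_id == cid &
      surface$year == yr
    rows[[length(rows) + 1L]] <- data.frame(
      indicator = ind, country_id = cid, survey_year = yr,
      age_group = surface$age_group[sel],
      value = surface$true_value[sel], effective_n = 1e6,
      is_national = TRUE, is_biased = FALSE,
      raw_numerator = round(surface$true_value[sel] * 1e6),
      raw_denominator = 1e6, contra_prev = 0.3, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
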