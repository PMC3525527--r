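#' Generate a nested geographic hierarchy
#'
#' Builds a country -> subregion -> region mapping of the kind used to pool
#' survey information across space: countries nest in subregions, subregions
#' in regions, regions in a single global level. Exactly one region is
#' flagged as High Income (it carries its own age pattern of exposure to
#' primary infertility in the hierarchical model), unless the hierarchy has
#' a single region, in which case that region is the High-Income one.
#'
#' @param n_regions number of regions (>= 1)
#' @param n_subregions_per_region subregions nested in each region (>= 1)
#' @param n_countries_per_subregion countries nested in each subregion (>= 1)
#' @param seed integer seed; labels and the High-Income draw are
#'   deterministic in it
#' @param china_country optional country id to flag with the `china_rule`
#'   (no secondary-infertility observations or aggregates for it)
#' @return a `hierarchy` object: a data.frame with columns `country_id`,
#'   `subregion_id`, `region_id`, `is_high_income`, `china_rule`
#' @export
generate_hierarchy <- function(n_regions, n_subregions_per_region,
                               n_countries_per_subregion, seed = 1L,
                               china_country = NULL) {
  counts <- c(n_regions, n_subregions_per_region, n_countries_per_subregion)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("all hierarchy counts must be positive integers")
  withr_seed(seed)
  regions <- sprintf("R%02d", seq_len(n_regions))
  hi_region <- if (n_regions == 1) regions else sample(regions, 1L)
  rows <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
    do.call(rbind, lapply(seq_len(n_subregions_per_region), function(s) {
      sub <- sprintf("%s.S%02d", regions[r], s)
      data.frame(
        country_id = sprintf("%s.C%02d", sub, seq_len(n_countries_per_subregion)),
        subregion_id = sub,
        region_id = regions[r],
        stringsAsFactors = FALSE
      )
    }))
  }))
  rows$is_high_income <- rows$region_id == hi_region
  rows$china_rule <- FALSE
  if (!is.null(china_country)) {
    if (!china_country %in% rows$country_id)
      stop("china_country not in the generated hierarchy")
    rows$china_rule <- rows$country_id == china_country
  }
  class(rows) <- c("hierarchy", "data.frame")
  rows
}

#' @export
print.hierarchy <- function(x, ...) {
  cat(sprintf("<hierarchy> %d countries / %d subregions / %d regions (High Income: %s)\n",
              nrow(x), length(unique(x$subregion_id)),
              length(unique(x$region_id)),
              unique(x$region_id[x$is_high_income])))
  invisible(x)
}

validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  # one parent per unit at every level
  sub_parent <- unique(h[, c("subregion_id", "region_id")])
  if (anyDuplicated(sub_parent$subregion_id))
    stop("a subregion maps to more than one region")
  if (anyDuplicated(h$country_id))
    stop("a country appears more than once")
  invisible(h)
}

# Local, restorable RNG seeding so generators never disturb the caller's
# RNG stream.
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Write / read a hierarchy as YAML
#'
#' @param h a `hierarchy`
#' @param path file path
#' @return `read_hierarchy_yaml` returns a `hierarchy`
#' @export
write_hierarchy_yaml <- function(h, path) {
  validate_hierarchy(h)
  yaml::write_yaml(lapply(seq_len(nrow(h)), function(i) as.list(h[i, ])), path)
  invisible(path)
}

#' @rdname write_hierarchy_yaml
#' @export
read_hierarchy_yaml <- function(path) {
  rows <- yaml::read_yaml(path)
  h <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  class(h) <- c("hierarchy", "data.frame")
  validate_hierarchy(h)
}
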