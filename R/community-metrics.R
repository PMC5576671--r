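# Univariate community responses per transect: density, species richness,
# Shannon diversity, and the square-root + z-score transform applied to all
# responses before mixed-model analysis.

#' Shannon diversity index
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} over species with positive abundance, where
#' \eqn{p_i} is the relative abundance. Natural logarithm (nats), matching
#' the convention of community-ecology software.
#'
#' @param abundances nonnegative numeric vector.
#' @return H' in nats.
#' @examples
#' shannon(c(1, 1, 1, 1)) # log(4)
#' @export
shannon <- function(abundances) {
  stopifnot(is.numeric(abundances), all(abundances >= 0))
  total <- sum(abundances)
  if (total == 0) stop("Shannon index undefined for an all-zero abundance vector")
  p <- abundances[abundances > 0] / total
  -sum(p * log(p))
}

#' Species richness
#'
#' Number of species with positive abundance.
#'
#' @param abundances nonnegative numeric vector.
#' @return integer count.
#' @export
richness <- function(abundances) {
  stopifnot(is.numeric(abundances), all(abundances >= 0))
  sum(abundances > 0)
}

#' Square-root transform and z-standardize a response
#'
#' Fish densities are square-root transformed towards normality; all
#' responses are then standardized (mean subtracted, divided by the standard
#' deviation) over the whole vector jointly — not per group — so that model
#' coefficients are comparable across responses.
#'
#' @param values numeric vector.
#' @param transform `"sqrt"` or `"none"`.
#' @return numeric vector with attributes `transform_tag` (`"sqrt+z"` or
#'   `"z"`), `center` and `scale`.
#' @export
transform_standardize <- function(values, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(values))
  if (transform == "sqrt") {
    if (any(values < 0)) stop("square-root transform requires nonnegative values")
    values <- sqrt(values)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance response")
  m <- mean(values)
  structure((values - m) / s,
            transform_tag = if (transform == "sqrt") "sqrt+z" else "z",
            center = m, scale = s)
}

#' Per-transect univariate responses
#'
#' Builds the tidy response table for the univariate mixed models: total,
#' juvenile, subadult and adult fish density (per 100 m^2), species richness
#' and Shannon index for every transect, together with its mean seagrass
#' cover.
#'
#' @param survey a [seagrass_survey()].
#' @param rules optional [age_class_rules()]; defaults to rules derived from
#'   the survey's species table.
#' @return data.frame with one row per transect: site, management, season,
#'   transect, mean_cover_pct, total_density, juvenile_density,
#'   subadult_density, adult_density, richness, shannon.
#' @export
transect_responses <- function(survey, rules = NULL) {
  if (is.null(rules)) {
    if (is.null(survey$species_table))
      stop("age-class rules required (no species table in survey)")
    rules <- age_class_rules(survey$species_table)
  }
  total <- aggregate_density(survey, level = "transect")
  out <- total$samples[c("site", "management", "season", "transect")]
  cov <- transect_cover(survey)
  key <- function(d) paste(d$site, d$season, d$transect, sep = ".")
  out$mean_cover_pct <- cov$mean_cover_pct[match(key(out), key(cov))]
  out$total_density <- rowSums(total$values)
  for (cls in AGE_CLASSES) {
    dt <- aggregate_density(survey, level = "transect", age_class = cls,
                            rules = rules)
    out[[paste0(cls, "_density")]] <- rowSums(dt$values)
  }
  out$richness <- apply(total$values, 1, richness)
  out$shannon <- apply(total$values, 1, function(a)
    if (sum(a) == 0) NA_real_ else shannon(a))
  out
}

#' Transform a response table for model fitting
#'
#' Applies the modelling transform to a [transect_responses()] table:
#' density columns are square-root transformed and z-standardized, diversity
#' indices and mean cover are z-standardized, each over the whole survey
#' jointly. Grouping columns are untouched.
#'
#' @param responses a [transect_responses()] table.
#' @return the table with transformed numeric response columns.
#' @export
standardized_responses <- function(responses) {
  for (col in names(responses)) {
    if (!is.numeric(responses[[col]])) next
    tr <- if (grepl("_density$", col)) "sqrt" else "none"
    v <- responses[[col]]
    ok <- !is.na(v)
    v[ok] <- as.vector(transform_standardize(v[ok], tr))
    responses[[col]] <- v
  }
  responses
}
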