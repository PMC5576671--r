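# Species-density synchrony: the slope of every species pair's site-level
# densities within each management level, and the paired comparison of mean
# slopes between managements. Synchronous (positive) covariance outside MPAs
# is the signature of an unselective seasonal driver such as fishing;
# neutral or negative covariance (compensatory dynamics) stabilizes the
# aggregate community.

#' Per-pair density slopes within a management level
#'
#' For every unordered pair of the shared species set (species observed in
#' both management levels), the slope of the alphabetically later species'
#' density on the earlier one, over that management level's site x season
#' points (site-level mean densities). Each pair is fitted as a mixed model
#' with a site random intercept; when that fit is singular or fails (common
#' with few sites) it falls back to ordinary least squares, tagged. Pairs
#' whose predictor has zero variance are excluded and listed in the
#' `excluded` attribute. Optionally the Pearson correlation is computed
#' instead of the regression slope.
#'
#' @param site_densities a site-level, mean-aggregated [aggregate_density()]
#'   table covering both management levels.
#' @param management `"MPA"` or `"open"`: which level to compute.
#' @param shared_species optional character vector overriding the shared
#'   species set.
#' @param statistic `"slope"` (regression slope, default) or `"correlation"`
#'   (Pearson r; symmetric in the pair).
#' @param method `"auto"` (mixed model with OLS fallback) or `"ols"`.
#' @return data.frame of class `"pair_slope_table"`: `species_i, species_j,
#'   management, slope, n, fit_tag`; attribute `excluded`.
#' @export
pairwise_slopes <- function(site_densities, management,
                            shared_species = NULL,
                            statistic = c("slope", "correlation"),
                            method = c("auto", "ols")) {
  statistic <- match.arg(statistic); method <- match.arg(method)
  stopifnot(inherits(site_densities, "density_table"),
            site_densities$level == "site")
  samples <- site_densities$samples
  if (is.null(shared_species)) {
    seen <- function(mg) {
      rows <- samples$management == mg
      site_densities$species[colSums(site_densities$values[rows, , drop = FALSE]) > 0]
    }
    shared_species <- intersect(seen("MPA"), seen("open"))
  }
  if (length(shared_species) < 2)
    stop("fewer than 2 species shared between management levels")
  shared_species <- sort(shared_species)

  rows <- samples$management == management
  if (sum(rows) < 2) stop("fewer than 2 site x season points in ", management)
  vals <- site_densities$values[rows, shared_species, drop = FALSE]
  site <- samples$site[rows]

  out <- list(); excluded <- character(0)
  pairs <- utils::combn(shared_species, 2)
  for (p in seq_len(ncol(pairs))) {
    sp_i <- pairs[1, p]; sp_j <- pairs[2, p]   # alphabetical: x = i, y = j
    x <- vals[, sp_i]; y <- vals[, sp_j]
    if (stats::sd(x) == 0 ||
        (statistic == "correlation" && stats::sd(y) == 0)) {
      excluded <- c(excluded, paste(sp_i, sp_j, sep = ":"))
      next
    }
    if (statistic == "correlation") {
      slope <- stats::cor(x, y); tag <- "pearson"
    } else if (method == "ols" || length(unique(site)) < 2) {
      slope <- stats::cov(x, y) / stats::var(x); tag <- "ols"
    } else {
      d <- data.frame(x = x, y = y, site = site)
      fit <- tryCatch(suppressWarnings(suppressMessages(
        lme4::lmer(y ~ x + (1 | site), data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
        error = function(e) NULL)
      if (is.null(fit)) {
        slope <- stats::cov(x, y) / stats::var(x); tag <- "ols"
      } else {
        slope <- unname(lme4::fixef(fit)["x"])
        tag <- if (lme4::isSingular(fit)) "lmm_singular" else "lmm"
      }
    }
    out[[length(out) + 1]] <- data.frame(
      species_i = sp_i, species_j = sp_j, management = management,
      slope = slope, n = length(x), fit_tag = tag, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no usable species pairs (all predictors constant)")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, excluded = excluded, statistic = statistic,
            class = c("pair_slope_table", "data.frame"))
}

#' Paired comparison of mean pair slopes between management levels
#'
#' Pairs the two tables on their common species pairs and runs a paired
#' t-test on the per-pair differences (open-access minus MPA). A positive
#' mean difference means species densities covary more synchronously outside
#' MPAs.
#'
#' @param mpa,open [pairwise_slopes()] tables for the two management levels.
#' @return list of class `"slope_comparison"`: `mean_mpa, mean_open,
#'   mean_difference, t, df, p, n_pairs, degenerate`.
#' @export
compare_mean_slopes <- function(mpa, open) {
  key <- function(tab) paste(tab$species_i, tab$species_j)
  common <- intersect(key(mpa), key(open))
  if (length(common) < 2) stop("fewer than 2 species pairs shared between tables")
  a <- mpa$slope[match(common, key(mpa))]
  b <- open$slope[match(common, key(open))]
  diffs <- b - a
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    t_stat <- if (all(diffs == 0)) 0 else Inf * sign(mean(diffs))
    p <- if (all(diffs == 0)) 1 else 0
    df <- length(diffs) - 1L
  } else {
    tt <- stats::t.test(b, a, paired = TRUE)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(mean_mpa = mean(a), mean_open = mean(b),
                 mean_difference = mean(diffs), t = t_stat, df = df, p = p,
                 n_pairs = length(common), degenerate = degenerate),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("Paired comparison of species-pair slopes (", x$n_pairs, " pairs)\n",
      "  mean MPA = ", signif(x$mean_mpa, 4),
      ", mean open-access = ", signif(x$mean_open, 4), "\n",
      "  t = ", signif(x$t, 4), ", df = ", x$df, ", p = ", signif(x$p, 4),
      if (x$degenerate) " [degenerate: zero-variance differences]", "\n",
      sep = "")
  invisible(x)
}
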