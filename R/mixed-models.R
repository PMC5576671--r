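# Univariate mixed models: season x management fixed effects, site random
# intercept. Estimation by REML (lme4), per-term marginal (Type III) F tests
# with Satterthwaite or residual denominator df, likelihood-ratio validation
# against the random-only null, marginal/conditional R-squared, Tukey
# all-pair season contrasts, and VIF screening of candidate covariates.
#
# "Site nested within management" reduces to a plain site random intercept
# here because site labels are unique across management levels.

#' Fit a linear mixed model for one community response
#'
#' @param response name of the response column in `data` (typically already
#'   square-root transformed and standardized, see
#'   [transform_standardize()]).
#' @param data data.frame with the response, the fixed-effect columns and the
#'   random grouping column.
#' @param fixed character vector of fixed-effect terms, e.g.
#'   `c("season", "management", "season:management")`.
#' @param random name of the random-intercept grouping column.
#' @param ddf denominator-df method for the per-term F tests:
#'   `"satterthwaite"` (default) or `"residual"` (n minus the number of fixed
#'   coefficients).
#' @param reml fit by REML (`TRUE`, for estimates) or ML (`FALSE`, for
#'   likelihood-ratio tests).
#' @return object of class `"lmm_fit"`: the underlying `lmerMod`, the fixed
#'   coefficient table, variance components, Type III `anova` table (columns
#'   `term, f, df_num, df_den, p`), log-likelihood, and Nakagawa R-squared.
#' @export
fit_lmm <- function(response, data, fixed = c("season", "management",
                                              "season:management"),
                    random = "site", ddf = c("satterthwaite", "residual"),
                    reml = TRUE) {
  ddf <- match.arg(ddf)
  stopifnot(response %in% names(data), random %in% names(data))
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  if (stats::sd(y) == 0) stop("response has zero variance")
  if (length(unique(data[[random]])) < 2)
    stop("random grouping needs at least 2 levels")

  has_fixed <- length(fixed) > 0
  rhs <- c(if (has_fixed) fixed else "1", paste0("(1|", random, ")"))
  form <- stats::reformulate(rhs, response = response)
  model <- lmerTest::lmer(form, data = data, REML = reml)
  conv <- model@optinfo$conv$lme4
  converged <- is.null(conv$messages) || length(conv$messages) == 0

  vc <- as.data.frame(lme4::VarCorr(model))
  var_site <- vc$vcov[vc$grp == random][1]
  var_res <- vc$vcov[vc$grp == "Residual"][1]

  coefs <- as.data.frame(stats::coef(summary(model)))
  names(coefs) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(coefs))]

  anova_tab <- NULL
  if (has_fixed) {
    a <- stats::anova(model, type = 3, ddf = "Satterthwaite")
    anova_tab <- data.frame(term = rownames(a), f = a[["F value"]],
                            df_num = a$NumDF, df_den = a$DenDF,
                            p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
    if (ddf == "residual") {
      df_den <- nrow(data) - length(lme4::fixef(model))
      anova_tab$df_den <- df_den
      anova_tab$p <- stats::pf(anova_tab$f, anova_tab$df_num, df_den,
                               lower.tail = FALSE)
    }
  }

  fit <- structure(list(model = model, response = response, fixed = fixed,
                        random = random, reml = reml, ddf = ddf,
                        n = nrow(data), converged = converged,
                        coefficients = coefs,
                        varcomp = c(site = var_site, residual = var_res),
                        loglik = as.numeric(stats::logLik(model)),
                        anova = anova_tab),
                   class = "lmm_fit")
  fit$r2 <- tryCatch(nakagawa_r2(fit), error = function(e) c(marginal = NA_real_,
                                                             conditional = NA_real_))
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model:", x$response, "~",
      paste(x$fixed, collapse = " + "), "+ (1|", x$random, ")",
      if (x$reml) "[REML]" else "[ML]", "\n")
  cat("Variance components: site =", signif(x$varcomp["site"], 4),
      ", residual =", signif(x$varcomp["residual"], 4), "\n")
  if (!is.null(x$anova)) {
    cat("Type III tests (", x$ddf, " ddf):\n", sep = "")
    print.data.frame(format(x$anova, digits = 4), row.names = FALSE)
  }
  cat("R2 marginal =", signif(x$r2["marginal"], 3),
      ", conditional =", signif(x$r2["conditional"], 3), "\n")
  invisible(x)
}

#' Likelihood-ratio test against the random-effects-only null
#'
#' Both fits must be maximum-likelihood (`reml = FALSE`) fits of nested fixed
#' structures on the same data.
#'
#' @param full,null `"lmm_fit"` objects (ML).
#' @return named numeric `c(chisq, df, p)`.
#' @export
lrt_vs_null <- function(full, null) {
  stopifnot(inherits(full, "lmm_fit"), inherits(null, "lmm_fit"))
  if (full$reml || null$reml)
    stop("likelihood-ratio tests require ML fits (reml = FALSE)")
  if (full$n != null$n) stop("fits are not on the same data")
  if (!all(null$fixed %in% full$fixed))
    stop("null fixed structure is not nested in the full structure")
  k_full <- length(lme4::fixef(full$model))
  k_null <- length(lme4::fixef(null$model))
  if (k_null > k_full) stop("null model has more fixed parameters than full")
  chisq <- 2 * (full$loglik - null$loglik)
  if (chisq < -1e-6) stop("negative LRT statistic: models are not nested")
  chisq <- max(chisq, 0)
  df <- k_full - k_null
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  c(chisq = chisq, df = df, p = p)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed plus
#' random effects (conditional):
#' \deqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{site} + \sigma^2_{res})}
#' \deqn{R^2_c = (\sigma^2_f + \sigma^2_{site}) / (\sigma^2_f +
#'   \sigma^2_{site} + \sigma^2_{res})}
#' with \eqn{\sigma^2_f} the variance of the fixed-effect predictions.
#'
#' @param fit an `"lmm_fit"`, or a list with elements `var_fixed`, `var_site`,
#'   `var_residual` for a hand-built decomposition.
#' @return named numeric `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "lmm_fit")) {
    X <- stats::model.matrix(fit$model)
    pred <- as.vector(X %*% lme4::fixef(fit$model))
    var_f <- stats::var(pred)
    var_site <- fit$varcomp["site"]
    var_res <- fit$varcomp["residual"]
  } else {
    var_f <- fit$var_fixed; var_site <- fit$var_site; var_res <- fit$var_residual
  }
  total <- var_f + var_site + var_res
  if (!is.finite(total) || total <= 0)
    stop("all variance components are zero; R-squared undefined")
  c(marginal = unname(var_f / total),
    conditional = unname((var_f + var_site) / total))
}

#' Tukey all-pair comparisons of factor levels
#'
#' Estimated marginal means for each level of `factor`, with all pairwise
#' differences and single-step (studentized-range / multivariate-t) adjusted
#' p-values. When the model contains an interaction with a grouping factor,
#' pass it as `by` to obtain the pairwise season contrasts within each
#' management level.
#'
#' @param fit an `"lmm_fit"`.
#' @param factor name of the factor whose levels are compared.
#' @param by optional conditioning factor.
#' @return data.frame: `contrast` (and `by` column if given), `estimate, se,
#'   df, t, p` (Tukey-adjusted).
#' @export
tukey_pairs <- function(fit, factor = "season", by = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  vars <- unique(unlist(strsplit(fit$fixed, ":", fixed = TRUE)))
  if (!factor %in% vars)
    stop("factor '", factor, "' is not in the fixed structure")
  emm <- emmeans::emmeans(fit$model, specs = factor, by = by,
                          lmer.df = "satterthwaite")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  names(prs)[names(prs) == "SE"] <- "se"
  names(prs)[names(prs) == "t.ratio"] <- "t"
  names(prs)[names(prs) == "p.value"] <- "p"
  prs
}

#' Variance inflation factors
#'
#' For each predictor column, the VIF \eqn{1 / (1 - R^2_j)} from regressing
#' that column on all the others. Perfectly collinear predictors are reported
#' as `Inf` and flagged rather than raising an error.
#'
#' @param x data.frame or matrix of numeric predictor columns (at least 2,
#'   each non-constant).
#' @return named numeric vector of VIFs with attribute
#'   `collinear` (logical vector flagging infinite entries).
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("VIF needs at least two predictors")
  if (any(vapply(x, function(col) stats::sd(col) == 0, TRUE)))
    stop("constant predictor column")
  out <- numeric(ncol(x))
  names(out) <- names(x)
  for (j in seq_len(ncol(x))) {
    fit <- stats::lm(x[[j]] ~ ., data = x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # collinear fits warn
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  structure(out, collinear = !is.finite(out))
}

#' Table of univariate mixed-model results
#'
#' Fits the default season x management mixed model to each listed response
#' and assembles the per-term F table with likelihood-ratio validation and
#' R-squared, one block per response — the layout of a standard
#' density-and-diversity results table.
#'
#' @param data per-transect response table (see [transect_responses()]).
#' @param responses named character vector: output label -> column name.
#' @param sqrt_transform logical vector (recycled): square-root transform the
#'   response before standardizing? Densities are; diversity indices are not.
#' @param ddf denominator-df method, see [fit_lmm()].
#' @return data.frame with columns `response, term, f, df_num, df_den, p,
#'   r2_marginal, r2_conditional, lrt_chisq, lrt_df, lrt_p`.
#' @export
lmm_response_table <- function(data,
                               responses = c(total = "total_density",
                                             juvenile = "juvenile_density",
                                             subadult = "subadult_density",
                                             adult = "adult_density",
                                             richness = "richness",
                                             shannon = "shannon"),
                               sqrt_transform = c(TRUE, TRUE, TRUE, TRUE,
                                                  FALSE, FALSE),
                               ddf = "satterthwaite") {
  sqrt_transform <- rep_len(sqrt_transform, length(responses))
  blocks <- list()
  for (i in seq_along(responses)) {
    col <- responses[[i]]
    d <- data[!is.na(data[[col]]), ]
    d$.resp <- as.vector(transform_standardize(
      d[[col]], if (sqrt_transform[i]) "sqrt" else "none"))
    fit <- fit_lmm(".resp", d, ddf = ddf)
    full_ml <- fit_lmm(".resp", d, ddf = ddf, reml = FALSE)
    null_ml <- fit_lmm(".resp", d, fixed = character(0), reml = FALSE)
    lrt <- lrt_vs_null(full_ml, null_ml)
    tab <- fit$anova
    tab$response <- names(responses)[i]
    tab$r2_marginal <- fit$r2["marginal"]
    tab$r2_conditional <- fit$r2["conditional"]
    tab$lrt_chisq <- lrt["chisq"]; tab$lrt_df <- lrt["df"]; tab$lrt_p <- lrt["p"]
    blocks[[i]] <- tab[c("response", "term", "f", "df_num", "df_den", "p",
                         "r2_marginal", "r2_conditional",
                         "lrt_chisq", "lrt_df", "lrt_p")]
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
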