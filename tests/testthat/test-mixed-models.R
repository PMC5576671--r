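make_lmm_data <- function(n_per = 10, site_sd = 0, effect = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(season = c("SR", "LR", "D"),
                   site = c("s1", "s2", "s3", "s4"),
                   rep = seq_len(n_per), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$management <- ifelse(d$site %in% c("s1", "s2"), "MPA", "open")
  u <- rnorm(4, 0, site_sd); names(u) <- c("s1", "s2", "s3", "s4")
  d$y <- rnorm(nrow(d)) + u[d$site] + effect * (d$management == "open")
  d
}

test_that("with no site variance the fixed effects reduce to least squares", {
  d <- make_lmm_data(site_sd = 0, seed = 2)
  fit <- fit_lmm("y", d)
  ols <- lm(y ~ season + management + season:management, data = d)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)[rownames(fit$coefficients)]),
               tolerance = 1e-4)
  expect_lt(fit$varcomp[["site"]], 0.05)
})

test_that("a known management effect is recovered within 3 SE", {
  d <- make_lmm_data(n_per = 17, site_sd = 0, effect = 1, seed = 3)  # n ~ 200
  fit <- fit_lmm("y", d, fixed = "management")
  est <- fit$coefficients["managementopen", ]
  expect_lt(abs(est$estimate - 1), 3 * est$se)
  expect_error(fit_lmm("y", transform(d, y = 1)), "zero variance")
})

test_that("the residual ddf option reports n minus the coefficient count", {
  d <- make_lmm_data(seed = 4)
  fit <- fit_lmm("y", d, ddf = "residual")
  expect_true(all(fit$anova$df_den == nrow(d) - 6))
  expect_equal(fit$anova$p,
               pf(fit$anova$f, fit$anova$df_num, nrow(d) - 6, lower.tail = FALSE))
})

test_that("REML variance components ignore the fixed-effect coding", {
  d <- make_lmm_data(site_sd = 0.8, seed = 5)
  fit_treatment <- fit_lmm("y", d)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  fit_sum <- fit_lmm("y", d)
  options(old)
  expect_equal(fit_treatment$varcomp, fit_sum$varcomp, tolerance = 1e-6)
})

test_that("the likelihood-ratio test matches its chi-squared reference", {
  d <- make_lmm_data(site_sd = 0.5, effect = 0.8, seed = 6)
  full <- fit_lmm("y", d, reml = FALSE)
  null <- fit_lmm("y", d, fixed = character(0), reml = FALSE)
  lrt <- lrt_vs_null(full, null)
  expect_equal(lrt[["chisq"]],
               2 * (as.numeric(logLik(full$model)) -
                    as.numeric(logLik(null$model))))
  expect_equal(lrt[["df"]], 5)
  # independent upper-tail CDF via the gamma identity
  expect_equal(lrt[["p"]],
               pgamma(lrt[["chisq"]] / 2, shape = lrt[["df"]] / 2,
                      lower.tail = FALSE), tolerance = 1e-12)
  # full model compared with itself: no evidence, p = 1
  self <- lrt_vs_null(full, full)
  expect_equal(self[["chisq"]], 0)
  expect_equal(self[["p"]], 1)
  expect_error(lrt_vs_null(fit_lmm("y", d), null), "ML")
})

test_that("Nakagawa R-squared identities hold", {
  hand <- nakagawa_r2(list(var_fixed = 1, var_site = 1, var_residual = 2))
  expect_equal(unname(hand), c(0.25, 0.5))
  d <- make_lmm_data(site_sd = 0.7, effect = 1, seed = 7)
  fit <- fit_lmm("y", d)
  r2 <- fit$r2
  expect_true(r2[["marginal"]] <= r2[["conditional"]])
  expect_true(r2[["conditional"]] <= 1)
  # recompute from the components
  X <- model.matrix(fit$model)
  vf <- var(as.vector(X %*% lme4::fixef(fit$model)))
  expect_equal(r2[["marginal"]],
               vf / (vf + fit$varcomp[["site"]] + fit$varcomp[["residual"]]))
  # no fixed effects: marginal variance is zero
  null <- fit_lmm("y", d, fixed = character(0))
  expect_equal(null$r2[["marginal"]], 0)
  expect_error(nakagawa_r2(list(var_fixed = 0, var_site = 0,
                                var_residual = 0)), "zero")
})

test_that("Tukey all-pair contrasts match the classical HSD in a balanced design", {
  set.seed(8)
  d <- expand.grid(season = c("SR", "LR", "D"), site = paste0("s", 1:4),
                   rep = 1:6, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + 0.7 * (d$season == "LR")
  fit <- fit_lmm("y", d, fixed = "season")
  tk <- tukey_pairs(fit, "season")
  expect_equal(nrow(tk), 3)           # C(3,2) contrasts

  # classical Tukey HSD computed from scratch (balanced one-way, the site
  # variance here is estimated at the boundary so the models coincide)
  if (fit$varcomp[["site"]] < 1e-10) {
    ols <- lm(y ~ season, data = d)
    s2 <- sum(residuals(ols)^2) / ols$df.residual
    n_per <- nrow(d) / 3
    means <- tapply(d$y, d$season, mean)
    for (r in seq_len(nrow(tk))) {
      lv <- strsplit(as.character(tk$contrast[r]), " - ")[[1]]
      diff_hand <- means[[lv[1]]] - means[[lv[2]]]
      q <- abs(diff_hand) / sqrt(s2 / n_per)
      p_hand <- ptukey(q, nmeans = 3, df = ols$df.residual, lower.tail = FALSE)
      expect_equal(tk$estimate[r], unname(diff_hand), tolerance = 1e-8)
      expect_equal(tk$p[r], p_hand, tolerance = 1e-6)
    }
  }

  # noiseless identical level means: all contrasts zero with p = 1
  d0 <- d; d0$y <- rep(c(1, 2), length.out = nrow(d0))  # varies, not by season
  fit0 <- fit_lmm("y", d0, fixed = "season")
  tk0 <- tukey_pairs(fit0, "season")
  expect_equal(tk0$estimate, rep(0, 3), tolerance = 1e-12)
  expect_equal(tk0$p, rep(1, 3), tolerance = 1e-9)
  expect_error(tukey_pairs(fit, "management"), "not in the fixed structure")
})

test_that("interaction models compare seasons within each management level", {
  d <- make_lmm_data(n_per = 8, site_sd = 0.3, seed = 9)
  d$y <- d$y + 1.2 * (d$season == "SR") * (d$management == "open")
  fit <- fit_lmm("y", d)
  tk <- tukey_pairs(fit, "season", by = "management")
  expect_equal(nrow(tk), 6)
  expect_setequal(unique(tk$management), c("MPA", "open"))
  # the induced seasonal contrast is visible only in the open level
  # (levels are alphabetical, so the pair appears as "LR - SR")
  sr_lr_open <- tk$p[tk$management == "open" & grepl("LR - SR", tk$contrast)]
  sr_lr_mpa <- tk$p[tk$management == "MPA" & grepl("LR - SR", tk$contrast)]
  expect_lt(sr_lr_open, 0.05)
  expect_gt(sr_lr_mpa, 0.05)
})

test_that("variance inflation factors follow the 1/(1-R2) identity", {
  set.seed(10)
  x1 <- rnorm(100)
  x2 <- rnorm(100)
  x2 <- residuals(lm(x2 ~ x1))                 # exactly orthogonal
  v <- vif(data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)

  # construct predictors with R2 exactly 0.64
  e <- residuals(lm(rnorm(100) ~ x1))
  x3 <- 0.8 * x1 / sd(x1) + sqrt(1 - 0.64) * e / sd(e)
  v2 <- vif(data.frame(x1 = x1 / sd(x1), x3 = x3))
  expect_equal(unname(v2), rep(1 / (1 - 0.64), 2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(v2[1]), 2.7778, tolerance = 1e-4, ignore_attr = TRUE)

  # agreement with the standard regression-diagnostic implementation
  set.seed(11)
  z <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  z$b <- z$b + 0.5 * z$a
  fit <- lm(rnorm(60) ~ a + b + c, data = z)
  expect_equal(unname(vif(z)), unname(car::vif(fit)), tolerance = 1e-10,
               ignore_attr = TRUE)

  dup <- vif(data.frame(a = z$a, b = z$a))
  expect_true(all(is.infinite(dup)))
  expect_true(all(attr(dup, "collinear")))
  expect_error(vif(data.frame(a = rep(1, 5), b = rnorm(5))), "constant")
})

test_that("the response table assembles per-term tests for every response", {
  sv <- generate_survey(small_config(), seed = 23)
  resp <- transect_responses(sv)
  tab <- lmm_response_table(resp, responses = c(total = "total_density",
                                                richness = "richness"),
                            sqrt_transform = c(TRUE, FALSE))
  expect_equal(nrow(tab), 6)      # 2 responses x 3 terms
  expect_true(all(tab$lrt_chisq >= -1e-6))
  expect_true(all(tab$r2_marginal <= tab$r2_conditional + 1e-9))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
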