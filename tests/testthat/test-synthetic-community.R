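test_that("the default design yields 111 transects split 51 MPA / 60 open", {
  sv <- generate_survey(small_config(), seed = 1)
  roster <- unique(sv$cover[c("site", "management", "season", "transect")])
  expect_equal(nrow(roster), 111)
  expect_equal(sum(roster$management == "MPA"), 51)
  expect_equal(sum(roster$management == "open"), 60)
  expect_true(all(table(paste(sv$cover$site, sv$cover$season,
                              sv$cover$transect)) == 6))
})

test_that("generation is deterministic given config and seed", {
  cfg <- small_config()
  a <- generate_survey(cfg, seed = 42)
  b <- generate_survey(cfg, seed = 42)
  expect_identical(a$fish, b$fish)
  expect_identical(a$cover, b$cover)
  c <- generate_survey(cfg, seed = 43)
  expect_false(identical(a$fish, c$fish))
})

test_that("generated values respect the recording conventions", {
  sv <- generate_survey(small_config(), seed = 5)
  expect_true(all(sv$cover$cover_pct %% 10 == 0))
  expect_true(all(sv$cover$cover_pct >= 0 & sv$cover$cover_pct <= 100))
  expect_true(all(sv$fish$length_cm %% 5 == 0))
  expect_true(all(sv$fish$length_cm > 0))
  expect_error(generator_config(theta = 0), "theta")
  expect_error(generator_config(n_species = 1), "n_species")
})

test_that("ground truth follows the stated log-linear structure", {
  # no synchrony, no cover effect, flat seasons: expectation exp(alpha + site)
  cfg <- small_config(season_sd = 0, beta_mean = 0, beta_sd = 0,
                      phi_mpa = 0, phi_open = 0)
  gt <- ground_truth(cfg)$density
  for (sp in cfg$species[1:3]) {
    for (st in cfg$design$sites$site) {
      rows <- gt$species == sp & gt$site == st
      expected <- exp(cfg$alpha[match(sp, cfg$species)] + cfg$u_site[st])
      expect_equal(gt$expected_density[rows], rep(expected, 3),
                   ignore_attr = TRUE)
    }
  }
  # log-linearity: adding log(2) to one season's response doubles that
  # season's expectation for that species and leaves the others unchanged
  cfg2 <- cfg
  cfg2$gamma[1, 2] <- cfg2$gamma[1, 2] + log(2)
  gt2 <- ground_truth(cfg2)$density
  sp1 <- cfg$species[1]
  s2 <- cfg$design$seasons[2]
  r_target <- gt$species == sp1 & gt$season == s2
  expect_equal(gt2$expected_density[r_target], 2 * gt$expected_density[r_target])
  expect_equal(gt2$expected_density[!r_target], gt$expected_density[!r_target])
})

test_that("simulated means match closed-form expectations (Monte Carlo)", {
  cfg <- small_config(theta = 4)
  n_rep <- 200
  gt <- ground_truth(cfg)$density
  key <- paste(gt$site, gt$season, gt$species)
  sums <- numeric(length(key)); sq <- numeric(length(key)); n_tr <- numeric(length(key))
  for (r in seq_len(n_rep)) {
    sv <- generate_survey(cfg, seed = 9000 + r)
    dt <- aggregate_density(sv, "transect")
    cell <- paste(dt$samples$site, dt$samples$season)
    for (i in seq_len(nrow(gt))) {
      rows <- cell == paste(gt$site[i], gt$season[i])
      v <- dt$values[rows, gt$species[i]]
      sums[i] <- sums[i] + sum(v); sq[i] <- sq[i] + sum(v^2)
      if (r == 1) n_tr[i] <- sum(rows)
    }
  }
  n_obs <- n_tr * n_rep
  emp_mean <- sums / n_obs
  emp_sd <- sqrt(pmax(sq / n_obs - emp_mean^2, 0))
  mcse <- emp_sd / sqrt(n_obs)
  # abundant cells: enough signal for a meaningful 3-MCSE comparison
  big <- gt$expected_density > 0.5
  expect_true(any(big))
  dev <- abs(emp_mean[big] - gt$expected_density[big]) / pmax(mcse[big], 1e-12)
  expect_lt(mean(dev > 3), 0.05)
})

test_that("a flat configuration shows no systematic season differences", {
  cfg <- small_config(season_sd = 0, phi_mpa = 0, phi_open = 0,
                      a_mpa = 0, a_open = 0)
  n_rep <- 60
  not_rejected <- 0
  for (r in seq_len(n_rep)) {
    sv <- generate_survey(cfg, seed = 500 + r)
    dt <- aggregate_density(sv, "transect")
    v <- dt$values[, which.max(colSums(dt$values))]
    p <- stats::kruskal.test(v, factor(dt$samples$season))$p.value
    not_rejected <- not_rejected + (p > 0.05)
  }
  expect_gte(not_rejected / n_rep, 0.9 - 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the management contrast shapes cover variability and synchrony", {
  cfg <- small_config()          # a_open > a_mpa, phi_open > 0 by default
  # seasonal variance of site-mean cover is larger outside MPAs
  sv <- generate_survey(cfg, seed = 21)
  cov <- transect_cover(sv)
  site_season <- stats::aggregate(mean_cover_pct ~ site + season, cov, mean)
  seas_var <- tapply(site_season$mean_cover_pct, site_season$site, stats::var)
  mgmt <- cfg$design$sites$management[match(names(seas_var),
                                            cfg$design$sites$site)]
  expect_gt(mean(seas_var[mgmt == "open"]), mean(seas_var[mgmt == "MPA"]))

  # ground-truth expectations: between-season log-density spread is larger
  # in open sites, the mechanism behind their synchronous fluctuations
  gt <- ground_truth(cfg)$density
  spread <- stats::aggregate(expected_density ~ site + species, gt,
                             function(x) diff(range(log(x))))
  m <- cfg$design$sites$management[match(spread$site, cfg$design$sites$site)]
  expect_gt(mean(spread$expected_density[m == "open"]),
            mean(spread$expected_density[m == "MPA"]))
})

test_that("counts are nonnegative integers approaching Poisson as theta grows", {
  design <- survey_design(sites = "S1", management = "MPA",
                          transects_per_site = 150L, seasons = "SR")
  cfg <- generator_config(design = design, n_species = 6, theta = 1e6,
                          season_sd = 0, a_mpa = 0, a_open = 0,
                          phi_mpa = 0, phi_open = 0, beta_mean = 0,
                          beta_sd = 0, cover_kappa = 1e5,
                          f_season = 0, g_cover = 0)
  sv <- generate_survey(cfg, seed = 2)
  dt <- aggregate_density(sv, "transect")
  expect_true(all(dt$values >= 0))
  expect_true(all(dt$values == round(dt$values)))
  ratio <- apply(dt$values, 2, stats::var) / colMeans(dt$values)
  # variance/mean near 1 for the abundant species
  ab <- colMeans(dt$values) > 1
  expect_true(all(abs(ratio[ab] - 1) < 0.5))
})
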