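test_that("Bray-Curtis matches the formula, conventions and vegan", {
  expect_equal(bray_curtis(rbind(a = c(1, 2, 3), b = c(1, 2, 3)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(5, 0, 0), b = c(0, 5, 0)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(2, 1)))["a", "b"], 1 / 3)
  # double-zero convention: two empty samples are identical, not undefined
  expect_equal(bray_curtis(rbind(a = c(0, 0), b = c(0, 0)))["a", "b"], 0)
  expect_error(bray_curtis(rbind(c(-1, 2), c(0, 1))), "nonnegative")

  set.seed(4)
  m <- matrix(rpois(6 * 5, 4), 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:5)))
  d <- bray_curtis(m)
  expect_true(isSymmetric(unclass(d)))
  expect_equal(diag(d), rep(0, 6), ignore_attr = TRUE)
  # brute-force pairwise oracle and the vegan implementation
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], bc_pair(m[i, ], m[j, ]))
  expect_equal(unclass(d), as.matrix(vegan::vegdist(m, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  # species-order permutation and joint doubling leave d unchanged
  expect_equal(unclass(bray_curtis(m[, 5:1])), unclass(d))
  expect_equal(unclass(bray_curtis(2 * m)), unclass(d))
})

test_that("nMDS recovers exactly embeddable configurations", {
  set.seed(5)
  pts <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(pts))
  ord <- nmds(d, k = 2, n_restarts = 10, seed = 1)
  expect_lt(ord$stress, 1e-3)
  # rank order of configuration distances equals that of the input
  conf <- as.matrix(dist(ord$points))
  lower <- lower.tri(d)
  expect_equal(order(conf[lower]), order(d[lower]))
})

test_that("nMDS stress trace is non-increasing and restarts are stable", {
  set.seed(6)
  m <- matrix(rpois(8 * 6, 5), 8, 6)
  d <- bray_curtis(m)
  ord <- nmds(d, n_restarts = 4, seed = 2)
  expect_true(all(diff(ord$stress_trace) <= 1e-12))
  expect_equal(ord$stress, min(ord$restart_stress))
  # same seed reproduces the configuration exactly
  ord2 <- nmds(d, n_restarts = 4, seed = 2)
  expect_identical(ord$points, ord2$points)
  # on a well-determined input, different seeds reach the same stress
  pts <- matrix(rnorm(12), 6, 2)
  de <- as.matrix(dist(pts))
  s1 <- nmds(de, n_restarts = 8, seed = 3)$stress
  s2 <- nmds(de, n_restarts = 8, seed = 4)$stress
  expect_equal(s1, s2, tolerance = 1e-6)
  # coincident samples embed at the same point
  dd <- bray_curtis(rbind(a = c(3, 1), b = c(3, 1), c = c(0, 5)))
  oo <- nmds(dd, n_restarts = 4, seed = 5)
  expect_lt(sqrt(sum((oo$points["a", ] - oo$points["b", ])^2)), 1e-4)
  expect_error(nmds(matrix(c(0, NA, NA, 0), 2)), "finite")
})

# independent one-way PERMANOVA pseudo-F from the distance-based identity:
# SS_total = sum_{i<j} d^2 / n, SS_within = group sums of d^2 / n_g
brute_force_permanova_f <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

test_that("PERMANOVA pseudo-F matches the brute-force identity and vegan", {
  set.seed(7)
  m <- matrix(rpois(8 * 5, 6), 8, 5)
  groups <- rep(c("a", "b"), each = 4)
  d <- bray_curtis(m)
  res <- permanova(d, data.frame(g = groups), terms = "g", n_perm = 99)
  expect_equal(res$f[1], brute_force_permanova_f(d, groups), tolerance = 1e-6)
  expect_equal(sum(res$r2[1:2]), 1, tolerance = 1e-9)

  va <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = groups),
                       permutations = 99, by = "terms")
  expect_equal(res$f[1], va$F[1], tolerance = 1e-10)
  expect_equal(res$ss[1:2], va$SumOfSqs[1:2], tolerance = 1e-10)

  # two crossed terms against vegan's sequential decomposition
  dat <- data.frame(g = groups, h = rep(c("x", "y"), 4))
  res2 <- permanova(d, dat, terms = c("g", "h"), n_perm = 49)
  va2 <- vegan::adonis2(as.dist(d) ~ g + h, data = dat, permutations = 49,
                        by = "terms")
  expect_equal(res2$f[1:2], va2$F[1:2], tolerance = 1e-10)
  expect_equal(res2$r2[1:3], va2$R2[1:3], tolerance = 1e-10)
})

test_that("PERMANOVA validates its inputs", {
  d <- bray_curtis(matrix(rpois(12, 5), 4, 3))
  expect_error(permanova(d, data.frame(g = rep("a", 4)), terms = "g"),
               "constant predictor")
  expect_error(permanova(d, data.frame(g = c("a", "a", "b", "b")),
                         terms = "g", n_perm = 0), "n_perm")
  expect_error(permanova(d, data.frame(g = c("a", "a", "b", "b")),
                         terms = "h"), "not found")
})

test_that("strata constrain every permutation to within-site shuffles", {
  sv <- generate_survey(small_config(), seed = 17)
  dt <- aggregate_density(sv, "site", "sum")
  d <- bray_curtis(dt)
  res <- permanova(d, dt$samples, strata = "site", n_perm = 199, seed = 3)
  perms <- attr(res, "permutations")
  site <- dt$samples$site
  for (b in seq_len(nrow(perms)))
    expect_identical(site[perms[b, ]], site)
  # and without strata, permutations do break sites
  res_free <- permanova(d, dt$samples, n_perm = 50, seed = 3)
  free <- attr(res_free, "permutations")
  expect_true(any(apply(free, 1, function(p) !identical(site[p], site))))
})

test_that("SIMPER contributions decompose Bray-Curtis exactly", {
  # two single-sample groups: contributions sum to their distance
  m <- rbind(a = c(3, 0, 2), b = c(1, 1, 1))
  st <- simper(m, c("g1", "g2"))
  expect_equal(sum(st$average), bc_pair(m[1, ], m[2, ]))

  # absent species contribute zero
  m2 <- rbind(a = c(3, 0, 0), b = c(1, 2, 0), c = c(0, 1, 0), d = c(2, 2, 0))
  st2 <- simper(m2, c("g1", "g1", "g2", "g2"))
  expect_equal(st2$average[st2$species == "sp3"], 0)

  # random table against a brute-force pair-averaging oracle
  set.seed(8)
  m3 <- matrix(rpois(4 * 3, 4), 4, 3,
               dimnames = list(NULL, paste0("sp", 1:3)))
  g <- c("g1", "g1", "g2", "g2")
  st3 <- simper(m3, g, n_perm = 99, seed = 1)
  oracle <- numeric(3)
  for (i in 1:2) for (j in 3:4) {
    denom <- sum(m3[i, ] + m3[j, ])
    oracle <- oracle + abs(m3[i, ] - m3[j, ]) / denom
  }
  oracle <- oracle / 4
  expect_equal(st3$average, unname(oracle[match(st3$species, colnames(m3))]),
               tolerance = 1e-12)
  # overall equals the mean between-group Bray-Curtis, and vegan agrees
  expect_equal(attr(st3, "overall"), sum(oracle), tolerance = 1e-12)
  vs <- summary(vegan::simper(m3, g, permutations = 0))[[1]]
  expect_equal(st3$average, vs$average[match(st3$species, rownames(vs))],
               tolerance = 1e-10)
  expect_error(simper(m3, c("g1", "g1", "g1", "g1")), "two groups")
})
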