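# Multivariate community structure: Bray-Curtis dissimilarities, non-metric
# MDS by stress majorization with isotonic regression, PERMANOVA with
# strata-constrained permutations, and SIMPER species contributions.

as_values_matrix <- function(x) {
  if (inherits(x, "density_table")) x$values
  else if (is.matrix(x)) x
  else as.matrix(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between every pair
#' of samples (rows). Two all-zero samples are assigned distance 0 by
#' convention, so tables filtered to a rare age class never produce NaN.
#'
#' @param x a [aggregate_density()] table or a nonnegative numeric matrix
#'   (samples x species).
#' @return symmetric matrix of class `"dissimilarity_matrix"` with zero
#'   diagonal and entries in \[0, 1\], attribute `method = "bray-curtis"`.
#' @examples
#' bray_curtis(rbind(a = c(1, 2), b = c(2, 1))) # 1/3 off-diagonal
#' @export
bray_curtis <- function(x) {
  m <- as_values_matrix(x)
  if (any(m < 0)) stop("Bray-Curtis requires nonnegative abundances")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  structure(d, method = "bray-curtis", class = c("dissimilarity_matrix", "matrix"))
}

# isotonic (monotone nondecreasing) fit of y against the order of x;
# ties in x are kept in a stable order so the fit is deterministic
monotone_fit <- function(x, y) {
  ord <- order(x)
  fit <- numeric(length(y))
  fit[ord] <- stats::isoreg(y[ord])$yf
  fit
}

kruskal_stress1 <- function(dconf, dhat) {
  denom <- sum(dconf^2)
  if (denom == 0) return(0)
  sqrt(sum((dconf - dhat)^2) / denom)
}

#' Non-metric multidimensional scaling
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities, minimizing
#' Kruskal's stress-1
#' \eqn{\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}}
#' where \eqn{\hat d} is the isotonic regression of configuration distances
#' on the dissimilarity order. Optimization is by Guttman-transform
#' majorization; an update that fails to decrease stress terminates the
#' restart, so the recorded stress trace is non-increasing. The first restart
#' starts from the metric (classical) MDS solution, subsequent restarts from
#' random configurations; the best restart is returned.
#'
#' @param d a [bray_curtis()] matrix (or any symmetric dissimilarity matrix).
#' @param k embedding dimension.
#' @param n_restarts number of restarts.
#' @param max_iter iteration cap per restart.
#' @param tol stop when stress improves by less than this.
#' @param seed seed for the random restarts.
#' @return object of class `"nmds_ordination"`: `points` (n x k, labelled),
#'   `stress`, `stress_trace` (best restart), `restart_stress`, `converged`,
#'   `seed`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 20L, max_iter = 300L, tol = 1e-7,
                 seed = 1L) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("dissimilarities must be finite")
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  lower <- lower.tri(d)
  delta <- d[lower]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  run_restart <- function(X) {
    X <- scale(X, scale = FALSE)
    trace <- numeric(0)
    conf_d <- as.matrix(stats::dist(X))
    dhat_v <- monotone_fit(delta, conf_d[lower])
    stress <- kruskal_stress1(conf_d[lower], dhat_v)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      trace[it] <- stress
      dhat <- matrix(0, n, n)
      dhat[lower] <- dhat_v
      dhat <- dhat + t(dhat)
      # Guttman transform towards the monotone targets
      ratio <- ifelse(conf_d > 0, dhat / conf_d, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X_new <- B %*% X / n
      conf_new <- as.matrix(stats::dist(X_new))
      dhat_new <- monotone_fit(delta, conf_new[lower])
      stress_new <- kruskal_stress1(conf_new[lower], dhat_new)
      if (stress_new > stress + 1e-12) break      # majorization stalled
      improved <- stress - stress_new
      X <- X_new; conf_d <- conf_new; dhat_v <- dhat_new; stress <- stress_new
      if (improved < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = stress, trace = c(trace, stress), converged = converged)
  }

  restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1) {
      cm <- suppressWarnings(stats::cmdscale(d, k = k))
      if (ncol(cm) < k) cbind(cm, matrix(stats::rnorm(n * (k - ncol(cm)), 0, 1e-4),
                                         n, k - ncol(cm))) else cm
    } else matrix(stats::rnorm(n * k), n, k)
    restarts[[r]] <- run_restart(X0)
  }
  stresses <- vapply(restarts, `[[`, numeric(1), "stress")
  best <- restarts[[which.min(stresses)]]
  X <- best$X
  # principal-axis orientation for a deterministic reported configuration
  if (n > 1 && k > 1) {
    sv <- svd(scale(X, scale = FALSE))
    X <- scale(X, scale = FALSE) %*% sv$v
  }
  # report the configuration on the scale of the input dissimilarities
  # (stress-1 is scale-invariant, so this is cosmetic but makes trajectory
  # metrics comparable across ordinations)
  dc <- stats::dist(X)
  if (sum(dc^2) > 0) X <- X * sqrt(sum(delta^2) / sum(dc^2))
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  if (!best$converged)
    warning("nMDS did not converge within max_iter; best configuration returned")
  structure(list(points = X, stress = best$stress, stress_trace = best$trace,
                 restart_stress = stresses, converged = best$converged,
                 k = k, seed = seed),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("nMDS ordination:", nrow(x$points), "samples in", x$k,
      "dimensions; stress-1 =", signif(x$stress, 4),
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

# one within-strata permutation of 1..n (identity strata = free shuffle)
strata_permutation <- function(strata) {
  p <- seq_along(strata)
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    if (length(idx) > 1) p[idx] <- sample(idx)
  }
  p
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a dissimilarity matrix by a sequence of predictor terms using
#' sequential (Type I) sums of squares on the Gower-centered inner-product
#' matrix, and tests each term's pseudo-F against permutations of the sample
#' labels. When `strata` is given, permutations are constrained to shuffle
#' samples only within each stratum (e.g. within sites, for repeated seasonal
#' surveys of the same sites). The p-value is the permutation tail
#' probability \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, never zero.
#'
#' @param d a [bray_curtis()] matrix.
#' @param data data.frame of predictors, rows aligned with `d`.
#' @param terms character vector of model terms, fitted sequentially (default
#'   season, management, their interaction).
#' @param strata optional: a column name in `data`, or a vector of stratum
#'   labels, constraining the permutations.
#' @param n_perm number of permutations.
#' @param seed permutation RNG seed.
#' @return data.frame of class `"permanova_table"` with columns
#'   `term, df, ss, r2, f, p` plus `Residual` and `Total` rows; attributes
#'   `n_perm`, `strata`, `permutations` (the matrix of permutations used).
#' @export
permanova <- function(d, data,
                      terms = c("season", "management", "season:management"),
                      strata = NULL, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(nrow(data) == n)
  if (n_perm < 1) stop("n_perm must be at least 1")
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in base_vars) {
    if (!v %in% names(data)) stop("predictor not found in data: ", v)
    if (length(unique(data[[v]])) < 2) stop("constant predictor: ", v)
  }
  strata_lab <- if (is.null(strata)) NULL
    else if (length(strata) == 1 && is.character(strata) && strata %in% names(data))
      as.character(data[[strata]])
    else as.character(strata)
  if (!is.null(strata_lab) && length(strata_lab) != n)
    stop("strata must label every sample")

  # Gower-centered inner-product matrix
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (d^2) %*% C
  ss_total <- sum(diag(G))

  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (j in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(j)]), data)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    ranks[j] <- qx$rank
  }
  df_terms <- diff(c(1L, ranks))      # intercept absorbs 1 df
  if (any(df_terms < 1)) stop("aliased term(s) in the sequential model")
  df_res <- n - ranks[length(terms)]

  seq_ss <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    diff(c(0, tr))
  }
  ss <- seq_ss(G)
  ss_res <- ss_total - sum(ss)
  f_obs <- (ss / df_terms) / (ss_res / df_res)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- matrix(0L, n_perm, n)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- if (is.null(strata_lab)) sample(n) else strata_permutation(strata_lab)
    perms[b, ] <- p
    Gp <- G[p, p]
    ss_p <- seq_ss(Gp)
    ss_res_p <- ss_total - sum(ss_p)
    f_p <- (ss_p / df_terms) / (ss_res_p / df_res)
    exceed <- exceed + (f_p >= f_obs - 1e-12)
  }
  pval <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    ss = c(ss, ss_res, ss_total),
    r2 = c(ss, ss_res, ss_total) / ss_total,
    f = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, n_perm = n_perm, strata = strata_lab, permutations = perms,
            class = c("permanova_table", "data.frame"))
}

#' @export
print.permanova_table <- function(x, ...) {
  cat("PERMANOVA (", attr(x, "n_perm"), " permutations",
      if (!is.null(attr(x, "strata"))) ", strata-constrained", "):\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' SIMPER species contributions
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity into
#' per-species contributions: for each between-group sample pair the species'
#' share \eqn{|x_i - y_i| / \sum_k (x_k + y_k)}, averaged over all pairs.
#' Contributions sum to the mean between-group dissimilarity. An optional
#' permutation test reports, per species, the probability of an equal or
#' larger contribution when group labels are shuffled.
#'
#' @param x a [aggregate_density()] table or matrix (samples x species).
#' @param groups two-level grouping vector aligned with the samples.
#' @param n_perm permutations for per-species p-values (0 = none).
#' @param seed permutation RNG seed.
#' @return data.frame of class `"simper_table"`, species ranked by
#'   contribution: `species, average, cumulative, mean_<group1>,
#'   mean_<group2>` (and `p` when permuted); attribute
#'   `overall` = mean between-group dissimilarity.
#' @export
simper <- function(x, groups, n_perm = 0L, seed = 1L) {
  m <- as_values_matrix(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  levs <- unique(groups)
  if (length(levs) != 2) stop("SIMPER needs exactly two groups")
  if (!all(table(groups) >= 1)) stop("both groups must be non-empty")

  contrib <- function(g) {
    ia <- which(g == levs[1]); ib <- which(g == levs[2])
    acc <- numeric(ncol(m))
    for (i in ia) for (j in ib) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom > 0) acc <- acc + abs(m[i, ] - m[j, ]) / denom
    }
    acc / (length(ia) * length(ib))
  }
  avg <- contrib(groups)

  pvals <- NULL
  if (n_perm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    exceed <- numeric(ncol(m))
    for (b in seq_len(n_perm))
      exceed <- exceed + (contrib(sample(groups)) >= avg - 1e-12)
    pvals <- (1 + exceed) / (1 + n_perm)
  }

  ord <- order(avg, decreasing = TRUE)
  out <- data.frame(species = colnames(m) %||% paste0("sp", seq_len(ncol(m))),
                    average = avg, stringsAsFactors = FALSE)[ord, ]
  out$cumulative <- cumsum(out$average) / max(sum(avg), .Machine$double.eps)
  mg1 <- colMeans(m[groups == levs[1], , drop = FALSE])[ord]
  mg2 <- colMeans(m[groups == levs[2], , drop = FALSE])[ord]
  out[[paste0("mean_", levs[1])]] <- mg1
  out[[paste0("mean_", levs[2])]] <- mg2
  if (!is.null(pvals)) out$p <- pvals[ord]
  rownames(out) <- NULL
  structure(out, overall = sum(avg), groups = levs,
            class = c("simper_table", "data.frame"))
}

#' @export
print.simper_table <- function(x, ...) {
  cat("SIMPER between", paste(attr(x, "groups"), collapse = " and "),
      "- mean between-group dissimilarity", signif(attr(x, "overall"), 4), "\n")
  print.data.frame(utils::head(format(as.data.frame(x), digits = 3), 10),
                   row.names = FALSE)
  invisible(x)
}
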