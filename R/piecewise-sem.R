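# Piecewise structural equation models: a DAG of causal claims (season ->
# seagrass cover -> fish response, with or without a direct season -> fish
# path), each endogenous node fitted as a mixed model with a site random
# intercept, tested globally through the d-separation basis set and Fisher's
# C statistic. Season, a 3-level factor, is a composite exogenous variable:
# it enters every regression as its dummy columns tested jointly, and the
# signs of its coefficients are not interpretable.

#' Define a path model (DAG of causal claims)
#'
#' @param edges data.frame with columns `from`, `to`, one row per claimed
#'   causal path.
#' @param composite character vector of node names that are multi-level
#'   factors entered as composite variables (jointly-tested dummy columns);
#'   composites may only appear as sources.
#' @param random name of the random-intercept grouping column used by every
#'   node model.
#' @return object of class `"path_model"` with `nodes` in topological order,
#'   `edges`, `composite`, `random`.
#' @export
path_model <- function(edges, composite = "season", random = "site") {
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to), stringsAsFactors = FALSE)
  nodes <- unique(c(edges$from, edges$to))
  # Kahn topological sort; failure means a cycle
  remaining <- edges
  order <- character(0)
  avail <- setdiff(nodes, remaining$to)
  while (length(avail)) {
    order <- c(order, avail[1])
    remaining <- remaining[remaining$from != avail[1], , drop = FALSE]
    avail <- setdiff(setdiff(nodes, order), remaining$to)
  }
  if (length(order) != length(nodes)) stop("path model contains a cycle")
  bad <- intersect(composite, edges$to)
  if (length(bad))
    stop("composite variable(s) may only be exogenous sources: ",
         paste(bad, collapse = ", "))
  structure(list(nodes = order, edges = edges,
                 composite = intersect(composite, nodes), random = random),
            class = "path_model")
}

parents_of <- function(model, node) model$edges$from[model$edges$to == node]

#' Convenience constructor for the seasonal seagrass mediation model
#'
#' The candidate topologies for one fish response: season drives seagrass
#' cover; cover drives the fish response; and optionally season also drives
#' the response directly. Omitting the direct path puts the season-response
#' independence claim in the basis set, so Fisher's C tests whether the
#' seasonal signal in fish is fully cover-mediated.
#'
#' @param response name of the fish response column.
#' @param cover name of the seagrass cover column.
#' @param direct include the direct season -> response path?
#' @return a [path_model()].
#' @export
seagrass_path_model <- function(response = "total_density",
                                cover = "mean_cover_pct", direct = FALSE) {
  e <- data.frame(from = c("season", cover),
                  to = c(cover, response), stringsAsFactors = FALSE)
  if (direct) e <- rbind(e, data.frame(from = "season", to = response))
  path_model(e)
}

#' D-separation basis set of a path model
#'
#' One independence claim per non-adjacent node pair: the pair's later node
#' (in topological order; the endogenous one if only one is endogenous) is
#' regressed on the earlier node plus the union of both nodes' parents.
#' Pairs of exogenous variables are allowed to covary freely and generate no
#' claim. Claims involving a composite variable condition on / test all its
#' dummy columns jointly.
#'
#' @param model a [path_model()].
#' @return list of claims, each `list(x, y, conditioning)` meaning
#'   `y` is claimed independent of `x` given `conditioning`.
#' @export
basis_set <- function(model) {
  nodes <- sort(model$nodes)
  adj <- paste(model$edges$from, model$edges$to)
  exo <- setdiff(nodes, model$edges$to)
  # transitive reachability, to orient claims from cause to effect
  reach <- function(from, to) {
    frontier <- from
    seen <- character(0)
    while (length(frontier)) {
      nxt <- unique(model$edges$to[model$edges$from %in% frontier])
      nxt <- setdiff(nxt, seen)
      if (to %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    FALSE
  }
  claims <- list()
  if (length(nodes) < 2) return(claims)
  for (i in seq_len(length(nodes) - 1)) {
    for (j in (i + 1):length(nodes)) {
      a <- nodes[i]; b <- nodes[j]          # alphabetical: a < b
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      if (a %in% exo && b %in% exo) next
      # response is the effect end: a descendant, or the endogenous node, or
      # (both endogenous, causally unordered) the alphabetically later one
      if (reach(b, a) || b %in% exo) { tmp <- a; a <- b; b <- tmp }
      cond <- setdiff(union(parents_of(model, a), parents_of(model, b)),
                      c(a, b))
      claims[[length(claims) + 1]] <- list(x = a, y = b, conditioning = cond)
    }
  }
  claims
}

#' Fisher's C statistic
#'
#' Combines the basis-set p-values: \eqn{C = -2 \sum_i \ln p_i}, compared to
#' a chi-squared distribution with \eqn{2k} degrees of freedom. An empty
#' basis set (saturated model) gives C = 0, p = 1. The model is accepted —
#' consistent with the data, no missing paths — when p > the significance
#' level.
#'
#' @param pvalues numeric vector of basis-claim p-values in (0, 1].
#' @return named numeric `c(c, df, p)`.
#' @export
fishers_c <- function(pvalues) {
  if (length(pvalues) == 0) return(c(c = 0, df = 0, p = 1))
  if (any(pvalues <= 0))
    stop("p-values must be positive; floor degenerate claims at machine precision")
  if (any(pvalues > 1)) stop("p-values must be at most 1")
  C <- -2 * sum(log(pvalues))
  df <- 2 * length(pvalues)
  c(c = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

# fit one node model: response ~ predictors (+ (1|random) when available);
# falls back to ordinary least squares when the mixed fit is impossible
fit_node <- function(response, predictors, data, random) {
  rhs <- if (length(predictors)) predictors else "1"
  use_lmm <- !is.null(random) && random %in% names(data) &&
    length(unique(data[[random]])) >= 2
  if (use_lmm) {
    form <- stats::reformulate(c(rhs, paste0("(1|", random, ")")),
                               response = response)
    fit <- tryCatch(suppressWarnings(suppressMessages(
      lmerTest::lmer(form, data = data))), error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, tag = "lmm"))
  }
  form <- stats::reformulate(rhs, response = response)
  list(fit = stats::lm(form, data = data), tag = "ols")
}

# p-value for one predictor in a node fit: joint Type III F for composites,
# coefficient t-test otherwise
term_p <- function(nodefit, term, composite) {
  fit <- nodefit$fit
  if (term %in% composite) {
    a <- if (nodefit$tag == "lmm") stats::anova(fit, type = 3, ddf = "Satterthwaite")
      else stats::anova(fit)
    p <- a[rownames(a) == term, ncol(a)]
    return(as.numeric(p))
  }
  cf <- suppressWarnings(stats::coef(summary(fit)))
  as.numeric(cf[term, ncol(cf)])
}

#' Fit a piecewise structural equation model
#'
#' Fits every endogenous node's regression (mixed model with the model's
#' random intercept where the grouping is available, otherwise ordinary least
#' squares, tagged), evaluates each d-separation claim, and combines the
#' claim p-values into Fisher's C. Standardized coefficients are the raw
#' coefficients scaled by sd(x)/sd(y); coefficients of composite variables
#' are reported per dummy column but flagged sign-uninterpretable.
#'
#' @param model a [path_model()].
#' @param data data.frame with one row per replicate (e.g. transect) holding
#'   every node column and the random grouping column.
#' @param management_subset optional `"MPA"` or `"open"`: restrict to one
#'   management level (the split used when season and management interact).
#' @param alpha significance level for the acceptance rule.
#' @return object of class `"sem_fit"`: `paths` (from, to, estimate,
#'   std_estimate, p, interpretable, fit_tag), `claims` (x, y,
#'   conditioning, p), `fisher_c = c(c, df, p)`, `accepted`, `node_r2`, `n`.
#' @export
fit_psem <- function(model, data, management_subset = NULL, alpha = 0.05) {
  if (!is.null(management_subset))
    data <- data[data$management == management_subset, , drop = FALSE]
  missing_cols <- setdiff(c(model$nodes, model$random), names(data))
  if (length(missing_cols))
    stop("data lacks node column(s): ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[model$nodes]), , drop = FALSE]
  for (comp in model$composite) data[[comp]] <- factor(data[[comp]])

  endo <- intersect(model$nodes, unique(model$edges$to))
  node_fits <- list()
  node_r2 <- c()
  paths <- list()
  for (node in endo) {
    pars <- parents_of(model, node)
    nf <- fit_node(node, pars, data, model$random)
    if (is.null(nf$fit)) stop("could not fit node model: ", node)
    node_fits[[node]] <- nf
    node_r2[node] <- if (nf$tag == "lmm") {
      vc <- as.data.frame(lme4::VarCorr(nf$fit))
      X <- stats::model.matrix(nf$fit)
      vf <- stats::var(as.vector(X %*% lme4::fixef(nf$fit)))
      vs <- vc$vcov[vc$grp == model$random][1]
      vr <- vc$vcov[vc$grp == "Residual"][1]
      (vf + vs) / (vf + vs + vr)
    } else suppressWarnings(summary(nf$fit)$r.squared)
    cf <- suppressWarnings(stats::coef(summary(nf$fit)))
    sdy <- stats::sd(data[[node]])
    for (par in pars) {
      if (par %in% model$composite) {
        rows <- grep(paste0("^", par), rownames(cf))
        for (r in rows) {
          paths[[length(paths) + 1]] <- data.frame(
            from = par, to = node, coefficient = rownames(cf)[r],
            estimate = cf[r, 1], std_estimate = NA_real_,
            p = term_p(nf, par, model$composite),
            interpretable = FALSE, fit_tag = nf$tag, stringsAsFactors = FALSE)
        }
      } else {
        est <- cf[par, 1]
        paths[[length(paths) + 1]] <- data.frame(
          from = par, to = node, coefficient = par, estimate = est,
          std_estimate = est * stats::sd(data[[par]]) / sdy,
          p = term_p(nf, par, model$composite),
          interpretable = TRUE, fit_tag = nf$tag, stringsAsFactors = FALSE)
      }
    }
  }
  paths <- if (length(paths)) do.call(rbind, paths) else NULL

  claims <- basis_set(model)
  claim_rows <- list()
  pvals <- numeric(0)
  for (cl in claims) {
    nf <- fit_node(cl$y, c(cl$x, cl$conditioning), data, model$random)
    p <- term_p(nf, cl$x, model$composite)
    if (!is.finite(p)) p <- 1
    if (p <= 0) {
      warning("d-separation claim p-value of 0 floored at machine precision")
      p <- .Machine$double.eps
    }
    pvals <- c(pvals, p)
    claim_rows[[length(claim_rows) + 1]] <- data.frame(
      x = cl$x, y = cl$y,
      conditioning = paste(cl$conditioning, collapse = "+"),
      p = p, fit_tag = nf$tag, stringsAsFactors = FALSE)
  }
  fc <- fishers_c(pvals)
  structure(list(model = model,
                 paths = paths,
                 claims = if (length(claim_rows)) do.call(rbind, claim_rows)
                          else NULL,
                 fisher_c = fc, accepted = unname(fc["p"] > alpha),
                 node_r2 = node_r2, node_fits = node_fits, n = nrow(data),
                 management_subset = management_subset),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Piecewise SEM",
      if (!is.null(x$management_subset)) paste0("(", x$management_subset, " sites)"),
      "- N =", x$n, "\n")
  cat("Fisher's C =", signif(x$fisher_c["c"], 4), "df =", x$fisher_c["df"],
      "p =", signif(x$fisher_c["p"], 4),
      if (x$accepted) "[accepted]\n" else "[rejected: missing path(s)]\n")
  if (!is.null(x$paths)) {
    cat("Paths:\n")
    print.data.frame(format(x$paths, digits = 3), row.names = FALSE)
  }
  cat("Conditional R2 per node:\n")
  print(round(x$node_r2, 3))
  invisible(x)
}
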