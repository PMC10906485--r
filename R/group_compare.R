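#' Holm-Bonferroni step-down adjustment
#'
#' Step-down multiple-testing correction over `m` comparisons: sort the raw
#' p-values ascending, multiply the i-th smallest by (m - i + 1), enforce a
#' running maximum, cap at 1, and return in the original order. Delegates to
#' [stats::p.adjust()] with `method = "holm"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p, m = length(p)) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p)) stop("m must be at least length(p)")
  stats::p.adjust(p, method = "holm", n = m)
}

# One-way ANOVA F statistics for a (possibly multi-column) response matrix
# Y (n x r) under fixed group labels. Returns a list with per-column F,
# within-group mean square, and the L x r matrix of group means.
anova_stats <- function(Y, groups) {
  Y <- as.matrix(Y)
  g <- factor(groups)
  n <- nrow(Y)
  L <- nlevels(g)
  G <- stats::model.matrix(~ g - 1)           # n x L indicators
  ng <- colSums(G)
  means <- (t(G) %*% Y) / ng                  # L x r
  grand <- colMeans(Y)
  t1 <- colSums(Y^2)
  t2 <- colSums(means^2 * ng)
  ssb <- t2 - n * grand^2
  ssw <- t1 - t2
  msb <- ssb / (L - 1)
  msw <- ssw / (n - L)
  list(F = msb / msw, msw = msw, means = means, ng = ng,
       df1 = L - 1, df2 = n - L)
}

# Pairwise t statistics between group means given per-simulation means and
# within-group mean squares. means: L x r, msw: length r.
pairwise_t <- function(means, msw, ng, pairs) {
  t(vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    (means[a, ] - means[b, ]) / sqrt(msw * (1 / ng[a] + 1 / ng[b]))
  }, numeric(length(msw))))
}

#' Phylogenetic ANOVA with a Brownian simulation null
#'
#' One-way ANOVA of a trait across groups, with the null distribution of F
#' obtained by simulating Brownian motion on the phylogeny (rate set to the
#' ML Brownian rate of the observed trait) `n_sims` times, keeping the
#' observed group labels fixed, and recomputing F for each simulated trait
#' (the simulation construction of Garland et al. as popularized by
#' phytools::phylANOVA). The phylogenetic p-value uses the +1-corrected tail
#' frequency `(1 + #\{F_sim >= F_obs\}) / (1 + n_sims)`, so it is never
#' exactly zero. Pairwise post hoc t statistics (pooled within-group
#' variance) are referred to the same simulation null and Holm-adjusted over
#' the L(L-1)/2 comparisons; classical (F- and t-distribution) p-values are
#' reported alongside.
#'
#' @param response named numeric trait vector (names = tip labels).
#' @param groups factor (or coercible), same order as `response`; every
#'   level needs >= 2 members.
#' @param tree a `phylo` object containing all of `names(response)`.
#' @param n_sims number of Brownian simulations (default 1000; fewer than
#'   100 triggers a warning, fewer than 1 an error).
#' @param seed integer seed for the simulation null (required: results are
#'   reproducible bit-for-bit given `seed` and `n_sims`).
#' @return object of class `phyl_anova`: list with `f_stat`, `df1`, `df2`,
#'   `p_classical`, `p_phylogenetic`, `n_sims`, `seed`, `group_means`,
#'   `pairwise_t`, `pairwise_p_raw`, `pairwise_p_classical`,
#'   `pairwise_p_holm`.
#' @export
phyl_anova <- function(response, groups, tree, n_sims = 1000, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_sims < 1) stop("n_sims must be at least 1")
  if (n_sims < 100) warning("n_sims < 100: phylogenetic p-values will be coarse")
  response <- as.numeric_named(response)
  g <- factor(groups)
  counts <- table(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) {
    stop("group level(s) with fewer than 2 members: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  if (stats::var(response) == 0) stop("constant response: zero total variance")
  if (!is.null(names(response))) {
    ord <- match(normalize_label(names(response)),
                 normalize_label(tree$tip.label))
    if (anyNA(ord)) {
      stop("response taxa absent from tree: ",
           paste(names(response)[is.na(ord)], collapse = ", "))
    }
    if (length(ord) != length(tree$tip.label)) {
      tree <- prune_tree(tree, names(response))
    }
  }
  C <- phylo_vcv(tree)
  if (!is.null(names(response))) {
    idx <- match(normalize_label(names(response)),
                 normalize_label(rownames(C)))
    C <- C[idx, idx]
  }
  n <- length(response)
  L <- nlevels(g)

  obs <- anova_stats(response, g)
  f_obs <- unname(obs$F)
  p_classical <- stats::pf(f_obs, obs$df1, obs$df2, lower.tail = FALSE)

  # ML Brownian rate of the observed trait (intercept-only GLS under C)
  U <- chol_cov(C)
  yw <- backsolve(U, response, transpose = TRUE)
  ones_w <- backsolve(U, rep(1, n), transpose = TRUE)
  mu <- sum(ones_w * yw) / sum(ones_w^2)
  rate <- sum((yw - mu * ones_w)^2) / n

  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * n_sims), n, n_sims)
  Ysim <- sqrt(rate) * crossprod(U, Z)        # columns ~ N(0, rate * C)

  sim <- anova_stats(Ysim, g)
  p_phylo <- (1 + sum(sim$F >= f_obs)) / (1 + n_sims)

  pairs <- t(utils::combn(L, 2L))
  t_obs <- drop(pairwise_t(obs$means, obs$msw, obs$ng, pairs))
  t_sim <- pairwise_t(sim$means, sim$msw, sim$ng, pairs)  # m x n_sims
  m <- nrow(pairs)
  p_raw <- vapply(seq_len(m), function(i) {
    (1 + sum(abs(t_sim[i, ]) >= abs(t_obs[i]))) / (1 + n_sims)
  }, numeric(1))
  p_class_pair <- 2 * stats::pt(-abs(t_obs), df = obs$df2)
  p_holm <- holm_adjust(p_raw, m = m)

  lev <- levels(g)
  pair_names <- paste(lev[pairs[, 1L]], lev[pairs[, 2L]], sep = " vs ")
  to_mat <- function(v) {
    M <- matrix(NA_real_, L, L, dimnames = list(lev, lev))
    for (i in seq_len(m)) {
      M[pairs[i, 1L], pairs[i, 2L]] <- v[i]
      M[pairs[i, 2L], pairs[i, 1L]] <- v[i]
    }
    M
  }
  names(t_obs) <- names(p_raw) <- names(p_holm) <- names(p_class_pair) <-
    pair_names
  group_means <- drop(obs$means)
  names(group_means) <- lev

  structure(list(
    f_stat = f_obs, df1 = obs$df1, df2 = obs$df2,
    p_classical = p_classical, p_phylogenetic = p_phylo,
    n_sims = n_sims, seed = as.integer(seed),
    group_means = group_means,
    pairwise_t = to_mat(abs(t_obs)), pairwise_t_signed = t_obs,
    pairwise_p_raw = p_raw, pairwise_p_raw_mat = to_mat(p_raw),
    pairwise_p_classical = p_class_pair,
    pairwise_p_holm = p_holm, pairwise_p_holm_mat = to_mat(p_holm),
    levels = lev
  ), class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F(%d, %d) = %.3f\n", x$df1, x$df2, x$f_stat))
  cat(sprintf("  P (classical)     = %.4g\n", x$p_classical))
  cat(sprintf("  P (phylogenetic)  = %.4g   [%d Brownian simulations, seed %d]\n",
              x$p_phylogenetic, x$n_sims, x$seed))
  cat("Pairwise contrasts (simulation-null p, Holm-adjusted):\n")
  tab <- data.frame(t = round(x$pairwise_t_signed, 3),
                    p_raw = round(x$pairwise_p_raw, 4),
                    p_holm = round(x$pairwise_p_holm, 4))
  print(tab)
  invisible(x)
}

#' Post hoc pairwise contrasts for a phylogenetic ANOVA
#'
#' Convenience wrapper around [phyl_anova()] returning the pairwise tables
#' only: t statistics between level means (pooled within-group variance),
#' raw simulation-null p-values, classical t-distribution p-values, and
#' Holm-adjusted p-values over the L(L-1)/2 comparisons.
#'
#' @inheritParams phyl_anova
#' @return data.frame with one row per level pair.
#' @export
posthoc_pairwise <- function(response, groups, tree, n_sims = 1000, seed) {
  res <- phyl_anova(response, groups, tree, n_sims = n_sims, seed = seed)
  pairs <- strsplit(names(res$pairwise_p_raw), " vs ", fixed = TRUE)
  data.frame(
    level_a = vapply(pairs, `[`, character(1), 1L),
    level_b = vapply(pairs, `[`, character(1), 2L),
    t = unname(res$pairwise_t_signed),
    p_raw = unname(res$pairwise_p_raw),
    p_classical = unname(res$pairwise_p_classical),
    p_holm = unname(res$pairwise_p_holm),
    stringsAsFactors = FALSE
  )
}

#' Estimated marginal group means under a phylogenetic covariance
#'
#' Level means estimated as the coefficients of a one-way GLS fit under C
#' with cell-means coding; standard errors come from the GLS coefficient
#' covariance. With `C` the identity these are the arithmetic group means
#' with the usual pooled-variance standard errors. Arithmetic means are
#' reported alongside, since on a clustered tree the GLS means shrink
#' toward the clade root states.
#'
#' @param response named numeric vector, taxon-aligned with `C`.
#' @param groups factor (or coercible), same order as `response`.
#' @param C phylogenetic covariance matrix.
#' @return data.frame with columns `level`, `n`, `mean_gls`, `se_gls`,
#'   `mean_arithmetic`.
#' @export
marginal_means <- function(response, groups, C) {
  g <- factor(groups)
  X <- stats::model.matrix(~ g - 1)
  colnames(X) <- levels(g)
  rownames(X) <- names(response)
  fit <- fit_gls(X, response, C)
  data.frame(
    level = levels(g),
    n = as.integer(table(g)),
    mean_gls = unname(fit$beta),
    se_gls = unname(fit$se),
    mean_arithmetic = as.numeric(tapply(as.numeric(response), g, mean)),
    stringsAsFactors = FALSE
  )
}
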