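# Independent oracles used across tests. These deliberately take the slow,
# literal route (edge-set enumeration, leave-one-out refits, explicit
# matrix inverses) so they share no code path with the implementation.

# Brute-force Brownian VCV: for each tip, enumerate the edge set of its
# root-to-tip path; shared branch length is the summed length of the
# intersection of the two edge sets.
bf_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_edge <- function(node) which(tree$edge[, 2L] == node)
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge(node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1L]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}

# Literal step-down Holm adjustment.
bf_holm <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(ord)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Leave-one-out Cook's distance oracle for OLS:
# D_i = sum_j (yhat_j - yhat_j(-i))^2 / (p * sigma2_hat).
loo_cooks <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  yhat <- fit$fitted.values
  sigma2 <- sum(fit$residuals^2) / (n - p)
  vapply(seq_len(n), function(i) {
    fit_i <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
    yhat_i <- drop(X %*% fit_i$coefficients)
    sum((yhat - yhat_i)^2) / (p * sigma2)
  }, numeric(1))
}

# Explicit-inverse GLS oracle: beta = (X' C^-1 X)^-1 X' C^-1 y.
explicit_gls <- function(X, y, C) {
  Ci <- solve(C)
  XtCi <- t(X) %*% Ci
  cov_unscaled <- solve(XtCi %*% X)
  beta <- drop(cov_unscaled %*% XtCi %*% y)
  resid <- y - drop(X %*% beta)
  sigma2 <- drop(t(resid) %*% Ci %*% resid) / (nrow(X) - ncol(X))
  list(beta = beta, se = sqrt(diag(cov_unscaled) * sigma2), sigma2 = sigma2)
}

# Random non-ultrametric tree with positive branch lengths.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}
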