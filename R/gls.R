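# Cholesky factor of a covariance matrix, with an eigenvalue-clipping
# fallback for near-singular matrices (e.g. zero-length terminal branches).
chol_cov <- function(C, clip = 1e-10) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    E <- eigen((C + t(C)) / 2, symmetric = TRUE)
    vals <- pmax(E$values, clip)
    U <- tryCatch(chol(E$vectors %*% (vals * t(E$vectors))),
                  error = function(e) NULL)
    if (is.null(U)) stop("phylogenetic covariance matrix is singular")
  }
  U
}

check_alignment <- function(design, response, C) {
  taxa <- rownames(C)
  rn <- rownames(design)
  yn <- names(response)
  if (!is.null(taxa)) {
    if (!is.null(rn) && !identical(rn, taxa)) {
      stop("taxon-order mismatch between design matrix and covariance")
    }
    if (!is.null(yn) && !identical(yn, taxa)) {
      stop("taxon-order mismatch between response and covariance")
    }
  }
  invisible(TRUE)
}

#' Phylogenetic generalized least squares fit
#'
#' Fits the linear model `response = design %*% beta + e`, with
#' `e ~ N(0, sigma2 * C)` and C a phylogenetic covariance from
#' [phylo_vcv()] (optionally lambda-transformed). Estimation is by GLS:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, computed through the Cholesky factor
#' of C (whitening). The reported `sigma2` is the unbiased estimate
#' RSS/(n - p); the log-likelihood is the maximized (ML-scale) Gaussian
#' likelihood, so AIC values are comparable across fixed-effect structures.
#' AIC counts k = p + 1 parameters (coefficients plus sigma2).
#'
#' R-squared is the GLS generalization 1 - RSS_C / TSS_C, where TSS_C comes
#' from the intercept-only GLS fit under the same C; it is reported only for
#' models containing an intercept. Cook's distances are computed on the
#' whitened model (standard OLS leverage formula after premultiplying X and
#' y by the inverse Cholesky factor of C).
#'
#' @param design n x p numeric model matrix (include an intercept column for
#'   the usual regression setting); rows aligned with the taxa of `C`.
#' @param response numeric vector of length n.
#' @param C n x n phylogenetic covariance matrix; the identity reduces the
#'   fit to ordinary least squares.
#' @return an object of class `gls_fit`: a list with elements `beta`, `se`,
#'   `t_stats`, `p_values`, `df_residual`, `sigma2`, `loglik`, `aic`,
#'   `r_squared`, `residuals`, `fitted`, `cooks_d`, `n_obs`,
#'   `predictor_names`, `k`.
#' @export
fit_gls <- function(design, response, C) {
  design <- as.matrix(design)
  response <- as.numeric_named(response)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  n <- length(response)
  p <- ncol(design)
  if (nrow(design) != n || nrow(C) != n) {
    stop("dimension mismatch between design, response and covariance")
  }
  if (p >= n) stop("more parameters than observations")
  check_alignment(design, response, C)

  U <- chol_cov(C)
  Xw <- backsolve(U, design, transpose = TRUE)
  yw <- backsolve(U, response, transpose = TRUE)

  XtX <- crossprod(Xw)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    stop("rank-deficient design matrix (collinear or constant predictors)")
  }
  XtX_inv <- chol2inv(chol(XtX))
  beta <- drop(XtX_inv %*% crossprod(Xw, yw))
  names(beta) <- colnames(design)

  fitted <- drop(design %*% beta)
  resid <- response - fitted
  rw <- yw - drop(Xw %*% beta)
  rss <- sum(rw^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  se <- stats::setNames(sqrt(diag(XtX_inv) * sigma2), colnames(design))
  t_stats <- beta / se
  p_values <- 2 * stats::pt(-abs(t_stats), df = df_res)

  logdetC <- 2 * sum(log(diag(U)))
  s2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi) + n * log(s2_ml) + logdetC + n)
  k <- p + 1
  aic <- -2 * loglik + 2 * k

  # R^2 against the GLS intercept-only fit under the same C
  has_intercept <- any(apply(design, 2L, function(col) {
    all(abs(col - col[1L]) < 1e-12) && abs(col[1L]) > 0
  }))
  r_squared <- NA_real_
  if (has_intercept) {
    ones_w <- backsolve(U, rep(1, n), transpose = TRUE)
    mu0 <- sum(ones_w * yw) / sum(ones_w^2)
    tss <- sum((yw - mu0 * ones_w)^2)
    r_squared <- if (tss > 0) 1 - rss / tss else NA_real_
  }

  # Cook's distance on the whitened model
  h <- rowSums((Xw %*% XtX_inv) * Xw)
  cooks_d <- (rw^2 * h) / (p * sigma2 * (1 - h)^2)
  names(cooks_d) <- names(response)
  names(resid) <- names(response)
  names(fitted) <- names(response)

  structure(list(
    beta = beta, se = se, t_stats = t_stats, p_values = p_values,
    df_residual = df_res, sigma2 = sigma2, loglik = loglik, aic = aic,
    r_squared = r_squared, residuals = resid, fitted = fitted,
    cooks_d = cooks_d, n_obs = n, predictor_names = colnames(design), k = k
  ), class = "gls_fit")
}

as.numeric_named <- function(x) {
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  x
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("Generalized least squares fit (n = %d, df = %d)\n",
              x$n_obs, x$df_residual))
  tab <- data.frame(Estimate = x$beta, `Std.Error` = x$se,
                    t = x$t_stats, `p` = x$p_values,
                    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("sigma2 = %.4g  logLik = %.3f  AIC = %.2f  R2 = %s\n",
              x$sigma2, x$loglik, x$aic,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

#' Cook's distances for a GLS model
#'
#' Influence diagnostics computed on the whitened model: X and y are
#' premultiplied by the inverse Cholesky factor of C, then the standard OLS
#' Cook's distance formula is applied. With `C` the identity this is the
#' textbook OLS Cook's distance.
#'
#' @inheritParams fit_gls
#' @return numeric vector of Cook's distances in taxon order.
#' @export
cooks_distance_gls <- function(design, response, C) {
  n <- length(response)
  p <- ncol(as.matrix(design))
  if (n - p < 2) stop("need at least 2 residual degrees of freedom")
  fit_gls(design, response, C)$cooks_d
}

# Profile log-likelihood of an intercept-only Gaussian model with
# covariance sigma2 * C, maximized over the mean and sigma2 (ML scale).
loglik_intercept_only <- function(response, C) {
  n <- length(response)
  U <- chol_cov(C)
  yw <- backsolve(U, response, transpose = TRUE)
  ones_w <- backsolve(U, rep(1, n), transpose = TRUE)
  mu <- sum(ones_w * yw) / sum(ones_w^2)
  rss <- sum((yw - mu * ones_w)^2)
  logdetC <- 2 * sum(log(diag(U)))
  -0.5 * (n * log(2 * pi) + n * log(rss / n) + logdetC + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Estimates the phylogenetic-signal parameter lambda of a single trait by
#' maximizing the intercept-only Gaussian log-likelihood over
#' lambda-transformed covariances `lambda_transform(C, lambda)` on \[0, 1\]
#' (bounded scalar optimization, tolerance 1e-8, with both endpoints
#' checked). Significance against lambda = 0 is assessed by a likelihood
#' ratio test; by default the plain upper chi-squared(1) tail is used
#' (conservative at the boundary), with the 50:50 point-mass/chi-squared
#' boundary mixture available via `mixture = TRUE`.
#'
#' @param response named numeric trait vector, taxon-aligned with `C`.
#' @param C Brownian covariance from [phylo_vcv()].
#' @param mixture logical; use the boundary 50:50 mixture null for the LRT
#'   p-value instead of the plain chi-squared(1) tail.
#' @return an object of class `lambda_result`: list with `lambda_hat`,
#'   `loglik_hat`, `loglik_zero`, `lrt_stat`, `p_value`, `mixture`.
#' @export
pagels_lambda <- function(response, C, mixture = FALSE) {
  response <- as.numeric_named(response)
  n <- length(response)
  if (n < 4L) stop("need at least 4 taxa to estimate lambda")
  if (stats::var(response) == 0) stop("constant response: lambda undefined")
  stopifnot(is.matrix(C), nrow(C) == n)
  off <- C[upper.tri(C)]
  if (all(abs(off) < 1e-12 * max(diag(C)))) {
    stop("lambda unidentifiable: star-tree covariance (all off-diagonals zero)")
  }
  check_alignment(matrix(1, n, 1, dimnames = list(rownames(C), NULL)),
                  response, C)

  ll <- function(lam) loglik_intercept_only(response, lambda_transform(C, lam))
  opt <- stats::optimise(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  cand_lam <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll(0), ll(1))
  best <- which.max(cand_ll)
  lambda_hat <- cand_lam[best]
  loglik_hat <- cand_ll[best]
  loglik_zero <- cand_ll[2L]
  lrt <- max(0, 2 * (loglik_hat - loglik_zero))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (lrt <= 0) 1 else 0.5 * p

  structure(list(lambda_hat = lambda_hat, loglik_hat = loglik_hat,
                 loglik_zero = loglik_zero, lrt_stat = lrt, p_value = p,
                 mixture = mixture),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4f  (logLik = %.3f)\n",
              x$lambda_hat, x$loglik_hat))
  cat(sprintf("LRT vs lambda = 0: chisq = %.3f, P = %.4g%s\n",
              x$lrt_stat, x$p_value,
              if (x$mixture) " (boundary mixture)" else ""))
  invisible(x)
}

#' Phylogenetic ANCOVA with a slope-heterogeneity test
#'
#' Fits `response ~ continuous * factor` by GLS under C (treatment coding,
#' first level alphabetically as the reference) and tests the interaction:
#' for a 2-level factor the t-test on the interaction coefficient, for more
#' levels a likelihood-ratio test against the additive model. Used in the
#' pipeline to test whether behavioral and RGC-derived acuities share an
#' acuity-eye size slope and may be pooled.
#'
#' @param response,continuous_pred numeric vectors, taxon-aligned with `C`.
#' @param factor_pred factor (or coercible) with >= 2 levels, each with
#'   >= 2 observations.
#' @param C phylogenetic covariance matrix.
#' @return list with `fit_full`, `fit_reduced` (`gls_fit` objects),
#'   `p_interaction`, and `test` (`"t"` or `"lrt"`).
#' @export
ancova_interaction <- function(response, continuous_pred, factor_pred, C) {
  f <- factor(factor_pred)
  f <- factor(f, levels = sort(levels(f)))
  counts <- table(f)
  if (nlevels(f) < 2L) stop("factor must have at least 2 levels")
  if (any(counts < 2L)) {
    stop("factor level(s) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  df <- data.frame(x = as.numeric(continuous_pred), g = f)
  X_full <- stats::model.matrix(~ x * g, data = df)
  X_red <- stats::model.matrix(~ x + g, data = df)
  rownames(X_full) <- rownames(X_red) <- names(response)
  fit_full <- fit_gls(X_full, response, C)
  fit_red <- fit_gls(X_red, response, C)

  if (nlevels(f) == 2L) {
    ix <- grep("^x:g", names(fit_full$beta))
    p_int <- unname(fit_full$p_values[ix])
    test <- "t"
  } else {
    stat <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
    p_int <- stats::pchisq(stat, df = nlevels(f) - 1L, lower.tail = FALSE)
    test <- "lrt"
  }
  list(fit_full = fit_full, fit_reduced = fit_red,
       p_interaction = p_int, test = test)
}

#' Residual cascade: relative eye size and residual acuity
#'
#' Stage 1 regresses log eye size on log body mass by PGLS under C;
#' the residuals are "relative eye size" (positive values mean larger eyes
#' than the allometric expectation for that body mass). Stage 2 regresses
#' log acuity on relative eye size under the same C; the residuals are
#' "residual acuity", the part of acuity not explained by eye investment.
#'
#' @param log_acuity,log_eye,log_mass named numeric vectors (already
#'   log-transformed), taxon-aligned with `C`.
#' @param C phylogenetic covariance matrix.
#' @return list with `relative_eye_size`, `residual_acuity`, `stage1`,
#'   `stage2` (the two `gls_fit` objects).
#' @export
residual_cascade <- function(log_acuity, log_eye, log_mass, C) {
  taxa <- names(log_acuity)
  X1 <- cbind(`(Intercept)` = 1, log_mass = as.numeric(log_mass))
  rownames(X1) <- taxa
  stage1 <- fit_gls(X1, log_eye, C)
  rel <- stage1$residuals
  if (stats::var(rel) < 1e-20) {
    stop("relative eye size is constant (zero residual variance); ",
         "stage-2 design is rank-deficient")
  }
  X2 <- cbind(`(Intercept)` = 1, relative_eye_size = as.numeric(rel))
  rownames(X2) <- taxa
  stage2 <- fit_gls(X2, log_acuity, C)
  list(relative_eye_size = rel, residual_acuity = stage2$residuals,
       stage1 = stage1, stage2 = stage2)
}
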