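make_design <- function(x, taxa = NULL) {
  X <- cbind(`(Intercept)` = 1, x = x)
  rownames(X) <- taxa
  X
}

test_that("a perfect linear relationship is fit exactly", {
  X <- make_design(c(1, 2, 3))
  fit <- fit_gls(X, c(1, 2, 3), diag(3))
  expect_equal(unname(fit$beta), c(0, 1), tolerance = 1e-12)
  expect_equal(unname(fit$residuals), rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    x <- rnorm(n); z <- rnorm(n)
    y <- 1 + 0.5 * x - 0.3 * z + rnorm(n)
    X <- cbind(`(Intercept)` = 1, x = x, z = z)
    fit <- fit_gls(X, y, diag(n))
    ols <- summary(lm(y ~ x + z))
    expect_equal(unname(fit$beta), unname(coef(ols)[, 1]), tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(coef(ols)[, 2]), tolerance = 1e-10)
    expect_equal(unname(fit$t_stats), unname(coef(ols)[, 3]),
                 tolerance = 1e-10)
    expect_equal(fit$r_squared, ols$r.squared, tolerance = 1e-10)
    # scaled identity leaves coefficients, SEs and t statistics unchanged
    fit2 <- fit_gls(X, y, 3.7 * diag(n))
    expect_equal(fit2$beta, fit$beta, tolerance = 1e-10)
    expect_equal(fit2$se, fit$se, tolerance = 1e-10)
    expect_equal(fit2$t_stats, fit$t_stats, tolerance = 1e-10)
  }
})

test_that("PGLS on the worked 3-taxon tree matches the explicit-inverse oracle", {
  C <- phylo_vcv(parse_newick("((A:1,B:1):0.5,C:1.5);"))
  X <- make_design(c(0, 1, 2), rownames(C))
  y <- c(A = 0, B = 2, C = 3)
  fit <- fit_gls(X, y, C)
  oracle <- explicit_gls(X, y, unclass(C)[, ])
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-10)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-10)
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(111)
  tr <- simulate_yule_tree(25, seed = 7)
  C <- phylo_vcv(tr)
  x <- simulate_bm(tr, sigma2 = 1)
  y <- 1 + 0.5 * x + simulate_bm(tr, sigma2 = 0.3)
  fit <- fit_gls(make_design(x, tr$tip.label), y, C)
  df <- data.frame(y = y, x = x, row.names = tr$tip.label)
  df$sp <- factor(tr$tip.label, levels = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("log-likelihood is invariant to a consistent taxon permutation", {
  set.seed(121)
  tr <- simulate_yule_tree(15, seed = 3)
  C <- unclass(phylo_vcv(tr))[, ]
  x <- rnorm(15); y <- 1 + x + rnorm(15)
  X <- make_design(x, rownames(C))
  fit <- fit_gls(X, setNames(y, rownames(C)), C)
  perm <- sample(15)
  fit_p <- fit_gls(X[perm, ], setNames(y[perm], rownames(C)[perm]),
                   C[perm, perm])
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(sort(names(fit_p$beta)), sort(names(fit$beta)))
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-9)
})

test_that("degenerate designs and misalignment are rejected", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_gls(X, c(1, 2, 3, 4), diag(4)), "rank-deficient")
  expect_error(fit_gls(diag(3), c(1, 2, 3), diag(3)), "more parameters")
  C <- phylo_vcv(parse_newick("((A:1,B:1):0.5,C:1.5);"))
  Xn <- make_design(1:3, c("C", "B", "A"))
  expect_error(fit_gls(Xn, setNames(1:3, c("C", "B", "A")), C), "mismatch")
  expect_error(fit_gls(make_design(1:3), 1:3, diag(4)), "dimension")
})

test_that("Cook's distance matches OLS formulas and the leave-one-out oracle", {
  set.seed(131)
  n <- 20
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  X <- make_design(x)
  d <- cooks_distance_gls(X, y, diag(n))
  expect_equal(unname(d), unname(cooks.distance(lm(y ~ x))),
               tolerance = 1e-10)
  expect_equal(unname(d), loo_cooks(X, y), tolerance = 1e-8)

  # a gross outlier dominates
  y_out <- y; y_out[7] <- y_out[7] + 25
  d_out <- cooks_distance_gls(X, y_out, diag(n))
  expect_equal(which.max(d_out), 7L)
  expect_true(all(d >= 0))
})

test_that("whitened Cook's distance under a tree covariance matches a manual whitening", {
  set.seed(141)
  tr <- simulate_yule_tree(18, seed = 9)
  C <- unclass(phylo_vcv(tr))[, ]
  x <- rnorm(18); y <- 1 + x + drop(t(chol(C)) %*% rnorm(18))
  X <- make_design(x, rownames(C))
  d <- cooks_distance_gls(X, setNames(y, rownames(C)), C)
  U <- chol(C)
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  expect_equal(unname(d), loo_cooks(Xw, yw), tolerance = 1e-8)
})

test_that("residual cascade recovers injected eye-investment offsets", {
  set.seed(151)
  hits <- 0L
  for (rep in 1:10) {
    sim <- simulate_dataset(synthetic_params(n_tips = 50, seed = 1000 + rep))
    C <- phylo_vcv(sim$tree)
    log_eye <- sim$truth$log_eye
    marked <- sample(sim$tree$tip.label, 10)
    offset <- 3 * sd(sim$truth$noise_eye)
    log_eye[marked] <- log_eye[marked] + offset
    cas <- residual_cascade(sim$truth$log_acuity, log_eye,
                            sim$truth$log_mass, C)
    if (mean(cas$relative_eye_size[marked]) >
        mean(cas$relative_eye_size[setdiff(names(log_eye), marked)])) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 10L)
})

test_that("zero residual noise makes the stage-2 design degenerate", {
  sim <- simulate_dataset(synthetic_params(n_tips = 20, seed = 5,
                                           sigma2_eye = 0,
                                           sigma2_acuity = 0))
  C <- phylo_vcv(sim$tree)
  expect_error(residual_cascade(sim$truth$log_acuity, sim$truth$log_eye,
                                sim$truth$log_mass, C),
               "constant|rank-deficient")
})
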