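test_that("Holm adjustment applies the step-down rule", {
  expect_equal(holm_adjust(c(0.04, 0.01, 0.03)), c(0.06, 0.03, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(holm_adjust(0.02), 0.02)   # single comparison unchanged
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(-0.1)), "\\[0, 1\\]")

  set.seed(401)
  for (rep in 1:200) {
    p <- runif(sample(1:8, 1))
    expect_equal(holm_adjust(p), bf_holm(p))
    expect_true(all(holm_adjust(p) >= p))
  }
  # m larger than the vector length
  expect_equal(holm_adjust(c(0.01, 0.04), m = 4), bf_holm(c(0.01, 0.04), 4))
})

test_that("phylogenetic ANOVA is reproducible and classically calibrated on a star tree", {
  star <- parse_newick(paste0("(", paste0("t", 1:30, ":1", collapse = ","),
                              ");"))
  set.seed(411)
  y <- setNames(rnorm(30), star$tip.label)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  res1 <- phyl_anova(y, g, star, n_sims = 3000, seed = 99)
  res2 <- phyl_anova(y, g, star, n_sims = 3000, seed = 99)
  expect_identical(res1$p_phylogenetic, res2$p_phylogenetic)
  expect_identical(res1$pairwise_p_raw, res2$pairwise_p_raw)

  # classical F test agrees with stats::anova
  ref <- anova(lm(y ~ g))
  expect_equal(res1$f_stat, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res1$p_classical, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # on a star tree the simulation null converges to the classical p
  mc_se <- sqrt(res1$p_classical * (1 - res1$p_classical) / 3000)
  expect_lt(abs(res1$p_phylogenetic - res1$p_classical), 4 * mc_se + 1e-3)
})

test_that("a strongly shifted group is detected on a star tree", {
  star <- parse_newick(paste0("(", paste0("t", 1:24, ":1", collapse = ","),
                              ");"))
  g <- factor(rep(c("a", "b"), each = 12))
  set.seed(421)
  detected <- 0L
  for (rep in 1:10) {
    y <- rnorm(24)
    y[g == "b"] <- y[g == "b"] + 5 * sd(y)
    names(y) <- star$tip.label
    res <- phyl_anova(y, g, star, n_sims = 300, seed = rep)
    if (res$p_phylogenetic < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 10L)
})

test_that("increasing a group shift never decreases F (noise held fixed)", {
  set.seed(431)
  n <- 30
  noise <- rnorm(n)
  g <- factor(rep(c("a", "b"), each = n / 2))
  f_at <- function(shift) {
    y <- noise + shift * (g == "b")
    anova(lm(y ~ g))$`F value`[1]
  }
  shifts <- seq(0.5, 5, by = 0.5)
  fs <- vapply(shifts, f_at, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("ANOVA input validation catches degenerate cases", {
  tr <- simulate_yule_tree(12, seed = 5)
  y <- setNames(rnorm(12), tr$tip.label)
  expect_error(phyl_anova(y, factor(rep("a", 12)), tr, seed = 1),
               "at least 2 groups")
  expect_error(phyl_anova(y, factor(c("a", rep("b", 11))), tr, seed = 1),
               "fewer than 2")
  expect_error(phyl_anova(setNames(rep(1, 12), tr$tip.label),
                          factor(rep(c("a", "b"), 6)), tr, seed = 1),
               "constant|variance")
  expect_error(phyl_anova(y, factor(rep(c("a", "b"), 6)), tr, n_sims = 0,
                          seed = 1), "at least 1")
  expect_warning(phyl_anova(y, factor(rep(c("a", "b"), 6)), tr, n_sims = 50,
                            seed = 1), "coarse")
})

test_that("post hoc contrasts have the right combinatorics and Holm behavior", {
  tr <- simulate_yule_tree(40, seed = 31)
  set.seed(441)
  y <- simulate_bm(tr)
  g4 <- factor(rep(c("a", "b", "c", "d"), each = 10))
  tab <- posthoc_pairwise(y, g4, tr, n_sims = 200, seed = 2)
  expect_equal(nrow(tab), 6)              # 4 levels -> 6 contrasts
  expect_equal(tab$p_holm, bf_holm(tab$p_raw), tolerance = 1e-12)

  g2 <- factor(rep(c("a", "b"), each = 20))
  tab2 <- posthoc_pairwise(y, g2, tr, n_sims = 200, seed = 2)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$p_holm, tab2$p_raw)   # Holm is the identity for m = 1
})

test_that("marginal means reduce to arithmetic means under identity C", {
  set.seed(451)
  n <- 24
  y <- setNames(rnorm(n), paste0("s", 1:n))
  g <- factor(rep(c("a", "b"), each = n / 2))
  mm <- marginal_means(y, g, diag(n))
  expect_equal(mm$mean_gls, mm$mean_arithmetic, tolerance = 1e-10)
  s_pool <- sqrt(sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (n - 2))
  expect_equal(mm$se_gls, rep(s_pool / sqrt(n / 2), 2), tolerance = 1e-10)
})

test_that("GLS marginal means on a clustered tree match the explicit oracle", {
  tr <- simulate_yule_tree(20, seed = 61)
  C <- phylo_vcv(tr)
  set.seed(461)
  y <- simulate_bm(tr)
  # one clade vs the rest: split at the root's first daughter clade
  g <- factor(ifelse(seq_len(20) <= 10, "cladeA", "rest"))
  mm <- marginal_means(y, g, C)
  X <- stats::model.matrix(~ g - 1)
  oracle <- explicit_gls(X, y, unclass(C)[, ])
  expect_equal(mm$mean_gls, unname(oracle$beta), tolerance = 1e-8)
  expect_equal(mm$se_gls, unname(oracle$se), tolerance = 1e-8)
})
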