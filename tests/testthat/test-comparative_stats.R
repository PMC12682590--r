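test_that("PGLS reduces to OLS on a star tree", {
  set.seed(101)
  tr <- star_tree(8)
  x <- setNames(rnorm(8), tr$tip.label)
  y <- setNames(1.5 * x + rnorm(8), tr$tip.label)
  fit <- pgls_fit(y, x, tr)
  ols <- summary(lm(y[tr$tip.label] ~ x[tr$tip.label]))$coefficients
  expect_equal(unname(fit$coefficients), unname(ols[, "Estimate"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$standard_errors), unname(ols[, "Std. Error"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$t_values), unname(ols[, "t value"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$p_values), unname(ols[, "Pr(>|t|)"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$t_values),
               unname(fit$coefficients / fit$standard_errors),
               tolerance = 1e-10)
})

test_that("PGLS recovers an exact linear relationship on any tree", {
  tr <- gen_tree(10, seed = 3)
  x <- setNames(seq(-1, 1, length.out = 10), tr$tip.label)
  y <- 2 * x + 1
  fit <- pgls_fit(y, x, tr)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)
})

test_that("PGLS agrees with the nlme Brownian GLS reference", {
  skip_if_not_installed("nlme")
  tr <- gen_tree(12, seed = 8)
  x <- simulate_bm(tr, 1, 1, seed = 21)[, 1]
  y <- -0.5 * x + simulate_bm(tr, 0.5, 1, seed = 22)[, 1]
  fit <- pgls_fit(y, x, tr)
  df <- data.frame(y = y, x = x, sp = names(y))
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  ref_sum <- summary(ref)$tTable
  expect_equal(unname(fit$coefficients), unname(ref_sum[, "Value"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors), unname(ref_sum[, "Std.Error"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$t_values), unname(ref_sum[, "t-value"]),
               tolerance = 1e-6)
})

test_that("the lambda = 0 structure matches OLS on an ultrametric tree", {
  set.seed(55)
  tr <- gen_tree(9, seed = 12)
  x <- setNames(rnorm(9), tr$tip.label)
  y <- setNames(rnorm(9), tr$tip.label)
  V0 <- lambda_transform(bm_vcv(tr), 0)
  core <- suturemorph:::gls_core(y, cbind(1, x), V0)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(as.numeric(core$beta)), unname(ols), tolerance = 1e-10)
})

test_that("Pagel's lambda ML matches the phytools reference", {
  skip_if_not_installed("phytools")
  tr <- gen_tree(48, seed = 30)
  # mix Brownian signal with white noise so the ML optimum is interior
  y <- simulate_bm(tr, 1, 1, seed = 31)[, 1]
  set.seed(32)
  y <- y + rnorm(48, sd = 0.4)
  mine <- fit_pagel_lambda(y, tr)
  ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(mine$lambda_hat, ref$lambda, tolerance = 0.01)
  expect_equal(mine$log_likelihood, ref$logL, tolerance = 1e-3)
  expect_error(fit_pagel_lambda(setNames(rep(1, 48), tr$tip.label), tr),
               "constant")
})

test_that("one-way ANOVA satisfies the F = t^2 identity and invariances", {
  set.seed(77)
  v <- rnorm(16)
  g <- rep(c("a", "b"), each = 8)
  res <- anova_oneway(v, g)
  expect_equal(res$F, res$pairwise$t[1]^2, tolerance = 1e-10)
  expect_equal(res$p, res$pairwise$p[1], tolerance = 1e-10)

  v3 <- rnorm(18)
  g3 <- rep(c("a", "b", "c"), each = 6)
  base <- anova_oneway(v3, g3)
  shifted <- anova_oneway(v3 + 100, g3)
  scaled <- anova_oneway(v3 * -3.5, g3)
  expect_equal(shifted$F, base$F, tolerance = 1e-9)
  expect_equal(scaled$F, base$F, tolerance = 1e-9)
  expect_equal(nrow(base$pairwise), 3L)
  expect_true(all(base$eta2g >= 0 & base$eta2g <= 1))

  flat <- anova_oneway(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$F, 0)
  expect_equal(flat$eta2g, 0)
  expect_error(anova_oneway(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("phylogenetic ANOVA is reproducible and bounded by the add-one rule", {
  tr <- gen_tree(14, seed = 40)
  y <- simulate_bm(tr, 1, 1, seed = 41)[, 1]
  g <- setNames(rep(c("generalised", "saltatorial", "cursorial"),
                    times = c(5, 5, 4)), tr$tip.label)
  r1 <- phyl_anova(y, g, tr, n_sim = 200, seed = 9)
  r2 <- phyl_anova(y, g, tr, n_sim = 200, seed = 9)
  expect_identical(r1$p_sim, r2$p_sim)
  expect_identical(r1$pairwise_sim, r2$pairwise_sim)
  expect_gte(r1$p_sim, 1 / 201)
  expect_lte(r1$p_sim, 1)
  expect_gte(min(r1$pairwise_sim$p_sim), 1 / 201)
})

test_that("phylogenetic ANOVA matches parametric ANOVA on a star tree", {
  tr <- star_tree(24)
  set.seed(50)
  y <- setNames(rnorm(24), tr$tip.label)
  g <- setNames(rep(c("a", "b", "c"), each = 8), tr$tip.label)
  par_p <- anova_oneway(y, g)$p
  sim_p <- phyl_anova(y, g, tr, n_sim = 2000, seed = 51)$p_sim
  expect_lt(abs(sim_p - par_p), 0.03)
})

test_that("phylogenetic ANOVA agrees with the phytools reference", {
  skip_if_not_installed("phytools")
  tr <- gen_tree(14, seed = 60)
  y <- simulate_bm(tr, 1, 1, seed = 61)[, 1]
  y[1:5] <- y[1:5] + 1.5
  g <- setNames(rep(c("g", "s", "c"), times = c(5, 5, 4)), tr$tip.label)
  mine <- phyl_anova(y, g, tr, n_sim = 2000, seed = 62)
  ref <- phytools::phylANOVA(tr, factor(g[tr$tip.label]), y[tr$tip.label],
                             nsim = 2000, posthoc = FALSE)
  expect_equal(mine$F, ref$F, tolerance = 1e-8)
  expect_lt(abs(mine$p_sim - ref$Pf), 0.04)
})

test_that("Procrustes PGLS detects collinear shape structure and validates input", {
  tr <- gen_tree(10, seed = 70)
  x <- simulate_bm(tr, 1, 1, seed = 71)[, 1]
  direction <- rnorm(24)
  set.seed(72)
  Y <- outer(x, direction) + matrix(rnorm(240, sd = 1e-4), 10, 24)
  rownames(Y) <- tr$tip.label
  res <- procrustes_pgls(Y, x, tr, n_perm = 199, seed = 73)
  expect_gt(res$r_squared, 0.99)
  expect_lte(res$p_perm, 0.05)
  expect_equal(res$fitted_component_variances[1], 1, tolerance = 1e-6)

  res2 <- procrustes_pgls(Y, x, tr, n_perm = 199, seed = 73)
  expect_identical(res$p_perm, res2$p_perm)
  expect_gte(res$p_perm, 1 / 200)

  const <- setNames(rep(1, 10), tr$tip.label)
  expect_error(procrustes_pgls(Y, const, tr), "constant")
})

test_that("Shapiro-Wilk wrapper enforces its domain", {
  sw <- shapiro_wilk(qnorm(((1:50) - 0.5) / 50))
  expect_gt(sw$W, 0.99)
  expect_lte(sw$W, 1)
  set.seed(80)
  expect_lte(shapiro_wilk(rexp(40))$W, 1)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "between 3 and 5000")
})
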