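# Generalised least squares internals shared by the phylogenetic models.
# V is factored once per call via its Cholesky root; the GLS problem is
# reduced to ordinary least squares on whitened data.
gls_core <- function(y, X, V) {
  R <- tryCatch(chol(V), error = function(e) {
    stop_validation("phylogenetic covariance matrix is singular or not positive definite; check for zero-length branches or duplicated taxa")
  })
  A <- backsolve(R, X, transpose = TRUE)
  b <- backsolve(R, y, transpose = TRUE)
  qrA <- qr(A)
  beta <- qr.coef(qrA, b)
  resid_w <- b - A %*% beta
  quad <- sum(resid_w^2)
  XtVX_inv <- chol2inv(qr.R(qrA))
  n <- length(y)
  logdetV <- 2 * sum(log(diag(R)))
  sigma2_ml <- quad / n
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetV + n)
  list(beta = beta, quad = quad, XtVX_inv = XtVX_inv, loglik = loglik,
       logdetV = logdetV)
}

#' Phylogenetic generalised least squares regression
#'
#' Fits `response ~ predictor` by generalised least squares with the
#' Brownian-motion phylogenetic covariance of `tree` as error structure:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`. With `lambda_mode = "ml"`, Pagel's
#' lambda is first estimated by maximum likelihood on the residual structure
#' and V is lambda-transformed before the fit; `"fixed_1"` uses the pure
#' Brownian V. Standard errors come from `sigma2 * (X' V^-1 X)^-1` with
#' `sigma2` estimated as the residual quadratic form over `n - q` degrees of
#' freedom; t-tests are two-sided on `n - q` df.
#'
#' @param response,predictor Named numeric vectors (species names).
#' @param tree A `"phylo"` object. Unmatched species are pruned with a
#'   warning; at least 4 matched species are required.
#' @param lambda_mode `"fixed_1"` (default, Brownian) or `"ml"`.
#' @return An object of class `pgls_result` with `coefficients`,
#'   `standard_errors`, `t_values`, `p_values`, `lambda_used`,
#'   `log_likelihood`, `n`, `df_residual` and `residuals`.
#' @export
pgls_fit <- function(response, predictor, tree,
                     lambda_mode = c("fixed_1", "ml")) {
  lambda_mode <- match.arg(lambda_mode)
  m <- match_species(tree, response = response, predictor = predictor)
  y <- m$response
  x <- m$predictor
  if (anyNA(y) || anyNA(x)) stop_validation("missing values in response or predictor")
  n <- length(y)
  X <- cbind("(Intercept)" = 1, predictor = x)
  V <- bm_vcv(m$tree)
  lambda_used <- 1
  if (lambda_mode == "ml") {
    prof <- function(lam) gls_core(y, X, lambda_transform(V, lam))$loglik
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    lls <- vapply(cand, prof, numeric(1))
    lambda_used <- cand[which.max(lls)]
    V <- lambda_transform(V, lambda_used)
  }
  fit <- gls_core(y, X, V)
  q <- ncol(X)
  df <- n - q
  if (df <= 0) stop_validation("not enough species for the requested model")
  sigma2 <- fit$quad / df
  se <- sqrt(sigma2 * diag(fit$XtVX_inv))
  tval <- as.numeric(fit$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df)
  coef <- stats::setNames(as.numeric(fit$beta), colnames(X))
  structure(list(coefficients = coef,
                 standard_errors = stats::setNames(se, colnames(X)),
                 t_values = stats::setNames(tval, colnames(X)),
                 p_values = stats::setNames(pval, colnames(X)),
                 lambda_used = lambda_used,
                 log_likelihood = fit$loglik,
                 sigma2 = sigma2,
                 n = n,
                 df_residual = df,
                 residuals = stats::setNames(as.numeric(y - X %*% fit$beta),
                                             names(y))),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS (n = %d, lambda = %.4g)\n", x$n, x$lambda_used))
  tab <- data.frame(Estimate = x$coefficients, SE = x$standard_errors,
                    t = x$t_values, p = x$p_values)
  print(tab, digits = 5)
  invisible(x)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximises the multivariate-normal log-likelihood of a species trait vector
#' (with its mean estimated by GLS) over the lambda-transformed Brownian
#' covariance, for lambda in `[0, 1]`. Used to quantify phylogenetic signal,
#' e.g. in model residuals, and to choose between standard and phylogenetic
#' ANOVA.
#'
#' @param values Named numeric vector of species trait values (>= 4 species
#'   after matching; must not be constant).
#' @param tree A `"phylo"` object.
#' @return A list with `lambda_hat` and `log_likelihood`.
#' @export
fit_pagel_lambda <- function(values, tree) {
  m <- match_species(tree, values = values)
  y <- m$values
  if (stats::sd(y) == 0) {
    stop_validation("`values` is constant: lambda likelihood is degenerate")
  }
  X <- matrix(1, length(y), 1)
  V <- bm_vcv(m$tree)
  prof <- function(lam) gls_core(y, X, lambda_transform(V, lam))$loglik
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(0, opt$maximum, 1)
  lls <- vapply(cand, prof, numeric(1))
  best <- which.max(lls)
  list(lambda_hat = cand[best], log_likelihood = lls[best])
}

#' One-way fixed-effects ANOVA with effect size and pairwise tests
#'
#' Standard one-way F test on `(k - 1, n - k)` degrees of freedom, the
#' generalised eta-squared effect size (which in a one-way between-subjects
#' design reduces to `SS_between / SS_total`), per-group means, and post-hoc
#' pairwise pooled-variance two-sample t-tests with multiplicity adjustment.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length; every level must
#'   be observed at least once.
#' @param p_adjust Adjustment method for the pairwise table (default
#'   `"holm"`); any method known to [stats::p.adjust()].
#' @return An object of class `anova_result` with `F`, `p`, `eta2g`,
#'   `group_means`, `pairwise` (`group_i`, `group_j`, `t`, `p`, `p_adjusted`),
#'   `df` and `n`.
#' @export
anova_oneway <- function(values, groups, p_adjust = "holm") {
  values <- as.numeric(values)
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups)) {
    stop_validation("`values` and `groups` must have the same length")
  }
  if (anyNA(values) || anyNA(groups)) stop_validation("missing values not allowed")
  k <- nlevels(groups)
  if (k < 2L) stop_validation("need at least 2 groups")
  counts <- table(groups)
  if (any(counts == 0)) stop_validation("every group needs at least one observation")
  n <- length(values)
  if (n <= k) stop_validation("total n must exceed the number of groups")
  if (max(values) - min(values) == 0) {
    # identical values everywhere: define F = 0 rather than a 0/0 ratio
    ss_b <- ss_w <- ss_t <- 0
    Fv <- 0
    pv <- 1
  } else {
    tab <- stats::anova(stats::lm(values ~ groups))
    ss_b <- tab$`Sum Sq`[1]
    ss_w <- tab$`Sum Sq`[2]
    ss_t <- ss_b + ss_w
    Fv <- tab$`F value`[1]
    pv <- tab$`Pr(>F)`[1]
  }
  eta2g <- if (ss_t > 0) ss_b / ss_t else 0
  means <- tapply(values, groups, mean)
  pairs <- utils::combn(levels(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    va <- values[groups == pr[1]]
    vb <- values[groups == pr[2]]
    na <- length(va); nb <- length(vb)
    sp2 <- (sum((va - mean(va))^2) + sum((vb - mean(vb))^2)) / (na + nb - 2)
    tt <- if (sp2 > 0) (mean(va) - mean(vb)) / sqrt(sp2 * (1 / na + 1 / nb)) else 0
    c(t = tt, p = 2 * stats::pt(-abs(tt), na + nb - 2))
  })
  pairwise <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                         t = pw["t", ], p = pw["p", ],
                         p_adjusted = stats::p.adjust(pw["p", ], p_adjust))
  rownames(pairwise) <- NULL
  structure(list(F = Fv, p = pv, eta2g = eta2g,
                 group_means = means, pairwise = pairwise,
                 df = c(k - 1L, n - k), n = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, eta2G = %.3g\n",
              x$df[1], x$df[2], x$F, x$p, x$eta2g))
  invisible(x)
}

# Vectorised one-way F statistics for an n x R matrix of replicate datasets.
f_stat_matrix <- function(Y, groups) {
  groups <- droplevels(as.factor(groups))
  n <- nrow(Y)
  k <- nlevels(groups)
  counts <- as.numeric(table(groups))
  G <- stats::model.matrix(~ groups - 1)
  M <- crossprod(G, Y) / counts
  grand <- colMeans(Y)
  SSt <- colSums(Y^2) - n * grand^2
  SSb <- colSums(M^2 * counts) - n * grand^2
  SSw <- pmax(SSt - SSb, 0)
  (SSb / (k - 1)) / (SSw / (n - k))
}

# Vectorised pooled-variance two-sample t statistics for one group pair.
pair_t_matrix <- function(Y, groups, a, b) {
  ia <- which(groups == a)
  ib <- which(groups == b)
  na <- length(ia); nb <- length(ib)
  Ya <- Y[ia, , drop = FALSE]; Yb <- Y[ib, , drop = FALSE]
  Ma <- colMeans(Ya); Mb <- colMeans(Yb)
  SSa <- colSums(Ya^2) - na * Ma^2
  SSb <- colSums(Yb^2) - nb * Mb^2
  sp2 <- (SSa + SSb) / (na + nb - 2)
  (Ma - Mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Simulation-based phylogenetic ANOVA
#'
#' Compares the observed one-way F statistic against a null distribution of F
#' statistics from traits simulated under Brownian motion on the phylogeny,
#' following the simulation approach of Garland-style phylogenetic ANOVA. The
#' Brownian rate for the simulations is estimated from the data by GLS: the
#' phylogenetic mean is `(1' V^-1 y) / (1' V^-1 1)` and the rate is the
#' residual quadratic form divided by n. The main p-value uses the add-one
#' estimator `p = (1 + #\{F_sim >= F_obs\}) / (n_sim + 1)`. Pairwise
#' pooled-variance t statistics are referred to their own simulated nulls
#' (two-sided) and adjusted across pairs.
#'
#' @param values Named numeric vector of species trait values.
#' @param groups Named factor/character of species group memberships.
#' @param tree A `"phylo"` object.
#' @param n_sim Number of Brownian simulations (>= 99; default 1000).
#' @param seed Integer seed for reproducibility (or `NULL`).
#' @param p_adjust Adjustment for the pairwise table (default `"holm"`).
#' @return An object of class `phyl_anova_result` with `F`, `p_sim`, `n_sim`,
#'   `pairwise_sim`, `sigma2`, `seed` and the parametric `anova` result.
#' @export
phyl_anova <- function(values, groups, tree, n_sim = 1000L, seed = NULL,
                       p_adjust = "holm") {
  if (is.null(names(groups))) stop_validation("`groups` must be a named vector")
  gchr <- stats::setNames(as.character(groups), trimws(names(groups)))
  m <- match_species(tree, values = values, groups_chr = gchr)
  y <- m$values
  g <- droplevels(as.factor(m$groups_chr))
  if (!is.numeric(n_sim) || n_sim < 99) stop_validation("`n_sim` must be >= 99")
  n_sim <- as.integer(n_sim)
  obs <- anova_oneway(y, g, p_adjust = p_adjust)
  V <- bm_vcv(m$tree)
  ones <- matrix(1, length(y), 1)
  core <- gls_core(y, ones, V)
  sigma2 <- core$quad / length(y)
  if (sigma2 <= 0) stop_validation("data have no phylogenetic variance to simulate from")
  R <- chol(sigma2 * V)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(length(y) * n_sim), nrow = length(y))
  })
  Ysim <- crossprod(R, Z)
  Fsim <- f_stat_matrix(Ysim, g)
  p_sim <- (1 + sum(Fsim >= obs$F)) / (n_sim + 1)
  pairs <- utils::combn(levels(g), 2)
  pw_p <- apply(pairs, 2, function(pr) {
    t_obs <- obs$pairwise$t[obs$pairwise$group_i == pr[1] &
                              obs$pairwise$group_j == pr[2]]
    t_sim <- pair_t_matrix(Ysim, g, pr[1], pr[2])
    (1 + sum(abs(t_sim) >= abs(t_obs))) / (n_sim + 1)
  })
  pairwise_sim <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                             t = obs$pairwise$t, p_sim = pw_p,
                             p_adjusted = stats::p.adjust(pw_p, p_adjust))
  rownames(pairwise_sim) <- NULL
  structure(list(F = obs$F, p_sim = p_sim, n_sim = n_sim,
                 pairwise_sim = pairwise_sim, sigma2 = sigma2,
                 seed = seed, anova = obs),
            class = "phyl_anova_result")
}

#' @export
print.phyl_anova_result <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F = %.4g, p_sim = %.4g (%d simulations)\n",
              x$F, x$p_sim, x$n_sim))
  invisible(x)
}

#' Phylogenetic regression of multivariate shape on a predictor
#'
#' Regresses Procrustes shape coordinates on a scalar predictor under a
#' Brownian error structure: the vectorised shapes and design matrix are
#' whitened by the inverse matrix square root of the phylogenetic covariance,
#' an ordinary least-squares fit is performed in the transformed space, and
#' `r_squared = SS_model / SS_total` is computed there. Significance comes
#' from residual-randomisation permutation (RRPP): residuals of the
#' intercept-only reduced model are randomly re-assigned across species,
#' the statistic is recomputed for each permutation, and the add-one
#' estimator gives `p_perm`. The fitted shape values (in the original space)
#' are decomposed by PCA to report the variance fractions of the fitted
#' components.
#'
#' @param shapes An `aligned_shapes` object from [gpa_align()], or a numeric
#'   species x variables matrix with species rownames.
#' @param predictor Named numeric vector (species names); must vary.
#' @param tree A `"phylo"` object.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed (or `NULL`).
#' @return An object of class `proc_pgls_result` with `r_squared`, `p_perm`,
#'   `n_perm`, `fitted_component_variances`, `coefficients`, `n` and `seed`.
#' @export
procrustes_pgls <- function(shapes, predictor, tree, n_perm = 999L,
                            seed = NULL) {
  Y <- if (inherits(shapes, "aligned_shapes")) shapes_matrix(shapes) else as.matrix(shapes)
  if (is.null(rownames(Y))) {
    stop_validation("`shapes` must carry species identifiers (rownames)")
  }
  if (!is.numeric(n_perm) || n_perm < 99) stop_validation("`n_perm` must be >= 99")
  n_perm <- as.integer(n_perm)
  if (is.null(names(predictor))) stop_validation("`predictor` must be a named vector")
  names(predictor) <- trimws(names(predictor))
  rownames(Y) <- trimws(rownames(Y))
  tree$tip.label <- trimws(tree$tip.label)
  common <- Reduce(intersect, list(tree$tip.label, rownames(Y), names(predictor)))
  dropped <- setdiff(unique(c(tree$tip.label, rownames(Y), names(predictor))), common)
  if (length(dropped) > 0L) {
    warning(sprintf("pruning %d unmatched species: %s", length(dropped),
                    paste(sort(dropped), collapse = ", ")), call. = FALSE)
  }
  if (length(common) < 4L) stop_validation("need at least 4 matched species")
  tree <- ape::keep.tip(tree, common)
  ord <- tree$tip.label
  Y <- Y[ord, , drop = FALSE]
  x <- predictor[ord]
  if (stats::sd(x) == 0) {
    stop_validation("`predictor` is constant across species: no model variance")
  }
  V <- bm_vcv(tree)
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) {
    stop_validation("phylogenetic covariance matrix is numerically singular; consider collapsing zero-length branches")
  }
  P <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  n <- length(ord)
  X <- cbind(1, x)
  TX <- P %*% X
  TXr <- P %*% matrix(1, n, 1)
  TY <- P %*% Y
  qr_full <- qr(TX)
  qr_red <- qr(TXr)
  res_red <- qr.resid(qr_red, TY)
  fit_red <- TY - res_red
  ss_total <- sum(res_red^2)
  if (ss_total <= 0) stop_validation("shapes carry no variance beyond the phylogenetic mean")
  ss_full_resid <- sum(qr.resid(qr_full, TY)^2)
  r2_obs <- (ss_total - ss_full_resid) / ss_total
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
  })
  r2_perm <- vapply(seq_len(n_perm), function(i) {
    Yp <- fit_red + res_red[perms[, i], , drop = FALSE]
    sst <- sum(qr.resid(qr_red, Yp)^2)
    ssf <- sum(qr.resid(qr_full, Yp)^2)
    (sst - ssf) / sst
  }, numeric(1))
  p_perm <- (1 + sum(r2_perm >= r2_obs)) / (n_perm + 1)
  beta <- qr.coef(qr_full, TY)
  fitted_orig <- X %*% beta
  fc <- sweep(fitted_orig, 2, colMeans(fitted_orig))
  sv <- svd(fc, nu = 0, nv = 0)$d
  eigv <- sv^2
  keep <- if (max(eigv) > 0) which(eigv > 1e-12 * max(eigv)) else integer(0)
  fractions <- if (length(keep)) eigv[keep] / sum(eigv[keep]) else numeric(0)
  structure(list(r_squared = r2_obs, p_perm = p_perm, n_perm = n_perm,
                 fitted_component_variances = fractions,
                 coefficients = beta, n = n, seed = seed),
            class = "proc_pgls_result")
}

#' @export
print.proc_pgls_result <- function(x, ...) {
  cat(sprintf("Procrustes PGLS: r^2 = %.4f, p_perm = %.4g (%d permutations, n = %d)\n",
              x$r_squared, x$p_perm, x$n_perm, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper around the standard Shapiro-Wilk algorithm, used to
#' decide whether continuous covariates (facial tilt, body mass) can enter
#' the regressions untransformed.
#'
#' @param values Numeric vector with `3 <= n <= 5000` and non-zero variance.
#' @return A list with elements `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop_validation("missing values not allowed")
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop_validation("Shapiro-Wilk requires between 3 and 5000 observations")
  }
  if (stats::sd(values) == 0) {
    stop_validation("`values` is constant: normality test undefined")
  }
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value)
}
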