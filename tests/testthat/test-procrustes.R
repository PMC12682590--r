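test_that("centroid size matches closed forms and is homogeneous of degree 1", {
  square <- landmark_config("sq", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(centroid_size(square), sqrt(2))

  set.seed(5)
  cfg <- random_config(43, 3, "r")
  cs <- centroid_size(cfg)
  expect_equal(centroid_size(landmark_config("r2", 3.7 * cfg$coords)),
               3.7 * cs, tolerance = 1e-12)

  # direct per-landmark sum oracle
  ctr <- colMeans(cfg$coords)
  brute <- sqrt(sum(apply(cfg$coords, 1, function(p) sum((p - ctr)^2))))
  expect_equal(cs, brute, tolerance = 1e-12)

  expect_error(centroid_size(landmark_config("z", matrix(1, 4, 2))),
               "coincide")
})

test_that("GPA exactly superimposes similarity-transformed copies", {
  set.seed(7)
  base <- random_config(30, 2, "a")$coords
  moved <- similarity_transform(base, angle = pi / 2, scale = 1, shift = c(3, -2))
  res <- gpa_align(list(landmark_config("a", base), landmark_config("b", moved)))
  rss <- sqrt(sum((res$shapes[[1]] - res$shapes[[2]])^2))
  expect_lt(rss, 1e-10)
  expect_true(res$converged)
  # aligned shapes have unit centroid size and zero centroid by construction
  for (sh in res$shapes) {
    expect_lt(max(abs(colMeans(sh))), 1e-10)
    expect_equal(sqrt(sum(sh^2)), 1, tolerance = 1e-10)
  }
})

test_that("GPA objective is non-increasing and output is invariant to input pose", {
  set.seed(21)
  configs <- lapply(1:5, function(i) random_config(20, 2, paste0("s", i)))
  res <- gpa_align(configs)
  expect_true(all(diff(res$objective_trace) <= 1e-12))

  # pre-transforming one input must not change the aligned result
  configs2 <- configs
  configs2[[3]]$coords <- similarity_transform(configs2[[3]]$coords)
  res2 <- gpa_align(configs2)
  for (i in 1:5) {
    expect_equal(res2$shapes[[i]], res$shapes[[i]], tolerance = 1e-8)
  }
  expect_equal(res2$mean_shape, res$mean_shape, tolerance = 1e-8)
})

test_that("GPA works for 3D configurations", {
  set.seed(31)
  base <- random_config(43, 3, "a")$coords
  rot <- similarity_transform(base, angle = 1.1, scale = 2, shift = c(1, 2, 3))
  res <- gpa_align(list(landmark_config("a", base), landmark_config("b", rot)))
  expect_lt(sqrt(sum((res$shapes[[1]] - res$shapes[[2]])^2)), 1e-10)
  expect_equal(unname(res$centroid_sizes[["b"]] / res$centroid_sizes[["a"]]), 2,
               tolerance = 1e-10)
})

test_that("shape PCA has orthogonal scores and reconstructs the data", {
  set.seed(9)
  configs <- perturbed_configs(10, 15, 2)
  res <- gpa_align(configs)
  pca <- pca_shapes(res)
  expect_true(all(diff(pca$variance_fractions) <= 1e-12))
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-12)
  gram <- crossprod(pca$scores)
  offdiag <- abs(gram[upper.tri(gram)])
  expect_lt(max(offdiag / max(diag(gram))), 1e-8)

  # full-rank reconstruction of the centred data
  Y <- t(vapply(res$shapes, as.vector, numeric(30)))
  recon <- sweep(pca$scores %*% t(pca$loadings), 2, pca$center, `+`)
  expect_equal(unname(recon), unname(Y), tolerance = 1e-10)
})

test_that("degenerate PCA inputs behave as rank dictates", {
  base <- random_config(12, 2, "a")$coords
  same <- lapply(1:4, function(i) landmark_config(paste0("s", i), base))
  pca0 <- pca_shapes(gpa_align(same))
  expect_length(pca0$variance_fractions, 0)

  other <- similarity_transform(base) + matrix(rnorm(24, sd = 0.3), 12, 2)
  two <- gpa_align(list(landmark_config("a", base), landmark_config("b", other),
                        landmark_config("c", base)))
  pca1 <- pca_shapes(two)
  expect_equal(pca1$variance_fractions[1], 1, tolerance = 1e-10)

  expect_error(pca_shapes(gpa_align(same[1:2])), "at least 3")
})

test_that("PCA variance fractions are invariant to specimen order", {
  set.seed(13)
  configs <- perturbed_configs(6, 10, 2)
  v1 <- pca_shapes(gpa_align(configs))$variance_fractions
  v2 <- pca_shapes(gpa_align(configs[c(4, 2, 6, 1, 5, 3)]))$variance_fractions
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("digitisation-direction normalisation makes reversal harmless", {
  set.seed(3)
  cv <- sine_curve(0.08, 6, 120)
  rev_cv <- curve2d(cv$specimen_id, cv$points[rev(seq_len(nrow(cv$points))), ])
  o1 <- orient_curves(list(cv))[[1]]
  o2 <- orient_curves(list(rev_cv))[[1]]
  expect_equal(o1$points, o2$points)
  expect_equal(sinuosity_index(cv), sinuosity_index(rev_cv), tolerance = 1e-12)
})

test_that("3D landmark CSV reader enforces a consistent landmark count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,landmark_index,x,y,z",
               "a,1,0,0,0", "a,2,1,0,0", "a,3,0,1,0",
               "b,1,0,0,1", "b,2,1,0,1", "b,3,0,1,1"), path)
  configs <- read_landmarks(path)
  expect_length(configs, 2)
  expect_equal(dim(configs[[1]]$coords), c(3L, 3L))

  writeLines(c("specimen_id,landmark_index,x,y,z",
               "a,1,0,0,0", "a,2,1,0,0", "b,1,0,0,1"), path)
  expect_error(read_landmarks(path), "differ in landmark count")
})
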