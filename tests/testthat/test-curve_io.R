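test_that("CSV curves read back exactly what was written", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,point_index,x,y",
               "s1,1,0,0", "s1,2,1,0", "s1,3,2,0"), path)
  curves <- read_curves(path, "csv")
  expect_length(curves, 1L)
  expect_equal(curves[[1]]$specimen_id, "s1")
  expect_equal(curves[[1]]$points,
               cbind(x = c(0, 1, 2), y = c(0, 0, 0)))

  cv2 <- curve2d("zig", cbind(c(0, 0.3, 1.2, 2), c(0, 0.7, -0.4, 0.1)))
  out <- withr::local_tempfile(fileext = ".csv")
  write_curves(list(curves[[1]], cv2), out, "csv")
  back <- read_curves(out, "csv")
  expect_equal(back[[2]]$points, cv2$points, tolerance = 1e-12)
})

test_that("TPS dialect roundtrips and ignores foreign keywords with a warning", {
  path <- withr::local_tempfile(fileext = ".tps")
  cv <- curve2d("spec A", cbind(c(0, 1, 2, 3), c(0, 1, 0, -1)))
  write_curves(cv, path, "tps")
  back <- read_curves(path, "tps")
  expect_equal(back[[1]]$specimen_id, "spec A")
  expect_equal(back[[1]]$points, cv$points, tolerance = 1e-12)

  writeLines(c("LM=2", "0 0", "1 1", "IMAGE=foo.jpg", "ID=a"), path)
  expect_warning(curves <- read_curves(path, "tps"), "IMAGE")
  expect_equal(curves[[1]]$specimen_id, "a")
})

test_that("malformed curve files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_curves(path, "csv"), "no curve records|parse")

  writeLines(c("specimen_id,point_index,x,y", "s1,1,0,0"), path)
  expect_error(read_curves(path, "csv"), "fewer than 2")

  tps <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=2", "0 0", "1 1", "ID=a", "LM=2", "2 2", "3 3", "ID=a"), tps)
  expect_error(read_curves(tps, "tps"), "duplicate specimen_id")

  writeLines(c("LM=3", "0 0", "1 1", "ID=a"), tps)
  expect_error(read_curves(tps, "tps"), "numeric coordinates")
})

test_that("consecutive duplicate points are cleaned with a warning", {
  expect_warning(cv <- curve2d("d", cbind(c(0, 0, 1), c(0, 0, 1))),
                 "duplicate")
  expect_equal(nrow(cv$points), 2L)
  expect_error(suppressWarnings(curve2d("d", cbind(c(1, 1), c(2, 2)))),
               "at least 2 distinct")
})

test_that("equidistant resampling places points at analytic arc-length positions", {
  seg <- curve2d("seg", cbind(c(0, 1), c(0, 0)))
  rs <- resample_equidistant(seg, 5)
  expect_equal(rs$points[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(rs$points[, 2], rep(0, 5))

  elbow <- curve2d("elbow", cbind(c(0, 1, 1), c(0, 0, 1)))
  rs3 <- resample_equidistant(elbow, 3)
  expect_equal(unname(rs3$points), cbind(c(0, 1, 1), c(0, 0, 1)))

  expect_error(resample_equidistant(seg, 1), ">= 2")
})

test_that("resampled semicircle length matches the analytic arc length", {
  rs <- resample_equidistant(semicircle_curve(radius = 1), 250)
  len <- sum(sqrt(rowSums(diff(rs$points)^2)))
  # analytic arc length = pi/2 * diameter = pi for radius 1
  expect_lt(abs(len - pi) / pi, 0.001)
})

test_that("resampling is idempotent, length-contracting, and densification-invariant", {
  # exact idempotence where the resampled vertices already sit at equal
  # chord spacing
  straight <- resample_equidistant(curve2d("s", cbind(c(0, 2), c(0, 1))), 9)
  expect_equal(resample_equidistant(straight, 9)$points, straight$points,
               tolerance = 1e-12)
  # for smooth curves re-resampling moves points only at second order in the
  # chord-versus-arc contraction
  xs <- seq(0, 1, length.out = 2001)
  smooth <- curve2d("sine", cbind(xs, 0.05 * sin(2 * pi * 2 * xs)))
  s1 <- resample_equidistant(smooth, 250)
  s2 <- resample_equidistant(s1, 250)
  expect_lt(max(abs(s2$points - s1$points)), 1e-5)

  set.seed(11)
  x <- sort(runif(40)); y <- cumsum(rnorm(40, sd = 0.1))
  cv <- curve2d("r", cbind(x, y))
  r1 <- resample_equidistant(cv, 50)

  src_len <- sum(sqrt(rowSums(diff(cv$points)^2)))
  rs_len <- sum(sqrt(rowSums(diff(r1$points)^2)))
  expect_lte(rs_len, src_len + 1e-12)
  seg <- resample_equidistant(curve2d("s", cbind(c(0, 3), c(0, 4))), 7)
  expect_equal(sum(sqrt(rowSums(diff(seg$points)^2))), 5)

  # insert collinear midpoints: output must not change
  p <- cv$points
  dense <- matrix(NA_real_, 2 * nrow(p) - 1, 2)
  dense[seq(1, nrow(dense), 2), ] <- p
  dense[seq(2, nrow(dense), 2), ] <- (p[-nrow(p), ] + p[-1, ]) / 2
  r_dense <- resample_equidistant(curve2d("r", dense), 50)
  expect_equal(r_dense$points, r1$points, tolerance = 1e-9)
})

test_that("flip_y negates the y axis on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(curve2d("s", cbind(c(0, 1), c(2, 3))), path, "csv")
  flipped <- read_curves(path, "csv", flip_y = TRUE)
  expect_equal(flipped[[1]]$points[, 2], c(-2, -3))
})
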