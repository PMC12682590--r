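#' Construct a landmark configuration
#'
#' @param specimen_id Single character label.
#' @param coords Numeric k x d matrix of landmark coordinates, d = 2 or 3.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, coords) {
  if (!is.character(specimen_id) || length(specimen_id) != 1L ||
      !nzchar(specimen_id)) {
    stop_validation("`specimen_id` must be a single non-empty string")
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  d <- ncol(coords)
  if (!d %in% c(2L, 3L)) {
    stop_validation("`coords` must have 2 or 3 columns")
  }
  if (!all(is.finite(coords))) {
    stop_validation(sprintf("configuration '%s' contains non-finite coordinates",
                            specimen_id))
  }
  if (nrow(coords) * d <= d) {
    stop_validation(sprintf("configuration '%s' is degenerate (k*d must exceed d)",
                            specimen_id))
  }
  structure(list(specimen_id = specimen_id, coords = coords),
            class = "landmark_config")
}

#' Read 3D landmark configurations from CSV
#'
#' Expects columns `specimen_id,landmark_index,x,y,z` (or `x,y` for 2D data).
#' All specimens must share the same landmark count.
#'
#' @param path CSV file path.
#' @return List of [landmark_config] objects.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "landmark_index", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("'%s': missing required column(s): %s",
                            path, paste(missing_cols, collapse = ", ")))
  }
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  counts <- table(df$specimen_id)
  if (length(unique(counts)) != 1L) {
    stop_validation(sprintf("'%s': specimens differ in landmark count (%s)",
                            path, paste(sort(unique(counts)), collapse = ", ")))
  }
  lapply(unique(df$specimen_id), function(id) {
    rec <- df[df$specimen_id == id, , drop = FALSE]
    rec <- rec[order(rec$landmark_index), , drop = FALSE]
    landmark_config(as.character(id), as.matrix(rec[, coord_cols]))
  })
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from their
#' centroid — the standard geometric size measure retained alongside
#' Procrustes shape variables.
#'
#' @param config A [landmark_config], [curve2d], or a bare coordinate matrix.
#' @return A positive scalar.
#' @examples
#' centroid_size(landmark_config("sq", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
#' @export
centroid_size <- function(config) {
  coords <- extract_coords(config)
  if (nrow(coords) < 2L) stop_validation("need at least 2 landmarks")
  centred <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(centred^2))
  if (cs == 0) {
    stop_validation("all landmarks coincide: centroid size is zero")
  }
  cs
}

extract_coords <- function(config) {
  if (inherits(config, "landmark_config")) return(config$coords)
  if (inherits(config, "curve2d")) return(config$points)
  coords <- as.matrix(config)
  storage.mode(coords) <- "double"
  coords
}

config_id <- function(config, fallback) {
  if (inherits(config, c("landmark_config", "curve2d"))) {
    if (!is.null(config$specimen_id)) return(config$specimen_id)
  }
  fallback
}

# Optimal proper rotation Q (det +1) minimising ||X Q - M||_F (Kabsch).
kabsch_rotation <- function(X, M, allow_reflection = FALSE) {
  s <- svd(crossprod(X, M))
  Q <- s$u %*% t(s$v)
  if (!allow_reflection && det(Q) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    Q <- u %*% t(s$v)
  }
  Q
}

# Rotate a set of centred shapes so the mean shape sits in a canonical
# principal-axes frame with deterministic axis signs. This pins down the
# arbitrary global rotation left over after GPA so that results do not depend
# on the orientation in which specimens were digitised.
canonicalise_orientation <- function(shapes, mean_shape) {
  s <- svd(mean_shape)
  V <- s$v
  for (j in seq_len(ncol(V))) {
    pivot <- which.max(abs(V[, j]))
    if (V[pivot, j] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) {
    j <- ncol(V)  # flip the least-variance axis to stay a proper rotation
    V[, j] <- -V[, j]
  }
  list(shapes = lapply(shapes, function(x) x %*% V),
       mean_shape = mean_shape %*% V)
}

#' Generalised Procrustes alignment
#'
#' Iteratively translates each configuration to the origin, scales it to unit
#' centroid size and rotates it onto the current mean shape by orthogonal
#' Procrustes superimposition, recomputing the mean until it stabilises.
#' Rotations are proper (determinant +1) by default, preserving anatomical
#' chirality. Semi-landmarks are treated as fixed points (no sliding). After
#' convergence the whole set is rotated into a canonical principal-axes frame
#' of the mean shape, making the output invariant to arbitrary similarity
#' transforms of the inputs.
#'
#' @param configs List of [landmark_config] objects (or coordinate matrices)
#'   sharing landmark count and dimension.
#' @param max_iter Maximum number of mean-update iterations (default 100).
#' @param tol Convergence tolerance on the root-mean-square change of the mean
#'   shape (default 1e-10).
#' @param allow_reflection If `TRUE`, improper rotations are permitted.
#' @return An object of class `aligned_shapes`: `shapes` (list of aligned
#'   k x d matrices), `centroid_sizes`, `mean_shape`, `iterations`,
#'   `converged`, `specimen_ids` and `objective_trace` (sum of squared
#'   Procrustes distances to the mean after each iteration).
#' @export
gpa_align <- function(configs, max_iter = 100L, tol = 1e-10,
                      allow_reflection = FALSE) {
  stopifnot(is.list(configs))
  if (length(configs) < 2L) {
    stop_validation("GPA needs at least 2 configurations")
  }
  ids <- vapply(seq_along(configs), function(i) {
    config_id(configs[[i]], sprintf("specimen_%03d", i))
  }, character(1))
  mats <- lapply(configs, extract_coords)
  k <- nrow(mats[[1]])
  d <- ncol(mats[[1]])
  ok <- vapply(mats, function(m) nrow(m) == k && ncol(m) == d, logical(1))
  if (!all(ok)) {
    stop_validation("all configurations must share landmark count and dimension")
  }
  sizes <- vapply(mats, centroid_size, numeric(1))
  shapes <- lapply(seq_along(mats), function(i) {
    centred <- sweep(mats[[i]], 2, colMeans(mats[[i]]))
    centred / sizes[i]
  })
  mean_shape <- shapes[[1]]
  converged <- FALSE
  iterations <- 0L
  objective_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    shapes <- lapply(shapes, function(x) {
      x %*% kabsch_rotation(x, mean_shape, allow_reflection)
    })
    new_mean <- Reduce(`+`, shapes) / length(shapes)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    nm_size <- sqrt(sum(new_mean^2))
    if (nm_size == 0) stop_validation("degenerate mean shape during GPA")
    new_mean <- new_mean / nm_size
    objective_trace <- c(objective_trace,
                         sum(vapply(shapes,
                                    function(x) sum((x - new_mean)^2),
                                    numeric(1))))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    iterations <- iter
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("GPA did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  canon <- canonicalise_orientation(shapes, mean_shape)
  structure(list(shapes = canon$shapes,
                 centroid_sizes = stats::setNames(sizes, ids),
                 mean_shape = canon$mean_shape,
                 iterations = iterations,
                 converged = converged,
                 specimen_ids = ids,
                 objective_trace = objective_trace),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("<aligned_shapes> %d specimens, %d x %d landmarks; %d iterations (%s)\n",
              length(x$shapes), nrow(x$mean_shape), ncol(x$mean_shape),
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Vectorise aligned shapes into a specimens x (k*d) matrix.
shapes_matrix <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  Y <- t(vapply(aligned$shapes, as.vector,
                numeric(length(aligned$mean_shape))))
  rownames(Y) <- aligned$specimen_ids
  Y
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the vectorised Procrustes-aligned
#' coordinates. Components with numerically null variance (below
#' `1e-12 * max eigenvalue`) are dropped, so `variance_fractions` sums to 1
#' over the retained components.
#'
#' @param aligned An [gpa_align()] result.
#' @return An object of class `shape_pca`: `scores` (specimen x component),
#'   `variance_fractions`, `loadings`, `center`.
#' @export
pca_shapes <- function(aligned) {
  Y <- shapes_matrix(aligned)
  if (nrow(Y) < 3L) {
    stop_validation("shape PCA needs at least 3 specimens")
  }
  centre <- colMeans(Y)
  Yc <- sweep(Y, 2, centre)
  s <- svd(Yc)
  eig <- s$d^2 / (nrow(Y) - 1)
  if (max(eig) <= 0) {
    keep <- integer(0)
  } else {
    keep <- which(eig > 1e-12 * max(eig))
  }
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], nrow = length(keep))
  rownames(scores) <- rownames(Y)
  if (length(keep) > 0L) {
    colnames(scores) <- paste0("PC", seq_along(keep))
  }
  structure(list(scores = scores,
                 variance_fractions = if (length(keep)) eig[keep] / sum(eig[keep]) else numeric(0),
                 loadings = s$v[, keep, drop = FALSE],
                 center = centre),
            class = "shape_pca")
}

#' Normalise the digitisation direction of suture curves
#'
#' Digitisation may start at either end of a suture. Each curve is re-ordered
#' so that, once its endpoint chord is provisionally aligned with the x axis,
#' the first point has the smaller x coordinate: the point order is reversed
#' when the chord vector points in the negative-x half-plane (ties broken on
#' y). Sinuosity and spectral scores are reversal-invariant, so this only
#' standardises the frame for joint Procrustes alignment.
#'
#' @param curves List of [curve2d] objects.
#' @return The list with point orders standardised.
#' @export
orient_curves <- function(curves) {
  lapply(curves, function(cv) {
    stopifnot(inherits(cv, "curve2d"))
    p <- cv$points
    chord <- p[nrow(p), ] - p[1, ]
    reverse <- chord[1] < 0 || (chord[1] == 0 && chord[2] < 0)
    if (reverse) {
      cv$points <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    cv
  })
}

#' Resample, orient and superimpose a set of suture curves
#'
#' Convenience wrapper for the 2D suture pathway: equidistant resampling to
#' `n` semi-landmarks, digitisation-direction normalisation, then generalised
#' Procrustes alignment.
#'
#' @param curves List of [curve2d] objects.
#' @param n Number of semi-landmarks (default 250).
#' @param ... Passed to [gpa_align()].
#' @return A list with `aligned` (an `aligned_shapes`) and `resampled`
#'   (the oriented, resampled curves).
#' @export
align_curves <- function(curves, n = 250L, ...) {
  resampled <- lapply(orient_curves(curves), resample_equidistant, n = n)
  aligned <- gpa_align(resampled, ...)
  list(aligned = aligned, resampled = resampled)
}
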