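# Shared fixture builders; everything is generated in code at test time.

# A dense semicircle of the given radius, centred on the origin of its chord.
semicircle_curve <- function(radius = 1, n = 2001L, id = "semi") {
  theta <- seq(0, pi, length.out = n)
  curve2d(id, cbind(radius * cos(theta), radius * sin(theta)))
}

# A sampled sine suture y = a * sin(2*pi*f*x) on the unit chord.
sine_curve <- function(a, f, n = 250L, id = "sine") {
  x <- seq(0, 1, length.out = n)
  curve2d(id, cbind(x, a * sin(2 * pi * f * x)))
}

# Random landmark configuration.
random_config <- function(k, d, id, sd = 1) {
  landmark_config(id, matrix(rnorm(k * d, sd = sd), k, d))
}

# A family of configurations sharing a common base shape with independent
# perturbations — the realistic regime for Procrustes alignment (fully
# unrelated random shapes make the GPA mean nearly degenerate).
perturbed_configs <- function(n, k, d, sd = 0.15) {
  base <- matrix(rnorm(k * d), k, d)
  lapply(seq_len(n), function(i) {
    landmark_config(sprintf("s%02d", i),
                    base + matrix(rnorm(k * d, sd = sd), k, d))
  })
}

# Apply a random similarity transform (proper rotation + translation + scale)
# to a coordinate matrix.
similarity_transform <- function(coords, angle = NULL, scale = NULL,
                                 shift = NULL) {
  d <- ncol(coords)
  if (is.null(angle)) angle <- runif(1, 0, 2 * pi)
  if (is.null(scale)) scale <- runif(1, 0.5, 2)
  if (is.null(shift)) shift <- rnorm(d, sd = 5)
  R <- if (d == 2) {
    matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  } else {
    ax <- diag(3)
    Rz <- matrix(c(cos(angle), sin(angle), 0, -sin(angle), cos(angle), 0,
                   0, 0, 1), 3, 3)
    Rz
  }
  sweep(scale * coords %*% R, 2, shift, `+`)
}

# Star phylogeny with unit-depth tips.
star_tree <- function(n) {
  labels <- sprintf("t%02d", seq_len(n))
  read_newick(paste0("(", paste0(labels, ":1", collapse = ","), ");"))
}

# Independent brute-force Brownian covariance: walk the edge matrix with a
# parent map and sum shared root-to-MRCA path lengths for every tip pair.
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  edge_len <- numeric(max(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    edge_len[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  depth_of <- function(node) {
    sum(edge_len[setdiff(path_to_root(node), root)])
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(path_to_root(i), path_to_root(j))
      mrca <- shared[which.max(vapply(shared, depth_of, numeric(1)))]
      V[i, j] <- depth_of(mrca)
    }
  }
  V
}
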