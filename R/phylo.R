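#' Read and validate a phylogeny
#'
#' Parses a Newick string or file into an `ape` `"phylo"` tree and validates
#' it for comparative analysis: unique tip labels, branch lengths present,
#' finite and non-negative. Zero-length terminal branches are permitted but
#' trigger a warning because they risk a singular Brownian covariance matrix.
#'
#' @param x A Newick string (ending in `;`) or a path to a Newick file.
#' @return A `"phylo"` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tree <- tryCatch(
    suppressWarnings(
      if (grepl("[();]", x)) ape::read.tree(text = x) else ape::read.tree(x)
    ),
    error = function(e) {
      stop_validation(sprintf("cannot parse Newick input: %s",
                              conditionMessage(e)))
    })
  if (is.null(tree)) stop_validation("cannot parse Newick input")
  validate_phylogeny(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly unchanged, if valid.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_validation("`tree` must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop_validation(sprintf("duplicate tip label(s): %s",
                            paste(dups, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    stop_validation("tree has no branch lengths")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop_validation("tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop_validation("tree has negative branch lengths")
  }
  terminal <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[terminal] == 0)) {
    warning("tree has zero-length terminal branch(es); the Brownian covariance matrix may be singular",
            call. = FALSE)
  }
  tree
}

#' Summary checks for a time-scaled tree
#'
#' Reports tip count, root-to-tip depth range and the relative deviation from
#' ultrametricity, `(max depth - min depth) / max depth`.
#'
#' @param tree A `"phylo"` object.
#' @return A list with `n_tips`, `depths` (named per tip), `depth_range` and
#'   `ultrametric_deviation`.
#' @export
tree_check <- function(tree) {
  validate_phylogeny(tree)
  depths <- tip_depths(tree)
  rng <- range(depths)
  list(n_tips = length(tree$tip.label),
       depths = depths,
       depth_range = rng,
       ultrametric_deviation = if (rng[2] > 0) (rng[2] - rng[1]) / rng[2] else 0)
}

# Root-to-tip depths in tip-label order.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  stats::setNames(d, tree$tip.label)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian trait evolution on a rooted time-scaled tree, the expected
#' trait covariance between two species is the shared path length from the
#' root to their most recent common ancestor; the variance of each species is
#' its root-to-tip depth. This is the error-covariance structure (V) used by
#' the phylogenetic regressions in this package.
#'
#' @param tree A valid `"phylo"` object.
#' @return A symmetric positive semi-definite species x species matrix with
#'   tip labels as dimnames, in `tree$tip.label` order.
#' @export
bm_vcv <- function(tree) {
  validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of V by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is the full Brownian structure, `lambda = 0`
#' removes all phylogenetic covariance (a star phylogeny). The upper bound of
#' 1 is the standard definition on ultrametric trees.
#'
#' @param V A phylogenetic covariance matrix, e.g. from [bm_vcv()].
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  assert_scalar_number(lambda, "lambda", 0, 1)
  V <- as.matrix(V)
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vl
}

#' Simulate traits under Brownian motion on a tree
#'
#' Each replicate is a multivariate-normal draw with mean zero and covariance
#' `sigma2 * V`, where V is the Brownian covariance of the tree. Reproducible
#' under a fixed seed; the caller's RNG state is restored on exit.
#'
#' @param tree A valid `"phylo"` object.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param n_reps Number of independent replicate trait vectors.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A species x `n_reps` numeric matrix with tip labels as rownames.
#' @export
simulate_bm <- function(tree, sigma2 = 1, n_reps = 1L, seed = NULL) {
  validate_phylogeny(tree)
  assert_scalar_number(sigma2, "sigma2")
  if (sigma2 <= 0) stop_validation("`sigma2` must be positive")
  stopifnot(n_reps >= 1)
  V <- bm_vcv(tree)
  R <- chol(sigma2 * V)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(nrow(V) * n_reps), nrow = nrow(V))
  })
  X <- crossprod(R, Z)
  rownames(X) <- tree$tip.label
  X
}

# Match named data vectors to the tree's tips: trim whitespace, prune to the
# intersection with a warning when species are dropped on either side.
match_species <- function(tree, ..., min_n = 4L) {
  vecs <- list(...)
  stopifnot(length(vecs) >= 1L)
  for (nm in names(vecs)) {
    if (is.null(names(vecs[[nm]]))) {
      stop_validation(sprintf("`%s` must be a named vector (species names)", nm))
    }
    names(vecs[[nm]]) <- trimws(names(vecs[[nm]]))
  }
  tips <- trimws(tree$tip.label)
  tree$tip.label <- tips
  common <- Reduce(intersect, c(list(tips), lapply(vecs, names)))
  dropped <- setdiff(union(tips, unlist(lapply(vecs, names))), common)
  if (length(dropped) > 0L) {
    warning(sprintf("pruning %d unmatched species: %s", length(dropped),
                    paste(sort(dropped), collapse = ", ")), call. = FALSE)
  }
  if (length(common) < min_n) {
    stop_validation(sprintf("only %d species shared between tree and data (need >= %d)",
                            length(common), min_n))
  }
  tree <- ape::keep.tip(tree, common)
  ord <- tree$tip.label
  vecs <- lapply(vecs, function(v) v[ord])
  c(list(tree = tree), vecs)
}
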