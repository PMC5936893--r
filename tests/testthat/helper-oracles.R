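# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Shared path length between two tips by explicit root-to-tip path
# intersection: each root-to-tip path is a set of edges (identified by their
# child node); the shared path length is the summed length of the common
# edges.
oracle_shared_paths <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1
  elen <- numeric(max(tree$edge))          # edge length indexed by child node
  elen[tree$edge[, 2]] <- tree$edge.length
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path_edges <- lapply(seq_len(n), function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v)
      v <- parent[v]
    }
    nodes
  })
  sigma <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      sigma[i, j] <- sum(elen[shared])
    }
  }
  sigma
}

# Random rooted tree with integer branch lengths (exact arithmetic for the
# path-intersection comparison).
random_int_tree <- function(n_tips) {
  tree <- ape::rtree(n_tips, rooted = TRUE)
  tree$edge.length <- sample(1:5, length(tree$edge.length), replace = TRUE)
  tree
}

# Dense multivariate-normal log-density at (mu, Sigma), no Cholesky reuse.
oracle_mvn_logdensity <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  -n / 2 * log(2 * pi) - 0.5 * determinant(Sigma, logarithm = TRUE)$modulus[1] -
    0.5 * drop(t(r) %*% solve(Sigma) %*% r)
}

# Exhaustive shortest-window scan for the HPD interval.
oracle_hpd <- function(x, mass) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(xs[1], xs[n])
  if (m >= n) return(best)
  for (i in seq_len(n - m + 1)) {
    if (xs[i + m - 1] - xs[i] < best[2] - best[1]) best <- c(xs[i], xs[i + m - 1])
  }
  best
}

# A small ready-made synthetic system shared by several tests.
make_system <- function(n = 12, seed = 99) {
  set.seed(seed)
  tree <- simulate_tree(n)
  coords <- simulate_coordinates(n, taxa = tree$tip.label)
  list(tree = tree, coords = coords,
       S = normalize_covariance(phylo_covariance(tree, tree$tip.label)),
       W = spatial_similarity(distance_matrix(coords)))
}
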