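#' Simulate an ultrametric pure-birth tree
#'
#' Desk-scale stand-in for a dated language/species tree: a Yule (pure
#' birth) tree with contemporaneous tips, rescaled so the root-to-tip depth
#' equals `depth`. Reproducible for a given seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param model Currently `"yule"`.
#' @param seed Optional integer seed.
#' @param depth Root-to-tip depth after rescaling (default 1).
#' @return A `phylo` object; `is_ultrametric()` holds.
#' @export
simulate_tree <- function(n_tips, model = c("yule"), seed = NULL, depth = 1) {
  model <- match.arg(model)
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (depth / d)
  tree
}

#' Emulate a posterior tree sample by perturbing branch lengths
#'
#' Multiplies every edge length by an independent lognormal factor (median
#' 1) and re-stretches the terminal branches so the tree stays ultrametric
#' at the original depth — a cheap emulation of tree-to-tree branch-length
#' uncertainty on a fixed topology.
#'
#' @param tree Ultrametric `phylo`.
#' @param n_trees Number of perturbed copies.
#' @param sdlog Lognormal standard deviation of the edge multipliers
#'   (default 0.1).
#' @param seed Optional integer seed.
#' @return `multiPhylo` of length `n_trees`.
#' @export
simulate_tree_set <- function(tree, n_trees, sdlog = 0.1, seed = NULL) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  target <- max(ape::node.depth.edgelength(tree))
  out <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- tree
    tr$edge.length <- tr$edge.length * stats::rlnorm(length(tr$edge.length), 0, sdlog)
    dep <- ape::node.depth.edgelength(tr)
    tip_edges <- match(seq_len(n), tr$edge[, 2])
    parent_depth <- dep[tr$edge[tip_edges, 1]]
    new_depth <- max(dep[seq_len(n)])
    tr$edge.length[tip_edges] <- new_depth - parent_depth
    tr$edge.length <- tr$edge.length * (target / new_depth)
    out[[i]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

#' Simulate uniform coordinates in a lat/lon box
#'
#' Default box is a Eurasian-like window (lat 5-65, lon -10-95).
#'
#' @param n Number of points (>= 1).
#' @param lat_range,lon_range Length-2 numeric bounds (degrees).
#' @param seed Optional integer seed.
#' @param taxa Optional labels (default `t1..tn`, matching
#'   [simulate_tree()]).
#' @return A `geo_points` object.
#' @export
simulate_coordinates <- function(n, lat_range = c(5, 65), lon_range = c(-10, 95),
                                 seed = NULL, taxa = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (lat_range[1] >= lat_range[2] || lon_range[1] >= lon_range[2]) {
    stop("inverted coordinate box")
  }
  if (lat_range[1] < -90 || lat_range[2] > 90 ||
      lon_range[1] <= -180 || lon_range[2] > 180) stop("box out of bounds")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  geo_points(taxa,
             lat = stats::runif(n, lat_range[1], lat_range[2]),
             lon = stats::runif(n, lon_range[1], lon_range[2]))
}

#' Draw traits from the phylogenetic-spatial covariance model
#'
#' Multivariate-normal draws with mean `X beta` and covariance
#' `sigma2 * V(lambda, phi)` where V mixes the independent, phylogenetic and
#' spatial components (see [combine_covariance()]). With `sigma2 = 0` the
#' deterministic mean is returned.
#'
#' @param sigma_star Unit-diagonal phylogenetic covariance.
#' @param w Spatial similarity.
#' @param weights `cov_weights` (the generating lambda, phi).
#' @param X Design matrix (`NULL` = zero mean).
#' @param beta Coefficients matching `X`.
#' @param sigma2 Scale (>= 0), default 1.
#' @param n_rep Number of independent replicate draws.
#' @param seed Optional integer seed.
#' @return Numeric vector (one replicate) or n x n_rep matrix.
#' @export
simulate_trait <- function(sigma_star, w, weights, X = NULL, beta = NULL,
                           sigma2 = 1, n_rep = 1, seed = NULL) {
  S <- component_matrix(sigma_star, "sigma")
  n <- nrow(S)
  mu <- if (is.null(X) || is.null(beta)) rep(0, n) else drop(as.matrix(X) %*% beta)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (sigma2 == 0) {
    out <- matrix(mu, n, n_rep)
    return(if (n_rep == 1) drop(out) else out)
  }
  if (!is.null(seed)) set.seed(seed)
  V <- combine_covariance(weights, sigma_star, w)
  L <- t(chol(V))
  Z <- matrix(stats::rnorm(n * n_rep), n, n_rep)
  out <- mu + sqrt(sigma2) * (L %*% Z)
  if (n_rep == 1) drop(out) else out
}

#' Simulate a complete analysis-ready dataset
#'
#' One call producing everything a fit consumes — tree (plus optional
#' perturbed tree sample), coordinates, design matrix, response — with the
#' generating parameters stored verbatim for recovery tests.
#'
#' @param n_tips Number of taxa (default 44, the scale the model is meant
#'   for).
#' @param lambda,phi Generating covariance weights.
#' @param beta Coefficients; default intercept 0. A named element
#'   `binary` adds a balanced 0/1 covariate with that effect size.
#' @param sigma2 Trait scale (default 1).
#' @param n_trees Number of perturbed trees to emit (default 1 = just the
#'   generating tree).
#' @param seed Integer seed (drives tree, coordinates, covariate and trait).
#' @return Object of class `psgls_sim`: list with `tree`, `trees`, `coords`,
#'   `X`, `y`, `params`.
#' @export
simulate_dataset <- function(n_tips = 44, lambda = 0, phi = 0,
                             beta = c(`(Intercept)` = 0), sigma2 = 1,
                             n_trees = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(n_tips)
  coords <- simulate_coordinates(n_tips, taxa = tree$tip.label)
  X <- matrix(1, n_tips, 1, dimnames = list(NULL, "(Intercept)"))
  b <- beta
  if ("binary" %in% names(beta)) {
    z <- rep(c(0, 1), length.out = n_tips)[sample.int(n_tips)]
    X <- cbind(X, binary = z)
    b <- c(beta[setdiff(names(beta), "binary")], binary = unname(beta["binary"]))
    if (!"(Intercept)" %in% names(b)) b <- c(`(Intercept)` = 0, b)
    b <- b[colnames(X)]
  }
  Sstar <- normalize_covariance(phylo_covariance(tree, tree$tip.label))
  W <- spatial_similarity(distance_matrix(coords))
  wts <- covariance_weights(lambda, phi)
  y <- simulate_trait(Sstar, W, wts, X = X, beta = b, sigma2 = sigma2)
  trees <- if (n_trees > 1) simulate_tree_set(tree, n_trees) else c(tree)
  structure(
    list(tree = tree, trees = trees, coords = coords, X = X, y = y,
         sigma_star = Sstar, w = W,
         params = list(lambda = lambda, phi = phi, beta = b,
                       sigma2 = sigma2, seed = seed, n_tips = n_tips)),
    class = "psgls_sim"
  )
}

#' Weight-recovery experiment over a grid of generating truths
#'
#' For each true `(lambda, phi)` pair, simulates `reps` traits on one
#' simulated tree + coordinate set and re-estimates the weights with the
#' exhaustive grid search, reporting the mean and SD of the estimates and
#' the rejection rates of the likelihood-ratio tests at `alpha`. This is the
#' package's identifiability check: a purely phylogenetic trait should be
#' attributed to ancestry, a purely spatial one to proximity, and an i.i.d.
#' trait to neither.
#'
#' Rejection columns: `reject_lambda` / `reject_phi` test the single-weight
#' model against independent errors (df 1); `reject_joint` tests the joint
#' model against independent errors (df 2).
#'
#' @param truth Two-column matrix/data frame of generating `(lambda, phi)`
#'   pairs.
#' @param reps Replicate traits per truth (>= 1).
#' @param n_tips Taxa per dataset (default 44).
#' @param sigma2 Generating scale (default 1).
#' @param X,beta Optional fixed effects added to the generating mean and to
#'   the fitted design; with these set, per-coefficient mean estimates are
#'   reported (`mean_beta_*`).
#' @param step Grid increment (default 0.02).
#' @param alpha LRT level for the rejection-rate columns (default 0.05).
#' @param seed Integer seed.
#' @param out Optional TSV path for the recovery table.
#' @return Data frame, one row per truth.
#' @export
identifiability_experiment <- function(truth, reps = 200, n_tips = 44,
                                       sigma2 = 1, X = NULL, beta = NULL,
                                       step = 0.02, alpha = 0.05,
                                       seed = 1, out = NULL) {
  truth <- as.matrix(truth)
  if (ncol(truth) != 2) stop("truth must have two columns (lambda, phi)")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  tree <- simulate_tree(n_tips)
  coords <- simulate_coordinates(n_tips, taxa = tree$tip.label)
  S <- normalize_covariance(phylo_covariance(tree, tree$tip.label))$sigma
  W <- spatial_similarity(distance_matrix(coords))$w
  if (is.null(X)) X <- matrix(1, n_tips, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  }

  grid <- grid_points(step, "both")
  cache <- build_grid_cache(S, W, X, grid)
  i_neither <- which(grid$lambda == 0 & grid$phi == 0)
  idx_lam_only <- which(grid$phi == 0)
  idx_phi_only <- which(grid$lambda == 0)

  rows <- lapply(seq_len(nrow(truth)), function(r) {
    wts <- covariance_weights(truth[r, 1], truth[r, 2])
    Y <- simulate_trait(S, W, wts, X = X, beta = beta, sigma2 = sigma2,
                        n_rep = reps)
    Y <- as.matrix(Y)
    ll <- grid_loglik(cache, Y)                      # n_grid x reps
    best <- apply(ll, 2, which.max)
    ll_both <- ll[cbind(best, seq_len(reps))]
    ll_lam <- apply(ll[idx_lam_only, , drop = FALSE], 2, max)
    ll_phi <- apply(ll[idx_phi_only, , drop = FALSE], 2, max)
    ll_nil <- ll[i_neither, ]
    p_lam <- stats::pchisq(pmax(2 * (ll_lam - ll_nil), 0), 1, lower.tail = FALSE)
    p_phi <- stats::pchisq(pmax(2 * (ll_phi - ll_nil), 0), 1, lower.tail = FALSE)
    p_joint <- stats::pchisq(pmax(2 * (ll_both - ll_nil), 0), 2, lower.tail = FALSE)
    res <- data.frame(
      lambda = truth[r, 1], phi = truth[r, 2],
      mean_lambda_hat = mean(grid$lambda[best]),
      sd_lambda_hat = stats::sd(grid$lambda[best]),
      mean_phi_hat = mean(grid$phi[best]),
      sd_phi_hat = stats::sd(grid$phi[best]),
      reject_lambda = mean(p_lam < alpha),
      reject_phi = mean(p_phi < alpha),
      reject_joint = mean(p_joint < alpha)
    )
    if (!is.null(beta)) {
      B <- matrix(NA_real_, ncol(X), reps)
      for (g in unique(best)) {
        cols <- which(best == g)
        e <- cache[[g]]
        Yt <- backsolve(e$R, Y[, cols, drop = FALSE], transpose = TRUE)
        B[, cols] <- e$XtX_inv %*% crossprod(e$Xt, Yt)
      }
      mb <- rowMeans(B)
      for (j in seq_along(mb)) {
        res[[paste0("mean_beta_", colnames(X)[j])]] <- mb[j]
      }
    }
    res
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out)) {
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
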