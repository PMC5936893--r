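#' Shortest (highest-density) interval of a sample
#'
#' Empirical HPD: the shortest contiguous window of the sorted sample that
#' contains `ceiling(mass * n)` points. No kernel smoothing is applied, which
#' keeps the interval honest for grid-discrete estimates such as the
#' covariance weights.
#'
#' @param x Numeric vector (at least one finite value).
#' @param mass Probability mass in (0, 1\] (default 0.95).
#' @return Named numeric `c(lo, hi)`.
#' @examples
#' hpd_interval(1:100, 0.95)  # width 94
#' @export
hpd_interval <- function(x, mass = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty sample")
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lo = xs[1], hi = xs[n]))
  starts <- seq_len(n - m + 1)
  widths <- xs[starts + m - 1] - xs[starts]
  i <- which.min(widths)
  c(lo = xs[i], hi = xs[i + m - 1])
}

#' Mean p-value and significance stars across trees
#'
#' Aggregates per-tree p-values the way posterior-ensemble tables report
#' them: the arithmetic mean p across trees, starred at strict thresholds
#' `***` < 0.001, `**` < 0.01, `*` < 0.05.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return List with `mean_p` and `stars`.
#' @export
summarize_significance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- mean(p)
  stars <- if (m < 0.001) "***" else if (m < 0.01) "**" else if (m < 0.05) "*" else ""
  list(mean_p = m, stars = stars)
}

#' Fit the grid model across a sample of trees
#'
#' Runs [profile_grid_fit()] once per tree of a (posterior) tree sample and
#' aggregates: the spatial similarity W is computed once (coordinates do not
#' depend on the tree); each tree contributes its unit-diagonal phylogenetic
#' covariance. Summaries per parameter (lambda', phi, gamma and every
#' regression coefficient) are the across-tree mean and empirical 95% HPD;
#' significance is the mean p-value across trees ([summarize_significance()]).
#'
#' @param trees A list of `phylo` objects / `multiPhylo` with identical tip
#'   sets.
#' @param y Response vector ordered as `taxa`.
#' @param X Design matrix (intercept first); `NULL` for intercept-only.
#' @param coords `geo_points` for the same taxa (any order; matched by label).
#' @param taxa Taxon order of `y`/`X` rows; defaults to `coords$taxon`.
#' @param step Grid increment (default 0.02).
#' @param mode Grid mode, see [profile_grid_fit()].
#' @param transform,rho Spatial similarity transform, see
#'   [spatial_similarity()].
#' @param keep_fits Keep every per-tree `grid_fit` (memory-heavy for large
#'   samples); the per-tree parameter table is always kept.
#' @return Object of class `ensemble_summary`: `summary` (data frame with
#'   parameter, mean, hpd_lo, hpd_hi, mean_p, stars), `per_tree` (long data
#'   frame of per-tree estimates), `n_trees`, and optionally `fits`.
#' @export
fit_over_trees <- function(trees, y, X = NULL, coords, taxa = NULL,
                           step = 0.02, mode = "both",
                           transform = "linear", rho = NULL,
                           keep_fits = FALSE) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0) stop("empty tree list")
  if (is.null(taxa)) taxa <- coords$taxon
  tipset <- sort(trees[[1]]$tip.label)
  if (!identical(sort(taxa), tipset)) stop("taxa do not match the trees' tip set")
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tipset)) {
      stop("tree ", i, " has a different tip set")
    }
  }
  ord <- match(taxa, coords$taxon)
  if (any(is.na(ord))) stop("coordinates missing for some taxa")
  W <- spatial_similarity(distance_matrix(coords[ord, , drop = FALSE]),
                          transform = transform, rho = rho)

  fits <- vector("list", length(trees))
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    Sstar <- normalize_covariance(phylo_covariance(trees[[i]], taxa))
    f <- profile_grid_fit(y, X, Sstar, W, step = step, mode = mode)
    if (keep_fits) fits[[i]] <- f
    est <- c(lambda_prime = f$weights$lambda_prime, phi = f$weights$phi,
             gamma = f$weights$gamma, f$fit$beta)
    pv <- c(lambda_prime = unname(f$lrt_p["lambda"]), phi = unname(f$lrt_p["phi"]),
            gamma = NA_real_, f$fit$p_values)
    rows[[i]] <- data.frame(tree = i, parameter = names(est),
                            estimate = unname(est), p = unname(pv),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  per_tree <- do.call(rbind, rows)

  params <- unique(per_tree$parameter)
  summ <- do.call(rbind, lapply(params, function(pp) {
    sub <- per_tree[per_tree$parameter == pp, ]
    hpd <- hpd_interval(sub$estimate, 0.95)
    if (all(is.na(sub$p))) {
      mp <- NA_real_; st <- ""
    } else {
      sg <- summarize_significance(sub$p)
      mp <- sg$mean_p; st <- sg$stars
    }
    data.frame(parameter = pp, mean = mean(sub$estimate),
               hpd_lo = hpd[["lo"]], hpd_hi = hpd[["hi"]],
               mean_p = mp, stars = st, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_tree = per_tree, n_trees = length(trees),
                 fits = if (keep_fits) fits else NULL,
                 mode = mode, step = step),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble over", x$n_trees, "trees (mode:", x$mode, ")\n")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write an ensemble report as TSV
#'
#' One row per parameter with mean, HPD bounds, mean p and stars; optionally
#' the per-tree long table alongside.
#'
#' @param ens An `ensemble_summary`.
#' @param path Output path for the summary TSV.
#' @param per_tree_path Optional path for the per-tree long-format TSV.
#' @export
write_ensemble_tsv <- function(ens, path, per_tree_path = NULL) {
  utils::write.table(ens$summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(per_tree_path)) {
    utils::write.table(ens$per_tree, per_tree_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
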