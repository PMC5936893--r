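#' Covariance mixing weights
#'
#' The model covariance is a convex mixture of an independent component, a
#' phylogenetic component and a spatial component, parameterized by an
#' ancestry weight `lambda` and a proximity weight `phi`, both in \[0, 1\].
#' The derived shares are `lambda_prime = (1 - phi) * lambda` (proportion of
#' modelled covariance attributable to ancestry), `phi` (spatial share) and
#' `gamma = (1 - phi) * (1 - lambda)` (independent share); the three always
#' sum to one.
#'
#' @param lambda Ancestry weight in \[0, 1\].
#' @param phi Spatial weight in \[0, 1\].
#' @return Object of class `cov_weights`: list with `lambda`, `phi`,
#'   `lambda_prime`, `gamma`.
#' @examples
#' covariance_weights(0.5, 0.5)  # lambda' = 0.25, gamma = 0.25
#' @export
covariance_weights <- function(lambda, phi) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (!is.finite(phi) || phi < 0 || phi > 1) stop("phi must be in [0, 1]")
  structure(list(lambda = lambda, phi = phi,
                 lambda_prime = (1 - phi) * lambda,
                 gamma = (1 - phi) * (1 - lambda)),
            class = "cov_weights")
}

#' @export
print.cov_weights <- function(x, ...) {
  cat(sprintf("weights: lambda = %.4g, phi = %.4g  (lambda' = %.4g, gamma = %.4g)\n",
              x$lambda, x$phi, x$lambda_prime, x$gamma))
  invisible(x)
}

#' Combine phylogenetic and spatial components into a model covariance
#'
#' Builds `V = gamma * I + lambda' * Sigma* + phi * W` from unit-diagonal
#' components, so V itself has unit diagonal. If V is numerically indefinite
#' with smallest eigenvalue no lower than -1e-8, a ridge of
#' `|min eigenvalue| + 1e-10` on the diagonal repairs it (numerical-noise
#' tolerance); a smaller eigenvalue is a hard error, since it signals a
#' genuinely invalid spatial matrix at these weights.
#'
#' @param weights A `cov_weights` object (or list with `lambda`, `phi`).
#' @param sigma_star Unit-diagonal phylogenetic covariance: a `phylo_cov`
#'   (see [normalize_covariance()]) or a plain matrix.
#' @param w Spatial similarity: a `spatial_sim` or a plain matrix. Taxa must
#'   match `sigma_star` in the same order.
#' @return n x n covariance matrix V.
#' @export
combine_covariance <- function(weights, sigma_star, w) {
  if (!inherits(weights, "cov_weights")) weights <- covariance_weights(weights$lambda, weights$phi)
  S <- component_matrix(sigma_star, "sigma")
  W <- component_matrix(w, "w")
  if (!identical(dim(S), dim(W))) stop("sigma_star and w are not conformable")
  if (!is.null(rownames(S)) && !is.null(rownames(W)) &&
      !identical(rownames(S), rownames(W))) {
    stop("taxon order differs between sigma_star and w")
  }
  V <- diag(weights$gamma, nrow(S)) + weights$lambda_prime * S + weights$phi * W
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    if (min(ev) > -1e-8) {
      V <- V + diag(abs(min(ev)) + 1e-10, nrow(V))
    } else {
      stop("combined covariance is not positive definite at these weights ",
           sprintf("(min eigenvalue %.3g)", min(ev)))
    }
  }
  V
}

component_matrix <- function(x, which) {
  m <- if (inherits(x, "phylo_cov")) x$sigma
       else if (inherits(x, "spatial_sim")) x$w
       else as.matrix(x)
  if (nrow(m) != ncol(m)) stop(which, " component is not square")
  m
}

#' Generalized least squares with known covariance structure
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 V)` by maximum likelihood for a
#' fixed V. The scale sigma^2 is profiled analytically:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, `sigma^2 = RSS_V / n`, and the profiled
#' log-likelihood is `-n/2 log(2 pi sigma^2) - log|V|/2 - n/2`. Coefficient
#' standard errors use the unbiased residual variance `RSS_V / (n - k)` with
#' `(X' V^-1 X)^-1`, and two-sided p-values come from a t reference with
#' n - k degrees of freedom, so with V = I the fit reduces exactly to OLS
#' inference.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column).
#' @param V Symmetric positive-definite covariance (n x n).
#' @return Object of class `psgls_fit` with `beta`, `se`, `sigma2`, `loglik`,
#'   `n`, `k`, `p_values`, `residuals`.
#' @examples
#' set.seed(1)
#' y <- rnorm(10); X <- cbind(1, rnorm(10))
#' gls_fit(y, X, diag(10))  # equals OLS
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) stop("y, X, V are not conformable")
  k <- ncol(X)
  if (n < k + 1) stop("need n >= k + 1 observations")
  R <- tryCatch(chol(V), error = function(e) stop("singular covariance V: ", conditionMessage(e)))
  logdet <- 2 * sum(log(diag(R)))
  # whiten: solve R' z = x  (so z = R'^-1 x and z'z = x' V^-1 x)
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xt)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) stop("collinear design: X' V^-1 X is singular"))
  beta <- drop(XtX_inv %*% crossprod(Xt, yt))
  resid_t <- yt - Xt %*% beta
  rss <- sum(resid_t^2)
  sigma2 <- rss / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  loglik <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  # se/p use the unbiased residual variance so the V = I case reduces to OLS
  se <- sqrt(rss / (n - k) * diag(XtX_inv))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- c("(Intercept)", paste0("x", seq_len(k - 1)))[seq_len(k)]
  names(beta) <- names(se) <- names(p) <- nm
  structure(
    list(beta = beta, se = se, sigma2 = sigma2, loglik = loglik,
         n = n, k = k, p_values = p,
         residuals = drop(y - X %*% beta)),
    class = "psgls_fit"
  )
}

#' @export
print.psgls_fit <- function(x, ...) {
  cat("GLS fit (ML): n =", x$n, " logLik =", format(x$loglik, digits = 7),
      " sigma2 =", format(x$sigma2, digits = 5), "\n")
  tab <- data.frame(estimate = x$beta, se = x$se, p = x$p_values)
  print(tab, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' Computes `2 * (logLik_full - logLik_reduced)` and refers it to a
#' chi-square with `df` degrees of freedom (the number of freed parameters).
#' The default plain chi-square reference is conservative when the null pins
#' a variance-component weight to the boundary of \[0, 1\]; the
#' `"mixture"` option uses the boundary-adjusted 50:50 mixture of
#' chi-square(0) and chi-square(df).
#'
#' @param full,reduced Objects with a `loglik` field ([gls_fit()] /
#'   [profile_grid_fit()] results), or bare numeric log-likelihoods.
#' @param df Degrees of freedom (positive integer).
#' @param null `"chisq"` (default) or `"mixture"`.
#' @return p-value.
#' @export
likelihood_ratio_test <- function(full, reduced, df, null = c("chisq", "mixture")) {
  null <- match.arg(null)
  ll_full <- if (is.numeric(full)) full else full$loglik
  ll_red <- if (is.numeric(reduced)) reduced else reduced$loglik
  if (df < 1 || df != round(df)) stop("df must be a positive integer")
  stat <- 2 * (ll_full - ll_red)
  if (stat < -1e-8) stop("models are not nested: full log-likelihood below reduced")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (null == "mixture") p <- if (stat == 0) 1 else 0.5 * p
  p
}

# ---- grid engine ------------------------------------------------------------
#
# For fixed (Sigma*, W, X) every grid point's Cholesky factor, log|V| and
# whitened design are computed once; each response (or matrix of replicate
# responses) then costs one triangular solve per grid point. Grid points
# where V is not positive definite get logLik -Inf and are excluded from the
# argmax; if every point fails, that is an error.

grid_points <- function(step, mode) {
  if (step <= 0 || step > 1) stop("grid step must be in (0, 1]")
  ncell <- 1 / step
  if (abs(ncell - round(ncell)) > 1e-9) stop("grid step must divide 1 exactly")
  vals <- seq(0, 1, by = step)
  lam_vals <- if (mode %in% c("both", "lambda_only")) vals else 0
  phi_vals <- if (mode %in% c("both", "phi_only")) vals else 0
  # lexicographic in (lambda, phi): ties resolve to smallest lambda, then phi
  g <- expand.grid(phi = phi_vals, lambda = lam_vals,
                   KEEP.OUT.ATTRS = FALSE)[, c("lambda", "phi")]
  g[order(g$lambda, g$phi), , drop = FALSE]
}

build_grid_cache <- function(S, W, X, grid) {
  n <- nrow(S)
  X <- as.matrix(X)
  I_n <- diag(n)
  lapply(seq_len(nrow(grid)), function(i) {
    wts <- covariance_weights(grid$lambda[i], grid$phi[i])
    V <- wts$gamma * I_n + wts$lambda_prime * S + wts$phi * W
    V <- (V + t(V)) / 2
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(ok = FALSE))
    Xt <- backsolve(R, X, transpose = TRUE)
    XtX_inv <- tryCatch(solve(crossprod(Xt)), error = function(e) NULL)
    if (is.null(XtX_inv)) return(list(ok = FALSE))
    list(ok = TRUE, R = R, logdet = 2 * sum(log(diag(R))),
         Xt = Xt, XtX_inv = XtX_inv)
  })
}

# log-likelihood of every grid point for every response column of Y
grid_loglik <- function(cache, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  out <- matrix(-Inf, length(cache), ncol(Y))
  for (i in seq_along(cache)) {
    e <- cache[[i]]
    if (!e$ok) next
    Yt <- backsolve(e$R, Y, transpose = TRUE)
    B <- e$XtX_inv %*% crossprod(e$Xt, Yt)
    rss <- colSums((Yt - e$Xt %*% B)^2)
    sigma2 <- pmax(rss / n, .Machine$double.eps)
    out[i, ] <- -n / 2 * log(2 * pi * sigma2) - e$logdet / 2 - n / 2
  }
  out
}

#' Profiled maximum-likelihood fit over a (lambda, phi) grid
#'
#' Evaluates the GLS model at every point of an exhaustive grid over the
#' active covariance weights and returns the maximum-likelihood point, the
#' fit there, the whole log-likelihood surface, and likelihood-ratio tests
#' against the nested models. With the default step 0.02 each active axis has
#' 51 points (2601 evaluations when both weights are active). Exact ties in
#' log-likelihood resolve to the smallest lambda, then the smallest phi
#' (parsimony toward the null).
#'
#' Modes: `"both"` fits lambda and phi jointly; `"lambda_only"` / `"phi_only"`
#' pin the other weight to 0; `"neither"` is the independent-errors model.
#' `lrt_p` contains, for `"both"`: `lambda` (both vs phi-only, df 1), `phi`
#' (both vs lambda-only, df 1) and `joint` (both vs neither, df 2); for the
#' single-weight modes: the test of that weight against `"neither"` (df 1).
#'
#' @param y Response vector (NAs dropped listwise together with X, Sigma*, W).
#' @param X Design matrix with intercept; defaults to intercept-only.
#' @param sigma_star Unit-diagonal phylogenetic covariance (`phylo_cov` or
#'   matrix).
#' @param w Spatial similarity (`spatial_sim` or matrix).
#' @param step Grid increment; must divide 1 exactly (default 0.02).
#' @param mode One of `"both"`, `"lambda_only"`, `"phi_only"`, `"neither"`.
#' @param null Reference for the LRTs, passed to [likelihood_ratio_test()].
#' @return Object of class `grid_fit`: `weights` (`cov_weights` at the ML
#'   point), `fit` (`psgls_fit` there), `surface` (lambda x phi log-likelihood
#'   matrix), `lrt_p`, `nested_loglik`, `step`, `mode`, `n_dropped`.
#' @export
profile_grid_fit <- function(y, X = NULL, sigma_star, w, step = 0.02,
                             mode = c("both", "lambda_only", "phi_only", "neither"),
                             null = "chisq") {
  mode <- match.arg(mode)
  S <- component_matrix(sigma_star, "sigma")
  W <- component_matrix(w, "w")
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  keep <- is.finite(y) & apply(is.finite(X), 1, all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " rows with missing response or covariates")
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    S <- S[keep, keep, drop = FALSE]; W <- W[keep, keep, drop = FALSE]
  }
  res <- grid_fit_engine(y, X, S, W, step, mode)

  # nested-model log-likelihoods for the LRTs (cheap: <= 103 extra points)
  nested <- c(both = NA_real_, lambda_only = NA_real_,
              phi_only = NA_real_, neither = NA_real_)
  nested[[mode]] <- res$loglik
  need <- switch(mode,
    both = c("lambda_only", "phi_only", "neither"),
    lambda_only = "neither",
    phi_only = "neither",
    neither = character(0))
  for (m in need) nested[[m]] <- grid_fit_engine(y, X, S, W, step, m)$loglik
  lrt_p <- switch(mode,
    both = c(
      lambda = likelihood_ratio_test(nested[["both"]], nested[["phi_only"]], 1, null),
      phi    = likelihood_ratio_test(nested[["both"]], nested[["lambda_only"]], 1, null),
      joint  = likelihood_ratio_test(nested[["both"]], nested[["neither"]], 2, null)),
    lambda_only = c(lambda = likelihood_ratio_test(nested[["lambda_only"]],
                                                   nested[["neither"]], 1, null)),
    phi_only = c(phi = likelihood_ratio_test(nested[["phi_only"]],
                                             nested[["neither"]], 1, null)),
    neither = stats::setNames(numeric(0), character(0)))

  wts <- covariance_weights(res$lambda, res$phi)
  V <- combine_covariance(wts, S, W)
  fit <- gls_fit(y, X, V)
  structure(
    list(weights = wts, fit = fit, surface = res$surface, lrt_p = lrt_p,
         nested_loglik = nested, step = step, mode = mode,
         n_dropped = n_dropped),
    class = "grid_fit"
  )
}

grid_fit_engine <- function(y, X, S, W, step, mode) {
  grid <- grid_points(step, mode)
  cache <- build_grid_cache(S, W, X, grid)
  ll <- grid_loglik(cache, y)[, 1]
  if (all(!is.finite(ll))) {
    stop("covariance not positive definite at any grid point (mode ", mode, ")")
  }
  best <- which.max(ll)  # first max = smallest lambda, then phi (grid ordering)
  lam_vals <- sort(unique(grid$lambda))
  phi_vals <- sort(unique(grid$phi))
  surface <- matrix(ll, length(phi_vals), length(lam_vals))  # filled phi-fastest
  surface <- t(surface)
  dimnames(surface) <- list(lambda = format(lam_vals), phi = format(phi_vals))
  list(lambda = grid$lambda[best], phi = grid$phi[best],
       loglik = ll[best], surface = surface)
}

#' @export
print.grid_fit <- function(x, ...) {
  cat("Phylogenetic-spatial GLS grid fit (mode: ", x$mode,
      ", step ", x$step, ")\n", sep = "")
  print(x$weights)
  cat("logLik at ML point:", format(x$fit$loglik, digits = 7), "\n")
  if (length(x$lrt_p)) {
    cat("LRT p-values:", paste(names(x$lrt_p),
        format(x$lrt_p, digits = 3), sep = " = ", collapse = ", "), "\n")
  }
  print(x$fit)
  invisible(x)
}
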