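#' Drop indicator years with too many missing countries
#'
#' Development-indicator panels (countries x years) often have patchy early
#' years. A year column is excluded when more than `max_missing` countries
#' lack a value for it; the default tolerates a single missing country.
#' Column order is preserved.
#'
#' @param panel Numeric matrix or data frame, countries in rows (rownames),
#'   years in columns (colnames).
#' @param max_missing Maximum number of missing countries a retained year may
#'   have (default 1).
#' @return The filtered panel (matrix).
#' @export
filter_years <- function(panel, max_missing = 1) {
  panel <- as.matrix(panel)
  keep <- colSums(is.na(panel)) <= max_missing
  if (!any(keep)) stop("every year exceeds the missing-country threshold")
  panel[, keep, drop = FALSE]
}

#' Standardize indicator values within each year
#'
#' Subtracts the cross-country mean and divides by the cross-country standard
#' deviation (n - 1 denominator) separately for every year column, removing
#' broad secular trends before years are averaged. Missing cells stay
#' missing.
#'
#' @param panel Countries x years matrix.
#' @return Matrix of z-scores with the same shape and dimnames.
#' @export
standardize_by_year <- function(panel) {
  panel <- as.matrix(panel)
  out <- apply(panel, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) < 2) stop("a year has fewer than 2 non-missing values")
    s <- stats::sd(v)
    if (s == 0) stop("a year has zero spread; cannot standardize")
    (col - mean(v)) / s
  })
  dimnames(out) <- dimnames(panel)
  out
}

#' Average standardized yearly scores per country
#'
#' Per-country mean over the available (non-missing) standardized years.
#'
#' @param panel Countries x years matrix of z-scores.
#' @return Named numeric vector, one score per country.
#' @export
average_country_scores <- function(panel) {
  panel <- as.matrix(panel)
  if (any(rowSums(!is.na(panel)) == 0)) {
    stop("some countries have no non-missing values: ",
         paste(rownames(panel)[rowSums(!is.na(panel)) == 0], collapse = ", "))
  }
  rowMeans(panel, na.rm = TRUE)
}

#' One-way ANOVA of indicator values by country
#'
#' Treats the yearly values as replicates and asks how much of the total
#' variance the country factor explains: eta-squared =
#' SS_between / SS_total, with the F statistic on (k - 1, N - k) degrees of
#' freedom. A large eta-squared justifies collapsing years to a single
#' per-country average.
#'
#' @param panel Countries x years matrix (raw values by default).
#' @param standardized If `TRUE`, run the ANOVA on within-year z-scores
#'   instead of raw values.
#' @return List with `F`, `eta2`, `p`, `df`.
#' @export
country_anova <- function(panel, standardized = FALSE) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 2 || ncol(panel) < 2) stop("need >= 2 countries and >= 2 years")
  if (standardized) panel <- standardize_by_year(panel)
  long <- data.frame(
    value = as.vector(panel),
    country = factor(rep(rownames(panel), times = ncol(panel)))
  )
  long <- long[!is.na(long$value), ]
  fit <- stats::aov(value ~ country, data = long)
  tab <- stats::anova(fit)
  ss_b <- tab[["Sum Sq"]][1]
  ss_w <- tab[["Sum Sq"]][2]
  if (ss_b + ss_w <= 0) stop("zero total sum of squares; ANOVA degenerate")
  list(F = tab[["F value"]][1],
       eta2 = ss_b / (ss_b + ss_w),
       p = tab[["Pr(>F)"]][1],
       df = unname(tab[["Df"]][1:2]))
}

#' Bivariate ordinary least-squares screen
#'
#' Slope (with intercept) of `y` on a single predictor, with t-based 95%
#' confidence interval and two-sided p-value — the standard first-pass screen
#' of each covariate against each outcome before any covariance modelling.
#'
#' @param y Response vector.
#' @param x Single predictor vector.
#' @param conf Confidence level (default 0.95).
#' @return List with `beta`, `ci` (length 2), `p`, `intercept`, `n`.
#' @export
bivariate_ols <- function(y, x, conf = 0.95) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("predictor has no spread")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = conf)
  list(beta = unname(stats::coef(fit)["x"]),
       ci = c(lo = ci[1], hi = ci[2]),
       p = sm$coefficients["x", "Pr(>|t|)"],
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       n = length(y))
}

#' Validate a recent-culture predictor table
#'
#' Checks religion percentages (catholic, protestant, orthodox, muslim,
#' other) lie in \[0, 100\] and sum to at most 100 (plus tolerance), and that
#' the communism indicator is binary. The "other" category is the complement
#' and is excluded from regression designs (see [religion_design()]).
#'
#' @param tbl Data frame with columns `catholic`, `protestant`, `orthodox`,
#'   `muslim`, `other`, `communism`.
#' @param tol Tolerance on the percentage sum (default 0.5).
#' @return The table, invisibly, or an error.
#' @export
predictor_table <- function(tbl, tol = 0.5) {
  rel <- c("catholic", "protestant", "orthodox", "muslim", "other")
  miss <- setdiff(c(rel, "communism"), names(tbl))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pm <- as.matrix(tbl[, rel])
  if (any(pm < 0 | pm > 100, na.rm = TRUE)) stop("religion percentages must be in [0, 100]")
  sums <- rowSums(pm)
  if (any(sums > 100 + tol, na.rm = TRUE)) stop("religion percentages sum above 100")
  if (!all(tbl$communism %in% c(0, 1))) stop("communism must be 0/1")
  invisible(tbl)
}

#' Regression design from the predictor table
#'
#' Intercept, the four named religion percentages and the communism dummy;
#' the complement category "other" is left out to avoid the dummy-variable
#' trap.
#'
#' @param tbl A validated predictor table (see [predictor_table()]).
#' @return Design matrix with columns `(Intercept)`, `catholic`,
#'   `protestant`, `orthodox`, `muslim`, `communism`.
#' @export
religion_design <- function(tbl) {
  predictor_table(tbl)
  X <- cbind(1, tbl$catholic, tbl$protestant, tbl$orthodox, tbl$muslim, tbl$communism)
  colnames(X) <- c("(Intercept)", "catholic", "protestant", "orthodox",
                   "muslim", "communism")
  X
}

#' Read the master country table
#'
#' Reads a CSV with one row per country/taxon: `country`, `taxon`, `lat`,
#' `lon`, wide year columns per indicator (e.g. `hdi_1980`, `hdi_1990`, ...),
#' religion percentages and the communism indicator. Only presence of the
#' core columns is enforced here; indicator panels are extracted with
#' [indicator_panel()].
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_country_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("country", "taxon", "lat", "lon")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tbl$taxon)) stop("duplicate taxa")
  check_coords(tbl$lat, tbl$lon)
  tbl
}

#' Extract a countries-x-years indicator panel from the master table
#'
#' Collects the wide columns `<prefix>_<year>` into a numeric matrix with
#' countries as rows (named by `taxon`) and years as columns.
#'
#' @param tbl Master table (see [read_country_table()]).
#' @param prefix Indicator prefix, e.g. `"hdi"`.
#' @return Countries x years matrix.
#' @export
indicator_panel <- function(tbl, prefix) {
  cols <- grep(paste0("^", prefix, "_[0-9]{4}$"), names(tbl), value = TRUE)
  if (length(cols) == 0) stop("no year columns found for prefix '", prefix, "'")
  m <- as.matrix(tbl[, cols])
  rownames(m) <- tbl$taxon
  colnames(m) <- sub(paste0("^", prefix, "_"), "", cols)
  storage.mode(m) <- "double"
  m
}
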