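make_panel <- function() {
  m <- rbind(c(1.0, 2.0, 3.0, 4.0),
             c(2.0, 3.0, 4.0, 5.0),
             c(3.0, 4.0, 5.0, 6.0),
             c(4.0, 5.0, 6.0, 7.0))
  dimnames(m) <- list(paste0("c", 1:4), paste0("y", 1:4))
  m
}

test_that("year filtering drops columns exceeding the missingness budget", {
  p <- make_panel()
  p[1:2, 1] <- NA  # 2 missing -> dropped
  p[3, 2] <- NA    # 1 missing -> kept
  out <- filter_years(p)
  expect_equal(colnames(out), c("y2", "y3", "y4"))
  expect_equal(filter_years(make_panel()), make_panel())
  allna <- make_panel(); allna[1:3, ] <- NA
  expect_error(filter_years(allna), "every year")
})

test_that("within-year standardization gives mean-0 sd-1 columns", {
  p <- make_panel()
  z <- standardize_by_year(p)
  expect_equal(unname(z[, 1]), unname(scale(p[, 1])[, 1]))
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(standardize_by_year(cbind(v = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  p[, 2] <- 5
  expect_error(standardize_by_year(p), "zero spread")
  pna <- make_panel(); pna[2, 3] <- NA
  expect_true(is.na(standardize_by_year(pna)[2, 3]))
})

test_that("country scores average the available standardized years", {
  z <- rbind(a = c(1, -1), b = c(0.5, NA), c = c(0.5, 1.5))
  expect_equal(average_country_scores(z), c(a = 0, b = 0.5, c = 1))
  z["b", ] <- NA
  expect_error(average_country_scores(z), "b")
})

test_that("country ANOVA matches the hand-computed partition", {
  # 2 countries x 2 years, constant within country: all variance is between
  p <- rbind(c1 = c(1, 1), c2 = c(3, 3))
  colnames(p) <- c("y1", "y2")
  res <- suppressWarnings(country_anova(p))  # perfect fit warns in aov
  expect_equal(res$eta2, 1)
  expect_equal(res$df, c(1, 2))
  # hand ANOVA: SS_between = 4, SS_within = 0
  expect_equal(res$eta2, 4 / (4 + 0))

  # equal country means, within-country variation only
  p2 <- rbind(c1 = c(1, 3), c2 = c(3, 1))
  colnames(p2) <- c("y1", "y2")
  res2 <- country_anova(p2)
  expect_equal(res2$eta2, 0)
  expect_equal(res2$F, 0)
})

test_that("eta-squared computed two ways agrees, and matches aov directly", {
  set.seed(13)
  p <- matrix(rnorm(40, rep(1:8, 5)), 8, 5,
              dimnames = list(paste0("c", 1:8), paste0("y", 1:5)))
  res <- country_anova(p)
  long <- data.frame(v = as.vector(p), g = factor(rep(rownames(p), 5)))
  tab <- anova(aov(v ~ g, data = long))
  ss <- tab[["Sum Sq"]]
  expect_equal(res$eta2, ss[1] / sum(ss), tolerance = 1e-12)
  expect_equal(res$eta2, 1 - ss[2] / sum(ss), tolerance = 1e-12)
  expect_equal(res$F, tab[["F value"]][1])
  expect_equal(res$p, tab[["Pr(>F)"]][1])
})

test_that("the preprocessing order filter -> standardize -> average matters", {
  p <- make_panel()
  p[1, 1] <- 10  # outlier year value
  scores <- average_country_scores(standardize_by_year(filter_years(p)))
  # permuting: averaging before standardizing gives different numbers
  avg_first <- scale(rowMeans(filter_years(p)))[, 1]
  expect_false(isTRUE(all.equal(unname(scores), unname(avg_first))))
  # appending a complete duplicate year leaves the averages unchanged
  z <- standardize_by_year(make_panel())
  expect_equal(average_country_scores(cbind(z, z[, 2, drop = FALSE])),
               average_country_scores(z))
})

test_that("bivariate OLS returns slope, t-interval and p", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- suppressWarnings(bivariate_ols(2 * x + 1, x))  # exact fit warns
  expect_equal(perfect$beta, 2, tolerance = 1e-10)
  expect_lt(perfect$p, 1e-10)
  y_orth <- c(1, -1, 0, 1, -1)  # zero covariance with x by construction
  y_orth <- y_orth - sum(y_orth * scale(x, scale = FALSE)) * scale(x, scale = FALSE) /
    sum(scale(x, scale = FALSE)^2)
  res <- bivariate_ols(drop(y_orth), x)
  expect_equal(res$beta, 0, tolerance = 1e-10)
  expect_error(bivariate_ols(x, rep(1, 5)), "spread")
  # agrees with lm/confint
  set.seed(14)
  y <- rnorm(20); x2 <- rnorm(20)
  res2 <- bivariate_ols(y, x2)
  ci <- confint(lm(y ~ x2))["x2", ]
  expect_equal(unname(res2$ci), unname(ci), tolerance = 1e-10)
})

test_that("predictor table validation and design construction", {
  tbl <- data.frame(catholic = c(60, 10), protestant = c(20, 5),
                    orthodox = c(5, 70), muslim = c(5, 10),
                    other = c(10, 5), communism = c(0, 1))
  expect_silent(predictor_table(tbl))
  X <- religion_design(tbl)
  expect_equal(colnames(X),
               c("(Intercept)", "catholic", "protestant", "orthodox",
                 "muslim", "communism"))
  expect_false("other" %in% colnames(X))
  bad <- tbl; bad$communism <- c(0, 2)
  expect_error(predictor_table(bad), "communism")
  bad2 <- tbl; bad2$muslim <- 150
  expect_error(predictor_table(bad2), "\\[0, 100\\]|sum above")
})

test_that("the master CSV round-trips panels, coordinates and predictors", {
  path <- system.file("extdata", "synthetic_countries.csv", package = "psgls")
  tbl <- read_country_table(path)
  expect_equal(nrow(tbl), 12)
  predictor_table(tbl)
  panel <- indicator_panel(tbl, "hdi")
  expect_equal(dim(panel), c(12, 6))
  expect_equal(colnames(panel)[1], "1980")
  kept <- filter_years(panel)
  expect_false("1980" %in% colnames(kept))  # 3 countries missing in 1980
  expect_true("1990" %in% colnames(kept))   # single missing country tolerated
  scores <- average_country_scores(standardize_by_year(kept))
  expect_length(scores, 12)
  aov_res <- country_anova(kept)
  expect_gt(aov_res$eta2, 0.8)  # country dominates year-to-year noise
  ols <- bivariate_ols(scores, tbl$muslim)
  expect_true(is.finite(ols$beta) && is.finite(ols$p))
})
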