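test_that("KS normality statistic is small for normal, large for exponential", {
  set.seed(31)
  d_norm <- ks_normality(rnorm(5000))
  expect_lt(d_norm$statistic, 0.03)
  d_exp <- ks_normality(rexp(500))
  expect_gt(d_exp$statistic, 0.05)
  expect_error(ks_normality(rep(2, 100)), "constant")
  expect_error(ks_normality(1:5), "at least 8")
})

test_that("Fisher's ratio matches hand arithmetic and is shift-invariant", {
  expect_equal(fishers_ratio(c(1, 1), c(1, 1, 2, 2)), 0.75)
  # means 1 vs 0, variances 0.5 each -> 1
  expect_equal(fishers_ratio(c(0.5, 1.5), c(-0.5, 0.5)), 1.0)
  expect_error(fishers_ratio(c(3, 3, 3), c(3, 3)), "zero")
  expect_error(fishers_ratio(1, c(1, 2)), "at least 2")
  set.seed(1)
  a <- rnorm(20); b <- rnorm(25, 1)
  expect_equal(fishers_ratio(a + 100, b + 100), fishers_ratio(a, b),
               tolerance = 1e-9)
  expect_equal(fishers_ratio(a, a), 0)
})

test_that("spearman_rho equals the brute-force rank oracle, including ties", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  set.seed(17)
  for (k in 1:25) {
    n <- sample(3:12, 1)
    x <- sample(1:5, n, replace = TRUE) + runif(n, 0, 0.01) * (k %% 2)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(23)
  for (k in 1:10) {
    x <- rnorm(50)
    y <- rnorm(50)
    r0 <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r0, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3), r0, tolerance = 1e-12)
    expect_equal(spearman_rho(-x, y), -r0, tolerance = 1e-12)
  }
})

test_that("class summary recovers generator moments and degenerates safely", {
  set.seed(41)
  n <- 400
  tab <- tibble::tibble(
    subject = rep(c("a", "b"), each = n / 2),
    label = factor(rep(c("high", "low"), n / 2),
                   levels = c("high", "low", "unlabeled")),
    SCL = ifelse(rep(c(TRUE, FALSE), n / 2), rnorm(n, 4, 1), rnorm(n, 2, 1)),
    NSSCR = ifelse(rep(c(TRUE, FALSE), n / 2), rnorm(n, 18, 3), rnorm(n, 8, 3))
  )
  s <- feature_class_summary(tab, c("SCL", "NSSCR"))
  expect_equal(s$mean_high[s$feature == "SCL"], 4, tolerance = 2 * 1 / sqrt(n / 2) * 2)
  expect_equal(s$mean_low[s$feature == "SCL"], 2, tolerance = 2 * 1 / sqrt(n / 2) * 2)
  expect_gt(s$fisher_mean[s$feature == "NSSCR"], 1)
  # high == low distributions give near-zero separability
  tab2 <- tab
  tab2$SCL <- rnorm(n)
  s2 <- feature_class_summary(tab2, "SCL")
  expect_lt(s2$fisher_mean, 0.1)
  # unlabeled-only data warns and returns empty
  tab3 <- dplyr::mutate(tab, label = factor("unlabeled",
                                            levels = levels(tab$label)))
  expect_warning(s3 <- feature_class_summary(tab3, "SCL"), "no labeled")
  expect_equal(nrow(s3), 0)
})

test_that("correlation matrices have unit diagonals and null off-diagonals", {
  set.seed(51)
  tab <- tibble::tibble(a = rnorm(1000), b = rnorm(1000), c = rnorm(1000))
  m <- correlation_matrix(tab, c("a", "b", "c"))
  expect_equal(m$variable, c("a", "b", "c"))
  expect_equal(diag(as.matrix(m[, -1])), c(1, 1, 1), ignore_attr = TRUE)
  expect_lt(max(abs(m$b[1]), abs(m$c[1]), abs(m$c[2])), 0.1)
  tab$d <- tab$a^3 # monotone map of a
  m2 <- correlation_matrix(tab, "a", "d")
  expect_equal(m2$d, 1)
})
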