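# deterministic learnable table: the target is a noiseless monotone
# function of temperature and CO2
make_learnable_table <- function(n_subj = 4, n_per = 60, seed = 19,
                                 noise = 0) {
  set.seed(seed)
  tab <- tibble::tibble(
    subject = rep(sprintf("S%d", seq_len(n_subj)), each = n_per),
    Temperature = runif(n_subj * n_per, 20, 32),
    CO2 = runif(n_subj * n_per, 400, 1800),
    Humid = runif(n_subj * n_per, 40, 85),
    IR = runif(n_subj * n_per, 50, 300)
  )
  tab$SCL <- 2 + 0.15 * (tab$Temperature - 20) + 0.001 * tab$CO2 +
    rnorm(nrow(tab), 0, noise)
  tab
}

test_that("a deterministic signal is learned (R2 > 0.9), pure noise is not", {
  tab <- make_learnable_table()
  ev <- evaluate_model(tab, "SCL", c("Temperature", "CO2"),
                       model_spec("random_forest", seed = 3),
                       scheme = "split_70_30")
  expect_gt(ev$mean_r2, 0.9)
  expect_equal(ev$mean_r2, mean(ev$folds$r2))

  set.seed(77)
  r2s <- vapply(1:10, function(i) {
    tab$noise_target <- rnorm(nrow(tab))
    evaluate_model(tab, "noise_target", c("Temperature", "CO2"),
                   model_spec("random_forest", seed = i),
                   scheme = "split_70_30", n_repeats = 2)$mean_r2
  }, numeric(1))
  expect_lte(max(r2s), 0.1)
})

test_that("loso produces one fold per subject and never trains on it", {
  tab <- make_learnable_table(n_subj = 3)
  # plant a subject-unique marker: if training ever saw the held-out
  # subject, a linear model could exploit this leakage column perfectly
  tab$leak <- as.numeric(factor(tab$subject))
  ev <- evaluate_model(tab, "SCL", c("Temperature", "CO2"),
                       model_spec("linear"), scheme = "loso")
  expect_equal(sort(ev$folds$fold), sort(unique(tab$subject)))
  expect_equal(ev$folds$n_train + ev$folds$n_test,
               rep(nrow(tab), 3))
  expect_error(
    evaluate_model(dplyr::filter(tab, subject == "S1"), "SCL",
                   c("Temperature", "CO2"), scheme = "loso"),
    "2 subjects"
  )
})

test_that("evaluations are reproducible given the seed", {
  tab <- make_learnable_table(noise = 0.2)
  a <- evaluate_model(tab, "SCL", c("Temperature", "CO2"),
                      model_spec("random_forest", seed = 11), "split_70_30")
  b <- evaluate_model(tab, "SCL", c("Temperature", "CO2"),
                      model_spec("random_forest", seed = 11), "split_70_30")
  expect_identical(a$folds, b$folds)
})

test_that("tidy and glance expose folds and summary", {
  tab <- make_learnable_table()
  ev <- evaluate_model(tab, "SCL", c("Temperature", "CO2"),
                       model_spec("linear"), "split_70_30", n_repeats = 3)
  td <- tidy(ev)
  expect_equal(nrow(td), 3)
  expect_true(all(c("fold", "r2", "family", "scheme") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$mean_r2, mean(td$r2))
  expect_equal(gl$n_folds, 3)
})

test_that("model ranking orders families by mean R2 with alphabetical ties", {
  tab <- make_learnable_table(noise = 0.02)
  res <- lapply(c("random_forest", "linear", "support_vector"), function(f) {
    evaluate_model(tab, "SCL", c("Temperature", "CO2"),
                   model_spec(f, seed = 5), "split_70_30", n_repeats = 2)
  })
  rk <- rank_models(res)
  expect_equal(nrow(rk), 3)
  expect_true(all(diff(rk$mean_r2) <= 0))
  # linear truth -> the linear model should win on this fixture
  expect_equal(rk$family[1], "linear")
  # ties broken by name
  fake <- res
  fake[[1]]$mean_r2 <- 0.5
  fake[[2]]$mean_r2 <- 0.5
  fake[[3]]$mean_r2 <- 0.5
  rk2 <- rank_models(fake)
  expect_equal(rk2$family, sort(rk2$family))
})

test_that("Shapley attributions satisfy local accuracy and rank coefficients", {
  set.seed(13)
  n <- 150
  tab <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  tab$y <- 3 * tab$x1 + 1 * tab$x2 # x3 is null
  fit <- fit_model(model_spec("linear", seed = 2), tab, "y",
                   c("x1", "x2", "x3"))
  sh <- shapley_summary(fit, tab[1:60, ], n_perm = 32)
  # local accuracy: attributions + baseline == prediction, exactly
  total <- rowSums(as.matrix(sh$values)) + sh$baseline
  expect_equal(total, sh$prediction, tolerance = 1e-6)
  expect_equal(sh$summary$feature[1:2], c("x1", "x2"))
  expect_lt(sh$summary$mean_abs_attribution[sh$summary$feature == "x3"], 0.05)

  # the same identity holds for the nonparametric families
  fit_rf <- fit_model(model_spec("random_forest", seed = 2), tab, "y",
                      c("x1", "x2", "x3"))
  sh_rf <- shapley_summary(fit_rf, tab[1:40, ], n_perm = 16)
  expect_equal(rowSums(as.matrix(sh_rf$values)) + sh_rf$baseline,
               sh_rf$prediction, tolerance = 1e-6)
})

test_that("reverse models recover the feature that drives the environment", {
  set.seed(29)
  n <- 240
  tab <- tibble::tibble(
    subject = rep(c("a", "b"), each = n / 2),
    SCL = runif(n, 2, 4),
    NSSCR = runif(n, 2, 20),
    TVSymp = runif(n), MTVSymp = runif(n), EDASymp = runif(n),
    dphEDA = rnorm(n, 0, 0.01)
  )
  # temperature is a deterministic monotone function of SCL alone
  tab$Temperature <- 20 + 4 * (tab$SCL - 2)^1.5
  tab$CO2 <- runif(n, 400, 1800)
  tab$Humid <- runif(n, 40, 85)
  tab$IR <- runif(n, 50, 300)
  rev <- reverse_models(tab, model_spec("random_forest", seed = 7),
                        scheme = "split_70_30")
  expect_setequal(names(rev$evaluations), c("Temperature", "CO2", "Humid", "IR"))
  expect_gt(rev$evaluations$Temperature$mean_r2, 0.9)
  expect_equal(rev$attributions$Temperature$summary$feature[1], "SCL")
  # targets unrelated to the features are not learnable
  expect_lt(rev$evaluations$CO2$mean_r2, 0.1)
})

test_that("the comparison grid covers scheme x family x target", {
  tab <- make_learnable_table(noise = 0.1)
  tab$NSSCR <- 5 + 0.01 * tab$CO2 + rnorm(nrow(tab), 0, 0.5)
  g <- model_comparison_grid(
    tab, targets = c("SCL", "NSSCR"),
    features = c("Temperature", "CO2", "Humid", "IR"),
    families = c("random_forest", "linear"),
    schemes = c("loso", "split_70_30"), seed = 2, n_repeats = 2
  )
  expect_equal(nrow(g$grid), 4) # 2 schemes x 2 families
  expect_true(all(c("SCL", "NSSCR") %in% names(g$grid)))
  expect_length(g$results, 8)
})
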