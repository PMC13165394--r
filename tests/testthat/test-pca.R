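# helper: two columns with exact sample correlation r
two_col_with_cor <- function(r, n = 40, seed = 8) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  xc <- scale(x)[, 1]
  ec <- lm.fit(cbind(1, xc), e)$residuals
  ec <- ec / sd(ec)
  cbind(a = xc, b = r * xc + sqrt(1 - r^2) * ec)
}

test_that("two-feature correlation eigenvalues are 1 +/- r", {
  m <- two_col_with_cor(0.5)
  fit <- des_pca(m, n_retained = 2)
  expect_equal(fit$explained_variance_ratio, c(0.75, 0.25),
               tolerance = 1e-10)
  iso <- des_pca(two_col_with_cor(0), n_retained = 2)
  expect_equal(iso$explained_variance_ratio, c(0.5, 0.5),
               tolerance = 1e-10)
  dup <- cbind(a = m[, 1], b = 2 * m[, 1] + 3)
  rank1 <- des_pca(dup, n_retained = 1)
  expect_equal(rank1$explained_variance_ratio, c(1, 0), tolerance = 1e-10)
})

test_that("full-rank reconstruction reproduces the standardized matrix", {
  sim <- simulate_des_systems(latent_spec(80, seed = 14))
  m <- des_feature_matrix(sim$table)
  fit <- des_pca(sim$table)
  z <- sweep(sweep(m, 2, fit$center), 2, fit$scale, "/")
  full_scores <- z %*% fit$loadings
  expect_equal(full_scores %*% t(fit$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(fit$loadings), diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(fit$explained_variance_ratio), 1, tolerance = 1e-9)
})

test_that("explained variance is invariant to row order and feature scale", {
  sim <- simulate_des_systems(latent_spec(60, seed = 5))
  fit <- des_pca(sim$table)
  tab2 <- sim$table[sample(nrow(sim$table)), ]
  expect_equal(des_pca(tab2)$explained_variance_ratio,
               fit$explained_variance_ratio, tolerance = 1e-9)
  m <- des_feature_matrix(sim$table)
  m_scaled <- sweep(m, 2, seq(0.1, 2, length.out = 20), "*")
  expect_equal(des_pca(m_scaled)$explained_variance_ratio,
               fit$explained_variance_ratio, tolerance = 1e-9)
})

test_that("cumulative variance is monotone and complete", {
  sim <- simulate_des_systems(latent_spec(50, seed = 6))
  fit <- des_pca(sim$table)
  cv <- sapply(1:20, cumulative_variance, model = fit)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[20], 1)
  expect_equal(cumulative_variance(fit, 1),
               fit$explained_variance_ratio[1])
  expect_error(cumulative_variance(fit, 0), "k")
  expect_error(cumulative_variance(fit, 21), "k")
})

test_that("frozen projection is exact on training data and linear", {
  sim <- simulate_des_systems(latent_spec(70, seed = 9))
  fit <- des_pca(sim$table)
  expect_equal(predict(fit, sim$table), fit$scores, tolerance = 1e-12)
  mean_row <- matrix(fit$center, 1, dimnames = list(NULL, des_features()))
  expect_equal(drop(predict(fit, mean_row)), rep(0, 5),
               ignore_attr = TRUE)
  dev_row <- mean_row
  dev_row[1, "rel_mu"] <- fit$center["rel_mu"] + 1
  one <- predict(fit, dev_row)
  dev_row[1, "rel_mu"] <- fit$center["rel_mu"] + 2
  expect_equal(predict(fit, dev_row), 2 * one, tolerance = 1e-12)
})

test_that("constant columns are rejected by name", {
  sim <- simulate_des_systems(latent_spec(30, seed = 2))
  m <- des_feature_matrix(sim$table)
  m[, "mu_self"] <- 4.2
  expect_error(des_pca(m), "mu_self")
})

test_that("loading magnitudes classify into the documented bins", {
  expect_equal(as.character(classify_loading(c(0.38, 0.47, -0.30))),
               c("moderate", "strong", "negligible"))
  expect_equal(as.character(classify_loading(c(-0.45, 0.31, 0.3099))),
               c("strong", "moderate", "negligible"))
  expect_error(classify_loading(1.2), "<= 1")
})

test_that("loading persistence is 1 against itself and high across halves", {
  sim <- simulate_des_systems(latent_spec(1200, seed = 17))
  fit <- des_pca(sim$table)
  expect_equal(unname(loading_persistence(fit, fit)), rep(1, 5),
               tolerance = 1e-12)
  half <- seq_len(600)
  fit_a <- des_pca(sim$table[half, ])
  fit_b <- des_pca(sim$table[-half, ])
  expect_true(all(loading_persistence(fit_a, fit_b) >= 0.9))
})

test_that("serialized models project identically after reload", {
  sim <- simulate_des_systems(latent_spec(40, seed = 3))
  fit <- des_pca(sim$table)
  path <- withr::local_tempfile(fileext = ".json")
  write_des_pca(fit, path)
  back <- read_des_pca(path)
  expect_equal(predict(back, sim$table), fit$scores, tolerance = 1e-12)
  expect_equal(back$explained_variance_ratio,
               fit$explained_variance_ratio)
})

test_that("retention can follow a cumulative-variance target", {
  sim <- simulate_des_systems(latent_spec(200, seed = 12))
  fit <- des_pca(sim$table, cumvar_target = 0.9)
  expect_true(cumulative_variance(fit, fit$n_retained) >= 0.9)
  expect_true(fit$n_retained == 1 ||
                cumulative_variance(fit, fit$n_retained - 1) < 0.9)
})
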