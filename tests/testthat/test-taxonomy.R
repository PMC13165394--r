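test_that("regime naming follows centroid geometry and handles degeneracy", {
  # clear-cut 5-cluster geometry in 5 PC dimensions
  cen <- rbind(
    c( 4,  0,  0,  0, 0),   # top PC1 -> interaction driven
    c( 0, -4,  0,  0, 0),   # bottom PC2 -> destabilization driven
    c( 3,  3,  0,  0, 0),   # high PC1 & PC2 -> high barrier
    c(-2,  2,  0,  2, 0),   # low PC1, high PC2 -> weak interaction
    c(-4,  1,  4, -4, 0))   # lowest PC1, high PC3, low PC4 -> failure
  reg <- label_regimes(cen)
  expect_equal(unname(reg),
               c("interaction_driven", "destabilization_driven",
                 "high_barrier", "weak_interaction", "failure"))
  # all centroids identical -> everything intermediate
  expect_true(all(label_regimes(matrix(0, 4, 5)) == "intermediate"))
  expect_error(label_regimes(matrix(1:4, 4, 1)), "2 PC")
})

test_that("regime naming is invariant to cluster index permutation", {
  set.seed(15)
  cen <- matrix(rnorm(25, sd = 2), 5, 5)
  base <- label_regimes(cen)
  perm <- sample(5)
  permuted <- label_regimes(cen[perm, ])
  expect_equal(unname(permuted), unname(base[as.character(perm)]))
})

test_that("the fitted taxonomy classifies its own training rows identically", {
  sim <- simulate_des_systems(latent_spec(400, seed = 23))
  fit <- des_taxonomy(sim$table, k_range = 2:8)
  pred <- predict(fit, sim$table)
  expect_identical(pred$cluster, fit$clusters$labels)
  expect_identical(pred$regime,
                   unname(fit$regimes[as.character(fit$clusters$labels)]))
  # a row placed exactly at a centroid has distance zero
  cen_row <- des_feature_matrix(sim$table)[1, , drop = FALSE]
  cen_row[1, ] <- fit$pca$center +
    fit$pca$scale * drop(fit$pca$loadings[, 1:5] %*%
                           fit$clusters$centroids[2, ])
  p2 <- predict(fit, cen_row)
  expect_equal(p2$cluster, 2L)
  expect_equal(p2$distance_to_centroid, 0, tolerance = 1e-8)
})

test_that("held-out systems around a regime centroid are assigned to it", {
  spec <- latent_spec(900, seed = 41)
  sim <- simulate_des_systems(spec)
  fit <- des_taxonomy(sim$table, k_range = 2:8)
  # which fitted cluster corresponds to planted regime 5 (most extreme)?
  target <- as.integer(names(which.max(
    table(fit$clusters$labels[sim$true_labels == 5]))))
  # fresh draws from the same generator, restricted to that regime
  sim2 <- simulate_des_systems(latent_spec(900, seed = 42))
  rows <- sim2$table[sim2$true_labels == 5, ]
  pred <- predict(fit, rows)
  expect_gte(mean(pred$cluster == target), 0.95)
})

test_that("end-to-end holdout projection recovers the planted regimes", {
  sim <- simulate_des_systems(latent_spec(1000, seed = 61))
  train <- seq_len(700)
  # variance-guided retention: the planted between-regime geometry has
  # rank k - 1, so a fixed five-component cut would add a noise axis
  fit <- des_taxonomy(sim$table[train, ], cumvar_target = 0.9,
                      k_range = 2:8)
  pred <- predict(fit, sim$table[-train, ])
  ari <- mclust::adjustedRandIndex(pred$cluster, sim$true_labels[-train])
  expect_gte(ari, 0.9)
})

test_that("hydration occupancy tables normalize per condition", {
  reg <- c("failure", "interaction_driven", "interaction_driven",
           "weak_interaction", "failure", "interaction_driven")
  wet <- c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  occ <- hydration_occupancy(reg, wet)
  expect_equal(colSums(occ$fractions), c(dry = 1, wet = 1))
  expect_equal(sum(occ$counts), 6)
  expect_equal(occ$counts["failure", "wet"], 0)
  all_dry <- hydration_occupancy(reg, rep(FALSE, 6))
  expect_true(all(all_dry$counts[, "wet"] == 0))
  expect_error(hydration_occupancy(character(), logical()), "empty")
})

test_that("wet systems drawn from favorable regimes avoid the peripheral one", {
  sim <- simulate_des_systems(latent_spec(800, seed = 77))
  fit <- des_taxonomy(sim$table, k_range = 2:8)
  # the fitted cluster corresponding to the peripheral planted regime 5
  target <- as.integer(names(which.max(
    table(fit$clusters$labels[sim$true_labels == 5]))))
  # wet rows generated around the means of the other regimes only
  sim_wet <- simulate_des_systems(latent_spec(300, wet_fraction = 1,
                                              seed = 78))
  keep <- sim_wet$true_labels != 5
  pred <- predict(fit, sim_wet$table[keep, ])
  occ <- hydration_occupancy(pred$regime, rep(TRUE, sum(keep)))
  expect_equal(unname(colSums(occ$fractions)[["wet"]]), 1)
  expect_lte(mean(pred$cluster == target), 0.05)
})

test_that("taxonomy summary and print expose the fitted quantities", {
  sim <- simulate_des_systems(latent_spec(250, seed = 19))
  fit <- des_taxonomy(sim$table, k_range = 2:7)
  s <- summary(fit)
  expect_equal(s$k, fit$k)
  expect_equal(sum(s$sizes), 250)
  expect_output(print(fit), "Solvation-regime taxonomy")
  expect_output(print(s), "clustering: k =")
})
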