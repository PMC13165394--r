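test_that("mixture aggregation is the mole-fraction weighted sum", {
  one <- data.frame(mole_fraction = 1, E_tot = -10)
  expect_equal(aggregate_mixture_property(one, "E_tot"), -10)
  two <- data.frame(mole_fraction = c(0.5, 0.5), E_tot = c(-10, -20))
  expect_equal(aggregate_mixture_property(two, "E_tot"), -15)
  three <- data.frame(mole_fraction = c(0.2, 0.3, 0.5),
                      E_tot = c(-5, -10, -20))
  expect_equal(aggregate_mixture_property(three, "E_tot"), -14)
})

test_that("aggregation is order-invariant and homogeneous in the energies", {
  set.seed(10)
  for (rep in 1:20) {
    m <- sample(2:4, 1)
    x <- rexp(m); x <- x / sum(x)
    comps <- data.frame(mole_fraction = x, mu = rnorm(m))
    v <- aggregate_mixture_property(comps, "mu")
    perm <- sample(m)
    expect_equal(aggregate_mixture_property(comps[perm, ], "mu"), v)
    scaled <- comps; scaled$mu <- 3.7 * scaled$mu
    expect_equal(aggregate_mixture_property(scaled, "mu"), 3.7 * v)
  }
})

test_that("aggregation rejects empty input and bad fraction sums", {
  expect_error(aggregate_mixture_property(
    data.frame(mole_fraction = numeric(), E_tot = numeric()), "E_tot"),
    "non-empty")
  bad <- data.frame(mole_fraction = c(0.5, 0.3), E_tot = c(-1, -2))
  expect_error(aggregate_mixture_property(bad, "E_tot"), "deviation")
})

test_that("relative descriptors are exact differences and idempotent", {
  rec <- data.frame(mu_sat = -3.2, mu_water = -7.1, solv_mu = -5.0,
                    solute_Etot = -20, solute_Emisfit = -5,
                    solute_Ehbond = -12, solute_Evdw = -8,
                    solv_Etot = -15, solv_Emisfit = -4,
                    solv_Ehbond = -4.5, solv_Evdw = -6)
  out <- derive_relative_descriptors(rec)
  expect_equal(out$rel_mu, -3.2 - (-5.0))
  expect_equal(out$rel_mu_water, 3.9)
  expect_equal(out$rel_Ehbond, -7.5)
  rec2 <- rec; rec2$mu_sat <- -5.0; rec2$solv_mu <- -5.0
  expect_equal(derive_relative_descriptors(rec2)$rel_mu, 0)
  expect_identical(derive_relative_descriptors(out), out)
  expect_error(derive_relative_descriptors(rec[, -1]), "mu_sat")
})

test_that("fusion thermodynamics follow dS = dH/Tm and vanish at Tm", {
  expect_equal(fusion_gibbs(20, 400, 400)$dG_fus, 0)
  expect_equal(fusion_gibbs(20, 400, 300)$dG_fus, 5)
  z <- fusion_gibbs(0, 350, 298)
  expect_equal(z$dG_fus, 0)
  expect_equal(z$dS_fus, 0)
  expect_error(fusion_gibbs(20, -1, 300), "T_m")
  expect_error(fusion_gibbs(20, 400, 0), "'T'")
  # sign change exactly at Tm, monotone decreasing in T for dH > 0
  Ts <- seq(250, 500, by = 10)
  g <- sapply(Ts, function(Tt) fusion_gibbs(25, 380, Tt)$dG_fus)
  expect_true(all(g[Ts < 380] > 0), all(g[Ts > 380] < 0))
  expect_true(all(diff(g) < 0))
})

test_that("assemble_table builds a valid 20-feature table from components", {
  rec <- simulate_component_records(8, wet_fraction = 0.5, seed = 21)
  tab <- assemble_table(rec$components, rec$solute, rec$metadata)
  expect_s3_class(tab, "des_table")
  expect_equal(nrow(tab), 8)
  expect_true(all(des_features() %in% names(tab)))
  expect_length(check_rel_identities <- dessolv:::check_rel_identities(tab), 0)
  # solvent energies agree with direct weighted sums, API included
  id <- tab$system_id[1]
  cc <- rec$components[rec$components$system_id == id, ]
  expect_equal(tab$solv_Etot[1], sum(cc$mole_fraction * cc$E_tot))
  # wet flag mirrors the water component
  wet_ids <- unique(rec$components$system_id[rec$components$role == "water"])
  expect_setequal(tab$system_id[tab$is_wet], wet_ids)
})

test_that("assemble_table supports solute-free weighting", {
  rec <- simulate_component_records(4, seed = 5)
  tab <- assemble_table(rec$components, rec$solute, rec$metadata,
                        normalization = "solute_free")
  id <- tab$system_id[1]
  cc <- rec$components[rec$components$system_id == id &
                         rec$components$role != "API", ]
  w <- cc$mole_fraction / sum(cc$mole_fraction)
  expect_equal(tab$solv_mu[1], sum(w * cc$mu))
})

test_that("assemble_table rejects broken inputs with the offending system", {
  rec <- simulate_component_records(3, seed = 2)
  bad <- rec$components
  bad$mole_fraction[bad$system_id == "S00002"] <-
    bad$mole_fraction[bad$system_id == "S00002"] * 0.8
  expect_error(assemble_table(bad, rec$solute, rec$metadata), "S00002")
  dup_sol <- rbind(rec$solute, rec$solute[1, ])
  expect_error(assemble_table(rec$components, dup_sol), "duplicate")
})

test_that("descriptor tables round-trip through CSV", {
  sim <- simulate_des_systems(latent_spec(25, wet_fraction = 0.3, seed = 33))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(sim$table, path)
  back <- read_descriptor_table(path)
  expect_equal(des_feature_matrix(back), des_feature_matrix(sim$table),
               tolerance = 0)
  expect_equal(as.data.frame(back), as.data.frame(sim$table))
  expect_identical(attr(back, "feature_order"), des_features())
})

test_that("table validation catches missing values and duplicate ids", {
  sim <- simulate_des_systems(latent_spec(10, seed = 1))
  tab <- as.data.frame(sim$table)
  tab$logx_sle[3] <- NA
  expect_error(as_des_table(tab), "logx_sle")
  tab2 <- as.data.frame(sim$table)
  tab2$system_id[2] <- tab2$system_id[1]
  expect_error(as_des_table(tab2), "duplicate")
  tab3 <- as.data.frame(sim$table)
  tab3$rel_mu[5] <- tab3$rel_mu[5] + 1e-3
  expect_error(as_des_table(tab3), "rel_mu")
})
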