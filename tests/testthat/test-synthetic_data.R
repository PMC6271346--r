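# Synthetic generators: seston samples, isolate libraries, consumers.

test_that("noise-free samples sit on the mixing manifold and unmix exactly", {
  R0 <- table3_input()
  g <- gen_pond_samples(synthetic_scenario(R0, n_samples = 6, seed = 1,
                                           cv = 0))
  res <- chemtax_fit(g$samples, R0, unmix_config(bound_factor = 1))
  expect_lt(max(abs(res$abundances - g$truth$abundances)), 1e-6)
  # weight-percent convention
  expect_equal(unname(rowSums(unclass(g$samples))), rep(100, 6))
})

test_that("generation is deterministic under a fixed seed", {
  R0 <- table3_input()
  sc <- synthetic_scenario(R0, n_samples = 5, seed = 77, cv = 0.1)
  g1 <- gen_pond_samples(sc)
  g2 <- gen_pond_samples(sc)
  expect_identical(unclass(g1$samples), unclass(g2$samples))
  expect_identical(g1$truth$abundances, g2$truth$abundances)
})

test_that("presets pin the stated group masses by construction", {
  g <- gen_pond_samples(preset_scenario("heterotroph_dominated",
                                        n_samples = 6, seed = 2))
  het <- c("Ascomycetes", "Zygomycetes", "Basidiomycetes", "Actinobacteria",
           "Firmicutes", "Proteobacteria")
  expect_equal(unname(rowSums(g$truth$abundances[, het])), rep(0.90, 6))

  g <- gen_pond_samples(preset_scenario("green_algae_dominated",
                                        n_samples = 4, seed = 2))
  expect_equal(unname(g$truth$abundances[, "Green algae"]), rep(0.80, 4))

  g <- gen_pond_samples(preset_scenario("cyanobacteria_mixed",
                                        n_samples = 4, seed = 2))
  expect_equal(unname(g$truth$abundances[, "Cyanobacteria"]), rep(0.50, 4))
})

test_that("isolate libraries recover their generating means", {
  R0 <- table3_input()
  # cv = 0: every isolate is the taxon mean
  lib0 <- gen_isolate_library(R0, cv = 0, n_per_taxon = 2, seed = 5)
  expect_equal(lib0[[1]]$values, lib0[[2]]$values)
  R_rebuilt <- build_ratio_matrix(lib0, min_mean_pct = 0,
                                  drop_single_species = FALSE)
  expect_equal(unclass(R_rebuilt)[, colnames(R0)], unclass(R0),
               ignore_attr = TRUE, tolerance = 1e-10)

  # law of large numbers at cv = 0.2
  lib <- gen_isolate_library(R0, cv = 0.2, n_per_taxon = 200, seed = 5)
  R_hat <- build_ratio_matrix(lib, min_mean_pct = 0,
                              drop_single_species = FALSE)
  nz <- unclass(R0) > 0
  rel <- unclass(R_hat)[, colnames(R0)][nz] / unclass(R0)[nz]
  expect_lt(max(abs(rel - 1)), 0.05)
})

test_that("held-out isolates identify to their taxon of origin", {
  R0 <- table3_input()
  lib <- reference_library(gen_isolate_library(R0, cv = 0.2,
                                               n_per_taxon = 5, seed = 8))
  queries <- gen_isolate_library(R0, cv = 0.2, n_per_taxon = 5, seed = 9)
  hits <- vapply(queries, function(q)
    identify_isolate(q, lib, 1)$taxon == q$meta$taxon, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("consumers reproduce seston at neutral retention settings", {
  seston <- toy_profile(c("16:0" = 40, "18:0" = 15, "18:3ω3" = 15,
                          "a-15:0" = 10, "20:5ω3" = 10, "22:6ω3" = 10),
                        id = "seston")
  spec <- consumer_spec(retention = c(autotrophs = 1), de_novo_safa = 0,
                        phospholipid_pufa_boost = 1, cv = 0)
  cons <- gen_consumer_profiles(seston, spec, seed = 1)
  expect_named(cons, c("neutral", "acetone_mobile", "free_fa",
                       "phospholipid"))
  for (fr in names(cons)) {
    expect_equal(cons[[fr]]$values[names(seston$values)], seston$values,
                 tolerance = 1e-12)
    expect_equal(retention_ratio(cons[[fr]], seston), 1, tolerance = 1e-12)
  }
})

test_that("retention factors propagate to measurable enrichment", {
  seston <- toy_profile(c("16:0" = 45, "18:0" = 18, "18:3ω3" = 15,
                          "a-15:0" = 10, "20:5ω3" = 2, "22:6ω3" = 10),
                        id = "seston")
  spec <- consumer_spec(retention = c("20:5ω3" = 3), cv = 0)
  cons <- gen_consumer_profiles(seston, spec, seed = 1)
  rr <- retention_ratio(cons$neutral, seston, fa_set = "20:5ω3")
  # exact closed form: factor / renormalization constant
  Z <- 1 + 2 * 0.02
  expect_equal(rr, 3 / Z, tolerance = 1e-10)

  # suppressing bacterial markers empties the bacterial signal
  spec0 <- consumer_spec(retention = c(bacteria = 0), cv = 0)
  cons0 <- gen_consumer_profiles(seston, spec0, seed = 1)
  mp <- marker_proportions(cons0$neutral)
  expect_equal(unname(mp["bacteria"]), 0)

  # phospholipids conserve PUFA at least as hard as reserve lipids
  spec2 <- consumer_spec(retention = c("20:5ω3" = 2),
                         phospholipid_pufa_boost = 1.5, cv = 0)
  cons2 <- gen_consumer_profiles(seston, spec2, seed = 1)
  expect_gte(retention_ratio(cons2$phospholipid, seston, "20:5ω3"),
             retention_ratio(cons2$neutral, seston, "20:5ω3") - 1e-12)

  # de novo saturates dilute dietary FAs but add 16:0/18:0 mass
  spec3 <- consumer_spec(retention = c(autotrophs = 1), de_novo_safa = 0.2,
                         phospholipid_pufa_boost = 1, cv = 0)
  cons3 <- gen_consumer_profiles(seston, spec3, seed = 1)
  expect_gt(unname(cons3$neutral$values["16:0"]),
            unname(seston$values["16:0"]))
  expect_equal(retention_ratio(cons3$neutral, seston, "18:3ω3"), 0.8,
               tolerance = 1e-10)
})
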