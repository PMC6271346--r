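# Unmixing engine: per-sample solve, bounded ratio optimization, protocols.

test_that("a pure taxon signature is attributed entirely to that taxon", {
  R <- table3_input()
  Fmat <- unclass(R) / rowSums(unclass(R))
  for (tx in c("Diatoms", "Proteobacteria", "Ascomycetes")) {
    s <- setNames(Fmat[tx, ], colnames(R))
    a <- solve_abundances(R, s)
    expect_equal(unname(a$abundances[tx]), 1, tolerance = 1e-8)
    expect_lt(a$rmse, 1e-12)
  }
})

test_that("a 50:50 green algae / diatom mixture is resolved to 1e-6", {
  R <- table3_input()
  two <- unclass(R)[c("Green algae", "Diatoms"), ]
  Fmat <- two / rowSums(two)
  s <- setNames(0.5 * Fmat[1, ] + 0.5 * Fmat[2, ], colnames(two))
  a <- solve_abundances(two, s)
  expect_equal(unname(a$abundances), c(0.5, 0.5), tolerance = 1e-6)
  # and the exhaustive grid search agrees
  g <- grid_simplex_opt(Fmat, s, res = 1e-4)
  expect_equal(unname(a$abundances), unname(g), tolerance = 2e-4)
})

test_that("solver matches the exhaustive simplex grid on random instances", {
  set.seed(202)
  for (trial in 1:25) {
    k <- sample(2:3, 1)
    nf <- sample(4:8, 1)
    Fmat <- matrix(runif(k * nf, 0.05, 1), k, nf)
    Fmat <- Fmat / rowSums(Fmat)
    colnames(Fmat) <- paste0(14 + seq_len(nf), ":0")
    rownames(Fmat) <- paste0("t", seq_len(k))
    a_true <- as.vector(rdirichlet(1, rep(1, k)))
    s <- setNames(as.vector(t(Fmat) %*% a_true), colnames(Fmat))
    a <- solve_abundances(Fmat, s)
    g <- grid_simplex_opt(Fmat, s, res = 1e-4)
    expect_lt(max(abs(a$abundances - g)), 2.5e-4)
  }
})

test_that("solver rejects degenerate inputs", {
  R <- table3_input()
  expect_error(solve_abundances(R, c("16:0" = 1, "18:0" = 1)), "fewer than 3")
  s <- setNames(rep(0, ncol(R)), colnames(R))
  expect_error(solve_abundances(R, s), "all-zero")
})

test_that("noise-free data from the input matrix is a fixed point", {
  R0 <- table3_input()
  g <- gen_pond_samples(synthetic_scenario(R0, n_samples = 8, seed = 3,
                                           cv = 0))
  res <- chemtax_fit(g$samples, R0)
  expect_lt(res$rmse, 1e-10)
  expect_true(res$converged)
  expect_equal(unclass(res$ratio_out),
               unclass(R0)[, colnames(res$ratio_out)],
               ignore_attr = TRUE)
  expect_lt(max(abs(res$abundances - g$truth$abundances)), 1e-6)
})

test_that("result invariants hold on noisy data: simplex rows, bounds, zeros", {
  R0 <- table3_input()
  g <- gen_pond_samples(synthetic_scenario(R0, n_samples = 12, seed = 5,
                                           cv = 0.10))
  res <- chemtax_fit(g$samples, R0, unmix_config(max_iter = 120))
  expect_true(all(res$abundances >= 0))
  expect_equal(unname(rowSums(res$abundances)), rep(1, 12), tolerance = 1e-9)
  Rin <- unclass(R0)[, colnames(res$ratio_out)]
  Rout <- unclass(res$ratio_out)
  nz <- Rin > 0
  expect_true(all(Rout[!nz] == 0))            # structural zeros preserved
  expect_true(all(Rout[, "16:0"] == 1))       # reference frozen
  rel <- Rout[nz] / Rin[nz]
  expect_true(all(rel >= 0.5 - 1e-9 & rel <= 1.5 + 1e-9))
  # RMSE trajectory is non-increasing
  expect_true(all(diff(res$rmse_history) <= 1e-12))
})

test_that("bound adjustment moves a perturbed element toward the truth", {
  R0 <- table3_input()
  R_true <- unclass(R0)
  R_true["Diatoms", "20:5ω3"] <- R_true["Diatoms", "20:5ω3"] * 1.3
  R_true <- taxon_ratio_matrix(R_true)
  g <- gen_pond_samples(synthetic_scenario(R_true, n_samples = 20, seed = 4,
                                           cv = 0))
  res <- chemtax_fit(g$samples, R0)
  fitted <- unclass(res$ratio_out)["Diatoms", "20:5ω3"]
  true_v <- unclass(R_true)["Diatoms", "20:5ω3"]
  start_v <- unclass(R0)["Diatoms", "20:5ω3"]
  # more than half of the injected shift is recovered ...
  expect_lt(abs(fitted - true_v), 0.5 * abs(start_v - true_v))
  # ... and adjusting helps relative to a frozen-matrix fit
  frozen <- chemtax_fit(g$samples, R0, unmix_config(bound_factor = 1))
  expect_lt(mean(abs(res$abundances - g$truth$abundances)),
            mean(abs(frozen$abundances - g$truth$abundances)))
})

test_that("bound_factor = 1 degenerates to plain per-sample solving", {
  R0 <- table3_input()
  g <- gen_pond_samples(synthetic_scenario(R0, n_samples = 6, seed = 9,
                                           cv = 0.10))
  res <- chemtax_fit(g$samples, R0, unmix_config(bound_factor = 1))
  expect_equal(unclass(res$ratio_out),
               unclass(R0)[, colnames(res$ratio_out)], ignore_attr = TRUE)
  a1 <- solve_abundances(R0, unclass(g$samples)[1, ])
  expect_equal(res$abundances[1, ], a1$abundances, tolerance = 1e-12)
})

test_that("successive runs never degrade the fit and reduce to one run", {
  R0 <- table3_input()
  g0 <- gen_pond_samples(synthetic_scenario(R0, n_samples = 6, seed = 2,
                                            cv = 0))
  cfg1 <- unmix_config(n_successive_runs = 1)
  r1 <- successive_runs(g0$samples, R0, cfg1)
  f1 <- chemtax_fit(g0$samples, R0, cfg1)
  expect_equal(r1$abundances, f1$abundances)
  expect_equal(unclass(r1$ratio_out), unclass(f1$ratio_out))

  cfg <- unmix_config(n_successive_runs = 3, max_iter = 80)
  for (s in c(1, 2, 3)) {
    g <- gen_pond_samples(synthetic_scenario(R0, n_samples = 10, seed = s,
                                             cv = 0.10))
    r <- successive_runs(g$samples, R0, cfg)
    expect_lte(r$rmse, r$run_rmse[1] + 1e-12)
    first_fit <- chemtax_fit(g$samples, R0, cfg)
    expect_lte(r$rmse, first_fit$rmse + 1e-12)
  }
})

test_that("randomized starts are reproducible and order-consistent", {
  R0 <- table3_input()
  g <- gen_pond_samples(synthetic_scenario(R0, n_samples = 8, seed = 6,
                                           cv = 0.10))
  cfg <- unmix_config(n_random_starts = 8, best_fraction = 0.25,
                      max_iter = 60, seed = 42)
  r1 <- randomized_starts(g$samples, R0, cfg)
  r2 <- randomized_starts(g$samples, R0, cfg)
  expect_identical(r1$abundances, r2$abundances)
  expect_identical(unclass(r1$ratio_out), unclass(r2$ratio_out))
  # the averaged-best refit beats the median start
  expect_lte(r1$rmse, stats::median(r1$start_rmse) + 1e-12)
})

test_that("per-location runs restrict taxa and zero out the excluded ones", {
  R0 <- table3_input()
  taxa <- rownames(R0)
  het <- c("Ascomycetes", "Zygomycetes", "Basidiomycetes", "Actinobacteria",
           "Firmicutes", "Proteobacteria")
  aut <- setdiff(taxa, het)
  # location A: only heterotrophs present; location B: only autotrophs
  A_true <- matrix(0, 8, length(taxa), dimnames = list(NULL, taxa))
  set.seed(13)
  A_true[1:4, het] <- rdirichlet(4, rep(2, length(het)))
  A_true[5:8, aut] <- rdirichlet(4, rep(2, length(aut)))
  sc <- synthetic_scenario(R0, n_samples = 8, true_abundances = A_true,
                           cv = 0.05, seed = 13,
                           location = rep(c("A", "B"), each = 4))
  g <- gen_pond_samples(sc)
  cfg <- unmix_config(max_iter = 60)
  # restricted taxon sets lose their group-specific FAs; the engine warns
  out <- suppressWarnings(
    run_by_location(g$samples, R0, list(A = het, B = aut), cfg))
  expect_true(all(out$abundances[1:4, aut] == 0))
  expect_true(all(out$abundances[5:8, het] == 0))
  expect_equal(unname(rowSums(out$abundances)), rep(1, 8), tolerance = 1e-9)
  # restricting to the true taxon sets must not hurt recovery vs pooled
  pooled <- chemtax_fit(g$samples, R0, cfg)
  expect_lte(mean(abs(out$abundances - A_true)),
             mean(abs(pooled$abundances - A_true)) + 0.01)

  # a single location holding all taxa reproduces the plain fit
  g2 <- gen_pond_samples(synthetic_scenario(R0, n_samples = 4, seed = 3,
                                            cv = 0.05))
  out2 <- run_by_location(g2$samples, R0, list(all = taxa), cfg)
  expect_equal(out2$abundances, chemtax_fit(g2$samples, R0, cfg)$abundances)
  expect_error(run_by_location(g2$samples, R0, list(all = c("Diatoms", "Qux")),
                               cfg), "Qux")
})
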