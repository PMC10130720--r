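make_tiny_bundle <- function(naive = FALSE) {
  ph <- data.frame(
    plant_id = rep(c("a", "b"), each = 2),
    site = "S1",
    elevation_m = 100,
    flower_idx = rep(1:2, 2),
    y = c(1, 1.2, 2, 2.1)
  )
  v <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  G <- structure(list(values = v, individual_ids = c("a", "b")),
                 class = "relatedness_matrix")
  build_model_matrices(ph, model_spec("y", naive = naive), G)
}

test_that("design matrices have the expected dimensions and alignment", {
  b <- make_tiny_bundle()
  expect_equal(dim(b$Z1), c(4L, 2L))
  expect_equal(dim(b$Z3), c(4L, 2L))
  expect_equal(dim(b$Z2), c(4L, 1L))
  expect_equal(ncol(b$X), 2L)         # intercept + elevation
  bn <- make_tiny_bundle(naive = TRUE)
  expect_null(bn$Z2)
  expect_equal(colnames(bn$X), "intercept")
  expect_equal(b$q, 2L)
  expect_equal(b$N, 4L)
})

test_that("plants absent from the GRM are rejected by name", {
  b <- make_tiny_bundle()
  ph <- data.frame(plant_id = c("a", "a", "zz", "zz"), site = "S1",
                   elevation_m = 1, flower_idx = c(1, 2, 1, 2), y = 1:4)
  G <- structure(list(values = diag(2), individual_ids = c("a", "b")),
                 class = "relatedness_matrix")
  expect_error(build_model_matrices(ph, model_spec("y"), G), "zz")
})

test_that("heritability and evolvability are per-draw arithmetic", {
  draws <- cbind(V_a = c(1, 0, 2), V_s = c(1, 1, 0), V_i = c(1, 1, 1),
                 V_error = c(1, 1, 1))
  h2 <- heritability(draws)
  expect_equal(unname(h2$draws), c(0.25, 0, 0.5))
  e <- evolvability(draws, trait_mean = 2)
  expect_equal(unname(e$draws), c(25, 0, 50))   # percent of squared mean
  expect_equal(evolvability(cbind(V_a = 0.04, V_s = 0, V_i = 0, V_error = 1),
                            trait_mean = 2)$mean, 1)
  expect_error(evolvability(draws, trait_mean = 0), "positive trait mean")
})

test_that("zero additive variance concentrates the heritability posterior at zero", {
  tr0 <- list(t1 = list(mean = 10, V_a = 0, V_s = 1, V_i = 1, V_error = 1,
                        elevation_slope = 0))
  cfg <- sim_config(traits = tr0, n_loci = 400, plants_per_site = 20, seed = 61)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(g)))
  fit <- fit_univariate_animal_model(
    build_model_matrices(ph, model_spec("t1"), G),
    chain = chain_control(2500, 500, 2, seed = 1))
  h2 <- heritability(fit)
  expect_lt(h2$ci95[1], 0.05)
  expect_lt(h2$mean, 0.15)
})

test_that("posterior means agree with an independent REML fit on a strong-contrast instance", {
  cs <- clone_pair_study(seed = 11)
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(cs$genotypes)))
  b <- build_model_matrices(cs$phenotypes, model_spec("tr", naive = TRUE), G)
  rem <- reml_fit_animal(b)
  expect_equal(rem$convergence, 0)
  fit <- fit_univariate_animal_model(b, chain = chain_control(8000, 2000, 3, seed = 3))
  for (comp in c("V_a", "V_i", "V_error")) {
    expect_lt(abs(fit$point[comp] / rem[[comp]] - 1), 0.15)
  }
})

test_that("two chains at different seeds agree on the heritability posterior", {
  cs <- clone_pair_study(seed = 21)
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(cs$genotypes)))
  b <- build_model_matrices(cs$phenotypes, model_spec("tr", naive = TRUE), G)
  f1 <- fit_univariate_animal_model(b, chain = chain_control(6000, 1500, 3, seed = 101))
  f2 <- fit_univariate_animal_model(b, chain = chain_control(6000, 1500, 3, seed = 202))
  expect_lt(abs(heritability(f1)$mean - heritability(f2)$mean), 0.02)
})

test_that("shuffling input rows leaves the fitted posterior unchanged up to MC noise", {
  cs <- clone_pair_study(n_pairs = 30, n_loci = 600, seed = 31)
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(cs$genotypes)))
  ph <- cs$phenotypes
  set.seed(1)
  ph2 <- ph[sample(nrow(ph)), ]
  f1 <- fit_univariate_animal_model(
    build_model_matrices(ph, model_spec("tr", naive = TRUE), G),
    chain = chain_control(4000, 1000, 3, seed = 5))
  f2 <- fit_univariate_animal_model(
    build_model_matrices(ph2, model_spec("tr", naive = TRUE), G),
    chain = chain_control(4000, 1000, 3, seed = 5))
  expect_lt(abs(heritability(f1)$mean - heritability(f2)$mean), 0.03)
})

test_that("variance draws respect positivity and ratio ranges", {
  cs <- clone_pair_study(n_pairs = 25, n_loci = 500, seed = 41)
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(cs$genotypes)))
  fit <- fit_univariate_animal_model(
    build_model_matrices(cs$phenotypes, model_spec("tr", naive = TRUE), G),
    chain = chain_control(1500, 500, 2, seed = 1))
  expect_true(all(fit$draws[, c("V_a", "V_i", "V_error")] > 0))
  h2 <- heritability(fit)
  expect_true(all(h2$draws >= 0 & h2$draws <= 1))
})

test_that("bivariate model recovers a strong genetic correlation and bounds r_G", {
  # two traits with correlated breeding values on a strong-contrast sample
  set.seed(51)
  n_pairs <- 60; L <- 1200
  p <- runif(L, 0.1, 0.5)
  founders <- vapply(p, function(pp) rbinom(n_pairs, 2, pp), integer(n_pairs))
  dos <- founders[rep(seq_len(n_pairs), each = 2), ]
  rownames(dos) <- sprintf("P%03d", seq_len(2 * n_pairs))
  g <- genotype_matrix(dos, sites = rep(c("S1", "S2"), each = n_pairs))
  cfg <- sim_config(n_sites = 2, plants_per_site = n_pairs, n_loci = L,
                    elevation_per_site = c(200, 600), r_G = 0.8,
                    env_corr = 0,
                    traits = list(
                      t1 = list(mean = 10, V_a = 4, V_s = 0, V_i = 1,
                                V_error = 1, elevation_slope = 0),
                      t2 = list(mean = 10, V_a = 4, V_s = 0, V_i = 1,
                                V_error = 1, elevation_slope = 0)),
                    seed = 51)
  ph <- simulate_phenotypes(g, cfg)
  truth <- attr(ph, "truth")
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(g)))
  fit <- fit_bivariate_animal_model(
    build_model_matrices(ph, model_spec(c("t1", "t2"), naive = TRUE), G),
    chain = chain_control(3000, 1000, 2, seed = 2))
  expect_true(all(abs(fit$draws[, "r_G"]) <= 1))
  expect_lt(abs(fit$point["r_G"] - truth$r_G_realized), 0.15)

  # null additive covariance: credible interval straddles zero
  cfg0 <- cfg; cfg0$r_G <- 0; cfg0$seed <- 52
  ph0 <- simulate_phenotypes(g, cfg0)
  fit0 <- fit_bivariate_animal_model(
    build_model_matrices(ph0, model_spec(c("t1", "t2"), naive = TRUE), G),
    chain = chain_control(3000, 1000, 2, seed = 2))
  expect_lt(fit0$ci95["r_G", 1], 0)
  expect_gt(fit0$ci95["r_G", 2], 0)
})

test_that("identical specs give equal DIC up to Monte Carlo error", {
  cs <- clone_pair_study(n_pairs = 25, n_loci = 500, seed = 71)
  G <- stabilize_for_inversion(vanraden_grm(impute_missing(cs$genotypes)))
  b <- build_model_matrices(cs$phenotypes, model_spec("tr", naive = TRUE), G)
  f1 <- fit_univariate_animal_model(b, chain = chain_control(4000, 1000, 3, seed = 7))
  f2 <- fit_univariate_animal_model(b, chain = chain_control(4000, 1000, 3, seed = 8))
  expect_lt(abs(f1$dic - f2$dic), 5)
})
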