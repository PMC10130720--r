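test_that("identical configs give byte-identical studies and no RNG leakage", {
  cfg <- sim_config(n_loci = 300, plants_per_site = 10, seed = 99)
  s1 <- simulate_study(cfg)
  set.seed(777)                      # ambient RNG state must not matter
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$fitness, s2$fitness)
  expect_identical(s1$census, s2$census)
  # generator restores the caller's RNG stream
  set.seed(123); a <- rnorm(1)
  set.seed(123); invisible(simulate_study(cfg)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_loci = 50), "n_loci")
  expect_error(sim_config(flowers_per_plant = 1), "flowers_per_plant")
  expect_error(sim_config(fitness = list(max_prob = 1.5)), "max_prob")
  expect_error(sim_config(fitness = list(omega_sd = -1)), "omega")
  tr <- list(t1 = list(mean = 10, V_a = -1, V_s = 0, V_i = 1, V_error = 1,
                       elevation_slope = 0))
  expect_error(sim_config(traits = tr), "non-negative")
})

test_that("unrelated-sample limit: GRM off-diagonals centred at zero", {
  cfg <- sim_config(sibship_mean = 1, migration = 1, n_loci = 1500,
                    plants_per_site = 30, seed = 21)
  g <- simulate_genotypes(cfg)
  G <- vanraden_grm(impute_missing(g))
  off <- G$values[upper.tri(G$values)]
  expect_lt(abs(mean(off)), 0.02)
  expect_lt(sd(off), 0.1)
  expect_lt(abs(mean(diag(G$values)) - 1), 0.05)
})

test_that("full-sib pairs average VanRaden relatedness near the pedigree 0.5", {
  # big families => many sib pairs; pedigree expectation for full sibs 0.5
  cfg <- sim_config(sibship_mean = 5, migration = 0, n_loci = 1500,
                    plants_per_site = 40, n_sites = 3,
                    elevation_per_site = c(100, 400, 700), seed = 31)
  g <- simulate_genotypes(cfg)
  fam <- attr(g, "family")
  G <- vanraden_grm(impute_missing(g))
  same_fam <- outer(fam, fam, "==") & upper.tri(G$values)
  expect_gte(sum(same_fam), 200)
  expect_lt(abs(mean(G$values[same_fam]) - 0.5), 0.05)
})

test_that("sibship structure creates variance in pairwise relatedness", {
  g <- simulate_genotypes(sim_config(n_loci = 500, plants_per_site = 15, seed = 5))
  G <- vanraden_grm(impute_missing(g))
  expect_gt(var(G$values[upper.tri(G$values)]), 0)
})

test_that("phenotypes decompose as configured", {
  # all plant-level variance off: replicate scatter is pure residual
  tr0 <- list(t1 = list(mean = 30, V_a = 0, V_s = 0, V_i = 0, V_error = 4,
                        elevation_slope = 0))
  cfg <- sim_config(traits = tr0, plants_per_site = 20, n_loci = 300, seed = 8)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  within_var <- mean(tapply(ph$t1, ph$plant_id, var))
  expect_lt(abs(within_var - 4) / 4, 0.15)
  plant_means <- tapply(ph$t1, ph$plant_id, mean)
  expect_lt(var(plant_means), 4)   # only V_error / m remains among plants

  # realized h2 bookkeeping matches the target at the default design
  cfg2 <- sim_config(seed = 12)
  truth <- attr(simulate_phenotypes(simulate_genotypes(cfg2), cfg2), "truth")
  expect_lt(abs(truth$realized$flower_weight_mg$h2 - 0.14), 0.03)
  expect_lt(truth$realized$standard_area_mm2$h2, 0.01)
})

test_that("mean realized heritability is calibrated across replicate studies", {
  h2 <- vapply(1:8, function(s) {
    cfg <- sim_config(n_loci = 400, seed = s)
    attr(simulate_phenotypes(simulate_genotypes(cfg), cfg),
         "truth")$realized$flower_weight_mg$h2
  }, 0)
  expect_lt(abs(mean(h2) - 0.14), 0.02)
})

test_that("solved environmental correlation yields the target plant-mean correlation", {
  r <- vapply(1:6, function(s) {
    st <- simulate_study(sim_config(n_loci = 400, seed = 400 + s))
    pm <- aggregate(st$phenotypes[c("flower_weight_mg", "standard_area_mm2")],
                    by = list(st$phenotypes$plant_id), mean)
    cor(pm[[2]], pm[[3]])
  }, 0)
  expect_lt(abs(mean(r) - 0.43), 0.10)
})

test_that("flat fitness surface (omega -> infinity) carries no selection signal", {
  cfg <- sim_config(n_loci = 300, plants_per_site = 40,
                    fitness = list(omega_sd = 1e6), seed = 17)
  st <- simulate_study(cfg)
  truth <- st$truth$fitness
  expect_lt(abs(truth$gamma_true), 1e-6)
  expect_lt(abs(cor(st$fitness$fruits / st$fitness$flower_scars,
                    tapply(st$phenotypes$standard_area_mm2,
                           st$phenotypes$plant_id, mean)[st$fitness$plant_id])),
            0.2)
})

test_that("Gaussian surface truth: analytic gamma negative with optimum at the mean", {
  grad <- wildqg:::gaussian_surface_gradients(theta_s = 0, omega_s = 3.26)
  expect_lt(grad$gamma, 0)
  expect_lt(abs(grad$beta), 1e-8)
  # closed form -1/(1+omega^2) for the mean-centred optimum
  expect_equal(grad$gamma, -1 / (1 + 3.26^2), tolerance = 1e-6)
  # default width is solved so the standardized quadratic gradient is -0.086
  st <- simulate_study(sim_config(n_loci = 300, plants_per_site = 10, seed = 2))
  expect_equal(st$truth$fitness$gamma_true, -0.086, tolerance = 2e-3)
})

test_that("study round-trips through plain-text files", {
  st <- simulate_study(sim_config(n_loci = 150, plants_per_site = 5,
                                  missing_rate = 0.05, seed = 3))
  dir <- withr::local_tempdir()
  write_study(st, dir, vcf = TRUE)
  expect_true(all(file.exists(file.path(dir, c("genotypes.tsv", "phenotypes.csv",
                                               "fitness.csv", "census.csv",
                                               "truth.json", "genotypes.vcf")))))
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(unname(g2$dosages), unname(st$genotypes$dosages))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$realized$flower_weight_mg$h2_target, 0.14, tolerance = 1e-8)
})
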