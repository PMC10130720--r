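balanced_nested_data <- function(n_sites, plants_per_site, m, v_site, v_plant,
                                 v_within, seed, mean = 50) {
  set.seed(seed)
  site <- rep(seq_len(n_sites), each = plants_per_site * m)
  plant <- rep(seq_len(n_sites * plants_per_site), each = m)
  s_eff <- rnorm(n_sites, 0, sqrt(v_site))
  # exact realized variances so the estimator is tested against a known truth
  if (v_site > 0) s_eff <- (s_eff - mean(s_eff)) / sd(s_eff) * sqrt(v_site)
  p_eff <- rnorm(n_sites * plants_per_site, 0, 1)
  p_eff <- (p_eff - mean(p_eff)) / sd(p_eff) * sqrt(v_plant)
  data.frame(plant_id = sprintf("p%03d", plant),
             site = sprintf("S%d", site),
             y = mean + s_eff[site] + p_eff[plant] +
               rnorm(length(plant), 0, sqrt(v_within)))
}

test_that("variance partition sums to 100 and matches known generating proportions", {
  # proportions mirroring a strongly site-structured floral trait: 53/33/14
  d <- balanced_nested_data(30, 15, 5, v_site = 5.3, v_plant = 3.3,
                            v_within = 1.4, seed = 1)
  p <- partition_trait_variance(d, "y")
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)
  expect_lt(max(abs(p$percent - c(53, 33, 14))), 5)
  expect_equal(repeatability(d, "y"), 100 - unname(p$percent["within"]),
               tolerance = 1e-9)
})

test_that("degenerate partitions behave: pure noise, zero residual, permuted sites", {
  d0 <- balanced_nested_data(6, 10, 4, v_site = 0, v_plant = 0, v_within = 2,
                             seed = 2)
  p0 <- partition_trait_variance(d0, "y")
  expect_gt(p0$percent["within"], 90)
  expect_lt(repeatability(d0, "y"), 10)

  d1 <- balanced_nested_data(6, 10, 4, v_site = 2, v_plant = 2, v_within = 0,
                             seed = 3)
  d1$y <- round(d1$y, 12)
  expect_gt(repeatability(d1, "y"), 99.9)

  d2 <- balanced_nested_data(10, 12, 4, v_site = 4, v_plant = 1, v_within = 1,
                             seed = 4)
  site_of_plant <- unique(d2[c("plant_id", "site")])
  set.seed(5)
  site_of_plant$site <- sample(site_of_plant$site)
  d2$site <- site_of_plant$site[match(d2$plant_id, site_of_plant$plant_id)]
  p2 <- partition_trait_variance(d2, "y")
  expect_lt(p2$percent["site"], 10)   # permuting site labels kills the site share
})

test_that("default synthetic study lands near the study-system descriptive values", {
  parts <- matrix(0, 4, 3)
  Rw <- cvw <- numeric(4)
  for (s in 1:4) {
    st <- simulate_study(sim_config(n_loci = 300, seed = 500 + s))
    parts[s, ] <- partition_trait_variance(st$phenotypes, "flower_weight_mg")$percent
    Rw[s] <- repeatability(st$phenotypes, "flower_weight_mg")
    pm <- tapply(st$phenotypes$flower_weight_mg, st$phenotypes$plant_id, mean)
    cvw[s] <- coefficient_of_variation(pm)
  }
  expect_lt(max(abs(colMeans(parts) - c(53, 33, 14))), 6)
  expect_true(all(Rw > 75 & Rw < 95))
  expect_lt(abs(mean(cvw) - 21), 5)
})

test_that("coefficient of variation uses the sample SD of plant means", {
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_error(coefficient_of_variation(c(-2, 0)), "positive")
})

test_that("phenotypic correlation returns Pearson r with a t-test p-value", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(phenotypic_correlation(x, x * 2)$r, 1)
  set.seed(6)
  a <- rnorm(200); b <- rnorm(200)
  b <- residuals(lm(b ~ a))   # orthogonalized
  pc <- phenotypic_correlation(a, b)
  expect_lt(abs(pc$r), 1e-12)
  expect_identical(pc$p, cor.test(a, b)$p.value)
  expect_error(phenotypic_correlation(x, rep(1, 5)), "zero variance")

  rs <- vapply(1:5, function(s) {
    st <- simulate_study(sim_config(n_loci = 300, seed = 600 + s))
    pm <- aggregate(st$phenotypes[c("flower_weight_mg", "standard_area_mm2")],
                    by = list(st$phenotypes$plant_id), mean)
    phenotypic_correlation(pm[[2]], pm[[3]])$r
  }, 0)
  expect_lt(abs(mean(rs) - 0.43), 0.10)
})

test_that("visitation summaries reproduce the census arithmetic", {
  # single census: 1 visit over 100 flowers
  cen <- data.frame(site = "S1", census_id = 1, duration_min = 3,
                    flowers_surveyed = 100, taxon = "bee", visits = 1)
  v <- visitation_summary(cen)
  expect_equal(v$rate_per_flower_per_census, 0.01)

  # synthetic censuses: waiting time decreases with rate; shares sum near 100
  st <- simulate_study(sim_config(n_loci = 150, plants_per_site = 5, seed = 9))
  vs <- visitation_summary(st$census)
  expect_gte(vs$rate_per_flower_per_census, 0)
  expect_true(vs$waiting_time_h > 0)
  cen2 <- st$census
  cen2$visits <- cen2$visits * 2
  expect_lt(visitation_summary(cen2)$waiting_time_h, vs$waiting_time_h)
})

test_that("waiting-time helper matches the printed-rate arithmetic", {
  expect_equal(waiting_time_hours(0.015, 3), 3.3)
  expect_equal(waiting_time_hours(0.03, 3), 1.7)
  expect_identical(waiting_time_hours(0), Inf)
})
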