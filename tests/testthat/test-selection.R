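test_that("fruit set is fruits over scars, excluding zero-scar plants", {
  rec <- data.frame(plant_id = c("a", "b", "c"), fruits = c(3, 0, 0),
                    flower_scars = c(10, 7, 0))
  fs <- fruit_set(rec)
  expect_equal(fs$fruit_set, c(0.3, 0))
  expect_equal(attr(fs, "n_excluded"), 1L)
  expect_equal(mean(fs$fruit_set), mean(c(3 / 10, 0 / 7)))
  expect_error(fruit_set(data.frame(plant_id = "a", fruits = 5,
                                    flower_scars = 3)), "exceed")
})

test_that("flat fitness surfaces give near-zero coefficients and unit mean relative fitness", {
  d <- flat_fitness_data(n = 120, seed = 2)
  sf <- fit_fitness_surface(merge(
    aggregate(trait ~ plant_id, d$phenotypes, mean), d$fitness, by = "plant_id"),
    "trait", covariates = character(0))
  cc <- selection_coefficients(sf)
  expect_lt(abs(cc["s"]), 0.05)
  expect_lt(abs(cc["c"]), 0.05)
  der <- attr(cc, "detail")
  expect_equal(der$w_mean, 1, tolerance = 1e-8)
  # effective df of the trait smooth shrinks toward nothing
  edf <- sum(sf$fit$edf[-1])
  expect_lt(edf, 1.5)
})

test_that("monotone and stabilizing surfaces are recovered qualitatively", {
  set.seed(3)
  n <- 200
  z <- rnorm(n)
  tab <- data.frame(plant_id = seq_len(n), trait = z, flower_scars = 30L)
  # logistic-linear fitness: monotone fitted surface
  tab$fruits <- rbinom(n, 30, plogis(-0.5 + 0.8 * z))
  sf <- fit_fitness_surface(tab, "trait", covariates = character(0))
  zs <- seq(-2, 2, length.out = 21)
  pred <- predict(sf$fit, newdata = data.frame(.z_trait = zs), type = "response")
  expect_true(all(diff(pred) > 0))
  cc <- selection_coefficients(sf)
  expect_gt(cc["s"], 0.1)

  # Gaussian stabilizing fitness with the optimum at the mean: interior max
  tab$fruits <- rbinom(n, 30, 0.6 * exp(-z^2 / (2 * 1.5^2)))
  sf2 <- fit_fitness_surface(tab, "trait", covariates = character(0))
  pred2 <- predict(sf2$fit, newdata = data.frame(.z_trait = zs), type = "response")
  expect_gt(which.max(pred2), 5)
  expect_lt(which.max(pred2), 17)
  expect_lt(selection_coefficients(sf2)["c"], 0)
})

test_that("identity-link unpenalized limit reproduces Lande-Arnold OLS coefficients", {
  set.seed(4)
  n <- 300
  z1 <- rnorm(n); z2 <- rnorm(n)
  w <- 2 + 0.3 * z1 - 0.15 * z1^2 + 0.1 * z2 + 0.08 * z1 * z2 +
    rnorm(n, 0, 0.2)
  fitlm <- lm(w ~ z1 + I(z1^2) + z2 + I(z2^2) + I(z1 * z2))
  pf <- function(zz) {
    as.numeric(predict(fitlm, newdata = data.frame(z1 = zz[, 1], z2 = zz[, 2])))
  }
  der <- average_derivatives(pf, cbind(z1, z2), step = 1e-3)
  b <- coef(fitlm)
  wbar <- mean(fitted(fitlm))
  beta_la <- c(mean(b["z1"] + 2 * b["I(z1^2)"] * z1 + b["I(z1 * z2)"] * z2),
               mean(b["z2"] + 2 * b["I(z2^2)"] * z2 + b["I(z1 * z2)"] * z1)) / wbar
  gamma_la <- matrix(c(2 * b["I(z1^2)"], b["I(z1 * z2)"],
                       b["I(z1 * z2)"], 2 * b["I(z2^2)"]), 2, 2) / wbar
  expect_lt(max(abs(der$beta - beta_la)), 1e-6)
  expect_lt(max(abs(der$gamma - gamma_la)), 1e-6)
  expect_equal(der$gamma, t(der$gamma))
})

test_that("stabilizing-selection simulations recover the standardized quadratic gradient", {
  st <- simulate_study(sim_config(plants_per_site = 334, seed = 5))
  sel <- estimate_selection(st$phenotypes, st$fitness,
                            c("standard_area_mm2", "flower_weight_mg"))
  g_hat <- sel$coefficients["gamma_standard_area_mm2"]
  g_true <- st$truth$fitness$gamma_true
  expect_lt(g_hat, 0)
  expect_lt(abs(g_hat - g_true) / abs(g_true), 0.25)
  # no direct selection on the other trait
  expect_lt(abs(sel$coefficients["beta_flower_weight_mg"]), 0.05)
})

test_that("bootstrap is deterministic given a seed and rejects degenerate traits", {
  d <- flat_fitness_data(n = 60, seed = 6)
  b1 <- bootstrap_selection(d$phenotypes, d$fitness, "trait",
                            covariates = character(0), n_boot = 100, seed = 9)
  b2 <- bootstrap_selection(d$phenotypes, d$fitness, "trait",
                            covariates = character(0), n_boot = 100, seed = 9)
  expect_identical(b1$se, b2$se)
  expect_identical(b1$p, b2$p)
  expect_true(all(c("s_trait", "c_trait") %in% b1$term))
  expect_error(bootstrap_selection(d$phenotypes, d$fitness, "trait",
                                   n_boot = 50, seed = 1), "n_boot")
  d$phenotypes$trait <- 1
  expect_error(bootstrap_selection(d$phenotypes, d$fitness, "trait",
                                   covariates = character(0),
                                   n_boot = 100, seed = 1),
               "constant|zero variance")
})
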