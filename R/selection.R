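#' Per-plant fruit set
#'
#' Fruit set — the proportion of flowers that developed into a fruit — is
#' the female-fitness proxy: `fruits / flower_scars`. Plants with zero
#' flower scars carry no information and are excluded (with a count).
#'
#' @param records `data.frame` with `plant_id`, `fruits`, `flower_scars`.
#' @return `data.frame` with `plant_id`, `fruits`, `flower_scars`,
#'   `fruit_set`; excluded-plant count in the `"n_excluded"` attribute.
#' @export
fruit_set <- function(records) {
  stopifnot(all(c("plant_id", "fruits", "flower_scars") %in% names(records)))
  if (any(records$fruits > records$flower_scars, na.rm = TRUE)) {
    stopf("fruits cannot exceed flower scars")
  }
  drop <- records$flower_scars < 1 | is.na(records$flower_scars)
  if (any(drop)) vlog(sprintf("excluding %d plant(s) with zero flower scars", sum(drop)))
  out <- records[!drop, , drop = FALSE]
  out$fruit_set <- out$fruits / out$flower_scars
  attr(out, "n_excluded") <- sum(drop)
  out
}

# assemble the plant-level selection table: plant-mean traits + fitness
# counts + site/elevation covariates
plant_selection_table <- function(phenotypes, fitness, traits) {
  pm <- aggregate(phenotypes[traits], by = list(plant_id = phenotypes$plant_id), mean)
  cov <- unique(phenotypes[c("plant_id", "site", "elevation_m")])
  tab <- merge(merge(pm, cov, by = "plant_id"), fitness, by = "plant_id")
  fruit_set(tab)
}

smooth_k <- function(x, k_max = 10) {
  max(3, min(k_max, length(unique(x)) - 1))
}

#' Fit a spline-based binomial fitness surface
#'
#' Penalized-spline additive model for absolute fitness (fruits out of
#' flower scars, binomial with logit link) over one or two
#' variance-standardized plant-mean traits, with site as a ridge-penalized
#' (random-effect) factor term and elevation as a penalized spline;
#' smoothing parameters are chosen by REML.
#'
#' @param records plant-level table with trait means, `fruits`,
#'   `flower_scars` and (when used) `site`, `elevation_m`.
#' @param traits one or two trait column names.
#' @param covariates any of `c("site", "elevation")`; use `character(0)`
#'   for a covariate-free surface.
#' @param k basis dimension for the trait smooths.
#' @return object of class `fitness_surface`: the mgcv fit plus the
#'   standardization (per-trait mean and SD) and the plant table.
#' @export
fit_fitness_surface <- function(records, traits,
                                covariates = c("site", "elevation"),
                                k = 6) {
  if (nrow(records) < 30) stopf("need at least 30 plants to fit a fitness surface")
  records <- fruit_set(records)
  center <- vapply(records[traits], mean, 0)
  scale <- vapply(records[traits], sd, 0)
  if (any(scale == 0)) stopf("trait(s) with zero variance: %s",
                             paste(traits[scale == 0], collapse = ", "))
  dat <- records
  for (tr in traits) dat[[paste0(".z_", tr)]] <- (dat[[tr]] - center[tr]) / scale[tr]

  terms <- sprintf("s(.z_%s, k = %d)", traits, smooth_k(dat[[traits[1]]], k))
  if ("site" %in% covariates) {
    dat$site <- factor(dat$site)
    if (nlevels(dat$site) > 1) terms <- c(terms, "s(site, bs = 're')")
  }
  if ("elevation" %in% covariates) {
    ke <- length(unique(dat$elevation_m))
    if (ke >= 4) {
      terms <- c(terms, sprintf("s(elevation_m, k = %d)", min(4, ke - 1)))
    } else if (ke >= 2) {
      terms <- c(terms, "elevation_m")
    }
  }
  form <- as.formula(paste("cbind(fruits, flower_scars - fruits) ~",
                           paste(terms, collapse = " + ")))
  # extended Fellner-Schall REML iteration: same smoothing criterion as
  # the default Newton path, noticeably faster on repeated small fits
  fit <- mgcv::gam(form, family = stats::binomial(link = "logit"),
                   data = dat, method = "REML", optimizer = "efs")
  if (!fit$converged) stopf("fitness-surface fit did not converge")
  structure(list(fit = fit, traits = traits, center = center, scale = scale,
                 covariates = covariates, data = dat),
            class = "fitness_surface")
}

#' Averaged derivatives of relative fitness over observed phenotypes
#'
#' Generic engine behind the selection estimators: given a predictor of
#' expected absolute fitness over standardized trait values, relative
#' fitness is `w(z) = W(z) / Wbar` with `Wbar` the mean prediction over the
#' observed plants, and the coefficients are the first and second partial
#' derivatives of `w`, approximated by central finite differences of step
#' `step` (in SD units) and averaged over the observed phenotype
#' distribution.
#'
#' @param predict_fun function taking an n x d matrix of standardized trait
#'   values (rows = the observed plants, in order) and returning expected
#'   absolute fitness per plant; other covariates must be closed over at
#'   each plant's own values.
#' @param z n x d matrix of observed standardized trait values.
#' @param step finite-difference step (default 1e-3 SD).
#' @return list with `beta` (length-d averaged first derivatives), `gamma`
#'   (d x d symmetric averaged second derivatives, no halving), `W_bar`,
#'   and `w_mean` (mean relative fitness, 1 by construction).
#' @export
average_derivatives <- function(predict_fun, z, step = 1e-3) {
  z <- as.matrix(z)
  d <- ncol(z)
  if (step < 1e-8) stopf("finite-difference step underflow")
  W0 <- predict_fun(z)
  W_bar <- mean(W0)
  if (!is.finite(W_bar) || W_bar <= 0) stopf("degenerate fitness predictions")
  beta <- numeric(d)
  gamma <- matrix(0, d, d)
  Wp <- Wm <- vector("list", d)
  for (j in seq_len(d)) {
    zp <- z; zp[, j] <- zp[, j] + step
    zm <- z; zm[, j] <- zm[, j] - step
    Wp[[j]] <- predict_fun(zp)
    Wm[[j]] <- predict_fun(zm)
    beta[j] <- mean((Wp[[j]] - Wm[[j]]) / (2 * step)) / W_bar
    gamma[j, j] <- mean((Wp[[j]] - 2 * W0 + Wm[[j]]) / step^2) / W_bar
  }
  if (d > 1) {
    for (j in 1:(d - 1)) for (l in (j + 1):d) {
      zpp <- z; zpp[, j] <- zpp[, j] + step; zpp[, l] <- zpp[, l] + step
      zpm <- z; zpm[, j] <- zpm[, j] + step; zpm[, l] <- zpm[, l] - step
      zmp <- z; zmp[, j] <- zmp[, j] - step; zmp[, l] <- zmp[, l] + step
      zmm <- z; zmm[, j] <- zmm[, j] - step; zmm[, l] <- zmm[, l] - step
      gamma[j, l] <- gamma[l, j] <-
        mean((predict_fun(zpp) - predict_fun(zpm) -
                predict_fun(zmp) + predict_fun(zmm)) / (4 * step^2)) / W_bar
    }
  }
  dimnames(gamma) <- list(colnames(z), colnames(z))
  names(beta) <- colnames(z)
  list(beta = beta, gamma = gamma, W_bar = W_bar, w_mean = mean(W0) / W_bar)
}

#' Selection coefficients from a fitted fitness surface
#'
#' For a univariate surface the averaged first and second derivatives are
#' the standardized selection differentials (`s`, `c`); for a bivariate
#' surface they are the standardized gradients (`beta` per trait, the
#' `gamma` matrix including the pairwise interaction). Traits were
#' variance-standardized before fitting, so all coefficients are in
#' SD units. Quadratic coefficients follow the averaged-second-derivative
#' convention without halving (twice the corresponding quadratic
#' regression coefficient).
#'
#' @param surface a `fitness_surface`.
#' @param step finite-difference step in SD units.
#' @return named numeric vector: `s`, `c` (univariate) or `beta_<trait>`,
#'   `gamma_<trait>` and `gamma_<t1>.<t2>` (bivariate); the full list from
#'   [average_derivatives()] is attached as `"detail"`.
#' @export
selection_coefficients <- function(surface, step = 1e-3) {
  dat <- surface$data
  traits <- surface$traits
  zcols <- paste0(".z_", traits)
  z <- as.matrix(dat[zcols])
  colnames(z) <- traits
  predict_fun <- function(zz) {
    nd <- dat
    for (j in seq_along(traits)) nd[[zcols[j]]] <- zz[, j]
    as.numeric(predict(surface$fit, newdata = nd, type = "response"))
  }
  der <- average_derivatives(predict_fun, z, step = step)
  out <- if (length(traits) == 1) {
    c(s = unname(der$beta), c = unname(der$gamma[1, 1]))
  } else {
    v <- c(der$beta, diag(der$gamma), der$gamma[1, 2])
    names(v) <- c(paste0("beta_", traits), paste0("gamma_", traits),
                  paste0("gamma_", traits[1], ".", traits[2]))
    v
  }
  attr(out, "detail") <- der
  out
}

#' Full standardized selection analysis on plant-level data
#'
#' Runs one univariate fitness surface per trait (selection differentials
#' `s`, `c`) and, with two traits, the bivariate surface (gradients `beta`,
#' `gamma` and their interaction), mirroring the usual
#' differential/gradient table.
#'
#' @param phenotypes flower-level phenotype records.
#' @param fitness per-plant fitness counts (`plant_id`, `fruits`,
#'   `flower_scars`).
#' @param traits trait column names (1 or 2).
#' @param covariates covariates for the surface fits.
#' @param k,step passed to the surface fit / derivative engine.
#' @return object of class `selection_estimates`: named coefficient vector
#'   plus the fitted surfaces.
#' @export
estimate_selection <- function(phenotypes, fitness, traits,
                               covariates = c("site", "elevation"),
                               k = 6, step = 1e-3) {
  tab <- plant_selection_table(phenotypes, fitness, traits)
  coefs <- c()
  surfaces <- list()
  for (tr in traits) {
    sf <- fit_fitness_surface(tab, tr, covariates, k)
    cc <- selection_coefficients(sf, step)
    names(cc) <- paste0(names(cc), "_", tr)
    coefs <- c(coefs, cc)
    surfaces[[tr]] <- sf
  }
  if (length(traits) == 2) {
    sf2 <- fit_fitness_surface(tab, traits, covariates, k)
    coefs <- c(coefs, selection_coefficients(sf2, step))
    surfaces$bivariate <- sf2
  }
  structure(list(coefficients = coefs, surfaces = surfaces, table = tab,
                 traits = traits, covariates = covariates, k = k, step = step),
            class = "selection_estimates")
}

#' @export
print.selection_estimates <- function(x, ...) {
  cat("standardized selection coefficients (averaged derivatives):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Bootstrap standard errors and p-values for selection coefficients
#'
#' Plants (the independent sampling unit) are resampled with replacement,
#' every surface is refitted and the coefficients recomputed. SE is the SD
#' over replicates; the two-sided p-value is
#' `2 * min(frac <= 0, frac >= 0)` with a +1 continuity correction. Failed
#' refits are dropped and counted; more than 10\% failures is an error.
#'
#' @param phenotypes,fitness,traits,covariates,k,step as in
#'   [estimate_selection()].
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return `data.frame` with `term`, `estimate`, `se`, `p`; replicate draws
#'   in the `"replicates"` attribute, failure count in `"n_failed"`.
#' @export
bootstrap_selection <- function(phenotypes, fitness, traits,
                                covariates = c("site", "elevation"),
                                n_boot = 2000, seed = 1L, k = 6, step = 1e-3) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  est <- estimate_selection(phenotypes, fitness, traits, covariates, k, step)
  tab <- est$table
  if (any(vapply(tab[traits], sd, 0) == 0)) {
    stopf("constant trait: nothing to resample over")
  }
  one_rep <- function(d) {
    coefs <- c()
    for (tr in traits) {
      cc <- selection_coefficients(fit_fitness_surface(d, tr, covariates, k), step)
      names(cc) <- paste0(names(cc), "_", tr)
      coefs <- c(coefs, cc)
    }
    if (length(traits) == 2) {
      coefs <- c(coefs, selection_coefficients(
        fit_fitness_surface(d, traits, covariates, k), step))
    }
    coefs
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample(nrow(tab), replace = TRUE)
      tryCatch(one_rep(tab[idx, , drop = FALSE]), error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (mean(!ok) > 0.10) {
    stopf("%.0f%% of bootstrap refits failed", 100 * mean(!ok))
  }
  R <- do.call(rbind, reps[ok])
  B <- nrow(R)
  se <- apply(R, 2, sd)
  p <- vapply(seq_len(ncol(R)), function(j) {
    lo <- (sum(R[, j] <= 0) + 1) / (B + 1)
    hi <- (sum(R[, j] >= 0) + 1) / (B + 1)
    min(1, 2 * min(lo, hi))
  }, 0)
  out <- data.frame(term = names(est$coefficients),
                    estimate = unname(est$coefficients),
                    se = unname(se[names(est$coefficients)]),
                    p = unname(p[match(names(est$coefficients), colnames(R))]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicates") <- R
  attr(out, "n_failed") <- sum(!ok)
  out
}
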