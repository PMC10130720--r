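#' Configuration for a synthetic wild-population study
#'
#' Builds the parameter list that drives the synthetic-study generator. The
#' defaults emulate the design of a six-site field study of a bee-pollinated
#' shrub: 40 tagged plants per site, five replicate flowers per plant, a
#' genotyping-by-sequencing-style SNP panel with low between-site structure
#' but real variance in pairwise relatedness, one trait (flower dry weight,
#' mg) with narrow-sense heritability 0.14 and no selection, and one trait
#' (standard-petal area, mm\eqn{^2}) with essentially no additive variance
#' but under stabilizing selection through fruit set.
#'
#' @param n_sites number of sites (default 6).
#' @param plants_per_site plants tagged per site (default 40).
#' @param flowers_per_plant replicate flowers measured per plant (default 5;
#'   at least 2 is required to separate permanent-environment from residual
#'   variance).
#' @param n_loci number of biallelic SNP loci (default 2000; minimum 100).
#' @param founder_maf_range range of founder allele frequencies, in (0, 0.5].
#' @param sibship_mean mean sibship (full-sib family) size; 1 gives an
#'   essentially unrelated sample.
#' @param migration fraction of plants settling in a site other than their
#'   family's home site; 1 destroys any site-family association.
#' @param elevation_per_site elevation (m a.s.l.) of each site.
#' @param traits named list of per-trait parameter lists with elements
#'   `mean`, `V_a`, `V_s`, `V_i`, `V_error` (trait-squared units) and
#'   `elevation_slope` (trait units per metre). Defaults describe flower
#'   weight and standard-petal area calibrated to the study system.
#' @param r_G genetic correlation between the two traits' breeding values.
#' @param env_corr environmental correlation applied to the site,
#'   permanent-environment and flower-level residual effects shared by the
#'   two traits; `"auto"` solves for the value giving the target plant-mean
#'   phenotypic correlation `r_P_target`.
#' @param r_P_target target plant-mean phenotypic correlation used when
#'   `env_corr = "auto"` (default 0.43).
#' @param fitness list with the fitness-surface parameters: `trait` (focal
#'   trait for the Gaussian surface), `flowers_rate` (mean flower scars per
#'   plant twig), `theta` (optimum; `"mean"` places it at the realized trait
#'   mean), `omega_sd` (surface width in plant-mean SD units; the analytic
#'   standardized quadratic gradient at `theta = "mean"` is
#'   \eqn{-1/(1+\omega_{sd}^2)}), `max_prob` (fruit-set probability at the
#'   optimum).
#' @param census list with pollinator-census parameters: `n_per_site`,
#'   `duration_min`, `flowers_range`, `rate` (expected visits per flower per
#'   census) and `taxa` (named visit-share probabilities).
#' @param missing_rate fraction of genotype calls set to missing.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 6,
                       plants_per_site = 40,
                       flowers_per_plant = 5,
                       n_loci = 2000,
                       founder_maf_range = c(0.05, 0.5),
                       sibship_mean = 3,
                       migration = 0.1,
                       elevation_per_site = NULL,
                       traits = NULL,
                       r_G = 0.06,
                       env_corr = "auto",
                       r_P_target = 0.43,
                       fitness = NULL,
                       census = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  if (is.null(elevation_per_site)) {
    elevation_per_site <- round(seq(120, 850, length.out = n_sites))
  }
  if (is.null(traits)) {
    traits <- list(
      flower_weight_mg = list(mean = 20, V_a = 2.66, V_s = 10.07,
                              V_i = 3.61, V_error = 2.66,
                              elevation_slope = 0.002),
      standard_area_mm2 = list(mean = 55, V_a = 0.16, V_s = 63.6,
                               V_i = 66.6, V_error = 28.6,
                               elevation_slope = 0.005)
    )
  }
  fitness <- modifyList(list(trait = "standard_area_mm2", flowers_rate = 30,
                             theta = "mean", omega_sd = 3.2600,
                             max_prob = 0.5), fitness %||% list())
  census <- modifyList(list(n_per_site = 95, duration_min = 3,
                            flowers_range = c(20, 60), rate = 0.015,
                            taxa = c(Apis_mellifera = 0.91, Bombus_sp = 0.07,
                                     other = 0.02)), census %||% list())
  cfg <- structure(list(
    n_sites = as.integer(n_sites),
    plants_per_site = as.integer(plants_per_site),
    flowers_per_plant = as.integer(flowers_per_plant),
    n_loci = as.integer(n_loci),
    founder_maf_range = founder_maf_range,
    sibship_mean = sibship_mean,
    migration = migration,
    elevation_per_site = elevation_per_site,
    traits = traits,
    r_G = r_G,
    env_corr = env_corr,
    r_P_target = r_P_target,
    fitness = fitness,
    census = census,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_loci < 100) {
    stopf("n_loci must be >= 100 (got %d): fewer loci give a relatedness matrix too noisy to analyse", cfg$n_loci)
  }
  if (cfg$flowers_per_plant < 2) {
    stopf("flowers_per_plant must be >= 2 to separate permanent-environment from residual variance")
  }
  if (length(cfg$elevation_per_site) != cfg$n_sites) {
    stopf("elevation_per_site must have one value per site")
  }
  rng <- cfg$founder_maf_range
  if (length(rng) != 2 || rng[1] <= 0 || rng[2] > 0.5 || rng[1] > rng[2]) {
    stopf("founder_maf_range must lie in (0, 0.5]")
  }
  for (nm in names(cfg$traits)) {
    tp <- cfg$traits[[nm]]
    vals <- unlist(tp[c("V_a", "V_s", "V_i", "V_error")])
    if (any(!is.finite(vals)) || any(vals < 0)) {
      stopf("trait '%s': variance components must be finite and non-negative", nm)
    }
    if (!is.finite(tp$mean)) stopf("trait '%s': non-finite mean", nm)
  }
  if (cfg$fitness$max_prob <= 0 || cfg$fitness$max_prob > 1) {
    stopf("fitness max_prob must be in (0, 1]")
  }
  if (cfg$fitness$omega_sd <= 0) stopf("fitness width omega must be > 0")
  if (cfg$migration < 0 || cfg$migration > 1) stopf("migration must be in [0, 1]")
  invisible(cfg)
}

#' Construct a genotype matrix object
#'
#' @param dosages integer matrix (individuals x loci) with values in
#'   \{0, 1, 2\} or `NA` for missing calls.
#' @param sites character/factor of site labels, one per individual.
#' @param individual_ids,locus_ids optional identifier vectors; taken from
#'   `dimnames(dosages)` when absent.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sites,
                            individual_ids = rownames(dosages),
                            locus_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(locus_ids)) locus_ids <- paste0("locus", seq_len(ncol(dosages)))
  if (anyDuplicated(individual_ids)) stopf("duplicate individual IDs")
  if (anyDuplicated(locus_ids)) stopf("duplicate locus IDs")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA (found %d other values)", sum(bad))
  if (length(sites) != nrow(dosages)) stopf("one site label per individual required")
  dimnames(dosages) <- list(individual_ids, locus_ids)
  structure(list(dosages = dosages,
                 individual_ids = individual_ids,
                 locus_ids = locus_ids,
                 sites = as.character(sites)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %.2f%% missing, %d sites\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages)), length(unique(x$sites))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Simulate SNP genotypes with sibship structure
#'
#' Gene-dropping simulation: plants belong to full-sib families whose two
#' founding parents carry Hardy-Weinberg genotypes at shared allele
#' frequencies (so between-site differentiation is negligible); offspring
#' receive one allele from each parent per locus. Families have a home site
#' and a fraction `migration` of plants settle elsewhere, producing
#' cross-site relatives. With `sibship_mean = 1` every plant has private
#' parents and the sample is effectively unrelated.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with per-plant site labels; family
#'   assignments are kept in the `"family"` attribute.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(sub_seed(config$seed, "genotypes"), {
    n_sites <- config$n_sites
    n_plants <- n_sites * config$plants_per_site
    L <- config$n_loci

    # family sizes: 1 + Poisson(sibship_mean - 1), drawn until each site fills
    fam_site <- integer(0)
    fam_size <- integer(0)
    for (s in seq_len(n_sites)) {
      left <- config$plants_per_site
      while (left > 0) {
        sz <- 1L + rpois(1, max(0, config$sibship_mean - 1))
        sz <- min(sz, left)
        fam_site <- c(fam_site, s)
        fam_size <- c(fam_size, sz)
        left <- left - sz
      }
    }
    n_fam <- length(fam_size)
    family <- rep(seq_len(n_fam), fam_size)
    site <- rep(fam_site, fam_size)

    # migration: re-settle a fraction of plants in a random other site,
    # keeping site sizes balanced by swapping pairs
    mig <- which(runif(length(site)) < config$migration)
    if (length(mig) >= 2) {
      perm <- sample(mig)
      site[mig] <- site[perm]
    }

    p <- runif(L, config$founder_maf_range[1], config$founder_maf_range[2])
    # founder genotypes per family: two parents, HWE at p
    dos <- matrix(0L, n_plants, L)
    row <- 1L
    for (f in seq_len(n_fam)) {
      par1 <- rbinom(L, 2, p)
      par2 <- rbinom(L, 2, p)
      for (k in seq_len(fam_size[f])) {
        g1 <- rbinom(L, 1, par1 / 2)
        g2 <- rbinom(L, 1, par2 / 2)
        dos[row, ] <- as.integer(g1 + g2)
        row <- row + 1L
      }
    }

    if (config$missing_rate > 0) {
      miss <- runif(length(dos)) < config$missing_rate
      dos[miss] <- NA_integer_
    }

    ids <- sprintf("P%03d", seq_len(n_plants))
    rownames(dos) <- ids
    colnames(dos) <- sprintf("SNP%05d", seq_len(L))
    g <- genotype_matrix(dos, sites = sprintf("S%d", site))
    attr(g, "family") <- family
    attr(g, "allele_freq") <- p
    g
  })
}

# Solve the environmental cross-trait correlation that yields a target
# plant-mean phenotypic correlation, given the generating components.
solve_env_corr <- function(config) {
  tn <- names(config$traits)
  if (length(tn) < 2) return(0)
  t1 <- config$traits[[tn[1]]]; t2 <- config$traits[[tn[2]]]
  m <- config$flowers_per_plant
  gen_cov <- config$r_G * sqrt(t1$V_a * t2$V_a)
  env_sum <- sqrt(t1$V_s * t2$V_s) + sqrt(t1$V_i * t2$V_i) +
    sqrt(t1$V_error * t2$V_error) / m
  sd1 <- sqrt(t1$V_a + t1$V_s + t1$V_i + t1$V_error / m)
  sd2 <- sqrt(t2$V_a + t2$V_s + t2$V_i + t2$V_error / m)
  rho <- (config$r_P_target * sd1 * sd2 - gen_cov) / env_sum
  max(-0.99, min(0.99, rho))
}

# Correlated standard-normal pair generator (one shared correlation).
# With standardize = TRUE each column is centred and rescaled to unit
# sample variance, so realized effect variances equal their targets
# exactly; essential for the site effects, where only a handful of draws
# would otherwise make the realized variance partition very noisy.
rnorm2 <- function(n, rho, standardize = FALSE) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  if (standardize && n >= 3) {
    # empirical Gram-Schmidt: exact zero mean, unit sample variance and
    # exact sample correlation rho between the two effect vectors
    z1 <- (z1 - mean(z1)) / sd(z1)
    r2 <- stats::residuals(lm(z2 ~ z1))
    r2 <- r2 / sd(r2)
    z2 <- rho * z1 + sqrt(1 - rho^2) * r2
  } else {
    z2 <- rho * z1 + sqrt(1 - rho^2) * z2
  }
  cbind(z1, z2)
}

#' Simulate replicated floral phenotypes on simulated genotypes
#'
#' Breeding values are genotype-based: per-locus allelic effects are drawn,
#' summed over centred dosages, and rescaled so the realized additive
#' variance among plants equals the target `V_a` exactly. Phenotypes are
#' then trait mean + elevation slope x elevation + site effect +
#' permanent-environment effect + breeding value + flower-level residual.
#' Environmental effects shared by the two traits are correlated with
#' coefficient `env_corr` ("auto" solves for the plant-mean phenotypic
#' correlation target).
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return a `data.frame` of flower-level records (`plant_id`, `site`,
#'   `elevation_m`, `flower_idx`, one column per trait) with a `"truth"`
#'   attribute recording breeding values, generating parameters and
#'   realized h2 / e / r_G.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  if (!length(config$traits)) stopf("at least one trait must be configured")
  with_seed(sub_seed(config$seed, "phenotypes"), {
    dos <- genotypes$dosages
    if (anyNA(dos)) {
      # generate breeding values from the complete underlying genotypes:
      # mean-impute only for the BV sum
      mu_l <- colMeans(dos, na.rm = TRUE)
      idx <- which(is.na(dos))
      dos[idx] <- mu_l[(idx - 1) %/% nrow(dos) + 1]
    }
    n <- nrow(dos)
    L <- ncol(dos)
    m <- config$flowers_per_plant
    tn <- names(config$traits)
    n_tr <- length(tn)

    p_hat <- colMeans(dos) / 2
    Zc <- sweep(dos, 2, 2 * p_hat)

    # correlated per-locus effects -> breeding values, rescaled to V_a
    eff <- if (n_tr >= 2) rnorm2(L, config$r_G) else matrix(rnorm(L), L, 1)
    bv <- matrix(0, n, n_tr, dimnames = list(genotypes$individual_ids, tn))
    for (t in seq_len(n_tr)) {
      raw <- as.numeric(Zc %*% eff[, min(t, ncol(eff))])
      v <- var(raw)
      V_a <- config$traits[[t]]$V_a
      bv[, t] <- if (v > 0 && V_a > 0) raw * sqrt(V_a / v) else 0
    }

    rho <- if (identical(config$env_corr, "auto")) solve_env_corr(config) else config$env_corr
    site_f <- factor(genotypes$sites, levels = sprintf("S%d", seq_len(config$n_sites)))
    elev <- config$elevation_per_site[as.integer(site_f)]

    site_eff <- rnorm2(config$n_sites, rho, standardize = TRUE)
    i_eff <- rnorm2(n, rho, standardize = TRUE)
    res_eff <- rnorm2(n * m, rho, standardize = TRUE)

    out <- data.frame(
      plant_id = rep(genotypes$individual_ids, each = m),
      site = rep(as.character(site_f), each = m),
      elevation_m = rep(elev, each = m),
      flower_idx = rep(seq_len(m), n),
      stringsAsFactors = FALSE
    )
    for (t in seq_len(n_tr)) {
      tp <- config$traits[[t]]
      col_t <- min(t, 2)
      plant_part <- tp$mean + tp$elevation_slope * elev +
        sqrt(tp$V_s) * site_eff[as.integer(site_f), col_t] +
        sqrt(tp$V_i) * i_eff[, col_t] + bv[, t]
      out[[tn[t]]] <- rep(plant_part, each = m) +
        sqrt(tp$V_error) * res_eff[, col_t]
    }

    truth <- list(
      config = config,
      env_corr = rho,
      breeding_values = bv,
      realized = lapply(setNames(seq_len(n_tr), tn), function(t) {
        tp <- config$traits[[t]]
        tot <- tp$V_a + tp$V_s + tp$V_i + tp$V_error
        list(V_a = var(bv[, t]),
             h2 = if (tot > 0) var(bv[, t]) / tot else 0,
             e_pct = if (tp$mean > 0) 100 * var(bv[, t]) / tp$mean^2 else NA_real_,
             h2_target = if (tot > 0) tp$V_a / tot else 0)
      }),
      r_G_realized = if (n_tr >= 2 && sd(bv[, 1]) > 0 && sd(bv[, 2]) > 0)
        cor(bv[, 1], bv[, 2]) else NA_real_
    )
    attr(out, "truth") <- truth
    out
  })
}

# Gaussian fitness surface on the standardized trait scale and its
# standardized average derivatives under a N(0,1) phenotype distribution.
gaussian_surface_gradients <- function(theta_s, omega_s) {
  W <- function(z) exp(-(z - theta_s)^2 / (2 * omega_s^2))
  Wp <- function(z) W(z) * (-(z - theta_s) / omega_s^2)
  Wpp <- function(z) W(z) * ((z - theta_s)^2 / omega_s^4 - 1 / omega_s^2)
  EW <- integrate(function(z) W(z) * dnorm(z), -Inf, Inf)$value
  beta <- integrate(function(z) Wp(z) * dnorm(z), -Inf, Inf)$value / EW
  gamma <- integrate(function(z) Wpp(z) * dnorm(z), -Inf, Inf)$value / EW
  list(beta = beta, gamma = gamma, mean_fitness_factor = EW)
}

#' Simulate fruit-set fitness records under a Gaussian fitness surface
#'
#' Per plant, the number of flower scars on a surveyed twig is drawn as
#' 1 + Poisson(`flowers_rate` - 1) and fruits as Binomial(scars, p) with
#' p = `max_prob` exp(-(z - theta)^2 / (2 omega^2)) evaluated at the
#' plant-mean focal trait. The `"fitness_truth"` attribute stores the
#' analytic standardized selection gradients implied by (theta, omega,
#' trait SD): with the optimum at the trait mean the standardized quadratic
#' gradient is -1/(1 + omega_sd^2).
#'
#' @param phenotypes flower-level records from [simulate_phenotypes()].
#' @param config the same [sim_config()].
#' @return a `data.frame` (`plant_id`, `fruits`, `flower_scars`) with a
#'   `"fitness_truth"` attribute.
#' @export
simulate_fitness <- function(phenotypes, config) {
  fp <- config$fitness
  if (!fp$trait %in% names(phenotypes)) {
    stopf("focal fitness trait '%s' not present in phenotypes", fp$trait)
  }
  if (fp$omega_sd <= 0) stopf("fitness width omega must be > 0")
  with_seed(sub_seed(config$seed, "fitness"), {
    pm <- tapply(phenotypes[[fp$trait]], phenotypes$plant_id, mean)
    ids <- names(pm)
    mu <- mean(pm); s <- sd(pm)
    theta <- if (identical(fp$theta, "mean")) mu else fp$theta
    omega <- fp$omega_sd * s
    p <- fp$max_prob * exp(-(pm - theta)^2 / (2 * omega^2))
    scars <- 1L + rpois(length(pm), max(0, fp$flowers_rate - 1))
    fruits <- rbinom(length(pm), scars, p)
    out <- data.frame(plant_id = ids, fruits = fruits, flower_scars = scars,
                      stringsAsFactors = FALSE)
    theta_s <- (theta - mu) / s
    grad <- gaussian_surface_gradients(theta_s, fp$omega_sd)
    # empirical counterpart: averaged over the observed standardized means
    z <- (pm - mu) / s
    Wz <- exp(-(z - theta_s)^2 / (2 * fp$omega_sd^2))
    Wpp <- Wz * ((z - theta_s)^2 / fp$omega_sd^4 - 1 / fp$omega_sd^2)
    attr(out, "fitness_truth") <- list(
      trait = fp$trait, theta = theta, omega = omega,
      theta_s = theta_s, omega_s = fp$omega_sd, max_prob = fp$max_prob,
      beta_true = grad$beta, gamma_true = grad$gamma,
      gamma_true_empirical = mean(Wpp) / mean(Wz)
    )
    out
  })
}

#' Simulate pollinator censuses
#'
#' Each census surveys a patch of flowers for a fixed duration; visits are
#' Poisson with a per-flower visitation rate and visitors are assigned to
#' taxa multinomially, emulating a honeybee-dominated visitation regime.
#'
#' @param config a [sim_config()].
#' @return `data.frame` with one row per census x taxon: `site`,
#'   `census_id`, `duration_min`, `flowers_surveyed`, `taxon`, `visits`.
#' @export
simulate_census <- function(config) {
  cc <- config$census
  with_seed(sub_seed(config$seed, "census"), {
    rows <- list()
    cid <- 0L
    taxa <- names(cc$taxa)
    for (s in seq_len(config$n_sites)) {
      for (k in seq_len(cc$n_per_site)) {
        cid <- cid + 1L
        fl <- sample(cc$flowers_range[1]:cc$flowers_range[2], 1)
        total <- rpois(1, cc$rate * fl)
        by_taxon <- if (total > 0) {
          as.integer(stats::rmultinom(1, total, cc$taxa))
        } else {
          integer(length(taxa))
        }
        rows[[cid]] <- data.frame(
          site = sprintf("S%d", s), census_id = cid,
          duration_min = cc$duration_min, flowers_surveyed = fl,
          taxon = taxa, visits = by_taxon, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: genotypes, phenotypes, fitness records and
#' pollinator censuses, with all ground-truth parameters collected in
#' `$truth`.
#'
#' @param config a [sim_config()].
#' @return an object of class `simulated_study`: list with `genotypes`,
#'   `phenotypes`, `fitness`, `census`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g, config)
  fit <- simulate_fitness(ph, config)
  cen <- simulate_census(config)
  truth <- attr(ph, "truth")
  truth$fitness <- attr(fit, "fitness_truth")
  structure(list(genotypes = g, phenotypes = ph, fitness = fit,
                 census = cen, truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d plants, %d loci, %d flower records, %d fitness rows\n",
              nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              nrow(x$phenotypes), nrow(x$fitness)))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `genotypes.tsv` (individuals x loci dosage table, `NA` missing),
#' `phenotypes.csv`, `fitness.csv`, `census.csv` and `truth.json` under
#' `dir`. Optionally also writes `genotypes.vcf` with diploid GT fields.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @param vcf also write a VCF copy of the genotypes.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_table(study$genotypes, file.path(dir, "genotypes.tsv"))
  data.table::fwrite(study$phenotypes, file.path(dir, "phenotypes.csv"))
  data.table::fwrite(study$fitness, file.path(dir, "fitness.csv"))
  data.table::fwrite(study$census, file.path(dir, "census.csv"))
  truth <- study$truth
  truth$breeding_values <- NULL
  truth$config$traits <- truth$config$traits  # keep parameter echo
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (vcf) write_vcf(study$genotypes, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}
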