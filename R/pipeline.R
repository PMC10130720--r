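#' Configuration for a full pipeline run
#'
#' @param study an in-memory `simulated_study`, or `NULL` to read inputs
#'   from files.
#' @param genotypes,phenotypes,fitness,census input file paths (used when
#'   `study` is `NULL`); `fitness`/`census` may be `NA` to skip those
#'   stages.
#' @param traits trait column names (first trait is used for the
#'   naive-vs-full comparison; both enter the bivariate model).
#' @param qc list of QC thresholds passed to [apply_qc_filters()].
#' @param chain chain settings from [chain_control()] (the seed inside is
#'   overridden by `seed`).
#' @param priors prior settings from [default_priors()].
#' @param n_boot bootstrap replicates for the selection stage.
#' @param power_h2 heritability values at which to tabulate power.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param out_dir optional directory for stage artifacts and the report.
#' @return a `run_config` list.
#' @export
run_config <- function(study = NULL, genotypes = NULL, phenotypes = NULL,
                       fitness = NULL, census = NULL,
                       traits = c("flower_weight_mg", "standard_area_mm2"),
                       qc = list(), chain = chain_control(),
                       priors = default_priors(), n_boot = 500,
                       power_h2 = c(0.1, 0.14, 0.3, 0.5),
                       seed = 1L, out_dir = NULL) {
  if (is.null(study)) {
    for (f in c(genotypes, phenotypes)) {
      if (is.null(f) || !file.exists(f)) stopf("input file missing: %s", f %||% "(genotypes/phenotypes unset)")
    }
  }
  structure(list(study = study, genotypes = genotypes, phenotypes = phenotypes,
                 fitness = fitness, census = census, traits = traits, qc = qc,
                 chain = chain, priors = priors, n_boot = n_boot,
                 power_h2 = power_h2, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: genotype QC, relatedness (GRM), animal models (full,
#' naive and bivariate; heritability, evolvability, genetic correlation,
#' DIC comparison), selection (differentials, gradients, bootstrap),
#' descriptive statistics and censuses, and power. A stage whose inputs
#' are absent (no fitness or census table) is skipped with a warning; any
#' stage error halts the run naming the stage.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list with one element per stage plus a run
#'   log (seed, parameters, per-stage wall time).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list(log = list(seed = config$seed, started = format(Sys.time()),
                         stages = list()))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    res$log$stages[[name]] <<- round(proc.time()[3] - t0, 2)
    out
  }

  if (!is.null(config$study)) {
    g <- config$study$genotypes
    phenos <- config$study$phenotypes
    fit_tab <- config$study$fitness
    census <- config$study$census
  } else {
    g <- read_genotypes(config$genotypes)
    phenos <- as.data.frame(data.table::fread(config$phenotypes))
    site_map <- unique(phenos[c("plant_id", "site")])
    g$sites <- site_map$site[match(g$individual_ids, site_map$plant_id)]
    fit_tab <- if (!is.null(config$fitness) && !is.na(config$fitness) &&
                   file.exists(config$fitness)) {
      as.data.frame(data.table::fread(config$fitness))
    } else NULL
    census <- if (!is.null(config$census) && !is.na(config$census) &&
                  file.exists(config$census)) {
      as.data.frame(data.table::fread(config$census))
    } else NULL
  }
  traits <- config$traits

  qc <- t_stage("qc", do.call(apply_qc_filters, c(list(g), config$qc)))
  res$qc <- attr(qc, "qc_report")

  grm <- t_stage("grm", {
    stabilize_for_inversion(vanraden_grm(impute_missing(qc)))
  })
  res$grm <- c(relatedness_summary(grm, qc$sites),
               list(n_loci_used = grm$n_loci_used,
                    ridge_applied = grm$ridge_applied))

  phenos <- phenos[phenos$plant_id %in% grm$individual_ids, , drop = FALSE]

  res$animal <- t_stage("animal", {
    out <- list()
    for (tr in traits) {
      chain <- config$chain
      chain$seed <- sub_seed(config$seed, paste0("animal_", tr))
      cmp <- compare_naive_full(phenos, grm, tr, config$priors, chain)
      h2 <- heritability(cmp$full)
      ev <- evolvability(cmp$full)
      out[[tr]] <- list(
        h2 = h2$mean, h2_ci = unname(h2$ci95),
        h2_naive = cmp$table$h2_mean[cmp$table$model == "naive"],
        e_pct = ev$mean, e_ci = unname(ev$ci95),
        dic_full = cmp$table$dic[1], dic_naive = cmp$table$dic[2],
        delta_dic = cmp$delta_dic, preferred = cmp$preferred,
        V = as.list(cmp$full$point[c("V_a", "V_s", "V_i", "V_error")]))
    }
    if (length(traits) == 2) {
      chain <- config$chain
      chain$seed <- sub_seed(config$seed, "animal_bivariate")
      biv <- fit_bivariate_animal_model(
        build_model_matrices(phenos, model_spec(traits), grm),
        config$priors, chain)
      out$bivariate <- list(
        r_G = unname(biv$point["r_G"]),
        r_G_ci = unname(biv$ci95["r_G", ]))
    }
    out
  })

  if (!is.null(fit_tab)) {
    res$selection <- t_stage("selection", {
      boot <- bootstrap_selection(phenos, fit_tab, traits,
                                  n_boot = config$n_boot,
                                  seed = sub_seed(config$seed, "selection"))
      list(coefficients = boot, n_failed = attr(boot, "n_failed"))
    })
  } else {
    warning("no fitness table: selection stage skipped", call. = FALSE)
    res$selection <- NULL
  }

  res$descriptive <- t_stage("descriptive", {
    out <- list()
    pm <- aggregate(phenos[traits], by = list(plant_id = phenos$plant_id), mean)
    for (tr in traits) {
      part <- partition_trait_variance(phenos, tr)
      out[[tr]] <- list(percent = as.list(part$percent),
                        repeatability = repeatability(phenos, tr),
                        cv_pct = coefficient_of_variation(pm[[tr]]))
    }
    if (length(traits) == 2) {
      pc <- phenotypic_correlation(pm[[traits[1]]], pm[[traits[2]]])
      out$phenotypic_correlation <- list(r = pc$r, p = pc$p)
    }
    if (!is.null(census)) out$visitation <- visitation_summary(census)
    out
  })

  res$power <- t_stage("power", {
    n <- length(grm$individual_ids)
    emp <- var(grm$values[upper.tri(grm$values)])
    tab <- lapply(config$power_h2, function(h2) {
      list(h2 = h2,
           power_default = greml_power_h2(n, h2)$power,
           power_empirical = greml_power_h2(n, h2, var_rel = emp)$power)
    })
    h2s <- vapply(traits, function(tr) res$animal[[tr]]$h2, 0)
    rg_pow <- if (length(traits) == 2) {
      greml_power_rg(n, max(h2s[1], 1e-3), max(h2s[2], 1e-3),
                     rg = res$animal$bivariate$r_G)$power
    } else NA_real_
    list(n = n, var_rel_empirical = emp, h2_table = tab, power_rg = rg_pow)
  })

  res$log$finished <- format(Sys.time())
  class(res) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

#' Write a pipeline report as JSON and markdown
#'
#' The JSON file is the complete machine-readable report; the markdown
#' file formats the genetic-parameter and selection tables in the layout
#' of a quantitative-genetics results section. Every number printed in the
#' markdown is present in the JSON.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep2 <- report
  if (!is.null(rep2$selection)) {
    rep2$selection$coefficients <- as.data.frame(rep2$selection$coefficients)
  }
  jsonlite::write_json(rep2, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- c("# Pipeline report", "",
          sprintf("- seed: %d", report$log$seed),
          sprintf("- QC: %d -> %d loci, %d -> %d individuals",
                  report$qc$input$loci, report$qc$output$loci,
                  report$qc$input$individuals, report$qc$output$individuals),
          sprintf("- GRM: %d loci used, mean diagonal %.3f, %.0f%% of pairs < 0.2",
                  report$grm$n_loci_used, report$grm$mean_diag,
                  100 * report$grm$off$frac_below_0.2),
          "", "## Genetic parameters", "",
          "| trait | naive h2 | h2 | 95% CI | e (%) | 95% CI |",
          "|---|---|---|---|---|---|")
  for (tr in setdiff(names(report$animal), "bivariate")) {
    a <- report$animal[[tr]]
    md <- c(md, sprintf("| %s | %.2f | %.3f | %.3f-%.3f | %.3f | %.3f-%.3f |",
                        tr, a$h2_naive, a$h2, a$h2_ci[1], a$h2_ci[2],
                        a$e_pct, a$e_ci[1], a$e_ci[2]))
  }
  if (!is.null(report$animal$bivariate)) {
    md <- c(md, "", sprintf("Genetic correlation r_G = %.3f (95%% CI %.3f to %.3f)",
                            report$animal$bivariate$r_G,
                            report$animal$bivariate$r_G_ci[1],
                            report$animal$bivariate$r_G_ci[2]))
  }
  if (!is.null(report$selection)) {
    md <- c(md, "", "## Selection coefficients", "",
            "| term | estimate | SE | p |", "|---|---|---|---|")
    cf <- report$selection$coefficients
    for (i in seq_len(nrow(cf))) {
      md <- c(md, sprintf("| %s | %.4f | %.4f | %.4f |",
                          cf$term[i], cf$estimate[i], cf$se[i], cf$p[i]))
    }
  } else {
    md <- c(md, "", "## Selection coefficients", "",
            "(no fitness table supplied; stage skipped)")
  }
  if (!is.null(report$descriptive$visitation)) {
    v <- report$descriptive$visitation
    md <- c(md, "", "## Visitation", "",
            sprintf("- rate %.4f visits/flower/census; one visit every %.1f h",
                    v$rate_per_flower_per_census, v$waiting_time_h))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
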