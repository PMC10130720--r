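# Shared fixtures and brute-force oracles, all built in code.

# Hand-written toy matrix: 10 individuals x 5 loci, engineered so under
# the default thresholds exactly one locus fails each locus rule and one
# individual fails the call-rate rule:
#   L1 call rate 8/10 < 0.90; L2 monomorphic (MAF 0); L4 all heterozygous
#   (oHET 1 > 0.98); individual 10 called at 1 of the 3 loci surviving the
#   locus filters (0.33 < 0.85); L3 and L5 survive everything.
toy_qc_genotypes <- function() {
  dos <- rbind(
    c(0L, 2L, 0L, 1L, 0L),
    c(1L, 2L, 1L, 1L, 1L),
    c(0L, 2L, 0L, 1L, 1L),
    c(1L, 2L, 1L, 1L, 0L),
    c(0L, 2L, 0L, 1L, 0L),
    c(1L, 2L, 0L, 1L, 1L),
    c(0L, 2L, 1L, 1L, 0L),
    c(1L, 2L, 0L, 1L, 0L),
    c(NA, 2L, 0L, 1L, 0L),
    c(NA, 2L, NA, 1L, NA)
  )
  genotype_matrix(dos, sites = rep(c("S1", "S2"), each = 5))
}

# Brute-force per-locus stats by explicit loops.
naive_locus_stats <- function(g) {
  dos <- g$dosages
  out <- data.frame(locus_id = g$locus_ids, call_rate = NA_real_,
                    maf = NA_real_, ohet = NA_real_)
  for (k in seq_len(ncol(dos))) {
    v <- dos[, k]
    called <- v[!is.na(v)]
    out$call_rate[k] <- length(called) / length(v)
    if (length(called) > 0) {
      p <- sum(called) / (2 * length(called))
      out$maf[k] <- min(p, 1 - p)
      out$ohet[k] <- mean(called == 1)
    }
  }
  out
}

# Brute-force QC filter re-implementation with naive loops, same order.
naive_qc <- function(dos, lc = 0.90, maf = 0.01, ic = 0.85, oh = c(0.02, 0.98)) {
  keep_l <- logical(ncol(dos))
  for (k in seq_len(ncol(dos))) {
    v <- dos[, k]; called <- v[!is.na(v)]
    cr <- length(called) / length(v)
    p <- if (length(called)) sum(called) / (2 * length(called)) else NA
    keep_l[k] <- cr >= lc && !is.na(p) && min(p, 1 - p) > maf
  }
  dos <- dos[, keep_l, drop = FALSE]
  keep_i <- logical(nrow(dos))
  for (i in seq_len(nrow(dos))) {
    keep_i[i] <- mean(!is.na(dos[i, ])) >= ic
  }
  dos <- dos[keep_i, , drop = FALSE]
  keep_l2 <- logical(ncol(dos))
  for (k in seq_len(ncol(dos))) {
    v <- dos[, k]; called <- v[!is.na(v)]
    het <- if (length(called)) mean(called == 1) else NA
    keep_l2[k] <- !is.na(het) && het >= oh[1] && het <= oh[2]
  }
  dos[, keep_l2, drop = FALSE]
}

# Naive O(n^2 L) VanRaden GRM with explicit double loops.
naive_grm <- function(dos) {
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(dos)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(ncol(dos))) {
        s <- s + (dos[i, k] - 2 * p[k]) * (dos[j, k] - 2 * p[k])
      }
      G[i, j] <- s / denom
    }
  }
  G
}

# Small three-sample VCF, two good biallelic records plus one triallelic.
write_toy_vcf <- function(path, include_triallelic = TRUE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "A3", sep = "\t"),
    paste("1", "100", "snpA", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "snpB", "G", "C", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t"))
  if (include_triallelic) {
    lines <- c(lines, paste("1", "300", "snpC", "A", "T,C", ".", "PASS", ".",
                            "GT", "0/1", "1/2", "0/0", sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Clonal-pair sample: 2k individuals as k duplicated genotypes, giving the
# strongest possible additive-vs-permanent-environment contrast for the
# REML oracle comparison.
clone_pair_study <- function(n_pairs = 50, n_loci = 1500, seed = 11,
                             V_a = 4, V_i = 2, V_e = 2) {
  set.seed(seed)
  p <- runif(n_loci, 0.1, 0.5)
  founders <- vapply(p, function(pp) rbinom(n_pairs, 2, pp), integer(n_pairs))
  dos <- founders[rep(seq_len(n_pairs), each = 2), ]
  rownames(dos) <- sprintf("P%03d", seq_len(2 * n_pairs))
  g <- genotype_matrix(dos, sites = rep(c("S1", "S2"), each = n_pairs))
  cfg <- sim_config(n_sites = 2, plants_per_site = n_pairs,
                    n_loci = n_loci, elevation_per_site = c(200, 600),
                    traits = list(tr = list(mean = 20, V_a = V_a, V_s = 0,
                                            V_i = V_i, V_error = V_e,
                                            elevation_slope = 0)),
                    seed = seed)
  list(genotypes = g, phenotypes = simulate_phenotypes(g, cfg), config = cfg)
}

# Flat-fitness plant table: trait unrelated to binomial fruit set.
flat_fitness_data <- function(n = 80, seed = 1, p_fruit = 0.4, scars = 30) {
  set.seed(seed)
  list(
    phenotypes = data.frame(plant_id = sprintf("p%03d", seq_len(n)),
                            site = "S1", elevation_m = 100, flower_idx = 1,
                            trait = rnorm(n)),
    fitness = data.frame(plant_id = sprintf("p%03d", seq_len(n)),
                         fruits = rbinom(n, scars, p_fruit),
                         flower_scars = scars)
  )
}
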