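#' Read genotypes from a VCF or a dosage table
#'
#' Two input dialects are supported: VCF 4.x (GT field only; biallelic SNPs;
#' multiallelic records are skipped with a count) and a TSV dosage table
#' with individuals as rows, a header of locus IDs, a first column of
#' individual IDs, and entries 0/1/2 with `NA`, `.` or `./.` for missing.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param sites optional named vector/`data.frame` assigning a site to each
#'   individual; defaults to a single site `"S1"` when absent (VCF carries
#'   no site-of-origin field).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"), sites = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  g <- if (format == "vcf") read_vcf_genotypes(path) else read_dosage_table(path)
  if (nrow(g$dosages) == 0) stopf("empty input: no individuals in %s", path)
  if (!is.null(sites)) {
    if (is.data.frame(sites)) sites <- setNames(sites[[2]], sites[[1]])
    miss <- setdiff(g$individual_ids, names(sites))
    if (length(miss)) stopf("no site label for individuals: %s", paste(head(miss, 5), collapse = ", "))
    g$sites <- as.character(sites[g$individual_ids])
  }
  g
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi)) {
    warning(sprintf("skipped %d non-biallelic VCF record(s)", sum(multi)),
            call. = FALSE)
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stopf("no biallelic GT records in %s", path)
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(x, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  })
  dos <- t(dos)  # individuals x loci
  loci <- vcfR::getID(v)
  if (all(is.na(loci))) {
    loci <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  }
  colnames(dos) <- loci
  genotype_matrix(dos, sites = rep("S1", nrow(dos)))
}

read_dosage_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ".", "./."),
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stopf("malformed dosage table %s: need an ID column plus loci", path)
  ids <- dt[[1]]
  mat <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  bad <- which(!(mat %in% c(0L, 1L, 2L) | is.na(mat)))
  if (length(bad)) {
    stopf("malformed dosage table %s: non-dosage value near row %d",
          path, (bad[1] - 1) %% nrow(mat) + 1)
  }
  genotype_matrix(mat, sites = rep("S1", nrow(mat)))
}

#' Write a genotype matrix as a TSV dosage table
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(g, path) {
  dt <- data.table::data.table(individual_id = g$individual_ids)
  dt <- cbind(dt, data.table::as.data.table(g$dosages))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF (GT field only)
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individual_ids), collapse = "\t")),
             con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (k in seq_along(g$locus_ids)) {
    d <- g$dosages[, k]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c("1", k, g$locus_ids[k], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-locus call rate, minor allele frequency and observed heterozygosity
#'
#' All statistics are computed over non-missing calls only. Loci with zero
#' calls get `call_rate = 0` and `NA` for MAF and oHET.
#'
#' @param g a [genotype_matrix()].
#' @return `data.frame` with `locus_id`, `call_rate`, `maf`, `ohet`.
#' @export
compute_locus_stats <- function(g) {
  dos <- g$dosages
  if (nrow(dos) < 1) stopf("need at least one individual")
  n_called <- colSums(!is.na(dos))
  call_rate <- n_called / nrow(dos)
  p <- ifelse(n_called > 0, colSums(dos, na.rm = TRUE) / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  ohet <- ifelse(n_called > 0, colSums(dos == 1, na.rm = TRUE) / n_called, NA_real_)
  data.frame(locus_id = g$locus_ids, call_rate = call_rate, maf = maf,
             ohet = ohet, row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply SNP and individual quality-control filters
#'
#' Filters are applied in a fixed order: (1) loci genotyped in fewer than
#' `locus_call_rate_min` of individuals are removed; (2) loci with minor
#' allele frequency at or below `maf_min` are removed; (3) individuals
#' genotyped at fewer than `indiv_call_rate_min` of the surviving loci are
#' removed; (4) loci whose observed heterozygosity, recomputed on the
#' surviving individuals, falls outside `ohet_bounds` are removed. The
#' attached report records the count removed at each step so the effect of
#' the ordering stays visible.
#'
#' @param g a [genotype_matrix()].
#' @param locus_call_rate_min minimum locus call rate (default 0.90).
#' @param maf_min MAF threshold; loci are kept when MAF > `maf_min`
#'   (default 0.01).
#' @param indiv_call_rate_min minimum individual call rate (default 0.85).
#' @param ohet_bounds open interval of admissible observed heterozygosity
#'   (default `c(0.02, 0.98)`); loci with oHET strictly below the lower or
#'   strictly above the upper bound are removed.
#' @return the filtered [genotype_matrix()] with a `"qc_report"` attribute
#'   (list of per-step removal counts and surviving dimensions).
#' @export
apply_qc_filters <- function(g,
                             locus_call_rate_min = 0.90,
                             maf_min = 0.01,
                             indiv_call_rate_min = 0.85,
                             ohet_bounds = c(0.02, 0.98)) {
  thr <- c(locus_call_rate_min, maf_min, indiv_call_rate_min, ohet_bounds)
  if (any(thr < 0 | thr > 1)) stopf("all QC thresholds must lie in [0, 1]")
  n0 <- nrow(g$dosages); L0 <- ncol(g$dosages)

  st <- compute_locus_stats(g)
  keep1 <- st$call_rate >= locus_call_rate_min
  removed_callrate <- sum(!keep1)

  keep2 <- keep1 & !is.na(st$maf) & st$maf > maf_min
  removed_maf <- sum(keep1) - sum(keep2)

  dos <- g$dosages[, keep2, drop = FALSE]
  if (ncol(dos) == 0) stopf("QC removed all loci")
  ind_rate <- rowMeans(!is.na(dos))
  keep_ind <- ind_rate >= indiv_call_rate_min
  removed_ind <- sum(!keep_ind)
  if (!any(keep_ind)) stopf("QC removed all individuals")
  dos <- dos[keep_ind, , drop = FALSE]

  g2 <- genotype_matrix(dos, sites = g$sites[keep_ind])
  st2 <- compute_locus_stats(g2)
  keep_ohet <- !is.na(st2$ohet) & st2$ohet >= ohet_bounds[1] & st2$ohet <= ohet_bounds[2]
  removed_ohet <- sum(!keep_ohet)
  if (!any(keep_ohet)) stopf("QC removed all loci")
  out <- genotype_matrix(dos[, keep_ohet, drop = FALSE], sites = g$sites[keep_ind])

  attr(out, "qc_report") <- list(
    input = list(individuals = n0, loci = L0),
    loci_removed_call_rate = removed_callrate,
    loci_removed_maf = removed_maf,
    individuals_removed_call_rate = removed_ind,
    loci_removed_ohet = removed_ohet,
    loci_removed = removed_callrate + removed_maf + removed_ohet,
    individuals_removed = removed_ind,
    output = list(individuals = nrow(out$dosages), loci = ncol(out$dosages)),
    thresholds = list(locus_call_rate_min = locus_call_rate_min,
                      maf_min = maf_min,
                      indiv_call_rate_min = indiv_call_rate_min,
                      ohet_bounds = ohet_bounds),
    order = c("locus_call_rate", "maf", "individual_call_rate", "ohet")
  )
  out
}

#' Mean-dosage imputation of missing genotype calls
#'
#' Missing dosages are replaced by the locus mean dosage (twice the
#' estimated allele frequency), the standard behaviour of realized
#' relatedness implementations. The result is a numeric matrix (imputed
#' values are generally fractional).
#'
#' @param g a [genotype_matrix()].
#' @return list with `dosages` (complete numeric matrix),
#'   `individual_ids`, `locus_ids`, `sites`, `n_imputed`.
#' @export
impute_missing <- function(g) {
  dos <- g$dosages
  storage.mode(dos) <- "double"
  n_called <- colSums(!is.na(dos))
  if (any(n_called == 0)) {
    stopf("%d locus/loci with zero calls: filter before imputing", sum(n_called == 0))
  }
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos))
    dos[idx] <- mu[(idx - 1) %/% nrow(dos) + 1]
  }
  list(dosages = dos, individual_ids = g$individual_ids,
       locus_ids = g$locus_ids, sites = g$sites, n_imputed = n_imp)
}
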