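#' Genome-wide realized relatedness matrix (VanRaden method 1)
#'
#' Centres each locus by twice its sample allele frequency and scales the
#' cross-product matrix by a single global denominator:
#' \deqn{G = ZZ' / (2 \sum_k p_k (1 - p_k)),}
#' with allele frequencies estimated from the analysed sample itself.
#' Entries measure excess allele sharing relative to the sample average, so
#' off-diagonal values are frequently negative. Monomorphic loci carry no
#' information and are excluded from both numerator and denominator (their
#' count is recorded).
#'
#' @param g a complete dosage matrix: either the list returned by
#'   [impute_missing()], a [genotype_matrix()] without missing calls, or a
#'   plain numeric matrix (individuals x loci).
#' @return an object of class `relatedness_matrix`: list with `values`
#'   (symmetric n x n matrix), `individual_ids`, `n_loci_used`,
#'   `n_monomorphic`.
#' @export
vanraden_grm <- function(g) {
  dos <- if (is.matrix(g)) g else g$dosages
  ids <- if (is.matrix(g)) rownames(g) %||% paste0("ind", seq_len(nrow(g))) else g$individual_ids
  if (anyNA(dos)) stopf("missing dosages present: impute first")
  if (nrow(dos) < 2) stopf("need at least two individuals")
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  n_mono <- sum(!poly)
  if (!any(poly)) stopf("all loci are monomorphic: relatedness undefined")
  if (n_mono > 0) vlog(sprintf("dropping %d monomorphic locus/loci from the GRM", n_mono))
  Z <- sweep(dos[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, individual_ids = ids,
                 n_loci_used = sum(poly), n_monomorphic = n_mono),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("relatedness_matrix: %d individuals, %d loci used; mean diag %.3f; off-diagonal range [%.3f, %.3f]\n",
              nrow(x$values), x$n_loci_used, mean(diag(x$values)),
              min(off), max(off)))
  invisible(x)
}

#' Summaries of pairwise realized relatedness
#'
#' @param G a `relatedness_matrix`.
#' @param site_labels optional site label per individual (aligned with
#'   `G$individual_ids`); adds within-site summaries.
#' @return list with overall off-diagonal summaries (`min`, `max`, `mean`,
#'   quantiles, `frac_below_0.2`), the diagonal mean, and per-site
#'   summaries when labels are given.
#' @export
relatedness_summary <- function(G, site_labels = NULL) {
  v <- G$values
  off <- v[upper.tri(v)]
  out <- list(
    n = nrow(v),
    mean_diag = mean(diag(v)),
    off = list(min = min(off), max = max(off), mean = mean(off),
               quantiles = quantile(off, c(0.025, 0.25, 0.5, 0.75, 0.975)),
               var = var(off), frac_below_0.2 = mean(off < 0.2))
  )
  if (!is.null(site_labels)) {
    if (length(site_labels) != nrow(v)) stopf("site_labels must align with individuals")
    out$within_site <- lapply(split(seq_len(nrow(v)), site_labels), function(idx) {
      if (length(idx) < 2) return(NULL)
      w <- v[idx, idx][upper.tri(diag(length(idx)))]
      list(min = min(w), max = max(w), mean = mean(w),
           frac_below_0.2 = mean(w < 0.2))
    })
  }
  out
}

#' Ridge-stabilize a relatedness matrix for inversion
#'
#' The animal model needs an invertible additive covariance; duplicated or
#' near-duplicated individuals can make the realized GRM singular. A ridge
#' is added to the diagonal and doubled until the smallest eigenvalue
#' exceeds `tol`.
#'
#' @param G a `relatedness_matrix`.
#' @param ridge initial ridge (default 1e-6).
#' @param tol minimum admissible smallest eigenvalue (default 1e-8).
#' @return the stabilized `relatedness_matrix`; the total ridge applied is
#'   recorded in `$ridge_applied` and the resulting minimum eigenvalue in
#'   `$min_eigenvalue`.
#' @export
stabilize_for_inversion <- function(G, ridge = 1e-6, tol = 1e-8) {
  v <- (G$values + t(G$values)) / 2
  ev_min <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
  applied <- 0
  r <- ridge
  while (ev_min + applied <= tol) {
    applied <- applied + r
    r <- r * 2
  }
  if (applied == 0) applied <- ridge  # always apply at least the base ridge
  v <- v + diag(applied, nrow(v))
  ev_min_new <- ev_min + applied
  G$values <- v
  G$ridge_applied <- applied
  G$min_eigenvalue <- ev_min_new
  G
}

#' Write / read a GRM as a square TSV with ID header row and column
#' @param G a `relatedness_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grm <- function(G, path) {
  dt <- data.table::data.table(individual_id = G$individual_ids)
  dt <- cbind(dt, data.table::as.data.table(G$values))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  ids <- dt[[1]]
  v <- as.matrix(dt[, -1, with = FALSE])
  dimnames(v) <- list(ids, ids)
  structure(list(values = (v + t(v)) / 2, individual_ids = ids,
                 n_loci_used = NA_integer_, n_monomorphic = NA_integer_),
            class = "relatedness_matrix")
}
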