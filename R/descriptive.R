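#' Nested variance partition of a replicated floral trait
#'
#' Moment (expected-mean-squares) decomposition of flower-level variance
#' into site, among-individual-within-site and within-individual
#' components, using the classical unbalanced nested-ANOVA coefficients.
#' Negative moment estimates are truncated at zero and the percentages
#' renormalized to sum to 100. Plants with a single flower record are
#' excluded.
#'
#' @param data flower-level records (`plant_id`, `site`, trait column).
#' @param trait trait column name.
#' @return list with `components` (site, individual, within variances),
#'   `percent` (summing to 100) and the mean squares.
#' @export
partition_trait_variance <- function(data, trait) {
  y <- data[[trait]]
  if (is.null(y)) stopf("trait '%s' not found", trait)
  keep <- ave(seq_along(y), data$plant_id, FUN = length) >= 2
  if (any(!keep)) vlog(sprintf("excluding %d single-replicate record(s)", sum(!keep)))
  y <- y[keep]
  plant <- factor(data$plant_id[keep])
  site <- factor(data$site[keep])
  if (nlevels(site) < 2) stopf("need at least two sites")
  site_of_plant <- site[match(levels(plant), plant)]
  if (min(table(site_of_plant)) < 2) stopf("need at least two plants per site")

  N <- length(y)
  m_j <- as.numeric(table(plant))
  n_s <- as.numeric(table(site))
  q <- nlevels(plant); G <- nlevels(site)

  ybar_p <- tapply(y, plant, mean)
  ybar_s <- tapply(y, site, mean)
  ybar <- mean(y)

  ssw <- sum((y - ybar_p[plant])^2)
  ssp <- sum(m_j * (ybar_p - ybar_s[site_of_plant])^2)
  sss <- sum(n_s * (ybar_s - ybar)^2)
  msw <- ssw / (N - q)
  msp <- ssp / (q - G)
  mss <- sss / (G - 1)

  sum_m2_by_site <- tapply(m_j^2, site_of_plant, sum)
  k1 <- (N - sum(sum_m2_by_site / n_s)) / (q - G)
  k2 <- (sum(sum_m2_by_site / n_s) - sum(m_j^2) / N) / (G - 1)
  k3 <- (N - sum(n_s^2) / N) / (G - 1)

  v_e <- msw
  v_p <- max(0, (msp - msw) / k1)
  v_s <- max(0, (mss - v_e - k2 * v_p) / k3)
  comp <- c(site = v_s, individual = v_p, within = v_e)
  list(components = comp,
       percent = 100 * comp / sum(comp),
       mean_squares = c(site = mss, individual = msp, within = msw))
}

#' Within-plant repeatability of a replicated trait
#'
#' The among-plant fraction of flower-level variance: site plus individual
#' components over the total, in percent. Equals `100 - within%` from
#' [partition_trait_variance()].
#'
#' @inheritParams partition_trait_variance
#' @return repeatability in percent.
#' @export
repeatability <- function(data, trait) {
  p <- partition_trait_variance(data, trait)
  unname(p$percent["site"] + p$percent["individual"])
}

#' Coefficient of variation of plant means
#'
#' `100 * SD / mean` with the sample (n-1) standard deviation.
#'
#' @param plant_means numeric vector of per-plant trait means.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(plant_means) {
  m <- mean(plant_means)
  if (!is.finite(m) || m <= 0) stopf("CV undefined for non-positive mean")
  100 * sd(plant_means) / m
}

#' Phenotypic correlation of plant means between two traits
#'
#' Pearson product-moment correlation with the two-sided t-test p-value.
#'
#' @param x,y equal-length vectors of per-plant trait means (n >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
phenotypic_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stopf("need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pollinator-census visitation summary
#'
#' The visitation rate is the mean over censuses of total visits per
#' surveyed flower; taxon shares are percentages of total visits (rounded
#' to integers); the expected waiting time for one visit to a flower is
#' `duration / rate` converted to hours and rounded to one decimal.
#'
#' @param censuses `data.frame` with `site`, `census_id`, `duration_min`,
#'   `flowers_surveyed`, `taxon`, `visits` (one row per census x taxon).
#' @return list with `n_censuses`, `total_visits`, `flowers_surveyed`,
#'   `rate_per_flower_per_census`, `visit_share_pct` (named, rounded),
#'   `waiting_time_h`, and per-site rates.
#' @export
visitation_summary <- function(censuses) {
  need <- c("site", "census_id", "duration_min", "flowers_surveyed", "taxon", "visits")
  stopifnot(all(need %in% names(censuses)))
  per_census <- aggregate(cbind(visits = censuses$visits),
                          by = list(census_id = censuses$census_id), sum)
  fl <- unique(censuses[c("census_id", "flowers_surveyed", "duration_min", "site")])
  per_census <- merge(per_census, fl, by = "census_id")
  if (any(per_census$flowers_surveyed <= 0)) stopf("census with zero flowers surveyed")
  rate <- mean(per_census$visits / per_census$flowers_surveyed)
  duration <- per_census$duration_min[1]
  total <- sum(censuses$visits)
  by_taxon <- tapply(censuses$visits, censuses$taxon, sum)
  share <- if (total > 0) round(100 * by_taxon / total) else by_taxon * NA
  site_rate <- tapply(per_census$visits / per_census$flowers_surveyed,
                      per_census$site, mean)
  list(n_censuses = nrow(per_census),
       total_visits = total,
       flowers_surveyed = sum(per_census$flowers_surveyed),
       rate_per_flower_per_census = rate,
       visit_share_pct = share,
       waiting_time_h = if (rate > 0) round(duration / rate / 60, 1) else Inf,
       rate_by_site = site_rate)
}

#' Expected waiting time for one visit to a flower
#'
#' Converts a per-flower visitation rate observed in censuses of a given
#' duration into the expected time until a flower receives one visit, in
#' hours, rounded to one decimal.
#'
#' @param rate visits per flower per census.
#' @param duration_min census duration in minutes (default 3).
#' @return hours, one decimal.
#' @export
waiting_time_hours <- function(rate, duration_min = 3) {
  if (rate <= 0) return(Inf)
  round(duration_min / rate / 60, 1)
}
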