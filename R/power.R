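#' GREML power to detect SNP heritability
#'
#' Sampling-variance approximation for a GREML heritability estimate from
#' unrelated (or weakly related) individuals:
#' \deqn{se(\hat h^2) = \sqrt{2 / (n^2 \, var_{rel})},}
#' where `var_rel` is the variance of the off-diagonal relatedness. The
#' test statistic is non-central chi-squared with one degree of freedom and
#' non-centrality `(h2 / se)^2`. The conventional unrelated-sample value
#' `var_rel = 2e-5` is the default; when the study sample contains
#' relatives, pass the empirical off-diagonal variance of the GRM
#' (`var_rel = "auto"` with a `grm`), which raises power.
#'
#' @param n number of individuals.
#' @param h2 hypothesized heritability in [0, 1].
#' @param var_rel variance of pairwise relatedness, or `"auto"` to compute
#'   it from `grm`.
#' @param alpha significance level.
#' @param grm optional `relatedness_matrix` used when `var_rel = "auto"`.
#' @param one_sided use a one-sided normal approximation instead of the
#'   chi-squared test.
#' @return list with `se_h2`, `ncp`, `power`, `var_rel`.
#' @export
greml_power_h2 <- function(n, h2, var_rel = 2e-5, alpha = 0.05,
                           grm = NULL, one_sided = FALSE) {
  if (h2 < 0 || h2 > 1) stopf("h2 must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (identical(var_rel, "auto")) {
    if (is.null(grm)) stopf("var_rel = 'auto' requires a relatedness matrix")
    off <- grm$values[upper.tri(grm$values)]
    var_rel <- var(off)
  }
  if (var_rel <= 0) stopf("var_rel must be > 0")
  se <- sqrt(2 / (n^2 * var_rel))
  ncp <- (h2 / se)^2
  power <- if (one_sided) {
    pnorm(qnorm(1 - alpha), mean = h2 / se, lower.tail = FALSE)
  } else {
    pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
  }
  list(se_h2 = se, ncp = ncp, power = power, var_rel = var_rel)
}

#' GREML power to detect a genetic correlation (overlapping samples)
#'
#' Delta-method sampling variance for the genetic-correlation estimate
#' `rg = cov_g / sqrt(h2_1 h2_2)` from a bivariate GREML analysis in which
#' the same individuals are measured for both traits. The (co)variance
#' estimates have sampling (co)variances
#' `var(h2_t) = 2/(n^2 v)`, `var(cov_g) = (1 + rp^2)/(n^2 v)`,
#' `cov(h2_1, h2_2) = 2 rp^2/(n^2 v)`, `cov(h2_t, cov_g) = 2 rp/(n^2 v)`
#' with `v = var_rel` and `rp` the phenotypic correlation. Power is a
#' two-sided normal test at `alpha` (equals `alpha` exactly at `rg = 0`).
#'
#' @param n number of individuals (measured for both traits).
#' @param h2_1,h2_2 heritabilities of the two traits (both > 0).
#' @param rg hypothesized genetic correlation in [-1, 1].
#' @param rp phenotypic correlation between the traits (defaults to
#'   `rg * sqrt(h2_1 * h2_2)`, the genetic contribution alone).
#' @param var_rel variance of pairwise relatedness.
#' @param alpha significance level.
#' @return list with `se_rg`, `power`.
#' @export
greml_power_rg <- function(n, h2_1, h2_2, rg, rp = NULL,
                           var_rel = 2e-5, alpha = 0.05) {
  if (abs(rg) > 1) stopf("rg must be in [-1, 1]")
  if ((h2_1 <= 0 || h2_2 <= 0) && rg != 0) {
    stopf("genetic correlation undefined when a heritability is zero")
  }
  h2_1 <- max(h2_1, 1e-12); h2_2 <- max(h2_2, 1e-12)
  if (is.null(rp)) rp <- rg * sqrt(h2_1 * h2_2)
  base <- 1 / (n^2 * var_rel)
  cg <- rg * sqrt(h2_1 * h2_2)
  v_h1 <- 2 * base; v_h2 <- 2 * base
  v_cg <- (1 + rp^2) * base
  c_h1h2 <- 2 * rp^2 * base
  c_h1cg <- 2 * rp * base * sqrt(h2_1 * h2_2) / max(sqrt(h2_1 * h2_2), 1e-12)
  c_h2cg <- c_h1cg
  d_cg <- 1 / sqrt(h2_1 * h2_2)
  d_h1 <- -rg / (2 * h2_1)
  d_h2 <- -rg / (2 * h2_2)
  v_rg <- d_cg^2 * v_cg + d_h1^2 * v_h1 + d_h2^2 * v_h2 +
    2 * d_cg * d_h1 * c_h1cg + 2 * d_cg * d_h2 * c_h2cg +
    2 * d_h1 * d_h2 * c_h1h2
  se <- sqrt(max(v_rg, 0))
  z <- qnorm(1 - alpha / 2)
  power <- pnorm(-z, mean = rg / se) + pnorm(z, mean = rg / se, lower.tail = FALSE)
  list(se_rg = se, power = power)
}
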