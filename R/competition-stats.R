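# Sperm-competition and fertility-phenotype statistics: chi-squared
# goodness of fit of offspring paternity counts against an expected sperm-
# mix ratio, Wilson intervals for sired fractions, the litter-size trend
# against the number of miRNAs inactivated, and paired rate comparisons.

#' Construct a competition assay record
#'
#' @param counts length-2 integer vector: offspring sired by genotype A and
#'   genotype B.
#' @param ratio expected mix ratio (A:B), default 1:1.
#' @param type assay type: sequential mating, mixed-sperm IVF, or
#'   co-artificial-insemination. Sequential-mating assays are analyzed
#'   identically but tagged, since first-male advantage is reported
#'   descriptively.
#' @param replicate optional replicate id.
#' @return a `competition_assay`.
#' @export
competition_assay <- function(counts, ratio = c(1, 1),
                              type = c("mixed_IVF", "sequential_mating",
                                       "co_AI"),
                              replicate = NA_character_) {
  type <- match.arg(type)
  counts <- as.integer(counts)
  if (length(counts) != 2 || any(counts < 0) || sum(counts) == 0) {
    stop("counts must be two nonnegative integers, not both zero")
  }
  if (length(ratio) != 2 || any(ratio <= 0)) {
    stop("expected ratio components must be positive")
  }
  structure(list(counts = counts, ratio = ratio, type = type,
                 replicate = replicate),
            class = "competition_assay")
}

#' Reconstruct integer counts from a printed percentage and total
#'
#' Nearest-integer rounding of pct% of n for genotype A, with the remainder
#' to genotype B; verifies sum preservation. Useful for re-testing printed
#' summary values.
#'
#' @param pct percentage sired by genotype A (0-100).
#' @param n total offspring.
#' @return length-2 integer vector (A, B).
#' @export
counts_from_percent <- function(pct, n) {
  if (pct < 0 || pct > 100) stop("pct must lie in [0, 100]")
  a <- as.integer(round(pct / 100 * n))
  out <- c(a, as.integer(n) - a)
  stopifnot(sum(out) == n)
  out
}

#' Chi-squared goodness of fit of paternity counts
#'
#' Pearson goodness of fit of the observed two-genotype offspring counts
#' against the expected mix ratio; df = 1; no continuity correction (with
#' the assay sizes in view the correction is immaterial, and plain Pearson
#' is the common default). An exact binomial test is available behind
#' `exact = TRUE` and is advised when an expected count falls below 1.
#'
#' @param assay a `competition_assay` (or length-2 counts).
#' @param ratio expected ratio when raw counts are given.
#' @param exact use an exact binomial test instead.
#' @return list: statistic, df, p.value, expected, method.
#' @export
paternity_gof <- function(assay, ratio = c(1, 1), exact = FALSE) {
  if (!inherits(assay, "competition_assay")) {
    assay <- competition_assay(assay, ratio = ratio)
  }
  obs <- assay$counts
  pr <- assay$ratio / sum(assay$ratio)
  expected <- sum(obs) * pr
  if (exact) {
    bt <- stats::binom.test(obs[1], sum(obs), p = pr[1])
    return(list(statistic = NA_real_, df = NA_real_, p.value = bt$p.value,
                expected = expected, method = "exact binomial"))
  }
  if (any(expected < 1)) {
    warning("expected count below 1; exact test advised")
  }
  stat <- sum((obs - expected)^2 / expected)
  list(statistic = stat, df = 1L, p.value = pchisq(stat, 1,
                                                   lower.tail = FALSE),
       expected = expected, method = "pearson chi-squared")
}

#' Fraction sired by genotype A with a 95% Wilson score interval
#'
#' @param assay a `competition_assay` (or length-2 counts).
#' @param conf_level confidence level (default 0.95).
#' @return list: fraction, lower, upper, n.
#' @export
paternity_fraction_ci <- function(assay, conf_level = 0.95) {
  if (!inherits(assay, "competition_assay")) {
    assay <- competition_assay(assay)
  }
  x <- assay$counts[1]; n <- sum(assay$counts)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(fraction = p, lower = max(0, centre - half),
       upper = min(1, centre + half), n = n)
}

#' Litter-size trend against the number of miRNAs inactivated
#'
#' Ordinary least squares of mean litter size per genotype on the number of
#' family miRNAs inactivated, with R-squared and the F test for the slope.
#'
#' @param n_mirnas_inactivated numeric vector, one entry per genotype.
#' @param litter_sizes numeric vector of mean litter sizes (same length),
#'   or a list of per-genotype observations (averaged first).
#' @return list: slope, intercept, r.squared, f.statistic, p.value.
#' @export
litter_trend <- function(n_mirnas_inactivated, litter_sizes) {
  if (is.list(litter_sizes)) {
    litter_sizes <- vapply(litter_sizes, mean, numeric(1))
  }
  x <- as.numeric(n_mirnas_inactivated); y <- as.numeric(litter_sizes)
  if (length(unique(x)) < 3) stop("at least 3 distinct x values required")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = sm$r.squared,
       f.statistic = unname(fstat[1]),
       p.value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)))
}

#' Paired comparison of per-replicate rates
#'
#' Paired t-test on per-replicate rate differences, with a Wilcoxon
#' signed-rank test reported as a sensitivity analysis. All-identical pairs
#' give t = 0, p = 1; nonzero constant differences (zero variance) yield an
#' explicit degenerate status.
#'
#' @param rate_a,rate_b numeric vectors of paired rates.
#' @return list: mean_diff, statistic, p.value, wilcoxon_p, status.
#' @export
rate_compare <- function(rate_a, rate_b) {
  if (length(rate_a) != length(rate_b) || length(rate_a) < 2) {
    stop("at least 2 paired replicates required")
  }
  d <- rate_a - rate_b
  if (sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (all(abs(d) < 1e-12)) {
      return(list(mean_diff = 0, statistic = 0, p.value = 1,
                  wilcoxon_p = 1, status = "ok"))
    }
    return(list(mean_diff = mean(d), statistic = NA_real_,
                p.value = NA_real_, wilcoxon_p = NA_real_,
                status = "degenerate: zero variance of differences"))
  }
  tt <- t.test(rate_a, rate_b, paired = TRUE)
  wt <- suppressWarnings(wilcox.test(rate_a, rate_b, paired = TRUE))
  list(mean_diff = mean(d), statistic = unname(tt$statistic),
       p.value = tt$p.value, wilcoxon_p = wt$p.value, status = "ok")
}
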