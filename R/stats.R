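#' Two-factor repeated-measures ANOVA
#'
#' Classical fully-within-subject decomposition for a balanced two-factor
#' design: cell values are first averaged per participant x factor1 x
#' factor2, then each effect is tested against its own effect-by-participant
#' interaction (via `stats::aov` with an
#' `Error(participant/(factor1 * factor2))` stratum). No sphericity
#' correction is applied — degrees of freedom are the classical ones, e.g.
#' (1, n-1) for a two-level factor and (2, 2(n-1)) for a three-level factor.
#'
#' @param data A tibble in long format.
#' @param dv Name of the dependent-variable column (string).
#' @param participant Name of the participant id column.
#' @param factor1,factor2 Names of the two within-subject factor columns.
#' @return A tibble with one row per effect (`factor1`, `factor2`,
#'   `factor1:factor2`): `effect`, `F`, `df_num`, `df_den`, `p`.
#' @export
rm_anova_2way <- function(data, dv, participant = "participant",
                          factor1, factor2) {
  stopifnot(all(c(dv, participant, factor1, factor2) %in% names(data)))
  d <- data |>
    dplyr::group_by(.data[[participant]], .data[[factor1]],
                    .data[[factor2]]) |>
    dplyr::summarise(.y = mean(.data[[dv]]), .groups = "drop") |>
    dplyr::rename(.id = 1, .f1 = 2, .f2 = 3)
  d$.id <- factor(d$.id); d$.f1 <- factor(d$.f1); d$.f2 <- factor(d$.f2)
  counts <- table(d$.id, d$.f1, d$.f2)
  if (any(counts != 1))
    stop("design is not complete and balanced: every participant needs ",
         "exactly one value per factor combination")
  fit <- aov(.y ~ .f1 * .f2 + Error(.id / (.f1 * .f2)), data = d)
  sm <- summary(fit)
  pull_effect <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab)                       # Residuals row
    ss_eff <- tab[i, "Sum Sq"]
    # numerically zero effect sums of squares (e.g. identical cell values)
    # are reported as F = 0 rather than a 0/0 artefact
    if (ss_eff < 1e-10 * max(1, sum(tab[, "Sum Sq"]))) {
      return(tibble::tibble(F = 0, df_num = tab[i, "Df"],
                            df_den = tab[err, "Df"], p = 1))
    }
    tibble::tibble(F = tab[i, "F value"],
                   df_num = tab[i, "Df"], df_den = tab[err, "Df"],
                   p = tab[i, "Pr(>F)"])
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(pull_effect("Error: .id:.f1", ".f1"),
                  effect = factor1, .before = 1),
    dplyr::mutate(pull_effect("Error: .id:.f2", ".f2"),
                  effect = factor2, .before = 1),
    dplyr::mutate(pull_effect("Error: .id:.f1:.f2", ".f1:.f2"),
                  effect = paste0(factor1, ":", factor2), .before = 1))
  out
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test on the element-wise differences, reporting
#' Cohen's d for paired designs, `d = t / sqrt(n)` (the mean difference in
#' units of its SD). Optionally appends the JZS Bayes factor.
#'
#' @param x,y Paired numeric vectors.
#' @param bayes Logical: also compute `bf10` via [bf10_ttest()].
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return A one-row tibble: `t`, `df`, `p`, `cohens_d`, `mean_diff`, and
#'   `bf10` when requested.
#' @examples
#' paired_t(c(1, 2, 3, 5), c(0, 1, 2, 3))
#' @export
paired_t <- function(x, y, bayes = FALSE, prior_scale = 0.707) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0)
    stop("zero variance of the paired differences: t undefined")
  tt <- t.test(x, y, paired = TRUE)
  n <- length(x)
  out <- tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                        p = tt$p.value, cohens_d = unname(tt$statistic) / sqrt(n),
                        mean_diff = unname(tt$estimate))
  if (bayes)
    out$bf10 <- bf10_ttest(out$t, n, prior_scale)
  out
}

#' Cohen's d implied by a paired t statistic
#'
#' For a paired design, `d = t / sqrt(n)`: the mean difference expressed in
#' units of the difference SD. Useful for recovering effect sizes from
#' reported test statistics.
#'
#' @param t Observed paired t statistic.
#' @param n Number of pairs.
#' @return Cohen's d.
#' @examples
#' paired_t_effect_size(2.76, 23)   # ~ 0.6
#' @export
paired_t_effect_size <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Default Bayesian t-test of Rouder et al. (2009): the alternative places a
#' Cauchy prior of scale `prior_scale` on the standardised effect size, and
#' the Bayes factor against the point null is computed by numerically
#' integrating the marginal likelihood over the Cauchy prior (equivalently,
#' over `g` with an inverse-gamma(1/2, prior_scale^2 / 2) mixing density).
#' `prior_scale = 0.707` is the conventional medium width.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design); `df = n - 1`.
#' @param prior_scale Cauchy prior scale (> 0).
#' @return BF10, the evidence for the alternative over the null.
#' @examples
#' bf10_ttest(2.76, 23)   # ~ 4.4
#' @export
bf10_ttest <- function(t, n, prior_scale = 0.707) {
  stopifnot(n >= 2, prior_scale > 0)
  nu <- n - 1
  r <- prior_scale
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      r / sqrt(2 * pi) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }
  m1 <- integrate(integrand, 0, Inf, rel.tol = 1e-10)
  if (m1$message != "OK")
    stop("numerical integration failed: ", m1$message)
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  m1$value / m0
}

# Gauss hypergeometric 2F1(a, b; c; z) by series, |z| < 1
hyp2f1 <- function(a, b, c, z, tol = 1e-12, max_iter = 10000L) {
  term <- 1
  total <- 1
  for (k in 0:(max_iter - 1L)) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) return(total)
  }
  stop("hypergeometric series did not converge")
}

# Sampling density of Pearson r given population rho, up to rho-free factors
cor_lik_kernel <- function(rho, r, n) {
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 3 / 2)) *
    vapply(rho, function(p) hyp2f1(0.5, 0.5, n - 0.5, (p * r + 1) / 2),
           numeric(1))
}

#' Bayes factor for a Pearson correlation
#'
#' Tests rho = 0 against a stretched-beta prior on rho: `rho = 2u - 1`,
#' `u ~ Beta(1/scale, 1/scale)`, so smaller `prior_scale` concentrates the
#' prior near zero; `prior_scale = 0.333` is the conventional medium width.
#' The marginal likelihood uses the exact sampling density of the observed
#' correlation (via the Gauss hypergeometric function) integrated over the
#' prior.
#'
#' @param r_obs Observed Pearson correlation, `|r_obs| < 1`.
#' @param n Number of pairs (>= 3).
#' @param prior_scale Stretched-beta prior scale (> 0).
#' @return BF10.
#' @export
bf10_correlation <- function(r_obs, n, prior_scale = 0.333) {
  stopifnot(abs(r_obs) < 1, n >= 3, prior_scale > 0)
  alpha <- 1 / prior_scale
  log_norm <- lbeta(alpha, alpha) + (2 * alpha - 1) * log(2)
  prior <- function(rho) exp((alpha - 1) * log1p(-rho^2) - log_norm)
  m1 <- integrate(function(rho) cor_lik_kernel(rho, r_obs, n) * prior(rho),
                  -1, 1, rel.tol = 1e-9)
  if (m1$message != "OK")
    stop("numerical integration failed: ", m1$message)
  m1$value / cor_lik_kernel(0, r_obs, n)
}

#' Deming (errors-in-variables) regression
#'
#' Fits the line minimising the sum of squared distances measured
#' perpendicular to the line under the assumed ratio of error variances
#' `variance_ratio = var(error in y) / var(error in x)` (default 1:
#' orthogonal regression). Unlike ordinary least squares it treats both
#' variables as noisy, so swapping x and y (at ratio 1) gives the inverse
#' line.
#'
#' @param x,y Numeric vectors.
#' @param variance_ratio Assumed error-variance ratio (default 1).
#' @return A one-row tibble: `slope`, `intercept`, `variance_ratio`, `n`.
#' @export
deming_fit <- function(x, y, variance_ratio = 1) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(n >= 2, variance_ratio > 0)
  sxx <- sum((x - mean(x))^2) / (n - 1)
  syy <- sum((y - mean(y))^2) / (n - 1)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  if (sxx == 0 && syy == 0)
    stop("both variables are constant: line undefined")
  lam <- variance_ratio
  slope <- if (sxy == 0) {
    if (syy >= lam * sxx) Inf else 0
  } else {
    (syy - lam * sxx + sqrt((syy - lam * sxx)^2 + 4 * lam * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(y) - slope * mean(x)
  tibble::tibble(slope = slope, intercept = intercept,
                 variance_ratio = variance_ratio, n = n)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the values with replacement `reps` times, recomputes the
#' statistic, and returns the percentile interval of the resampled
#' distribution. Deterministic under `seed`.
#'
#' @param values Numeric vector.
#' @param statistic Function of a numeric vector (default `mean`).
#' @param reps Bootstrap repetitions (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A one-row tibble: `estimate`, `lo`, `hi`, `level`, `reps`.
#' @export
bootstrap_ci <- function(values, statistic = mean, reps = 10000L,
                         level = 0.95, seed = 1L) {
  stopifnot(length(values) >= 1)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(reps),
           function(i) statistic(sample(values, length(values),
                                        replace = TRUE)),
           numeric(1))
  })
  qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(estimate = statistic(values), lo = qs[1], hi = qs[2],
                 level = level, reps = reps)
}

#' Pearson correlation with Bayes factor
#'
#' @param x,y Numeric vectors.
#' @param prior_scale Prior scale for [bf10_correlation()].
#' @return A one-row tibble: `r`, `n`, `p` (two-sided), `bf10`.
#' @export
correlation_test <- function(x, y, prior_scale = 0.333) {
  keep <- complete.cases(x, y)
  ct <- stats::cor.test(x[keep], y[keep])
  tibble::tibble(r = unname(ct$estimate), n = sum(keep), p = ct$p.value,
                 bf10 = bf10_correlation(unname(ct$estimate), sum(keep),
                                         prior_scale))
}
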