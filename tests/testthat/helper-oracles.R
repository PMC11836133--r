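# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementation.

# Brute-force within-subject two-way ANOVA from raw sums of squares
anova2_bruteforce <- function(y, id, f1, f2) {
  id <- factor(id); f1 <- factor(f1); f2 <- factor(f2)
  g <- mean(y)
  m_id <- tapply(y, id, mean); m_1 <- tapply(y, f1, mean)
  m_2 <- tapply(y, f2, mean)
  m_12 <- tapply(y, interaction(f1, f2), mean)
  m_i1 <- tapply(y, interaction(id, f1), mean)
  m_i2 <- tapply(y, interaction(id, f2), mean)
  n <- nlevels(id); a <- nlevels(f1); b <- nlevels(f2)
  ss1 <- n * b * sum((m_1 - g)^2)
  ss2 <- n * a * sum((m_2 - g)^2)
  ss12 <- n * sum((m_12 - g)^2) - ss1 - ss2
  ss_id <- a * b * sum((m_id - g)^2)
  ss_i1 <- b * sum((m_i1 - g)^2) - ss1 - ss_id
  ss_i2 <- a * sum((m_i2 - g)^2) - ss2 - ss_id
  ss_tot <- sum((y - g)^2)
  ss_i12 <- ss_tot - ss_id - ss1 - ss2 - ss12 - ss_i1 - ss_i2
  f_of <- function(ss_eff, df_eff, ss_err, df_err)
    (ss_eff / df_eff) / (ss_err / df_err)
  list(
    F1 = f_of(ss1, a - 1, ss_i1, (a - 1) * (n - 1)),
    F2 = f_of(ss2, b - 1, ss_i2, (b - 1) * (n - 1)),
    F12 = f_of(ss12, (a - 1) * (b - 1), ss_i12, (a - 1) * (b - 1) * (n - 1)))
}

# Deming slope by direct numerical minimisation of ratio-weighted
# perpendicular squared distances (intercept profiled out)
deming_bruteforce <- function(x, y, lambda = 1) {
  obj <- function(bb) {
    a <- mean(y) - bb * mean(x)
    sum((y - a - bb * x)^2) / (lambda + bb^2)
  }
  stats::optimize(obj, c(-100, 100), tol = 1e-12)$minimum
}

# JZS t-test Bayes factor by the alternative route: Cauchy prior on the
# standardised effect, marginal likelihood via the noncentral t density
bf10_ttest_ncp <- function(t, n, r = 0.707) {
  nu <- n - 1
  num <- suppressWarnings(stats::integrate(function(d)
    stats::dt(t, nu, ncp = d * sqrt(n)) * stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-9)$value)
  num / stats::dt(t, nu)
}

# Small deterministic trial table for psychometric / scoring tests
make_scored_block <- function(pse = 0, sigma = 4, mismatches = c(-12, -6, -3, 3, 6, 12),
                              n_rep = 50, seed = 1) {
  withr::with_seed(seed, {
    mm <- rep(mismatches, each = n_rep)
    p <- pnorm((mm - pse) / sigma)
    resp <- ifelse(runif(length(mm)) < p, "felt_larger", "felt_smaller")
    tibble::tibble(participant = 1L, schedule_kind = "abrupt",
                   magnitude = 12, trial = seq_along(mm),
                   mismatch_mm = mm, response = resp)
  })
}
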