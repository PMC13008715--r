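# Independent straight-line re-evaluation of the four printed statistics,
# kept deliberately separate from the package's vectorized implementations:
# scalar arithmetic only, no shared code.

oracle_stats <- function(a, b, c, d,
                         alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                         gamma11 = 1) {
  n <- a + b + c + d

  ror <- (a * d) / (b * c)
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror_low <- exp(log(ror) - 1.96 * se_ror)
  ror_high <- exp(log(ror) + 1.96 * se_ror)

  prr <- (a * (c + d)) / (c * (a + b))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  prr_low <- exp(log(prr) - 1.96 * se_prr)
  prr_high <- exp(log(prr) + 1.96 * se_prr)

  dev <- abs(a * d - b * c) - n / 2
  if (dev < 0) dev <- 0
  chi2 <- n * dev * dev / ((a + b) * (c + d) * (a + c) * (b + d))

  ic <- log2(a * n / ((a + b) * (a + c)))
  gam <- gamma11 * (n + alpha) * (n + beta) / ((a + b + alpha1) * (a + c + beta1))
  e_ic <- log2(((a + gamma11) * (n + alpha) * (n + beta)) /
                 ((n + gam) * (a + b + alpha1) * (a + c + beta1)))
  v_ic <- (1 / (log(2)^2)) * (
    (n - a + gam - gamma11) / ((a + gamma11) * (1 + n + gam)) +
      (n - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
      (n - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + n + beta)))
  ic025 <- e_ic - 2 * sqrt(v_ic)

  ebgm <- a * n / ((a + c) * (a + b))
  ebgm05 <- exp(log(ebgm) - 1.96 * se_ror)
  ebgm95 <- exp(log(ebgm) + 1.96 * se_ror)

  c(ror = ror, ror_low = ror_low, ror_high = ror_high,
    prr = prr, prr_low = prr_low, prr_high = prr_high,
    chi2 = chi2,
    ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = ic025,
    ebgm = ebgm, ebgm05 = ebgm05, ebgm95 = ebgm95)
}

# Random strictly-positive 2x2 tables for property tests.
random_tables <- function(n, max_cell = 100, seed = 42) {
  withr::with_seed(seed, {
    data.frame(a = sample(1:max_cell, n, TRUE), b = sample(1:max_cell, n, TRUE),
               c = sample(1:max_cell, n, TRUE), d = sample(1:max_cell, n, TRUE))
  })
}

rel_err <- function(x, y) {
  abs(x - y) / pmax(abs(y), .Machine$double.eps)
}
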