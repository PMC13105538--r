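# Independent brute-force transliterations of the disproportionality
# closed forms, coded separately from the package implementation.

oracle_prr <- function(n11, n10, n01, n00) {
  (n11 / (n11 + n10)) / (n01 / (n01 + n00))
}

oracle_chi2 <- function(n11, n10, n01, n00, yates = FALSE) {
  nn <- n11 + n10 + n01 + n00
  corr <- if (yates) nn / 2 else 0
  num <- abs(n11 * n00 - n10 * n01) - corr
  if (num < 0) num <- 0
  nn * num^2 /
    ((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

oracle_ror <- function(n11, n10, n01, n00) {
  est <- (n11 * n00) / (n10 * n01)
  se <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
  c(est = est, lo = exp(log(est) - 1.96 * se),
    hi = exp(log(est) + 1.96 * se))
}

# random strictly-positive 2x2 tables
random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(a = sample(1:500, n, TRUE), b = sample(1:500, n, TRUE),
             c = sample(1:500, n, TRUE), d = sample(1:500, n, TRUE))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
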