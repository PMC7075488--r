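# Shared fixtures, built in code.

# K x K correlation matrix with constant off-diagonal rbar
const_corr <- function(k, rbar) {
  r <- matrix(rbar, k, k)
  diag(r) <- 1
  r
}

# the tau-equivalent population quantities used throughout: lambda = 0.70,
# K = 3 per factor
tau_alpha <- function() 3 * 0.49 / (1 + 2 * 0.49)           # 0.742424...
tau_r_pop <- function(phi) phi * tau_alpha()                # alpha * phi

tau_model <- function(phi) factor_model(rep(0.7, 3), rep(0.7, 3), phi)

# pooled-variance two-sample t, written independently of stats::t.test,
# as a brute-force oracle
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# brute-force Pearson chi-square from first principles
chisq_oracle <- function(x) {
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  sum((x - e)^2 / e)
}
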