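# Convergence diagnostics for the independence sampler.
#
# split_rhat: classic potential scale reduction computed on split chains
# (each chain halved), guarding against within-chain trends.
# ess_basic: multi-chain effective sample size from the pooled
# autocorrelation function with Geyer's initial-positive-sequence
# truncation.

split_rhat <- function(draws) {
  # draws: iterations x chains matrix for one parameter
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split); len <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- len * var(means)
  if (W <= 0) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

ess_basic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  max_lag <- min(n - 1, 200)
  rho <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    a <- acf(draws[, j], lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    rho[, j] <- a
  }
  rho_mean <- rowMeans(rho)
  # Geyer: sum paired autocorrelations while positive
  tau <- 1
  k <- 1
  while (k + 1 <= max_lag) {
    pair <- rho_mean[k + 1] + rho_mean[k + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, (n * m) / tau)
}
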