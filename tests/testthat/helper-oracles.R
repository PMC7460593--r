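# Independent oracles used across tests.

# Brute-force loop version of the dose-averaged LET (never calls the
# package's vectorised implementation).
letd_loop_oracle <- function(let, weight) {
  num <- 0
  den <- 0
  for (i in seq_along(let)) {
    num <- num + let[i] * weight[i]
    den <- den + weight[i]
  }
  num / den
}

# Random small LET spectrum for property tests.
random_spectrum <- function(n = NULL) {
  n <- n %||% sample(1:50, 1)
  let_spectrum("protons", let = runif(n, 0.1, 120),
               dose_weight = runif(n, 0, 10) + 1e-6)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Permutation test of a mean difference (two-sided), used to cross-check
# the rejection direction of the t-based procedure.
permutation_p <- function(x, y, n_perm = 400) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  n_x <- length(x)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), n_x)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Noiseless survival observations from known LQ parameters.
exact_lq_observations <- function(alpha, beta, doses = c(0, 1, 3, 5)) {
  survival_observations(doses, exp(-alpha * doses - beta * doses^2))
}
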