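# Fixtures used across the suite: small parameter constructors and a
# generator of random stable linear systems for the covariance oracles.

fig2_params <- function() cerna_preset("fig2")$params

# fully decoupled network: no miRNA-ceRNA binding
decoupled_params <- function(b1 = 100, b2 = 100, beta = 100) {
  cerna_params(b1 = b1, b2 = b2, beta = beta,
               kplus1 = 0, kplus2 = 0,
               kminus1 = 0, kminus2 = 0,
               kappa1 = 0, kappa2 = 0,
               sigma1 = 1, sigma2 = 1)
}

# random stable (A, Gamma) pair: A = -(M M^T + eps I) is symmetric negative
# definite plus an antisymmetric part to exercise complex spectra; Gamma is
# a random PSD matrix
random_stable_system <- function(n = 5) {
  M <- matrix(rnorm(n * n), n)
  A <- -(M %*% t(M) + diag(n) * 0.5)
  S <- matrix(rnorm(n * n), n)
  A <- A + (S - t(S)) / 2
  G0 <- matrix(rnorm(n * n), n)
  Gamma <- G0 %*% t(G0) + diag(n) * 0.1
  list(A = A, Gamma = Gamma)
}

# synthetic response curve with prescribed mean/variance laws, bypassing the
# simulator: used to test the capacity machinery against closed forms
synthetic_curve <- function(f, m2, var_m2, channel = "tf",
                            estimator = "lna") {
  structure(data.frame(f = f, n = NA_real_, m2 = m2, var_m2 = var_m2),
            class = c("cerna_response", "data.frame"),
            channel = channel, estimator = estimator, fixed = NULL)
}
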