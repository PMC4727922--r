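#' Jacobian of the deterministic drift at the steady state
#'
#' Analytic 5x5 Jacobian `A = dg/dx` of the mass-action drift of the species
#' `(m1, m2, mu, c1, c2)`, evaluated at a steady state. All eigenvalues have
#' negative real part at a stable steady state.
#'
#' @param params a [cerna_params()] object.
#' @param ss a [steady_state()] object.
#' @return 5x5 matrix with species dimnames.
#' @export
lna_jacobian <- function(params, ss) {
  stopifnot(inherits(params, "cerna_params"),
            inherits(ss, "cerna_steady_state"))
  m1 <- ss$m1; m2 <- ss$m2; mu <- ss$mu
  k1p <- params$kplus1; k2p <- params$kplus2
  k1m <- params$kminus1; k2m <- params$kminus2
  A <- rbind(
    c(-params$d1 - k1p * mu, 0, -k1p * m1, k1m, 0),
    c(0, -params$d2 - k2p * mu, -k2p * m2, 0, k2m),
    c(-k1p * mu, -k2p * mu, -params$delta - k1p * m1 - k2p * m2,
      k1m + params$kappa1, k2m + params$kappa2),
    c(k1p * mu, 0, k1p * m1, -(params$sigma1 + k1m + params$kappa1), 0),
    c(0, k2p * mu, k2p * m2, 0, -(params$sigma2 + k2m + params$kappa2)))
  dimnames(A) <- list(.species, .species)
  A
}

#' Diffusion matrix of the chemical Langevin noise
#'
#' Assembles the 5x5 diffusion matrix `Gamma` with
#' `<eta_a(t) eta_b(t')> = Gamma_ab delta(t - t')` from the independent
#' Poisson noise channels of the network: each of the 14 elementary reactions
#' contributes its stationary propensity times the outer product of its
#' stoichiometry vector,
#' \deqn{\Gamma = \sum_r a_r(\bar x)\, s_r s_r^\top.}
#' Reactions sharing species produce the off-diagonal (cross-species)
#' entries; e.g. the association channel enters `m1` and `mu` with sign -1
#' and `c1` with +1, giving `Gamma[m1, c1] = -k1+ m1 mu - k1- c1` together
#' with the dissociation channel.
#'
#' @inheritParams lna_jacobian
#' @return Symmetric positive semidefinite 5x5 matrix (molecules^2/min).
#' @export
lna_diffusion <- function(params, ss) {
  stopifnot(inherits(params, "cerna_params"),
            inherits(ss, "cerna_steady_state"))
  rs <- reaction_system(params, ss$occupancy)
  a <- rs$propensity(as.numeric(ss))
  S <- rs$stoich
  G <- crossprod(S * sqrt(a)) # sum_r a_r s_r s_r^T
  dimnames(G) <- list(.species, .species)
  (G + t(G)) / 2
}

#' Stationary covariance via the spectral (eigendecomposition) formula
#'
#' Solves the stationary fluctuation problem by diagonalising the Jacobian,
#' `A = B diag(lambda) B^{-1}`, and assembling
#' \deqn{C_{ab} = -\sum_{p,q,r,s} B_{ap} B_{br}
#'   \frac{\Gamma_{qs}}{\lambda_p + \lambda_r} (B^{-1})_{pq} (B^{-1})_{rs}.}
#' Requires a stable, diagonalisable `A`; on a defective Jacobian the
#' function falls back to [covariance_lyapunov()] with a warning. The
#' imaginary residue of the complex arithmetic is asserted to be below
#' `1e-8` before being discarded.
#'
#' @param A stable 5x5 (or n x n) Jacobian.
#' @param Gamma symmetric diffusion matrix of matching dimension.
#' @return Real symmetric stationary covariance matrix.
#' @seealso [covariance_lyapunov()] for the independent solver.
#' @export
covariance_spectral <- function(A, Gamma) {
  stopifnot(is.matrix(A), is.matrix(Gamma), all(dim(A) == dim(Gamma)))
  e <- eigen(A)
  lam <- e$values
  if (any(Re(lam) >= 0))
    stop("Jacobian is not stable (eigenvalue with non-negative real part)")
  denom <- outer(lam, lam, "+")
  if (any(abs(denom) < 1e-12 * max(abs(lam))))
    stop("marginally stable spectrum: lambda_p + lambda_r ~ 0")
  B <- e$vectors
  sv <- svd(B, nu = 0, nv = 0)$d
  rc <- min(sv) / max(sv)
  if (!is.finite(rc) || rc < 1e-10) {
    warning("near-defective Jacobian; falling back to Lyapunov solver")
    return(covariance_lyapunov(A, Gamma))
  }
  Binv <- solve(B)
  Gt <- Binv %*% Gamma %*% t(Binv)
  Ct <- -Gt / denom
  C <- B %*% Ct %*% t(B)
  im <- max(abs(Im(C)))
  if (im > 1e-8 * max(1, max(abs(Re(C)))))
    stop(sprintf("imaginary residue %.3e too large in spectral covariance", im))
  C <- Re(C)
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(A)
  C
}

#' Stationary covariance via the continuous Lyapunov equation
#'
#' Independent route to the stationary covariance: solves
#' `A C + C A^T = -Gamma` by Kronecker vectorisation,
#' `(I (x) A + A (x) I) vec(C) = -vec(Gamma)`. Serves as the numerical
#' ground truth against which the spectral formula is validated.
#'
#' @inheritParams covariance_spectral
#' @return Real symmetric stationary covariance matrix.
#' @export
covariance_lyapunov <- function(A, Gamma) {
  stopifnot(is.matrix(A), is.matrix(Gamma), all(dim(A) == dim(Gamma)))
  if (any(Re(eigen(A, only.values = TRUE)$values) >= 0))
    stop("Jacobian is not stable (eigenvalue with non-negative real part)")
  n <- nrow(A)
  M <- kronecker(diag(n), A) + kronecker(A, diag(n))
  C <- matrix(solve(M, -as.vector(Gamma)), n, n)
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(A)
  C
}

#' Linear noise approximation of the ceRNA network
#'
#' Gaussian approximation of the stationary copy-number fluctuations around
#' the deterministic steady state: computes the Jacobian `A`, the diffusion
#' matrix `Gamma` and the stationary covariance `C` satisfying the
#' fluctuation-dissipation relation `A C + C A^T + Gamma = 0`.
#'
#' @param params a [cerna_params()] object.
#' @param input occupancies (length-3 vector or [tf_input()]), or an already
#'   solved [steady_state()].
#' @param method `"lyapunov"` (default, numerically robust) or `"spectral"`
#'   (eigendecomposition formula).
#' @return An object of class `cerna_lna`: list with `ss`, `A`, `Gamma`,
#'   `C`, `eigenvalues`, per-species `var` and `fano`.
#' @examples
#' pre <- cerna_preset("fig2")
#' r <- lna(pre$params, c(0.9, 0.71, 0.9))
#' r$fano
#' @export
lna <- function(params, input, method = c("lyapunov", "spectral")) {
  method <- match.arg(method)
  ss <- if (inherits(input, "cerna_steady_state")) input
        else steady_state(params, input)
  A <- lna_jacobian(params, ss)
  G <- lna_diffusion(params, ss)
  C <- if (method == "spectral") covariance_spectral(A, G)
       else covariance_lyapunov(A, G)
  x <- as.numeric(ss)
  v <- pmax(diag(C), 0)
  structure(list(ss = ss, A = A, Gamma = G, C = C,
                 eigenvalues = eigen(A, only.values = TRUE)$values,
                 var = setNames(v, .species),
                 fano = setNames(ifelse(x > 0, v / x, NA_real_), .species),
                 method = method),
            class = "cerna_lna")
}

#' @export
print.cerna_lna <- function(x, digits = 4, ...) {
  cat("Linear noise approximation (", x$method, " solver)\n", sep = "")
  cat("  means:", paste(signif(as.numeric(x$ss), digits), collapse = ", "),
      "\n")
  cat("  variances:", paste(signif(x$var, digits), collapse = ", "), "\n")
  cat("  Fano factors:", paste(signif(x$fano, digits), collapse = ", "),
      "\n")
  invisible(x)
}
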