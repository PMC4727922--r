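#' Soft repression threshold of a ceRNA
#'
#' The miRNA level at which spontaneous and miRNA-mediated decay of ceRNA `i`
#' balance:
#' \deqn{\mu_{0,i} = \frac{d_i}{k_i^+}\left(1 +
#'   \frac{k_i^-}{\sigma_i + \kappa_i}\right).}
#' Below this level the ceRNA is essentially free, far above it the ceRNA is
#' repressed, and around it the ceRNA is maximally susceptible to changes in
#' the miRNA pool.
#'
#' @param params a [cerna_params()] object.
#' @param i ceRNA index, 1 or 2.
#' @return The threshold in molecules; `Inf` when `ki+ = 0` (the ceRNA is
#'   decoupled from the miRNA).
#' @export
mirna_threshold <- function(params, i) {
  stopifnot(inherits(params, "cerna_params"), i %in% c(1, 2))
  kp <- if (i == 1) params$kplus1 else params$kplus2
  km <- if (i == 1) params$kminus1 else params$kminus2
  sg <- if (i == 1) params$sigma1 else params$sigma2
  kk <- if (i == 1) params$kappa1 else params$kappa2
  d <- if (i == 1) params$d1 else params$d2
  if (kp == 0) return(Inf)
  (d / kp) * (1 + km / (sg + kk))
}

#' Sigmoidal repression gain of a ceRNA
#'
#' Stationary fraction of the unrepressed level retained at free-miRNA level
#' `mu`:
#' \deqn{F_i[\bar\mu] = \frac{\mu_{0,i}}{\mu_{0,i} + \bar\mu},}
#' so that \eqn{\bar m_i = (b_i \bar n_i / d_i)\, F_i[\bar\mu]}. Monotone
#' decreasing in `mu`, equal to 1 at `mu = 0` and 1/2 at the threshold.
#'
#' @param mu free miRNA level(s), >= 0.
#' @inheritParams mirna_threshold
#' @return Gain value(s) in `(0, 1]`.
#' @export
cerna_gain <- function(mu, params, i) {
  if (any(mu < 0)) stop("miRNA level mu must be >= 0")
  mu0 <- mirna_threshold(params, i)
  if (is.infinite(mu0)) return(rep(1, length(mu)))
  mu0 / (mu0 + mu)
}

#' Classify the repression regime of a ceRNA
#'
#' Compares the stationary free-miRNA level with the soft threshold
#' [mirna_threshold()]. The boundaries of the qualitative regimes are set by a
#' configurable ratio band (default one decade on either side).
#'
#' @param mu stationary free miRNA level, >= 0.
#' @param mu0 threshold, > 0 (may be `Inf`).
#' @param ratio_band half-width of the susceptible band as a ratio (default
#'   10: free below `mu0/10`, repressed above `10*mu0`).
#' @return `"free"`, `"susceptible"` or `"repressed"` (vectorised over `mu`).
#' @export
classify_regime <- function(mu, mu0, ratio_band = 10) {
  stopifnot(all(mu >= 0), mu0 > 0, ratio_band > 1)
  r <- mu / mu0
  out <- rep("susceptible", length(r))
  out[r < 1 / ratio_band] <- "free"
  out[r > ratio_band] <- "repressed"
  out
}

# Closed-form free-ceRNA levels at a trial free-miRNA level (the scalar
# reduction of the stationary conditions: both ceRNA equations are explicit
# once mu is fixed).
.m_of_mu <- function(params, n, mu) {
  m <- numeric(2)
  b <- c(params$b1, params$b2)
  d <- c(params$d1, params$d2)
  for (i in 1:2) {
    mu0 <- mirna_threshold(params, i)
    gain <- if (is.infinite(mu0)) 1 else mu0 / (mu0 + mu)
    m[i] <- b[i] * n[i] / d[i] * gain
  }
  m
}

.c_of_mu <- function(params, m, mu) {
  c(params$kplus1 * mu * m[1] / (params$sigma1 + params$kminus1 + params$kappa1),
    params$kplus2 * mu * m[2] / (params$sigma2 + params$kminus2 + params$kappa2))
}

# Picard update for mu: rhs of the miRNA stationary condition evaluated at
# the closed-form ceRNA/complex levels.
.mu_update <- function(params, n, mu) {
  m <- .m_of_mu(params, n, mu)
  cc <- .c_of_mu(params, m, mu)
  num <- params$beta * n[3] +
    (params$kminus1 + params$kappa1) * cc[1] +
    (params$kminus2 + params$kappa2) * cc[2]
  den <- params$delta + params$kplus1 * m[1] + params$kplus2 * m[2]
  num / den
}

#' Deterministic steady state of the ceRNA network
#'
#' Solves the coupled stationary conditions for the five species
#' `(m1, m2, mu, c1, c2)` at fixed promoter occupancies. The system is
#' reduced to a scalar fixed-point problem in the free-miRNA level: given
#' `mu`, both free-ceRNA levels follow in closed form through the sigmoidal
#' gain and the complexes through their own balance; the miRNA balance then
#' updates `mu`. A damped Picard iteration is used, with a bracketing
#' root-finder on the miRNA balance as fallback.
#'
#' @param params a [cerna_params()] object.
#' @param input a [tf_input()] object, or a length-3 occupancy vector
#'   `(n1, n2, nmu)`.
#' @param tol relative residual tolerance of the stationary conditions.
#' @param max_iter maximum Picard iterations before falling back.
#' @param ratio_band passed to [classify_regime()].
#' @return An object of class `cerna_steady_state`: a list with molecule
#'   numbers `m1, m2, mu, c1, c2`, thresholds `mu0` (length 2), regime labels
#'   `regime` (length 2), the residual norm and convergence flag.
#' @examples
#' pre <- cerna_preset("fig2")
#' steady_state(pre$params, c(0.9, 0.71, 0.9))
#' @export
steady_state <- function(params, input, tol = 1e-10, max_iter = 1e5,
                         ratio_band = 10) {
  stopifnot(inherits(params, "cerna_params"))
  n <- if (inherits(input, "cerna_input")) input$n else as.numeric(input)
  if (length(n) != 3L || any(n < 0) || any(n > 1))
    stop("occupancies must be three values in [0, 1]")

  mu_cap <- params$beta * n[3] / params$delta
  if (mu_cap == 0) {
    mu <- 0
  } else {
    # damped Picard iteration on the scalar miRNA balance
    mu <- mu_cap / 2
    alpha <- 0.5
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mu_new <- (1 - alpha) * mu + alpha * .mu_update(params, n, mu)
      if (abs(mu_new - mu) <= tol * max(mu_new, 1)) {
        mu <- mu_new
        converged <- TRUE
        break
      }
      mu <- mu_new
    }
    if (!converged) {
      # bracketing fallback on the balance equation
      bal <- function(mu) mu - .mu_update(params, n, mu)
      mu <- tryCatch(
        uniroot(bal, c(0, mu_cap * (1 + 1e-9)), tol = tol)$root,
        error = function(e)
          stop("steady-state solver did not converge: ", conditionMessage(e),
               call. = FALSE))
    }
  }

  m <- .m_of_mu(params, n, mu)
  cc <- .c_of_mu(params, m, mu)
  res <- .ss_residual(params, n, m, mu, cc)
  if (res > 1e3 * tol)
    stop(sprintf("steady-state residual %.3e exceeds tolerance", res))

  mu0 <- c(mirna_threshold(params, 1), mirna_threshold(params, 2))
  regime <- vapply(1:2, function(i)
    if (is.infinite(mu0[i])) "free"
    else classify_regime(mu, mu0[i], ratio_band), character(1))

  structure(list(m1 = m[1], m2 = m[2], mu = mu, c1 = cc[1], c2 = cc[2],
                 mu0 = mu0, regime = regime, residual = res,
                 occupancy = setNames(n, c("n1", "n2", "nmu")),
                 params = params),
            class = "cerna_steady_state")
}

# max relative residual of the three stationary conditions
.ss_residual <- function(params, n, m, mu, cc) {
  r1 <- m[1] * (params$d1 + params$kplus1 * mu) -
    (params$b1 * n[1] + params$kminus1 * cc[1])
  r2 <- m[2] * (params$d2 + params$kplus2 * mu) -
    (params$b2 * n[2] + params$kminus2 * cc[2])
  rmu <- mu * (params$delta + params$kplus1 * m[1] + params$kplus2 * m[2]) -
    (params$beta * n[3] + (params$kminus1 + params$kappa1) * cc[1] +
       (params$kminus2 + params$kappa2) * cc[2])
  rc1 <- cc[1] * (params$sigma1 + params$kminus1 + params$kappa1) -
    params$kplus1 * mu * m[1]
  rc2 <- cc[2] * (params$sigma2 + params$kminus2 + params$kappa2) -
    params$kplus2 * mu * m[2]
  scale <- max(params$b1 * n[1], params$b2 * n[2], params$beta * n[3], 1)
  max(abs(c(r1, r2, rmu, rc1, rc2))) / scale
}

#' @export
print.cerna_steady_state <- function(x, digits = 4, ...) {
  cat("ceRNA network steady state (molecules)\n")
  cat(sprintf("  m1 = %s   m2 = %s   mu = %s\n",
              signif(x$m1, digits), signif(x$m2, digits), signif(x$mu, digits)))
  cat(sprintf("  c1 = %s   c2 = %s\n", signif(x$c1, digits),
              signif(x$c2, digits)))
  cat(sprintf("  thresholds mu0 = (%s, %s); regimes: ceRNA1 %s, ceRNA2 %s\n",
              signif(x$mu0[1], digits), signif(x$mu0[2], digits),
              x$regime[1], x$regime[2]))
  invisible(x)
}

#' @export
as.double.cerna_steady_state <- function(x, ...) {
  setNames(c(x$m1, x$m2, x$mu, x$c1, x$c2), .species)
}

#' Locate the susceptibility crossover of a ceRNA along the competitor input
#'
#' Finds the TF1 copy number at which ceRNA `i` transitions into its
#' susceptible regime as the competitor is activated. Two operational
#' definitions are supported:
#' \describe{
#'   \item{`"fano"` (default)}{the input at which the stationary Fano factor
#'     of the free ceRNA level peaks (computed with the linear noise
#'     approximation). This is the observable signature of susceptibility:
#'     copy-number fluctuations are maximal where supply and sequestration
#'     are balanced.}
#'   \item{`"threshold"`}{the root of \eqn{\bar\mu(f_1) = \mu_{0,i}}. Since
#'     \eqn{\bar\mu} saturates as the competitor titrates the miRNA pool,
#'     this equation can lack a root even when the ceRNA passes through its
#'     susceptible window; `NA` is returned (with a warning) in that case.}
#' }
#'
#' @param params a [cerna_params()] object.
#' @param i ceRNA index (1 or 2).
#' @param n2,nmu fixed occupancies of the target and miRNA promoters.
#' @param f_range range of `f1` searched.
#' @param method `"fano"` or `"threshold"`.
#' @param n_grid grid resolution of the initial scan.
#' @return The crossover `f1` in molecules (`NA` if the threshold equation
#'   has no root).
#' @examples
#' pre <- cerna_preset("fig2")
#' f <- susceptibility_crossover(pre$params, 2, n2 = 0.71, nmu = 0.9)
#' log(f)
#' @export
susceptibility_crossover <- function(params, i, n2, nmu,
                                     f_range = c(1, 30),
                                     method = c("fano", "threshold"),
                                     n_grid = 200) {
  method <- match.arg(method)
  stopifnot(i %in% c(1, 2), length(f_range) == 2L, f_range[1] > 0)
  lf <- seq(log(f_range[1]), log(f_range[2]), length.out = n_grid)
  if (method == "threshold") {
    mu0 <- mirna_threshold(params, i)
    g <- function(f1) {
      n1 <- tf_occupancy(f1, params)
      steady_state(params, c(n1, n2, nmu))$mu - mu0
    }
    vals <- vapply(exp(lf), g, numeric(1))
    sgn <- which(diff(sign(vals)) != 0)
    if (length(sgn) == 0L) {
      warning("mu(f1) never crosses mu0_", i,
              " on the given range; no threshold crossover")
      return(NA_real_)
    }
    j <- sgn[1]
    return(uniroot(g, exp(lf[c(j, j + 1)]), tol = 1e-10)$root)
  }
  # Fano-peak definition via the LNA
  ff <- function(lf1) {
    n1 <- tf_occupancy(exp(lf1), params)
    r <- lna(params, c(n1, n2, nmu))
    r$fano[i]
  }
  vals <- vapply(lf, ff, numeric(1))
  j <- which.max(vals)
  if (j == 1L || j == n_grid) {
    warning("Fano factor of ceRNA", i, " has no interior peak on the range")
    return(exp(lf[j]))
  }
  opt <- optimize(ff, interval = lf[c(j - 1, j + 1)], maximum = TRUE,
                  tol = 1e-6)
  exp(opt$maximum)
}
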