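#' Input-output response curve of a regulatory channel
#'
#' Mean and variance of the target level `m2` along a grid of input TF copy
#' numbers, for the post-transcriptional channel (input `f1`, the
#' competitor's TF) or the direct transcriptional channel (input `f2`). The
#' three estimators are the deterministic steady state (variance 0), the
#' linear noise approximation (deterministic mean, Gaussian variance) and
#' the Gillespie simulation (time-averaged mean and variance pooled over
#' replicates).
#'
#' The default grid merges log-spaced points in `f` (the natural axis of
#' the scans) with points uniform in occupancy over the requested range,
#' with the `f = 0` endpoint prepended when the range starts at zero
#' occupancy.
#'
#' @param params a [cerna_params()] object, or a [cerna_preset()] (in which
#'   case channel, range and fixed occupancies are taken from the preset).
#' @param channel `"mirna"` or `"tf"`.
#' @param fixed named occupancies of the two non-input promoters
#'   (`c(n2=, nmu=)` for the miRNA channel, `c(n1=, nmu=)` for the TF
#'   channel).
#' @param n_range occupancy range of the swept input, in `[0, 1)`.
#' @param f_grid explicit input grid (overrides `n_range`/`n_points`).
#' @param estimator `"lna"`, `"deterministic"` or `"ga"`.
#' @param n_points grid density (default 50).
#' @param seed,replicates,t_end,burn_in Gillespie options (estimator
#'   `"ga"`).
#' @param ... unused.
#' @return An object of class `cerna_response`: data frame with columns
#'   `f`, `n`, `m2`, `var_m2` (and `se_m2` for GA), plus attributes
#'   `channel`, `estimator`, `fixed`.
#' @examples
#' rc <- response_curve(cerna_preset("fig2"), estimator = "lna",
#'                      n_points = 15)
#' head(rc)
#' @export
response_curve <- function(params, ...) UseMethod("response_curve")

#' @rdname response_curve
#' @export
response_curve.cerna_preset <- function(params, estimator = "lna",
                                        n_points = 50, ...) {
  pre <- params
  response_curve(pre$params, channel = pre$channel, fixed = pre$fixed,
                 n_range = pre$input_n_range, estimator = estimator,
                 n_points = n_points, ...)
}

#' @rdname response_curve
#' @export
response_curve.cerna_params <- function(params, channel = c("mirna", "tf"),
                                        fixed, n_range = c(0, 0.99),
                                        f_grid = NULL,
                                        estimator = c("lna", "deterministic",
                                                      "ga"),
                                        n_points = 50, seed = 1,
                                        replicates = 3, t_end = 3000,
                                        burn_in = 300, ...) {
  channel <- match.arg(channel)
  estimator <- match.arg(estimator)
  if (is.null(f_grid)) f_grid <- .input_grid(params, n_range, n_points)
  if (is.unsorted(f_grid, strictly = TRUE))
    stop("input grid must be strictly increasing")

  if (estimator == "ga") {
    sc <- moment_scan(params, channel, f_grid, fixed,
                      replicates = replicates, seed = seed, t_end = t_end,
                      burn_in = burn_in)
    m2 <- sc[sc$species == "m2", ]
    out <- data.frame(f = m2$f, n = tf_occupancy(m2$f, params),
                      m2 = m2$mean, var_m2 = m2$var, se_m2 = m2$se_mean)
  } else {
    rows <- lapply(f_grid, function(f) {
      n_in <- tf_occupancy(f, params)
      occ <- .channel_occupancy(channel, n_in, fixed)
      if (estimator == "deterministic") {
        ss <- steady_state(params, occ)
        c(m2 = ss$m2, var_m2 = 0)
      } else {
        r <- lna(params, occ)
        c(m2 = r$ss$m2, var_m2 = unname(r$var["m2"]))
      }
    })
    rows <- do.call(rbind, rows)
    out <- data.frame(f = f_grid, n = tf_occupancy(f_grid, params),
                      m2 = rows[, "m2"], var_m2 = rows[, "var_m2"])
  }
  structure(out, class = c("cerna_response", "data.frame"),
            channel = channel, estimator = estimator, fixed = fixed,
            params = params, seed = if (estimator == "ga") seed else NULL)
}

# input grid over the occupancy range: log-spaced points in f (the natural
# axis of the scans) merged with points uniform in occupancy (which
# concentrate where the Hill response actually moves), plus an f = 0
# endpoint when the range starts at zero occupancy
.input_grid <- function(params, n_range, n_points) {
  stopifnot(length(n_range) == 2L, n_range[1] < n_range[2], n_range[2] < 1)
  f_hi <- occupancy_inverse(n_range[2], params)
  from_zero <- n_range[1] <= 0
  f_lo <- if (from_zero) f_hi * 1e-3 else occupancy_inverse(n_range[1], params)
  k <- n_points - as.integer(from_zero)
  k1 <- ceiling(k / 2)
  g_log <- exp(seq(log(f_lo), log(f_hi), length.out = k1))
  n_lo <- max(n_range[1], tf_occupancy(f_lo, params))
  g_occ <- occupancy_inverse(seq(n_lo, n_range[2], length.out = k - k1 + 2),
                             params)
  g <- sort(unique(c(g_log, g_occ[-c(1, length(g_occ))], f_hi)))
  if (from_zero) g <- c(0, g)
  g
}

#' @export
plot.cerna_response <- function(x, ...) {
  sdv <- sqrt(pmax(x$var_m2, 0))
  plot(x$f, x$m2, type = "l", xlab = attr(x, "channel"), log = "",
       ylab = "target m2 (molecules)",
       ylim = range(c(x$m2 - sdv, x$m2 + sdv)), ...)
  lines(x$f, x$m2 + sdv, lty = 3)
  lines(x$f, x$m2 - sdv, lty = 3)
  invisible(x)
}

#' Amplitude of variation (AOV) of a response curve
#'
#' The difference between the target level at the endpoints of the input
#' range, `m2(f_max) - m2(f_min)`: the size of the target's derepression
#' window, blind to noise.
#'
#' @param curve a [response_curve()] object (>= 2 points).
#' @return AOV in molecules (signed).
#' @export
response_aov <- function(curve) {
  stopifnot(inherits(curve, "cerna_response"), nrow(curve) >= 2)
  curve$m2[nrow(curve)] - curve$m2[1]
}

# derivative of the mean response on an arbitrary evaluation grid; a
# monotone sample gets a monotonicity-preserving interpolant so that the
# squared derivative in the capacity integrand cannot pick up spline
# overshoot
.curve_derivative <- function(curve, smooth = NULL) {
  if (is.null(smooth)) smooth <- identical(attr(curve, "estimator"), "ga")
  if (smooth && nrow(curve) >= 8) {
    fit <- smooth.spline(curve$f, curve$m2, df = max(5, nrow(curve) / 2))
    mfun <- function(f) predict(fit, f)$y
    dfun <- function(f) predict(fit, f, deriv = 1)$y
  } else {
    d <- diff(curve$m2)
    tol <- 1e-8 * max(diff(range(curve$m2)), 1)
    method <- if (all(d >= -tol) || all(d <= tol)) "monoH.FC" else "natural"
    sp <- splinefun(curve$f, curve$m2, method = method)
    mfun <- sp
    dfun <- function(f) sp(f, deriv = 1)
  }
  list(mean = mfun, deriv = dfun)
}

#' Optimal input distribution of a small-noise Gaussian channel
#'
#' The TF-level density that maximises the mutual information between input
#' and target in the small-noise Gaussian approximation:
#' \deqn{p_{opt}(f) = \frac{1}{Z}\left[\frac{(d\bar m_2/df)^2}
#'   {2\pi e\,\sigma^2_{m_2}(f)}\right]^{1/2},}
#' with `Z` the normalising integral over the input range. `Z` counts the
#' number of distinguishable output levels; the derivative enters squared,
#' so non-monotone response curves are accepted (with a warning, since
#' distinguishability is then overestimated).
#'
#' The derivative of the mean response is taken from a smoothing spline for
#' Gillespie-estimated curves (the derivative is squared, so sampling jitter
#' would otherwise be amplified) and from an interpolating spline otherwise.
#' `Z` is evaluated by the trapezoid rule on a refined grid.
#'
#' @param curve a [response_curve()] with strictly positive variance.
#' @param n_quad refinement of the quadrature grid.
#' @return An object of class `cerna_optimal_input`: data frame `f`,
#'   `density`, with attributes `Z` and `channel`.
#' @export
optimal_input <- function(curve, n_quad = 2000) {
  stopifnot(inherits(curve, "cerna_response"))
  bad <- curve$var_m2 <= 0
  if (all(bad))
    stop("optimal_input requires positive response variance on the grid ",
         "(use the 'lna' or 'ga' estimator)")
  if (any(bad)) {
    # a zero-variance point can only be an empty output (m2 = 0); the
    # Gaussian channel is undefined there, so the point is excluded
    if (any(curve$m2[bad] > sqrt(.Machine$double.eps)))
      stop("zero response variance at a non-empty output level")
    est <- attr(curve, "estimator")
    curve <- curve[!bad, , drop = FALSE]
    attr(curve, "estimator") <- est
    if (nrow(curve) < 4)
      stop("too few usable points after dropping zero-variance inputs")
  }
  d <- .curve_derivative(curve)
  vfun <- .variance_interpolant(curve)
  fg <- seq(min(curve$f), max(curve$f), length.out = n_quad)
  dm <- d$deriv(fg)
  dtol <- 1e-3 * max(abs(dm), 1e-300)
  if (any(dm < -dtol) && any(dm > dtol))
    warning("non-monotone response curve: capacity counts distinguishable ",
            "levels along both branches")
  psi <- abs(dm) / sqrt(2 * pi * exp(1) * pmax(vfun(fg), 1e-300))
  Z <- sum((psi[-1] + psi[-length(psi)]) / 2 * diff(fg))
  if (Z <= 0) {
    warning("flat response: degenerate optimal input (Z = 0)")
    dens <- rep(0, length(fg))
  } else {
    dens <- psi / Z
  }
  structure(data.frame(f = fg, density = dens),
            class = c("cerna_optimal_input", "data.frame"),
            Z = Z, channel = attr(curve, "channel"))
}

# positive interpolant of the response variance (interpolated on the log
# scale, so spline overshoot cannot drive it to zero or below)
.variance_interpolant <- function(curve) {
  v <- pmax(curve$var_m2, 1e-12)
  sp <- splinefun(curve$f, log(v), method = "natural")
  function(f) exp(sp(f))
}

#' Channel capacity from the optimal input
#'
#' `I = log2(Z)` bits, where `Z` is the normalisation of the optimal input
#' density. `Z < 1` means fewer than one distinguishable output level, so
#' the capacity is clamped to 0 bits.
#'
#' @param opt a [optimal_input()] object, or a bare non-negative `Z`.
#' @return Capacity in bits (>= 0).
#' @export
channel_capacity <- function(opt) {
  Z <- if (inherits(opt, "cerna_optimal_input")) attr(opt, "Z") else opt
  stopifnot(is.numeric(Z), length(Z) == 1L, Z >= 0)
  if (Z < 1) 0 else log2(Z)
}

#' Capacity limit of a Poissonian channel
#'
#' Closed-form capacity of a channel whose output is Poissonian
#' (`variance = mean`) and spans `[m_min, m_max]`:
#' \deqn{I = \log_2\left[\frac{2}{\sqrt{2\pi e}}
#'   \left(\sqrt{m_{max}} - \sqrt{m_{min}}\right)\right],}
#' clamped at 0 bits. This is the theoretical ceiling approached by a direct
#' transcriptional channel at large derepression.
#'
#' @param m_min,m_max output range in molecules, `0 <= m_min < m_max`.
#' @return Capacity in bits.
#' @export
poisson_limit_capacity <- function(m_min, m_max) {
  if (any(m_min < 0) || any(m_min >= m_max))
    stop("need 0 <= m_min < m_max")
  Z <- 2 / sqrt(2 * pi * exp(1)) * (sqrt(m_max) - sqrt(m_min))
  ifelse(Z < 1, 0, log2(Z))
}

#' Mutual information between input and target
#'
#' Plug-in estimates of `I(m2; f)` in bits. Two backends:
#' \describe{
#'   \item{semi-analytic}{for a [response_curve()]: the channel is Gaussian
#'     per input (`m2 | f ~ N(m2(f), var(f))`) and the input density is
#'     integrated numerically, `I = H(m2) - H(m2 | f)`. The default input
#'     density is the optimal one.}
#'   \item{empirical}{for paired samples `(f, m2)`: 2-D histogram plug-in
#'     with Freedman-Diaconis bin widths. The plug-in estimator is biased
#'     upward at small sample sizes.}
#' }
#'
#' @param x a `cerna_response` object, or a numeric vector of input samples.
#' @param ... passed on.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, ...) UseMethod("mutual_information")

#' @rdname mutual_information
#' @param input a `cerna_optimal_input`, or a function `p(f)`; defaults to
#'   the optimal input of the curve.
#' @param n_f,n_m integration resolutions over input and output.
#' @export
mutual_information.cerna_response <- function(x, input = NULL, n_f = 400,
                                              n_m = 600, ...) {
  if (any(x$var_m2 <= 0)) stop("requires positive response variance")
  if (is.null(input)) input <- optimal_input(x)
  pfun <- if (is.function(input)) input
          else splinefun(input$f, pmax(input$density, 0), method = "natural")
  d <- .curve_derivative(x)
  vfun <- .variance_interpolant(x)
  fg <- seq(min(x$f), max(x$f), length.out = n_f)
  w <- rep(diff(fg)[1], n_f); w[c(1, n_f)] <- w[1] / 2
  pf <- pmax(pfun(fg), 0)
  pf <- pf / sum(pf * w)
  mu <- d$mean(fg)
  s2 <- pmax(vfun(fg), 1e-12)
  # conditional entropy (Gaussian): mean of 0.5*log2(2*pi*e*s2)
  Hcond <- sum(pf * w * 0.5 * log2(2 * pi * exp(1) * s2))
  # marginal over a generous output grid
  mg <- seq(min(mu - 5 * sqrt(s2)), max(mu + 5 * sqrt(s2)),
            length.out = n_m)
  dm <- diff(mg)[1]
  pm <- numeric(n_m)
  for (i in seq_len(n_f))
    pm <- pm + pf[i] * w[i] * dnorm(mg, mu[i], sqrt(s2[i]))
  pm <- pm / sum(pm * dm)
  nz <- pm > 0
  Hm <- -sum(pm[nz] * log2(pm[nz]) * dm)
  max(Hm - Hcond, 0)
}

#' @rdname mutual_information
#' @param m2 output samples paired with the input samples in `x`.
#' @export
mutual_information.default <- function(x, m2, ...) {
  f <- as.numeric(x)
  if (length(f) == 0L || length(f) != length(m2))
    stop("need paired non-empty samples of input and output")
  if (length(unique(f)) < 2L) stop("need at least 2 distinct input values")
  bf <- .fd_breaks(f)
  bm <- .fd_breaks(m2)
  tab <- table(cut(f, bf, include.lowest = TRUE),
               cut(m2, bm, include.lowest = TRUE))
  p <- tab / sum(tab)
  pf <- rowSums(p); pm <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pf, pm)[nz]))
}

.fd_breaks <- function(x) {
  n <- length(x)
  iqr <- stats::IQR(x)
  h <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(range(x)) / ceiling(sqrt(n))
  if (h <= 0) h <- 1
  k <- max(2, ceiling(diff(range(x)) / h))
  seq(min(x) - 1e-9, max(x) + 1e-9, length.out = k + 1)
}

#' Reconstruct the TF-channel input range matching a target output range
#'
#' For protocols that compare the two channels at identical output ranges,
#' the direct channel's occupancy window is chosen so that
#' `b2 n2 / d2` spans `[m2_min, m2_max]`. Occupancies are clamped just below
#' promoter saturation (`n_cap`) when the upper target is not reachable.
#'
#' @param params TF-channel parameters (no miRNA: capacities come from the
#'   decoupled birth-death response).
#' @param m2_range target output range (molecules), typically the endpoints
#'   of the miRNA-channel response.
#' @param n_cap occupancy ceiling (default 0.9999, just below saturation).
#' @return Occupancy range `c(n_lo, n_hi)` for the TF-channel input.
#' @export
match_tf_input_range <- function(params, m2_range, n_cap = 0.9999) {
  stopifnot(length(m2_range) == 2L, m2_range[1] < m2_range[2], params$b2 > 0)
  n <- params$d2 * m2_range / params$b2
  if (n[2] > n_cap) n[2] <- n_cap
  if (n[1] >= n[2]) stop("target output range not reachable by this channel")
  pmin(pmax(n, 0), n_cap)
}

#' Compare the miRNA-mediated and transcriptional channels
#'
#' Runs the full protocol -- response curve, optimal input, capacity -- for
#' the post-transcriptional channel (input `f1`) and the direct channel
#' (input `f2`) and returns capacities, their difference and the AOVs.
#'
#' @param mirna,tf [cerna_preset()] objects (or lists with the same fields)
#'   describing the two channels.
#' @param estimator passed to [response_curve()].
#' @param n_points grid density.
#' @param seed master seed (Gillespie estimator).
#' @param match_output_range force the TF-channel occupancy window to map
#'   onto the miRNA channel's output range (default: taken from the TF
#'   preset's `match_output_range` flag).
#' @param mi_check also compute the semi-analytic sampled-MI cross-check for
#'   both channels (slower).
#' @param ... Gillespie options forwarded to [response_curve()].
#' @return An object of class `cerna_capacity`: list with `I_tf`,
#'   `I_mirna`, `dI = I_tf - I_mirna`, `aov_tf`, `aov_mirna`, `Z_tf`,
#'   `Z_mirna`, the two curves and (optionally) `mi_tf`, `mi_mirna`.
#' @examples
#' cc <- compare_channels(cerna_preset("fig9", "mirna"),
#'                        cerna_preset("fig9", "tf"), n_points = 25)
#' cc$dI
#' @export
compare_channels <- function(mirna, tf, estimator = "lna", n_points = 50,
                             seed = 1, match_output_range = NULL,
                             mi_check = FALSE, ...) {
  cm <- response_curve(mirna$params, channel = "mirna", fixed = mirna$fixed,
                       n_range = mirna$input_n_range, estimator = estimator,
                       n_points = n_points, seed = seed, ...)
  if (is.null(match_output_range))
    match_output_range <- isTRUE(tf$match_output_range)
  tf_range <- tf$input_n_range
  if (match_output_range)
    tf_range <- match_tf_input_range(tf$params,
                                     range(cm$m2[c(1, nrow(cm))]))
  ct <- response_curve(tf$params, channel = "tf", fixed = tf$fixed,
                       n_range = tf_range, estimator = estimator,
                       n_points = n_points, seed = seed + 1, ...)
  om <- optimal_input(cm)
  ot <- optimal_input(ct)
  out <- list(I_tf = channel_capacity(ot), I_mirna = channel_capacity(om),
              Z_tf = attr(ot, "Z"), Z_mirna = attr(om, "Z"),
              aov_tf = response_aov(ct), aov_mirna = response_aov(cm),
              curve_tf = ct, curve_mirna = cm,
              tf_n_range = tf_range, estimator = estimator, seed = seed)
  out$dI <- out$I_tf - out$I_mirna
  if (mi_check) {
    out$mi_tf <- mutual_information(ct, ot)
    out$mi_mirna <- mutual_information(cm, om)
  }
  class(out) <- "cerna_capacity"
  out
}

#' @export
print.cerna_capacity <- function(x, digits = 3, ...) {
  cat("Channel comparison (", x$estimator, " estimator)\n", sep = "")
  cat(sprintf("  I_TF    = %s bits (AOV %s molecules)\n",
              signif(x$I_tf, digits), signif(x$aov_tf, digits + 1)))
  cat(sprintf("  I_miRNA = %s bits (AOV %s molecules)\n",
              signif(x$I_mirna, digits), signif(x$aov_mirna, digits + 1)))
  cat(sprintf("  dI = I_TF - I_miRNA = %s bits\n", signif(x$dI, digits)))
  invisible(x)
}

#' Export a capacity summary as JSON
#'
#' @param x a `cerna_capacity` object.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
export_capacity_json <- function(x, path) {
  stopifnot(inherits(x, "cerna_capacity"))
  jsonlite::write_json(
    list(I_tf_bits = x$I_tf, I_mirna_bits = x$I_mirna, dI_bits = x$dI,
         Z_tf = x$Z_tf, Z_mirna = x$Z_mirna,
         aov_tf = x$aov_tf, aov_mirna = x$aov_mirna,
         estimator = x$estimator, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @importFrom stats dnorm IQR
NULL
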