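#' Exact stochastic simulation of the ceRNA network
#'
#' Direct-method Gillespie simulation of a [reaction_system()]. The sampler
#' draws the waiting time and the reaction index from two uniforms per event
#' and is exact for the well-mixed chemical master equation. R's RNG is used
#' throughout, so results are fully reproducible from `seed`.
#'
#' @param system a `cerna_reactions` object.
#' @param t_end simulation horizon (min).
#' @param seed integer seed for the pseudo-random stream.
#' @param initial integer initial state `(m1, m2, mu, c1, c2)`; default is
#'   the deterministic steady state rounded to integers (unbiased at
#'   stationarity, shortens burn-in).
#' @param max_events safety cap on the number of recorded events.
#' @return An object of class `cerna_trajectory`: list with `times` (event
#'   times, min), `states` (piecewise-constant integer states, one row per
#'   event time), `reaction` (1-based index of the fired reaction), `seed`,
#'   `t_end` and a truncation flag.
#' @examples
#' pre <- cerna_preset("fig2")
#' rs <- reaction_system(pre$params, c(0.5, 0.71, 0.9))
#' tr <- simulate_ssa(rs, t_end = 50, seed = 1)
#' @export
simulate_ssa <- function(system, t_end, seed, initial = NULL,
                         max_events = 5e6) {
  stopifnot(inherits(system, "cerna_reactions"), t_end > 0)
  if (is.null(initial)) initial <- .default_initial(system)
  initial <- as.integer(round(initial))
  if (length(initial) != 5L || any(initial < 0))
    stop("initial state must be 5 non-negative integers")
  set.seed(as.integer(seed))
  out <- ssa_trajectory_cpp(unname(system$rates), initial, t_end,
                            as.integer(max_events))
  colnames(out$states) <- .species
  structure(list(times = out$times, states = out$states,
                 reaction = out$reaction, n_events = out$n_events,
                 t_end = t_end, t_final = out$t_final,
                 truncated = out$truncated, seed = seed,
                 system = system),
            class = "cerna_trajectory")
}

.default_initial <- function(system) {
  ss <- steady_state(system$params, system$occupancy)
  pmax(round(as.numeric(ss)), 0)
}

#' @export
print.cerna_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d events over %.1f min (seed %d)%s\n",
              x$n_events, x$t_final, x$seed,
              if (isTRUE(x$truncated)) " [truncated at max_events]" else ""))
  invisible(x)
}

#' @export
plot.cerna_trajectory <- function(x, species = c("m1", "m2", "mu"), ...) {
  idx <- match(species, .species)
  matplot(x$times, x$states[, idx, drop = FALSE], type = "s", lty = 1,
          xlab = "time (min)", ylab = "molecules", ...)
  legend("topright", legend = species, col = seq_along(idx), lty = 1,
         bty = "n")
  invisible(x)
}

#' Time-averaged stationary statistics of a trajectory
#'
#' Time-weighted means, variances and Fano factors over the window
#' `[burn_in, t_end]`; each state's weight is the holding time of its
#' segment.
#'
#' @param traj a [simulate_ssa()] trajectory.
#' @param burn_in portion of the path (min) discarded as relaxation
#'   transient; must be smaller than the trajectory duration.
#' @return An object of class `cerna_stats`: data frame with one row per
#'   species and columns `mean`, `var`, `fano` (NA when the mean is zero),
#'   plus attributes `weight` (window length, min), `n_events` and `burn_in`.
#' @export
stationary_stats <- function(traj, burn_in = 0) {
  stopifnot(inherits(traj, "cerna_trajectory"))
  if (burn_in >= traj$t_final)
    stop("burn_in must be smaller than the trajectory duration")
  t <- c(traj$times, traj$t_final)
  lo <- pmax(t[-length(t)], burn_in)
  w <- pmax(t[-1] - lo, 0)
  W <- sum(w)
  if (W <= 0) stop("empty averaging window")
  X <- traj$states
  m <- colSums(X * w) / W
  v <- colSums(X^2 * w) / W - m^2
  fano <- ifelse(m > 0, v / m, NA_real_)
  out <- data.frame(species = .species, mean = m, var = pmax(v, 0),
                    fano = fano, row.names = NULL)
  structure(out, class = c("cerna_stats", "data.frame"),
            weight = W, n_events = sum(traj$times > burn_in),
            burn_in = burn_in)
}

# Moment-accumulating SSA run (no stored path); returns per-species mean,
# full 5x5 second-moment matrix, window weight and event counts.
ssa_moments <- function(system, t_end, seed, burn_in, initial = NULL) {
  stopifnot(inherits(system, "cerna_reactions"))
  if (is.null(initial)) initial <- .default_initial(system)
  set.seed(as.integer(seed))
  out <- ssa_moments_cpp(unname(system$rates),
                         as.integer(round(initial)), t_end, burn_in)
  names(out$mean) <- .species
  dimnames(out$second_moment) <- list(.species, .species)
  out$cov <- out$second_moment - outer(out$mean, out$mean)
  out
}

#' Stationary moments of the target and miRNA along an input grid
#'
#' Runs replicated moment-accumulating SSA simulations at each TF1 (miRNA
#' channel) or TF2 (TF channel) copy number in `f_grid` and pools the
#' time-averaged moments. Per-point, per-replicate seeds are derived
#' deterministically from the master seed.
#'
#' @param params a [cerna_params()] object.
#' @param channel `"mirna"` (input `f1`) or `"tf"` (input `f2`).
#' @param f_grid input TF copy numbers.
#' @param fixed named occupancies of the two non-input promoters, e.g.
#'   `c(n2 = 0.71, nmu = 0.9)` for the miRNA channel.
#' @param replicates independent runs pooled per grid point.
#' @param seed master seed.
#' @param t_end,burn_in simulation horizon and discarded transient (min).
#' @return A long-format data frame of class `cerna_moment_scan` with
#'   columns `f`, `species` (`m2`, `mu`), `mean`, `se_mean`, `var`, `se_var`,
#'   `fano`, `replicates`.
#' @export
moment_scan <- function(params, channel = c("mirna", "tf"), f_grid, fixed,
                        replicates = 4, seed = 1, t_end = 4000,
                        burn_in = 400) {
  channel <- match.arg(channel)
  stopifnot(length(f_grid) >= 1, replicates >= 1)
  seeds <- derive_seeds(seed, length(f_grid) * replicates)
  dim(seeds) <- c(length(f_grid), replicates)
  rows <- list()
  for (g in seq_along(f_grid)) {
    n_in <- tf_occupancy(f_grid[g], params)
    occ <- .channel_occupancy(channel, n_in, fixed)
    rs <- reaction_system(params, occ)
    means <- vars <- matrix(NA_real_, replicates, 2)
    for (r in seq_len(replicates)) {
      mom <- ssa_moments(rs, t_end, seeds[g, r], burn_in)
      means[r, ] <- mom$mean[c("m2", "mu")]
      vars[r, ] <- diag(mom$cov)[c("m2", "mu")]
    }
    for (k in 1:2) {
      mbar <- mean(means[, k]); vbar <- mean(vars[, k])
      rows[[length(rows) + 1L]] <- data.frame(
        f = f_grid[g], species = c("m2", "mu")[k],
        mean = mbar,
        se_mean = if (replicates > 1) sd(means[, k]) / sqrt(replicates) else NA,
        var = vbar,
        se_var = if (replicates > 1) sd(vars[, k]) / sqrt(replicates) else NA,
        fano = if (mbar > 0) vbar / mbar else NA_real_,
        replicates = replicates)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("cerna_moment_scan", "data.frame"),
            channel = channel, seed = seed, t_end = t_end, burn_in = burn_in)
}

# map the swept input occupancy + fixed occupancies to (n1, n2, nmu)
.channel_occupancy <- function(channel, n_in, fixed) {
  fixed <- as.list(fixed)
  if (channel == "mirna") {
    if (!all(c("n2", "nmu") %in% names(fixed)))
      stop("miRNA channel requires fixed = c(n2 = ..., nmu = ...)")
    c(n_in, fixed$n2, fixed$nmu)
  } else {
    if (!all(c("n1", "nmu") %in% names(fixed)))
      stop("TF channel requires fixed = c(n1 = ..., nmu = ...)")
    c(fixed$n1, n_in, fixed$nmu)
  }
}

# deterministic stream of sub-seeds below 2^31 from one master seed
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Export a trajectory or statistics table as CSV
#'
#' @param x a `cerna_trajectory`, `cerna_stats` or any data frame produced by
#'   the scan/sweep drivers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  if (inherits(x, "cerna_trajectory")) {
    df <- data.frame(time = x$times, x$states)
  } else {
    df <- as.data.frame(x)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
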