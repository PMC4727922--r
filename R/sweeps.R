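#' Configuration for a parameter sweep
#'
#' Builds (or reads) the configuration consumed by [run_sweep()]. The
#' protocol names mirror the published scan protocols: `"binding"`
#' (association-rate plane), `"recycling"` (recycling-rate plane),
#' `"occupancy"` (promoter-occupancy plane, variants A/B), `"aov"`
#' (capacity versus derepression amplitude) and `"omega"` (joint
#' miRNA-turnover/binding rescaling).
#'
#' @param protocol one of `"binding"`, `"recycling"`, `"occupancy"`,
#'   `"aov"`, `"omega"`.
#' @param variant occupancy-plane variant, `"A"` or `"B"` (protocol
#'   `"occupancy"` only).
#' @param grid_n points per swept axis (reduced desk-scale default 5 for
#'   planes, 8 for 1-D scans).
#' @param estimator response-curve estimator.
#' @param n_points input-grid density per capacity evaluation.
#' @param replicates Gillespie replicates (estimator `"ga"`).
#' @param seed master seed; every output row records the seed used.
#' @param overrides named list of sweep-range overrides, e.g.
#'   `list(log_kplus1 = c(-6, 2))`.
#' @return A list of class `cerna_sweep_config`.
#' @export
sweep_config <- function(protocol = c("binding", "recycling", "occupancy",
                                      "aov", "omega"),
                         variant = "A", grid_n = NULL,
                         estimator = "lna", n_points = 30, replicates = 3,
                         seed = 1, overrides = list()) {
  protocol <- match.arg(protocol)
  if (is.null(grid_n))
    grid_n <- if (protocol %in% c("aov", "omega")) 8L else 5L
  structure(list(protocol = protocol, variant = variant,
                 grid_n = as.integer(grid_n), estimator = estimator,
                 n_points = n_points, replicates = replicates,
                 seed = as.integer(seed), overrides = overrides),
            class = "cerna_sweep_config")
}

#' Read / write a sweep configuration (JSON or YAML)
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @param config a [sweep_config()] object.
#' @return `read_sweep_config()` returns a `cerna_sweep_config`;
#'   `write_sweep_config()` returns `path` invisibly.
#' @export
read_sweep_config <- function(path) {
  x <- read_config(path)
  do.call(sweep_config, x)
}

#' @rdname read_sweep_config
#' @export
write_sweep_config <- function(config, path) {
  stopifnot(inherits(config, "cerna_sweep_config"))
  write_config(unclass(config), path)
}

#' Run a configured sweep
#'
#' Dispatches on the configured protocol. All drivers return long-format
#' data frames (class `cerna_sweep`) with one row per grid point, capacities
#' in bits, AOVs in molecules, a status column (failed points are flagged,
#' not dropped) and the seed used, plus a manifest attribute (config echo
#' and wall-clock time).
#'
#' @param config a [sweep_config()] object.
#' @return A `cerna_sweep` data frame.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "cerna_sweep_config"))
  t0 <- Sys.time()
  out <- switch(config$protocol,
    binding = binding_rate_sweep(config),
    recycling = recycling_sweep(config),
    occupancy = occupancy_sweep(config),
    aov = aov_capacity_curve(config),
    omega = omega_sweep(config))
  attr(out, "manifest") <- list(
    config = unclass(config),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("cernacap")))
  out
}

.sweep_row <- function(point, cc, seed) {
  data.frame(point, I_tf = cc$I_tf, I_mirna = cc$I_mirna, dI = cc$dI,
             aov_tf = cc$aov_tf, aov_mirna = cc$aov_mirna,
             status = "ok", seed = seed)
}

.sweep_fail <- function(point, seed, msg) {
  data.frame(point, I_tf = NA_real_, I_mirna = NA_real_, dI = NA_real_,
             aov_tf = NA_real_, aov_mirna = NA_real_,
             status = paste("failed:", msg), seed = seed)
}

.as_sweep <- function(rows, protocol, config) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cerna_sweep", "data.frame"),
            protocol = protocol, config = unclass(config))
}

#' Capacity over the miRNA-ceRNA association-rate plane
#'
#' Evaluates both channel capacities on a grid over
#' `(ln k1+, ln k2+)` at the association-rate preset, holding all other
#' rates fixed.
#'
#' @param config a [sweep_config()] (protocol `"binding"`).
#' @return A `cerna_sweep` data frame with columns `log_kplus1`,
#'   `log_kplus2`, capacities and AOVs.
#' @export
binding_rate_sweep <- function(config = sweep_config("binding")) {
  prem <- cerna_preset("fig5", "mirna")
  pret <- cerna_preset("fig5", "tf")
  rng <- modifyList(prem$sweep, config$overrides)
  g1 <- seq(rng$log_kplus1[1], rng$log_kplus1[2], length.out = config$grid_n)
  g2 <- seq(rng$log_kplus2[1], rng$log_kplus2[2], length.out = config$grid_n)
  grid <- expand.grid(log_kplus1 = g1, log_kplus2 = g2)
  seeds <- derive_seeds(config$seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pm <- prem; pt <- pret
    pm$params$kplus1 <- pt$params$kplus1 <- exp(grid$log_kplus1[i])
    pm$params$kplus2 <- pt$params$kplus2 <- exp(grid$log_kplus2[i])
    tryCatch(
      .sweep_row(grid[i, ],
                 compare_channels(pm, pt, estimator = config$estimator,
                                  n_points = config$n_points,
                                  seed = seeds[i],
                                  replicates = config$replicates),
                 seeds[i]),
      error = function(e) .sweep_fail(grid[i, ], seeds[i],
                                      conditionMessage(e)))
  })
  .as_sweep(rows, "binding", config)
}

#' Capacity over the miRNA-recycling-rate plane
#'
#' Grid over `(ln kappa1, ln kappa2)` at the recycling preset: differential
#' complex processing (catalytic versus stoichiometric decay) between the
#' competitor and the target.
#'
#' @param config a [sweep_config()] (protocol `"recycling"`).
#' @return A `cerna_sweep` data frame with columns `log_kappa1`,
#'   `log_kappa2`, capacities and AOVs.
#' @export
recycling_sweep <- function(config = sweep_config("recycling")) {
  prem <- cerna_preset("fig6", "mirna")
  pret <- cerna_preset("fig6", "tf")
  rng <- modifyList(prem$sweep, config$overrides)
  g1 <- seq(rng$log_kappa1[1], rng$log_kappa1[2], length.out = config$grid_n)
  g2 <- seq(rng$log_kappa2[1], rng$log_kappa2[2], length.out = config$grid_n)
  grid <- expand.grid(log_kappa1 = g1, log_kappa2 = g2)
  seeds <- derive_seeds(config$seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pm <- prem; pt <- pret
    pm$params$kappa1 <- pt$params$kappa1 <- exp(grid$log_kappa1[i])
    pm$params$kappa2 <- pt$params$kappa2 <- exp(grid$log_kappa2[i])
    tryCatch(
      .sweep_row(grid[i, ],
                 compare_channels(pm, pt, estimator = config$estimator,
                                  n_points = config$n_points,
                                  seed = seeds[i],
                                  replicates = config$replicates),
                 seeds[i]),
      error = function(e) .sweep_fail(grid[i, ], seeds[i],
                                      conditionMessage(e)))
  })
  .as_sweep(rows, "recycling", config)
}

#' Capacity difference over the promoter-occupancy plane
#'
#' Grid over fixed occupancies `(n1, n2)`. The plane's axes are the
#' occupancies held fixed for the channel they do not drive: at a grid
#' point, `I_TF` is computed with the competitor promoter frozen at `n1`
#' (input `f2` swept over the full range) and `I_miRNA` with the target
#' promoter frozen at `n2` (input `f1` swept over the full range); `dI`
#' is their difference.
#'
#' @param config a [sweep_config()] (protocol `"occupancy"`, `variant`
#'   `"A"` = weak catalytic decay on both complexes, `"B"` = strongly
#'   catalytically degraded target with a stoichiometrically degraded
#'   competitor).
#' @return A `cerna_sweep` data frame with columns `n1`, `n2`, capacities
#'   and AOVs.
#' @export
occupancy_sweep <- function(config = sweep_config("occupancy")) {
  name <- if (identical(config$variant, "B")) "fig7B" else "fig7A"
  pre <- cerna_preset(name)
  rng <- modifyList(pre$sweep, config$overrides)
  g1 <- seq(rng$n1[1], rng$n1[2], length.out = config$grid_n)
  g2 <- seq(rng$n2[1], rng$n2[2], length.out = config$grid_n)
  grid <- expand.grid(n1 = g1, n2 = g2)
  seeds <- derive_seeds(config$seed, nrow(grid))
  nmu <- unname(pre$fixed["nmu"])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pm <- pre
    pm$channel <- "mirna"
    pm$fixed <- c(n2 = grid$n2[i], nmu = nmu)
    pt <- pre
    pt$channel <- "tf"
    pt$fixed <- c(n1 = grid$n1[i], nmu = nmu)
    tryCatch(
      .sweep_row(grid[i, ],
                 compare_channels(pm, pt, estimator = config$estimator,
                                  n_points = config$n_points,
                                  seed = seeds[i],
                                  replicates = config$replicates),
                 seeds[i]),
      error = function(e) .sweep_fail(grid[i, ], seeds[i],
                                      conditionMessage(e)))
  })
  .as_sweep(rows, "occupancy", config)
}

#' Capacity as a function of the derepression amplitude (AOV)
#'
#' Sweeps the transcription rate that controls the output range (`b1` for
#' the miRNA channel, `b2` for the pure transcriptional channel without
#' miRNAs) and records `(AOV, capacity)` pairs per channel. The minimum
#' target level is held at the preset's `exp(ln_m2min)`: it arises
#' naturally for the miRNA channel and fixes the lower occupancy endpoint
#' for the TF channel.
#'
#' @param config a [sweep_config()] (protocol `"aov"`); `grid_n` points per
#'   channel, log-spaced over the tabulated transcription-rate ranges.
#' @return A `cerna_sweep` data frame with columns `channel`, `b`, `aov`,
#'   `capacity`, `m2min`, `poisson_limit`.
#' @export
aov_capacity_curve <- function(config = sweep_config("aov")) {
  prem <- cerna_preset("fig8", "mirna")
  pret <- cerna_preset("fig8", "tf")
  m2min_target <- exp(pret$ln_m2min)
  seeds <- derive_seeds(config$seed, 2L * config$grid_n)
  rows <- list()
  b1g <- exp(seq(log(prem$sweep$b1[1]), log(prem$sweep$b1[2]),
                 length.out = config$grid_n))
  for (i in seq_along(b1g)) {
    pm <- prem
    pm$params$b1 <- b1g[i]
    row <- tryCatch({
      rc <- response_curve(pm, estimator = config$estimator,
                           n_points = config$n_points, seed = seeds[i],
                           replicates = config$replicates)
      Z <- attr(optimal_input(rc), "Z")
      data.frame(channel = "mirna", b = b1g[i], aov = response_aov(rc),
                 capacity = channel_capacity(Z), m2min = rc$m2[1],
                 poisson_limit = if (rc$m2[nrow(rc)] > rc$m2[1])
                   poisson_limit_capacity(rc$m2[1], rc$m2[nrow(rc)])
                 else 0,
                 status = "ok", seed = seeds[i])
    }, error = function(e)
      data.frame(channel = "mirna", b = b1g[i], aov = NA, capacity = NA,
                 m2min = NA, poisson_limit = NA,
                 status = paste("failed:", conditionMessage(e)),
                 seed = seeds[i]))
    rows[[length(rows) + 1L]] <- row
  }
  b2g <- exp(seq(log(pret$sweep$b2[1]), log(pret$sweep$b2[2]),
                 length.out = config$grid_n))
  for (i in seq_along(b2g)) {
    pt <- pret
    pt$params$b2 <- b2g[i]
    sd_i <- seeds[config$grid_n + i]
    n_hi <- min(pret$input_n_range[2], 0.99)
    n_lo <- m2min_target * pt$params$d2 / pt$params$b2
    row <- if (n_lo >= n_hi) {
      # derepression window closed: below-threshold point, zero capacity
      data.frame(channel = "tf", b = b2g[i],
                 aov = pt$params$b2 * n_hi / pt$params$d2 - m2min_target,
                 capacity = 0, m2min = m2min_target, poisson_limit = 0,
                 status = "ok", seed = sd_i)
    } else tryCatch({
      rc <- response_curve(pt$params, channel = "tf", fixed = pt$fixed,
                           n_range = c(n_lo, n_hi),
                           estimator = config$estimator,
                           n_points = config$n_points, seed = sd_i,
                           replicates = config$replicates)
      Z <- attr(optimal_input(rc), "Z")
      data.frame(channel = "tf", b = b2g[i], aov = response_aov(rc),
                 capacity = channel_capacity(Z), m2min = rc$m2[1],
                 poisson_limit = poisson_limit_capacity(rc$m2[1],
                                                        rc$m2[nrow(rc)]),
                 status = "ok", seed = sd_i)
    }, error = function(e)
      data.frame(channel = "tf", b = b2g[i], aov = NA, capacity = NA,
                 m2min = NA, poisson_limit = NA,
                 status = paste("failed:", conditionMessage(e)),
                 seed = sd_i))
    rows[[length(rows) + 1L]] <- row
  }
  .as_sweep(rows, "aov", config)
}

#' Capacities and target noise along the miRNA-pool rescaling
#'
#' Applies [rescale_omega()] over a log-spaced `omega` grid to the
#' matched-output-range presets and records both capacities, their
#' difference and the Fano factor of the target (linear noise
#' approximation, evaluated at the mid-range input). The AOV stays
#' approximately constant across `omega` by construction; small `omega`
#' corresponds to a large pool of weakly interacting miRNAs, where the
#' titration noise disappears and the two channels converge.
#'
#' @param config a [sweep_config()] (protocol `"omega"`).
#' @return A `cerna_sweep` data frame with columns `omega`, capacities,
#'   AOVs and `fano_m2`.
#' @export
omega_sweep <- function(config = sweep_config("omega")) {
  prem <- cerna_preset("fig9", "mirna")
  pret <- cerna_preset("fig9", "tf")
  rng <- modifyList(prem$sweep, config$overrides)
  og <- exp(seq(rng$log_omega[1], rng$log_omega[2],
                length.out = config$grid_n))
  seeds <- derive_seeds(config$seed, length(og))
  rows <- lapply(seq_along(og), function(i) {
    pm <- prem
    pm$params <- rescale_omega(pm$params, og[i])
    row <- tryCatch({
      cc <- compare_channels(pm, pret, estimator = config$estimator,
                             n_points = config$n_points, seed = seeds[i],
                             replicates = config$replicates)
      mid <- occupancy_inverse(0.5, pm$params)
      r <- lna(pm$params, c(tf_occupancy(mid, pm$params),
                            pm$fixed["n2"], pm$fixed["nmu"]))
      df <- .sweep_row(data.frame(omega = og[i]), cc, seeds[i])
      df$fano_m2 <- unname(r$fano["m2"])
      df
    }, error = function(e) {
      df <- .sweep_fail(data.frame(omega = og[i]), seeds[i],
                        conditionMessage(e))
      df$fano_m2 <- NA_real_
      df
    })
    row
  })
  .as_sweep(rows, "omega", config)
}

#' @export
print.cerna_sweep <- function(x, ...) {
  proto <- attr(x, "protocol")
  if (is.null(proto)) proto <- "?"
  cat("Sweep '", proto, "': ", nrow(x), " rows (",
      sum(x$status != "ok"), " failed)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.cerna_sweep <- function(x, value = NULL, ...) {
  protocol <- attr(x, "protocol")
  if (protocol %in% c("binding", "recycling", "occupancy")) {
    axes <- names(x)[1:2]
    if (is.null(value)) value <- "dI"
    g1 <- sort(unique(x[[axes[1]]])); g2 <- sort(unique(x[[axes[2]]]))
    z <- matrix(x[[value]][order(x[[axes[2]]], x[[axes[1]]])],
                length(g1), length(g2))
    image(g1, g2, z, xlab = axes[1], ylab = axes[2],
          col = hcl.colors(32, "viridis"), main = value, ...)
  } else if (protocol == "aov") {
    plot(x$aov, x$capacity, col = ifelse(x$channel == "tf", 1, 4),
         pch = 19, log = "x", xlab = "AOV (molecules)",
         ylab = "capacity (bits)", ...)
    legend("topleft", c("TF channel", "miRNA channel"), col = c(1, 4),
           pch = 19, bty = "n")
  } else {
    matplot(x$omega, cbind(x$I_tf, x$I_mirna), type = "b", pch = c(1, 19),
            lty = 1, log = "x", xlab = "omega", ylab = "capacity (bits)",
            ...)
    legend("bottomleft", c("I_TF", "I_miRNA"), pch = c(1, 19), col = 1:2,
           bty = "n")
  }
  invisible(x)
}

#' Write a sweep table and its manifest
#'
#' Writes the long-format CSV next to a JSON run manifest (config echo,
#' package version, wall clock).
#'
#' @param x a `cerna_sweep`.
#' @param path output `.csv` path; the manifest goes to
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  stopifnot(inherits(x, "cerna_sweep"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  man <- attr(x, "manifest")
  if (!is.null(man))
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
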