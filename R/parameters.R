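#' Kinetic parameters of the ceRNA titration network
#'
#' Container for all rate constants of the two-ceRNA / one-miRNA network and
#' the promoter (Hill) parameters shared by the three transcription factors.
#' Defaults are deliberately absent for the network rates: a parameter set is
#' either built explicitly, read from a config file ([read_params()]) or taken
#' from a packaged preset ([cerna_preset()]).
#'
#' The TF-DNA binding and unbinding rates enter the stationary occupancy only
#' through their ratio, so the container stores `kratio` = k_out/k_in
#' (units molecules^h) together with a nominal `kin = 1`.
#'
#' @param b1,b2 ceRNA transcription rates (molecules/min).
#' @param beta miRNA transcription rate (molecules/min).
#' @param d1,d2 spontaneous ceRNA degradation rates (1/min), must be > 0.
#' @param delta spontaneous miRNA degradation rate (1/min), must be > 0.
#' @param kplus1,kplus2 miRNA-ceRNA complex association rates
#'   (1/molecule/min).
#' @param kminus1,kminus2 complex dissociation rates (1/min).
#' @param kappa1,kappa2 catalytic complex decay rates (1/min); the miRNA is
#'   recycled.
#' @param sigma1,sigma2 stoichiometric complex decay rates (1/min); the miRNA
#'   is degraded with the complex.
#' @param kratio ratio k_out/k_in of the TF-DNA unbinding and binding rates
#'   (molecules^h).
#' @param h Hill cooperativity (number of TF molecules bound), integer >= 1.
#' @param kin nominal TF-DNA binding rate (only the ratio matters).
#'
#' @return An object of class `cerna_params` (a named list of the rates).
#' @examples
#' p <- cerna_params(b1 = 120, b2 = 100, beta = 100,
#'                   kplus1 = 2e-3, kplus2 = 1e-3,
#'                   kminus1 = 5e-4, kminus2 = 1e-3,
#'                   kappa1 = 3e-4, kappa2 = 4e-4,
#'                   sigma1 = 0.5, sigma2 = 1)
#' mirna_threshold(p, 1)
#' @export
cerna_params <- function(b1, b2, beta, d1 = 0.1, d2 = 0.1, delta = 0.1,
                         kplus1, kplus2, kminus1, kminus2,
                         kappa1, kappa2, sigma1, sigma2,
                         kratio = 63300, h = 5L, kin = 1) {
  p <- list(b1 = b1, b2 = b2, beta = beta, d1 = d1, d2 = d2, delta = delta,
            kplus1 = kplus1, kplus2 = kplus2,
            kminus1 = kminus1, kminus2 = kminus2,
            kappa1 = kappa1, kappa2 = kappa2,
            sigma1 = sigma1, sigma2 = sigma2,
            kratio = kratio, h = as.integer(h), kin = kin)
  validate_params(p)
  class(p) <- "cerna_params"
  p
}

validate_params <- function(p) {
  num <- setdiff(names(p), "h")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    if (p[[f]] < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  for (f in c("d1", "d2", "delta", "kratio", "kin"))
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0", call. = FALSE)
  if (p$h < 1L) stop("Hill cooperativity h must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.cerna_params <- function(x, ...) {
  cat("ceRNA network kinetic parameters\n")
  cat(sprintf("  transcription   b1 = %g, b2 = %g, beta = %g  [molec/min]\n",
              x$b1, x$b2, x$beta))
  cat(sprintf("  degradation     d1 = %g, d2 = %g, delta = %g  [1/min]\n",
              x$d1, x$d2, x$delta))
  cat(sprintf("  association     k1+ = %g, k2+ = %g  [1/molec/min]\n",
              x$kplus1, x$kplus2))
  cat(sprintf("  dissociation    k1- = %g, k2- = %g  [1/min]\n",
              x$kminus1, x$kminus2))
  cat(sprintf("  catalytic       kappa1 = %g, kappa2 = %g  [1/min]\n",
              x$kappa1, x$kappa2))
  cat(sprintf("  stoichiometric  sigma1 = %g, sigma2 = %g  [1/min]\n",
              x$sigma1, x$sigma2))
  cat(sprintf("  promoter        h = %d, k_out/k_in = %g\n", x$h, x$kratio))
  invisible(x)
}

#' Rescale miRNA turnover and binding rates
#'
#' Applies the joint rescaling `delta -> omega * delta`,
#' `ki+ -> omega * ki+` (i = 1, 2) that tunes the size of the miRNA pool and
#' the strength of individual miRNA-ceRNA interactions while leaving the mean
#' target response essentially unchanged (exactly unchanged when complex
#' dissociation and recycling return negligible flux). Small `omega`
#' corresponds to a large population of weakly interacting miRNAs.
#'
#' @param params a [cerna_params()] object.
#' @param omega positive rescaling factor; `omega = 1` is the identity.
#' @return A `cerna_params` object with `delta`, `kplus1`, `kplus2` rescaled.
#' @examples
#' p <- cerna_preset("fig9", channel = "mirna")$params
#' rescale_omega(p, 0.5)$delta
#' @export
rescale_omega <- function(params, omega) {
  stopifnot(inherits(params, "cerna_params"))
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega <= 0)
    stop("omega must be a single positive number")
  params$delta <- params$delta * omega
  params$kplus1 <- params$kplus1 * omega
  params$kplus2 <- params$kplus2 * omega
  params
}

#' Read / write kinetic parameter sets as structured-text config
#'
#' Parameter sets are stored as flat key-value maps whose names match the
#' [cerna_params()] fields. The dialect is chosen from the file extension:
#' `.json` via jsonlite, `.yaml`/`.yml` via yaml.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param params a `cerna_params` object.
#' @return `read_params()` returns a `cerna_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  x <- read_config(path)
  do.call(cerna_params, x)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cerna_params"))
  write_config(unclass(params), path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config extension '", ext, "' (use json or yaml)"))
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("unsupported config extension '", ext, "' (use json or yaml)"))
  invisible(path)
}
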