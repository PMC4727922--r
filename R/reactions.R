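#' Reaction system of the ceRNA network
#'
#' Builds the 14-reaction mass-action system over the species
#' `(m1, m2, mu, c1, c2)`: three zeroth-order syntheses (promoter occupancies
#' are frozen at their fast-equilibrium values, so transcription propensities
#' are constants), three spontaneous decays, two miRNA-ceRNA associations,
#' two dissociations, two catalytic complex decays (the miRNA is returned to
#' the free pool) and two stoichiometric complex decays (the miRNA is lost
#' with the complex).
#'
#' @param params a [cerna_params()] object.
#' @param input a [tf_input()] object or length-3 occupancy vector
#'   `(n1, n2, nmu)`.
#' @return An object of class `cerna_reactions`: list with `stoich` (14 x 5
#'   integer matrix), `rates` (the 14 rate constants consumed by the
#'   propensity law), `propensity(x)` (function returning the 14 propensities
#'   at integer state `x`), `params`, `occupancy`.
#' @examples
#' pre <- cerna_preset("fig2")
#' rs <- reaction_system(pre$params, c(0.5, 0.71, 0.9))
#' rs$propensity(c(2, 0, 3, 0, 0))
#' @export
reaction_system <- function(params, input) {
  stopifnot(inherits(params, "cerna_params"))
  n <- if (inherits(input, "cerna_input")) input$n else as.numeric(input)
  if (length(n) != 3L || any(n < 0) || any(n > 1))
    stop("occupancies must be three values in [0, 1]")

  stoich <- matrix(c(
     1,  0,  0,  0,  0,   # synthesis m1
     0,  1,  0,  0,  0,   # synthesis m2
     0,  0,  1,  0,  0,   # synthesis mu
    -1,  0,  0,  0,  0,   # decay m1
     0, -1,  0,  0,  0,   # decay m2
     0,  0, -1,  0,  0,   # decay mu
    -1,  0, -1,  1,  0,   # association 1
     0, -1, -1,  0,  1,   # association 2
     1,  0,  1, -1,  0,   # dissociation 1
     0,  1,  1,  0, -1,   # dissociation 2
     0,  0,  1, -1,  0,   # catalytic decay c1 (miRNA recycled)
     0,  0,  1,  0, -1,   # catalytic decay c2
     0,  0,  0, -1,  0,   # stoichiometric decay c1 (miRNA lost)
     0,  0,  0,  0, -1),  # stoichiometric decay c2
    ncol = 5, byrow = TRUE,
    dimnames = list(c("syn_m1", "syn_m2", "syn_mu", "deg_m1", "deg_m2",
                      "deg_mu", "assoc_1", "assoc_2", "dissoc_1", "dissoc_2",
                      "cat_1", "cat_2", "stoich_1", "stoich_2"), .species))

  rates <- c(params$b1 * n[1], params$b2 * n[2], params$beta * n[3],
             params$d1, params$d2, params$delta,
             params$kplus1, params$kplus2,
             params$kminus1, params$kminus2,
             params$kappa1, params$kappa2,
             params$sigma1, params$sigma2)
  names(rates) <- rownames(stoich)

  propensity <- function(x) {
    stopifnot(length(x) == 5L, all(x >= 0))
    c(rates[1], rates[2], rates[3],
      rates[4] * x[1], rates[5] * x[2], rates[6] * x[3],
      rates[7] * x[3] * x[1], rates[8] * x[3] * x[2],
      rates[9] * x[4], rates[10] * x[5],
      rates[11] * x[4], rates[12] * x[5],
      rates[13] * x[4], rates[14] * x[5])
  }

  structure(list(stoich = stoich, rates = rates, propensity = propensity,
                 params = params,
                 occupancy = setNames(n, c("n1", "n2", "nmu"))),
            class = "cerna_reactions")
}

#' @export
print.cerna_reactions <- function(x, ...) {
  cat("ceRNA reaction system: 14 reactions over (m1, m2, mu, c1, c2)\n")
  cat("  synthesis propensities:",
      paste(signif(x$rates[1:3], 4), collapse = ", "), "molec/min\n")
  invisible(x)
}
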