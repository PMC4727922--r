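#' Equilibrium promoter occupancy under cooperative TF binding
#'
#' Fractional occupancy of a promoter bound cooperatively by `h` copies of a
#' transcription factor present at copy number `f`, at binding/unbinding
#' equilibrium:
#' \deqn{\bar n(f) = \frac{f^h}{f^h + k_{out}/k_{in}}.}
#' Strictly increasing in `f`, with `n(0) = 0` and `n -> 1` at saturation.
#'
#' @param f TF copy number(s), >= 0 (vectorised).
#' @param params a [cerna_params()] object (uses `h` and `kratio`).
#' @return Occupancies in `[0, 1)`.
#' @seealso [occupancy_inverse()]
#' @export
tf_occupancy <- function(f, params) {
  stopifnot(inherits(params, "cerna_params"))
  if (any(!is.finite(f) & !is.infinite(f)) || any(f < 0, na.rm = TRUE))
    stop("TF copy number f must be >= 0")
  fh <- f^params$h
  ifelse(is.infinite(fh), 1, fh / (fh + params$kratio))
}

#' TF copy number producing a given promoter occupancy
#'
#' Closed-form inverse of [tf_occupancy()]:
#' \deqn{f(n) = \left(\frac{n}{1-n}\, k_{out}/k_{in}\right)^{1/h}.}
#' Used to map occupancy ranges (the natural specification of an input range)
#' to TF copy-number ranges.
#'
#' @param n occupancy value(s) in `(0, 1)` (vectorised); `n = 0` maps to 0.
#' @param params a [cerna_params()] object.
#' @return TF copy numbers.
#' @export
occupancy_inverse <- function(n, params) {
  stopifnot(inherits(params, "cerna_params"))
  if (any(n < 0 | n >= 1, na.rm = TRUE))
    stop("occupancy n must lie in [0, 1)")
  out <- (n / (1 - n) * params$kratio)^(1 / params$h)
  out[n == 0] <- 0
  out
}

#' TF input for the three promoters
#'
#' Bundles the TF copy numbers `(f1, f2, fmu)` and the corresponding
#' equilibrium occupancies `(n1, n2, nmu)`. Either copy numbers (`f`) or
#' occupancies (`n`) can be given; the other is filled in via
#' [tf_occupancy()] / [occupancy_inverse()].
#'
#' @param params a [cerna_params()] object.
#' @param f numeric length-3 vector of TF copy numbers `(f1, f2, fmu)`.
#' @param n numeric length-3 vector of occupancies `(n1, n2, nmu)` in
#'   `[0, 1)`.
#' @return An object of class `cerna_input` with elements `f` and `n`.
#' @examples
#' p <- cerna_preset("fig2")$params
#' tf_input(p, n = c(0.5, 0.71, 0.9))
#' @export
tf_input <- function(params, f = NULL, n = NULL) {
  stopifnot(inherits(params, "cerna_params"))
  if (is.null(f) == is.null(n))
    stop("supply exactly one of 'f' (copy numbers) or 'n' (occupancies)")
  if (is.null(n)) {
    stopifnot(length(f) == 3L)
    n <- tf_occupancy(f, params)
  } else {
    stopifnot(length(n) == 3L)
    f <- occupancy_inverse(n, params)
  }
  structure(list(f = setNames(as.numeric(f), c("f1", "f2", "fmu")),
                 n = setNames(as.numeric(n), c("n1", "n2", "nmu"))),
            class = "cerna_input")
}

#' @export
print.cerna_input <- function(x, ...) {
  cat("TF input: f = (", paste(signif(x$f, 4), collapse = ", "),
      "), n = (", paste(signif(x$n, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
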