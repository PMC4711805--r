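#' Kernel specification for mean-shift density estimation
#'
#' A kernel is written `K(x) = c_kd * k(||x||^2)` with profile `k` and shadow
#' `g(x) = -k'(x)`; the shadow supplies the weights of the mean-shift update.
#'
#' * `gaussian`: `k(x) = exp(-x/2)`, `g(x) = exp(-x/2) / 2` (the shadow is the
#'   profile up to a constant, which cancels in the update). Guarantees
#'   monotone density ascent along every trajectory.
#' * `flat`: `k = g = 1` on `[0, 1]`, `0` beyond — the update moves a point to
#'   the centroid of the data within distance `h`.
#'
#' @param name `"gaussian"` (default) or `"flat"`.
#' @param dimension Feature-space dimension `d` (4 for nucleotide counts);
#'   only used for the normalisation constant `c_kd`.
#' @return A `kernel_spec` object: list with `name`, profile `k`, shadow `g`,
#'   normalisation `c_kd` and `dimension`.
#' @export
kernel_spec <- function(name = c("gaussian", "flat"), dimension = 4L) {
  name <- match.arg(name)
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1L)
  if (name == "gaussian") {
    spec <- list(
      name = name,
      k = function(x) exp(-x / 2),
      g = function(x) 0.5 * exp(-x / 2),
      c_kd = (2 * pi)^(-dimension / 2),
      dimension = dimension
    )
  } else {
    # unit-ball volume^-1 normalises the flat kernel to integrate to 1
    spec <- list(
      name = name,
      k = function(x) as.numeric(x <= 1),
      g = function(x) as.numeric(x <= 1),
      c_kd = gamma(dimension / 2 + 1) / pi^(dimension / 2),
      dimension = dimension
    )
  }
  structure(spec, class = "kernel_spec")
}

as_kernel_spec <- function(kernel, dimension) {
  if (inherits(kernel, "kernel_spec")) {
    return(kernel)
  }
  kernel_spec(kernel, dimension = dimension)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s, d = %d, c_kd = %.6g\n", x$name, x$dimension, x$c_kd))
  invisible(x)
}
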