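#' Boltzmann constant [J/K]
#' @noRd
.kB <- 1.380649e-23

#' Convert micrometres to metres
#'
#' All internal quantities are SI; configuration files and the experiment
#' helpers accept micrometre conveniences through this helper.
#'
#' @param x numeric vector of lengths in micrometres.
#' @return lengths in metres.
#' @export
#' @examples
#' um(1.2) # 1.2e-06
um <- function(x) x * 1e-6

## row-wise cross product of two n x 3 matrices
vec_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

vec_norm <- function(x) sqrt(sum(x^2))

## scalar checks used by the constructors
check_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be positive", call. = FALSE)
  invisible(x)
}
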