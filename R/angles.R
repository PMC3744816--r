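#' Circular angle helpers
#'
#' Torsion angles are stored internally on the half-open interval
#' (-180, 180]; inputs on [0, 360) are accepted everywhere and wrapped.
#'
#' @param x numeric vector of angles in degrees.
#' @return `wrap_angle` returns angles wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(300, 180, -190))  # -60, 180, 170
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' @rdname wrap_angle
#' @param a,b angles in degrees.
#' @return `circ_dist` returns the absolute circular distance in [0, 180].
#' @export
circ_dist <- function(a, b) abs(wrap_angle(a - b))

#' @rdname wrap_angle
#' @return `circ_mean` returns the circular mean direction in (-180, 180].
#' @export
circ_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' @rdname wrap_angle
#' @return `circ_sd` returns the circular standard deviation in degrees
#'   (sqrt(-2 log R), the mean-resultant-length form).
#' @export
circ_sd <- function(x) {
  r <- x * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

# angle at vertex b (degrees) for points a-b-c
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(max(ct, -1), 1)) * 180 / pi
}
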