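#' Faddeeva function by Weideman's rational approximation
#'
#' Evaluates the scaled complex complementary error function
#' \eqn{w(z) = e^{-z^2} \mathrm{erfc}(-iz)}, the building block of the true
#' (convolution) Voigt line shape. The rational approximation follows
#' Weideman's construction: the coefficients are obtained from a single FFT of
#' a sampled auxiliary function and the polynomial is evaluated in the Möbius
#' variable \eqn{Z = (L + iz)/(L - iz)}. Accuracy improves with `order`;
#' at `order = 24` the relative error is below 1e-6 across the upper
#' half-plane (in practice ~1e-10 for moderate arguments).
#'
#' Arguments in the lower half-plane are handled through the reflection
#' identity \eqn{w(z) = 2 e^{-z^2} - \overline{w(\bar z)}}.
#'
#' @param z complex vector of evaluation points.
#' @param order integer, number of rational-approximation terms (>= 8).
#' @return complex vector of the same length as `z`.
#' @examples
#' faddeeva(0 + 0i)            # exactly 1
#' faddeeva(1i)                # exp(1) * erfc(1) ~ 0.42758
#' @export
faddeeva <- function(z, order = 24L) {
  stopifnot(is.numeric(order), length(order) == 1L)
  order <- as.integer(order)
  if (order < 8L) stop("'order' must be at least 8")
  z <- as.complex(z)

  a <- weideman_coefficients(order)
  L <- sqrt(order / sqrt(2))

  lower <- Im(z) < 0
  zz <- z
  zz[lower] <- Conj(z[lower])

  Z <- (L + 1i * zz) / (L - 1i * zz)
  p <- rep(0 + 0i, length(zz))
  for (cf in a) p <- p * Z + cf
  w <- 2 * p / (L - 1i * zz)^2 + (1 / sqrt(pi)) / (L - 1i * zz)
  if (any(lower)) {
    w[lower] <- 2 * exp(-z[lower]^2) - Conj(w[lower])
  }
  w
}

# Polynomial coefficients of Weideman's approximation (highest degree first),
# cached per order.
weideman_coefficients <- local({
  cache <- list()
  function(order) {
    key <- as.character(order)
    if (!is.null(cache[[key]])) return(cache[[key]])
    N <- order
    M <- 2L * N
    M2 <- 2L * M
    L <- sqrt(N / sqrt(2))
    k <- seq(-M + 1L, M - 1L)
    t <- L * tan((k * pi / M) / 2)
    f <- c(0, exp(-t^2) * (L^2 + t^2))
    a <- Re(stats::fft(ifftshift_vec(f))) / M2
    a <- rev(a[2:(N + 1L)])
    cache[[key]] <<- a
    a
  }
})
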