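#' Bessel function of the first kind for complex argument
#'
#' Evaluates J0 or J1 at complex arguments, as needed by the Womersley
#' solution whose Bessel argument i^{3/2} alpha r/R lies on the ray
#' arg z = 3 pi/4. Base R's [besselJ()] accepts only real arguments, so the
#' evaluation is done here: an ascending power series for |z| <= 20 (where
#' cancellation error is bounded by exp(|Im z|) * eps < 1e-9) and the Hankel
#' asymptotic expansion beyond.
#'
#' @param z complex (or numeric) vector.
#' @param nu order, 0 or 1.
#' @return complex vector of J_nu(z).
#' @section Numerical range: |J_nu(z)| grows like exp(|Im z|); arguments with
#'   |Im z| > 650 (Womersley number beyond ~900) would overflow double
#'   precision and raise a numeric-range error.
#' @export
besselJ_complex <- function(z, nu) {
  if (!nu %in% c(0, 1)) stop("nu must be 0 or 1", call. = FALSE)
  z <- as.complex(z)
  if (any(abs(Im(z)) > 650))
    stop("numeric range: Bessel argument too large in imaginary part; ",
         "J_nu would overflow double precision", call. = FALSE)
  out <- complex(length(z))
  small <- Mod(z) <= 20
  if (any(small)) {
    zs <- z[small]
    term <- (zs / 2)^nu / gamma(nu + 1)
    s <- term
    for (k in 1:220) {
      term <- term * (-(zs / 2)^2) / (k * (k + nu))
      s <- s + term
      if (all(Mod(term) <= 1e-18 * Mod(s))) break
    }
    out[small] <- s
  }
  if (any(!small)) {
    # Hankel expansion, |arg z| < pi: J_nu(z) ~ sqrt(2/(pi z)) *
    #   (P(nu,z) cos(chi) - Q(nu,z) sin(chi)), chi = z - (nu/2 + 1/4) pi
    zl <- z[!small]
    mu4 <- 4 * nu^2
    chi <- zl - (nu / 2 + 0.25) * pi
    P <- 1 + 0i * zl
    Q <- 0i * zl
    ak <- 1 + 0i * zl
    for (k in 1:8) {
      ak <- ak * (mu4 - (2 * k - 1)^2) / (k * 8 * zl)
      if (k %% 2 == 0) P <- P + ak * (-1)^(k / 2)
      else Q <- Q + ak * (-1)^((k - 1) / 2)
    }
    out[!small] <- sqrt(2 / (pi * zl)) * (P * cos(chi) - Q * sin(chi))
  }
  out
}
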