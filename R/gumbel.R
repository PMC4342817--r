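# Gumbel (type-I extreme value) fitting for E-value calibration.
# No installed package provides a direct Gumbel MLE for this use, so the
# two standard likelihood equations are solved here (scale by uniroot,
# location in closed form given the scale).

.dgumbel <- function(x, mu, beta) {
  z <- (x - mu) / beta
  exp(-z - exp(-z)) / beta
}

# P(X >= x) under Gumbel(mu, beta); accurate for small upper tails.
.pgumbelUpper <- function(x, mu, lambda) {
  -expm1(-exp(-lambda * (x - mu)))
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location \code{mu} and inverse scale \code{lambda} of a Gumbel
#' distribution to a numeric sample by maximum likelihood.
#'
#' @param x Numeric vector (at least 10 values, non-degenerate).
#' @return List with elements \code{mu} and \code{lambda}.
#' @keywords internal
gumbelFit <- function(x) {
  if (length(x) < 10L) stop("too few values for a Gumbel fit")
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate scores (zero variance): cannot fit Gumbel")
  # Moment start: beta = sd * sqrt(6) / pi.
  beta0 <- s * sqrt(6) / pi
  xc <- x - mean(x)  # center for numerical stability; shift mu back later
  f <- function(beta) {
    w <- exp(-xc / beta)
    beta - mean(xc) + sum(xc * w) / sum(w)
  }
  lo <- beta0 / 20
  hi <- beta0 * 20
  # Widen the bracket if needed.
  for (i in 1:10) {
    if (sign(f(lo)) != sign(f(hi))) break
    lo <- lo / 4; hi <- hi * 4
  }
  if (sign(f(lo)) == sign(f(hi)))
    stop("Gumbel fit failed: no bracketing interval for the scale")
  beta <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  mu <- -beta * log(mean(exp(-xc / beta))) + mean(x)
  list(mu = mu, lambda = 1 / beta)
}
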