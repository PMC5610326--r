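# Modified Bessel functions K0, K1 for complex argument with Re(z) > 0.
#
# The horizontal-bilayer deformation fields are damped-oscillatory in rho and
# are represented on the basis K_nu(q*rho) with complex decay exponents q
# (Re q > 0). Base R only evaluates Bessel functions on the real axis, so the
# two functions needed are provided here: ascending series for small |z|,
# Steed-type continued fraction (Thompson-Barnett CF2) elsewhere. Both are
# standard algorithms for the right half-plane; accuracy is ~1e-13 relative
# over the argument range met in practice (|z| up to ~100, |arg z| < 80 deg).

.EULER_GAMMA <- 0.57721566490153286060651209

# ascending-series evaluation, vectorized; |z| modest (cancellation grows
# like eps*exp(|z| + Re z), keep below |z| ~ 5)
.cbesselK01_series <- function(z) {
  n <- length(z)
  z2 <- z * z / 4
  lg <- log(z / 2)
  # I0/I1 partial sums and the companion psi-weighted sums
  termI0 <- rep(1 + 0i, n)        # u_k = (z^2/4)^k / (k!)^2
  termI1 <- rep(1 + 0i, n)        # v_k = (z^2/4)^k / (k! (k+1)!)
  I0 <- termI0
  I1s <- termI1                   # I1 = (z/2) * I1s
  S0 <- rep(0 + 0i, n)            # sum u_k H_k, k >= 1
  S1 <- rep(1 + 0i, n) * 0        # sum (H_k + H_{k+1}) v_k, k >= 0 (k=0 term added below)
  Hk <- 0
  S1 <- S1 + termI1 * (0 + 1)     # k = 0: H_0 + H_1 = 1
  for (k in 1:80) {
    termI0 <- termI0 * z2 / (k * k)
    termI1 <- termI1 * z2 / (k * (k + 1))
    Hk <- Hk + 1 / k
    I0 <- I0 + termI0
    I1s <- I1s + termI1
    S0 <- S0 + termI0 * Hk
    S1 <- S1 + termI1 * (2 * Hk + 1 / (k + 1))
    if (max(Mod(termI0)) < 1e-18 * max(Mod(I0), 1)) break
  }
  I1 <- (z / 2) * I1s
  K0 <- -(lg + .EULER_GAMMA) * I0 + S0
  K1 <- 1 / z + lg * I1 - (z / 4) * (S1 - 2 * .EULER_GAMMA * I1s)
  list(K0 = K0, K1 = K1)
}

# Thompson-Barnett CF2, order 0; valid Re z > 0, best for |z| >= ~2
.cbesselK01_cf <- function(z) {
  n <- length(z)
  b <- 2 * (1 + z)
  d <- 1 / b
  h <- d
  delh <- d
  q1 <- rep(0 + 0i, n)
  q2 <- rep(1 + 0i, n)
  a1 <- 0.25
  q <- rep(a1, n) + 0i
  cc <- rep(a1, n) + 0i
  a <- rep(-a1, n) + 0i
  s <- 1 + q * delh
  active <- rep(TRUE, n)
  for (i in 2:20000) {
    a[active] <- a[active] - 2 * (i - 1)
    cc[active] <- -a[active] * cc[active] / i
    qnew <- (q1[active] - b[active] * q2[active]) / a[active]
    q1[active] <- q2[active]
    q2[active] <- qnew
    q[active] <- q[active] + cc[active] * qnew
    b[active] <- b[active] + 2
    d[active] <- 1 / (b[active] + a[active] * d[active])
    delh[active] <- (b[active] * d[active] - 1) * delh[active]
    h[active] <- h[active] + delh[active]
    dels <- q[active] * delh[active]
    s[active] <- s[active] + dels
    conv <- Mod(dels) < 1e-16 * Mod(s[active])
    if (any(conv)) {
      idx <- which(active)
      active[idx[conv]] <- FALSE
    }
    if (!any(active)) break
  }
  if (any(active))
    stop("continued fraction for complex besselK failed to converge; |z| = ",
         paste(signif(Mod(z[active]), 4), collapse = ", "))
  h <- a1 * h
  K0 <- sqrt(pi / (2 * z)) * exp(-z) / s
  K1 <- K0 * (z + 0.5 - h) / z
  list(K0 = K0, K1 = K1)
}

#' Modified Bessel functions of the second kind, orders 0 and 1, complex z
#'
#' Requires Re(z) > 0 (the decaying half-plane used for the bilayer basis).
#'
#' @param z complex (or numeric) vector with positive real parts.
#' @return list with components `K0`, `K1` (complex vectors).
#' @keywords internal
#' @export
cbesselK01 <- function(z) {
  z <- as.complex(z)
  if (any(Re(z) <= 0)) stop("cbesselK01 requires Re(z) > 0")
  out0 <- complex(length(z))
  out1 <- complex(length(z))
  small <- Mod(z) < 2
  if (any(small)) {
    r <- .cbesselK01_series(z[small])
    out0[small] <- r$K0
    out1[small] <- r$K1
  }
  if (any(!small)) {
    r <- .cbesselK01_cf(z[!small])
    out0[!small] <- r$K0
    out1[!small] <- r$K1
  }
  list(K0 = out0, K1 = out1)
}
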