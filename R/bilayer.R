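# Horizontal (quasi-flat) bilayer region around the pore.
#
# Deformation fields: n(rho) - radial director projection, alpha(rho) -
# relative area stretch, both on the neutral surface of the upper monolayer;
# the neutral-surface height follows from local volumetric incompressibility,
#   H(rho) = h - (h^2/2) * (n' + n/rho) - h * alpha.
# The elastic energy (both monolayers, dimensionless tension sigma =
# sigma0/K_t) is
#   W_b = 2*pi*K_t Int_{R0}^Inf rho { l^2 (s + J0)^2 - l^2 J0^2
#           + t^2 + A alpha^2 + sigma w^2 } drho,
# with s = n' + n/rho (splay), w = (h^2/2) s' + h alpha' (= -H', area tilt),
# t = n + w (tilt). Variation gives two Euler-Lagrange equations
#   A alpha = h * (T'/1 + T/rho),   h^2 * L1[T] + 2 t - 2 l^2 s' = 0,
# where T = t + sigma*w and L1 is the order-1 cylindrical operator. The
# decaying solutions are K_1(q rho) for n (K_0(q rho) for alpha and s) with
# two complex exponents q, the roots of a quadratic in x = q^2 derived below.
# Energy on solutions is evaluated exactly from the boundary-flux identity
# for quadratic functionals; quadrature is kept for component breakdowns and
# cross-checks.

# Quadratic a2*x^2 + a1*x + a0 = 0 in x = q^2 for the decay exponents.
# Derived from the functional via the K-family ansatz:
#   omega = c1*x / (1 - c2*x),  tau = 1 + omega,
#   h^2 x (tau + sigma*omega) + 2 tau = 2 l^2 x,
# with c1 = h^2 (A+2)/(2A), c2 = h^2 (1+sigma)/A.
.bilayer_char_coefs <- function(lipid, sigma = 0) {
  h2 <- lipid$h^2
  A <- lipid$A
  l2 <- lipid$l2
  P <- 1 + sigma
  c1 <- h2 * (A + 2) / (2 * A)
  c2 <- h2 * P / A
  list(a2 = c1 * h2 * P - c2 * (h2 - 2 * l2),
       a1 = (h2 - 2 * l2) + 2 * c1 - 2 * c2,
       a0 = 2,
       c1 = c1, c2 = c2)
}

#' Characteristic decay exponents of the horizontal bilayer region
#'
#' Roots of the characteristic equation of the Euler-Lagrange system of the
#' bilayer-region elastic functional, in the convention n(rho) ~ K_1(q rho):
#' Re(q) > 0 so that deformations decay away from the pore. For all physical
#' lipid parameter sets the two exponents form a complex-conjugate pair
#' (damped oscillatory decay). Branch convention: `q[1]` has Im(q) >= 0;
#' swapping the sign of the inner square root exchanges the two.
#'
#' @param lipid [lipid_parameters()] object.
#' @param sigma dimensionless lateral tension sigma0/K_t (>= 0).
#' @return complex vector `c(q1, q2)` in 1/nm.
#' @export
characteristic_roots <- function(lipid, sigma = 0) {
  stopifnot(inherits(lipid, "lipid_parameters"), sigma >= 0)
  cf <- .bilayer_char_coefs(lipid, sigma)
  if (abs(cf$a2) < 1e-14)
    stop("degenerate lipid parameters: leading characteristic coefficient vanishes")
  disc <- as.complex(cf$a1^2 - 4 * cf$a2 * cf$a0)
  sq <- sqrt(disc)
  x <- c((-cf$a1 + sq), (-cf$a1 - sq)) / (2 * cf$a2)
  q <- sqrt(x)
  q <- ifelse(Re(q) < 0, -q, q)
  if (any(Re(q) <= 1e-12))
    stop("non-decaying characteristic root encountered; parameters: h^2*A + 4*l^2 = ",
         lipid$h^2 * lipid$A + 4 * lipid$l2)
  q[order(-Im(q))]
}

# Per-root structure constants of the K-family ansatz:
#   n = K1(q rho), s = -q K0, alpha = amp*K0, w = omega*K1, t = tau*K1.
.bilayer_mode <- function(lipid, sigma, q) {
  cf <- .bilayer_char_coefs(lipid, sigma)
  x <- q * q
  omega <- cf$c1 * x / (1 - cf$c2 * x)
  tau <- 1 + omega
  amp <- -lipid$h * q * (tau + sigma * omega) / lipid$A   # alpha amplitude
  list(q = q, omega = omega, tau = tau, amp = amp)
}

# Values of the mode fields and the derivatives needed by boundary terms,
# at radii rho (vectorized). Returns complex matrices: one column per rho.
.bilayer_mode_fields <- function(mode, rho) {
  q <- mode$q
  z <- q * rho
  K <- cbesselK01(z)
  K0 <- K$K0; K1 <- K$K1
  dK1 <- -q * K0 - K1 / rho          # d/drho K1(q rho)
  n <- K1
  s <- -q * K0
  sp <- q * q * K1                   # s'
  alpha <- mode$amp * K0
  w <- mode$omega * K1
  t <- mode$tau * K1
  tp <- mode$tau * dK1
  wp <- mode$omega * dK1
  np <- dK1
  rbind(n = n, np = np, s = s, sp = sp, alpha = alpha,
        w = w, wp = wp, t = t, tp = tp)
}

#' Solve the horizontal bilayer region for given junction data
#'
#' Selects the two decaying degrees of freedom of the general solution and
#' fixes them by the junction conditions `n(R0) = n0` and `H(R0) = Z0`
#' (neutral-surface height from local incompressibility). The returned
#' object carries real field functions `n(rho)`, `alpha(rho)`, `H(rho)`.
#'
#' @param lipid [lipid_parameters()] object.
#' @param env [environment_parameters()] object (only `sigma0` is used here).
#' @param R0 junction circle radius, nm (> 0).
#' @param Z0 junction circle height, nm.
#' @param n0 director radial projection at the junction (|n0| < 1).
#' @return object of class `bilayer_solution`.
#' @export
solve_bilayer <- function(lipid, env, R0, Z0, n0) {
  stopifnot(R0 > 0, abs(n0) < 1)
  sigma <- env$sigma0 / lipid$K_t
  q <- characteristic_roots(lipid, sigma)
  conj_pair <- abs(Im(q[1]) + Im(q[2])) < 1e-9 * max(1, abs(Im(q[1])))
  modes <- lapply(q, .bilayer_mode, lipid = lipid, sigma = sigma)
  # real generators: columns of field values per unit coefficient
  gen_fields <- function(rho) {
    F1 <- .bilayer_mode_fields(modes[[1]], rho)
    if (conj_pair) {
      # coefficients c, conj(c): field = 2*Re(c * F1); generators Re, -Im
      list(2 * Re(F1), -2 * Im(F1))
    } else {
      F2 <- .bilayer_mode_fields(modes[[2]], rho)
      list(Re(F1), Re(F2))
    }
  }
  h <- lipid$h
  G <- gen_fields(R0)
  # boundary rows: n(R0); H(R0) - h = -(h^2/2) s - h alpha
  bc_row <- function(Fm) c(Fm["n", 1], -(h^2 / 2) * Fm["s", 1] - h * Fm["alpha", 1])
  Mbc <- cbind(bc_row(G[[1]]), bc_row(G[[2]]))
  rhs <- c(n0, Z0 - h)
  rc <- rcond(Mbc)
  if (!is.finite(rc) || rc < 1e-14)
    stop(sprintf("singular junction system in bilayer solve (R0 = %.4g, q = %s)",
                 R0, paste(format(q, digits = 4), collapse = ", ")))
  if (rc < 1e-12)
    warning(sprintf("ill-conditioned bilayer junction system (rcond = %.2e)", rc))
  coef <- solve(Mbc, rhs)
  sol <- list(lipid = lipid, env = env, sigma = sigma,
              R0_applied = R0, Z0_applied = Z0, n0_applied = n0,
              q = q, modes = modes, conj_pair = conj_pair, coef = coef,
              gen_fields = gen_fields)
  class(sol) <- "bilayer_solution"
  sol
}

# all real fields at radii rho: matrix fields x rho
.bilayer_fields <- function(sol, rho) {
  G <- sol$gen_fields(rho)
  sol$coef[1] * G[[1]] + sol$coef[2] * G[[2]]
}

#' Deformation fields of a bilayer solution
#'
#' @param sol `bilayer_solution`.
#' @param rho radii, nm (>= R0).
#' @return data.frame with columns `rho`, `n`, `alpha`, `H`.
#' @export
bilayer_fields <- function(sol, rho) {
  Fm <- .bilayer_fields(sol, rho)
  h <- sol$lipid$h
  data.frame(rho = rho,
             n = Fm["n", ],
             alpha = Fm["alpha", ],
             H = h - (h^2 / 2) * Fm["s", ] - h * Fm["alpha", ])
}

#' Elastic energy of the horizontal bilayer region
#'
#' On Euler-Lagrange solutions the quadratic part of the functional equals a
#' boundary flux at rho = R0 (the fields decay at infinity), which is the
#' default evaluation; `method = "quadrature"` integrates the energy density
#' instead and additionally reports the splay/tilt/stretch components.
#'
#' @param sol `bilayer_solution`.
#' @param method `"boundary"` (exact, default) or `"quadrature"`.
#' @return for `"boundary"` a number (kBT); for `"quadrature"` a list with
#'   `total`, `splay`, `tilt`, `stretch`, `tension` (kBT).
#' @export
bilayer_energy <- function(sol, method = c("boundary", "quadrature")) {
  method <- match.arg(method)
  lip <- sol$lipid
  Kt <- lip$K_t
  h <- lip$h
  l2 <- lip$l2
  A <- lip$A
  sg <- sol$sigma
  J0 <- lip$J0
  R0 <- sol$R0_applied
  # linear (spontaneous-curvature) part integrates exactly:
  # 2 pi Kt * 2 l^2 J0 * [rho n]_{R0}^{Inf} = -4 pi B J0 R0 n0
  W_lin <- -4 * pi * lip$B * J0 * R0 * sol$n0_applied
  if (method == "boundary") {
    Fm <- .bilayer_fields(sol, R0)
    Tq <- Fm["t", 1] + sg * Fm["w", 1]
    Tqp <- Fm["tp", 1] + sg * Fm["wp", 1]
    Wq <- -pi * Kt * R0 * (Fm["n", 1] * (2 * l2 * Fm["s", 1] - h^2 * Tqp) +
                             Fm["np", 1] * h^2 * Tq +
                             2 * h * Tq * Fm["alpha", 1])
    return(unname(Wq + W_lin))
  }
  # quadrature path: Gauss-Legendre panels out to where energy density decayed
  qmin <- min(Re(sol$q))
  rho_max <- R0 + max(30, 15 / qmin)
  gl <- .gauss_legendre_panels(R0, rho_max, n_panels = 8, n_nodes = 40)
  Fm <- .bilayer_fields(sol, gl$x)
  pref <- 2 * pi * Kt * gl$x
  splay <- sum(gl$w * pref * l2 * Fm["s", ]^2) + W_lin
  tilt <- sum(gl$w * pref * Fm["t", ]^2)
  stretch <- sum(gl$w * pref * A * Fm["alpha", ]^2)
  tension <- sum(gl$w * pref * sg * Fm["w", ]^2)
  list(total = splay + tilt + stretch + tension,
       splay = splay, tilt = tilt, stretch = stretch, tension = tension)
}

# fixed Gauss-Legendre rule on [a, b] split into panels (graded towards a,
# where the integrands decay exponentially)
.gauss_legendre_panels <- function(a, b, n_panels = 8, n_nodes = 40) {
  gl <- .gl_rule(n_nodes)
  # geometric grading: panel widths double
  wfrac <- 2^(seq_len(n_panels) - 1)
  edges <- a + (b - a) * c(0, cumsum(wfrac)) / sum(wfrac)
  xs <- NULL
  ws <- NULL
  for (i in seq_len(n_panels)) {
    lo <- edges[i]; hi <- edges[i + 1]
    xs <- c(xs, (hi - lo) / 2 * gl$x + (hi + lo) / 2)
    ws <- c(ws, (hi - lo) / 2 * gl$w)
  }
  list(x = xs, w = ws)
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1] (cached)
.gl_cache <- new.env(parent = emptyenv())
.gl_rule <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  out <- list(x = x[ord], w = w[ord])
  .gl_cache[[key]] <- out
  out
}
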