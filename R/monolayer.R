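# Vertical (edge-lining) monolayer region.
#
# The neutral surface is a near-cylinder R(z) = R_v + u(z); the tail-end
# surface M(z) = M_v + m(z); v(z) is the director z-projection, beta(z) the
# lateral stretch. Local volumetric incompressibility eliminates u:
#   u = R_v^2/(2 R_v^2 + h^2) * (2 m + 2 h beta + h^2 v'),
# and the normal's z-projection is N_z = -u'. The elastic functional
# (per Eq-style density, one mirror half; total carries a factor 2)
#   W = Int 2 pi R sqrt(1 + R'^2) { B/2 (v' + 1/R + J0)^2 - B/2 J0^2
#        + K_t/2 (v + u')^2 + K_A/2 beta^2 + sigma0 } dz - 2 sigma0 pi (R0^2 - r^2)
# is expanded to second order in the jet x = (v, v', v'', m, m', beta, beta'),
# giving a constant-coefficient quadratic Lagrangian density
#   G0 + L.x + x' Q x / 2.
# The Euler-Lagrange system then has the exponential-operator form
#   M(q) = T(-q)^T Q T(q)  (T maps field amplitudes to jet amplitudes),
# whose determinant roots give the characteristic exponents and null vectors
# the amplitude ratios; the constant particular solution solves
# M(0) y_p = -L|_fields. This reproduces the known structure: beta == 0,
# four exponentials shared by v and m, and a constant particular term in m.

.JET <- c("v", "vp", "vpp", "m", "mp", "beta", "betap")

#' Equilibrium outer (tail-end) radius of a monolayer cylinder
#'
#' Local volumetric incompressibility for the reference cylinder:
#' `M_v = R_v + h - h^2/(2 R_v)`.
#'
#' @param lipid [lipid_parameters()].
#' @param R_v neutral-surface radius of the reference cylinder, nm (> h/2).
#' @return M_v, nm.
#' @export
equilibrium_cylinder <- function(lipid, R_v) {
  if (R_v <= lipid$h / 2)
    stop("R_v must exceed h/2 for a geometrically sensible cylinder (R_v = ",
         R_v, ", h = ", lipid$h, ")")
  R_v + lipid$h - lipid$h^2 / (2 * R_v)
}

# Quadratic expansion of the energy density around the reference cylinder.
# Returns labelled pieces (splay/tilt/stretch/tension), each with G0 (scalar
# density), L (length-7), Q (7x7 symmetric), plus helper constants.
#
# radial_force: the reference cylinder is not an equilibrium state, so the
# expansion has first-order (linear) terms. The component conjugate to the
# meridional director rotation v' integrates exactly to a boundary term
# (int v' dz = v(Z0) - v(z_lo)) and is always kept. The component conjugate
# to the radial displacement u ("drop"/"literal") is the radial expansion
# force of the bent cylinder; retained literally it drives u ~ R_v/2,
# far outside the small-deviation regime the expansion is valid in, so by
# default it is dropped and deviations are penalized harmonically. The
# "literal" option retains it (it reproduces the known constant particular
# term of m(z)) and is used for cross-validation only.
.monolayer_quadform <- function(lipid, env, R_v,
                                radial_force = c("drop", "literal")) {
  radial_force <- match.arg(radial_force)
  stopifnot(R_v > 0)
  h <- lipid$h
  B <- lipid$B
  Kt <- lipid$K_t
  KA <- lipid$K_A
  J0 <- lipid$J0
  s0 <- 1 / R_v + J0
  sig0 <- env$sigma0
  a <- R_v^2 / (2 * R_v^2 + h^2)
  e <- function(i) { x <- numeric(7); x[i] <- 1; x }
  U <- a * (h^2 * e(2) + 2 * e(4) + 2 * h * e(6))      # u
  Up <- a * (h^2 * e(3) + 2 * e(5) + 2 * h * e(7))     # u'
  S1 <- e(2) - U / R_v^2                               # first-order splay
  Tt <- e(1) + Up                                      # tilt v + u'
  piece <- function(G0, L, Q) list(G0 = G0, L = L, Q = (Q + t(Q)) / 2)
  zeroQ <- matrix(0, 7, 7)
  zeroL <- numeric(7)
  # splay: B-terms of the expansion of R*sqrt(1+R'^2) * [B/2((s)^2 - J0^2)]
  Eb <- B / 2 * (s0^2 - J0^2)
  Q_splay <- 2 * pi * (2 * B * s0 / R_v^2 * outer(U, U) +       # R_v*B*s0*s2 with s2=u^2/R_v^3
                         R_v * B * outer(S1, S1) +               # R_v*B/2*s1^2
                         B * s0 * (outer(U, S1) + outer(S1, U)) +
                         R_v * (B / 2) * (s0^2 - J0^2) * outer(Up, Up))
  e2 <- e(2)
  L_splay <- if (radial_force == "literal")
    2 * pi * (Eb * U + R_v * B * s0 * S1)
  else
    2 * pi * R_v * B * s0 * e2
  G_splay <- 2 * pi * R_v * Eb
  # tilt
  Q_tilt <- 2 * pi * R_v * Kt * outer(Tt, Tt)
  # stretch
  Q_stretch <- 2 * pi * R_v * KA * outer(e(6), e(6))
  # lateral tension (area term); vanishes at sigma0 = 0
  Q_tension <- 2 * pi * R_v * sig0 * outer(Up, Up)
  L_tension <- if (radial_force == "literal") 2 * pi * sig0 * U else numeric(7)
  G_tension <- 2 * pi * R_v * sig0
  pieces <- list(
    splay = piece(G_splay, L_splay, Q_splay),
    tilt = piece(0, zeroL, Q_tilt),
    stretch = piece(0, zeroL, Q_stretch),
    tension = piece(G_tension, L_tension, Q_tension)
  )
  tot <- Reduce(function(x, y) list(G0 = x$G0 + y$G0, L = x$L + y$L, Q = x$Q + y$Q),
                pieces)
  list(pieces = pieces, G0 = tot$G0, L = tot$L, Q = tot$Q,
       a = a, s0 = s0, U = U, Up = Up, R_v = R_v,
       radial_force = radial_force)
}

# jet-amplitude map: field amplitudes (v, m, beta) -> jet amplitudes, for
# exponential dependence exp(q z)
.jet_T <- function(q) {
  T <- matrix(0 + 0i, 7, 3)
  T[1, 1] <- 1; T[2, 1] <- q; T[3, 1] <- q^2
  T[4, 2] <- 1; T[5, 2] <- q
  T[6, 3] <- 1; T[7, 3] <- q
  T
}

# Euler-Lagrange symbol M(q) = T(-q)^T Q T(q) (plain transpose, no conjugation)
.el_symbol <- function(Q, q) t(.jet_T(-q)) %*% Q %*% .jet_T(q)

.det3 <- function(M) {
  M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
}

# characteristic exponents and amplitude vectors.
# det M(q) is an even polynomial in q; fit it in x = q^2 and solve.
.monolayer_basis <- function(qf) {
  Q <- qf$Q
  scale_x <- 1 / qf$R_v^2 + 1  # typical magnitude of q^2
  xs <- scale_x * c(-2.5, -1.7, -0.9, -0.3, 0.3, 0.9, 1.7, 2.5, 3.5, -3.5, 4.5)
  dets <- vapply(xs, function(x) {
    q <- sqrt(as.complex(x))
    d <- .det3(.el_symbol(Q, q))
    stopifnot(abs(Im(d)) < 1e-6 * max(abs(d), 1))
    Re(d)
  }, numeric(1))
  V <- outer(xs, 0:4, "^")
  cf <- qr.solve(V, dets)             # coefficients of det in x^0..x^4
  cf[abs(cf) < 1e-9 * max(abs(cf))] <- 0
  deg <- max(which(cf != 0)) - 1L
  if (deg < 2) stop("degenerate monolayer characteristic polynomial")
  xroots <- polyroot(cf[1:(deg + 1L)])
  xroots <- xroots[Mod(xroots) > 1e-7 * max(Mod(xroots))]
  # exponents +-sqrt(x); keep representatives with Im >= 0, generators Re/Im
  gens <- list()
  for (x in xroots) {
    for (sgn in c(1, -1)) {
      q <- sgn * sqrt(x)
      if (Im(q) < -1e-12) next               # conjugate spans the same real space
      Mq <- .el_symbol(Q, q)
      sv <- svd(Mq)
      phi <- sv$v[, 3]
      if (sv$d[3] > 1e-8 * sv$d[1])
        stop("no null vector at characteristic exponent q = ", format(q))
      if (abs(Im(q)) < 1e-12 && max(abs(Im(phi))) < 1e-10) {
        gens[[length(gens) + 1L]] <- list(q = Re(q) + 0i, phi = as.complex(Re(phi)), part = "re")
      } else {
        gens[[length(gens) + 1L]] <- list(q = q, phi = phi, part = "re")
        gens[[length(gens) + 1L]] <- list(q = q, phi = phi, part = "im")
      }
    }
  }
  # constant particular solution
  M0 <- Re(.el_symbol(Q, 0 + 0i))
  L0 <- qf$L[c(1, 4, 6)]
  y_p <- solve(M0, -L0)
  list(gens = gens, y_p = y_p)
}

# jets (7 x length(z)) of one generator / of the particular solution
.gen_jet <- function(gen, z) {
  base <- .jet_T(gen$q) %*% gen$phi
  jc <- base %*% t(exp(gen$q * z))
  if (gen$part == "re") Re(jc) else Im(jc)
}
.part_jet <- function(y_p, z) {
  J <- matrix(0, 7, length(z))
  J[1, ] <- y_p[1]; J[4, ] <- y_p[2]; J[6, ] <- y_p[3]
  J
}

#' Pore geometry: generalized coordinates and junction circle
#'
#' @param r pore waist radius at the neutral surface, nm (> 0).
#' @param L hydrophobic-belt half-height, nm (0 for a hydrophilic pore).
#' @param R0 junction circle radius, nm.
#' @param Z0 junction circle height, nm (> L).
#' @return object of class `pore_geometry`.
#' @export
pore_geometry <- function(r, L = 0, R0, Z0) {
  stopifnot(r > 0, L >= 0, R0 > 0, Z0 > L)
  structure(list(r = r, L = L, R0 = R0, Z0 = Z0), class = "pore_geometry")
}

# director boundary value at the belt rim (local incompressibility of the
# hydrophobic belt): v(L) = -L / sqrt(L^2 + (h - L)^2)
.belt_rim_director <- function(h, L) -L / sqrt(L^2 + (h - L)^2)

#' Solve the vertical monolayer region
#'
#' Builds the exponential general solution of the Euler-Lagrange system of
#' the second-order elastic functional and fixes its coefficients by the
#' boundary set: at the equator (hydrophilic, z = 0) mirror symmetry
#' `v(0) = 0` and the waist condition `R(0) = r`; at the belt rim
#' (hydrophobic, z = L) `R(L) = r` and the incompressibility director value
#' `v(L) = -L/sqrt(L^2 + (h-L)^2)`; at the junction `R(Z0) = R0` and
#' `v(Z0) = junction_director`.
#'
#' @param lipid [lipid_parameters()].
#' @param env [environment_parameters()].
#' @param geometry [pore_geometry()].
#' @param mode `"hydrophilic"` or `"hydrophobic"`.
#' @param junction_director director z-projection at the junction circle
#'   (conjugation with the bilayer region: `n(R0) - v(Z0) = 1`).
#' @param R_v reference cylinder radius, nm; defaults to the waist radius r.
#' @param radial_force treatment of the first-order radial force of the bent
#'   reference cylinder: `"drop"` (default; harmonic deviations) or
#'   `"literal"` (retain as printed; cross-validation of the expansion only —
#'   see the methods vignette).
#' @return object of class `monolayer_solution`.
#' @export
solve_monolayer <- function(lipid, env, geometry, mode = c("hydrophilic", "hydrophobic"),
                            junction_director, R_v = geometry$r,
                            radial_force = c("drop", "literal")) {
  mode <- match.arg(mode)
  ctx <- .monolayer_context(lipid, env, R_v, match.arg(radial_force))
  .monolayer_solve_ctx(ctx, geometry, mode, junction_director)
}

# reusable context: quadform + basis for fixed (lipid, env, R_v)
.monolayer_context <- function(lipid, env, R_v, radial_force = "drop") {
  qf <- .monolayer_quadform(lipid, env, R_v, radial_force)
  bas <- .monolayer_basis(qf)
  list(lipid = lipid, env = env, R_v = R_v, qf = qf, bas = bas)
}

.monolayer_solve_ctx <- function(ctx, geometry, mode, junction_director) {
  lipid <- ctx$lipid; env <- ctx$env
  qf <- ctx$qf; bas <- ctx$bas
  r <- geometry$r; L <- geometry$L; R0 <- geometry$R0; Z0 <- geometry$Z0
  h <- lipid$h
  if (mode == "hydrophilic") {
    if (L != 0) stop("hydrophilic mode requires L = 0")
    z_lo <- 0
    v_lo <- 0
  } else {
    if (L < 0 || L >= h) stop("hydrophobic mode requires 0 <= L < h")
    if (Z0 <= L) stop("junction height Z0 must exceed the belt half-height L")
    z_lo <- L
    v_lo <- .belt_rim_director(h, L)
  }
  ngen <- length(bas$gens)
  ends <- c(z_lo, Z0)
  Jend <- lapply(bas$gens, .gen_jet, z = ends)    # 7 x 2 each
  Jp <- .part_jet(bas$y_p, ends)
  U <- qf$U
  # constraint rows: v(z_lo), u(z_lo), v(Z0), u(Z0)
  Cmat <- matrix(0, 4, ngen)
  for (k in seq_len(ngen)) {
    Cmat[1, k] <- Jend[[k]][1, 1]
    Cmat[2, k] <- sum(U * Jend[[k]][, 1])
    Cmat[3, k] <- Jend[[k]][1, 2]
    Cmat[4, k] <- sum(U * Jend[[k]][, 2])
  }
  b <- c(v_lo - Jp[1, 1],
         (r - ctx$R_v) - sum(U * Jp[, 1]),
         junction_director - Jp[1, 2],
         (R0 - ctx$R_v) - sum(U * Jp[, 2]))
  if (nrow(Cmat) == ncol(Cmat)) {
    rc <- rcond(Cmat)
    if (!is.finite(rc) || rc < 1e-13)
      stop(sprintf("ill-conditioned monolayer boundary system (rcond = %.2e, Z0 - z_lo = %.3g nm)",
                   rc, Z0 - z_lo))
    coef <- solve(Cmat, b)
  } else {
    # leftover freedom: close by energy minimization (natural conditions)
    EM <- .monolayer_energy_matrices(ctx, z_lo, Z0)
    K <- rbind(cbind(EM$E, t(Cmat)), cbind(Cmat, matrix(0, 4, 4)))
    sol <- solve(K, c(-EM$f, b))
    coef <- sol[seq_len(ngen)]
  }
  out <- list(lipid = lipid, env = env, ctx = ctx, geometry = geometry,
              mode = mode, z_lo = z_lo, v_lo = v_lo,
              junction_director = junction_director,
              R_v = ctx$R_v, M_v = ctx$R_v + h - h^2 / (2 * ctx$R_v),
              coef = coef)
  class(out) <- "monolayer_solution"
  out
}

# energy matrices over the generator basis on [z_lo, Z1]:
# W(c)/2 per half: 0.5 c'Ec + f'c + W0  (the mirror factor is applied later)
.monolayer_energy_matrices <- function(ctx, z_lo, Z1) {
  qf <- ctx$qf; bas <- ctx$bas
  gl <- .gl_rule(32)
  zs <- (Z1 - z_lo) / 2 * gl$x + (Z1 + z_lo) / 2
  ws <- (Z1 - z_lo) / 2 * gl$w
  ngen <- length(bas$gens)
  jets <- lapply(bas$gens, .gen_jet, z = zs)
  jp <- .part_jet(bas$y_p, zs)
  Qj <- lapply(jets, function(J) qf$Q %*% J)
  Qp <- qf$Q %*% jp
  E <- matrix(0, ngen, ngen)
  f <- numeric(ngen)
  for (j in seq_len(ngen)) {
    for (k in j:ngen) {
      E[j, k] <- E[k, j] <- sum(ws * colSums(jets[[j]] * Qj[[k]]))
    }
    f[j] <- sum(ws * colSums(jets[[j]] * (Qp + qf$L)))
  }
  W0 <- sum(ws * (0.5 * colSums(jp * Qp) + colSums(qf$L * jp) + qf$G0))
  list(E = E, f = f, W0 = W0, zs = zs, ws = ws, jets = jets, jp = jp)
}

# full jet of a solution at z values
.monolayer_jet <- function(sol, z) {
  J <- .part_jet(sol$ctx$bas$y_p, z)
  for (k in seq_along(sol$coef))
    J <- J + sol$coef[k] * .gen_jet(sol$ctx$bas$gens[[k]], z)
  J
}

#' Deformation fields of a monolayer solution
#'
#' @param sol `monolayer_solution`.
#' @param z heights, nm (within `[z_lo, Z0]`).
#' @return data.frame with columns `z`, `v`, `m`, `beta`, `u`, `R`, `M`.
#' @export
monolayer_fields <- function(sol, z) {
  J <- .monolayer_jet(sol, z)
  u <- colSums(sol$ctx$qf$U * J)
  data.frame(z = z, v = J[1, ], m = J[4, ], beta = J[6, ], u = u,
             R = sol$R_v + u, M = sol$M_v + J[4, ])
}

#' Elastic energy of the vertical monolayer region
#'
#' Integrates the quadratic energy density over `[z_lo, Z0]` and doubles it
#' for the two mirror-symmetric halves; at nonzero lateral tension the
#' reference-area term `-2 sigma0 pi (R0^2 - r^2)` is included.
#'
#' @param sol `monolayer_solution`.
#' @param breakdown if `TRUE`, also return splay/tilt/stretch components.
#' @return energy in kBT (number), or a list with `total` and components.
#' @export
monolayer_energy <- function(sol, breakdown = FALSE) {
  ctx <- sol$ctx
  g <- sol$geometry
  gl <- .gl_rule(32)
  zs <- (g$Z0 - sol$z_lo) / 2 * gl$x + (g$Z0 + sol$z_lo) / 2
  ws <- (g$Z0 - sol$z_lo) / 2 * gl$w
  J <- .monolayer_jet(sol, zs)     # assembled jets: cancellation-safe
  qf <- ctx$qf
  dens <- 0.5 * colSums(J * (qf$Q %*% J)) + colSums(qf$L * J) + qf$G0
  tens_ref <- -2 * ctx$env$sigma0 * pi * (g$R0^2 - g$r^2)
  total <- 2 * sum(ws * dens) + tens_ref
  if (!breakdown) return(total)
  comp <- vapply(qf$pieces, function(p) {
    d <- 0.5 * colSums(J * (p$Q %*% J)) + colSums(p$L * J) + p$G0
    2 * sum(ws * d)
  }, numeric(1))
  comp["tension"] <- comp["tension"] + tens_ref
  c(list(total = total), as.list(comp))
}
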