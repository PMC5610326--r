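# Conjugation of the two elastic regions and the hydrophobic belt, and
# optimization of the junction circle (R0, Z0).
#
# For a fixed pore state (r, L) and junction circle (R0, Z0) the regions are
# coupled by continuity of the neutral surfaces (H(R0) = Z0, R(Z0) = R0) and
# of the director, n(R0) - v(Z0) = 1. The junction director value n0 is the
# single remaining scalar freedom; both regional energies are exact
# quadratics in their boundary data, so n0 is eliminated by exact quadratic
# minimization (the variational natural condition). (R0, Z0) are then
# optimized by gradient descent with Newton polishing until
# |grad W| < 1e-7 kBT/nm.

# --- bilayer energy as an exact quadratic in (n0, Z0 - h) at fixed R0 ------

.bilayer_quad <- function(lipid, env, R0) {
  sigma <- env$sigma0 / lipid$K_t
  q <- characteristic_roots(lipid, sigma)
  conj_pair <- abs(Im(q[1]) + Im(q[2])) < 1e-9 * max(1, abs(Im(q[1])))
  m1 <- .bilayer_mode(lipid, sigma, q[1])
  F1 <- .bilayer_mode_fields(m1, R0)
  if (conj_pair) {
    G <- list(2 * Re(F1), -2 * Im(F1))
  } else {
    m2 <- .bilayer_mode(lipid, sigma, q[2])
    G <- list(Re(F1), Re(.bilayer_mode_fields(m2, R0)))
  }
  h <- lipid$h; Kt <- lipid$K_t; l2 <- lipid$l2
  # boundary-flux bilinear form on the generator pair
  wfun <- function(Fu, Fv) {
    Tv <- Fv["t", 1] + sigma * Fv["w", 1]
    Tvp <- Fv["tp", 1] + sigma * Fv["wp", 1]
    -pi * Kt * R0 * (Fu["n", 1] * (2 * l2 * Fv["s", 1] - h^2 * Tvp) +
                       Fu["np", 1] * h^2 * Tv + 2 * h * Tv * Fu["alpha", 1])
  }
  S <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    S[i, j] <- wfun(G[[i]], G[[j]])
  S <- (S + t(S)) / 2
  Lb <- -4 * pi * lipid$B * lipid$J0 * R0 * c(G[[1]]["n", 1], G[[2]]["n", 1])
  # coef -> (n0, Z0 - h)
  bc_row <- function(Fm) c(Fm["n", 1], -(h^2 / 2) * Fm["s", 1] - h * Fm["alpha", 1])
  Mbc <- cbind(bc_row(G[[1]]), bc_row(G[[2]]))
  Minv <- solve(Mbc)
  # W_b(y) = y' A y + l . y, y = (n0, Z0 - h)
  A <- t(Minv) %*% S %*% Minv
  lvec <- as.vector(t(Minv) %*% Lb)
  list(A = A, l = lvec)
}

# --- per-(r, L, mode) context and the hot-path energy --------------------

.edge_context <- function(lipid, env, r, L, mode, R_v = r) {
  mctx <- .monolayer_context(lipid, env, R_v)
  W_h <- if (mode == "hydrophobic") belt_energy(r, L, env) else 0
  z_lo <- if (mode == "hydrophobic") L else 0
  v_lo <- if (mode == "hydrophobic") .belt_rim_director(lipid$h, L) else 0
  list(lipid = lipid, env = env, r = r, L = L, mode = mode,
       mctx = mctx, W_h = W_h, z_lo = z_lo, v_lo = v_lo)
}

# total energy at fixed junction circle, with the junction director
# eliminated by exact quadratic minimization. Returns W and the pieces.
.edge_energy <- function(ectx, R0, Z0, details = FALSE) {
  lipid <- ectx$lipid; env <- ectx$env
  if (!is.finite(R0) || !is.finite(Z0) || R0 > 1e4 || Z0 > 50)
    return(list(W = 1e8, feasible = FALSE))
  viol <- max(0, 0.05 - R0) + max(0, ectx$z_lo + 0.05 - Z0)
  if (viol > 0)   # smooth wall pushing back into the feasible region
    return(list(W = 1e6 * (1 + viol)^2, feasible = FALSE))
  bq <- tryCatch(.bilayer_quad(lipid, env, R0), error = function(e) NULL)
  if (is.null(bq) || !all(is.finite(bq$A)) || !all(is.finite(bq$l)))
    return(list(W = 2e6, feasible = FALSE))
  dZ <- Z0 - lipid$h
  # W_b(n0) = a_b n0^2 + b_b n0 + c_b
  a_b <- bq$A[1, 1]
  b_b <- 2 * bq$A[1, 2] * dZ + bq$l[1]
  c_b <- bq$A[2, 2] * dZ^2 + bq$l[2] * dZ
  # monolayer: coefficients linear in vj through the boundary rows
  mctx <- ectx$mctx
  bas <- mctx$bas
  ngen <- length(bas$gens)
  ends <- c(ectx$z_lo, Z0)
  Jend <- lapply(bas$gens, .gen_jet, z = ends)
  Jp <- .part_jet(bas$y_p, ends)
  U <- mctx$qf$U
  Cmat <- matrix(0, 4, ngen)
  for (k in seq_len(ngen)) {
    Cmat[1, k] <- Jend[[k]][1, 1]
    Cmat[2, k] <- sum(U * Jend[[k]][, 1])
    Cmat[3, k] <- Jend[[k]][1, 2]
    Cmat[4, k] <- sum(U * Jend[[k]][, 2])
  }
  # column equilibration (growing exponentials dominate on long domains)
  csc <- apply(abs(Cmat), 2, max)
  csc[csc == 0] <- 1
  Cs <- sweep(Cmat, 2, csc, "/")
  rc <- rcond(Cs)
  if (!is.finite(rc) || rc < 1e-12)
    return(list(W = 1e6 * 2, feasible = FALSE))
  b0 <- c(ectx$v_lo - Jp[1, 1],
          (ectx$r - mctx$R_v) - sum(U * Jp[, 1]),
          -Jp[1, 2],
          (R0 - mctx$R_v) - sum(U * Jp[, 2]))
  db <- c(0, 0, 1, 0)
  cc <- solve(Cs, cbind(b0, db)) / csc   # coef = cc[,1] + vj * cc[,2]
  # energy from assembled solution jets: for nearly degenerate exponential
  # bases (|q| Z0 << 1) the coefficients are large and mutually cancelling,
  # so quadratic forms over the raw basis would amplify rounding; summing
  # the jets first keeps the cancellation in one well-conditioned place
  gl <- .gl_rule(32)
  zs <- (Z0 - ectx$z_lo) / 2 * gl$x + (Z0 + ectx$z_lo) / 2
  ws <- (Z0 - ectx$z_lo) / 2 * gl$w
  jets <- lapply(bas$gens, .gen_jet, z = zs)
  J0s <- .part_jet(bas$y_p, zs)
  Jds <- 0
  for (k in seq_len(ngen)) {
    J0s <- J0s + cc[k, 1] * jets[[k]]
    Jds <- Jds + cc[k, 2] * jets[[k]]
  }
  Qf <- mctx$qf$Q; Lf <- mctx$qf$L; G0f <- mctx$qf$G0
  QJ0 <- Qf %*% J0s
  QJd <- Qf %*% Jds
  m0 <- 2 * sum(ws * (0.5 * colSums(J0s * QJ0) + colSums(Lf * J0s) + G0f))
  m1 <- 2 * sum(ws * (colSums(Jds * QJ0) + colSums(Lf * Jds)))
  m2 <- sum(ws * colSums(Jds * QJd))
  tens_ref <- -2 * env$sigma0 * pi * (R0^2 - ectx$r^2)
  # vj = n0 - 1; W(n0) = (a_b + m2) n0^2 + ... expand m-quadratic in n0
  A2 <- a_b + m2
  A1 <- b_b + m1 - 2 * m2
  A0 <- c_b + m0 - m1 + m2 + tens_ref + ectx$W_h - pi * ectx$r^2 * 2 * env$sigma0
  if (A2 <= 0) return(list(W = 2e6, feasible = FALSE))
  n0 <- -A1 / (2 * A2)
  W <- A0 + A1 * n0 + A2 * n0^2
  if (!details) return(list(W = W, n0 = n0, feasible = TRUE))
  vj <- n0 - 1
  coef <- cc[, 1] + vj * cc[, 2]
  W_m <- m0 + m1 * vj + m2 * vj^2 + tens_ref
  W_b <- a_b * n0^2 + b_b * n0 + c_b
  list(W = W, n0 = n0, coef = coef, W_b = W_b, W_m = W_m, W_h = ectx$W_h,
       feasible = TRUE)
}

.edge_grad <- function(ectx, R0, Z0, dstep = 1e-5, extrapolate = FALSE) {
  g <- function(d)
    c((.edge_energy(ectx, R0 + d, Z0)$W - .edge_energy(ectx, R0 - d, Z0)$W) / (2 * d),
      (.edge_energy(ectx, R0, Z0 + d)$W - .edge_energy(ectx, R0, Z0 - d)$W) / (2 * d))
  if (!extrapolate) return(g(dstep))
  (4 * g(dstep / 2) - g(dstep)) / 3   # Richardson: removes the O(d^2) term
}

# FD Hessian of the total energy in (R0, Z0)
.edge_hess <- function(ectx, th, d = 1e-4) {
  f <- .edge_energy(ectx, th[1], th[2])$W
  hRR <- (.edge_energy(ectx, th[1] + d, th[2])$W - 2 * f + .edge_energy(ectx, th[1] - d, th[2])$W) / d^2
  hZZ <- (.edge_energy(ectx, th[1], th[2] + d)$W - 2 * f + .edge_energy(ectx, th[1], th[2] - d)$W) / d^2
  hRZ <- (.edge_energy(ectx, th[1] + d, th[2] + d)$W - .edge_energy(ectx, th[1] + d, th[2] - d)$W -
            .edge_energy(ectx, th[1] - d, th[2] + d)$W + .edge_energy(ectx, th[1] - d, th[2] - d)$W) / (4 * d^2)
  matrix(c(hRR, hRZ, hRZ, hZZ), 2, 2)
}

# gradient descent with backtracking line search to reach the basin, then
# damped Newton iterations on the gradient until |grad W| < tol. The wall
# height Z0 - z_lo has a floor of 0.05 nm (below it the wall degenerates);
# when the optimum presses against the floor, convergence is judged on the
# projected gradient (the Z0 component is inactive there).
.descend_junction <- function(ectx, init, tol = 1e-7, maxit = 200) {
  floorZ <- ectx$z_lo + 0.0500001
  clamp <- function(th) c(th[1], max(th[2], floorZ))
  Wof <- function(a, b) .edge_energy(ectx, a, b)$W
  # boundary-aware gradient: one-sided in Z0 near the wall-height floor,
  # with the Z0 component projected out when the floor is active
  bgrad <- function(th, d, extrapolate = FALSE) {
    g1 <- function(dd) (Wof(th[1] + dd, th[2]) - Wof(th[1] - dd, th[2])) / (2 * dd)
    gR <- if (extrapolate) (4 * g1(d / 2) - g1(d)) / 3 else g1(d)
    if (th[2] - floorZ > 1.1 * d) {
      g2 <- function(dd) (Wof(th[1], th[2] + dd) - Wof(th[1], th[2] - dd)) / (2 * dd)
      gZ <- if (extrapolate) (4 * g2(d / 2) - g2(d)) / 3 else g2(d)
    } else {
      gZ <- (Wof(th[1], th[2] + d) - Wof(th[1], th[2])) / d
      if (gZ > 0) gZ <- 0     # floor active: Z0 direction blocked
    }
    c(gR, gZ)
  }
  th <- clamp(init)
  th[2] <- max(th[2], ectx$z_lo + 0.2)
  f <- .edge_energy(ectx, th[1], th[2])$W
  k <- 0
  while (f >= 1e6 && k < 12) {   # lift the start out of infeasible geometry
    th[2] <- th[2] + 0.2
    th[1] <- max(th[1], 0.2)
    f <- .edge_energy(ectx, th[1], th[2])$W
    k <- k + 1
  }
  step <- 0.1
  trace_n <- 0L
  g <- bgrad(th, 1e-5)
  gn <- sqrt(sum(g^2))
  # phase 1: energy descent
  for (it in seq_len(maxit)) {
    trace_n <- it
    if (gn < 1e-3) break
    moved <- FALSE
    repeat {
      thn <- clamp(th - step * g)
      fn <- .edge_energy(ectx, thn[1], thn[2])$W
      if (is.finite(fn) && fn <= f - 1e-4 * step * gn^2) {
        th <- thn; f <- fn
        step <- min(step * 1.8, 1)
        moved <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (!moved) break
    g <- bgrad(th, 1e-5)
    gn <- sqrt(sum(g^2))
  }
  # phase 2: safeguarded Newton on the gradient (Richardson-extrapolated
  # differences; quadratic convergence to |g| < tol). A step must both
  # reduce |grad| and not raise the energy beyond rounding slack, and is
  # kept short so the iteration cannot leave the basin.
  gd <- 2e-4   # wider step + Richardson: rounding floor ~ eps*W/gd << tol
  g <- bgrad(th, gd, extrapolate = TRUE)
  gn <- sqrt(sum(g^2))
  for (it in seq_len(30)) {
    trace_n <- trace_n + 1L
    if (gn < tol) break
    boundary <- th[2] - floorZ <= 1.1 * gd
    if (boundary) {
      d <- 1e-3   # one-dimensional Newton along R0 at the active floor
      hRR <- (Wof(th[1] + d, th[2]) - 2 * f + Wof(th[1] - d, th[2])) / d^2
      if (!is.finite(hRR) || hRR <= 0) break
      dn <- c(g[1] / hRR, 0)
    } else {
      d <- 1e-3   # Hessian from extrapolated-gradient differences
      H <- cbind((.edge_grad(ectx, th[1] + d, th[2], gd, extrapolate = TRUE) -
                    .edge_grad(ectx, th[1] - d, th[2], gd, extrapolate = TRUE)) / (2 * d),
                 (.edge_grad(ectx, th[1], th[2] + d, gd, extrapolate = TRUE) -
                    .edge_grad(ectx, th[1], th[2] - d, gd, extrapolate = TRUE)) / (2 * d))
      H <- (H + t(H)) / 2
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (!all(is.finite(ev)) || any(ev <= 0)) break
      dn <- solve(H, g)
    }
    if (sqrt(sum(dn^2)) > 0.2) dn <- dn * 0.2 / sqrt(sum(dn^2))
    accepted <- FALSE
    for (k in 0:6) {
      thn <- clamp(th - dn / 2^k)
      fn <- .edge_energy(ectx, thn[1], thn[2])$W
      if (!is.finite(fn) || fn > f + max(1e-7, 1e-10 * abs(f))) next
      gn2 <- bgrad(thn, gd, extrapolate = TRUE)
      if (all(is.finite(gn2)) && sqrt(sum(gn2^2)) < gn) {
        th <- thn; g <- gn2; gn <- sqrt(sum(g^2)); f <- fn
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  f <- .edge_energy(ectx, th[1], th[2])$W
  list(theta = th, W = f, grad_norm = gn, converged = gn < tol,
       iterations = trace_n)
}

#' Total edge energy at a fixed pore geometry
#'
#' Conjugates the horizontal bilayer region, the vertical monolayer region,
#' and (in hydrophobic mode) the belt at the given junction circle. The
#' junction director is eliminated variationally. `W_total = W_b + W_m + W_h
#' - 2 pi r^2 sigma0` (the belt term is absent in hydrophilic mode).
#'
#' @param lipid [lipid_parameters()].
#' @param env [environment_parameters()].
#' @param geometry [pore_geometry()].
#' @param mode `"hydrophilic"` or `"hydrophobic"`.
#' @return object of class `energy_breakdown`: fields `W_b`, `W_m`, `W_h`,
#'   `W_total`, components `splay`, `tilt`, `stretch`, `tension`, the
#'   junction director `n0`, and the belt geometry.
#' @export
total_energy <- function(lipid, env, geometry, mode = c("hydrophilic", "hydrophobic")) {
  mode <- match.arg(mode)
  ectx <- .edge_context(lipid, env, geometry$r, geometry$L, mode)
  ee <- .edge_energy(ectx, geometry$R0, geometry$Z0, details = TRUE)
  if (!isTRUE(ee$feasible)) stop("infeasible geometry for total_energy")
  # full regional solutions at the optimal junction director for components
  bsol <- solve_bilayer(lipid, env, geometry$R0, geometry$Z0, ee$n0)
  bq <- bilayer_energy(bsol, method = "quadrature")
  msol <- .monolayer_solve_ctx(ectx$mctx, geometry, mode, ee$n0 - 1)
  mq <- monolayer_energy(msol, breakdown = TRUE)
  out <- list(W_b = ee$W_b, W_m = ee$W_m, W_h = ee$W_h,
              W_total = ee$W,
              splay = bq$splay + mq$splay,
              tilt = bq$tilt + mq$tilt,
              stretch = bq$stretch + mq$stretch,
              tension = bq$tension + mq$tension - pi * geometry$r^2 * 2 * env$sigma0,
              n0 = ee$n0, geometry = geometry, mode = mode,
              bilayer = bsol, monolayer = msol)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown: %s, r = %.3g nm, 2L = %.3g nm>\n",
              x$mode, x$geometry$r, 2 * x$geometry$L))
  cat(sprintf("  W_total = %.4f kBT (W_b %.4f + W_m %.4f + W_h %.4f)\n",
              x$W_total, x$W_b, x$W_m, x$W_h))
  cat(sprintf("  splay %.4f | tilt %.4f | stretch %.4f | belt %.4f\n",
              x$splay, x$tilt, x$stretch, x$W_h))
  invisible(x)
}

#' Optimize the junction circle for a pore state (r, L)
#'
#' Minimizes the total edge energy over the junction coordinates (R0, Z0)
#' by gradient descent (central differences, backtracking line search, with
#' Newton polishing) until |grad W| < 1e-7 kBT/nm. Two standard starting
#' points are tried and the lower optimum kept.
#'
#' @param lipid [lipid_parameters()].
#' @param env [environment_parameters()].
#' @param r pore waist radius, nm.
#' @param L belt half-height, nm (0 in hydrophilic mode).
#' @param mode `"hydrophilic"` or `"hydrophobic"`.
#' @param init optional starting `c(R0, Z0)`; when given, only this start is
#'   used (warm starts in trajectory scans).
#' @param breakdown compute the full component breakdown at the optimum.
#' @param tol gradient-norm stopping threshold, kBT/nm.
#' @return list with `geometry` ([pore_geometry()]), `W` (kBT), `grad_norm`,
#'   `converged`, `iterations`, `n0` and (optionally) `breakdown`.
#' @export
optimize_junction <- function(lipid, env, r, L = 0,
                              mode = c("hydrophilic", "hydrophobic"),
                              init = NULL, breakdown = FALSE, tol = 1e-7) {
  mode <- match.arg(mode)
  if (mode == "hydrophilic") stopifnot(L == 0)
  ectx <- .edge_context(lipid, env, r, L, mode)
  h <- lipid$h
  inits <- if (!is.null(init)) list(init) else {
    i1 <- if (mode == "hydrophilic") c(r + h, h) else c(r + h, L + h / 2)
    list(i1, i1 * 1.2)
  }
  best <- NULL
  for (ini in inits) {
    res <- .descend_junction(ectx, ini, tol = tol)
    if (is.null(best) || res$W < best$W) best <- res
  }
  if (best$W >= 1e5 || !best$converged) {
    # start was separated from the basin; widen the net (the junction circle
    # can hug the waist, R0 - r << h, especially for wide belts)
    for (ini in list(c(r + 0.1, L + 0.45), c(r + 0.4 * h, L + 0.5 * h),
                     c(r + 0.25 * h, L + 0.3 * h), c(r + 1.5 * h, L + h),
                     c(max(r, h), h))) {
      res <- .descend_junction(ectx, ini, tol = tol)
      better <- (res$converged && !best$converged && res$W < best$W + 0.5) ||
        res$W < best$W
      if (better) best <- res
      if (best$converged && best$W < 1e5) break
    }
  }
  if (!best$converged)
    warning(sprintf("junction optimization stopped at |grad| = %.3g (r = %.3g, L = %.3g)",
                    best$grad_norm, r, L))
  if (best$theta[1] <= 0 || best$W >= 1e5)
    stop(sprintf("no feasible junction geometry found (r = %.3g, L = %.3g, mode = %s)",
                 r, L, mode))
  geom <- pore_geometry(r, L, best$theta[1], best$theta[2])
  out <- list(geometry = geom, W = best$W, grad_norm = best$grad_norm,
              converged = best$converged, iterations = best$iterations,
              n0 = .edge_energy(ectx, best$theta[1], best$theta[2])$n0)
  if (breakdown) out$breakdown <- total_energy(lipid, env, geom, mode)
  out
}
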