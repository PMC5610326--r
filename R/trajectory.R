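# Pore-formation trajectory: scan the generalized coordinates (r, L), build
# the optimal energy landscape W(r), the line tension gamma(r) = W/(2 pi r),
# and extract its features (transition barrier, metastable pore, asymptotic
# line tension).

.opt_junction_warm <- function(lipid, env, r, L, mode, init) {
  ectx <- .edge_context(lipid, env, r, L, mode)
  res <- .descend_junction(ectx, init)
  if (res$W >= 1e5) {
    h <- lipid$h
    for (ini in list(c(r + 0.4 * h, L + 0.5 * h), c(r + h, L + 0.8 * h),
                     c(r + 0.25 * h, L + 0.3 * h), c(max(r, h), h))) {
      alt <- .descend_junction(ectx, ini)
      if (alt$W < res$W) res <- alt
      if (res$W < 1e5) break
    }
  }
  list(W = res$W, R0 = res$theta[1], Z0 = res$theta[2],
       grad_norm = res$grad_norm, converged = res$converged,
       n0 = .edge_energy(ectx, res$theta[1], res$theta[2])$n0)
}

#' Scan the pore energy over the hydrophobic-belt height
#'
#' For a fixed pore radius, optimizes the junction circle at each belt
#' half-height L on a grid (plus the hydrophilic state at L = 0) and locates
#' the minima of W(L). The belt-state minimum is the local minimum with the
#' largest L (a boundary minimum at the upper end of the grid is accepted:
#' for narrow defects the optimal belt spans nearly the whole monolayer).
#'
#' @param lipid [lipid_parameters()].
#' @param env [environment_parameters()].
#' @param r pore radius, nm.
#' @param L_grid belt half-heights to scan, nm; default `seq(0.1, 0.95, by
#'   0.085) * h` (refined near the minimum).
#' @param refine parabolically refine the belt minimum (default TRUE).
#' @return list with `scan` (data.frame L, W, R0, Z0), `W_philic` (L = 0
#'   value), `belt_minimum` (list L, W or NULL), and `barrier` (max W between
#'   the two minima minus the lower minimum, NA if no belt minimum).
#' @export
scan_belt_height <- function(lipid, env, r, L_grid = NULL, refine = TRUE) {
  h <- lipid$h
  if (is.null(L_grid)) L_grid <- seq(0.10, 0.95, by = 0.085) * h
  L_grid <- sort(unique(L_grid[L_grid > 0 & L_grid < h]))
  phil <- .opt_junction_warm(lipid, env, r, 0, "hydrophilic", c(r + h, 0.8 * h))
  init <- c(r + h, L_grid[1] + h / 2)
  rows <- vector("list", length(L_grid))
  for (i in seq_along(L_grid)) {
    o <- .opt_junction_warm(lipid, env, r, L_grid[i], "hydrophobic", init)
    nxt <- L_grid[min(i + 1, length(L_grid))]
    init <- c(o$R0, max(o$Z0, nxt + 0.55))
    rows[[i]] <- data.frame(L = L_grid[i], W = o$W, R0 = o$R0, Z0 = o$Z0)
  }
  scan <- do.call(rbind, rows)
  scan <- scan[scan$W < 1e5, , drop = FALSE]   # drop failed junction solves
  if (nrow(scan) < 3)
    return(list(scan = scan, W_philic = phil$W, belt_minimum = NULL,
                barrier = NA_real_, r = r))
  W <- scan$W
  n <- nrow(scan)
  # local minima over the grid; boundary minimum at the top end allowed
  loc <- which(diff(sign(diff(W))) > 0) + 1L
  if (n >= 2 && W[n] < W[n - 1]) loc <- c(loc, n)
  belt_min <- NULL
  if (length(loc)) {
    i <- max(loc)  # largest-L minimum is the belt state
    Lm <- scan$L[i]; Wm <- W[i]
    if (refine && i > 1 && i < n) {
      xs <- scan$L[(i - 1):(i + 1)]; ys <- W[(i - 1):(i + 1)]
      d <- (ys[3] - 2 * ys[2] + ys[1])
      if (d > 0) {
        Lp <- xs[2] - (ys[3] - ys[1]) / (2 * d) * (xs[2] - xs[1])
        if (Lp > xs[1] && Lp < xs[3]) {
          o <- .opt_junction_warm(lipid, env, r, Lp, "hydrophobic",
                                  c(scan$R0[i], scan$Z0[i]))
          if (o$W < Wm) { Lm <- Lp; Wm <- o$W }
        }
      }
    }
    belt_min <- list(L = Lm, W = Wm)
  }
  barrier <- NA_real_
  if (!is.null(belt_min)) {
    between <- W[scan$L <= belt_min$L]
    barrier <- max(c(between, phil$W)) - min(belt_min$W, phil$W)
  }
  list(scan = scan, W_philic = phil$W, belt_minimum = belt_min,
       barrier = barrier, r = r)
}

.default_r_grid <- function(r_max = 50) {
  g <- c(seq(0.1, 0.5, by = 0.1), seq(0.55, 1.1, by = 0.05),
         seq(1.2, 3, by = 0.2), seq(3.4, 5, by = 0.4),
         6, 7, 8.5, 10, 13, 16, 20, 26, 33, 41, 50)
  sort(unique(g[g <= r_max + 1e-9]))
}

#' Optimal pore-formation trajectory W(r)
#'
#' For each radius the belt half-height L is optimized (scan plus
#' refinement) and the junction circle is optimized by gradient descent; the
#' optimal trajectory takes, at each r, the lower of the hydrophobic-defect
#' branch (belt-state minimum of W(L)) and the hydrophilic branch (L = 0).
#' Landscape features are extracted from the two branches: the
#' defect-to-pore transition radius (branch crossing, which is the maximum
#' of the optimal W(r)), the forward barrier (W at the crossing, relative to
#' the intact bilayer at W = 0), the metastable hydrophilic pore (local
#' minimum of W at a few nm) and the reverse barrier, the line-tension curve
#' with its minimum, and the large-radius asymptote gamma0 (evaluated at
#' r_max, with the slope of a linear fit of W(r) over the top range as a
#' consistency diagnostic).
#'
#' @param lipid [lipid_parameters()].
#' @param env [environment_parameters()].
#' @param r_grid radii to scan, nm (default: dense near the transition and
#'   metastable regions, log-sparse out to `r_max`).
#' @param r_max largest radius, nm (default 50).
#' @param hydrophobic if TRUE (default) compute the hydrophobic-defect
#'   branch at small radii; FALSE restricts to the hydrophilic branch (for
#'   line-tension work at larger radii).
#' @param r_phobic_max largest radius at which the belt scan is attempted
#'   (default 1.3 nm; the belt state disappears slightly above the
#'   transition radius).
#' @param L_grid passed to [scan_belt_height()].
#' @param r_philic_min smallest radius for which the hydrophilic branch is
#'   solved (default 0.45 nm: below the transition region the hydrophilic
#'   configuration is never optimal and its junction geometry degenerates).
#' @return object of class `pore_trajectory`: `points` (data.frame with r,
#'   regime, L_opt, W, gamma_pN, R0, Z0, n0, grad_norm), `features` (list),
#'   `lipid`, `env`.
#' @export
optimal_trajectory <- function(lipid, env, r_grid = NULL, r_max = 50,
                               hydrophobic = TRUE, r_phobic_max = 1.3,
                               L_grid = NULL, r_philic_min = 0.45) {
  if (is.null(r_grid)) r_grid <- .default_r_grid(r_max)
  r_grid <- sort(unique(r_grid))
  h <- lipid$h
  # hydrophilic branch, warm-started
  phil <- vector("list", length(r_grid))
  blank <- list(W = NA_real_, R0 = NA_real_, Z0 = NA_real_,
                grad_norm = NA_real_, converged = NA, n0 = NA_real_)
  first <- which(r_grid >= r_philic_min)[1]
  init <- c(r_grid[first] + h, 0.8 * h)
  for (i in seq_along(r_grid)) {
    if (i < first) { phil[[i]] <- blank; next }
    o <- .opt_junction_warm(lipid, env, r_grid[i], 0, "hydrophilic", init)
    init <- c(o$R0 + (if (i < length(r_grid)) r_grid[i + 1] - r_grid[i] else 0), o$Z0)
    phil[[i]] <- o
  }
  W_phil <- vapply(phil, `[[`, numeric(1), "W")
  # hydrophobic branch
  W_phob <- rep(NA_real_, length(r_grid))
  L_opt <- rep(NA_real_, length(r_grid))
  if (hydrophobic) {
    for (i in seq_along(r_grid)) {
      r <- r_grid[i]
      if (r > r_phobic_max) break
      sc <- scan_belt_height(lipid, env, r, L_grid = L_grid)
      if (!is.null(sc$belt_minimum)) {
        W_phob[i] <- sc$belt_minimum$W
        L_opt[i] <- sc$belt_minimum$L
      }
      if (!is.null(sc$belt_minimum) && sc$belt_minimum$W > sc$W_philic + 12) break
    }
  }
  regime <- ifelse(!is.na(W_phob) & (is.na(W_phil) | W_phob < W_phil),
                   "hydrophobic", "hydrophilic")
  W <- pmin(W_phil, W_phob, na.rm = TRUE)
  keep <- is.finite(W)
  if (!all(keep)) {
    r_grid <- r_grid[keep]; regime <- regime[keep]; W <- W[keep]
    W_phil <- W_phil[keep]; W_phob <- W_phob[keep]; L_opt <- L_opt[keep]
    phil <- phil[keep]
  }
  pts <- data.frame(
    r = r_grid, regime = regime,
    L_opt = ifelse(regime == "hydrophobic", L_opt, 0),
    L_phob = L_opt,
    W = W, W_philic = W_phil, W_phobic = W_phob,
    gamma_pN = line_tension_to_pN(W / (2 * pi * r_grid)),
    R0 = vapply(phil, `[[`, numeric(1), "R0"),
    Z0 = vapply(phil, `[[`, numeric(1), "Z0"),
    n0 = vapply(phil, `[[`, numeric(1), "n0"),
    grad_norm = vapply(phil, `[[`, numeric(1), "grad_norm"))
  feats <- .landscape_features(lipid, env, pts)
  structure(list(points = pts, features = feats, lipid = lipid, env = env),
            class = "pore_trajectory")
}

# feature extraction from the branch data
.landscape_features <- function(lipid, env, pts) {
  r <- pts$r
  f <- list()
  # transition: crossing of the two branches (maximum of the optimal W)
  has_phob <- !is.na(pts$W_phobic)
  f$r_transition <- NA_real_
  f$barrier_forward <- NA_real_
  if (any(has_phob)) {
    d <- pts$W_phobic - pts$W_philic
    idx <- which(has_phob & !is.na(pts$W_philic))
    sg <- which(diff(sign(d[idx])) != 0)
    if (length(sg)) {
      i <- idx[sg[1]]; j <- idx[sg[1] + 1]
      t <- d[i] / (d[i] - d[j])
      f$r_transition <- r[i] + t * (r[j] - r[i])
      f$barrier_forward <- pts$W_philic[i] + t * (pts$W_philic[j] - pts$W_philic[i])
    } else if (length(idx) && all(d[idx] > 0)) {
      # belt state never wins: transition at the smallest scanned radius
      f$r_transition <- r[idx[1]]
      f$barrier_forward <- max(pts$W[seq_len(idx[length(idx)])])
    }
  }
  if (is.na(f$r_transition) && any(has_phob) && any(r <= 3)) {
    # no explicit branch crossing on the grid (the belt branch ends between
    # two grid points): the transition is the maximum of the optimal W(r)
    sm <- which(r <= 3 & is.finite(pts$W))
    i <- sm[which.max(pts$W[sm])]
    ref <- .refine_parabola(r, -pts$W, i)   # refine the maximum
    f$r_transition <- ref$x
    f$barrier_forward <- -ref$y
  }
  if (is.na(f$barrier_forward) && any(has_phob))
    f$barrier_forward <- max(pts$W[r <= 2], na.rm = TRUE)
  # belt height at the transition (the nonzero minimum of W(L) there)
  f$belt_height_at_transition <- NA_real_
  ip <- which(has_phob & !is.na(pts$L_phob))
  if (length(ip) && !is.na(f$r_transition)) {
    f$belt_height_at_transition <-
      2 * stats::approx(r[ip], pts$L_phob[ip], xout = f$r_transition,
                        rule = 2)$y
  }
  # metastable minimum of the hydrophilic branch beyond the transition
  f$r_metastable <- NA_real_; f$W_metastable <- NA_real_
  f$depth_metastable <- NA_real_; f$barrier_reverse <- NA_real_
  hyd <- which(r > max(f$r_transition, 0.3, na.rm = TRUE) & r <= 12)
  if (length(hyd) >= 3) {
    Wp <- pts$W_philic[hyd]
    loc <- which(diff(sign(diff(Wp))) > 0) + 1L
    if (length(loc)) {
      i <- hyd[loc[which.min(Wp[loc])]]
      ref <- .refine_parabola(r, pts$W_philic, i)
      # reverse barrier = landscape maximum (transition) minus the minimum;
      # equals the depth of the metastable well on its small-r side
      rev <- if (!is.na(f$barrier_forward)) f$barrier_forward - ref$y
             else max(pts$W[r <= ref$x]) - ref$y
      if (rev >= 0.25) {   # shallower dips are below the numerical floor
        f$r_metastable <- ref$x; f$W_metastable <- ref$y
        f$barrier_reverse <- rev
        f$depth_metastable <- rev
      }
    }
  }
  # line tension: minimum over the hydrophilic branch and large-r asymptote
  gam <- line_tension_to_pN(pts$W_philic / (2 * pi * r))
  hyd2 <- which(r >= max(f$r_transition, 0.5, na.rm = TRUE))
  i <- hyd2[which.min(gam[hyd2])]
  ref <- .refine_parabola(r, gam, i)
  f$gamma_min_pN <- ref$y; f$r_at_gamma_min <- ref$x
  rmax <- max(r)
  f$gamma0_pN <- gam[length(gam)]
  top <- which(r >= 0.4 * rmax)
  if (length(top) >= 3) {
    fit <- stats::lm(pts$W_philic[top] ~ r[top])
    f$gamma0_fit_pN <- line_tension_to_pN(stats::coef(fit)[[2]] / (2 * pi))
  } else f$gamma0_fit_pN <- NA_real_
  lapply(f, unname)
}

.refine_parabola <- function(x, y, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(list(x = x[i], y = y[i]))
  xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  # quadratic through three (possibly unevenly spaced) points
  A <- cbind(1, xs, xs^2)
  cf <- tryCatch(solve(A, ys), error = function(e) NULL)
  if (is.null(cf) || cf[3] <= 0) return(list(x = x[i], y = y[i]))
  xv <- -cf[2] / (2 * cf[3])
  if (xv < xs[1] || xv > xs[3]) return(list(x = x[i], y = y[i]))
  list(x = xv, y = cf[1] + cf[2] * xv + cf[3] * xv^2)
}

#' @export
print.pore_trajectory <- function(x, ...) {
  f <- x$features
  cat(sprintf("<pore_trajectory: %s, %d radii in [%.2g, %.2g] nm>\n",
              x$lipid$name, nrow(x$points), min(x$points$r), max(x$points$r)))
  cat(sprintf("  transition: r = %.3g nm, forward barrier = %.3g kBT\n",
              f$r_transition, f$barrier_forward))
  if (!is.na(f$r_metastable))
    cat(sprintf("  metastable pore: r = %.3g nm, W = %.3g kBT (reverse barrier %.3g)\n",
                f$r_metastable, f$W_metastable, f$barrier_reverse))
  cat(sprintf("  line tension: min %.3g pN at r = %.3g nm; gamma0 = %.3g pN (fit %.3g)\n",
              f$gamma_min_pN, f$r_at_gamma_min, f$gamma0_pN, f$gamma0_fit_pN))
  invisible(x)
}

#' Line-tension curve of a trajectory
#'
#' @param traj `pore_trajectory`.
#' @return data.frame with `r`, `gamma_pN` (optimal branch), plus the
#'   features `gamma_min_pN`, `r_at_gamma_min`, `gamma0_pN` as attributes.
#' @export
line_tension_curve <- function(traj) {
  stopifnot(inherits(traj, "pore_trajectory"))
  out <- traj$points[, c("r", "gamma_pN")]
  attr(out, "gamma_min_pN") <- traj$features$gamma_min_pN
  attr(out, "r_at_gamma_min") <- traj$features$r_at_gamma_min
  attr(out, "gamma0_pN") <- traj$features$gamma0_pN
  out
}

#' Classical (thin-film) pore energy
#'
#' `E(r) = 2 pi r gamma - pi r^2 sigma0`, with a radius-dependent line
#' tension admitted (generalized thin-film relation).
#'
#' @param r pore radius, nm (vectorized).
#' @param gamma_pN line tension, pN (scalar or vector along `r`).
#' @param sigma0_mN_per_m lateral tension, mN/m.
#' @return energy in kBT.
#' @export
classical_energy <- function(r, gamma_pN, sigma0_mN_per_m = 0) {
  stopifnot(all(gamma_pN >= 0), sigma0_mN_per_m >= 0)
  2 * pi * r * line_tension_from_pN(gamma_pN) -
    pi * r^2 * tension_to_internal(sigma0_mN_per_m)
}

#' Critical radius of the classical pore model
#'
#' `r* = gamma / sigma0` (maximum of the classical energy).
#'
#' @param gamma_pN line tension, pN.
#' @param sigma0_mN_per_m lateral tension, mN/m (> 0).
#' @return critical radius in nm (`Inf` with a warning if sigma0 = 0).
#' @export
critical_radius <- function(gamma_pN, sigma0_mN_per_m) {
  stopifnot(gamma_pN >= 0, sigma0_mN_per_m >= 0)
  if (sigma0_mN_per_m == 0) {
    warning("critical radius is infinite at zero lateral tension")
    return(Inf)
  }
  # gamma [pN = 1e-12 N], sigma0 [mN/m = 1e-3 N/m]: r = gamma/sigma0 [1e-9 m]
  gamma_pN / sigma0_mN_per_m
}

#' Spontaneous pore closure rate from a line-tension curve
#'
#' Overdamped closure of a pore in a membrane of viscosity eta:
#' `dr/dt = -(1/(4 eta h)) (gamma(r) + r dgamma/dr)`; for constant gamma
#' this reduces to `dr/dt = -gamma/(4 eta h)`.
#'
#' @param gamma_curve data.frame with columns `r` (nm) and `gamma_pN`, or a
#'   function r -> gamma_pN.
#' @param eta membrane dynamic viscosity, Pa s.
#' @param h monolayer thickness, nm.
#' @return function mapping radius (nm) to dr/dt in nm/ns.
#' @export
closure_rate <- function(gamma_curve, eta, h) {
  stopifnot(eta > 0, h > 0)
  if (is.function(gamma_curve)) {
    gfun <- gamma_curve
    dgfun <- function(r, d = 1e-4) (gfun(r + d) - gfun(r - d)) / (2 * d)
  } else {
    sp <- stats::splinefun(gamma_curve$r, gamma_curve$gamma_pN, method = "natural")
    gfun <- sp
    dgfun <- function(r) sp(r, deriv = 1)
  }
  function(r) {
    # gamma [pN = 1e-12 N]; eta*h [Pa s nm = 1e-9 N s/m]
    # dr/dt = -(gamma + r gamma')/(4 eta h)  [1e-3 m/s = 1e-6 nm/ns? careful]
    # 1 pN / (Pa s nm) = 1e-12 N / (1e-9 N s/m) = 1e-3 m/s = 1 nm/us = 1e-3 nm/ns
    -(gfun(r) + r * dgfun(r)) / (4 * eta * h) * 1e-3
  }
}
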