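# Independent numerical oracles built at test time.

# --- complex modified Bessel I (ascending series; for Wronskian checks) ----
cbesselI01_series <- function(z) {
  z <- as.complex(z)
  z2 <- z * z / 4
  t0 <- rep(1 + 0i, length(z))
  t1 <- rep(1 + 0i, length(z))
  I0 <- t0
  I1s <- t1
  for (k in 1:80) {
    t0 <- t0 * z2 / (k * k)
    t1 <- t1 * z2 / (k * (k + 1))
    I0 <- I0 + t0
    I1s <- I1s + t1
    if (max(Mod(t0)) < 1e-18 * max(Mod(I0))) break
  }
  list(I0 = I0, I1 = I1s * z / 2)
}

# --- finite-difference minimizer of the bilayer-region functional ----------
# Discretizes the elastic functional on [R0, R0 + Lext] and minimizes the
# resulting quadratic form under the junction constraints (KKT solve).
fd_bilayer_oracle <- function(lipid, env, R0, Z0, n0, N = 2000, Lext = 35) {
  requireNamespace("Matrix", quietly = TRUE)
  sparse <- Matrix::sparseMatrix
  h <- lipid$h; l2 <- lipid$l2; A <- lipid$A; Kt <- lipid$K_t; J0 <- lipid$J0
  sg <- env$sigma0 / Kt
  rho <- seq(R0, R0 + Lext, length.out = N)
  dr <- rho[2] - rho[1]
  i <- c(2:(N - 1), 2:(N - 1)); j <- c(3:N, 1:(N - 2))
  v <- c(rep(1 / (2 * dr), N - 2), rep(-1 / (2 * dr), N - 2))
  i <- c(i, 1, 1, 1, N, N, N); j <- c(j, 1, 2, 3, N, N - 1, N - 2)
  v <- c(v, -1.5 / dr, 2 / dr, -0.5 / dr, 1.5 / dr, -2 / dr, 0.5 / dr)
  D1 <- sparse(i = i, j = j, x = v, dims = c(N, N))
  I <- Matrix::Diagonal(N)
  Z <- sparse(i = integer(0), j = integer(0), dims = c(N, N))
  Sn <- D1 + Matrix::Diagonal(N, 1 / rho)
  S <- cbind(Sn, Z)                                   # s(rho)
  Wm <- cbind((h^2 / 2) * D1 %*% Sn, h * D1)          # w = (h^2/2) s' + h a'
  Tm <- cbind(I, Z) + Wm                              # tilt
  Cm <- cbind(Z, I)                                   # alpha
  wq <- rep(dr, N); wq[c(1, N)] <- dr / 2
  Wd <- Matrix::Diagonal(N, wq * rho)
  M <- 2 * pi * Kt * (l2 * Matrix::t(S) %*% Wd %*% S + Matrix::t(Tm) %*% Wd %*% Tm +
                        A * Matrix::t(Cm) %*% Wd %*% Cm + sg * Matrix::t(Wm) %*% Wd %*% Wm)
  b <- as.vector(2 * pi * Kt * 2 * l2 * J0 * Matrix::t(S) %*% (wq * rho))
  Crows <- rbind(sparse(i = 1, j = 1, x = 1, dims = c(1, 2 * N)),
                 -(h^2 / 2) * S[1, , drop = FALSE] - h * Cm[1, , drop = FALSE],
                 sparse(i = c(1, 2, 3), j = c(N, N - 1, 2 * N), x = 1, dims = c(3, 2 * N)))
  rhs <- c(n0, Z0 - h, 0, 0, 0)
  KKT <- rbind(cbind(2 * M, Matrix::t(Crows)),
               cbind(Crows, sparse(i = integer(0), j = integer(0), dims = c(5, 5))))
  sol <- Matrix::solve(KKT, c(-b, rhs))
  y <- sol[seq_len(2 * N)]
  W <- as.numeric(Matrix::t(y) %*% M %*% y + sum(b * y))
  list(W = W, rho = rho, n = y[1:N], alpha = y[(N + 1):(2 * N)])
}

# --- raw (nonlinear) wall energy density and its numeric Taylor expansion --
wall_raw_density <- function(x, lipid, env, R_v) {
  h <- lipid$h
  a <- R_v^2 / (2 * R_v^2 + h^2)
  u <- a * (2 * x[4] + 2 * h * x[6] + h^2 * x[2])
  up <- a * (2 * x[5] + 2 * h * x[7] + h^2 * x[3])
  R <- R_v + u
  2 * pi * R * sqrt(1 + up^2) *
    (lipid$B / 2 * (x[2] + 1 / R + lipid$J0)^2 - lipid$B / 2 * lipid$J0^2 +
       lipid$K_t / 2 * (x[1] + up)^2 + lipid$K_A / 2 * x[6]^2 + env$sigma0)
}

wall_numeric_quadform <- function(lipid, env, R_v, d = 1e-4) {
  f <- function(x) wall_raw_density(x, lipid, env, R_v)
  f0 <- f(numeric(7))
  L <- numeric(7); Q <- matrix(0, 7, 7)
  for (i in 1:7) {
    ei <- numeric(7); ei[i] <- d
    L[i] <- (f(ei) - f(-ei)) / (2 * d)
    Q[i, i] <- (f(ei) - 2 * f0 + f(-ei)) / d^2
  }
  for (i in 1:6) for (j in (i + 1):7) {
    ei <- numeric(7); ei[i] <- d
    ej <- numeric(7); ej[j] <- d
    Q[i, j] <- Q[j, i] <- (f(ei + ej) - f(ei - ej) - f(ej - ei) + f(-ei - ej)) / (4 * d^2)
  }
  list(G0 = f0, L = L, Q = Q)
}

# --- finite-difference minimizer of the wall (vertical region) functional --
# Uses the numeric-Taylor quadratic expansion with the same radial-force
# treatment as the production solver (u-channel linear terms dropped, the
# pure v'-channel kept), so it independently checks the exponential-basis
# boundary-value solve and energy quadrature.
fd_wall_oracle <- function(lipid, env, R_v, z_lo, Z0, v_lo, u_lo, v_hi, u_hi,
                           N = 1500) {
  requireNamespace("Matrix", quietly = TRUE)
  sparse <- Matrix::sparseMatrix
  nq <- wall_numeric_quadform(lipid, env, R_v)
  # production radial-force treatment: only the v'-channel of L survives
  Lp <- numeric(7)
  Lp[2] <- 2 * pi * R_v * lipid$B * (1 / R_v + lipid$J0)
  h <- lipid$h
  a <- R_v^2 / (2 * R_v^2 + h^2)
  z <- seq(z_lo, Z0, length.out = N)
  dz <- z[2] - z[1]
  i <- c(2:(N - 1), 2:(N - 1)); j <- c(3:N, 1:(N - 2))
  v <- c(rep(1 / (2 * dz), N - 2), rep(-1 / (2 * dz), N - 2))
  i <- c(i, 1, 1, 1, N, N, N); j <- c(j, 1, 2, 3, N, N - 1, N - 2)
  v <- c(v, -1.5 / dz, 2 / dz, -0.5 / dz, 1.5 / dz, -2 / dz, 0.5 / dz)
  D1 <- sparse(i = i, j = j, x = v, dims = c(N, N))
  I <- Matrix::Diagonal(N)
  Z <- sparse(i = integer(0), j = integer(0), dims = c(N, N))
  Jx <- list(cbind(I, Z, Z), cbind(D1, Z, Z), cbind(D1 %*% D1, Z, Z),
             cbind(Z, I, Z), cbind(Z, D1, Z), cbind(Z, Z, I), cbind(Z, Z, D1))
  wq <- rep(dz, N); wq[c(1, N)] <- dz / 2
  Wd <- Matrix::Diagonal(N, wq)
  M <- Reduce(`+`, lapply(1:7, function(p) Reduce(`+`, lapply(1:7, function(q)
    0.5 * nq$Q[p, q] * Matrix::t(Jx[[p]]) %*% Wd %*% Jx[[q]]))))
  bvec <- Reduce(`+`, lapply(1:7, function(p) Lp[p] * as.vector(Matrix::t(Jx[[p]]) %*% wq)))
  Urow <- function(node)
    a * (h^2 * Jx[[2]][node, , drop = FALSE] + 2 * Jx[[4]][node, , drop = FALSE] +
           2 * h * Jx[[6]][node, , drop = FALSE])
  Crows <- rbind(Jx[[1]][1, , drop = FALSE], Urow(1),
                 Jx[[1]][N, , drop = FALSE], Urow(N))
  rhs <- c(v_lo, u_lo, v_hi, u_hi)
  KKT <- rbind(cbind(M + Matrix::t(M), Matrix::t(Crows)),
               cbind(Crows, sparse(i = integer(0), j = integer(0), dims = c(4, 4))))
  s <- Matrix::solve(KKT, c(-bvec, rhs))
  y <- s[seq_len(3 * N)]
  Whalf <- as.numeric(Matrix::t(y) %*% M %*% y + sum(bvec * y)) + nq$G0 * (Z0 - z_lo)
  list(W = 2 * Whalf, z = z, v = y[1:N], m = y[(N + 1):(2 * N)],
       beta = y[(2 * N + 1):(3 * N)])
}
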