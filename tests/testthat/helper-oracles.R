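# Independent oracles used by the unit tests.  These deliberately take a
# different computational route from the package implementation.

# Rotate a Voigt stiffness matrix by working on the full 3x3x3x3 tensor
# with an explicit 81-term contraction (oracle for rotate_to_global).
voigt_index <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))

voigt_to_tensor <- function(C) {
  Tt <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) for (b in 1:6) {
    i <- voigt_index[a, 1]; j <- voigt_index[a, 2]
    k <- voigt_index[b, 1]; l <- voigt_index[b, 2]
    Tt[i, j, k, l] <- Tt[j, i, k, l] <- Tt[i, j, l, k] <- Tt[j, i, l, k] <-
      C[a, b]
  }
  Tt
}

tensor_to_voigt <- function(Tt) {
  C <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6)
    C[a, b] <- Tt[voigt_index[a, 1], voigt_index[a, 2],
                  voigt_index[b, 1], voigt_index[b, 2]]
  C
}

rotate_tensor_oracle <- function(C, Q) {
  Tt <- voigt_to_tensor(C)
  Tr <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (u in 1:3)
      s <- s + Q[i, p] * Q[j, q] * Q[k, r] * Q[l, u] * Tt[p, q, r, u]
    Tr[i, j, k, l] <- s
  }
  tensor_to_voigt(Tr)
}

# Independent trilinear hexahedron stiffness by plain-R quadrature
# (oracle for the compiled element kernel).
hex8_stiffness_oracle <- function(X, C, ngauss = 2) {
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  gp <- if (ngauss == 2) c(-1, 1) / sqrt(3) else
    c(-sqrt(0.6), 0, sqrt(0.6))
  gw <- if (ngauss == 2) c(1, 1) else c(5, 8, 5) / 9
  K <- matrix(0, 24, 24)
  for (a in seq_along(gp)) for (b in seq_along(gp)) for (c in seq_along(gp)) {
    xi <- gp[a]; eta <- gp[b]; ze <- gp[c]
    dN <- t(vapply(1:8, function(n) {
      s <- sgn[n, ]
      0.125 * c(s[1] * (1 + s[2] * eta) * (1 + s[3] * ze),
                (1 + s[1] * xi) * s[2] * (1 + s[3] * ze),
                (1 + s[1] * xi) * (1 + s[2] * eta) * s[3])
    }, numeric(3)))
    J <- t(dN) %*% X
    dNx <- dN %*% t(solve(J))
    B <- matrix(0, 6, 24)
    for (n in 1:8) {
      cidx <- 3 * (n - 1)
      B[1, cidx + 1] <- dNx[n, 1]
      B[2, cidx + 2] <- dNx[n, 2]
      B[3, cidx + 3] <- dNx[n, 3]
      B[4, cidx + 2] <- dNx[n, 3]; B[4, cidx + 3] <- dNx[n, 2]
      B[5, cidx + 1] <- dNx[n, 3]; B[5, cidx + 3] <- dNx[n, 1]
      B[6, cidx + 1] <- dNx[n, 2]; B[6, cidx + 2] <- dNx[n, 1]
    }
    K <- K + gw[a] * gw[b] * gw[c] * det(J) * t(B) %*% C %*% B
  }
  K
}

# Strain of a trilinear interpolant by central finite differences at the
# element centre (oracle for strain recovery).
hex8_fd_strain_oracle <- function(X, Ue, h = 1e-6) {
  # map natural -> physical near the centre by Newton solve is overkill;
  # differentiate u(x) = N(xi(x)) u via chain rule with numeric J at 0
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  Nfun <- function(xi) vapply(1:8, function(n)
    0.125 * prod(1 + sgn[n, ] * xi), numeric(1))
  u_of_nat <- function(xi) as.numeric(t(Ue) %*% Nfun(xi))
  x_of_nat <- function(xi) as.numeric(t(X) %*% Nfun(xi))
  J <- matrix(0, 3, 3)  # dx/dxi by central differences
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    J[, k] <- (x_of_nat(e) - x_of_nat(-e)) / (2 * h)
  }
  G <- matrix(0, 3, 3)  # du/dxi
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    G[, k] <- (u_of_nat(e) - u_of_nat(-e)) / (2 * h)
  }
  H <- G %*% solve(J)  # du/dx
  eps <- (H + t(H)) / 2
  c(eps[1, 1], eps[2, 2], eps[3, 3],
    2 * eps[2, 3], 2 * eps[1, 3], 2 * eps[1, 2])
}

# unit cube node coordinates in the package's corner ordering
unit_cube <- function(a = 1) {
  a * rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
            c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
}
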