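# Meshes and independent oracles used across the test files.

# reference tetrahedron (unit right tet at the origin)
unit_tet <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# two tets sharing a face, all outer faces FIXED except one rim triangle
two_tet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1))
  tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  v <- tet_volumes(nodes, tets)
  tets[v < 0, c(3, 4)] <- tets[v < 0, c(4, 3)]
  tris <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4),
                c(2, 3, 5), c(2, 4, 5), c(3, 4, 5))
  region <- c("FIXED", "FIXED", "FIXED", "EXPOSED_RIM",
              "EXPOSED_CENTER", "EXPOSED_RIM")
  tet_mesh(nodes, tets, tris, region)
}

# axis-aligned unit cube [0,1]^3, n cells per axis, Kuhn 6-tet subdivision;
# used for the linear patch test (independent of the sphere generator)
cube_mesh <- function(n = 2L) {
  g <- seq(0, 1, length.out = n + 1L)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  colnames(nodes) <- NULL
  idx <- function(i, j, k) i + (n + 1L) * (j - 1L) + (n + 1L)^2L * (k - 1L)
  cell <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n)))
  corner <- function(di, dj, dk)
    idx(cell[, 1] + di, cell[, 2] + dj, cell[, 3] + dk)
  vs <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(0L, 1L, 0L),
              corner(1L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
              corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  kuhn <- list(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
               c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  tets <- do.call(rbind, lapply(kuhn, function(p) vs[, p, drop = FALSE]))
  storage.mode(tets) <- "integer"
  v <- tet_volumes(nodes, tets)
  tets[v < 0, c(3, 4)] <- tets[v < 0, c(4, 3)]
  list(nodes = nodes, tets = tets)
}

# independent element-stiffness oracle: Hessian (by central finite
# differences) of the element's linear elastic energy
#   E(u) = V * ( lambda/2 tr(eps)^2 + mu eps:eps ),  eps = sym(grad u)
# with the displacement gradient obtained from nodal values by solving the
# local interpolation system - no B-matrix involved.
element_stiffness_fd <- function(coords, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  Tm <- t(coords[2:4, , drop = FALSE]) - coords[1, ]
  vol <- det(Tm) / 6
  energy <- function(uvec) {
    U <- matrix(uvec, 4, 3, byrow = TRUE)
    # grad u: rows of U interpolated linearly; grad = t(U[2:4,]-U[1,]) %*% inv(Tm)
    Gu <- t(t(U[2:4, , drop = FALSE]) - U[1, ]) # 3x3: d(u)/d(local)
    Gu <- solve(t(Tm), Gu)                       # d(u_j)/d(x_i) in rows i
    eps <- (Gu + t(Gu)) / 2
    vol * (lam / 2 * sum(diag(eps))^2 + mu * sum(eps * eps))
  }
  h <- 1e-5
  K <- matrix(0, 12, 12)
  for (p in 1:12) for (q in p:12) {
    up <- uq <- upq <- u0 <- numeric(12)
    up[p] <- h; uq[q] <- h; upq[p] <- upq[p] + h; upq[q] <- upq[q] + h
    K[p, q] <- K[q, p] <-
      (energy(upq) - energy(up) - energy(uq) + energy(u0)) / h^2
  }
  K
}

# naive dense assembly oracle: explicit scatter loop over element matrices
dense_assemble_oracle <- function(mesh, mat) {
  n3 <- 3 * nrow(mesh$nodes)
  K <- matrix(0, n3, n3)
  for (e in seq_len(nrow(mesh$tets))) {
    nd <- mesh$tets[e, ]
    Ke <- element_stiffness(mesh$nodes[nd, , drop = FALSE], mat)
    dof <- as.vector(t(outer(3 * (nd - 1), 1:3, "+")))
    K[dof, dof] <- K[dof, dof] + Ke
  }
  K
}

# default hyperelastic parameters of the study
tbl1_material <- function(...) material_hyper(...)

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

lm_pre_test <- function(lm) as.matrix(lm[, c("x_pre", "y_pre", "z_pre")])
lm_intra_test <- function(lm) as.matrix(lm[, c("x_intra", "y_intra", "z_intra")])
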