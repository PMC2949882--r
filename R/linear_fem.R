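#' Linear elastic material
#'
#' Isotropic small-strain elasticity for the "mechanical" brain-shift model.
#' Defaults follow the values commonly used for brain parenchyma in
#' image-guided neurosurgery: Young's modulus 3 kPa, Poisson's ratio 0.45.
#'
#' @param E Young's modulus in Pa (> 0).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @return An object of class `material_linear`.
#' @export
material_linear <- function(E = 3000, nu = 0.45) {
  if (!(is.finite(E) && E > 0)) stop("E must be a positive, finite modulus")
  if (!(is.finite(nu) && nu > 0 && nu < 0.5)) stop("nu must lie in (0, 0.5)")
  structure(list(E = E, nu = nu), class = "material_linear")
}

lame_parameters <- function(mat) {
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  list(lambda = lam, mu = mu)
}

#' Craniotomy load specification
#'
#' Total force applied over the `EXPOSED_CENTER` boundary patch (distributed
#' over its nodes with boundary-triangle-area weights so the nodal forces sum
#' exactly to `center_force`), plus an optional uniform body-force density.
#'
#' @param center_force 3-vector, total force on the exposed-center patch (N).
#' @param body_force 3-vector, body force density (N/m^3), default zero.
#' @return An object of class `load_spec`.
#' @export
load_spec <- function(center_force = c(0, 0, 0), body_force = c(0, 0, 0)) {
  center_force <- as.numeric(center_force)
  body_force <- as.numeric(body_force)
  stopifnot(length(center_force) == 3L, length(body_force) == 3L)
  if (!all(is.finite(c(center_force, body_force))))
    stop("load components must be finite")
  structure(list(center_force = center_force, body_force = body_force),
            class = "load_spec")
}

#' Element stiffness of a constant-strain tetrahedron
#'
#' 12 x 12 stiffness matrix of a 4-node tetrahedron for isotropic linear
#' elasticity, from the strain-displacement (B) matrix with one-point
#' quadrature (exact: the strain is constant on the element). Degrees of
#' freedom are ordered (node1 x,y,z, node2 x,y,z, ...).
#'
#' @param coords 4 x 3 matrix of node coordinates (m), positive orientation.
#' @param mat a [material_linear()].
#' @return 12 x 12 symmetric positive-semidefinite matrix (N/m).
#' @export
element_stiffness <- function(coords, mat) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 3L)
  J <- t(coords[2:4, , drop = FALSE]) - coords[1, ]
  vol <- det(J) / 6
  if (!is.finite(vol) || vol <= 1e-14)
    stop("singular element: non-positive tetrahedron volume")
  Jinv <- solve(J)
  gradN <- rbind(-colSums(Jinv), Jinv)  # 4 x 3, rows = shape gradients
  # Voigt strain order (xx, yy, zz, xy, yz, zx) with engineering shear
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    g <- gradN[a, ]
    B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  lp <- lame_parameters(mat)
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lp$lambda
  diag(D)[1:3] <- lp$lambda + 2 * lp$mu
  diag(D)[4:6] <- lp$mu
  vol * t(B) %*% D %*% B
}

# area-weighted nodal distribution of the total center force; also body-force
# lumping. Returns the 3n load vector. Cap nodes that also lie on the FIXED
# surface (possible on coarse meshes where the rim ring does not enclose the
# cap) are displacement-constrained and cannot carry load, so the weights
# renormalize over the free cap nodes - keeping the applied total exact.
build_load_vector <- function(mesh, load) {
  n <- nrow(mesh$nodes)
  Fv <- numeric(3 * n)
  ctr <- which(mesh$region == "EXPOSED_CENTER")
  if (any(load$center_force != 0)) {
    if (length(ctr) == 0L)
      stop("mesh has no EXPOSED_CENTER triangles to carry the cap force")
    tris <- mesh$boundary_tris[ctr, , drop = FALSE]
    e1 <- mesh$nodes[tris[, 2], , drop = FALSE] - mesh$nodes[tris[, 1], , drop = FALSE]
    e2 <- mesh$nodes[tris[, 3], , drop = FALSE] - mesh$nodes[tris[, 1], , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area <- 0.5 * sqrt(rowSums(cr^2))
    w <- numeric(n)
    for (k in seq_along(area))
      w[tris[k, ]] <- w[tris[k, ]] + area[k] / 3
    w[dirichlet_nodes(mesh)] <- 0
    if (sum(w) <= 0)
      stop("every EXPOSED_CENTER node is displacement-constrained; refine the mesh")
    w <- w / sum(w)
    nz <- which(w > 0)
    for (i in 1:3) Fv[3 * (nz - 1) + i] <- w[nz] * load$center_force[i]
  }
  if (any(load$body_force != 0)) {
    vols <- tet_volumes(mesh$nodes, mesh$tets)
    wv <- numeric(n)
    for (e in seq_len(nrow(mesh$tets)))
      wv[mesh$tets[e, ]] <- wv[mesh$tets[e, ]] + vols[e] / 4
    for (i in 1:3) Fv[seq(i, 3 * n, by = 3)] <- Fv[seq(i, 3 * n, by = 3)] +
        wv * load$body_force[i]
  }
  Fv
}

dirichlet_nodes <- function(mesh) {
  fixed_tris <- which(mesh$region == "FIXED")
  if (length(fixed_tris) == 0L)
    stop("floating structure: mesh has no FIXED boundary triangles")
  sort(unique(as.integer(mesh$boundary_tris[fixed_tris, ])))
}

# cached E/nu-independent stiffness split and load weights for one mesh,
# used by both the one-shot solver and the optimizer loop
linear_operator <- function(mesh) {
  parts <- cpp_linear_stiffness_parts(mesh$nodes, mesh$tets - 1L)
  n3 <- 3L * nrow(mesh$nodes)
  ti <- as.numeric(parts$ti); tj <- as.numeric(parts$tj)
  Klam <- Matrix::sparseMatrix(i = ti, j = tj, x = as.numeric(parts$xlam),
                               dims = c(n3, n3))
  Kmu <- Matrix::sparseMatrix(i = ti, j = tj, x = as.numeric(parts$xmu),
                              dims = c(n3, n3))
  dn <- dirichlet_nodes(mesh)
  fixed_dof <- as.integer(outer(3L * (dn - 1L), 1:3, "+"))
  free <- setdiff(seq_len(n3), fixed_dof)
  list(Klam = Klam, Kmu = Kmu, dirichlet_nodes = dn, fixed_dof = fixed_dof,
       free = free, n3 = n3)
}

#' Assemble and constrain the linear system
#'
#' Assembles the global stiffness `K` and load vector `F` for the linear
#' elastic model and imposes the zero-displacement Dirichlet condition on all
#' nodes of `FIXED` boundary triangles in the rigidity-matrix convention:
#' constrained rows and columns are zeroed, their diagonal entries set to
#' one, and the corresponding right-hand-side entries set to the prescribed
#' value (zero). Symmetry is preserved.
#'
#' @param mesh a labeled [tet_mesh()].
#' @param mat a [material_linear()].
#' @param load a [load_spec()].
#' @return list of class `linear_system` with sparse symmetric `K` (N/m),
#'   `F` (N), and integer `dirichlet` (constrained node indices).
#' @export
assemble_and_constrain <- function(mesh, mat, load) {
  op <- linear_operator(mesh)
  lp <- lame_parameters(mat)
  K <- lp$lambda * op$Klam + lp$mu * op$Kmu
  Fv <- build_load_vector(mesh, load)
  fd <- op$fixed_dof
  K[fd, ] <- 0
  K[, fd] <- 0
  K[cbind(fd, fd)] <- 1
  Fv[fd] <- 0
  structure(list(K = K, F = Fv, dirichlet = op$dirichlet_nodes),
            class = "linear_system")
}

#' Solve the linear elastic ("mechanical") model
#'
#' Solves `K u = F` for the craniotomy load. Internally the constrained
#' degrees of freedom are eliminated and the reduced symmetric system is
#' solved by sparse Cholesky factorization (a conjugate-gradient option is
#' available behind `solver = "cg"`). The residual of the full constrained
#' system is checked against `tol`.
#'
#' @inheritParams assemble_and_constrain
#' @param solver `"direct"` (default, sparse Cholesky) or `"cg"`.
#' @param tol relative residual tolerance (default 1e-8; the iterative
#'   solver targets 1e-10).
#' @param operator optional precomputed internal operator (from repeated
#'   solves on one mesh); regular users can ignore it.
#' @return n x 3 displacement matrix (m) of class `displacement_field`,
#'   zero on Dirichlet nodes.
#' @export
solve_linear <- function(mesh, mat, load, solver = c("direct", "cg"),
                         tol = 1e-8, operator = NULL) {
  solver <- match.arg(solver)
  op <- if (is.null(operator)) linear_operator(mesh) else operator
  lp <- lame_parameters(mat)
  K <- lp$lambda * op$Klam + lp$mu * op$Kmu
  Fv <- build_load_vector(mesh, load)
  free <- op$free
  Kff <- K[free, free, drop = FALSE]
  bf <- Fv[free]
  if (solver == "direct") {
    uf <- as.numeric(Matrix::solve(Kff, bf))
  } else {
    uf <- cg_solve(Kff, bf, tol = 1e-10)
  }
  u <- numeric(op$n3)
  u[free] <- uf
  if (any(Fv != 0)) {
    res <- sqrt(sum((as.numeric(Kff %*% uf) - bf)^2)) / sqrt(sum(bf^2))
    if (!is.finite(res) || res > tol)
      stop(sprintf("linear solve did not reach tolerance: residual %.3g", res))
  }
  field <- matrix(u, ncol = 3L, byrow = TRUE)
  class(field) <- c("displacement_field", class(field))
  field
}

# plain conjugate gradients on the reduced SPD system
cg_solve <- function(A, b, tol = 1e-10, maxit = 10000L) {
  x <- numeric(length(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) / b2 < tol) return(x)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  stop(sprintf("conjugate gradients did not converge: residual %.3g",
               sqrt(rs) / b2))
}
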