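#' Hyperelastic material for the nonlinear brain-shift model
#'
#' Parameters of the stationary form of the polynomial hyper-viscoelastic
#' energy of order N = 2 in the invariants of the left Cauchy-Green tensor:
#'
#' \deqn{W = (1-g) \sum_{1 \le i+j \le 2} C_{ij0}(J_1-3)^i(J_2-3)^j
#'       + \kappa/2 (\sqrt{J_3}-1)^2}
#'
#' At long times only the fraction `1 - g` of the instantaneous stiffness
#' remains, where `g = g1 + g2` sums the relaxation coefficients; the
#' characteristic times `tau1`, `tau2` are stored for provenance but do not
#' enter the stationary solve. The volumetric penalty `kappa_vol` (not part
#' of the published polynomial, which is silent on the volumetric response)
#' enforces near-incompressibility; its default 50 kPa corresponds to the
#' Poisson ratio of about 0.45 used in the linear model.
#'
#' Defaults are the literature values used as the starting point of the
#' optimization: C100 = C010 = 263 Pa, C110 = 0, C200 = C020 = 491 Pa,
#' g1 = 0.450, g2 = 0.365.
#'
#' @param C100,C010,C110,C200,C020 polynomial coefficients (Pa).
#' @param g steady-state relaxation sum g1 + g2, in `[0, 1)`.
#' @param kappa_vol volumetric penalty modulus (Pa, > 0).
#' @param tau1,tau2 characteristic times (s), provenance only.
#' @return An object of class `material_hyper`.
#' @export
material_hyper <- function(C100 = 263, C010 = 263, C110 = 0,
                           C200 = 491, C020 = 491,
                           g = 0.450 + 0.365, kappa_vol = 5e4,
                           tau1 = 0.5, tau2 = 50) {
  cc <- c(C100, C010, C110, C200, C020)
  if (!all(is.finite(cc))) stop("polynomial coefficients must be finite")
  if (!(is.finite(g) && g >= 0 && g < 1)) stop("g must lie in [0, 1)")
  if (!(is.finite(kappa_vol) && kappa_vol > 0))
    stop("kappa_vol must be a positive modulus")
  structure(list(C100 = C100, C010 = C010, C110 = C110, C200 = C200,
                 C020 = C020, g = g, kappa_vol = kappa_vol,
                 tau1 = tau1, tau2 = tau2),
            class = "material_hyper")
}

hyper_par_vec <- function(mat)
  c(mat$C100, mat$C010, mat$C110, mat$C200, mat$C020, mat$g, mat$kappa_vol)

#' Invariants of the left Cauchy-Green tensor
#'
#' Computes `J1 = tr(B)`, `J2 = (J1^2 - tr(B^2)) / (2 J3)` and
#' `J3 = det(B)` for a symmetric positive-definite `B = F F^T`. Note that
#' this `J2` carries the `1/J3` scaling of the constitutive model used here
#' (it is not the classical second principal invariant).
#'
#' @param B 3 x 3 symmetric positive-definite matrix.
#' @return Named numeric vector `c(J1, J2, J3)`; `(3, 3, 1)` at identity.
#' @export
strain_invariants <- function(B) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == 3L, ncol(B) == 3L)
  if (max(abs(B - t(B))) > 1e-8 * max(1, max(abs(B))))
    stop("invalid strain: B must be symmetric")
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("invalid strain: B must be positive-definite")
  J1 <- sum(diag(B))
  J3 <- det(B)
  J2 <- (J1^2 - sum(B * B)) / (2 * J3)
  c(J1 = J1, J2 = J2, J3 = J3)
}

#' Stationary strain-energy density
#'
#' Evaluates the long-time (stationary) energy density of the polynomial
#' hyperelastic model at a given strain state: the instantaneous polynomial
#' scaled by `1 - g` plus the volumetric penalty. Zero at the undeformed
#' state.
#'
#' @param B 3 x 3 left Cauchy-Green tensor (or a `c(J1, J2, J3)` vector).
#' @param mat a [material_hyper()].
#' @return Energy density in Pa.
#' @export
steady_state_energy <- function(B, mat) {
  if (is.matrix(B)) J <- unname(strain_invariants(B))
  else { J <- unname(as.numeric(B)); stopifnot(length(J) == 3L) }
  a1 <- J[1] - 3; a2 <- J[2] - 3
  om <- 1 - mat$g
  om * (mat$C100 * a1 + mat$C010 * a2 + mat$C110 * a1 * a2 +
          mat$C200 * a1^2 + mat$C020 * a2^2) +
    0.5 * mat$kappa_vol * (sqrt(J[3]) - 1)^2
}

#' Stress and tangent of the hyperelastic model
#'
#' Analytic first derivative (first Piola-Kirchhoff stress, the
#' work-conjugate stress of the total-Lagrangian formulation; its
#' push-forward `P F^T / J` is the Cauchy stress) and second derivative
#' (9 x 9 material tangent `dP/dF`, major-symmetric) of the stationary
#' energy with respect to the deformation gradient.
#'
#' @param F 3 x 3 deformation gradient with positive determinant.
#' @param mat a [material_hyper()].
#' @return list with `W` (energy density, Pa), `P` (3 x 3 stress, Pa) and
#'   `A` (9 x 9 tangent, Pa; index pairing `(i, J) -> i + 3 (J - 1)`).
#' @export
stress_and_tangent <- function(F, mat) {
  F <- as.matrix(F)
  stopifnot(nrow(F) == 3L, ncol(F) == 3L)
  if (det(F) <= 0) stop("invalid strain: det(F) must be positive")
  out <- cpp_hyper_point(F, hyper_par_vec(mat), TRUE)
  if (!isTRUE(out$ok)) stop("invalid strain state for stress evaluation")
  list(W = out$W, P = out$P, A = out$A)
}

#' Small-strain moduli equivalent to the hyperelastic model
#'
#' Linearizes the stationary hyperelastic energy at the undeformed state and
#' returns the equivalent isotropic small-strain moduli. The shear modulus
#' equals `2 (1 - g) (C100 + C010)`; the first Lame parameter combines the
#' volumetric penalty with a (small) volumetric contribution of the
#' J3-scaled second invariant. Both are extracted from the analytic tangent
#' at identity.
#'
#' @param mat a [material_hyper()].
#' @return list with `mu`, `lambda`, `bulk` (Pa) and the equivalent `E`
#'   (Pa) and `nu` of a [material_linear()].
#' @export
small_strain_moduli <- function(mat) {
  A <- stress_and_tangent(diag(3), mat)$A
  mu <- A[2, 4]       # A_{(2,1),(1,2)} = A_1212 under pairing i + 3(J-1)
  lambda <- A[1, 5]   # A_{(1,1),(2,2)} = A_1122
  bulk <- lambda + 2 * mu / 3
  E <- mu * (3 * lambda + 2 * mu) / (lambda + mu)
  nu <- lambda / (2 * (lambda + mu))
  list(mu = mu, lambda = lambda, bulk = bulk, E = E, nu = nu)
}

#' Solve the nonlinear hyperelastic model
#'
#' Total-Lagrangian Newton solve of the stationary virtual-work equations on
#' the reference mesh, with the craniotomy load applied in equal increments.
#' Each Newton step is accepted only if it reduces the residual norm;
#' otherwise the step is halved (up to `max_halvings` times). The converged
#' state of each load step starts the next.
#'
#' @inheritParams solve_linear
#' @param mat a [material_hyper()].
#' @param steps number of equal load increments (default 5).
#' @param tol relative residual tolerance w.r.t. the external load norm
#'   (default 1e-8).
#' @param max_newton maximum Newton iterations per load step (default 50).
#' @param max_halvings maximum step halvings per Newton iteration (default 6).
#' @param u0 optional n x 3 initial displacement (warm start). When given,
#'   the full load is applied in a single step from `u0`; on failure the
#'   solver falls back to incremental loading from zero.
#' @return n x 3 displacement matrix (m) of class `displacement_field` with
#'   attributes `newton_iters` and `residual`.
#' @export
solve_nonlinear <- function(mesh, mat, load, steps = 5L, tol = 1e-8,
                            max_newton = 50L, max_halvings = 6L, u0 = NULL) {
  stopifnot(inherits(mat, "material_hyper"))
  op <- nonlinear_operator(mesh)
  Fext_full <- build_load_vector(mesh, load)
  if (!is.null(u0)) {
    u0v <- as.numeric(t(as.matrix(u0)))
    res <- try(newton_solve(op, mat, Fext_full, u0v, tol, max_newton,
                            max_halvings), silent = TRUE)
    if (!inherits(res, "try-error")) return(wrap_field(res, op))
  }
  u <- numeric(op$n3)
  iters <- 0L
  for (s in seq_len(steps)) {
    res <- newton_solve(op, mat, (s / steps) * Fext_full, u, tol,
                        max_newton, max_halvings)
    u <- res$u
    iters <- iters + res$iters
  }
  res$iters <- iters
  wrap_field(res, op)
}

nonlinear_operator <- function(mesh) {
  dn <- dirichlet_nodes(mesh)
  n3 <- 3L * nrow(mesh$nodes)
  fixed_dof <- as.integer(outer(3L * (dn - 1L), 1:3, "+"))
  list(nodes = mesh$nodes, tets0 = mesh$tets - 1L, n3 = n3,
       fixed_dof = fixed_dof, free = setdiff(seq_len(n3), fixed_dof))
}

wrap_field <- function(res, op) {
  field <- matrix(res$u, ncol = 3L, byrow = TRUE)
  class(field) <- c("displacement_field", class(field))
  attr(field, "newton_iters") <- res$iters
  attr(field, "residual") <- res$residual
  field
}

residual_norm <- function(op, mat, Fext, u) {
  asm <- cpp_hyper_assemble(op$nodes, op$tets0, u, hyper_par_vec(mat), FALSE)
  if (!isTRUE(asm$ok)) return(Inf)
  r <- asm$fint - Fext
  sqrt(sum(r[op$free]^2))
}

newton_solve <- function(op, mat, Fext, u, tol, max_newton, max_halvings) {
  free <- op$free
  fnorm <- sqrt(sum(Fext[free]^2))
  # absolute floor keeps the zero-load case well-posed
  target <- max(tol * fnorm, 1e-14 * max(1, fnorm))
  par <- hyper_par_vec(mat)
  rn <- residual_norm(op, mat, Fext, u)
  if (!is.finite(rn)) stop("invalid starting state for Newton iteration")
  iters <- 0L
  while (rn > target) {
    if (iters >= max_newton)
      stop(sprintf("Newton did not converge: residual %.3g after %d iterations (target %.3g)",
                   rn, iters, target))
    asm <- cpp_hyper_assemble(op$nodes, op$tets0, u, par, TRUE)
    if (!isTRUE(asm$ok)) stop("invalid state during Newton assembly")
    K <- Matrix::sparseMatrix(i = as.numeric(asm$ti), j = as.numeric(asm$tj),
                              x = as.numeric(asm$tx),
                              dims = c(op$n3, op$n3))
    Kff <- K[free, free, drop = FALSE]
    rhs <- -(asm$fint - Fext)[free]
    # tangent is SPD near stable states; fall back to LU if indefinite
    du <- tryCatch(
      as.numeric(Matrix::solve(
        Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE), rhs)),
      error = function(e) as.numeric(Matrix::solve(Kff, rhs)))
    step <- 1
    accepted <- FALSE
    for (h in 0:max_halvings) {
      utrial <- u
      utrial[free] <- u[free] + step * du
      rt <- residual_norm(op, mat, Fext, utrial)
      if (is.finite(rt) && rt < rn) {
        u <- utrial; rn <- rt; accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted)
      stop(sprintf("Newton step rejected after %d halvings: residual %.3g (target %.3g)",
                   max_halvings, rn, target))
    iters <- iters + 1L
  }
  list(u = u, iters = iters, residual = rn)
}
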