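test_that("strain invariants match hand-computed values", {
  expect_equal(unname(strain_invariants(diag(3))), c(3, 3, 1))
  expect_equal(unname(strain_invariants(diag(c(4, 1, 1)))), c(6, 2.25, 4))
  expect_equal(unname(strain_invariants(diag(c(4, 0.5, 0.5)))), c(5, 4.25, 1))
  expect_error(strain_invariants(diag(c(1, -1, 1))), "positive-definite")
  expect_error(strain_invariants(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
})

test_that("stationary energy is zero at identity and matches hand evaluation", {
  mat <- tbl1_material()
  expect_equal(mat$g, 0.815)  # g1 + g2 from the constitutive table
  expect_equal(steady_state_energy(diag(3), mat), 0)
  # isochoric uniaxial stretch lambda = 2: direct polynomial evaluation
  B <- diag(c(4, 0.5, 0.5))
  expect_equal(steady_state_energy(B, mat), 663.3984, tolerance = 1e-6)
  # isochoric part scales with (1 - g)
  m1 <- material_hyper(g = 0.5)
  m2 <- material_hyper(g = 0.75)
  expect_equal(steady_state_energy(B, m2) / steady_state_energy(B, m1),
               0.25 / 0.5)
  # volumetric term is unaffected by g
  Bv <- diag(c(1.1, 1.1, 1.1))
  iso <- function(m) steady_state_energy(Bv, m) -
    0.5 * m$kappa_vol * (sqrt(det(Bv)) - 1)^2
  expect_equal(iso(m2) / iso(m1), 0.5)
})

test_that("stress is the derivative of the energy (finite-difference oracle)", {
  mat <- tbl1_material()
  set.seed(3)
  for (trial in 1:3) {
    F <- diag(3) + matrix(stats::rnorm(9, sd = 0.1), 3, 3)
    st <- stress_and_tangent(F, mat)
    h <- 1e-6
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Wp <- steady_state_energy(Fp %*% t(Fp), mat)
      Wm <- steady_state_energy(Fm %*% t(Fm), mat)
      Pfd[i, j] <- (Wp - Wm) / (2 * h)
    }
    expect_lt(rel_err(st$P, Pfd), 1e-6)
  }
})

test_that("tangent matches finite differences of the stress and is major-symmetric", {
  mat <- tbl1_material()
  set.seed(4)
  F <- diag(3) + matrix(stats::rnorm(9, sd = 0.08), 3, 3)
  st <- stress_and_tangent(F, mat)
  expect_lt(max(abs(st$A - t(st$A))) / max(abs(st$A)), 1e-8)
  h <- 1e-6
  Afd <- matrix(0, 9, 9)
  for (j in 1:3) for (B in 1:3) {
    Fp <- F; Fp[j, B] <- Fp[j, B] + h
    Fm <- F; Fm[j, B] <- Fm[j, B] - h
    dP <- (stress_and_tangent(Fp, mat)$P - stress_and_tangent(Fm, mat)$P) / (2 * h)
    Afd[, j + 3 * (B - 1)] <- as.vector(dP)
  }
  expect_lt(rel_err(st$A, Afd), 1e-5)
})

test_that("stress vanishes at identity and energy is frame-indifferent", {
  mat <- tbl1_material()
  expect_equal(max(abs(stress_and_tangent(diag(3), mat)$P)), 0)
  set.seed(5)
  F <- diag(3) + matrix(stats::rnorm(9, sd = 0.1), 3, 3)
  W0 <- stress_and_tangent(F, mat)$W
  for (trial in 1:5) {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_lt(abs(stress_and_tangent(Q %*% F, mat)$W - W0),
              1e-10 * max(1, abs(W0)))
  }
})

test_that("small-strain moduli match the relaxation-scaled coefficient sum", {
  mod <- small_strain_moduli(tbl1_material())
  expect_equal(mod$mu, 2 * (1 - 0.815) * (263 + 263), tolerance = 1e-12)
  expect_equal(mod$mu, 194.62, tolerance = 1e-10)
  m0 <- small_strain_moduli(material_hyper(g = 0))
  expect_equal(m0$mu, 2 * (263 + 263), tolerance = 1e-12)
  mz <- small_strain_moduli(material_hyper(C100 = 1e-9, C010 = 1e-9))
  expect_lt(mz$mu, 1e-6)
  # finite-difference slope of the shear stress at identity
  mat <- tbl1_material()
  h <- 1e-7
  F <- diag(3); F[1, 2] <- h
  P <- stress_and_tangent(F, mat)$P
  expect_equal(P[1, 2] / h, mod$mu, tolerance = 1e-5)
})

test_that("discrete residual is the gradient of the discrete energy", {
  mesh <- two_tet_mesh()
  mat <- tbl1_material()
  op <- brainshift:::nonlinear_operator(mesh)
  set.seed(6)
  u <- stats::rnorm(op$n3, sd = 5e-3)
  asm <- brainshift:::cpp_hyper_assemble(op$nodes, op$tets0, u,
                                         brainshift:::hyper_par_vec(mat), FALSE)
  h <- 1e-7
  for (d in sample.int(op$n3, 6)) {
    up <- u; up[d] <- up[d] + h
    um <- u; um[d] <- um[d] - h
    ep <- brainshift:::cpp_hyper_assemble(op$nodes, op$tets0, up,
                                          brainshift:::hyper_par_vec(mat), FALSE)$energy
    em <- brainshift:::cpp_hyper_assemble(op$nodes, op$tets0, um,
                                          brainshift:::hyper_par_vec(mat), FALSE)$energy
    expect_equal(asm$fint[d], (ep - em) / (2 * h),
                 tolerance = 1e-5 * max(1, abs(asm$fint[d])))
  }
})

test_that("zero load returns the zero field without Newton corrections", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  u <- solve_nonlinear(mesh, tbl1_material(), load_spec(), steps = 1)
  expect_equal(max(abs(u)), 0)
  expect_identical(attr(u, "newton_iters"), 0L)
})

test_that("tiny loads reproduce the linearized elastic solution within 1%", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  mat <- tbl1_material()
  mod <- small_strain_moduli(mat)
  load <- load_spec(c(1e-3, 1e-3, 1e-3))
  un <- solve_nonlinear(mesh, mat, load, steps = 1, tol = 1e-9)
  ul <- solve_linear(mesh, material_linear(E = mod$E, nu = mod$nu), load)
  expect_lt(rel_err(un, ul), 0.01)
})

test_that("Newton converges quadratically near the solution", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  mat <- tbl1_material()
  load <- load_spec(c(-0.3, 0.3, 0.3))
  op <- brainshift:::nonlinear_operator(mesh)
  Fext <- brainshift:::build_load_vector(mesh, load)
  pv <- brainshift:::hyper_par_vec(mat)
  u <- as.vector(t(solve_nonlinear(mesh, mat, load, steps = 5, tol = 1e-3)))
  # full Newton corrections at full load, no halving
  rn <- numeric(3)
  for (k in 1:3) {
    asm <- brainshift:::cpp_hyper_assemble(op$nodes, op$tets0, u, pv, TRUE)
    K <- Matrix::sparseMatrix(i = as.numeric(asm$ti), j = as.numeric(asm$tj),
                              x = as.numeric(asm$tx), dims = c(op$n3, op$n3))
    r <- (asm$fint - Fext)[op$free]
    rn[k] <- sqrt(sum(r^2))
    du <- as.numeric(Matrix::solve(K[op$free, op$free], -r))
    u[op$free] <- u[op$free] + du
  }
  # superlinear contraction until the round-off floor
  fnorm <- sqrt(sum(Fext^2))
  expect_lt(rn[2] / rn[1], 0.05)
  expect_true(rn[3] < 0.05 * rn[2] || rn[3] < 1e-12 * fnorm)
})

test_that("larger volumetric penalty drives element volume ratios to one", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  load <- load_spec(c(-0.3, 0.3, 0.3))
  dev <- vapply(c(5e2, 5e3, 5e4), function(kap) {
    u <- solve_nonlinear(mesh, material_hyper(kappa_vol = kap), load)
    def <- mesh$nodes + u
    max(abs(tet_volumes(def, mesh$tets) /
              tet_volumes(mesh$nodes, mesh$tets) - 1))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("invalid material parameters are rejected", {
  expect_error(material_hyper(g = 1), "g must")
  expect_error(material_hyper(kappa_vol = -1), "kappa_vol")
  expect_error(material_linear(nu = 0.5), "nu")
  expect_error(material_linear(E = 0), "E must")
})
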