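#' Landmark pairs
#'
#' A set of corresponding anatomical landmarks: pre-operative (reference)
#' positions, observed intra-operative (deformed) positions, and the role of
#' each pair (`TRAIN` pairs drive the parameter optimization, `TEST` pairs
#' are held out for evaluation). Positions are in meters.
#'
#' @param pre k x 3 matrix of pre-operative positions (m).
#' @param intra k x 3 matrix of intra-operative positions (m).
#' @param role character vector with values `TRAIN` / `TEST`.
#' @return data.frame of class `landmark_pairs` with columns
#'   `x_pre, y_pre, z_pre, x_intra, y_intra, z_intra, role`.
#' @export
landmark_pairs <- function(pre, intra, role) {
  pre <- as.matrix(pre); intra <- as.matrix(intra)
  stopifnot(ncol(pre) == 3L, ncol(intra) == 3L, nrow(pre) == nrow(intra),
            length(role) == nrow(pre))
  role <- as.character(role)
  if (any(!role %in% c("TRAIN", "TEST"))) stop("role must be TRAIN or TEST")
  out <- data.frame(x_pre = pre[, 1], y_pre = pre[, 2], z_pre = pre[, 3],
                    x_intra = intra[, 1], y_intra = intra[, 2],
                    z_intra = intra[, 3], role = role)
  class(out) <- c("landmark_pairs", class(out))
  out
}

lm_pre <- function(lm) as.matrix(lm[, c("x_pre", "y_pre", "z_pre")])
lm_intra <- function(lm) as.matrix(lm[, c("x_intra", "y_intra", "z_intra")])

#' Read / write landmark pairs as CSV
#'
#' CSV schema: columns `x_pre, y_pre, z_pre, x_intra, y_intra, z_intra,
#' role` with coordinates in meters. [write_landmarks()] writes atomically.
#'
#' @param path CSV file path.
#' @return [read_landmarks()]: a `landmark_pairs` data.frame.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_pre", "y_pre", "z_pre", "x_intra", "y_intra", "z_intra", "role")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  landmark_pairs(as.matrix(d[, need[1:3]]), as.matrix(d[, need[4:6]]), d$role)
}

#' @rdname read_landmarks
#' @param lm a `landmark_pairs` data.frame.
#' @export
write_landmarks <- function(lm, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(as.data.frame(lm), tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Predict deformed landmark positions
#'
#' Displaces points by the finite-element field: each point is located in
#' the mesh and its displacement interpolated barycentrically from the
#' nodal values of its containing tetrahedron.
#'
#' @param mesh a [tet_mesh()].
#' @param field n x 3 displacement matrix from [solve_linear()] /
#'   [solve_nonlinear()].
#' @param points k x 3 matrix of reference positions (m).
#' @param location optional precomputed [locate_points()] result for
#'   `points` (avoids re-locating fixed landmarks in optimization loops).
#' @return k x 3 matrix of displaced positions (m).
#' @export
predict_positions <- function(mesh, field, points, location = NULL) {
  points <- as.matrix(points)
  loc <- if (is.null(location)) locate_points(mesh, points) else location
  disp <- matrix(0, nrow(points), 3L)
  for (q in seq_len(nrow(points))) {
    nd <- mesh$tets[loc$tet[q], ]
    disp[q, ] <- as.numeric(loc$bary[q, ] %*% field[nd, , drop = FALSE])
  }
  points + disp
}

#' Summed landmark distance cost
#'
#' The optimization cost: the sum of Euclidean distances between predicted
#' and observed landmark positions (meters).
#'
#' @param predicted,observed k x 3 matrices (m).
#' @return total distance (m).
#' @export
landmark_cost <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (nrow(predicted) != nrow(observed) || nrow(predicted) < 1L)
    stop("predicted and observed must be nonempty and of equal length")
  sum(sqrt(rowSums((predicted - observed)^2)))
}

#' Per-axis landmark error report
#'
#' Mean and maximum absolute per-axis errors plus mean/maximum Euclidean
#' error, reported in millimeters in the format of the clinical error
#' tables. Per-axis means are means of absolute deviations by default
#' (`signed = TRUE` gives signed means instead).
#'
#' @inheritParams landmark_cost
#' @param split label (`"TRAIN"` / `"TEST"`) recorded in the report.
#' @param model label (`"linear"` / `"nonlinear"`) recorded in the report.
#' @param signed report signed per-axis means instead of absolute.
#' @return data.frame of class `error_report` (one row; mm).
#' @export
error_report <- function(predicted, observed, split = "TEST",
                         model = "linear", signed = FALSE) {
  d <- (as.matrix(predicted) - as.matrix(observed)) * 1000  # mm
  eu <- sqrt(rowSums(d^2))
  ax <- abs(d)
  mean_ax <- if (signed) colMeans(d) else colMeans(ax)
  out <- data.frame(model = model, split = split,
                    mean_dx = mean_ax[1], mean_dy = mean_ax[2],
                    mean_dz = mean_ax[3],
                    max_dx = max(ax[, 1]), max_dy = max(ax[, 2]),
                    max_dz = max(ax[, 3]),
                    mean_euclidean = mean(eu), max_euclidean = max(eu))
  rownames(out) <- NULL
  class(out) <- c("error_report", class(out))
  out
}

#' Split landmarks into optimization and evaluation sets
#'
#' Deterministic random partition: `ceiling(n * fraction)` pairs become
#' `TRAIN`, the rest `TEST`.
#'
#' @param lm a `landmark_pairs` data.frame (roles are overwritten).
#' @param fraction train fraction in (0, 1), default 0.5.
#' @param seed integer seed.
#' @return `landmark_pairs` with updated `role`.
#' @export
split_landmarks <- function(lm, fraction = 0.5, seed = 1L) {
  n <- nrow(lm)
  if (n < 2L) stop("need at least two landmark pairs to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  ntr <- ceiling(n * fraction)
  idx <- withr_seed(seed, sample.int(n, ntr))
  lm$role <- ifelse(seq_len(n) %in% idx, "TRAIN", "TEST")
  lm
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- parameter transforms -------------------------------------------------
# Nelder-Mead works in an unconstrained space scaled by the initial values:
# moduli on the log scale, nu and g through a logistic map onto their open
# feasible intervals, force components scaled by the initial magnitude.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

free_param_names <- function(model) {
  if (model == "linear") c("E", "nu", "Fx", "Fy", "Fz")
  else c("C100", "C010", "C200", "C020", "g", "Fx", "Fy", "Fz")
}

encode_params <- function(model, p, init) {
  if (model == "linear") {
    c(log(p[["E"]] / init[["E"]]), logit(p[["nu"]] / 0.5),
      p[["Fx"]] / init$Fscale, p[["Fy"]] / init$Fscale,
      p[["Fz"]] / init$Fscale)
  } else {
    c(log(p[["C100"]] / init[["C100"]]), log(p[["C010"]] / init[["C010"]]),
      log(p[["C200"]] / init[["C200"]]), log(p[["C020"]] / init[["C020"]]),
      logit(p[["g"]]),
      p[["Fx"]] / init$Fscale, p[["Fy"]] / init$Fscale,
      p[["Fz"]] / init$Fscale)
  }
}

decode_params <- function(model, th, init) {
  if (model == "linear") {
    list(E = init[["E"]] * exp(th[1]), nu = 0.5 * inv_logit(th[2]),
         Fx = th[3] * init$Fscale, Fy = th[4] * init$Fscale,
         Fz = th[5] * init$Fscale)
  } else {
    list(C100 = init[["C100"]] * exp(th[1]), C010 = init[["C010"]] * exp(th[2]),
         C200 = init[["C200"]] * exp(th[3]), C020 = init[["C020"]] * exp(th[4]),
         g = inv_logit(th[5]),
         Fx = th[6] * init$Fscale, Fy = th[7] * init$Fscale,
         Fz = th[8] * init$Fscale)
  }
}

#' Optimize model parameters against training landmarks
#'
#' Nelder-Mead (simplex) minimization of the summed landmark distance
#' ([landmark_cost()]) over the model's free parameters: `E, nu, Fx, Fy, Fz`
#' for the linear model and `C100, C010, C200, C020, g, Fx, Fy, Fz` for the
#' nonlinear model (`C110` is held at its initial value, zero by default;
#' the characteristic times do not enter the stationary solve). Every cost
#' evaluation runs a forward solve and compares predicted to observed
#' positions of the `TRAIN` landmarks. Parameters are searched in a rescaled
#' unconstrained space (log moduli, logistic `nu` and `g`, force components
#' scaled by the initial force magnitude), so every trial point is feasible;
#' forward-solver failures receive a large penalty cost and are logged.
#'
#' @param model `"linear"` or `"nonlinear"`.
#' @param mesh a [tet_mesh()].
#' @param train a `landmark_pairs` data.frame; only `TRAIN` rows are used
#'   (all rows if none is marked).
#' @param init named list of initial parameter values (the perturbed starting
#'   guess): fields of [material_linear()] or [material_hyper()] plus
#'   `Fx, Fy, Fz` (N).
#' @param fixed named list of parameters held fixed (nonlinear: `C110`,
#'   `kappa_vol` default from [material_hyper()]).
#' @param maxit maximum Nelder-Mead iterations per round (default 500).
#' @param reltol relative convergence tolerance on the cost (default 1e-6).
#' @param restarts number of Nelder-Mead restarts from the incumbent best
#'   point (default 0; restarting re-inflates the collapsed simplex, which
#'   refines the fit but also drifts further along any flat cost
#'   directions - see the methods vignette on identifiability).
#' @param steps,solver_tol forward-solver controls (nonlinear load steps
#'   default 3 within the optimizer; tolerance 1e-8).
#' @param warm_start reuse the previous accepted solution as the Newton
#'   starting point of the next evaluation (nonlinear only, default TRUE).
#' @return list of class `optim_result`: `par` (named list), `value` (final
#'   cost, m), `initial_value`, `trace` (accepted best costs), `evals`,
#'   `iterations`, `converged`, `failures`.
#' @export
optimize_parameters <- function(model = c("linear", "nonlinear"), mesh, train,
                                init, fixed = list(), maxit = 500L,
                                reltol = 1e-6, restarts = 0L, steps = 3L,
                                solver_tol = 1e-8, warm_start = TRUE) {
  model <- match.arg(model)
  if (inherits(train, "landmark_pairs") && any(train$role == "TRAIN"))
    train <- train[train$role == "TRAIN", , drop = FALSE]
  if (nrow(train) < 1L) stop("empty training landmark set")
  pre <- lm_pre(train); obs <- lm_intra(train)
  loc <- locate_points(mesh, pre)
  op_lin <- if (model == "linear") linear_operator(mesh) else NULL

  init <- as.list(init)
  init$Fscale <- max(abs(c(init$Fx, init$Fy, init$Fz)), 1e-12)
  fixed <- utils::modifyList(list(C110 = 0, kappa_vol = 5e4), as.list(fixed))

  failures <- 0L
  last_u <- NULL
  forward <- function(p) {
    if (model == "linear") {
      solve_linear(mesh, material_linear(E = p$E, nu = p$nu),
                   load_spec(c(p$Fx, p$Fy, p$Fz)), operator = op_lin)
    } else {
      mat <- material_hyper(C100 = p$C100, C010 = p$C010, C110 = fixed$C110,
                            C200 = p$C200, C020 = p$C020, g = p$g,
                            kappa_vol = fixed$kappa_vol)
      u <- solve_nonlinear(mesh, mat, load_spec(c(p$Fx, p$Fy, p$Fz)),
                           steps = steps, tol = solver_tol,
                           u0 = if (warm_start) last_u else NULL)
      if (warm_start) last_u <<- u
      u
    }
  }

  penalty <- 1e6
  best <- list(value = Inf, par = NULL)
  trace <- numeric(0)
  evals <- 0L
  costfun <- function(th) {
    p <- decode_params(model, th, init)
    evals <<- evals + 1L
    val <- tryCatch({
      field <- forward(p)
      landmark_cost(predict_positions(mesh, field, pre, location = loc), obs)
    }, error = function(e) {
      failures <<- failures + 1L
      penalty
    })
    if (val < best$value) {
      best <<- list(value = val, par = p)
      trace <<- c(trace, val)
    }
    val
  }

  th0 <- encode_params(model, init, init)
  f0 <- costfun(th0)
  if (f0 >= penalty)
    stop("forward solver failed at the initial parameters")
  initial_value <- f0

  iters <- 0L
  conv <- FALSE
  th <- th0
  for (r in seq_len(restarts + 1L)) {
    fit <- stats::optim(th, costfun, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    iters <- iters + fit$counts[1L]
    conv <- fit$convergence == 0L
    th <- fit$par
  }

  structure(list(par = best$par, value = best$value,
                 initial_value = initial_value, trace = trace,
                 evals = evals, iterations = iters, converged = conv,
                 failures = failures, model = model),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat("<optim_result> model:", x$model,
      sprintf("cost %.4g -> %.4g m over %d evaluations (%d failures)\n",
              x$initial_value, x$value, x$evals, x$failures))
  utils::str(x$par, give.head = FALSE)
  invisible(x)
}
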