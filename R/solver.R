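# Quasi-steady oxygen solve and explicit concentration stepping.
#
# The oxygen equation has no time derivative: the field equilibrates
# instantly relative to the hourly cell dynamics, so the nonlinear Poisson
# problem  laplacian(C) = Q alpha C / (1 + Q1 C)  is re-solved after every
# concentration step. Discretization: standard 5-point Laplacian on the
# uniform grid, ghost-node reflection (homogeneous Neumann) on the outer
# walls, Dirichlet C = 1 on medium nodes. The nonlinearity is handled by
# Picard iteration: freeze k = Q alpha / (1 + Q1 C_old) and solve the linear
# system (L - diag(k)) C = 0 subject to the Dirichlet rows.

node_index <- function(i, j, nx) (j - 1L) * nx + i

# Sparse operator with Dirichlet identity rows at medium nodes and the
# (negated consumption excluded) Laplacian elsewhere. Built once per grid.
build_oxygen_operator <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  mask <- grid$medium_mask
  ihx2 <- 1 / grid$hx^2; ihy2 <- 1 / grid$hy^2
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(r, c, v) {
    ii <<- c(ii, r); jj <<- c(jj, c); xx <<- c(xx, v)
  }
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      r <- node_index(i, j, nx)
      if (mask[i, j]) {
        add(r, r, 1)
        next
      }
      add(r, r, -2 * (ihx2 + ihy2))
      # x neighbors (Neumann reflection doubles the interior neighbor)
      if (i > 1L && i < nx) {
        add(r, node_index(i - 1L, j, nx), ihx2)
        add(r, node_index(i + 1L, j, nx), ihx2)
      } else if (i == 1L) {
        add(r, node_index(2L, j, nx), 2 * ihx2)
      } else {
        add(r, node_index(nx - 1L, j, nx), 2 * ihx2)
      }
      # y neighbors
      if (j > 1L && j < ny) {
        add(r, node_index(i, j - 1L, nx), ihy2)
        add(r, node_index(i, j + 1L, nx), ihy2)
      } else if (j == 1L) {
        add(r, node_index(i, 2L, nx), 2 * ihy2)
      } else {
        add(r, node_index(i, ny - 1L, nx), 2 * ihy2)
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nx * ny, nx * ny))
}

#' Solve the quasi-steady oxygen field
#'
#' Solves the nonlinear reaction--diffusion problem
#' \eqn{\nabla^2 C = Q\,\alpha\,C/(1+Q_1 C)} on the grid with `C = 1`
#' prescribed on medium nodes (constant oxygen outside the cell phase) and a
#' zero-gradient condition on the outer walls, by Picard iteration on the
#' 5-point finite-difference discretization.
#'
#' @param alpha `nx` x `ny` concentration matrix in \[0, 1\].
#' @param grid A [sim_grid] with `medium_mask` set.
#' @param p A [model_params].
#' @param config A [sim_config] (supplies `picard_tol`, `picard_max_iter`).
#' @param c_init Optional warm-start field (default: all 1).
#' @param op Optional precomputed operator from an earlier call on the same
#'   grid (internal reuse during time stepping).
#' @return `nx` x `ny` oxygen matrix in \[0, 1\], with attribute
#'   `"iterations"`.
#' @export
solve_oxygen <- function(alpha, grid, p, config = sim_config(),
                         c_init = NULL, op = NULL) {
  p <- as_model_params(p)
  if (is.null(grid$medium_mask)) {
    stop_invalid_input("'grid' must have a medium_mask")
  }
  if (any(alpha < 0) | any(alpha > 1)) {
    stop_invalid_input("'alpha' must lie in [0, 1]")
  }
  nx <- grid$nx; ny <- grid$ny
  ones <- matrix(1, nx, ny)
  if (p$Q == 0 || all(alpha == 0)) {
    # no consumption anywhere: Laplace problem with constant Dirichlet data
    attr(ones, "iterations") <- 0L
    return(ones)
  }
  if (is.null(op)) op <- build_oxygen_operator(grid)
  maskv <- as.vector(grid$medium_mask)
  av <- as.vector(alpha)
  b <- as.numeric(maskv)          # rhs: 1 at Dirichlet rows, 0 elsewhere
  cv <- if (is.null(c_init)) rep(1, nx * ny) else as.vector(c_init)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    k <- p$Q * av / (1 + p$Q1 * cv)
    k[maskv] <- 0
    A <- op - Matrix::Diagonal(x = k)
    cnew <- as.numeric(Matrix::solve(A, b))
    delta <- max(abs(cnew - cv))
    cv <- cnew
    if (delta < config$picard_tol) break
    if (iter >= config$picard_max_iter) {
      stop_numerical(sprintf(
        "oxygen solve did not converge in %d Picard iterations (last residual %.3e)",
        iter, delta), data = list(residual = delta))
    }
  }
  cv <- pmin(1, pmax(0, cv))  # round-off guard; maximum principle bounds C
  cv[maskv] <- 1              # Dirichlet data exact despite LU round-off
  out <- matrix(cv, nx, ny)
  attr(out, "iterations") <- iter
  out
}

# Vectorized RK4 over one macro step dt with oxygen frozen. Works on plain
# numeric vectors (or matrices) of alpha.
rk4_alpha <- function(alpha, cfield, p, dt, substeps) {
  h <- dt / substeps
  # growth grouped so the s1 factors cancel exactly at c = 1
  gcoef <- (1 + p$s1) * cfield / (1 + p$s1 * cfield)
  dcoef <- (p$s2 + p$s3 * cfield) / (1 + p$s4 * cfield)
  f <- function(a) gcoef * a * (1 - a) - dcoef * a
  for (s in seq_len(substeps)) {
    k1 <- f(alpha)
    k2 <- f(alpha + h / 2 * k1)
    k3 <- f(alpha + h / 2 * k2)
    k4 <- f(alpha + h * k3)
    alpha <- alpha + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  alpha
}

#' Advance the concentration field by one time step
#'
#' Each node is advanced independently (cell motion is neglected, so the
#' concentration equation has no spatial operator) by classical 4th-order
#' Runge--Kutta sub-stepping with the oxygen field frozen at the current
#' quasi-steady solve. The result is clamped to \[0, 1\] only to absorb
#' floating-point round-off: any excursion beyond `1e-12` aborts with an
#' instability error (remedy: more `ode_substeps`).
#'
#' @param alpha `nx` x `ny` concentration matrix in \[0, 1\].
#' @param cfield `nx` x `ny` oxygen matrix.
#' @param p A [model_params].
#' @param config A [sim_config].
#' @return Concentration matrix at `t + dt`.
#' @export
step_alpha <- function(alpha, cfield, p, config = sim_config()) {
  p <- as_model_params(p)
  out <- rk4_alpha(alpha, cfield, p, config$dt, config$ode_substeps)
  check_clamp(out)
}

check_clamp <- function(a, tol = 1e-12) {
  over <- max(0, max(a) - 1, -min(a))
  if (is.na(over) || over > tol) {
    stop_numerical(sprintf(
      "concentration update left [0,1] by %.3e: integration unstable, increase ode_substeps",
      over))
  }
  pmin(pmax(a, 0), 1)  # first-arg order preserves matrix dims
}

#' Percent viability of a field relative to a reference
#'
#' Viability is the trapezoid-rule integral of the concentration field
#' expressed as a percentage of the integral of the reference (t = 0,
#' normalization-time) field, mirroring the normalized cell index which is
#' set to 1.0 (100 %) at treatment time.
#'
#' @param alpha Field to evaluate (`nx` x `ny` matrix).
#' @param reference Reference field on the same grid, with positive integral.
#' @param grid A [sim_grid].
#' @return A percentage (100 = reference mass).
#' @export
viability_percent <- function(alpha, reference, grid) {
  if (!identical(dim(alpha), dim(reference)) ||
      !identical(dim(alpha), c(grid$nx, grid$ny))) {
    stop_invalid_input("fields must both match the grid dimensions")
  }
  w <- trapezoid_weights(grid)
  ref_mass <- sum(w * reference)
  if (ref_mass <= 0) stop_invalid_input("reference field has zero mass")
  100 * sum(w * alpha) / ref_mass
}

#' Run a coupled viability simulation
#'
#' Alternates the quasi-steady oxygen solve and the per-node concentration
#' update from t = 0 (treatment/normalization time) to `t_end`, recording
#' the state every `record_every` hours and reducing each recorded field to
#' percent viability against the t = 0 field.
#'
#' When `Q = 0` the oxygen field is identically 1 (zero consumption with
#' unit Dirichlet data), every node's dynamics depend only on its own
#' concentration, and the solver evolves the set of distinct nodal values
#' instead of the full field; this is an exact algebraic compression, not an
#' approximation.
#'
#' @param state0 An [initial_state].
#' @param p A [model_params].
#' @param config A [sim_config].
#' @param keep_fields Record full alpha/c matrices at each recorded time
#'   (default `TRUE`); with `FALSE` only the viability series is kept.
#' @return An object of class `viab_sim`: list with `times` (hours),
#'   `viability` (percent, one per recorded time), `states` (list of
#'   `list(t, alpha, c)` or `NULL`), plus the inputs.
#' @export
simulate_viability <- function(state0, p, config = sim_config(),
                               keep_fields = TRUE) {
  if (!inherits(state0, "initial_state")) {
    stop_invalid_input("'state0' must be an initial_state")
  }
  p <- as_model_params(p)
  grid <- state0$grid
  nrec <- as.integer(round(config$t_end / config$record_every))
  stride <- as.integer(round(config$record_every / config$dt))
  nsteps <- as.integer(round(config$t_end / config$dt))
  times <- seq(0, by = config$record_every, length.out = nrec + 1L)

  if (p$Q == 0) {
    res <- simulate_compressed(state0, p, config, times, keep_fields)
  } else {
    res <- simulate_full(state0, p, config, times, stride, nsteps, keep_fields)
  }
  structure(list(times = times, viability = res$viability,
                 states = res$states, params = p, config = config,
                 grid = grid),
            class = "viab_sim")
}

# Q = 0 path: C == 1 everywhere; evolve unique alpha values only.
simulate_compressed <- function(state0, p, config, times, keep_fields) {
  grid <- state0$grid
  w <- trapezoid_weights(grid)
  av <- as.vector(state0$alpha)
  uv <- sort(unique(av))
  idx <- match(av, uv)
  wsum <- vapply(seq_along(uv), function(k) sum(w[idx == k]), numeric(1))
  ref_mass <- sum(wsum * uv)
  if (ref_mass <= 0) stop_invalid_input("initial field has zero cell mass")
  ones <- matrix(1, grid$nx, grid$ny)
  stride <- as.integer(round(config$record_every / config$dt))
  nsteps <- as.integer(round(config$t_end / config$dt))
  vals <- uv
  viability <- numeric(length(times))
  states <- if (keep_fields) vector("list", length(times)) else NULL
  rec <- 1L
  record <- function(t, vals, rec) {
    viability[rec] <<- 100 * sum(wsum * vals) / ref_mass
    if (keep_fields) {
      states[[rec]] <<- list(t = t,
                             alpha = matrix(vals[idx], grid$nx, grid$ny),
                             c = ones)
    }
  }
  record(0, vals, rec)
  if (nsteps > 0) {
    for (s in seq_len(nsteps)) {
      vals <- tryCatch(
        check_clamp(rk4_alpha(vals, 1, p, config$dt, config$ode_substeps)),
        viabsim_error = function(e) {
          stop_numerical(sprintf("at t = %g h: %s", s * config$dt,
                                 conditionMessage(e)))
        })
      if (s %% stride == 0L) {
        rec <- rec + 1L
        record(s * config$dt, vals, rec)
      }
    }
  }
  list(viability = viability, states = states)
}

simulate_full <- function(state0, p, config, times, stride, nsteps,
                          keep_fields) {
  grid <- state0$grid
  op <- build_oxygen_operator(grid)
  alpha <- state0$alpha
  cfield <- tryCatch(
    solve_oxygen(alpha, grid, p, config, op = op),
    viabsim_error = function(e) {
      stop_numerical(paste0("at t = 0 h: ", conditionMessage(e)))
    })
  viability <- numeric(length(times))
  states <- if (keep_fields) vector("list", length(times)) else NULL
  viability[1] <- 100
  if (keep_fields) states[[1]] <- list(t = 0, alpha = alpha, c = cfield)
  rec <- 1L
  if (nsteps > 0) {
    for (s in seq_len(nsteps)) {
      t_now <- s * config$dt
      wrap <- function(expr) {
        tryCatch(expr, viabsim_error = function(e) {
          stop_numerical(sprintf("at t = %g h: %s", t_now,
                                 conditionMessage(e)))
        })
      }
      alpha <- wrap(step_alpha(alpha, cfield, p, config))
      cfield <- wrap(solve_oxygen(alpha, grid, p, config,
                                  c_init = cfield, op = op))
      if (s %% stride == 0L) {
        rec <- rec + 1L
        viability[rec] <- viability_percent(alpha, state0$alpha, grid)
        if (keep_fields) {
          states[[rec]] <- list(t = t_now, alpha = alpha, c = cfield)
        }
      }
    }
  }
  list(viability = viability, states = states)
}

#' @export
print.viab_sim <- function(x, ...) {
  cat(sprintf("<viab_sim> %d recorded times over %g h; viability %0.2f%% -> %0.2f%%\n",
              length(x$times), x$config$t_end,
              x$viability[1], x$viability[length(x$viability)]))
  invisible(x)
}

#' Viability series of a simulation as a data frame
#'
#' @param sim A `viab_sim` object.
#' @return `data.frame(time_h, viability_pct)`.
#' @export
sim_viability_series <- function(sim) {
  data.frame(time_h = sim$times, viability_pct = sim$viability)
}
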