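#' Simulation grid
#'
#' Uniform node grid on the unit square. Fields (cell concentration, oxygen)
#' are stored as `nx` x `ny` matrices; row index i maps to
#' `x = (i-1)/(nx-1)`, column index j to `y = (j-1)/(ny-1)`.
#'
#' @param nx,ny Node counts per axis (>= 2).
#' @param medium_mask Optional `nx` x `ny` logical matrix, `TRUE` where the
#'   node lies outside the cell phase at t = 0 (culture medium; the oxygen
#'   Dirichlet anchor). Usually filled in by [image_to_alpha0].
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(nx = 50, ny = 50, medium_mask = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L) {
    stop_invalid_input("'nx' and 'ny' must be integers >= 2")
  }
  if (!is.null(medium_mask)) {
    if (!is.logical(medium_mask) || !identical(dim(medium_mask), c(nx, ny))) {
      stop_invalid_input("'medium_mask' must be a logical nx x ny matrix")
    }
    if (!any(medium_mask)) {
      stop_invalid_input("'medium_mask' must contain at least one TRUE node (oxygen source)")
    }
  }
  structure(list(nx = nx, ny = ny,
                 hx = 1 / (nx - 1), hy = 1 / (ny - 1),
                 x = seq(0, 1, length.out = nx),
                 y = seq(0, 1, length.out = ny),
                 medium_mask = medium_mask),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d nodes on the unit square", x$nx, x$ny))
  if (!is.null(x$medium_mask)) {
    cat(sprintf(" (%d medium nodes)", sum(x$medium_mask)))
  }
  cat("\n")
  invisible(x)
}

# Trapezoidal quadrature weights (product of 1-D trapezoid weights),
# as an nx x ny matrix.
trapezoid_weights <- function(grid) {
  wx <- rep(1, grid$nx); wx[c(1, grid$nx)] <- 0.5
  wy <- rep(1, grid$ny); wy[c(1, grid$ny)] <- 0.5
  outer(wx * grid$hx, wy * grid$hy)
}

#' Simulation configuration
#'
#' @param dt Time step in hours (default 1).
#' @param t_end Total simulated time in hours (default 72); must be a
#'   multiple of `dt`.
#' @param ode_substeps RK4 substeps per `dt` for the concentration update
#'   (default 10).
#' @param picard_tol Convergence tolerance (max successive-iterate
#'   difference) of the quasi-steady oxygen solve (default 1e-8).
#' @param picard_max_iter Maximum Picard iterations (default 100).
#' @param record_every Recording interval in hours (default `dt`); must be a
#'   multiple of `dt`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1, t_end = 72, ode_substeps = 10,
                       picard_tol = 1e-8, picard_max_iter = 100,
                       record_every = dt) {
  if (!is.finite(dt) || dt <= 0) stop_invalid_input("'dt' must be > 0")
  if (!is.finite(t_end) || t_end < 0) stop_invalid_input("'t_end' must be >= 0")
  nsteps <- t_end / dt
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    stop_invalid_input("'t_end' must be a multiple of 'dt'")
  }
  if (ode_substeps < 1) stop_invalid_input("'ode_substeps' must be >= 1")
  if (picard_tol <= 0 || picard_max_iter < 1) {
    stop_invalid_input("Picard tolerance and iteration cap must be positive")
  }
  rec <- record_every / dt
  if (abs(rec - round(rec)) > 1e-9 || record_every <= 0) {
    stop_invalid_input("'record_every' must be a positive multiple of 'dt'")
  }
  structure(list(dt = dt, t_end = t_end,
                 ode_substeps = as.integer(ode_substeps),
                 picard_tol = picard_tol,
                 picard_max_iter = as.integer(picard_max_iter),
                 record_every = record_every),
            class = "sim_config")
}

#' Initial simulation state
#'
#' Bundles the t = 0 cell-concentration field with its grid (including the
#' medium mask used as the oxygen Dirichlet anchor).
#'
#' @param alpha `nx` x `ny` matrix of cell concentrations in \[0, 1\];
#'   must be 0 on medium nodes.
#' @param grid A [sim_grid] whose `medium_mask` is set.
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(alpha, grid) {
  if (!inherits(grid, "sim_grid") || is.null(grid$medium_mask)) {
    stop_invalid_input("'grid' must be a sim_grid with a medium_mask")
  }
  if (!is.matrix(alpha) || !identical(dim(alpha), c(grid$nx, grid$ny))) {
    stop_invalid_input("'alpha' must be an nx x ny matrix")
  }
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop_invalid_input("'alpha' must lie in [0, 1]")
  }
  if (any(alpha[grid$medium_mask] != 0)) {
    stop_invalid_input("'alpha' must be 0 on medium nodes")
  }
  structure(list(alpha = alpha, grid = grid), class = "initial_state")
}
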