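#' Viability observation series
#'
#' Timestamped percent-viable observations from one modality: `"RTCA"`
#' (normalized cell index x 100) or `"flow"` (Annexin V/PI viable% +
#' early-apoptotic%, pooled because early-apoptotic cells remain adherent
#' and register as viable on the impedance sensor).
#'
#' @param times Hours from treatment; strictly increasing, >= 0.
#' @param values Percent viable, >= 0.
#' @param modality `"RTCA"` or `"flow"`.
#' @param n_replicates,sd Optional per-point replicate count and SD.
#' @return An object of class `viability_series` (a data frame with
#'   attributes).
#' @export
viability_series <- function(times, values, modality = c("RTCA", "flow"),
                             n_replicates = NULL, sd = NULL) {
  modality <- match.arg(modality)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) == 0L || length(times) != length(values)) {
    stop_invalid_input("'times' and 'values' must be nonempty and equal length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_invalid_input("'times' must be finite and >= 0")
  }
  if (any(diff(times) <= 0)) {
    stop_invalid_input("'times' must be strictly increasing")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_invalid_input("'values' must be finite and >= 0")
  }
  df <- data.frame(time_h = times, viability_pct = values)
  if (!is.null(sd)) df$sd <- as.numeric(sd)
  if (!is.null(n_replicates)) df$n_replicates <- as.integer(n_replicates)
  structure(df, modality = modality,
            class = c("viability_series", "data.frame"))
}

as_series_list <- function(data) {
  if (inherits(data, "viability_series")) return(list(data))
  if (is.list(data) && length(data) &&
      all(vapply(data, inherits, logical(1), "viability_series"))) {
    return(data)
  }
  stop_invalid_input("'data' must be a viability_series or a list of them")
}

#' Sum-of-squares objective
#'
#' The estimation objective: run one simulation under `p` and return
#' \eqn{SE = \sum_i (V_i^e - V_i^s)^2} summed over every point of every
#' supplied series with equal weight, where \eqn{V^e} is the observed and
#' \eqn{V^s} the simulated percent viability. Observation times must
#' coincide with recorded simulation times; no interpolation is performed.
#'
#' @param p A [model_params].
#' @param data A `viability_series` or list of them.
#' @param state0 An [initial_state].
#' @param config A [sim_config].
#' @return Nonnegative scalar.
#' @export
se_objective <- function(p, data, state0, config = sim_config()) {
  data <- as_series_list(data)
  sim <- simulate_viability(state0, p, config, keep_fields = FALSE)
  se_from_sim(sim, data)
}

se_from_sim <- function(sim, data) {
  total <- 0
  for (ser in data) {
    idx <- match_times(ser$time_h, sim$times)
    total <- total + sum((ser$viability_pct - sim$viability[idx])^2)
  }
  total
}

match_times <- function(times, grid_times, tol = 1e-6) {
  idx <- vapply(times, function(t) {
    d <- abs(grid_times - t)
    k <- which.min(d)
    if (d[k] > tol) NA_integer_ else k
  }, integer(1))
  if (any(is.na(idx))) {
    bad <- times[is.na(idx)]
    stop_invalid_input(paste0(
      "observation time(s) not on the simulation time grid (no interpolation): ",
      paste(bad, collapse = ", ")))
  }
  idx
}

#' Optimizer configuration
#'
#' Settings for the two-stage search: stage 1 is a bounded quasi-Newton
#' local solver (`stats::optim`, method `"L-BFGS-B"`) launched from
#' `n_starts` seeded Latin-hypercube points to locate the region of the
#' global minimum; stage 2 refines the incumbent with the Nelder--Mead
#' simplex (box kept by a finite penalty). Ties across starts break on
#' lowest SE, then lexicographically smallest parameter vector.
#'
#' @param n_starts Latin-hypercube multistart count (default 16).
#' @param seed Integer seed for the start design (mandatory for
#'   reproducibility; default 1).
#' @param s_upper,q_upper Upper bounds for the s-parameters (default 50) and
#'   for Q, Q1 (default 20); lower bounds are 0.
#' @param maxit_stage1 L-BFGS-B iteration cap per start (default 200).
#' @param maxit_stage2 Nelder--Mead evaluation cap (default 2000).
#' @param factr_stage1 L-BFGS-B `factr` convergence factor (default 1e4,
#'   i.e. ~2e-12 relative).
#' @param reltol_stage2 Nelder--Mead relative tolerance (default 1e-10).
#' @param starts Optional matrix of explicit stage-1 starting points (one
#'   row per start, columns in the order of the free parameters); replaces
#'   the Latin-hypercube design and overrides `n_starts`.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(n_starts = 16, seed = 1,
                             s_upper = 50, q_upper = 20,
                             maxit_stage1 = 200, maxit_stage2 = 2000,
                             factr_stage1 = 1e4, reltol_stage2 = 1e-10,
                             starts = NULL) {
  if (n_starts < 1) stop_invalid_input("'n_starts' must be >= 1")
  if (is.null(seed) || is.na(seed)) stop_invalid_input("'seed' is mandatory")
  if (!is.null(starts)) {
    starts <- as.matrix(starts)
    n_starts <- nrow(starts)
  }
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 s_upper = s_upper, q_upper = q_upper,
                 maxit_stage1 = as.integer(maxit_stage1),
                 maxit_stage2 = as.integer(maxit_stage2),
                 factr_stage1 = factr_stage1,
                 reltol_stage2 = reltol_stage2,
                 starts = starts),
            class = "optimizer_config")
}

param_bounds <- function(opt, free) {
  ub <- c(s1 = opt$s_upper, s2 = opt$s_upper, s3 = opt$s_upper,
          s4 = opt$s_upper, Q = opt$q_upper, Q1 = opt$q_upper)
  list(lower = stats::setNames(rep(0, length(free)), free),
       upper = ub[free])
}

# Shared two-stage engine. `free` names the parameters being estimated;
# `fixed` is a full model_params supplying the frozen values.
estimate_engine <- function(data, state0, config, opt, free, fixed,
                            control = NULL) {
  data <- as_series_list(data)
  bounds <- param_bounds(opt, free)
  make_params <- function(theta) {
    v <- unclass(fixed)
    v[free] <- as.list(pmin(pmax(theta, bounds$lower), bounds$upper))
    do.call(model_params, v)
  }
  n_eval <- 0L
  fn <- function(theta) {
    n_eval <<- n_eval + 1L
    if (any(!is.finite(theta))) return(1e12)
    # finite penalty outside the box (Nelder-Mead is unconstrained)
    pen <- sum(pmax(0, bounds$lower - theta)^2) +
      sum(pmax(0, theta - bounds$upper)^2)
    val <- tryCatch(
      se_objective(make_params(theta), data, state0, config),
      viabsim_error = function(e) NA_real_)
    if (!is.finite(val)) return(1e12 + 1e6 * pen)
    val + 1e6 * pen
  }

  # stage 1: seeded Latin-hypercube multistart, bounded quasi-Newton
  nfree <- length(free)
  if (!is.null(opt$starts)) {
    if (ncol(opt$starts) != nfree) {
      stop_invalid_input(sprintf("'starts' must have %d columns (free: %s)",
                                 nfree, paste(free, collapse = ",")))
    }
    starts <- opt$starts
  } else {
    starts <- withr::with_seed(opt$seed, lhs::randomLHS(opt$n_starts, nfree))
    starts <- sweep(starts, 2, bounds$upper - bounds$lower, `*`)
    starts <- sweep(starts, 2, bounds$lower, `+`)
  }
  colnames(starts) <- free
  stage1 <- vector("list", opt$n_starts)
  for (k in seq_len(opt$n_starts)) {
    res <- tryCatch(
      stats::optim(starts[k, ], fn, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = opt$maxit_stage1,
                                  factr = opt$factr_stage1)),
      error = function(e) list(par = starts[k, ], value = Inf,
                               convergence = -1L,
                               message = conditionMessage(e)))
    stage1[[k]] <- list(start = starts[k, ], par = res$par,
                        value = res$value,
                        convergence = res$convergence,
                        message = res$message %||% "")
  }
  vals <- vapply(stage1, `[[`, numeric(1), "value")
  if (all(!is.finite(vals))) {
    msgs <- vapply(seq_along(stage1), function(k) {
      sprintf("start %d: %s", k, stage1[[k]]$message)
    }, character(1))
    stop_numerical(paste0("all optimizer starts failed:\n",
                          paste(msgs, collapse = "\n")))
  }
  best_k <- pick_best(stage1)
  incumbent <- stage1[[best_k]]

  # stage 2: Nelder-Mead refinement from the stage-1 incumbent
  nm <- stats::optim(incumbent$par, fn, method = "Nelder-Mead",
                     control = list(maxit = opt$maxit_stage2,
                                    reltol = opt$reltol_stage2))
  if (nm$value <= incumbent$value) {
    final_par <- pmin(pmax(nm$par, bounds$lower), bounds$upper)
    final_se <- fn(final_par)
  } else {
    final_par <- incumbent$par
    final_se <- incumbent$value
  }
  params <- make_params(final_par)

  rel <- NULL
  if (!is.null(control)) {
    control <- as_model_params(control)
    rel <- vapply(free, function(nm_) {
      cv <- control[[nm_]]
      if (cv == 0) NA_real_ else 100 * (params[[nm_]] - cv) / cv
    }, numeric(1))
  }

  structure(list(
    params = params,
    se = final_se,
    free = free,
    frozen = setdiff(param_names(), free),
    frozen_values = unlist(unclass(fixed)[setdiff(param_names(), free)]),
    rel_change_pct = rel,
    stage1 = list(seed = opt$seed, n_starts = opt$n_starts,
                  starts = starts, best_start = best_k,
                  values = vals,
                  convergence = vapply(stage1, `[[`, numeric(1), "convergence")),
    stage2 = list(iterations = nm$counts[["function"]],
                  converged = nm$convergence == 0L,
                  value = nm$value),
    n_eval = n_eval,
    bounds = bounds), class = "estimation_result")
}

pick_best <- function(stage1) {
  vals <- vapply(stage1, `[[`, numeric(1), "value")
  cand <- which(vals == min(vals, na.rm = TRUE))
  if (length(cand) > 1L) {
    # lexicographically smallest parameter vector
    mats <- do.call(rbind, lapply(stage1[cand], `[[`, "par"))
    ord <- do.call(order, as.data.frame(mats))
    cand <- cand[ord[1]]
  }
  cand[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate all six parameters from control-line data
#'
#' Two-stage nonlinear least-squares fit of `s1`--`s4`, `Q`, `Q1` to one or
#' more viability series from an untreated control culture. Oxygen
#' parameters are estimated here only: under aerobic conditions they barely
#' influence viability, so treated cultures inherit the control values (see
#' [estimate_treatment]).
#'
#' @param data A `viability_series` or list of them (RTCA, optionally flow).
#' @param state0 An [initial_state].
#' @param config A [sim_config].
#' @param opt An [optimizer_config].
#' @return An `estimation_result`: fitted [model_params], final `se`,
#'   multistart and simplex diagnostics, bounds.
#' @export
estimate_control <- function(data, state0, config = sim_config(),
                             opt = optimizer_config()) {
  estimate_engine(data, state0, config, opt,
                  free = param_names(), fixed = model_params())
}

#' Estimate growth/death parameters for a treated culture
#'
#' Fits `s1`--`s4` with `Q`, `Q1` frozen at the control estimates, and
#' reports each fitted parameter's relative change against the control fit,
#' `100 * (theta_treat - theta_control) / theta_control` (the quantity the
#' treatment-effect figures are built from).
#'
#' @inheritParams estimate_control
#' @param frozen_q Numeric `c(Q, Q1)` from the control fit.
#' @param control A [model_params] from the control fit (for relative
#'   changes); optional.
#' @return An `estimation_result` with `rel_change_pct` filled in when
#'   `control` is supplied.
#' @export
estimate_treatment <- function(data, state0, config = sim_config(),
                               frozen_q, control = NULL,
                               opt = optimizer_config()) {
  if (missing(frozen_q) || length(frozen_q) != 2L || any(!is.finite(frozen_q))) {
    stop_invalid_input("'frozen_q' must be numeric c(Q, Q1) from a control fit")
  }
  fixed <- model_params(Q = frozen_q[[1]], Q1 = frozen_q[[2]])
  estimate_engine(data, state0, config, opt,
                  free = c("s1", "s2", "s3", "s4"), fixed = fixed,
                  control = control)
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result>\n  params: ")
  cat(sprintf("s1=%.4g s2=%.4g s3=%.4g s4=%.4g Q=%.4g Q1=%.4g\n",
              x$params$s1, x$params$s2, x$params$s3, x$params$s4,
              x$params$Q, x$params$Q1))
  cat(sprintf("  SE = %.6g  (free: %s; frozen: %s)\n", x$se,
              paste(x$free, collapse = ","),
              if (length(x$frozen)) paste(x$frozen, collapse = ",") else "none"))
  if (!is.null(x$rel_change_pct)) {
    cat("  rel change vs control (%):",
        paste(sprintf("%s=%+.1f", names(x$rel_change_pct),
                      x$rel_change_pct), collapse = " "), "\n")
  }
  invisible(x)
}

#' Relative RMS discrepancy between simulated and experimental series
#'
#' Summary error between a simulated and an experimental viability series on
#' matching time points, computed in normalized-cell-index units
#' (viability/100): `100 * RMS(residuals) / mean(experimental NCI)`. This
#' scale-invariant convention is this package's definition of the "SD
#' error" fit summary.
#'
#' @param sim,exp `viability_series` objects on matching time grids.
#' @return A percentage.
#' @export
sd_error <- function(sim, exp) {
  if (!inherits(sim, "viability_series") || !inherits(exp, "viability_series")) {
    stop_invalid_input("'sim' and 'exp' must be viability_series")
  }
  common <- intersect(round(sim$time_h, 6), round(exp$time_h, 6))
  if (length(common) == 0L) stop_invalid_input("series share no time points")
  si <- sim$viability_pct[match(common, round(sim$time_h, 6))] / 100
  ei <- exp$viability_pct[match(common, round(exp$time_h, 6))] / 100
  me <- mean(ei)
  if (me == 0) stop_invalid_input("experimental series has zero mean")
  100 * sqrt(mean((si - ei)^2)) / me
}
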