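# Synthetic-data generator: stands in for the raw RTCA impedance traces,
# Annexin V/PI snapshots and culture images that the estimation pipeline
# consumes, with known ground-truth parameters for recovery studies.

#' Canonical example parameter sets
#'
#' Reference conditions used throughout the examples, tests and vignette:
#' an untreated `"control"` culture (net growth, 72-h viability about 140 %
#' of the treatment-time mass; oxygen-consumption parameters Q = 5.32,
#' Q1 = 4.97, the nondimensional magnitude reported for colorectal-carcinoma
#' control cultures) and a `"treated"` culture whose death terms outweigh
#' growth so viability declines towards 50 % by 72 h (Q, Q1 inherited from
#' the control, as in the estimation protocol).
#'
#' @param case `"control"` or `"treated"`.
#' @return A [model_params].
#' @export
example_params <- function(case = c("control", "treated")) {
  case <- match.arg(case)
  switch(case,
         control = model_params(s1 = 1, s2 = 0.2, s3 = 0.4, s4 = 1,
                                Q = 5.32, Q1 = 4.97),
         treated = model_params(s1 = 1, s2 = 0.4, s3 = 0.35, s4 = 0,
                                Q = 5.32, Q1 = 4.97))
}

#' Synthetic-data configuration
#'
#' @param truth Ground-truth [model_params] used to simulate the data.
#' @param noise_sigma SD of the multiplicative Gaussian noise applied per
#'   RTCA sample (default 0.03, the order of typical impedance replicate
#'   scatter).
#' @param f_early Fraction of model-viable cells reported as early
#'   apoptotic in flow snapshots (default 0.10).
#' @param f_late Fraction of model-non-viable cells reported as late
#'   apoptotic (vs necrotic) (default 0.80; treated cultures here die
#'   predominantly through late apoptosis).
#' @param dirichlet_conc Concentration of the Dirichlet jitter applied to
#'   the four flow fractions (default 200; `Inf` disables jitter).
#' @param seed Integer seed; mandatory for any stochastic call.
#' @param sample_interval_min Raw RTCA sampling interval in minutes
#'   (default 15).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(truth, noise_sigma = 0.03, f_early = 0.10,
                         f_late = 0.80, dirichlet_conc = 200, seed,
                         sample_interval_min = 15) {
  truth <- as_model_params(truth)
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop_invalid_input("'noise_sigma' must be >= 0")
  }
  for (f in c(f_early = f_early, f_late = f_late)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      stop_invalid_input("'f_early' and 'f_late' must lie in [0, 1]")
    }
  }
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_invalid_input("'seed' is mandatory for synthetic data generation")
  }
  if (!(is.infinite(dirichlet_conc) || dirichlet_conc > 0)) {
    stop_invalid_input("'dirichlet_conc' must be > 0 (Inf disables jitter)")
  }
  if (sample_interval_min <= 0) {
    stop_invalid_input("'sample_interval_min' must be > 0")
  }
  structure(list(truth = truth, noise_sigma = noise_sigma,
                 f_early = f_early, f_late = f_late,
                 dirichlet_conc = dirichlet_conc, seed = as.integer(seed),
                 sample_interval_min = sample_interval_min),
            class = "synth_config")
}

#' Times of the RTCA fit points
#'
#' The five post-treatment hours at which RTCA observations enter the
#' estimation objective.
#' @return `c(24, 36, 48, 60, 72)`.
#' @export
rtca_fit_times <- function() c(24, 36, 48, 60, 72)

#' Times of the flow-cytometry fit points
#' @return `c(24, 72)`.
#' @export
flow_fit_times <- function() c(24, 72)

#' Generate a synthetic RTCA trace
#'
#' Simulates the ground-truth parameters and converts the viability curve to
#' a normalized cell index, `NCI(t) = viability(t)/100 * (1 + eps_t)`, with
#' i.i.d. multiplicative Gaussian noise per sample. The t = 0 sample is
#' pinned at exactly 1 (the instrument's normalization convention). The
#' trace is sampled every `sample_interval_min` minutes (values between
#' recorded simulation hours are linearly interpolated); the five-point fit
#' subset reads the same trace at the fit hours, where the sampled values
#' coincide with the exact recorded simulation values.
#'
#' @param state0 An [initial_state].
#' @param config A [sim_config].
#' @param synth A [synth_config].
#' @param raw Also emit a raw impedance trace `R(t) = R_t0 + F * CI(t)`
#'   (F = 15 ohm, CI anchored so NCI(0) = 1; default `FALSE`).
#' @param ci0 Cell index at treatment time used for the raw trace
#'   (default 1).
#' @param r_t0 Baseline resistance in ohm for the raw trace (default 100).
#' @return List with `fit` (a 5-point RTCA [viability_series]), `full`
#'   (`data.frame(time_h, nci)` at the raw sampling interval), `raw`
#'   (`data.frame(time_h, resistance_ohm)` or `NULL`), `truth`, `seed`, and
#'   `sim` (the underlying `viab_sim`).
#' @export
generate_rtca <- function(state0, config = sim_config(), synth,
                          raw = FALSE, ci0 = 1, r_t0 = 100) {
  if (!inherits(synth, "synth_config")) {
    stop_invalid_input("'synth' must be a synth_config")
  }
  sim <- simulate_viability(state0, synth$truth, config, keep_fields = FALSE)
  t_full <- seq(0, config$t_end, by = synth$sample_interval_min / 60)
  v_full <- stats::approx(sim$times, sim$viability, xout = t_full)$y
  fit_t <- rtca_fit_times()
  match_times(fit_t, sim$times)  # fit points must be exact recorded values

  eps <- withr::with_seed(synth$seed,
                          stats::rnorm(length(t_full), 0, synth$noise_sigma))
  nci_full <- v_full / 100 * (1 + eps)
  nci_full[t_full == 0] <- 1
  # the fit subset is the same instrument trace read at the fit hours
  nci_fit <- nci_full[match_times(fit_t, t_full)]

  fit <- viability_series(fit_t, 100 * nci_fit, modality = "RTCA")
  full <- data.frame(time_h = t_full, nci = nci_full)
  raw_df <- NULL
  if (raw) {
    raw_df <- data.frame(time_h = t_full,
                         resistance_ohm = r_t0 + 15 * ci0 * nci_full)
  }
  list(fit = fit, full = full, raw = raw_df,
       truth = synth$truth, seed = synth$seed, sim = sim)
}

#' Four-fraction Annexin V/PI snapshot
#'
#' One flow-cytometry measurement: percentages of viable (Annexin V- PI-),
#' early apoptotic (V+ PI-), late apoptotic (V+ PI+) and necrotic (V- PI+)
#' cells, summing to 100.
#'
#' @param t Hours from treatment.
#' @param viable_pct,early_pct,late_pct,necrosis_pct Percentages in
#'   \[0, 100\] summing to 100 (tolerance 1e-9).
#' @return An object of class `flow_fractions`.
#' @export
flow_fractions <- function(t, viable_pct, early_pct, late_pct, necrosis_pct) {
  v <- c(viable_pct = viable_pct, early_pct = early_pct,
         late_pct = late_pct, necrosis_pct = necrosis_pct)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100)) {
    stop_invalid_input("flow fractions must lie in [0, 100]")
  }
  if (abs(sum(v) - 100) > 1e-9) {
    stop_invalid_input(sprintf("flow fractions must sum to 100 (got %.12g)",
                               sum(v)))
  }
  structure(c(list(t = t), as.list(v)), class = "flow_fractions")
}

#' Pooled viability of a flow snapshot
#'
#' Early-apoptotic cells remain adherent (and enzymatically active), so for
#' comparison against impedance data they are pooled with the viable
#' fraction: pooled viability = viable% + early apoptotic%.
#'
#' @param x A [flow_fractions].
#' @return A percentage.
#' @export
pooled_viability <- function(x) {
  if (!inherits(x, "flow_fractions")) {
    stop_invalid_input("'x' must be a flow_fractions")
  }
  x$viable_pct + x$early_pct
}

#' Generate synthetic flow-cytometry snapshots
#'
#' Simulates the truth, reads the model viability `V(t)` at the requested
#' times, and splits it into the four Annexin V/PI fractions: viable
#' `V (1 - f_early)`, early apoptotic `V f_early`, late apoptotic
#' `(100 - V) f_late`, necrotic `(100 - V)(1 - f_late)`. The four base
#' fractions are then jittered by a Dirichlet draw with concentration
#' `dirichlet_conc * base/100` and rescaled to sum to 100 (`dirichlet_conc
#' = Inf` skips the jitter). The pooled viability series (viable + early) is
#' what the estimation objective consumes.
#'
#' @inheritParams generate_rtca
#' @param times Snapshot times in hours (default `flow_fit_times()`).
#' @return List with `fractions` (list of [flow_fractions]), `series` (the
#'   pooled flow [viability_series]), `truth`, `seed`.
#' @export
generate_flow <- function(state0, config = sim_config(), synth,
                          times = flow_fit_times()) {
  if (!inherits(synth, "synth_config")) {
    stop_invalid_input("'synth' must be a synth_config")
  }
  sim <- simulate_viability(state0, synth$truth, config, keep_fields = FALSE)
  idx <- match_times(times, sim$times)
  v <- sim$viability[idx]
  if (any(v < 0 | v > 100)) {
    stop_invalid_input(
      "model viability outside [0, 100]: flow fractions undefined (growing culture)")
  }
  base <- lapply(v, function(vi) {
    c(viable = vi * (1 - synth$f_early),
      early = vi * synth$f_early,
      late = (100 - vi) * synth$f_late,
      necro = (100 - vi) * (1 - synth$f_late))
  })
  jittered <- withr::with_seed(synth$seed + 1L, lapply(base, function(fr) {
    if (is.infinite(synth$dirichlet_conc)) return(fr)
    shape <- synth$dirichlet_conc * fr / 100
    g <- stats::rgamma(4, shape = shape)  # shape 0 -> exact 0
    if (sum(g) == 0) return(fr)
    100 * g / sum(g)
  }))
  fractions <- lapply(seq_along(times), function(k) {
    fr <- jittered[[k]]
    flow_fractions(times[k], fr[[1]], fr[[2]], fr[[3]], fr[[4]])
  })
  pooled <- vapply(fractions, pooled_viability, numeric(1))
  list(fractions = fractions,
       series = viability_series(times, pooled, modality = "flow"),
       truth = synth$truth, seed = synth$seed)
}

#' Generate a synthetic culture image
#'
#' Stand-in for a phase-contrast image of an adherent culture: a sum of
#' Gaussian intensity blobs at seeded random centers, normalized to
#' \[0, 1\] and quantized to 8 bits. Deterministic per seed.
#'
#' @param width,height Pixel dimensions (>= 16).
#' @param n_blobs Number of blobs (>= 1).
#' @param seed Integer seed.
#' @param sigma_range Blob SD range as a fraction of the smaller image
#'   dimension (default `c(0.04, 0.12)`).
#' @return A `height` x `width` intensity matrix in \[0, 1\] (256 levels).
#' @export
generate_blob_image <- function(width = 128, height = 128, n_blobs = 8,
                                seed, sigma_range = c(0.04, 0.12)) {
  if (width < 16 || height < 16) stop_invalid_input("dimensions must be >= 16")
  if (n_blobs < 1) stop_invalid_input("'n_blobs' must be >= 1")
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_invalid_input("'seed' is mandatory")
  }
  s <- min(width, height)
  pars <- withr::with_seed(seed, data.frame(
    cx = stats::runif(n_blobs, 0.1, 0.9) * width,
    cy = stats::runif(n_blobs, 0.1, 0.9) * height,
    sd = stats::runif(n_blobs, sigma_range[1], sigma_range[2]) * s,
    amp = stats::runif(n_blobs, 0.6, 1)))
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  img <- matrix(0, height, width)
  for (k in seq_len(n_blobs)) {
    img <- img + pars$amp[k] *
      exp(-((xs - pars$cx[k])^2 + (ys - pars$cy[k])^2) / (2 * pars$sd[k]^2))
  }
  img <- img - min(img)
  if (max(img) > 0) img <- img / max(img)
  round(img * 255) / 255
}
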