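# Shared fixtures, built once per test run and memoised.

.fix_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- force(expr)
  .fix_env[[name]]
}

blob64 <- function() fixture("blob64", generate_blob_image(64, 64, 6, seed = 1))

# initial states on the shared blob image at several resolutions
state_at <- function(n) {
  fixture(paste0("state", n),
          image_to_alpha0(blob64(), sim_grid(n, n)))
}

# control: net growth; treated: net death (viability declines below 100 %,
# so flow fractions are well defined). *_q0 variants zero the oxygen
# consumption for the constant-oxygen protocols.
p_control <- function() example_params("control")
p_treated <- function() example_params("treated")
p_control_q0 <- function() model_params(s1 = 1, s2 = 0.2, s3 = 0.4, s4 = 1)
p_treated_q0 <- function() model_params(s1 = 1, s2 = 0.4, s3 = 0.35, s4 = 0)

# a fast optimizer budget for mechanics-level tests (not recovery claims)
opt_fast <- function(seed = 1, ...) {
  optimizer_config(n_starts = 4, seed = seed, maxit_stage1 = 60,
                   maxit_stage2 = 400, ...)
}

# run a cmd_* function and map conditions to CLI exit codes (as cli_main does)
cli_main_status <- function(fn, cfg, ...) {
  tryCatch({ fn(cfg, ...); 0L },
           viabsim_invalid_input = function(e) 2L,
           error = function(e) 1L)
}

# noiseless synthetic dataset (RTCA fit points + pooled flow) for a truth
noiseless_data <- function(truth, state0, config = sim_config(), seed = 11) {
  sc <- synth_config(truth, noise_sigma = 0, dirichlet_conc = Inf, seed = seed)
  rt <- generate_rtca(state0, config, sc)
  fl <- generate_flow(state0, config, sc)
  list(rtca = rt$fit, flow = fl$series, sim = rt$sim)
}
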