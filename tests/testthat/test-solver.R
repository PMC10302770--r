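test_that("image-based initialization classifies cell and medium nodes", {
  # white disk on black with a fixed threshold: binary geometry
  n <- 41
  img <- matrix(0, n, n)
  cx <- (col(img) - (n + 1) / 2) / n; cy <- (row(img) - (n + 1) / 2) / n
  img[cx^2 + cy^2 < 0.09] <- 1
  g <- sim_grid(21, 21)
  st <- image_to_alpha0(img, g, alpha_seed = 0.7, threshold = 0.5)
  inside <- (g$x[row(st$alpha)] - 0.5)^2 + (g$y[col(st$alpha)] - 0.5)^2 < 0.07
  expect_true(all(st$alpha[inside] == 0.7))
  expect_true(all(st$alpha[!st$grid$medium_mask] == 0.7))
  expect_true(all(st$alpha[st$grid$medium_mask] == 0))

  # Otsu on the bimodal blob fixture: cell-node count equals the
  # brute-force count of resampled intensities above the chosen threshold
  st2 <- image_to_alpha0(blob64(), sim_grid(30, 30))
  thr <- attr(st2, "threshold")
  sampled <- viabsim:::resample_to_grid(blob64(), sim_grid(30, 30))
  expect_identical(sum(!st2$grid$medium_mask), sum(sampled > thr))
  expect_gt(sum(st2$grid$medium_mask), 0)

  # constant image: threshold undefined without an explicit one
  expect_error(image_to_alpha0(matrix(0.5, 32, 32), sim_grid(10, 10)),
               "threshold")
  flat <- image_to_alpha0(matrix(0, 32, 32), sim_grid(10, 10), threshold = 0.5)
  expect_true(all(flat$grid$medium_mask))
})

test_that("oxygen solve reduces to C == 1 without consumption", {
  st <- state_at(15)
  g <- st$grid
  expect_identical(solve_oxygen(matrix(0, 15, 15), g, p_control(), sim_config()),
                   structure(matrix(1, 15, 15), iterations = 0L))
  c2 <- solve_oxygen(st$alpha, g, model_params(Q = 0, Q1 = 3), sim_config())
  expect_true(all(c2 == 1))
})

test_that("oxygen solve matches the 1-D linear closed form", {
  # uniform alpha = 1, Q1 = 0, strip with medium at both x ends:
  # C(x) = cosh(sqrt(Q) (x - 1/2)) / cosh(sqrt(Q) / 2)
  nx <- 101
  mask <- matrix(FALSE, nx, 3); mask[c(1, nx), ] <- TRUE
  g <- sim_grid(nx, 3, medium_mask = mask)
  for (Q in c(1, 5.32)) {
    C <- solve_oxygen(matrix(1, nx, 3), g, model_params(Q = Q),
                      sim_config())
    exact <- cosh(sqrt(Q) * (g$x - 0.5)) / cosh(sqrt(Q) / 2)
    expect_lt(max(abs(C[, 2] - exact)), 1e-3)
    expect_true(all(C >= 0 & C <= 1))
  }
})

test_that("oxygen solve agrees with a dense Newton solve of the nonlinear system", {
  # independent oracle: assemble the same 5-point/reflection equations and
  # solve the full nonlinear system by damped Newton with a numerical
  # Jacobian and dense base-R linear algebra
  n <- 11
  st <- image_to_alpha0(blob64(), sim_grid(n, n))
  g <- st$grid
  p <- model_params(Q = 5.32, Q1 = 4.97)
  C <- solve_oxygen(st$alpha, g, p, sim_config())

  maskv <- as.vector(g$medium_mask)
  av <- as.vector(st$alpha)
  ih2 <- (n - 1)^2
  residual <- function(cv) {
    M <- matrix(cv, n, n)
    r <- numeric(n * n)
    for (j in 1:n) for (i in 1:n) {
      k <- (j - 1) * n + i
      if (maskv[k]) { r[k] <- cv[k] - 1; next }
      e <- if (i < n) M[i + 1, j] else M[i - 1, j]
      w <- if (i > 1) M[i - 1, j] else M[i + 1, j]
      no <- if (j < n) M[i, j + 1] else M[i, j - 1]
      so <- if (j > 1) M[i, j - 1] else M[i, j + 1]
      r[k] <- ih2 * (e + w + no + so - 4 * cv[k]) -
        p$Q * av[k] * cv[k] / (1 + p$Q1 * cv[k])
    }
    r
  }
  cv <- rep(1, n * n)
  for (it in 1:30) {
    r0 <- residual(cv)
    if (max(abs(r0)) < 1e-12) break
    J <- matrix(0, n * n, n * n)
    h <- 1e-7
    for (k in seq_len(n * n)) {
      cp <- cv; cp[k] <- cp[k] + h
      J[, k] <- (residual(cp) - r0) / h
    }
    cv <- cv - solve(J, r0)
  }
  expect_lt(max(abs(as.vector(C) - cv)), 1e-6)
})

test_that("oxygen solve reports non-convergence with the last residual", {
  st <- state_at(15)
  cfg <- sim_config(picard_max_iter = 1, picard_tol = 1e-14)
  expect_error(solve_oxygen(st$alpha, st$grid, p_control(), cfg),
               "did not converge")
})

test_that("concentration step matches the constant-oxygen closed form", {
  g <- sim_grid(5, 5, medium_mask = matrix(rep(c(TRUE, rep(FALSE, 4)), 5), 5))
  cfg <- sim_config()
  ones <- matrix(1, 5, 5)

  # fixed point at alpha = 0
  z <- matrix(0, 5, 5)
  expect_identical(step_alpha(z, ones, model_params(s1 = 2, s2 = 1), cfg), z)

  # pure logistic vs closed form over one hour
  a <- matrix(0.5, 5, 5)
  stepped <- step_alpha(a, ones, model_params(), cfg)
  expect_equal(stepped[1, 1], closed_form_alpha(0.5, 1, model_params(), 1),
               tolerance = 1e-6)

  # pure death at carrying capacity strictly decreases
  one <- matrix(1, 5, 5)
  out <- step_alpha(one, ones, model_params(s2 = 0.2), cfg)
  expect_true(all(out < 1))

  # violent stiffness is reported as an instability, not silently clamped
  expect_error(step_alpha(one, ones, model_params(s2 = 45, s3 = 45),
                          sim_config(ode_substeps = 1)),
               "ode_substeps")
})

test_that("viability reduction is 100 at reference, linear, and guarded", {
  st <- state_at(15)
  g <- st$grid
  expect_equal(viability_percent(st$alpha, st$alpha, g), 100)
  expect_equal(viability_percent(0.5 * st$alpha, st$alpha, g), 50)
  expect_error(viability_percent(st$alpha, matrix(0, 15, 15), g), "zero mass")
})

test_that("simulation holds fixed points and pure-death decay bounds", {
  st <- state_at(15)
  # p = 0 with alpha0 = 1 on cell nodes: exact fixed point, 100 % forever
  a1 <- matrix(0, 15, 15); a1[!st$grid$medium_mask] <- 1
  st1 <- initial_state(a1, st$grid)
  sim0 <- simulate_viability(st1, model_params(), sim_config())
  expect_true(all(sim0$viability == 100))

  # strong death: monotone decay, < 1 % by 72 h (e^{-s2 t} envelope)
  simd <- simulate_viability(st, model_params(s2 = 10), sim_config())
  expect_true(all(diff(simd$viability) <= 0))
  expect_lt(simd$viability[length(simd$viability)], 1)
})

test_that("simulation with Q = 0 reproduces the per-node closed form", {
  st <- state_at(30)
  p <- p_control_q0()
  sim <- simulate_viability(st, p, sim_config())
  cells <- !st$grid$medium_mask
  for (k in c(2, 25, 49, 73)) {
    t <- sim$times[k]
    exact <- closed_form_alpha(0.5, 1, p, t)
    expect_lt(max(abs(sim$states[[k]]$alpha[cells] - exact)), 1e-4)
    expect_true(all(sim$states[[k]]$c == 1))
  }
  expect_lt(max(abs(sim$viability -
                      100 * closed_form_alpha(0.5, 1, p, sim$times) / 0.5)),
            1e-4)
})

test_that("compressed and full solver paths agree at Q = 0", {
  # force the full Picard path with an infinitesimal Q and compare
  st <- state_at(11)
  cfg <- sim_config(t_end = 24)
  sim_c <- simulate_viability(st, p_treated_q0(), cfg)
  p_eps <- model_params(s1 = 1, s2 = 0.4, s3 = 0.35, s4 = 0, Q = 1e-10)
  sim_f <- simulate_viability(st, p_eps, cfg)
  expect_equal(sim_f$viability, sim_c$viability, tolerance = 1e-7)
})

test_that("72-h viability is stable under grid refinement", {
  p <- p_control()
  v <- vapply(c(50, 100), function(n) {
    st <- image_to_alpha0(blob64(), sim_grid(n, n))
    sim <- simulate_viability(st, p, sim_config(), keep_fields = FALSE)
    sim$viability[length(sim$viability)]
  }, numeric(1))
  expect_lt(abs(v[2] - v[1]), 0.5)
})

test_that("PGM images round-trip and PNG reads as grayscale", {
  img <- generate_blob_image(32, 24, 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- read_gray_image(path)
  expect_equal(dim(back), c(24, 32))
  expect_equal(back, img, tolerance = 1e-9)  # 8-bit quantized on both sides

  pngf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, pngf)
  frompng <- read_gray_image(pngf)
  expect_equal(frompng, img, tolerance = 1 / 255)
})
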