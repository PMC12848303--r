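# VerletMD against the closed-form harmonic oscillator and an independent
# velocity-Verlet reference; GNN-MD residual contracts; DenoisingLD
# counts, degeneracy and Gaussian-target convergence.

reference_verlet <- function(force_fn, x, v, h, n_steps, masses = 1) {
  a <- force_fn(x) / masses
  out <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    x <- x + v * h + 0.5 * a * h^2
    a_new <- force_fn(x) / masses
    v <- v + 0.5 * (a + a_new) * h
    a <- a_new
    out[[k]] <- list(x = x, v = v)
  }
  out
}

test_that("velocity Verlet conserves energy on the harmonic oscillator", {
  force_fn <- function(x) -x     # E = x^2/2, k = m = 1
  st0 <- list(x = matrix(c(1, 0, 0), 1), v = matrix(0, 1, 3))
  n <- ceiling(2 * pi / 0.01)
  tr <- verlet_md_rollout(list(force = force_fn), NULL, st0, n,
                          baseline_config("verlet_md",
                                          steps_per_snapshot = 1L),
                          snapshot_interval = 0.01)
  energy <- 0.5 * tr$coords[, 1, 1]^2 + 0.5 * tr$velocities[, 1, 1]^2 +
    0.5 * rowSums(tr$coords[, 1, 2:3]^2) + 0.5 * rowSums(tr$velocities[, 1, 2:3]^2)
  expect_lt(max(abs(energy - 0.5)) / 0.5, 1e-3)
  # and the endpoint returns near the start after one period
  expect_equal(tr$coords[n, 1, 1], cos(n * 0.01), tolerance = 1e-3)
})

test_that("verlet_md_rollout matches an independent reference step for step", {
  set.seed(17)
  W <- matrix(rnorm(9, sd = 0.3), 3, 3)
  force_fn <- function(x) x %*% W - 0.1 * x   # arbitrary smooth field
  x0 <- matrix(rnorm(12), 4, 3); v0 <- matrix(rnorm(12, sd = 0.3), 4, 3)
  masses <- c(1, 2, 1.5, 1)
  tr <- verlet_md_rollout(list(force = force_fn), NULL,
                          list(x = x0, v = v0), 6,
                          baseline_config("verlet_md",
                                          steps_per_snapshot = 3L),
                          masses = masses, snapshot_interval = 0.3)
  ref <- reference_verlet(force_fn, x0, v0, 0.1, 18, masses)
  for (s in 1:6) {
    expect_equal(snapshot(tr, s), ref[[s * 3]]$x, tolerance = 1e-12)
    expect_equal(matrix(tr$velocities[s, , ], ncol = 3), ref[[s * 3]]$v,
                 tolerance = 1e-12)
  }
})

test_that("zero force gives uniform linear motion under Verlet", {
  st0 <- list(x = matrix(0, 2, 3), v = matrix(c(1, 1, 0, 0, 0, 0), 2))
  tr <- verlet_md_rollout(function(x) x * 0, NULL, st0, 4,
                          baseline_config("verlet_md"))
  expect_equal(snapshot(tr, 4), st0$v * 4)
})

test_that("GNN-MD is a stateless residual step", {
  sys <- tiny_system()
  m <- tiny_model(seed = 2L)
  # zero displacement head: all message gates zeroed => identity step
  mz <- tiny_model(seed = 2L)
  for (nm in grep("(lig_l\\d+_W2|lig_l\\d+_b2|cpx_W2|cpx_b2)",
                  names(mz$params), value = TRUE)) {
    mz$params[[nm]][] <- 0
  }
  X <- sys$complex$ligand$coords
  expect_equal(gnn_md_step(mz, sys$complex, X), X)
  # k nested steps equal the rollout
  x1 <- gnn_md_step(m, sys$complex, X)
  x2 <- gnn_md_step(m, sys$complex, x1)
  x3 <- gnn_md_step(m, sys$complex, x2)
  ro <- gnn_md_rollout(m, sys$complex, X, 3)
  expect_identical(snapshot(ro, 3), x3)
  # displacement is rotation equivariant
  set.seed(60)
  R <- rand_rotation()
  cx <- binding_complex(ligand(sys$complex$ligand$atomic_numbers,
                               rotate_rows(X, R)),
                        rigid_protein(sys$complex$protein, R, c(0, 0, 0)),
                        sys$complex$cutoff_c)
  d0 <- gnn_md_step(m, sys$complex, X) - X
  d1 <- gnn_md_step(m, cx, rotate_rows(X, R)) - rotate_rows(X, R)
  expect_equal(d1, d0 %*% t(R), tolerance = 1e-5)
})

test_that("DenoisingLD runs exactly 10 score evaluations per snapshot and degenerates cleanly", {
  sys <- tiny_system()
  m <- tiny_model(seed = 3L)
  m$n_score_evals <- 0L
  X <- sys$complex$ligand$coords
  cfg <- baseline_config("denoising_ld", seed = 1L)
  expect_equal(cfg$steps_per_snapshot, 10L)
  invisible(denoising_ld_rollout(m, sys$complex, X, 3, cfg))
  expect_equal(m$n_score_evals, 30L)
  # zero score, zero noise: coordinates unchanged
  zero_cfg <- baseline_config("denoising_ld", seed = 1L, eta_scale = 0)
  out <- denoising_ld_step(function(x, sigma) x * 0, NULL, X, zero_cfg)
  expect_equal(out, X)
})

test_that("annealed Langevin with an analytic Gaussian score matches the closed-form mean recursion", {
  # noise-smoothed Gaussian target: score(x) = (mu - x) / (tau^2 + sigma^2)
  mu <- 1.2; tau <- 0.4
  score <- function(x, sigma) (mu - x) / (tau^2 + sigma^2)
  cfg <- baseline_config("denoising_ld", steps_per_snapshot = 10L,
                         sigma_max = 1, sigma_min = 0.01, eta_scale = 0.3)
  # the update is linear in x, so the mean obeys a deterministic recursion
  sigmas <- neuralmd:::denoising_sigmas(cfg)
  expected <- 0
  for (sg in sigmas) {
    eta <- cfg$eta_scale * sg^2
    expected <- expected + eta * (mu - expected) / (tau^2 + sg^2)
  }
  expect_lt(abs(expected - mu), abs(0 - mu))  # annealing moves toward mu
  finals <- vapply(1:500, function(s) {
    rng <- neuralmd:::local_rng(s)
    denoising_ld_step(score, NULL, matrix(0, 1, 3), cfg, rng = rng)[1, 1]
  }, numeric(1L))
  expect_lt(abs(mean(finals) - expected),
            5 * stats::sd(finals) / sqrt(500))
})

test_that("all baselines share the same BindingNet parameter set", {
  cfg <- bindingnet_config(hidden_dim = 8L, n_message_layers = 2L, seed = 0L)
  nms <- lapply(1:3, function(i) names(bindingnet(cfg)$params))
  expect_identical(nms[[1]], nms[[2]])
  expect_identical(nms[[2]], nms[[3]])
})
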