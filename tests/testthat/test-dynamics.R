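# Integrator oracles: free motion, the harmonic oscillator closed form,
# first-order convergence, SDE degeneracy/determinism/diffusion, losses,
# and gradients through the rollout.

test_that("augmented derivative is [v; F/m]", {
  st <- list(x = matrix(c(1, 0, 0), 1), v = matrix(0, 1, 3))
  d <- augmented_derivative(st, matrix(c(-1, 0, 0), 1), 1)
  expect_equal(d$dx, matrix(0, 1, 3))
  expect_equal(d$dv, matrix(c(-1, 0, 0), 1))
  d2 <- augmented_derivative(st, matrix(c(-1, 0, 0), 1), 2)
  expect_equal(d2$dv, matrix(c(-0.5, 0, 0), 1))
  d3 <- augmented_derivative(list(x = st$x, v = matrix(1, 1, 3)),
                             matrix(0, 1, 3), 1)
  expect_equal(d3$dx, matrix(1, 1, 3))
  expect_equal(d3$dv, matrix(0, 1, 3))
})

test_that("zero force gives exact free motion per snapshot", {
  for (sps in c(1L, 2L, 4L)) {
    tr <- integrate_ode(function(x) x * 0, NULL,
                        list(x = matrix(0, 3, 3),
                             v = matrix(rep(c(1, 0, 0), each = 3), 3)),
                        3, dynamics_config(steps_per_snapshot = sps))
    for (s in 1:3) {
      expect_equal(snapshot(tr, s),
                   matrix(rep(c(s, 0, 0), each = 3), 3))
    }
  }
})

test_that("Euler converges to cos(t) at first order on the harmonic oscillator", {
  # m = k = 1, x0 = 1, v0 = 0; exact x(t) = cos(t)
  errs <- vapply(c(2L, 4L, 8L), function(sps) {
    tr <- integrate_ode(function(x) -x, NULL,
                        list(x = matrix(c(1, 0, 0), 1),
                             v = matrix(0, 1, 3)),
                        4, dynamics_config(steps_per_snapshot = sps),
                        snapshot_interval = 0.25)
    max(abs(tr$coords[, 1, 1] - cos(0.25 * (1:4))))
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
  ratio <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratio > 1.7 & ratio < 2.3))
})

test_that("NeuralMD performs exactly steps_per_snapshot force evaluations per snapshot", {
  sys <- tiny_system()
  m <- tiny_model()
  m$n_force_evals <- 0L
  invisible(integrate_ode(m, sys$complex,
                          list(x = sys$complex$ligand$coords,
                               v = matrix(0, 8, 3)),
                          5, dynamics_config(steps_per_snapshot = 2L)))
  expect_equal(m$n_force_evals, 10L)   # 2 per snapshot, 5 snapshots
})

test_that("velocity initialization modes behave as specified", {
  x1 <- matrix(c(1, 0, 0), 1); x0 <- matrix(0, 1, 3)
  expect_equal(init_velocity(x1, x0), matrix(c(1, 0, 0), 1))
  expect_equal(init_velocity(x0, x0), matrix(0, 1, 3))
  lig <- ligand(c(6L, 6L), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  m <- tiny_model()
  m$params$head_W2[] <- 0; m$params$head_b2[] <- 0
  # uniform displacements: degenerate edge frames are skipped with a warning
  expect_warning(
    v <- init_velocity(lig$coords + 0.1, lig$coords, lig,
                       mode = "learned_mapping", model = m),
    "degenerate")
  expect_equal(v, matrix(0, 2, 3))
})

test_that("trajectory loss equals the MAE metric and its oracle", {
  set.seed(12)
  p <- array(rnorm(18), c(3, 2, 3)); t <- array(rnorm(18), c(3, 2, 3))
  tp <- trajectory(p); tt <- trajectory(t)
  expect_equal(trajectory_loss(tp, tp), 0)
  off <- p; off[, , 1] <- off[, , 1] + 1
  expect_equal(trajectory_loss(trajectory(off), tp), 1.0)
  expect_identical(trajectory_loss(tp, tt), mae(tp, tt))
  expect_error(trajectory_loss(tp, trajectory(array(0, c(2, 2, 3)))),
               class = "shape_mismatch")
})

test_that("SDE with zero noise equals the ODE bit for bit; same seed reproduces", {
  sys <- tiny_system()
  m <- tiny_model(seed = 2L)
  noise <- tiny_model(seed = 3L)
  noise$params$head_W2[] <- 0; noise$params$head_b2[] <- 0
  st0 <- list(x = sys$complex$ligand$coords, v = matrix(0.05, 8, 3))
  cfg <- dynamics_config(seed = 5L)
  ode <- integrate_ode(m, sys$complex, st0, 4, cfg)
  sde0 <- integrate_sde(m, noise, sys$complex, st0, 4, cfg)
  expect_identical(sde0$coords, ode$coords)

  noisy <- tiny_model(seed = 3L)   # head not zeroed: real noise
  s1 <- integrate_sde(m, noisy, sys$complex, st0, 4, cfg)
  s2 <- integrate_sde(m, noisy, sys$complex, st0, 4, cfg)
  expect_identical(s1$coords, s2$coords)
  s3 <- integrate_sde(m, noisy, sys$complex, st0, 4,
                      dynamics_config(seed = 6L))
  expect_gt(max(abs(s3$coords - s1$coords)), 0)
})

test_that("displacement variance grows linearly in time under pure noise", {
  # zero mean force, constant amplitude sigma: x(t) variance ~ sigma^2 t^3/3?
  # with velocity diffusion: Var[v_t] = sigma^2 t, standard Brownian growth.
  sigma <- 0.3
  n_seeds <- 400L
  vT <- matrix(NA_real_, n_seeds, 2L)
  for (s in seq_len(n_seeds)) {
    tr <- integrate_sde(function(x) x * 0,
                        function(x) matrix(sigma, 1, 3), NULL,
                        list(x = matrix(0, 1, 3), v = matrix(0, 1, 3)),
                        4, dynamics_config(seed = s))
    vT[s, ] <- c(tr$velocities[2, 1, 1], tr$velocities[4, 1, 1])
  }
  v2 <- apply(vT, 2, var)
  expect_lt(abs(v2[1] - sigma^2 * 2), 0.25 * sigma^2 * 2)
  expect_lt(abs(v2[2] - sigma^2 * 4), 0.25 * sigma^2 * 4)
  expect_lt(abs(v2[2] / v2[1] - 2), 0.5)
})

test_that("gradients through the integrator match finite differences", {
  sys <- tiny_system()
  lig2 <- ligand(c(6L, 6L), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  cx <- binding_complex(lig2, sys$complex$protein, 5)
  coords <- array(0, c(3, 2, 3))
  coords[1, , ] <- lig2$coords
  coords[2, , ] <- lig2$coords + 0.05
  coords[3, , ] <- lig2$coords + 0.12
  tr <- trajectory(coords)
  m <- tiny_model(seed = 11L, hidden = 4L, layers = 1L)
  segs <- list(list(t0 = 2L, len = 1L))
  cfg <- dynamics_config(alpha = 1)
  # a 2-atom ligand has exactly anti-parallel centered positions, so the
  # pair-frame edges are degenerate by construction (warned once)
  lg <- suppressWarnings(neuralmd:::neuralmd_loss_grads(m, cx, tr, segs, cfg))
  h <- 1e-5
  set.seed(44)
  for (rep in 1:8) {
    nm <- sample(names(m$params), 1)
    idx <- sample(length(m$params[[nm]]), 1)
    orig <- m$params[[nm]][idx]
    m$params[[nm]][idx] <- orig + h
    lp <- neuralmd:::neuralmd_loss_grads(m, cx, tr, segs, cfg)$loss
    m$params[[nm]][idx] <- orig - h
    lm <- neuralmd:::neuralmd_loss_grads(m, cx, tr, segs, cfg)$loss
    m$params[[nm]][idx] <- orig
    fd <- (lp - lm) / (2 * h)
    an <- lg$grads[[nm]][idx]
    expect_equal(an, fd, tolerance = max(1e-3 * max(abs(fd), abs(an)), 1e-7))
  }
})

test_that("training reduces the loss on a short toy trajectory", {
  sys <- tiny_system(n_snaps = 12L)
  m <- tiny_model(seed = 1L)
  res <- train_neuralmd(m, sys$complex, sys$trajectory,
                        dynamics_config(), epochs = 15L, lr = 3e-3,
                        segment_len = 4L)
  expect_lt(min(res$history$loss), res$history$loss[1])
  expect_equal(nrow(res$history), 15L)
})

test_that("rollout equivariance: rotating the system rotates every snapshot", {
  sys <- tiny_system()
  m <- tiny_model(seed = 8L)
  st0 <- list(x = sys$complex$ligand$coords, v = matrix(0.1, 8, 3))
  base <- integrate_ode(m, sys$complex, st0, 10, dynamics_config())
  set.seed(50)
  R <- rand_rotation(); tr <- rnorm(3, sd = 3)
  cx <- binding_complex(
    ligand(sys$complex$ligand$atomic_numbers, apply_rigid(st0$x, R, tr)),
    rigid_protein(sys$complex$protein, R, tr), sys$complex$cutoff_c)
  rot <- integrate_ode(m, cx, list(x = apply_rigid(st0$x, R, tr),
                                   v = rotate_rows(st0$v, R)),
                       10, dynamics_config())
  for (s in c(1L, 5L, 10L)) {
    expect_equal(snapshot(rot, s), apply_rigid(snapshot(base, s), R, tr),
                 tolerance = 1e-4)
  }
})
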