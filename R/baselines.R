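# Machine-learned dynamics baselines sharing the BindingNet backbone:
#   VerletMD    - force-field surrogate + velocity Verlet integration;
#   GNN-MD      - auto-regressive next-snapshot displacement prediction;
#   DenoisingLD - denoising score matching, annealed Langevin inference.
# Only the rollout logic and training signal differ between methods; the
# encoder parameters are the same set for all of them.

#' Baseline configuration
#'
#' @param kind `"verlet_md"`, `"gnn_md"` or `"denoising_ld"`.
#' @param steps_per_snapshot inner integration steps per emitted snapshot
#'   (VerletMD default 2, mirroring the neural ODE's 0.5-snapshot step;
#'   DenoisingLD default 10 annealed Langevin steps).
#' @param sigma_max,sigma_min geometric noise schedule endpoints for
#'   DenoisingLD, Angstrom (defaults 1.0 and 0.01).
#' @param eta_scale Langevin step-size factor: `eta_i = eta_scale *
#'   sigma_i^2` (default 0.05).
#' @param seed RNG seed for the Langevin noise.
#' @return a `baseline_config` list.
#' @export
baseline_config <- function(kind = c("verlet_md", "gnn_md", "denoising_ld"),
                            steps_per_snapshot = NULL, sigma_max = 1.0,
                            sigma_min = 0.01, eta_scale = 0.05, seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(steps_per_snapshot)) {
    steps_per_snapshot <- if (kind == "denoising_ld") 10L else 2L
  }
  structure(list(kind = kind,
                 steps_per_snapshot = as.integer(steps_per_snapshot),
                 sigma_max = sigma_max, sigma_min = sigma_min,
                 eta_scale = eta_scale, seed = as.integer(seed)),
            class = "baseline_config")
}

#' Velocity-Verlet rollout (VerletMD)
#'
#' Standard velocity Verlet, `x <- x + v h + a h^2 / 2`;
#' `v <- v + (a + a') h / 2`, with forces from either an analytic model
#' (a list with `$force(coords)` and optionally `$energy(coords)`) or a
#' [bindingnet()] force field, emitting states at snapshot boundaries.
#'
#' @param energy_model force provider: a `bindingnet_model`, a function
#'   `coords -> forces`, or a list with `$force` (and `$energy`).
#' @param complex a [binding_complex()] (`NULL` for analytic models).
#' @param state0 list with `x`, `v` matrices.
#' @param n_snaps snapshots to emit.
#' @param config a [baseline_config()] (uses `steps_per_snapshot`).
#' @param masses per-atom masses (default 1).
#' @param snapshot_interval snapshot spacing (default 1).
#' @return an `md_trajectory` with velocities.
#' @export
verlet_md_rollout <- function(energy_model, complex, state0, n_snaps,
                              config = baseline_config("verlet_md"),
                              masses = NULL, snapshot_interval = 1.0) {
  x <- as.matrix(state0$x); v <- as.matrix(state0$v)
  nl <- nrow(x)
  if (is.null(masses)) masses <- rep(1, nl)
  force_fn <- baseline_force_fn(energy_model, complex)
  h <- snapshot_interval / config$steps_per_snapshot
  a <- force_fn(x) / masses
  coords <- array(NA_real_, c(n_snaps, nl, 3L))
  vels <- array(NA_real_, c(n_snaps, nl, 3L))
  for (s in seq_len(n_snaps)) {
    for (k in seq_len(config$steps_per_snapshot)) {
      x <- x + v * h + 0.5 * a * h^2
      a_new <- force_fn(x) / masses
      v <- v + 0.5 * (a + a_new) * h
      a <- a_new
      if (!all(is.finite(x))) {
        stop_neuralmd("Verlet rollout diverged", "non_finite_state")
      }
    }
    coords[s, , ] <- x
    vels[s, , ] <- v
  }
  trajectory(coords, velocities = vels, snapshot_interval = snapshot_interval)
}

baseline_force_fn <- function(energy_model, complex) {
  if (is.function(energy_model)) return(energy_model)
  if (is.list(energy_model) && !inherits(energy_model, "bindingnet_model")) {
    stopifnot(is.function(energy_model$force))
    return(energy_model$force)
  }
  function(x) binding_force(energy_model, complex, x)
}

#' One auto-regressive step of GNN-MD
#'
#' The network's per-atom output vector is read as the displacement to
#' the next snapshot: `x_{t+1} = x_t + BindingNet(x_t)`. The residual
#' (displacement) parameterization keeps the step translation
#' equivariant. The rollout is stateless: k steps are k nested calls.
#'
#' @param position_model a [bindingnet()].
#' @param complex a [binding_complex()].
#' @param coords_t `N_l x 3` coordinates at time t.
#' @return `N_l x 3` coordinates at time t+1.
#' @export
gnn_md_step <- function(position_model, complex, coords_t) {
  out <- coords_t + binding_force(position_model, complex, coords_t)
  if (!all(is.finite(out))) {
    stop_neuralmd("GNN-MD step diverged", "non_finite_state")
  }
  out
}

#' GNN-MD rollout
#' @inheritParams gnn_md_step
#' @param n_snaps snapshots to emit.
#' @return an `md_trajectory`.
#' @export
gnn_md_rollout <- function(position_model, complex, coords_t, n_snaps) {
  nl <- nrow(coords_t)
  coords <- array(NA_real_, c(n_snaps, nl, 3L))
  x <- coords_t
  for (s in seq_len(n_snaps)) {
    x <- gnn_md_step(position_model, complex, x)
    coords[s, , ] <- x
  }
  trajectory(coords)
}

denoising_sigmas <- function(config) {
  exp(seq(log(config$sigma_max), log(config$sigma_min),
          length.out = config$steps_per_snapshot))
}

score_eval <- function(score_model, complex, x, sigma) {
  score_model$n_score_evals <-
    if (is.null(score_model$n_score_evals)) 1L else
      score_model$n_score_evals + 1L
  tape <- ad_tape()
  ctx <- bn_ctx()
  xn <- ad_node(tape, as.matrix(x))
  binding_force_tape(score_model, tape, ctx, complex, xn,
                     sigma = sigma)$val / sigma
}

#' One snapshot of annealed Langevin denoising (DenoisingLD)
#'
#' From `coords_t`, runs `steps_per_snapshot` (default 10) annealed
#' Langevin updates `x <- x + eta_i * score(x, sigma_i) +
#' sqrt(2 eta_i) * eps` down a geometric noise schedule, producing the
#' predicted next snapshot. The score model is the sigma-conditioned
#' BindingNet trained by denoising score matching.
#'
#' @param score_model a [bindingnet()] used as noise-conditional score.
#' @param complex a [binding_complex()].
#' @param coords_t `N_l x 3` current coordinates.
#' @param config a [baseline_config()].
#' @param rng seeded RNG (internal use); default derives from
#'   `config$seed`.
#' @return `N_l x 3` predicted next-snapshot coordinates.
#' @export
denoising_ld_step <- function(score_model, complex, coords_t,
                              config = baseline_config("denoising_ld"),
                              rng = NULL) {
  if (is.null(rng)) rng <- local_rng(config$seed)
  x <- as.matrix(coords_t)
  nl <- nrow(x)
  for (sigma in denoising_sigmas(config)) {
    eta <- config$eta_scale * sigma^2
    sc <- if (is.function(score_model)) {
      score_model(x, sigma)
    } else {
      score_eval(score_model, complex, x, sigma)
    }
    x <- x + eta * sc + sqrt(2 * eta) * matrix(rng$rnorm(nl * 3L), nl, 3L)
    if (!all(is.finite(x))) {
      stop_neuralmd("Langevin denoising diverged", "non_finite_state")
    }
  }
  x
}

#' DenoisingLD rollout
#' @inheritParams denoising_ld_step
#' @param n_snaps snapshots to emit.
#' @return an `md_trajectory`.
#' @export
denoising_ld_rollout <- function(score_model, complex, coords_t, n_snaps,
                                 config = baseline_config("denoising_ld")) {
  rng <- local_rng(config$seed)
  nl <- nrow(coords_t)
  coords <- array(NA_real_, c(n_snaps, nl, 3L))
  x <- coords_t
  for (s in seq_len(n_snaps)) {
    x <- denoising_ld_step(score_model, complex, x, config, rng = rng)
    coords[s, , ] <- x
  }
  trajectory(coords)
}

# --- baseline training -----------------------------------------------------

# Shared single-backprop trainer: `loss_fn(tape, ctx)` builds the scalar
# loss node on the tape from the current parameters.
train_generic <- function(model, loss_fn, epochs, lr, verbose = FALSE) {
  st <- adam_state(model$params)
  history <- data.frame(epoch = integer(), loss = numeric())
  best <- Inf; best_params <- model$params
  for (ep in seq_len(epochs)) {
    tape <- ad_tape()
    ctx <- bn_ctx()
    loss <- loss_fn(tape, ctx)
    if (!is.finite(loss$val[1L])) {
      model$params <- best_params
      warning("non-finite loss; restoring last good parameters")
      break
    }
    ad_backward(tape, loss)
    grads <- lapply(names(model$params), function(nm) {
      g <- ctx$pn[[nm]]$grad
      if (is.null(g)) model$params[[nm]] * 0 else g
    })
    names(grads) <- names(model$params)
    upd <- adam_step(model$params, grads, st, lr = lr)
    model$params <- upd$params
    st <- upd$state
    if (loss$val[1L] < best) {
      best <- loss$val[1L]; best_params <- model$params
    }
    history <- rbind(history, data.frame(epoch = ep, loss = loss$val[1L]))
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("epoch %d loss %.4f", ep, loss$val[1L]))
    }
  }
  model$params <- best_params
  list(model = model, history = history)
}

#' Train the VerletMD force surrogate
#'
#' Fits the force field per snapshot by matching finite-difference
#' accelerations implied by the training snapshots,
#' `F(x_t)/m ~ x_{t+1} - 2 x_t + x_{t-1}` (snapshot-interval units);
#' inference then integrates the fitted forces with velocity Verlet.
#' Training is per-snapshot (no rollout in the loss), which is exactly
#' what makes this family fragile over long rollouts.
#'
#' @param model a [bindingnet()].
#' @param complex a [binding_complex()].
#' @param traj training trajectory (>= 3 snapshots).
#' @param epochs,lr optimizer settings.
#' @param masses per-atom masses (default 1).
#' @param batch_size snapshots sampled per epoch (default all).
#' @param verbose print progress.
#' @return list with `model` and `history`.
#' @export
train_verlet_md <- function(model, complex, traj, epochs = 150L, lr = 3e-3,
                            masses = NULL, batch_size = NULL,
                            verbose = FALSE) {
  T_ <- n_snapshots(traj)
  stopifnot(T_ >= 3L)
  nl <- dim(traj$coords)[2]
  if (is.null(masses)) masses <- rep(1, nl)
  ts <- 2L:(T_ - 1L)
  targets <- lapply(ts, function(t) {
    (snapshot(traj, t + 1L) - 2 * snapshot(traj, t) +
       snapshot(traj, t - 1L)) * masses
  })
  rng <- local_rng(model$config$seed + 17L)
  loss_fn <- function(tape, ctx) {
    ks <- seq_along(ts)
    if (!is.null(batch_size) && batch_size < length(ks)) {
      ks <- order(rng$runif(length(ks)))[seq_len(batch_size)]
    }
    total <- NULL
    for (k in ks) {
      x <- ad_node(tape, snapshot(traj, ts[k]))
      f <- binding_force_tape(model, tape, ctx, complex, x)
      diff <- ad_sub(tape, f, targets[[k]])
      term <- ad_mean_all(tape, ad_mul(tape, diff, diff))
      total <- if (is.null(total)) term else ad_add(tape, total, term)
    }
    ad_scale(tape, total, 1 / length(ks))
  }
  train_generic(model, loss_fn, epochs, lr, verbose)
}

#' Train the GNN-MD displacement predictor
#'
#' Teacher-forced next-snapshot regression: minimizes the mean per-atom
#' deviation of `x_t + BindingNet(x_t)` from `x_{t+1}` over training
#' pairs.
#'
#' @inheritParams train_verlet_md
#' @return list with `model` and `history`.
#' @export
train_gnn_md <- function(model, complex, traj, epochs = 150L, lr = 3e-3,
                         batch_size = NULL, verbose = FALSE) {
  T_ <- n_snapshots(traj)
  stopifnot(T_ >= 2L)
  rng <- local_rng(model$config$seed + 23L)
  loss_fn <- function(tape, ctx) {
    ts <- seq_len(T_ - 1L)
    if (!is.null(batch_size) && batch_size < length(ts)) {
      ts <- order(rng$runif(length(ts)))[seq_len(batch_size)]
    }
    total <- NULL
    for (t in ts) {
      x <- ad_node(tape, snapshot(traj, t))
      dpred <- binding_force_tape(model, tape, ctx, complex, x)
      diff <- ad_sub(tape, dpred,
                     snapshot(traj, t + 1L) - snapshot(traj, t))
      term <- ad_mean_all(tape, ad_rownorm(tape, diff))
      total <- if (is.null(total)) term else ad_add(tape, total, term)
    }
    ad_scale(tape, total, 1 / length(ts))
  }
  train_generic(model, loss_fn, epochs, lr, verbose)
}

#' Train the DenoisingLD score model
#'
#' Denoising score matching: each training target snapshot `x_{t+1}` is
#' perturbed with Gaussian noise at a level sampled from the geometric
#' schedule, and the sigma-conditioned score is regressed against the
#' denoising direction, with the standard `sigma^2` loss weighting
#' (`|| sigma * score + eps ||^2`).
#'
#' @inheritParams train_verlet_md
#' @param config a [baseline_config()] (`"denoising_ld"`) for the noise
#'   schedule and seed.
#' @return list with `model` and `history`.
#' @export
train_denoising_ld <- function(model, complex, traj,
                               config = baseline_config("denoising_ld"),
                               epochs = 150L, lr = 3e-3, batch_size = NULL,
                               verbose = FALSE) {
  T_ <- n_snapshots(traj)
  stopifnot(T_ >= 2L)
  sigmas <- denoising_sigmas(config)
  rng <- local_rng(config$seed + 7L)
  loss_fn <- function(tape, ctx) {
    total <- NULL
    n_terms <- 0L
    ts <- 2L:T_
    if (!is.null(batch_size) && batch_size < length(ts)) {
      ts <- ts[order(rng$runif(length(ts)))[seq_len(batch_size)]]
    }
    for (t in ts) {
      xt <- snapshot(traj, t)
      nl <- nrow(xt)
      sigma <- sigmas[1L + floor(rng$runif(1L) * length(sigmas))]
      eps <- matrix(rng$rnorm(nl * 3L), nl, 3L)
      xn <- ad_node(tape, xt + sigma * eps)
      f <- binding_force_tape(model, tape, ctx, complex, xn, sigma = sigma)
      # score = f / sigma; loss = || sigma*score + eps ||^2 = || f + eps ||^2
      diff <- ad_add(tape, f, eps)
      term <- ad_mean_all(tape, ad_mul(tape, diff, diff))
      total <- if (is.null(total)) term else ad_add(tape, total, term)
      n_terms <- n_terms + 1L
    }
    ad_scale(tape, total, 1 / n_terms)
  }
  train_generic(model, loss_fn, epochs, lr, verbose)
}
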