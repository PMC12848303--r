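# NeuralMD dynamics: augmented second-order ODE/SDE rollout of ligand
# positions and velocities, trained end-to-end through the integrator.
#
# The augmented state [x; v] evolves under [dx/dt; dv/dt] = [v; F/m] with
# F from BindingNet; explicit Euler with a sub-snapshot step integrates
# positions and velocities simultaneously, and the whole rollout lives on
# the autodiff tape so the trajectory loss differentiates into the model
# parameters (including through the force's dependence on positions).

#' Dynamics solver configuration
#'
#' @param steps_per_snapshot Euler steps per emitted snapshot (default 2,
#'   i.e. step size 0.5 snapshot intervals).
#' @param alpha velocity-refinement coefficient: after each snapshot,
#'   `v <- v + alpha * ligand_only_net(x)` (default 0 = off).
#' @param velocity_init `"positional_momentum"` (difference of the last
#'   two snapshots) or `"learned_mapping"` (the ligand-only net applied to
#'   that difference).
#' @param seed RNG seed for the SDE noise.
#' @return a `dynamics_config` list.
#' @export
dynamics_config <- function(steps_per_snapshot = 2L, alpha = 0,
                            velocity_init = c("positional_momentum",
                                              "learned_mapping"),
                            seed = 0L) {
  stopifnot(steps_per_snapshot >= 1L)
  structure(list(steps_per_snapshot = as.integer(steps_per_snapshot),
                 alpha = alpha, velocity_init = match.arg(velocity_init),
                 seed = as.integer(seed)),
            class = "dynamics_config")
}

#' Augmented second-order derivative
#'
#' The derivative of the augmented state: `[dx/dt; dv/dt] = [v; F/m]`.
#'
#' @param state list with `x` and `v`, each `N_l x 3`.
#' @param force `N_l x 3` force matrix.
#' @param masses positive per-atom masses.
#' @return list with `dx` and `dv`.
#' @export
augmented_derivative <- function(state, force, masses) {
  stopifnot(all(masses > 0))
  list(dx = state$v, dv = as.matrix(force) / masses)
}

#' Initial velocity from snapshots
#'
#' Positional-momentum estimate `v = x_t - x_{t-1}`, or its learned
#' mapping through the ligand-only vector head.
#'
#' @param x_t,x_prev `N_l x 3` coordinate matrices.
#' @param lig a [ligand()] (needed for the learned mapping).
#' @param mode `"positional_momentum"` or `"learned_mapping"`.
#' @param model a [bindingnet()] (learned mapping only).
#' @return `N_l x 3` velocity matrix (Angstrom per snapshot interval).
#' @export
init_velocity <- function(x_t, x_prev, lig = NULL,
                          mode = c("positional_momentum", "learned_mapping"),
                          model = NULL) {
  mode <- match.arg(mode)
  dv <- as.matrix(x_t) - as.matrix(x_prev)
  if (mode == "positional_momentum") return(dv)
  stopifnot(!is.null(model), !is.null(lig))
  ligand_only_net(model, lig, dv)
}

#' Trajectory reconstruction loss (Angstrom)
#'
#' Mean over snapshots and atoms of the per-atom Euclidean deviation
#' between predicted and ground-truth coordinates; the training
#' objective, identical to the MAE metric.
#'
#' @param pred,truth `md_trajectory` objects of equal shape.
#' @return non-negative scalar; zero iff the trajectories are identical.
#' @export
trajectory_loss <- function(pred, truth) mae(pred, truth)

# Forces for a plain-function model (tests, oracles) or a BindingNet.
force_eval_tape <- function(model, tape, ctx, complex, x, sigma = NULL) {
  if (is.function(model)) {
    return(ad_node(tape, model(x$val)))
  }
  binding_force_tape(model, tape, ctx, complex, x)
}

#' Roll out the neural ODE (Newtonian dynamics)
#'
#' Explicit Euler on the augmented state with step
#' `h = snapshot_interval / steps_per_snapshot`; the state is emitted at
#' each snapshot boundary. With `alpha != 0`, the ligand-only net refines
#' the velocity at each boundary.
#'
#' @param model a [bindingnet()], or a function `coords -> forces` (used
#'   for analytic oracles).
#' @param complex a [binding_complex()] (may be `NULL` for function
#'   models).
#' @param state0 list with `x` and `v` (`N_l x 3`).
#' @param n_snaps number of snapshots to emit.
#' @param config a [dynamics_config()].
#' @param masses per-atom masses (default 1; snapshot-indexed model units
#'   absorb mass/time scales).
#' @param snapshot_interval snapshot spacing (default 1).
#' @return an `md_trajectory` (with velocities).
#' @export
integrate_ode <- function(model, complex, state0, n_snaps,
                          config = dynamics_config(), masses = NULL,
                          snapshot_interval = 1.0) {
  rollout_tape(model, NULL, complex, state0, n_snaps, config, masses,
               snapshot_interval, tape = NULL)$trajectory
}

#' Roll out the neural SDE (Langevin dynamics)
#'
#' Euler-Maruyama analogue of [integrate_ode()]: each velocity update
#' adds the learned per-atom noise amplitude gated by fresh standard
#' Gaussian noise, scaled by `sqrt(h)` so displacement variance is
#' step-size consistent. With the noise network frozen at zero, the
#' trajectory equals the ODE rollout bit for bit.
#'
#' @inheritParams integrate_ode
#' @param noise_net a [bindingnet()] whose ligand-only head returns the
#'   noise amplitude, or `NULL` for no noise.
#' @return an `md_trajectory`.
#' @export
integrate_sde <- function(model, noise_net, complex, state0, n_snaps,
                          config = dynamics_config(), masses = NULL,
                          snapshot_interval = 1.0) {
  rollout_tape(model, noise_net, complex, state0, n_snaps, config, masses,
               snapshot_interval, tape = NULL)$trajectory
}

# Shared rollout; when `tape` is supplied the returned snapshot nodes stay
# on it for training. Velocities are in Angstrom per snapshot interval.
rollout_tape <- function(model, noise_net, complex, state0, n_snaps, config,
                         masses = NULL, snapshot_interval = 1.0, tape = NULL,
                         ctx = NULL, noise_ctx = NULL) {
  nl <- nrow(as.matrix(state0$x))
  if (is.null(masses)) {
    masses <- if (!is.null(complex) && !is.function(model)) {
      rep(1, nl)
    } else rep(1, nl)
  }
  own_tape <- is.null(tape)
  if (own_tape) tape <- ad_tape()
  if (is.null(ctx)) ctx <- bn_ctx()
  if (is.null(noise_ctx)) noise_ctx <- bn_ctx()
  h <- snapshot_interval / config$steps_per_snapshot
  rng <- local_rng(config$seed)
  x <- if (is_ad_node(state0$x)) state0$x else ad_node(tape, as.matrix(state0$x))
  v <- if (is_ad_node(state0$v)) state0$v else ad_node(tape, as.matrix(state0$v))
  snaps_x <- vector("list", n_snaps)
  snaps_v <- vector("list", n_snaps)
  for (s in seq_len(n_snaps)) {
    for (k in seq_len(config$steps_per_snapshot)) {
      f <- force_eval_tape(model, tape, ctx, complex, x)
      a <- ad_mul(tape, f, 1 / masses)          # recycles down columns
      x_new <- ad_add(tape, x, ad_scale(tape, v, h))
      dv <- ad_scale(tape, a, h)
      if (!is.null(noise_net)) {
        amp <- if (is.function(noise_net)) {
          ad_node(tape, noise_net(x$val))
        } else {
          ligand_only_tape(noise_net, tape, noise_ctx,
                           complex$ligand$atomic_numbers, x)
        }
        eps <- matrix(rng$rnorm(nl * 3L), nl, 3L)
        dv <- ad_add(tape, dv,
                     ad_mul(tape, ad_mul(tape, amp, eps),
                            sqrt(h) / masses))
      }
      v <- ad_add(tape, v, dv)
      x <- x_new
      if (!all(is.finite(x$val))) {
        stop_neuralmd("rollout diverged to non-finite coordinates",
                      "non_finite_state")
      }
    }
    if (config$alpha != 0 && !is.function(model)) {
      refine <- ligand_only_tape(model, tape, ctx,
                                 complex$ligand$atomic_numbers, x)
      v <- ad_add(tape, v, ad_scale(tape, refine, config$alpha))
    }
    snaps_x[[s]] <- x
    snaps_v[[s]] <- v
  }
  coords <- array(NA_real_, c(n_snaps, nl, 3L))
  vels <- array(NA_real_, c(n_snaps, nl, 3L))
  for (s in seq_len(n_snaps)) {
    coords[s, , ] <- snaps_x[[s]]$val
    vels[s, , ] <- snaps_v[[s]]$val
  }
  list(trajectory = trajectory(coords, velocities = vels,
                               snapshot_interval = snapshot_interval),
       snap_nodes = snaps_x, tape = tape, ctx = ctx)
}

# --- optimization ----------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 10) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] * sc
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# Loss and parameter gradients for one teacher-forced training pass.
neuralmd_loss_grads <- function(model, complex, traj, segments, config,
                                noise_net = NULL) {
  tape <- ad_tape()
  ctx <- bn_ctx()
  noise_ctx <- bn_ctx()
  total <- NULL
  n_terms <- 0L
  for (seg in segments) {
    t0 <- seg$t0; len <- seg$len
    x0 <- snapshot(traj, t0)
    v0 <- snapshot(traj, t0) - snapshot(traj, t0 - 1L)
    ro <- rollout_tape(model, noise_net, complex,
                       list(x = x0, v = v0), len, config,
                       tape = tape, ctx = ctx, noise_ctx = noise_ctx)
    for (s in seq_len(len)) {
      diff <- ad_sub(tape, ro$snap_nodes[[s]],
                     snapshot(traj, t0 + s))
      term <- ad_mean_all(tape, ad_rownorm(tape, diff))
      total <- if (is.null(total)) term else ad_add(tape, total, term)
      n_terms <- n_terms + 1L
    }
  }
  loss <- ad_scale(tape, total, 1 / n_terms)
  ad_backward(tape, loss)
  pn <- ctx$pn
  grads <- lapply(names(model$params), function(nm) {
    g <- pn[[nm]]$grad
    if (is.null(g)) model$params[[nm]] * 0 else g
  })
  names(grads) <- names(model$params)
  list(loss = loss$val[1L], grads = grads)
}

#' Train NeuralMD on snapshot trajectories
#'
#' Gradient-based minimization of the trajectory loss over teacher-forced
#' rollout segments: the trajectory is cut into segments of `segment_len`
#' snapshots, each restarted from the ground-truth state (position from
#' the data, velocity from positional momentum), and the mean per-atom
#' deviation of the predicted snapshots is differentiated through the
#' integrator into the network parameters (Adam, global-norm gradient
#' clipping). Full-length rollouts are for evaluation only.
#'
#' @param model a [bindingnet()] (modified in place and returned).
#' @param complex a [binding_complex()].
#' @param traj training `md_trajectory`.
#' @param config a [dynamics_config()].
#' @param epochs number of passes (default 150).
#' @param lr Adam learning rate (default 3e-3).
#' @param segment_len teacher-forcing segment length in snapshots
#'   (default 8).
#' @param segments_per_epoch how many segments to sample per epoch
#'   (stochastic mini-batching; default `NULL` = all segments every
#'   epoch).
#' @param seg_start_range optional `c(lo, hi)` restricting segment start
#'   snapshots (used by the staged protocol to focus late-trajectory
#'   dynamics).
#' @param noise_net optional noise-amplitude net, trained jointly (SDE).
#' @param verbose print the loss every 25 epochs.
#' @param log_file optional path receiving one JSON record per epoch
#'   (line-oriented).
#' @return list with `model` and `history` (data.frame of epoch losses).
#' @export
train_neuralmd <- function(model, complex, traj, config = dynamics_config(),
                           epochs = 150L, lr = 3e-3, segment_len = 8L,
                           segments_per_epoch = NULL, seg_start_range = NULL,
                           noise_net = NULL, verbose = FALSE,
                           log_file = NULL) {
  T_ <- n_snapshots(traj)
  stopifnot(T_ >= 3L)
  if (is.null(seg_start_range)) seg_start_range <- c(2L, T_ - 1L)
  lo <- max(2L, seg_start_range[1L])
  hi <- min(T_ - 1L, seg_start_range[2L])
  starts <- if (is.null(segments_per_epoch)) {
    seq(lo, hi, by = segment_len)
  } else {
    seq(lo, max(lo, hi - segment_len + 1L))   # pool for random draws
  }
  segments <- lapply(starts, function(t0) {
    list(t0 = t0, len = min(segment_len, T_ - t0))
  })
  segments <- Filter(function(s) s$len >= 1L, segments)
  rng <- local_rng(config$seed + 31L)
  st <- adam_state(model$params)
  history <- data.frame(epoch = integer(), loss = numeric())
  best <- Inf; best_params <- model$params
  for (ep in seq_len(epochs)) {
    batch <- segments
    if (!is.null(segments_per_epoch) &&
        segments_per_epoch < length(segments)) {
      pick <- order(rng$runif(length(segments)))[seq_len(segments_per_epoch)]
      batch <- segments[pick]
    }
    lg <- neuralmd_loss_grads(model, complex, traj, batch, config,
                              noise_net = noise_net)
    if (lg$loss < best) {
      best <- lg$loss
      best_params <- model$params
    }
    # divergence safeguard: long-horizon rollouts can blow up; restart
    # from the best parameters seen instead of corrupting the model
    if (!is.finite(lg$loss) || lg$loss > 3 * best + 1) {
      model$params <- best_params
      st <- adam_state(model$params)
      history <- rbind(history, data.frame(epoch = ep, loss = lg$loss))
      next
    }
    upd <- adam_step(model$params, lg$grads, st, lr = lr)
    model$params <- upd$params
    st <- upd$state
    history <- rbind(history, data.frame(epoch = ep, loss = lg$loss))
    if (!is.null(log_file)) {
      cat(jsonlite::toJSON(list(epoch = ep, loss = lg$loss, lr = lr,
                                segment_len = segment_len),
                           auto_unbox = TRUE, digits = NA),
          "\n", file = log_file, append = TRUE)
    }
    if (verbose && ep %% 25L == 0L) {
      message(sprintf("epoch %d loss %.4f", ep, lg$loss))
    }
  }
  model$params <- best_params
  list(model = model, history = history)
}
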