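# Experiment drivers: temporal and by-complex data splits, per-method
# training + rollout + evaluation, and multi-seed report aggregation.

#' Temporal split of a single trajectory
#'
#' Contiguous split at `floor(T * train_fraction)`; the defaults
#' reproduce the 80/20 protocol (train on snapshots 1-80, test on
#' 81-100 for a 100-snapshot trajectory).
#'
#' @param traj an `md_trajectory` with at least 10 snapshots.
#' @param train_fraction fraction of snapshots for training (default 0.8).
#' @return list with `train` and `test` trajectories plus `split` (the
#'   last training snapshot index).
#' @export
split_single_trajectory <- function(traj, train_fraction = 0.8) {
  T_ <- n_snapshots(traj)
  if (T_ < 10L) stop_neuralmd("trajectory too short to split", "too_short")
  cut <- floor(T_ * train_fraction)
  if (cut < 2L || cut >= T_) {
    stop_neuralmd("split leaves an empty train or test segment", "too_short")
  }
  list(train = traj_window(traj, seq_len(cut)),
       test = traj_window(traj, (cut + 1L):T_),
       split = cut)
}

#' Random split of a set of complexes
#'
#' Seeded random partition by complex (never by snapshot) into train /
#' validation / test; disjoint and exhaustive.
#'
#' @param n_complexes number of complexes (>= 10).
#' @param fractions length-3 numeric summing to 1 (default 0.8/0.1/0.1).
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_multi_trajectory <- function(n_complexes, fractions = c(0.8, 0.1, 0.1),
                                   seed = 0L) {
  if (n_complexes < 10L) stop_neuralmd("need >= 10 complexes", "too_few")
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  rng <- local_rng(seed)
  perm <- order(rng$runif(n_complexes))
  n_train <- floor(n_complexes * fractions[1L])
  n_val <- floor(n_complexes * fractions[2L])
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n_complexes]))
}

#' Run a single-trajectory experiment
#'
#' For each seed: trains the chosen method on the first 80% of snapshots,
#' rolls the trained model out over the test segment starting from the
#' last training snapshot (velocity from positional momentum on the final
#' training pair), and scores MAE, RMSE, Matching, Stability and the
#' sliding-window ligand RMSF against the held-out snapshots. A
#' "freeze" reference (last training position held fixed) is always
#' reported alongside.
#'
#' @param system list with `complex` and `trajectory` (see
#'   [toy_system()]).
#' @param method one of `"neuralmd_ode"`, `"neuralmd_sde"`,
#'   `"verlet_md"`, `"gnn_md"`, `"denoising_ld"`, `"freeze"`.
#' @param seeds integer seeds; results are aggregated as mean and sample
#'   standard deviation (default `c(0, 42, 123)`).
#' @param train_fraction temporal split fraction (default 0.8).
#' @param epochs,lr training budget shared by all methods; for the
#'   neural ODE/SDE, `epochs` scales the stages of
#'   [train_neuralmd_protocol()] (and equals its bootstrap budget).
#' @param model_config a [bindingnet_config()]; the desk-scale default
#'   (hidden_dim 32, 2 layers, cutoff 8 Angstrom so the whole toy pocket
#'   stays inside the interaction horizon) keeps single-CPU training in
#'   minutes.
#' @param dyn_config a [dynamics_config()].
#' @param verbose print training progress.
#' @return an `nmd_report` list: per-seed metric rows (`runs`) and
#'   mean/sd aggregates (`summary`).
#' @export
run_experiment <- function(system, method = c("neuralmd_ode", "neuralmd_sde",
                                              "verlet_md", "gnn_md",
                                              "denoising_ld", "freeze"),
                           seeds = c(0L, 42L, 123L), train_fraction = 0.8,
                           epochs = 150L, lr = 3e-3,
                           model_config = NULL,
                           dyn_config = dynamics_config(alpha = 1),
                           verbose = FALSE) {
  method <- match.arg(method)
  sp <- split_single_trajectory(system$trajectory, train_fraction)
  runs <- lapply(seeds, function(seed) {
    pred <- predict_test_segment(system, method, sp, seed, epochs, lr,
                                 model_config, dyn_config, verbose)
    score_rollout(pred, sp, seed, method)
  })
  runs <- do.call(rbind, runs)
  metric_cols <- c("mae", "rmse", "matching", "stability", "freeze_mae")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(runs[[m]]), numeric(1L)),
    sd = vapply(metric_cols, function(m) stats::sd(runs[[m]]), numeric(1L)))
  structure(list(method = method, runs = runs, summary = summary),
            class = "nmd_report")
}

#' @export
print.nmd_report <- function(x, ...) {
  cat(sprintf("<nmd_report> method=%s, %d seed(s)\n", x$method, nrow(x$runs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Train (if needed) and roll out the test segment for one seed.
predict_test_segment <- function(system, method, sp, seed, epochs, lr,
                                 model_config, dyn_config, verbose) {
  complex <- system$complex
  train <- sp$train
  n_test <- n_snapshots(sp$test)
  T_tr <- n_snapshots(train)
  x_last <- snapshot(train, T_tr)
  v_last <- init_velocity(x_last, snapshot(train, T_tr - 1L))
  if (method == "freeze") {
    coords <- array(rep(x_last, each = n_test),
                    c(n_test, nrow(x_last), 3L))
    return(trajectory(coords))
  }
  if (is.null(model_config)) {
    model_config <- bindingnet_config(hidden_dim = 32L,
                                      n_message_layers = 2L, seed = seed,
                                      cutoff_c = 8.0)
  } else {
    model_config$seed <- seed
  }
  # the model's interaction horizon, not the simulator's physics
  complex <- binding_complex(complex$ligand, complex$protein,
                             cutoff_c = model_config$cutoff_c)
  model <- bindingnet(model_config)
  model$params$head_W2[] <- 0   # velocity refinement starts as identity
  dyn <- dyn_config
  dyn$seed <- seed
  switch(method,
    neuralmd_ode = {
      train_neuralmd_protocol(model, complex, train, dyn,
                              epochs = protocol_epochs(epochs),
                              verbose = verbose)
      integrate_ode(model, complex, list(x = x_last, v = v_last), n_test,
                    dyn)
    },
    neuralmd_sde = {
      noise_net <- bindingnet(model_config)
      # noise amplitude starts at zero and is learned jointly
      noise_net$params$head_W2[] <- 0
      train_neuralmd_protocol(model, complex, train, dyn,
                              epochs = protocol_epochs(epochs),
                              noise_net = noise_net, verbose = verbose)
      integrate_sde(model, noise_net, complex,
                    list(x = x_last, v = v_last), n_test, dyn)
    },
    verlet_md = {
      train_verlet_md(model, complex, train, epochs = epochs, lr = lr,
                      batch_size = 26L, verbose = verbose)
      verlet_md_rollout(model, complex, list(x = x_last, v = v_last),
                        n_test, baseline_config("verlet_md", seed = seed))
    },
    gnn_md = {
      train_gnn_md(model, complex, train, epochs = epochs, lr = lr,
                   batch_size = 24L, verbose = verbose)
      gnn_md_rollout(model, complex, x_last, n_test)
    },
    denoising_ld = {
      cfg <- baseline_config("denoising_ld", seed = seed)
      train_denoising_ld(model, complex, train, cfg, epochs = epochs,
                         lr = lr, batch_size = 24L, verbose = verbose)
      denoising_ld_rollout(model, complex, x_last, n_test, cfg)
    })
}

# Per-stage epoch budget of the staged protocol, scaled from the single
# `epochs` knob (which also equals the bootstrap/VerletMD budget).
protocol_epochs <- function(epochs) {
  pmax(5L, as.integer(round(epochs * c(1, 1 / 3, 1 / 3, 4 / 15))))
}

score_rollout <- function(pred, sp, seed, method) {
  test <- sp$test
  T_tr <- sp$split
  x_last <- snapshot(sp$train, n_snapshots(sp$train))
  n_test <- n_snapshots(test)
  freeze <- trajectory(array(rep(x_last, each = n_test),
                             c(n_test, nrow(x_last), 3L)))
  data.frame(method = method, seed = seed,
             mae = mae(pred, test), rmse = rmse(pred, test),
             matching = matching(pred, test),
             stability = stability(pred, test),
             freeze_mae = mae(freeze, test),
             stringsAsFactors = FALSE)
}

#' Run a multi-trajectory experiment
#'
#' Generalization across binding complexes: the set of systems is
#' partitioned 80/10/10 by complex ([split_multi_trajectory()]), one model
#' is trained on all training trajectories (visiting systems in sequence),
#' and each held-out test complex is rolled out from its first snapshot
#' and scored against its remaining snapshots. Metrics are averaged over
#' test complexes, then aggregated over seeds.
#'
#' @param systems list of systems, each with `complex` and `trajectory`
#'   (e.g. from [toy_system()] with different seeds); at least 10.
#' @param method one of `"neuralmd_ode"`, `"neuralmd_sde"`, `"gnn_md"`,
#'   `"verlet_md"`, `"denoising_ld"`.
#' @param seeds integer seeds (default `c(0, 42, 123)`).
#' @param fractions train/val/test fractions (default 0.8/0.1/0.1).
#' @param epochs per-system training epochs.
#' @param model_config optional [bindingnet_config()].
#' @param dyn_config a [dynamics_config()].
#' @return an `nmd_report` with per-seed rows averaged over test
#'   complexes.
#' @export
run_experiment_multi <- function(systems,
                                 method = c("neuralmd_ode", "neuralmd_sde",
                                            "gnn_md", "verlet_md",
                                            "denoising_ld"),
                                 seeds = c(0L, 42L, 123L),
                                 fractions = c(0.8, 0.1, 0.1),
                                 epochs = 10L, model_config = NULL,
                                 dyn_config = dynamics_config(alpha = 1)) {
  method <- match.arg(method)
  runs <- lapply(seeds, function(seed) {
    sp <- split_multi_trajectory(length(systems), fractions, seed = seed)
    cfg <- if (is.null(model_config)) {
      bindingnet_config(hidden_dim = 32L, n_message_layers = 2L,
                        seed = seed, cutoff_c = 8.0)
    } else {
      mc <- model_config; mc$seed <- seed; mc
    }
    model <- bindingnet(cfg)
    model$params$head_W2[] <- 0
    noise_net <- NULL
    if (method == "neuralmd_sde") {
      noise_net <- bindingnet(cfg)
      noise_net$params$head_W2[] <- 0
    }
    dyn <- dyn_config
    dyn$seed <- seed
    for (idx in sp$train) {
      sys <- systems[[idx]]
      cx <- binding_complex(sys$complex$ligand, sys$complex$protein,
                            cutoff_c = cfg$cutoff_c)
      switch(method,
        neuralmd_ode = ,
        neuralmd_sde = train_neuralmd(model, cx, sys$trajectory, dyn,
                                      epochs = epochs, lr = 1e-3,
                                      segment_len = 8L,
                                      segments_per_epoch = 2L,
                                      noise_net = noise_net),
        verlet_md = train_verlet_md(model, cx, sys$trajectory,
                                    epochs = epochs, lr = 1e-3,
                                    batch_size = 12L),
        gnn_md = train_gnn_md(model, cx, sys$trajectory, epochs = epochs,
                              lr = 1e-3, batch_size = 12L),
        denoising_ld = train_denoising_ld(
          model, cx, sys$trajectory,
          baseline_config("denoising_ld", seed = seed),
          epochs = epochs, lr = 1e-3, batch_size = 12L))
    }
    per_complex <- lapply(sp$test, function(idx) {
      sys <- systems[[idx]]
      cx <- binding_complex(sys$complex$ligand, sys$complex$protein,
                            cutoff_c = cfg$cutoff_c)
      T_ <- n_snapshots(sys$trajectory)
      x0 <- snapshot(sys$trajectory, 1L)
      truth <- traj_window(sys$trajectory, 2L:T_)
      v0 <- if (!is.null(sys$trajectory$velocities)) {
        matrix(sys$trajectory$velocities[1L, , ], ncol = 3L)
      } else matrix(0, nrow(x0), 3L)
      pred <- switch(method,
        neuralmd_ode = integrate_ode(model, cx, list(x = x0, v = v0),
                                     T_ - 1L, dyn),
        neuralmd_sde = integrate_sde(model, noise_net, cx,
                                     list(x = x0, v = v0), T_ - 1L, dyn),
        verlet_md = verlet_md_rollout(model, cx, list(x = x0, v = v0),
                                      T_ - 1L,
                                      baseline_config("verlet_md",
                                                      seed = seed)),
        gnn_md = gnn_md_rollout(model, cx, x0, T_ - 1L),
        denoising_ld = denoising_ld_rollout(
          model, cx, x0, T_ - 1L,
          baseline_config("denoising_ld", seed = seed)))
      c(mae = mae(pred, truth), rmse = rmse(pred, truth),
        matching = matching(pred, truth), stability = stability(pred, truth))
    })
    avg <- colMeans(do.call(rbind, per_complex))
    data.frame(method = method, seed = seed, mae = avg[["mae"]],
               rmse = avg[["rmse"]], matching = avg[["matching"]],
               stability = avg[["stability"]], freeze_mae = NA_real_,
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, runs)
  metric_cols <- c("mae", "rmse", "matching", "stability")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(runs[[m]]), numeric(1L)),
    sd = vapply(metric_cols, function(m) stats::sd(runs[[m]]), numeric(1L)))
  structure(list(method = method, runs = runs, summary = summary),
            class = "nmd_report")
}

#' Tail-rollout validation score on training data
#'
#' Rolls the model out over the last part of the training segment
#' (starting 24 and 20 snapshots before its end, velocity from positional
#' momentum) and returns the mean reconstruction MAE. Used as a
#' checkpoint-selection criterion that mimics the test protocol without
#' touching test data.
#'
#' @param model a [bindingnet()].
#' @param complex a [binding_complex()].
#' @param traj training `md_trajectory`.
#' @param config a [dynamics_config()].
#' @param horizon rollout length per probe (default 20).
#' @return non-negative scalar, Angstrom.
#' @export
tail_rollout_score <- function(model, complex, traj,
                               config = dynamics_config(), horizon = 20L) {
  T_ <- n_snapshots(traj)
  starts <- unique(pmax(2L, c(T_ - horizon - 4L, T_ - horizon)))
  scores <- vapply(starts, function(t0) {
    len <- min(horizon, T_ - t0)
    p <- integrate_ode(model, complex,
                       list(x = snapshot(traj, t0),
                            v = snapshot(traj, t0) - snapshot(traj, t0 - 1L)),
                       len, config)
    mae(p, traj_window(traj, (t0 + 1L):(t0 + len)))
  }, numeric(1L))
  mean(scores)
}

#' Staged NeuralMD training protocol
#'
#' The training recipe used by [run_experiment()] for the neural ODE/SDE:
#' \enumerate{
#'   \item bootstrap the force field by matching finite-difference
#'     accelerations per snapshot (cheap, stable);
#'   \item rollout fine-tuning through the integrator on teacher-forced
#'     segments of growing length (8, then 16 snapshots) with decreasing
#'     learning rate;
#'   \item a final low-rate stage on 20-snapshot segments drawn from the
#'     late (settled) part of the trajectory, matching the evaluation
#'     horizon.
#' }
#' After each stage the parameters are checkpointed; the checkpoint with
#' the best [tail_rollout_score()] is kept, so rollout fine-tuning can
#' never make the delivered model worse than the bootstrap.
#'
#' @param model a [bindingnet()] (modified in place).
#' @param complex a [binding_complex()].
#' @param traj training trajectory.
#' @param config a [dynamics_config()].
#' @param epochs per-stage epoch counts, length 4 (default
#'   `c(150, 50, 50, 40)`).
#' @param noise_net optional jointly-trained SDE noise net.
#' @param verbose print stage progress.
#' @return list with `model` and `selected` (checkpoint label).
#' @export
train_neuralmd_protocol <- function(model, complex, traj,
                                    config = dynamics_config(),
                                    epochs = c(150L, 50L, 50L, 40L),
                                    noise_net = NULL, verbose = FALSE) {
  T_ <- n_snapshots(traj)
  ck <- list()
  train_verlet_md(model, complex, traj, epochs = epochs[1L], lr = 3e-3,
                  batch_size = 26L, verbose = verbose)
  ck$bootstrap <- model$params
  train_neuralmd(model, complex, traj, config, epochs = epochs[2L],
                 lr = 1e-3, segment_len = 8L, segments_per_epoch = 3L,
                 noise_net = noise_net, verbose = verbose)
  ck$rollout8 <- model$params
  train_neuralmd(model, complex, traj, config, epochs = epochs[3L],
                 lr = 5e-4, segment_len = 16L, segments_per_epoch = 2L,
                 noise_net = noise_net, verbose = verbose)
  ck$rollout16 <- model$params
  train_neuralmd(model, complex, traj, config, epochs = epochs[4L],
                 lr = 1e-4, segment_len = 20L, segments_per_epoch = 2L,
                 seg_start_range = c(max(2L, T_ - 40L), T_ - 16L),
                 noise_net = noise_net, verbose = verbose)
  ck$rollout20 <- model$params
  scores <- vapply(names(ck), function(nm) {
    model$params <- ck[[nm]]
    tail_rollout_score(model, complex, traj, config)
  }, numeric(1L))
  sel <- names(which.min(scores))
  model$params <- ck[[sel]]
  if (verbose) {
    message(sprintf("checkpoint scores: %s; selected %s",
                    paste(sprintf("%s=%.3f", names(scores), scores),
                          collapse = ", "), sel))
  }
  list(model = model, selected = sel)
}

#' Write an experiment report as JSON
#'
#' @param report an `nmd_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(method = report$method, runs = report$runs,
                            summary = report$summary),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
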