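# Trajectory evaluation metrics: reconstruction (MAE, RMSE), validity
# (Matching, Stability over pairwise distances), and the sliding-window
# ligand RMSF used for oscillation analysis.
#
# MAE averages the per-atom Euclidean deviation while RMSE is taken per
# coordinate component; with isotropic errors this makes RMSE ~ 0.63 * MAE,
# matching the reported ordering of the two reconstruction metrics.

check_same_shape <- function(pred, truth) {
  stopifnot(inherits(pred, "md_trajectory"), inherits(truth, "md_trajectory"))
  if (!identical(dim(pred$coords), dim(truth$coords))) {
    stop_neuralmd("trajectories have different shapes", "shape_mismatch")
  }
}

#' Mean absolute trajectory error (Angstrom)
#'
#' Mean over snapshots and atoms of the per-atom Euclidean deviation
#' `||x_pred - x_true||`. Identical to the training loss.
#'
#' @param pred,truth `md_trajectory` objects of equal shape.
#' @return non-negative scalar, Angstrom; 0 iff the trajectories coincide.
#' @export
mae <- function(pred, truth) {
  check_same_shape(pred, truth)
  d <- pred$coords - truth$coords
  mean(sqrt(apply(d^2, c(1, 2), sum)))
}

#' Root-mean-square trajectory error
#'
#' Root of the mean squared per-component deviation over snapshots, atoms
#' and the three coordinate components.
#'
#' @inheritParams mae
#' @return non-negative scalar.
#' @export
rmse <- function(pred, truth) {
  check_same_shape(pred, truth)
  sqrt(mean((pred$coords - truth$coords)^2))
}

pair_distances <- function(X, pairs) {
  d <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

intra_pairs <- function(n) {
  if (n < 2L) stop_neuralmd("need at least 2 atoms for pair metrics",
                            "shape_mismatch")
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Matching metric (squared Angstrom)
#'
#' Mean squared error between predicted and ground-truth intra-ligand
#' pairwise distances, averaged over snapshots and unordered atom pairs.
#' Invariant under independent rigid motions of either trajectory.
#'
#' @inheritParams mae
#' @param pairs optional two-column index matrix restricting the pair set
#'   (e.g. bonded pairs only); default all unordered intra-ligand pairs.
#' @return non-negative scalar, squared Angstrom.
#' @export
matching <- function(pred, truth, pairs = NULL) {
  check_same_shape(pred, truth)
  nl <- dim(pred$coords)[2]
  if (is.null(pairs)) pairs <- intra_pairs(nl)
  errs <- vapply(seq_len(n_snapshots(pred)), function(t) {
    dp <- pair_distances(snapshot(pred, t), pairs)
    dt <- pair_distances(snapshot(truth, t), pairs)
    mean((dp - dt)^2)
  }, numeric(1L))
  mean(errs)
}

#' Stability metric (percent)
#'
#' Percentage of (snapshot, unordered atom pair) combinations whose
#' predicted pairwise distance stays within `delta` of the true distance;
#' a long-rollout sanity measure (bond breaking and collapse show up as
#' low stability).
#'
#' @inheritParams matching
#' @param delta distance tolerance, Angstrom (default 0.5).
#' @return scalar in `[0, 100]`.
#' @export
stability <- function(pred, truth, delta = 0.5, pairs = NULL) {
  check_same_shape(pred, truth)
  stopifnot(delta > 0)
  nl <- dim(pred$coords)[2]
  if (is.null(pairs)) pairs <- intra_pairs(nl)
  ok <- vapply(seq_len(n_snapshots(pred)), function(t) {
    dp <- pair_distances(snapshot(pred, t), pairs)
    dt <- pair_distances(snapshot(truth, t), pairs)
    mean(abs(dp - dt) <= delta)
  }, numeric(1L))
  100 * mean(ok)
}

#' Ligand root-mean-square fluctuation (Angstrom)
#'
#' Square root of the time- and atom-averaged squared deviation of each
#' atom from its time-mean position over the segment:
#' `sqrt(mean_t mean_i ||r_it - <r_i>||^2)`.
#'
#' @param traj_segment an `md_trajectory` with at least 2 snapshots.
#' @return non-negative scalar, Angstrom.
#' @export
rmsf_ligand <- function(traj_segment) {
  stopifnot(inherits(traj_segment, "md_trajectory"))
  T_ <- n_snapshots(traj_segment)
  if (T_ < 2L) stop_neuralmd("RMSF needs a segment of >= 2 snapshots",
                             "segment_too_short")
  X <- traj_segment$coords
  mean_pos <- apply(X, c(2, 3), mean)
  dev2 <- vapply(seq_len(T_), function(t) {
    mean(rowSums((matrix(X[t, , ], ncol = 3L) - mean_pos)^2))
  }, numeric(1L))
  sqrt(mean(dev2))
}

#' Sliding-window ligand RMSF
#'
#' Splits the trajectory into consecutive non-overlapping blocks of
#' `window` snapshots (trailing remainder dropped) and scores each with
#' [rmsf_ligand()]. Window labels are inclusive snapshot ranges, offset by
#' `start` so test segments can carry their original snapshot numbering
#' (e.g. windows `[81, 85]` ... `[96, 100]` for the last 20 of 100).
#'
#' @param traj an `md_trajectory` with at least `window` snapshots.
#' @param window block length in snapshots (default 5).
#' @param start snapshot number of the first trajectory entry (default 1).
#' @return a data.frame with columns `from`, `to`, `rmsf`.
#' @export
sliding_rmsf <- function(traj, window = 5L, start = 1L) {
  stopifnot(window >= 2L)
  T_ <- n_snapshots(traj)
  if (T_ < window) stop_neuralmd("trajectory shorter than one window",
                                 "segment_too_short")
  n_win <- T_ %/% window
  out <- data.frame(from = integer(n_win), to = integer(n_win),
                    rmsf = numeric(n_win))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * window + 1L):(w * window)
    out$from[w] <- start + idx[1L] - 1L
    out$to[w] <- start + idx[window] - 1L
    out$rmsf[w] <- rmsf_ligand(traj_window(traj, idx))
  }
  out
}
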