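# Independent double-loop oracles for every metric, plus closed-form spot
# values and the distributional MAE/RMSE relationship.

oracle_mae <- function(p, t) {
  tot <- 0; n <- 0
  for (s in seq_len(dim(p)[1])) for (i in seq_len(dim(p)[2])) {
    tot <- tot + sqrt(sum((p[s, i, ] - t[s, i, ])^2)); n <- n + 1
  }
  tot / n
}

oracle_rmse <- function(p, t) {
  tot <- 0; n <- 0
  for (s in seq_len(dim(p)[1])) for (i in seq_len(dim(p)[2])) for (k in 1:3) {
    tot <- tot + (p[s, i, k] - t[s, i, k])^2; n <- n + 1
  }
  sqrt(tot / n)
}

oracle_pair <- function(p, t, fn) {
  nl <- dim(p)[2]
  vals <- c()
  for (s in seq_len(dim(p)[1])) for (i in 1:(nl - 1)) for (j in (i + 1):nl) {
    dp <- sqrt(sum((p[s, i, ] - p[s, j, ])^2))
    dt <- sqrt(sum((t[s, i, ] - t[s, j, ])^2))
    vals <- c(vals, fn(dp, dt))
  }
  mean(vals)
}

oracle_rmsf <- function(x) {
  nl <- dim(x)[2]; T_ <- dim(x)[1]
  mean_pos <- apply(x, c(2, 3), mean)
  tot <- 0
  for (s in seq_len(T_)) for (i in seq_len(nl)) {
    tot <- tot + sum((x[s, i, ] - mean_pos[i, ])^2)
  }
  sqrt(tot / (T_ * nl))
}

test_that("metrics equal double-loop oracles on random trajectory pairs", {
  set.seed(14)
  for (rep in 1:20) {
    p <- array(rnorm(10 * 10 * 3, sd = 2), c(10, 10, 3))
    t <- array(rnorm(10 * 10 * 3, sd = 2), c(10, 10, 3))
    tp <- trajectory(p); tt <- trajectory(t)
    expect_equal(mae(tp, tt), oracle_mae(p, t), tolerance = 1e-12)
    expect_equal(rmse(tp, tt), oracle_rmse(p, t), tolerance = 1e-12)
    expect_equal(matching(tp, tt),
                 oracle_pair(p, t, function(dp, dt) (dp - dt)^2),
                 tolerance = 1e-12)
    expect_equal(stability(tp, tt),
                 100 * oracle_pair(p, t,
                                   function(dp, dt) abs(dp - dt) <= 0.5),
                 tolerance = 1e-12)
    expect_equal(rmsf_ligand(tp), oracle_rmsf(p), tolerance = 1e-12)
  }
})

test_that("closed-form spot values hold", {
  set.seed(2)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  t0 <- trajectory(x)
  expect_equal(mae(t0, t0), 0)
  expect_equal(rmse(t0, t0), 0)
  expect_equal(matching(t0, t0), 0)
  expect_equal(stability(t0, t0), 100)
  off <- x; off[, , 1] <- off[, , 1] + 1
  expect_equal(mae(trajectory(off), t0), 1.0)
  expect_equal(rmse(trajectory(off), t0), sqrt(1 / 3))
  # rigid rotation leaves distance-based metrics untouched
  R <- rand_rotation()
  rot <- x
  for (s in 1:4) rot[s, , ] <- x[s, , ] %*% t(R)
  expect_equal(matching(trajectory(rot), t0), 0, tolerance = 1e-12)
  expect_equal(stability(trajectory(rot), t0), 100)
  # two atoms with doubled distance
  a2 <- array(0, c(1, 2, 3)); a2[1, 2, 1] <- 1.5
  b2 <- a2; b2[1, 2, 1] <- 3.0
  expect_equal(matching(trajectory(b2), trajectory(a2)), 1.5^2)
  expect_equal(stability(trajectory(b2), trajectory(a2)), 0)
  # threshold: |delta d| = 0.6 > 0.5 on every snapshot
  c2 <- a2; c2[1, 2, 1] <- 2.1
  expect_equal(stability(trajectory(c2), trajectory(a2)), 0)
  expect_equal(stability(trajectory(c2), trajectory(a2), delta = 0.7), 100)
})

test_that("RMSE/MAE ratio approaches the chi-distribution constant for isotropic errors", {
  set.seed(31)
  err <- array(rnorm(200 * 20 * 3, sd = 0.7), c(200, 20, 3))
  base <- array(0, c(200, 20, 3))
  r <- rmse(trajectory(err), trajectory(base)) /
    mae(trajectory(err), trajectory(base))
  # E||e|| = s*sqrt(2)*gamma(2)/gamma(3/2) = 1.5958 s; rmse = s
  expect_equal(r, 1 / 1.5958, tolerance = 0.02)
})

test_that("RMSF matches the hand example and sliding windows label correctly", {
  x <- array(0, c(2, 1, 3)); x[2, 1, 1] <- 2
  expect_equal(rmsf_ligand(trajectory(x)), 1.0)
  static <- trajectory(array(1, c(5, 3, 3)))
  expect_equal(rmsf_ligand(static), 0)
  expect_error(rmsf_ligand(trajectory(array(0, c(1, 2, 3)))),
               class = "segment_too_short")

  set.seed(8)
  seg <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  tr <- trajectory(seg)
  sw <- sliding_rmsf(tr, window = 5, start = 81)
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$from, c(81L, 86L, 91L, 96L))
  expect_equal(sw$to, c(85L, 90L, 95L, 100L))
  for (w in 1:4) {
    idx <- ((w - 1) * 5 + 1):(w * 5)
    expect_identical(sw$rmsf[w],
                     rmsf_ligand(trajectory(seg[idx, , , drop = FALSE])))
  }
  # 7 snapshots, window 5 -> one window, remainder dropped
  expect_equal(nrow(sliding_rmsf(trajectory(seg[1:7, , , drop = FALSE]))), 1L)
  expect_error(sliding_rmsf(trajectory(seg[1:3, , , drop = FALSE])),
               class = "segment_too_short")
})
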