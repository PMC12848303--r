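# Reverse-mode automatic differentiation on a Wengert tape.
#
# Every value is a dense numeric matrix. Nodes are recorded on a tape in
# creation order; ad_backward() walks the tape in reverse, accumulating
# gradients. This is what lets the trajectory loss differentiate through
# the Euler/Verlet rollouts and the equivariant message passing.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$store <- new.env(parent = emptyenv())   # O(1) per-node slots
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  n <- tape$n + 1L
  tape$n <- n
  nd$id <- n
  assign(as.character(n), nd, envir = tape$store)
  class(nd) <- "ad_node"
  nd
}

is_ad_node <- function(x) inherits(x, "ad_node")

#' @noRd
ad_value <- function(x) if (is_ad_node(x)) x$val else x

ad_const <- function(tape, x) ad_node(tape, as_matrix(x))

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Seed the output node with gradient 1 and sweep the tape backwards.
ad_backward <- function(tape, out) {
  stopifnot(is_ad_node(out), length(out$val) == 1L)
  out$grad <- matrix(1, 1L, 1L)
  store <- tape$store
  for (i in seq.int(tape$n, 1L)) {
    nd <- get(as.character(i), envir = store, inherits = FALSE)
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pgrads <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      g <- pgrads[[k]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}

# --- elementwise -----------------------------------------------------------

ad_add <- function(tape, a, b) {
  if (!is_ad_node(b)) {
    return(ad_node(tape, a$val + b, list(a), function(g) list(g)))
  }
  if (!is_ad_node(a)) {
    return(ad_node(tape, a + b$val, list(b), function(g) list(g)))
  }
  ad_node(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  if (!is_ad_node(b)) {
    return(ad_node(tape, a$val - b, list(a), function(g) list(g)))
  }
  if (!is_ad_node(a)) {
    return(ad_node(tape, a - b$val, list(b), function(g) list(-g)))
  }
  ad_node(tape, a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  if (!is_ad_node(b)) {
    return(ad_node(tape, a$val * b, list(a), function(g) list(g * b)))
  }
  if (!is_ad_node(a)) {
    return(ad_node(tape, a * b$val, list(b), function(g) list(g * a)))
  }
  av <- a$val; bv <- b$val
  ad_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, list(a), function(g) list(g * s))
}

ad_exp <- function(tape, a) {
  v <- exp(a$val)
  ad_node(tape, v, list(a), function(g) list(g * v))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$val)
  ad_node(tape, v, list(a), function(g) list(g * (1 - v^2)))
}

ad_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  av <- a$val
  ad_node(tape, av * s, list(a), function(g) list(g * (s * (1 + av * (1 - s)))))
}

# --- linear algebra --------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- av %*% bv
  if (is_ad_node(a) && is_ad_node(b)) {
    ad_node(tape, v, list(a, b),
            function(g) list(g %*% t(bv), t(av) %*% g))
  } else if (is_ad_node(a)) {
    ad_node(tape, v, list(a), function(g) list(g %*% t(bv)))
  } else {
    ad_node(tape, v, list(b), function(g) list(t(av) %*% g))
  }
}

# x %*% W + row-broadcast bias
ad_linear <- function(tape, x, W, b) {
  xv <- x$val; Wv <- W$val; bv <- b$val
  v <- xv %*% Wv
  v <- sweep(v, 2L, as.vector(bv), "+")
  ad_node(tape, v, list(x, W, b), function(g) {
    list(g %*% t(Wv), t(xv) %*% g, matrix(colSums(g), 1L))
  })
}

# --- row-wise geometry ops -------------------------------------------------

scatter_add_rows <- function(x, idx, n_out) {
  out <- matrix(0, n_out, ncol(x))
  if (nrow(x) > 0L) {
    rs <- rowsum(x, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

ad_gather <- function(tape, x, idx) {
  nr <- nrow(x$val)
  ad_node(tape, x$val[idx, , drop = FALSE], list(x), function(g) {
    list(scatter_add_rows(g, idx, nr))
  })
}

# Mean-aggregate edge rows into n_out node rows; rows with no incoming
# edges stay zero (empty neighbourhoods contribute nothing).
ad_scatter_mean <- function(tape, x, idx, n_out) {
  cnt <- tabulate(idx, nbins = n_out)
  w <- numeric(n_out)
  w[cnt > 0L] <- 1 / cnt[cnt > 0L]
  v <- scatter_add_rows(x$val, idx, n_out) * w
  ad_node(tape, v, list(x), function(g) {
    gw <- g * w
    list(gw[idx, , drop = FALSE])
  })
}

ad_rownorm <- function(tape, x, eps = 0) {
  xv <- x$val
  n <- sqrt(rowSums(xv^2) + eps)
  ad_node(tape, matrix(n, ncol = 1L), list(x), function(g) {
    list((as.vector(g) / pmax(n, 1e-300)) * xv)
  })
}

# divide each row of x (n x k) by s (n x 1)
ad_rowdiv <- function(tape, x, s) {
  xv <- x$val; sv <- as.vector(s$val)
  v <- xv / sv
  ad_node(tape, v, list(x, s), function(g) {
    list(g / sv, matrix(-rowSums(g * xv) / sv^2, ncol = 1L))
  })
}

# multiply each row of x (n x k) by s (n x 1)
ad_rowscale <- function(tape, x, s) {
  xv <- ad_value(x); sv <- as.vector(ad_value(s))
  v <- xv * sv
  if (is_ad_node(x) && is_ad_node(s)) {
    ad_node(tape, v, list(x, s), function(g) {
      list(g * sv, matrix(rowSums(g * xv), ncol = 1L))
    })
  } else if (is_ad_node(x)) {
    ad_node(tape, v, list(x), function(g) list(g * sv))
  } else {
    ad_node(tape, v, list(s), function(g) {
      list(matrix(rowSums(g * xv), ncol = 1L))
    })
  }
}

ad_rowdot <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- matrix(rowSums(av * bv), ncol = 1L)
  if (is_ad_node(a) && is_ad_node(b)) {
    ad_node(tape, v, list(a, b),
            function(g) list(as.vector(g) * bv, as.vector(g) * av))
  } else if (is_ad_node(a)) {
    ad_node(tape, v, list(a), function(g) list(as.vector(g) * bv))
  } else {
    ad_node(tape, v, list(b), function(g) list(as.vector(g) * av))
  }
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# row-wise cross product of two n x 3 matrices
# d(a x b) pairing: <g, da x b> = <da, b x g>, <g, a x db> = <db, g x a>
ad_cross <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- cross_rows(av, bv)
  if (is_ad_node(a) && is_ad_node(b)) {
    ad_node(tape, v, list(a, b),
            function(g) list(cross_rows(bv, g), cross_rows(g, av)))
  } else if (is_ad_node(a)) {
    ad_node(tape, v, list(a), function(g) list(cross_rows(bv, g)))
  } else {
    ad_node(tape, v, list(b), function(g) list(cross_rows(g, av)))
  }
}

ad_cbind <- function(tape, ...) {
  args <- list(...)
  vals <- lapply(args, ad_value)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  live <- vapply(args, is_ad_node, TRUE)
  ad_node(tape, do.call(cbind, vals), args[live], function(g) {
    out <- vector("list", sum(live))
    j <- 0L
    for (k in seq_along(args)) {
      if (!live[k]) next
      j <- j + 1L
      out[[j]] <- g[, starts[k]:ends[k], drop = FALSE]
    }
    out
  })
}

ad_cols <- function(tape, x, j) {
  nc <- ncol(x$val)
  ad_node(tape, x$val[, j, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, j] <- g
    list(out)
  })
}

ad_mean_all <- function(tape, x) {
  n <- length(x$val)
  ad_node(tape, matrix(mean(x$val), 1L, 1L), list(x), function(g) {
    list(matrix(as.vector(g) / n, nrow(x$val), ncol(x$val)))
  })
}

ad_sum_all <- function(tape, x) {
  ad_node(tape, matrix(sum(x$val), 1L, 1L), list(x), function(g) {
    list(matrix(as.vector(g), nrow(x$val), ncol(x$val)))
  })
}

# row-broadcast: subtract the column-means row from every row
ad_center_rows <- function(tape, x) {
  m <- colMeans(x$val)
  n <- nrow(x$val)
  ad_node(tape, sweep(x$val, 2L, m), list(x), function(g) {
    list(sweep(g, 2L, colMeans(g)))
  })
}

# Smooth cosine cutoff envelope: 1 at d = 0, 0 at d = cutoff, C^1.
ad_cos_cutoff <- function(tape, d, cutoff) {
  dv <- pmin(ad_value(d), cutoff)
  v <- matrix(0.5 * (cos(pi * dv / cutoff) + 1), ncol = 1L)
  if (!is_ad_node(d)) return(ad_node(tape, v))
  ad_node(tape, v, list(d), function(g) {
    list(g * (-0.5 * pi / cutoff) * sin(pi * dv / cutoff))
  })
}

ad_scatter_sum <- function(tape, x, idx, n_out) {
  ad_node(tape, scatter_add_rows(x$val, idx, n_out), list(x), function(g) {
    list(g[idx, , drop = FALSE])
  })
}

# Gaussian radial basis expansion of a distance column (n x 1) onto
# `centers`; width is the spacing-derived std dev.
ad_rbf <- function(tape, d, centers, width) {
  dv <- as.vector(ad_value(d))
  z <- outer(dv, centers, "-") / width
  v <- exp(-0.5 * z^2)
  if (!is_ad_node(d)) return(ad_node(tape, v))
  ad_node(tape, v, list(d), function(g) {
    list(matrix(rowSums(g * v * (-z / width)), ncol = 1L))
  })
}
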