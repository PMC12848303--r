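# BindingNet: a multi-grained SE(3)-equivariant network mapping a
# protein-ligand complex geometry to per-ligand-atom forces.
#
# Three granularities, each with its own vector frames:
#   * ligand atoms      - pair frames on atom pairs within the cutoff;
#   * protein backbone  - one frame per residue from its N/CA/C triad;
#   * complex           - pair frames on consecutive pocket residues.
# Equivariant 3-vectors are only ever (a) carried as per-atom "vec"
# channels, (b) gated by rotation-invariant scalars obtained by
# scalarizing geometry onto the frames, or (c) relative-position vectors,
# so the predicted force field transforms exactly like the coordinates
# under rotations and is unchanged by translations. The frames' second
# axis is a pseudo-vector, which makes the features (deliberately)
# sensitive to reflection: chirality matters in a rigid pocket.

#' BindingNet hyperparameters
#'
#' @param hidden_dim width of the invariant feature channels (default 64).
#' @param n_message_layers number of ligand message-passing layers
#'   (default 3).
#' @param n_rbf number of Gaussian radial-basis centres on `[0, cutoff_c]`
#'   used to embed distances (default 16).
#' @param cutoff_c neighbour cutoff, Angstrom, shared by all three
#'   granularities (default 5).
#' @param seed parameter initialization seed.
#' @return a `bindingnet_config` list.
#' @export
bindingnet_config <- function(hidden_dim = 64L, n_message_layers = 3L,
                              n_rbf = 16L, cutoff_c = 5.0, seed = 0L) {
  stopifnot(hidden_dim >= 1L, n_message_layers >= 1L, n_rbf >= 2L,
            cutoff_c > 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_message_layers = as.integer(n_message_layers),
                 n_rbf = as.integer(n_rbf), cutoff_c = as.numeric(cutoff_c),
                 seed = as.integer(seed)),
            class = "bindingnet_config")
}

# Xavier-uniform matrix
xavier <- function(rng, n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(rng$runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Create a BindingNet model
#'
#' @param config a [bindingnet_config()].
#' @return a `bindingnet_model` environment holding `config`, the named
#'   parameter matrices in `params`, and bookkeeping counters
#'   (`n_force_evals` counts force-field evaluations during rollouts).
#' @export
bindingnet <- function(config = bindingnet_config()) {
  d <- config$hidden_dim
  nr <- config$n_rbf
  edge_in <- d + 9L + nr   # h_i+h_j, scal(u_i), scal(u_j), scal(vec_i), rbf
  pe_in <- d + 3L + nr     # residue-pair features
  rng <- local_rng(config$seed)
  p <- list(
    lig_emb = 0.5 * xavier(rng, 118L, d),
    res_emb = 0.5 * xavier(rng, 20L, d),
    bb_emb = 0.5 * xavier(rng, 3L, d),
    sig_W = xavier(rng, nr, d),
    prot_edge_W1 = xavier(rng, pe_in, d), prot_edge_b1 = matrix(0, 1L, d),
    prot_edge_W2 = xavier(rng, d, d), prot_edge_b2 = matrix(0, 1L, d),
    prot_bb_W1 = xavier(rng, pe_in, d), prot_bb_b1 = matrix(0, 1L, d),
    prot_bb_W2 = xavier(rng, d, d), prot_bb_b2 = matrix(0, 1L, d),
    cpx_W1 = xavier(rng, d + 3L + nr, d), cpx_b1 = matrix(0, 1L, d),
    cpx_W2 = xavier(rng, d, 2L), cpx_b2 = matrix(0, 1L, 2L),
    head_W1 = xavier(rng, d, d), head_b1 = matrix(0, 1L, d),
    head_W2 = xavier(rng, d, 1L), head_b2 = matrix(0, 1L, 1L)
  )
  for (l in seq_len(config$n_message_layers)) {
    p[[sprintf("lig_l%d_W1", l)]] <- xavier(rng, edge_in, d)
    p[[sprintf("lig_l%d_b1", l)]] <- matrix(0, 1L, d)
    p[[sprintf("lig_l%d_W2", l)]] <- xavier(rng, d, d + 2L)
    p[[sprintf("lig_l%d_b2", l)]] <- matrix(0, 1L, d + 2L)
  }
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$params <- p
  m$n_force_evals <- 0L
  m$warned_degenerate <- FALSE
  class(m) <- "bindingnet_model"
  m
}

#' @export
print.bindingnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<bindingnet_model> hidden_dim=%d, layers=%d, %d parameters\n",
              x$config$hidden_dim, x$config$n_message_layers, np))
  invisible(x)
}

#' Save / load a BindingNet checkpoint
#'
#' Single-file archive of config + weights; [load_model()] restores a
#' model whose forward pass is bit-identical.
#'
#' @param model a `bindingnet_model`.
#' @param path file path.
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  m <- bindingnet(obj$config)
  m$params <- obj$params
  m
}

# Leaf nodes for every parameter on this tape (created once per tape).
param_nodes <- function(model, tape, ctx) {
  if (!is.null(ctx$pn)) return(ctx$pn)
  pn <- lapply(model$params, function(w) ad_node(tape, w))
  ctx$pn <- pn
  pn
}

# Fresh forward context; one per tape.
bn_ctx <- function() new.env(parent = emptyenv())

rbf_centers <- function(config) {
  seq(0, config$cutoff_c, length.out = config$n_rbf)
}

rbf_width <- function(config) {
  config$cutoff_c / (config$n_rbf - 1L)
}

mlp2 <- function(tape, x, pn, w1, b1, w2, b2) {
  h <- ad_silu(tape, ad_linear(tape, x, pn[[w1]], pn[[b1]]))
  ad_linear(tape, h, pn[[w2]], pn[[b2]])
}

warn_degenerate <- function(model, what) {
  if (!model$warned_degenerate) {
    warning(sprintf("degenerate %s frame(s) skipped", what))
    model$warned_degenerate <- TRUE
  }
}

# Numeric edge-frame pre-pass: drop pairs whose difference or centered
# cross product is degenerate.
valid_pair_edges <- function(X, edges, center) {
  if (nrow(edges) == 0L) return(edges)
  Xi <- X[edges[, 1], , drop = FALSE]
  Xj <- X[edges[, 2], , drop = FALSE]
  dif <- Xi - Xj
  cr <- cross_rows(sweep(Xi, 2L, center), sweep(Xj, 2L, center))
  ok <- sqrt(rowSums(dif^2)) > EPS_NORM & sqrt(rowSums(cr^2)) > EPS_NORM
  edges[ok, , drop = FALSE]
}

#' Ligand module: atom-level equivariant message passing
#'
#' One-hot atomic-number embeddings are refined over ligand-internal edges
#' within the cutoff. Each edge carries invariant features (summed node
#' features, scalarized local direction aggregates and the running
#' equivariant vector projected onto the edge's pair frame, and a Gaussian
#' distance embedding); an MLP emits an invariant message plus two scalar
#' gates that update the per-atom equivariant vector channel
#' `vec_i <- vec_i + mean_j(gate1 * vec_i + gate2 * (x_i - x_j))`.
#'
#' @param model a [bindingnet()].
#' @param lig a [ligand()].
#' @param coords `N_l x 3` coordinates (defaults to the ligand's).
#' @return list with invariant features `h` (`N_l x hidden_dim`) and
#'   equivariant vectors `vec` (`N_l x 3`).
#' @export
ligand_module <- function(model, lig, coords = NULL) {
  if (is.null(coords)) coords <- lig$coords
  tape <- ad_tape()
  ctx <- bn_ctx()
  x <- ad_node(tape, as.matrix(coords))
  out <- ligand_module_tape(model, tape, ctx, lig$atomic_numbers, x)
  list(h = out$h$val, vec = out$vec$val)
}

ligand_module_tape <- function(model, tape, ctx, atomic_numbers, x,
                               sigma = NULL) {
  cfg <- model$config
  d <- cfg$hidden_dim
  pn <- param_nodes(model, tape, ctx)
  nl <- nrow(x$val)
  h <- ad_gather(tape, pn$lig_emb, atomic_numbers)
  if (!is.null(sigma)) {
    # noise-level conditioning for the denoising score model
    sr <- exp(-0.5 * ((sigma - rbf_centers(cfg)) / rbf_width(cfg))^2)
    semb <- ad_matmul(tape, matrix(rep(sr, each = nl), nl), pn$sig_W)
    h <- ad_add(tape, h, semb)
  }
  vec <- ad_const(tape, matrix(0, nl, 3L))
  X <- x$val
  edges <- neighbor_pairs(X, X, cfg$cutoff_c, exclude_self = TRUE)
  center <- colMeans(X)
  kept <- valid_pair_edges(X, edges, center)
  if (nrow(kept) < nrow(edges)) warn_degenerate(model, "ligand pair")
  edges <- kept
  if (nrow(edges) == 0L) {
    return(list(h = h, vec = vec, x = x))
  }
  ei <- edges[, 1]; ej <- edges[, 2]
  xc <- ad_center_rows(tape, x)
  xi <- ad_gather(tape, x, ei); xj <- ad_gather(tape, x, ej)
  rel <- ad_sub(tape, xi, xj)
  dist <- ad_rownorm(tape, rel)
  e1 <- ad_rowdiv(tape, rel, dist)
  cr <- ad_cross(tape, ad_gather(tape, xc, ei), ad_gather(tape, xc, ej))
  e2 <- ad_rowdiv(tape, cr, ad_rownorm(tape, cr))
  e3 <- ad_cross(tape, e1, e2)
  # translation-invariant local direction aggregate, scalarized per edge
  u <- ad_scatter_mean(tape, ad_sub(tape, xj, xi), ei, nl)  # mean_j (x_j - x_i)
  scal3 <- function(v) {
    ad_cbind(tape, ad_rowdot(tape, v, e1), ad_rowdot(tape, v, e2),
             ad_rowdot(tape, v, e3))
  }
  su_i <- scal3(ad_gather(tape, u, ei))
  su_j <- scal3(ad_gather(tape, u, ej))
  rbf <- ad_rbf(tape, dist, rbf_centers(cfg), rbf_width(cfg))
  envl <- ad_cos_cutoff(tape, dist, cfg$cutoff_c)
  for (l in seq_len(cfg$n_message_layers)) {
    hij <- ad_add(tape, ad_gather(tape, h, ei), ad_gather(tape, h, ej))
    sv_i <- scal3(ad_gather(tape, vec, ei))
    feat <- ad_cbind(tape, hij, su_i, su_j, sv_i, rbf)
    out <- mlp2(tape, feat, pn, sprintf("lig_l%d_W1", l),
                sprintf("lig_l%d_b1", l), sprintf("lig_l%d_W2", l),
                sprintf("lig_l%d_b2", l))
    msg <- ad_cols(tape, out, seq_len(d))
    # bounded gates: learned forces stay finite however far the rollout
    # strays, which keeps long rollouts from blowing up catastrophically
    g1 <- ad_tanh(tape, ad_cols(tape, out, d + 1L))
    g2 <- ad_tanh(tape, ad_cols(tape, out, d + 2L))
    h <- ad_add(tape, h,
                ad_scatter_mean(tape, ad_rowscale(tape, ad_silu(tape, msg),
                                                  envl), ei, nl))
    dvec <- ad_add(tape, ad_rowscale(tape, ad_gather(tape, vec, ei), g1),
                   ad_rowscale(tape, rel, g2))
    vec <- ad_add(tape, vec,
                  ad_scatter_mean(tape, ad_rowscale(tape, dvec, envl), ei, nl))
  }
  list(h = h, vec = vec, x = x)
}

#' Protein module: backbone-level residue encoding
#'
#' Residue-type embeddings refined by one message-passing layer over
#' residue pairs (C-alpha within the cutoff), with geometry scalarized on
#' each residue's backbone frame, plus per-residue backbone-bond features:
#' `h = z_tilde + (h_{N,Ca} + h_{Ca,C}) / 2`. The protein is rigid, so
#' the geometric part is precomputed once per complex and the encoding is
#' cached across snapshots.
#'
#' @param model a [bindingnet()].
#' @param protein a [protein_backbone()].
#' @return invariant residue features, `N_r x hidden_dim`.
#' @export
protein_module <- function(model, protein) {
  tape <- ad_tape()
  ctx <- bn_ctx()
  protein_module_tape(model, tape, ctx, protein)$val
}

# Rigid-geometry precomputation, cached on the model (linear scan over
# previously seen proteins; complexes per model are few and small).
protein_geometry <- function(model, protein) {
  if (is.null(model$geom_cache)) model$geom_cache <- list()
  for (entry in model$geom_cache) {
    if (identical(entry$protein, protein)) return(entry$geom)
  }
  cfg <- model$config
  nr <- length(protein$residue_types)
  frames <- vector("list", nr)
  ok <- logical(nr)
  for (i in seq_len(nr)) {
    frames[[i]] <- tryCatch(
      build_backbone_frame(protein$n_coords[i, ], protein$ca_coords[i, ],
                           protein$c_coords[i, ]),
      neuralmd_error = function(e) NULL)
    ok[i] <- !is.null(frames[[i]])
  }
  if (!all(ok)) warn_degenerate(model, "backbone")
  edges <- neighbor_pairs(protein$ca_coords, protein$ca_coords, cfg$cutoff_c,
                          exclude_self = TRUE)
  edges <- edges[ok[edges[, 1]] & ok[edges[, 2]], , drop = FALSE]
  scal_edge <- NULL; rbf_edge <- NULL
  if (nrow(edges) > 0L) {
    rel <- protein$ca_coords[edges[, 1], , drop = FALSE] -
      protein$ca_coords[edges[, 2], , drop = FALSE]
    scal_edge <- t(vapply(seq_len(nrow(edges)), function(k) {
      scalarize(rel[k, ], frames[[edges[k, 1]]])
    }, numeric(3L)))
    dd <- sqrt(rowSums(rel^2))
    z <- outer(dd, rbf_centers(cfg), "-") / rbf_width(cfg)
    rbf_edge <- exp(-0.5 * z^2)
  }
  bb_feat <- function(a, b) {
    v <- a - b
    out <- matrix(0, nr, 3L + cfg$n_rbf)
    for (i in seq_len(nr)) {
      if (!ok[i]) next
      dd <- sqrt(sum(v[i, ]^2))
      out[i, ] <- c(scalarize(v[i, ], frames[[i]]),
                    exp(-0.5 * ((dd - rbf_centers(cfg)) / rbf_width(cfg))^2))
    }
    out
  }
  geom <- list(ok = ok, frames = frames, edges = edges,
               scal_edge = scal_edge, rbf_edge = rbf_edge,
               bb_nca = bb_feat(protein$n_coords, protein$ca_coords),
               bb_cac = bb_feat(protein$ca_coords, protein$c_coords),
               type_idx = match(protein$residue_types, AA3))
  model$geom_cache <- c(model$geom_cache,
                        list(list(protein = protein, geom = geom)))
  geom
}

protein_module_tape <- function(model, tape, ctx, protein) {
  if (!is.null(ctx$h_p)) return(ctx$h_p)   # rigid protein: encode once
  cfg <- model$config
  d <- cfg$hidden_dim
  pn <- param_nodes(model, tape, ctx)
  g <- protein_geometry(model, protein)
  nr <- length(g$type_idx)
  zt <- ad_gather(tape, pn$res_emb, g$type_idx)
  if (nrow(g$edges) > 0L) {
    ei <- g$edges[, 1]; ej <- g$edges[, 2]
    hij <- ad_add(tape, ad_gather(tape, zt, ei), ad_gather(tape, zt, ej))
    feat <- ad_cbind(tape, hij, ad_const(tape, cbind(g$scal_edge, g$rbf_edge)))
    msg <- mlp2(tape, feat, pn, "prot_edge_W1", "prot_edge_b1",
                "prot_edge_W2", "prot_edge_b2")
    zt <- ad_add(tape, zt, ad_scatter_mean(tape, ad_silu(tape, msg), ei, nr))
  }
  bb_pair <- function(types, geom_feat) {
    emb <- ad_add(tape, ad_gather(tape, pn$bb_emb, rep(types[1], nr)),
                  ad_gather(tape, pn$bb_emb, rep(types[2], nr)))
    feat <- ad_cbind(tape, emb, ad_const(tape, geom_feat))
    mlp2(tape, feat, pn, "prot_bb_W1", "prot_bb_b1", "prot_bb_W2",
         "prot_bb_b2")
  }
  h_nca <- bb_pair(c(1L, 2L), g$bb_nca)   # N, CA
  h_cac <- bb_pair(c(2L, 3L), g$bb_cac)   # CA, C
  h_p <- ad_add(tape, zt,
                ad_scale(tape, ad_add(tape, h_nca, h_cac), 0.5))
  ctx$h_p <- h_p
  h_p
}

# Frames on consecutive pocket residues, centered on the pocket centroid.
pocket_frames <- function(model, protein, pocket) {
  if (is.null(model$pocket_cache)) model$pocket_cache <- list()
  for (entry in model$pocket_cache) {
    if (identical(entry$pocket, pocket) && identical(entry$protein, protein)) {
      return(entry$frames)
    }
  }
  ca <- protein$ca_coords
  K <- length(pocket)
  centroid <- colMeans(ca[pocket, , drop = FALSE])
  fr <- vector("list", K)
  for (k in seq_len(K)) {
    a <- pocket[k]
    b <- if (k < K) pocket[k + 1L] else if (K > 1L) pocket[k - 1L] else NA
    f <- if (is.na(b)) NULL else tryCatch(
      build_pair_frame(ca[a, ], ca[b, ], center = centroid),
      neuralmd_error = function(e) NULL)
    if (is.null(f)) {
      # fall back to the residue's own backbone frame
      f <- tryCatch(
        build_backbone_frame(protein$n_coords[a, ], ca[a, ],
                             protein$c_coords[a, ]),
        neuralmd_error = function(e) NULL)
    }
    fr[k] <- list(f)
  }
  model$pocket_cache <- c(model$pocket_cache,
                          list(list(pocket = pocket, protein = protein,
                                    frames = fr)))
  fr
}

#' Complex module: ligand-pocket interaction forces
#'
#' For every ligand-atom / pocket-residue pair within the cutoff, the
#' relative position is scalarized on the pocket-residue pair frame and
#' combined with the two invariant encodings; an MLP emits scalar gates
#' producing the equivariant interaction vector
#' `vec_ij = gate1 * vec_i + gate2 * (x_i - x_j)`. The force is the
#' internal term plus the aggregated interaction:
#' `F_i = vec_i + mean_j vec_ij` (an empty pocket leaves the external
#' term zero).
#'
#' @param model a [bindingnet()].
#' @param lig_enc output of [ligand_module()].
#' @param res_enc output of [protein_module()].
#' @param complex a [binding_complex()].
#' @param coords current `N_l x 3` ligand coordinates.
#' @return `N_l x 3` force matrix.
#' @export
complex_module <- function(model, lig_enc, res_enc, complex, coords) {
  tape <- ad_tape()
  ctx <- bn_ctx()
  x <- ad_node(tape, as.matrix(coords))
  h <- ad_node(tape, lig_enc$h)
  vec <- ad_node(tape, lig_enc$vec)
  hp <- ad_node(tape, res_enc)
  complex_module_tape(model, tape, ctx, h, vec, x, hp, complex)$val
}

complex_module_tape <- function(model, tape, ctx, h, vec, x, h_p, complex) {
  cfg <- model$config
  X <- x$val
  prot <- complex$protein
  pocket <- pocket_residues(complex, X)
  if (length(pocket) == 0L) return(vec)
  pairs <- neighbor_pairs(X, prot$ca_coords[pocket, , drop = FALSE],
                          cfg$cutoff_c)
  if (nrow(pairs) == 0L) return(vec)
  frames <- pocket_frames(model, prot, pocket)
  keep <- !vapply(frames[pairs[, 2]], is.null, TRUE)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(vec)
  li <- pairs[, 1]
  rj <- pocket[pairs[, 2]]
  xi <- ad_gather(tape, x, li)
  rel <- ad_sub(tape, xi, matrix(prot$ca_coords[rj, , drop = FALSE],
                                 ncol = 3L))
  dist <- ad_rownorm(tape, rel)
  fr <- frames[pairs[, 2]]
  E1 <- t(vapply(fr, `[[`, numeric(3L), "e1"))
  E2 <- t(vapply(fr, `[[`, numeric(3L), "e2"))
  E3 <- t(vapply(fr, `[[`, numeric(3L), "e3"))
  scal <- ad_cbind(tape, ad_rowdot(tape, rel, E1), ad_rowdot(tape, rel, E2),
                   ad_rowdot(tape, rel, E3))
  rbf <- ad_rbf(tape, dist, rbf_centers(cfg), rbf_width(cfg))
  hij <- ad_add(tape, ad_gather(tape, h, li), ad_gather(tape, h_p, rj))
  feat <- ad_cbind(tape, hij, scal, rbf)
  pnn <- param_nodes(model, tape, ctx)
  gates <- mlp2(tape, feat, pnn, "cpx_W1", "cpx_b1", "cpx_W2", "cpx_b2")
  g1 <- ad_tanh(tape, ad_cols(tape, gates, 1L))
  g2 <- ad_tanh(tape, ad_cols(tape, gates, 2L))
  vec_ij <- ad_add(tape, ad_rowscale(tape, ad_gather(tape, vec, li), g1),
                   ad_rowscale(tape, rel, g2))
  # smooth envelope + sum aggregation: interaction forces superpose and
  # vanish continuously at the cutoff boundary
  envl <- ad_cos_cutoff(tape, dist, cfg$cutoff_c)
  ad_add(tape, vec,
         ad_scatter_sum(tape, ad_rowscale(tape, vec_ij, envl), li, nrow(X)))
}

#' Predict the force field on the ligand
#'
#' Full BindingNet composition: ligand module, (cached) protein module,
#' complex module. Deterministic for fixed parameters and inputs; every
#' call increments the model's force-evaluation counter.
#'
#' @param model a [bindingnet()].
#' @param complex a [binding_complex()].
#' @param ligand_coords current `N_l x 3` ligand coordinates (defaults to
#'   the complex's stored ligand geometry).
#' @return `N_l x 3` matrix of per-atom forces (model units).
#' @export
binding_force <- function(model, complex, ligand_coords = NULL) {
  if (is.null(ligand_coords)) ligand_coords <- complex$ligand$coords
  tape <- ad_tape()
  ctx <- bn_ctx()
  x <- ad_node(tape, as.matrix(ligand_coords))
  binding_force_tape(model, tape, ctx, complex, x)$val
}

binding_force_tape <- function(model, tape, ctx, complex, x, sigma = NULL) {
  model$n_force_evals <- model$n_force_evals + 1L
  lig <- ligand_module_tape(model, tape, ctx, complex$ligand$atomic_numbers,
                            x, sigma = sigma)
  h_p <- protein_module_tape(model, tape, ctx, complex$protein)
  complex_module_tape(model, tape, ctx, lig$h, lig$vec, x, h_p, complex)
}

#' Ligand-only equivariant vector head
#'
#' A ligand-only BindingNet (no protein): the ligand module followed by a
#' scalar-gate head, returning one 3-vector per atom,
#' `out_i = gate(h_i) * vec_i`. Used for the velocity-mapping /
#' refinement module and as the learned noise amplitude of the SDE
#' solver. Equivariant under rotation of its vector inputs; a
#' zero-initialized head returns exactly zero.
#'
#' @param model a [bindingnet()].
#' @param lig a [ligand()].
#' @param vectors `N_l x 3` input vectors (coordinates or displacements).
#' @return `N_l x 3` matrix.
#' @export
ligand_only_net <- function(model, lig, vectors) {
  tape <- ad_tape()
  ctx <- bn_ctx()
  x <- ad_node(tape, as.matrix(vectors))
  ligand_only_tape(model, tape, ctx, lig$atomic_numbers, x)$val
}

ligand_only_tape <- function(model, tape, ctx, atomic_numbers, x) {
  out <- ligand_module_tape(model, tape, ctx, atomic_numbers, x)
  pn <- ctx$pn
  gate <- ad_tanh(tape, mlp2(tape, out$h, pn, "head_W1", "head_b1",
                             "head_W2", "head_b2"))
  ad_rowscale(tape, out$vec, gate)
}
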