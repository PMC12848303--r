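# Toy binding complexes with known classical dynamics.
#
# A chain-bonded ligand sits inside a ring of frozen pseudo-residues; the
# ligand evolves under harmonic bonds plus a Lennard-Jones pocket
# potential, integrated with velocity Verlet (optionally a BAOAB Langevin
# thermostat). This mirrors the semi-flexible setting of real binding
# trajectories -- rigid protein, flexible ligand, ~100 snapshots -- while
# keeping the true force law available as an oracle.

#' Classical force-field parameters for the toy complex
#'
#' @param bond_k harmonic bond stiffness, energy/A^2 (reduced units).
#' @param bond_r0 bond equilibrium length, Angstrom.
#' @param pocket_epsilon Lennard-Jones well depth for ligand-atom /
#'   pocket-C-alpha interactions, energy.
#' @param pocket_sigma Lennard-Jones size parameter, Angstrom.
#' @param friction_gamma Langevin friction, 1/time (0 = Newtonian).
#' @param temperature_kT thermostat temperature in energy units
#'   (0 = Newtonian).
#' @return a `toy_force_field` parameter list.
#' @export
toy_force_field <- function(bond_k = 4, bond_r0 = 1.5, pocket_epsilon = 0.5,
                            pocket_sigma = 4.0, friction_gamma = 0,
                            temperature_kT = 0) {
  stopifnot(bond_k > 0, pocket_sigma > 0, friction_gamma >= 0,
            temperature_kT >= 0)
  structure(list(bond_k = bond_k, bond_r0 = bond_r0,
                 pocket_epsilon = pocket_epsilon, pocket_sigma = pocket_sigma,
                 friction_gamma = friction_gamma,
                 temperature_kT = temperature_kT),
            class = "toy_force_field")
}

#' Build a toy binding complex
#'
#' A chain-bonded carbon ligand with randomized equilibrium geometry,
#' placed at the centre of a ring of pseudo-residues whose N/C-alpha/C
#' triads use tabulated backbone bond lengths (N-Ca 1.46 A, Ca-C 1.52 A).
#' Deterministic for a given seed.
#'
#' @param n_ligand_atoms number of ligand atoms (>= 2; default 8).
#' @param n_residues number of pocket residues (>= 2; default 10).
#' @param seed RNG seed.
#' @param ring_radius pocket ring radius, Angstrom (default 7).
#' @param cutoff_c complex interaction cutoff, Angstrom (default 5).
#' @return a list with `complex` (a [binding_complex()]) and `bonds`
#'   (an `(n-1) x 2` chain bond index matrix).
#' @export
make_toy_complex <- function(n_ligand_atoms = 8L, n_residues = 10L, seed = 0L,
                             ring_radius = 7.0, cutoff_c = 5.0) {
  stopifnot(n_ligand_atoms >= 2L, n_residues >= 2L)
  rng <- local_rng(seed)
  # ligand: bent random chain, ~1.5 A steps, centered at the origin
  coords <- matrix(0, n_ligand_atoms, 3L)
  dir <- normalize_vec(rng$rnorm(3L))
  for (i in seq_len(n_ligand_atoms - 1L)) {
    dir <- normalize_vec(dir + 0.8 * rng$rnorm(3L))
    coords[i + 1L, ] <- coords[i, ] + 1.5 * dir
  }
  coords <- sweep(coords, 2L, colMeans(coords))
  lig <- ligand(rep(6L, n_ligand_atoms), coords)
  # frozen pocket: residues on a jittered ring around the ligand
  ang <- 2 * pi * (seq_len(n_residues) - 1L) / n_residues
  ca <- cbind(ring_radius * cos(ang), ring_radius * sin(ang),
              rng$rnorm(n_residues, sd = 0.5))
  inward <- -ca / sqrt(rowSums(ca^2))
  tang <- cbind(-sin(ang), cos(ang), 0)
  n_at <- ca + 1.46 * (0.8 * tang + 0.6 * inward)
  c_at <- ca + 1.52 * (-0.8 * tang + 0.6 * inward)
  prot <- protein_backbone(rep(AA3, length.out = n_residues), n_at, ca, c_at)
  bonds <- cbind(seq_len(n_ligand_atoms - 1L), 2L:n_ligand_atoms)
  list(complex = binding_complex(lig, prot, cutoff_c = cutoff_c),
       bonds = bonds)
}

# Seeded RNG scoped away from the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(rnorm = with_state(stats::rnorm), runif = with_state(stats::runif))
}

#' Analytic toy forces on the ligand
#'
#' Harmonic chain-bond forces `-k (r - r0) r_hat` (equal and opposite on
#' the two bonded atoms) plus Lennard-Jones forces between every ligand
#' atom and every frozen pocket C-alpha.
#'
#' @param ligand_coords `N_l x 3` matrix, Angstrom.
#' @param bonds `(n_bonds) x 2` index matrix.
#' @param pocket_ca_coords `N_r x 3` matrix of frozen C-alpha positions.
#' @param ff a [toy_force_field()].
#' @return `N_l x 3` force matrix.
#' @export
toy_forces <- function(ligand_coords, bonds, pocket_ca_coords, ff) {
  X <- as.matrix(ligand_coords)
  F_ <- matrix(0, nrow(X), 3L)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    d <- X[i, ] - X[j, ]
    r <- sqrt(sum(d^2))
    if (r < 1e-6) stop_neuralmd("overlapping bonded atoms", "overlap_error")
    f <- -ff$bond_k * (r - ff$bond_r0) * d / r
    F_[i, ] <- F_[i, ] + f
    F_[j, ] <- F_[j, ] - f
  }
  if (ff$pocket_epsilon != 0) {
    P <- as.matrix(pocket_ca_coords)
    for (i in seq_len(nrow(X))) {
      d <- sweep(P, 2L, X[i, ], "-")      # vectors atom -> residue
      r2 <- rowSums(d^2)
      if (any(r2 < 1e-12)) stop_neuralmd("ligand/pocket overlap", "overlap_error")
      s2 <- ff$pocket_sigma^2 / r2
      s6 <- s2^3
      # dV/dr * (1/r) with V = 4 eps (s12 - s6); force on atom = -dV/dx_i
      coef <- 24 * ff$pocket_epsilon * (2 * s6^2 - s6) / r2
      F_[i, ] <- F_[i, ] - colSums(coef * d)
    }
  }
  F_
}

toy_potential <- function(ligand_coords, bonds, pocket_ca_coords, ff) {
  X <- as.matrix(ligand_coords)
  e <- 0
  for (b in seq_len(nrow(bonds))) {
    r <- sqrt(sum((X[bonds[b, 1L], ] - X[bonds[b, 2L], ])^2))
    e <- e + 0.5 * ff$bond_k * (r - ff$bond_r0)^2
  }
  if (ff$pocket_epsilon != 0) {
    P <- as.matrix(pocket_ca_coords)
    for (i in seq_len(nrow(X))) {
      r2 <- rowSums(sweep(P, 2L, X[i, ], "-")^2)
      s6 <- (ff$pocket_sigma^2 / r2)^3
      e <- e + sum(4 * ff$pocket_epsilon * (s6^2 - s6))
    }
  }
  e
}

#' Simulate a ground-truth ligand trajectory
#'
#' Velocity-Verlet integration of the toy force field with `substeps` fine
#' steps per emitted snapshot; with `friction_gamma > 0` or
#' `temperature_kT > 0` a BAOAB-style Langevin thermostat with seeded
#' Gaussian kicks is applied. The pocket never moves (semi-flexible
#' setting). Stability heuristic: `fine_dt <= 0.05 / sqrt(bond_k)`.
#'
#' @param complex a [binding_complex()] (only the ligand moves).
#' @param bonds chain bond index matrix.
#' @param ff a [toy_force_field()].
#' @param x0,v0 initial `N_l x 3` coordinates/velocities; default the
#'   complex's ligand coordinates and zero velocities.
#' @param fine_dt fine integration step (default 0.01).
#' @param n_snaps number of snapshots to emit (default 100).
#' @param substeps fine steps per snapshot (default 50).
#' @param masses per-atom masses; default 1 per atom (reduced units).
#' @param seed RNG seed for thermostat kicks.
#' @return an `md_trajectory` with `n_snaps` snapshots including
#'   velocities; snapshot interval is `fine_dt * substeps` rescaled to 1.
#' @export
simulate_ground_truth <- function(complex, bonds, ff = toy_force_field(),
                                  x0 = NULL, v0 = NULL, fine_dt = 0.01,
                                  n_snaps = 100L, substeps = 50L,
                                  masses = NULL, seed = 0L) {
  lig <- complex$ligand
  nl <- nrow(lig$coords)
  if (is.null(x0)) x0 <- lig$coords
  if (is.null(v0)) v0 <- matrix(0, nl, 3L)
  if (is.null(masses)) masses <- rep(1, nl)
  P <- complex$protein$ca_coords
  rng <- local_rng(seed)
  x <- as.matrix(x0); v <- as.matrix(v0)
  f <- toy_forces(x, bonds, P, ff)
  langevin <- ff$friction_gamma > 0 || ff$temperature_kT > 0
  cdamp <- exp(-ff$friction_gamma * fine_dt)
  csig <- sqrt(ff$temperature_kT * (1 - cdamp^2))
  Xout <- array(NA_real_, c(n_snaps, nl, 3L))
  Vout <- array(NA_real_, c(n_snaps, nl, 3L))
  for (s in seq_len(n_snaps)) {
    for (k in seq_len(substeps)) {
      v <- v + 0.5 * fine_dt * f / masses
      x <- x + 0.5 * fine_dt * v
      if (langevin) {
        v <- cdamp * v +
          (csig / sqrt(masses)) * matrix(rng$rnorm(nl * 3L), nl, 3L)
      }
      x <- x + 0.5 * fine_dt * v
      f <- toy_forces(x, bonds, P, ff)
      v <- v + 0.5 * fine_dt * f / masses
      if (!all(is.finite(x))) {
        stop_neuralmd("simulation diverged (non-finite coordinates)",
                      "non_finite_state")
      }
    }
    Xout[s, , ] <- x
    # velocities reported per snapshot interval (= substeps * fine_dt)
    Vout[s, , ] <- v * substeps * fine_dt
  }
  trajectory(Xout, velocities = Vout, snapshot_interval = 1.0)
}

#' Write a toy complex as a PDB file for visual inspection
#'
#' Ligand atoms as HETATM records (residue LIG), pocket backbone atoms as
#' ATOM records.
#'
#' @param complex a [binding_complex()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(complex, path) {
  tbl <- element_table()
  sym <- tbl$symb[match(complex$ligand$atomic_numbers, tbl$num)]
  lines <- character()
  serial <- 0L
  atom_line <- function(record, name, res, resno, xyz, ele) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            record, serial, substr(name, 1, 4), res, "A", resno,
            xyz[1], xyz[2], xyz[3], ele)
  }
  prot <- complex$protein
  for (i in seq_along(prot$residue_types)) {
    lines <- c(lines,
               atom_line("ATOM", "N", prot$residue_types[i], i,
                         prot$n_coords[i, ], "N"),
               atom_line("ATOM", "CA", prot$residue_types[i], i,
                         prot$ca_coords[i, ], "C"),
               atom_line("ATOM", "C", prot$residue_types[i], i,
                         prot$c_coords[i, ], "C"))
  }
  nres <- length(prot$residue_types)
  for (i in seq_along(sym)) {
    lines <- c(lines,
               atom_line("HETATM", paste0(sym[i], i), "LIG", nres + 1L,
                         complex$ligand$coords[i, ], sym[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Default study system: toy complex plus simulated trajectory
#'
#' Convenience wrapper producing the benchmark configuration used
#' throughout the package: an 8-atom ligand in a 10-residue frozen pocket,
#' 100 snapshots of Newtonian dynamics started from a gentle collective
#' push (centre-of-mass kick plus small internal excitation).
#'
#' @param seed RNG seed controlling geometry, initial velocities and any
#'   thermostat noise.
#' @param n_snaps number of snapshots (default 100).
#' @param ff force field (default [toy_force_field()]).
#' @return list with `complex`, `bonds`, `trajectory`.
#' @export
toy_system <- function(seed = 0L, n_snaps = 100L, ff = toy_force_field()) {
  tc <- make_toy_complex(seed = seed)
  nl <- nrow(tc$complex$ligand$coords)
  rng <- local_rng(seed + 1000L)
  v0 <- 0.05 * matrix(rng$rnorm(nl * 3L), nl, 3L)
  v0 <- sweep(v0, 2L, colMeans(v0))                 # internal motion only
  com_kick <- 0.4 * normalize_vec(rng$rnorm(3L))
  v0 <- sweep(v0, 2L, com_kick, "+")                # slow collective drift
  traj <- simulate_ground_truth(tc$complex, tc$bonds, ff, v0 = v0,
                                n_snaps = n_snaps, seed = seed)
  list(complex = tc$complex, bonds = tc$bonds, trajectory = traj)
}
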