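# Data model for ligands, rigid protein backbones, binding complexes and
# ligand trajectories, plus the neighbor searches every module shares.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

element_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      el <- e$elements
      tbl <<- data.frame(num = el$num, symb = toupper(as.character(el$symb)),
                         mass = el$mass, stringsAsFactors = FALSE)
    }
    tbl
  }
})

element_number <- function(symbol) {
  tbl <- element_table()
  i <- match(toupper(trimws(symbol)), tbl$symb)
  if (anyNA(i)) {
    bad <- unique(symbol[is.na(i)])
    stop_neuralmd(paste0("unknown element symbol(s): ",
                         paste(bad, collapse = ", ")), "unknown_element")
  }
  tbl$num[i]
}

#' Standard atomic masses for atomic numbers
#'
#' @param z integer vector of atomic numbers (1..118).
#' @return numeric vector of standard atomic weights, amu (IUPAC table as
#'   shipped with bio3d).
#' @export
atomic_masses <- function(z) {
  tbl <- element_table()
  i <- match(as.integer(z), tbl$num)
  if (anyNA(i)) {
    stop_neuralmd("atomic number outside the known element table",
                  "unknown_element")
  }
  tbl$mass[i]
}

#' Construct a ligand
#'
#' A small molecule as a set of atoms: atomic numbers, per-atom masses and
#' 3-D coordinates.
#'
#' @param atomic_numbers integer vector, length `N_l >= 2`, values in 1..118.
#' @param coords `N_l x 3` numeric matrix, Angstrom.
#' @param masses optional numeric vector, amu; defaults to the standard
#'   atomic weights for `atomic_numbers`.
#' @return a `ligand` object.
#' @export
ligand <- function(atomic_numbers, coords, masses = NULL) {
  atomic_numbers <- as.integer(atomic_numbers)
  coords <- as.matrix(coords)
  n <- length(atomic_numbers)
  if (n < 2L) stop_neuralmd("a ligand needs at least 2 atoms", "format_error")
  if (any(atomic_numbers < 1L | atomic_numbers > 118L)) {
    stop_neuralmd("atomic numbers must lie in 1..118", "unknown_element")
  }
  stopifnot(nrow(coords) == n, ncol(coords) == 3L, all(is.finite(coords)))
  if (is.null(masses)) masses <- atomic_masses(atomic_numbers)
  stopifnot(length(masses) == n, all(masses > 0))
  structure(list(atomic_numbers = atomic_numbers, masses = as.numeric(masses),
                 coords = coords),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand> %d atoms (elements: %s)\n", length(x$atomic_numbers),
              paste(sort(unique(x$atomic_numbers)), collapse = ",")))
  invisible(x)
}

#' Construct a rigid protein backbone
#'
#' Coarse-grained protein: one residue type plus the N, C-alpha, C backbone
#' coordinates per residue. The C-alpha position doubles as the
#' residue-level coordinate.
#'
#' @param residue_types character vector of three-letter amino-acid codes.
#' @param n_coords,ca_coords,c_coords `N_r x 3` matrices, Angstrom.
#' @return a `protein_backbone` object.
#' @export
protein_backbone <- function(residue_types, n_coords, ca_coords, c_coords) {
  residue_types <- toupper(as.character(residue_types))
  nr <- length(residue_types)
  if (nr < 2L) stop_neuralmd("need at least 2 residues", "empty_protein")
  if (!all(residue_types %in% AA3)) {
    stop_neuralmd("residue types must be standard three-letter amino-acid codes",
                  "format_error")
  }
  for (m in list(n_coords, ca_coords, c_coords)) {
    stopifnot(is.matrix(m), nrow(m) == nr, ncol(m) == 3L, all(is.finite(m)))
  }
  structure(list(residue_types = residue_types,
                 n_coords = as.matrix(n_coords),
                 ca_coords = as.matrix(ca_coords),
                 c_coords = as.matrix(c_coords)),
            class = "protein_backbone")
}

#' @export
print.protein_backbone <- function(x, ...) {
  cat(sprintf("<protein_backbone> %d residues\n", length(x$residue_types)))
  invisible(x)
}

#' Construct a binding complex
#'
#' @param ligand a [ligand()].
#' @param protein a [protein_backbone()].
#' @param cutoff_c interaction cutoff, Angstrom (default 5); used for
#'   ligand-internal edges, residue-residue edges and ligand-pocket edges.
#' @return a `binding_complex` object.
#' @export
binding_complex <- function(ligand, protein, cutoff_c = 5.0) {
  stopifnot(inherits(ligand, "ligand"), inherits(protein, "protein_backbone"),
            is.numeric(cutoff_c), cutoff_c > 0)
  structure(list(ligand = ligand, protein = protein,
                 cutoff_c = as.numeric(cutoff_c)),
            class = "binding_complex")
}

#' @export
print.binding_complex <- function(x, ...) {
  cat(sprintf("<binding_complex> %d ligand atoms, %d residues, cutoff %.1f A\n",
              length(x$ligand$atomic_numbers), length(x$protein$residue_types),
              x$cutoff_c))
  invisible(x)
}

#' Construct a ligand trajectory
#'
#' Ordered snapshots of ligand coordinates with uniform snapshot spacing,
#' optionally with per-snapshot velocities.
#'
#' @param coords `T x N_l x 3` array, Angstrom.
#' @param velocities optional `T x N_l x 3` array, Angstrom per
#'   snapshot interval.
#' @param snapshot_interval positive spacing between snapshots
#'   (dimensionless model time; default 1).
#' @return an `md_trajectory` object.
#' @export
trajectory <- function(coords, velocities = NULL, snapshot_interval = 1.0) {
  coords <- as_traj_array(coords)
  if (!is.null(velocities)) {
    velocities <- as_traj_array(velocities)
    stopifnot(identical(dim(velocities), dim(coords)))
  }
  stopifnot(dim(coords)[1] >= 1L, dim(coords)[3] == 3L,
            snapshot_interval > 0)
  structure(list(coords = coords, velocities = velocities,
                 snapshot_interval = as.numeric(snapshot_interval)),
            class = "md_trajectory")
}

as_traj_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<md_trajectory> %d snapshots x %d atoms%s (interval %g)\n",
              d[1], d[2], if (is.null(x$velocities)) "" else " (+velocities)",
              x$snapshot_interval))
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer snapshot count.
#' @export
n_snapshots <- function(traj) dim(traj$coords)[1]

#' Extract one snapshot's coordinate matrix
#' @param traj an `md_trajectory`.
#' @param t snapshot index (1-based).
#' @return `N_l x 3` matrix.
#' @export
snapshot <- function(traj, t) {
  matrix(traj$coords[t, , ], ncol = 3L)
}

#' Take a contiguous snapshot range of a trajectory
#' @param traj an `md_trajectory`.
#' @param idx integer snapshot indices (contiguous).
#' @return an `md_trajectory` over the selected snapshots.
#' @export
traj_window <- function(traj, idx) {
  trajectory(traj$coords[idx, , , drop = FALSE],
             velocities = if (is.null(traj$velocities)) NULL else
               traj$velocities[idx, , , drop = FALSE],
             snapshot_interval = traj$snapshot_interval)
}

# --- neighbor searches -----------------------------------------------------

#' All point pairs within a distance cutoff
#'
#' @param coords_a,coords_b `n x 3` matrices; pass the same matrix (and
#'   `exclude_self = TRUE`) for within-set pairs.
#' @param cutoff distance cutoff, Angstrom.
#' @param exclude_self drop `i == j` pairs (both directions of a within-set
#'   pair are still listed).
#' @return a two-column integer matrix of (i, j) index pairs with
#'   `||a_i - b_j|| <= cutoff`; zero rows when none qualify.
#' @export
neighbor_pairs <- function(coords_a, coords_b, cutoff, exclude_self = FALSE) {
  stopifnot(cutoff > 0)
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  keep <- d2 <= cutoff^2 + 1e-12
  if (exclude_self) diag(keep) <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  m <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Pocket residues of a binding complex
#'
#' Residues whose C-alpha lies within the complex cutoff of any ligand
#' atom; these form the interactive "pocket" region.
#'
#' @param complex a [binding_complex()].
#' @param ligand_coords optional `N_l x 3` matrix overriding the ligand's
#'   stored coordinates (the pocket moves with the ligand during rollout).
#' @return sorted, duplicate-free integer vector of residue indices
#'   (possibly empty).
#' @export
pocket_residues <- function(complex, ligand_coords = NULL) {
  if (is.null(ligand_coords)) ligand_coords <- complex$ligand$coords
  pr <- neighbor_pairs(complex$protein$ca_coords, ligand_coords,
                       complex$cutoff_c)
  sort(unique(pr[, 1]))
}
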