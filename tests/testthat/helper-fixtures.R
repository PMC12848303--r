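# Shared fixtures: rotation helpers, tiny structure files, small systems.

rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_rows <- function(X, R) X %*% t(R)

apply_rigid <- function(X, R, t) sweep(X %*% t(R), 2L, t, "+")

rigid_protein <- function(prot, R, t) {
  protein_backbone(prot$residue_types,
                   apply_rigid(prot$n_coords, R, t),
                   apply_rigid(prot$ca_coords, R, t),
                   apply_rigid(prot$c_coords, R, t))
}

reflect_protein <- function(prot) {
  protein_backbone(prot$residue_types, -prot$n_coords, -prot$ca_coords,
                   -prot$c_coords)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          record = "ATOM", altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, altloc, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], element)
}

# two complete residues + one residue missing CA + an altloc-B duplicate
fixture_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "CA", "ALA", "A", 1, c(1.46, 0, 0), element = "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, c(2.0, 1.4, 0)),
    pdb_atom_line(4, "CA", "ALA", "A", 1, c(9, 9, 9), altloc = "B",
                  element = "C"),
    pdb_atom_line(5, "N", "GLY", "A", 2, c(3.0, 2.0, 0.5)),
    pdb_atom_line(6, "CA", "GLY", "A", 2, c(4.4, 2.4, 0.6), element = "C"),
    pdb_atom_line(7, "C", "GLY", "A", 2, c(5.2, 3.6, 1.0)),
    pdb_atom_line(8, "N", "SER", "A", 3, c(6.0, 4.0, 1.2)),
    pdb_atom_line(9, "C", "SER", "A", 3, c(7.5, 5.0, 1.4)),
    "END")
  writeLines(lines, path)
  path
}

fixture_ligand_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "C1", "LIG", "A", 1, c(0, 0, 0), record = "HETATM",
                  element = "C"),
    pdb_atom_line(2, "C2", "LIG", "A", 1, c(1.5, 0, 0), record = "HETATM",
                  element = "C"),
    pdb_atom_line(3, "O1", "LIG", "A", 1, c(2.2, 1.1, 0), record = "HETATM",
                  element = "O"),
    pdb_atom_line(4, "O", "HOH", "A", 2, c(8, 8, 8), record = "HETATM",
                  element = "O"),
    "END")
  writeLines(lines, path)
  path
}

# ethane, 8 atoms, V2000
fixture_sdf <- function(path) {
  atoms <- rbind(
    c(-0.7560, 0.0000, 0.0000, "C"),
    c(0.7560, 0.0000, 0.0000, "C"),
    c(-1.1404, 0.6586, 0.7845, "H"),
    c(-1.1404, 0.3501, -0.9626, "H"),
    c(-1.1405, -1.0087, 0.1781, "H"),
    c(1.1404, -0.3501, 0.9626, "H"),
    c(1.1405, 1.0087, -0.1781, "H"),
    c(1.1404, -0.6586, -0.7845, "H"))
  lines <- c("ethane", "  fixture", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 8L, 7L),
             apply(atoms, 1, function(a) {
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       as.numeric(a[1]), as.numeric(a[2]), as.numeric(a[3]),
                       a[4])
             }),
             "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
             "  2  6  1  0", "  2  7  1  0", "  2  8  1  0",
             "M  END", "$$$$")
  writeLines(lines, path)
  path
}

tiny_model <- function(seed = 1L, hidden = 8L, layers = 2L, cutoff = 5) {
  bindingnet(bindingnet_config(hidden_dim = hidden, n_message_layers = layers,
                               seed = seed, cutoff_c = cutoff))
}

tiny_system <- function(seed = 0L, n_snaps = 12L) {
  toy_system(seed = seed, n_snaps = n_snaps)
}

expect_frame_valid <- function(f, tol = 1e-6) {
  for (e in list(f$e1, f$e2, f$e3)) {
    expect_equal(sqrt(sum(e^2)), 1, tolerance = tol)
  }
  expect_lt(abs(sum(f$e1 * f$e2)), tol)
  expect_lt(abs(sum(f$e1 * f$e3)), tol)
  expect_lt(abs(sum(f$e2 * f$e3)), tol)
  expect_lt(max(abs(f$e3 - neuralmd:::cross3(f$e1, f$e2))), tol)
}
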