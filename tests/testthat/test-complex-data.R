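test_that("ligand constructor validates atoms and fills masses", {
  lig <- ligand(c(6L, 1L), matrix(c(0, 0, 0, 1.1, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(lig$masses[1], 12.011, tolerance = 1e-2)
  expect_equal(lig$masses[2], 1.008, tolerance = 1e-2)
  expect_error(ligand(6L, matrix(0, 1, 3)), class = "format_error")
  expect_error(ligand(c(6L, 200L), matrix(0, 2, 3)),
               class = "unknown_element")
})

test_that("protein backbone constructor validates residues", {
  m <- matrix(rnorm(6), 2, 3)
  pb <- protein_backbone(c("ALA", "GLY"), m, m + 1, m + 2)
  expect_equal(length(pb$residue_types), 2L)
  expect_error(protein_backbone("ALA", m[1, , drop = FALSE],
                                m[1, , drop = FALSE], m[1, , drop = FALSE]),
               class = "empty_protein")
  expect_error(protein_backbone(c("XXX", "GLY"), m, m, m),
               class = "format_error")
})

test_that("neighbor_pairs equals a brute-force double loop", {
  # threshold behaviour
  a <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_true(any(neighbor_pairs(a, a, 5, exclude_self = TRUE)[, 1] == 1))
  expect_equal(nrow(neighbor_pairs(a, a, 2, exclude_self = TRUE)), 0L)
  expect_equal(nrow(neighbor_pairs(a[1, , drop = FALSE],
                                   a[1, , drop = FALSE], 1,
                                   exclude_self = TRUE)), 0L)
  set.seed(3)
  for (rep in 1:5) {
    A <- matrix(runif(60, 0, 10), 20, 3)
    got <- neighbor_pairs(A, A, 4, exclude_self = TRUE)
    want <- NULL
    for (i in 1:20) for (j in 1:20) {
      if (i != j && sqrt(sum((A[i, ] - A[j, ])^2)) <= 4) {
        want <- rbind(want, c(i, j))
      }
    }
    expect_equal(unname(got), unname(want[order(want[, 1], want[, 2]), ,
                                          drop = FALSE]))
    # symmetry on one point set
    key <- paste(got[, 1], got[, 2])
    rev <- paste(got[, 2], got[, 1])
    expect_true(all(rev %in% key))
  }
})

test_that("pocket_residues matches a brute-force scan and is sorted unique", {
  set.seed(9)
  for (rep in 1:5) {
    lig <- ligand(rep(6L, 4L), matrix(rnorm(12, sd = 2), 4, 3))
    nr <- 8L
    ca <- matrix(rnorm(nr * 3, sd = 6), nr, 3)
    prot <- protein_backbone(rep(c("ALA", "GLY"), 4), ca + 0.5, ca, ca - 0.5)
    cx <- binding_complex(lig, prot, cutoff_c = 5)
    got <- pocket_residues(cx)
    want <- which(vapply(seq_len(nr), function(j) {
      any(sqrt(rowSums(sweep(lig$coords, 2, ca[j, ])^2)) <= 5)
    }, logical(1L)))
    expect_equal(got, want)
    expect_false(is.unsorted(got))
    expect_equal(anyDuplicated(got), 0L)
  }
  # boundary: one CA just inside, all others far
  lig <- ligand(c(6L, 6L), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  ca <- rbind(c(4.9, 0, 0), c(50, 0, 0))
  prot <- protein_backbone(c("ALA", "GLY"), ca + 0.3, ca, ca - 0.3)
  expect_equal(pocket_residues(binding_complex(lig, prot, 5)), 1L)
  ca_far <- ca + 100
  prot_far <- protein_backbone(c("ALA", "GLY"), ca_far + 0.3, ca_far,
                               ca_far - 0.3)
  expect_equal(length(pocket_residues(binding_complex(lig, prot_far, 5))), 0L)
})

test_that("PDB protein reader keeps complete residues, first altloc, warns on drops", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fixture_pdb(path)
  w <- capture_warnings(pb <- read_protein_backbone(path))
  expect_true(any(grepl("dropped", w)))
  expect_equal(pb$residue_types, c("ALA", "GLY"))
  expect_equal(pb$ca_coords[1, ], c(1.46, 0, 0))   # altloc A kept, B ignored
  expect_equal(pb$n_coords[2, ], c(3.0, 2.0, 0.5))
})

test_that("ligand readers parse HETATM and SDF, excluding waters", {
  path <- withr::local_tempfile(fileext = ".pdb")
  fixture_ligand_pdb(path)
  lig <- read_ligand(path, "pdb-hetatm")
  expect_equal(sort(lig$atomic_numbers), c(6L, 6L, 8L))  # HOH excluded
  expect_equal(lig$masses[lig$atomic_numbers == 6L][1], 12.011,
               tolerance = 1e-2)

  sdf <- withr::local_tempfile(fileext = ".sdf")
  fixture_sdf(sdf)
  eth <- read_ligand(sdf, "sdf")
  expect_equal(length(eth$atomic_numbers), 8L)
  expect_equal(sum(eth$atomic_numbers == 6L), 2L)
  expect_equal(sum(eth$atomic_numbers == 1L), 6L)
  expect_equal(eth$coords[1, ], c(-0.756, 0, 0))

  empty <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("x", "y"), empty)
  expect_error(read_ligand(empty, "sdf"), class = "format_error")
})

test_that("trajectory container round trips bitwise and flags bad files", {
  set.seed(21)
  coords <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  vel <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  tr <- trajectory(coords, velocities = vel, snapshot_interval = 2)
  path <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(tr, path)
  back <- read_trajectory(path)$trajectory
  expect_identical(back$coords, coords)
  expect_identical(back$velocities, vel)
  expect_identical(back$snapshot_interval, 2)

  # with an attached complex
  sys <- tiny_system(n_snaps = 3L)
  write_trajectory(sys$trajectory, path, complex = sys$complex)
  rt <- read_trajectory(path)
  expect_identical(rt$trajectory$coords, sys$trajectory$coords)
  expect_equal(rt$complex$protein$ca_coords, sys$complex$protein$ca_coords)

  # T = 1 boundary
  one <- trajectory(array(rnorm(6), c(1, 2, 3)))
  write_trajectory(one, path)
  expect_identical(read_trajectory(path)$trajectory$coords, one$coords)

  bad <- withr::local_tempfile()
  writeBin(as.raw(1:32), bad)
  expect_error(read_trajectory(bad), class = "format_error")
})
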