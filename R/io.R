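# Structure and trajectory file I/O.
#
# Proteins come from PDB ATOM records (first MODEL, altloc blank/'A',
# waters and non-amino HETATM excluded); ligands from PDB HETATM blocks or
# SDF V2000. Trajectories use a single-file binary container that mirrors
# an HDF5-style dataset layout (see read_trajectory).

#' Read a rigid protein backbone from a PDB file
#'
#' Extracts one entry per residue holding all three backbone atoms
#' (N, CA, C). Residues missing any backbone atom are dropped with a
#' warning. Only the first MODEL is used; alternate locations other than
#' blank/'A' are discarded; waters and other HETATM records are ignored.
#'
#' @param pdb_source path to a PDB file.
#' @return a [protein_backbone()].
#' @export
read_protein_backbone <- function(pdb_source) {
  pdb <- tryCatch(bio3d::read.pdb(pdb_source, multi = FALSE, verbose = FALSE),
                  error = function(e) {
                    stop_neuralmd(paste0("cannot parse PDB: ",
                                         conditionMessage(e)), "format_error")
                  })
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0L) stop_neuralmd("no amino-acid ATOM records", "empty_protein")
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  keys <- unique(key)  # file order = chain/sequence order
  res <- list(types = character(), n = NULL, ca = NULL, cc = NULL)
  dropped <- 0L
  for (k in keys) {
    sub <- at[key == k, , drop = FALSE]
    xyz <- function(name) {
      r <- sub[sub$elety == name, , drop = FALSE]
      if (nrow(r) == 0L) return(NULL)
      as.numeric(r[1L, c("x", "y", "z")])
    }
    n <- xyz("N"); ca <- xyz("CA"); cc <- xyz("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) {
      dropped <- dropped + 1L
      next
    }
    res$types <- c(res$types, sub$resid[1L])
    res$n <- rbind(res$n, n); res$ca <- rbind(res$ca, ca)
    res$cc <- rbind(res$cc, cc)
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d residue(s) missing backbone atoms", dropped))
  }
  if (length(res$types) < 2L) {
    stop_neuralmd("fewer than 2 complete residues in PDB", "empty_protein")
  }
  rownames(res$n) <- rownames(res$ca) <- rownames(res$cc) <- NULL
  protein_backbone(res$types, res$n, res$ca, res$cc)
}

#' Read a small-molecule ligand
#'
#' @param source path to the structure file.
#' @param format `"pdb-hetatm"` (HETATM records of a PDB file, waters
#'   excluded) or `"sdf"` (V2000 molfile, first molecule).
#' @return a [ligand()]; masses are filled from the standard atomic-weight
#'   table, hydrogens are kept as present in the file.
#' @export
read_ligand <- function(source, format = c("pdb-hetatm", "sdf")) {
  format <- match.arg(format)
  if (format == "pdb-hetatm") read_ligand_pdb(source) else read_ligand_sdf(source)
}

read_ligand_pdb <- function(source) {
  pdb <- tryCatch(bio3d::read.pdb(source, multi = FALSE, verbose = FALSE),
                  error = function(e) {
                    stop_neuralmd(paste0("cannot parse PDB: ",
                                         conditionMessage(e)), "format_error")
                  })
  at <- pdb$atom
  at <- at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) < 2L) stop_neuralmd("no ligand HETATM records", "format_error")
  symb <- at$elesy
  if (any(is.na(symb) | symb == "")) {
    symb <- bio3d::atom2ele(at$elety)
  }
  ligand(element_number(symb), as.matrix(at[, c("x", "y", "z")]))
}

read_ligand_sdf <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) < 4L) stop_neuralmd("truncated SDF", "format_error")
  counts <- lines[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop_neuralmd("bad SDF counts line", "format_error")
  }
  if (length(lines) < 4L + n_atoms) {
    stop_neuralmd("SDF atom block truncated", "format_error")
  }
  block <- lines[5L:(4L + n_atoms)]
  coords <- t(vapply(block, function(l) {
    as.numeric(c(substr(l, 1, 10), substr(l, 11, 20), substr(l, 21, 30)))
  }, numeric(3L), USE.NAMES = FALSE))
  if (anyNA(coords)) stop_neuralmd("bad SDF coordinates", "format_error")
  symb <- trimws(substr(block, 32, 34))
  ligand(element_number(symb), coords)
}

# --- trajectory container --------------------------------------------------

TRAJ_MAGIC <- "NMDTRAJ1"

#' Write a trajectory container file
#'
#' Single-file binary container mirroring an HDF5-style layout: named
#' datasets `/ligand/atomic_numbers`, `/ligand/coordinates` (T x N_l x 3,
#' Angstrom, 64-bit reals), optional `/ligand/velocities`, and for an
#' attached complex `/protein/residue_types` and
#' `/protein/{n,ca,c}_coordinates`, plus the `snapshot_interval` attribute.
#' A JSON header records shapes; payloads are little-endian IEEE-754
#' doubles, so round trips are bitwise exact.
#'
#' @param traj an [trajectory()].
#' @param path output file path.
#' @param complex optional [binding_complex()] whose ligand identity and
#'   protein datasets are stored alongside the snapshots.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, complex = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  datasets <- list("/ligand/coordinates" = traj$coords)
  if (!is.null(traj$velocities)) {
    datasets[["/ligand/velocities"]] <- traj$velocities
  }
  meta <- list(snapshot_interval = traj$snapshot_interval)
  if (!is.null(complex)) {
    datasets[["/ligand/atomic_numbers"]] <-
      as.numeric(complex$ligand$atomic_numbers)
    datasets[["/protein/n_coordinates"]] <- complex$protein$n_coords
    datasets[["/protein/ca_coordinates"]] <- complex$protein$ca_coords
    datasets[["/protein/c_coordinates"]] <- complex$protein$c_coords
    meta$residue_types <- complex$protein$residue_types
    meta$cutoff_c <- complex$cutoff_c
  }
  shapes <- lapply(datasets, function(d) if (is.null(dim(d))) length(d) else dim(d))
  header <- jsonlite::toJSON(list(magic = TRAJ_MAGIC, meta = meta,
                                  shapes = shapes),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 8L, endian = "little")
  writeBin(hraw, con)
  for (nm in names(datasets)) {
    writeBin(as.vector(as.numeric(datasets[[nm]])), con, size = 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read a trajectory container file
#'
#' @param path file written by [write_trajectory()].
#' @return a list with `trajectory` (an `md_trajectory`) and, when protein
#'   datasets are present, `complex` (a [binding_complex()]).
#' @export
read_trajectory <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- tryCatch(readBin(con, "integer", size = 8L, endian = "little"),
                   error = function(e) NA)
  if (is.na(hlen) || hlen <= 0L || hlen > 1e7) {
    stop_neuralmd("not a trajectory container", "format_error")
  }
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                       simplifyVector = TRUE),
    error = function(e) stop_neuralmd("corrupt container header", "format_error"))
  if (!identical(header$magic, TRAJ_MAGIC)) {
    stop_neuralmd("bad container magic", "format_error")
  }
  shapes <- header$shapes
  if (is.null(shapes[["/ligand/coordinates"]])) {
    stop_neuralmd("missing dataset /ligand/coordinates", "format_error")
  }
  datasets <- list()
  for (nm in names(shapes)) {
    shp <- as.integer(shapes[[nm]])
    n <- prod(shp)
    v <- readBin(con, "double", n, size = 8L, endian = "little")
    if (length(v) != n) {
      stop_neuralmd(sprintf("dataset %s shape mismatch", nm), "format_error")
    }
    datasets[[nm]] <- if (length(shp) > 1L) array(v, shp) else v
  }
  traj <- trajectory(datasets[["/ligand/coordinates"]],
                     velocities = datasets[["/ligand/velocities"]],
                     snapshot_interval = header$meta$snapshot_interval)
  out <- list(trajectory = traj)
  if (!is.null(datasets[["/protein/ca_coordinates"]])) {
    prot <- protein_backbone(header$meta$residue_types,
                             datasets[["/protein/n_coordinates"]],
                             datasets[["/protein/ca_coordinates"]],
                             datasets[["/protein/c_coordinates"]])
    lig <- ligand(datasets[["/ligand/atomic_numbers"]],
                  matrix(traj$coords[1L, , ], ncol = 3L))
    cc <- header$meta$cutoff_c
    out$complex <- binding_complex(lig, prot,
                                   cutoff_c = if (is.null(cc)) 5.0 else cc)
  }
  out
}
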