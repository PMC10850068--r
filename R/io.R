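## Frame-ensemble readers and writers: a plain-text CSV serialization used
## by the synthetic mini-databank, and a multi-model PDB import via bio3d
## for standard-format trajectories.

#' Write / read a FrameEnsemble as CSV
#'
#' The native plain-text serialization: a topology CSV (one row per atom:
#' molecule, resid, name, electrons) and a trajectory CSV (one row per frame
#' per atom: frame, time, Lx, Ly, Lz, x, y, z in nm/ns, atoms in topology
#' order).
#'
#' @param traj a \linkS4class{FrameEnsemble}.
#' @param trajectory_path,topology_path output/input CSV paths.
#' @return \code{writeFrameEnsembleCSV} returns the paths invisibly;
#'   \code{readFrameEnsembleCSV} the \linkS4class{FrameEnsemble}.
#' @export
writeFrameEnsembleCSV <- function(traj, trajectory_path, topology_path) {
  utils::write.csv(traj@atoms, topology_path, row.names = FALSE, quote = FALSE)
  nf <- nFrames(traj); na <- nAtoms(traj)
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    time = rep(traj@times, each = na),
    Lx = rep(traj@box[, 1], each = na),
    Ly = rep(traj@box[, 2], each = na),
    Lz = rep(traj@box[, 3], each = na),
    x = as.vector(t(traj@coords[, , 1])),
    y = as.vector(t(traj@coords[, , 2])),
    z = as.vector(t(traj@coords[, , 3])))
  utils::write.csv(df, trajectory_path, row.names = FALSE, quote = FALSE)
  invisible(c(trajectory_path, topology_path))
}

#' @rdname writeFrameEnsembleCSV
#' @export
readFrameEnsembleCSV <- function(trajectory_path, topology_path) {
  atoms <- utils::read.csv(topology_path, stringsAsFactors = FALSE)
  df <- utils::read.csv(trajectory_path)
  frames <- unique(df$frame)
  nf <- length(frames); na <- nrow(atoms)
  stopifnot(nrow(df) == nf * na)
  coords <- array(0, dim = c(nf, na, 3))
  coords[, , 1] <- matrix(df$x, nf, na, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nf, na, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nf, na, byrow = TRUE)
  first <- !duplicated(df$frame)
  FrameEnsemble(coords,
                box = cbind(df$Lx[first], df$Ly[first], df$Lz[first]),
                times = df$time[first], atoms = atoms)
}

#' Read a multi-model PDB trajectory into a FrameEnsemble
#'
#' Imports a multi-model PDB file through bio3d. Coordinates are converted
#' from Angstrom to nm. Electron counts are assigned from the element symbol
#' (first letter of the atom name when the element field is absent); box
#' dimensions are taken from \code{box} (nm) since CRYST1 records are often
#' absent from trajectory exports.
#'
#' @param path PDB file with one MODEL per frame.
#' @param box length-3 box vector or \code{[n_frames, 3]} matrix, nm.
#' @param molecule_of function mapping a residue name to a universal
#'   molecule name (default: identity).
#' @param dt frame spacing, ns (default 1).
#' @return A \linkS4class{FrameEnsemble}.
#' @export
readFrameEnsemblePDB <- function(path, box, molecule_of = identity, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                              # [n_frames, 3*n_atoms], Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(0, dim = c(nf, na, 3))
  for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, by = 3,
                                              length.out = na)] / 10
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9']", "", pdb$atom$elety), 1, 1)
  periodic <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
  electrons <- periodic[toupper(elem)]
  if (anyNA(electrons))
    stop("cannot assign electron counts for element(s): ",
         paste(unique(elem[is.na(electrons)]), collapse = ", "))
  atoms <- data.frame(
    molecule = vapply(pdb$atom$resid, function(r)
      as.character(molecule_of(r)), character(1)),
    resid = as.integer(pdb$atom$resno),
    name = pdb$atom$elety,
    electrons = as.numeric(electrons), stringsAsFactors = FALSE)
  FrameEnsemble(coords, box = box, times = (seq_len(nf) - 1) * dt,
                atoms = atoms)
}

#' Write a JSON artifact in the databank layout
#'
#' Thin wrapper fixing the JSON conventions used for all databank artifacts
#' (scalars unboxed, full precision, nulls for NA).
#'
#' @param x object to serialize.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeDatabankJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
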