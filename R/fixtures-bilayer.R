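## A schematic bilayer FrameEnsemble exercising the whole analysis pipeline.

.toy_lipid_atoms <- data.frame(
  universal_atom = c("N1", "C1", "C1H1", "G1", "G1H1",
                     "C2", "C2H1", "C3", "C3H1",
                     "C21", "C21H1", "C22", "C22H1"),
  ff_atom = c("N", "C11", "H11", "G1", "HG1",
              "C2", "H2", "C3", "H3", "C21", "H21", "C22", "H22"),
  fragment = c("headgroup", "headgroup", "headgroup",
               "glycerol backbone", "glycerol backbone",
               "acyl chain sn-1", "acyl chain sn-1",
               "acyl chain sn-1", "acyl chain sn-1",
               "acyl chain sn-2", "acyl chain sn-2",
               "acyl chain sn-2", "acyl chain sn-2"),
  electrons = c(7, 6, 1, 6, 1, 6, 1, 6, 1, 6, 1, 6, 1),
  stringsAsFactors = FALSE)

## depth of each heavy atom below the leaflet surface, as a fraction of the
## monolayer thickness, and lateral offsets (nm) giving the molecule a
## non-degenerate three-dimensional shape
.toy_depth <- c(N1 = 0.05, C1 = 0.15, G1 = 0.30, C2 = 0.50, C3 = 0.75,
                C21 = 0.50, C22 = 0.75)
.toy_offset <- rbind(N1 = c(0, 0), C1 = c(0.05, 0.02), G1 = c(0, 0.06),
                     C2 = c(0.15, 0), C3 = c(0.18, 0.05),
                     C21 = c(-0.15, 0), C22 = c(-0.18, -0.05))

#' Mapping table of the schematic bilayer lipid
#'
#' @return A \linkS4class{MappingTable} for the toy POPC used by
#'   \code{\link{makeSyntheticBilayer}}.
#' @export
toyLipidMapping <- function() {
  MappingTable("POPC_toy", .toy_lipid_atoms[, c("universal_atom", "ff_atom",
                                                "fragment")])
}

#' Schematic bilayer trajectory with known observables
#'
#' Generates a \linkS4class{FrameEnsemble} of a flat bilayer: lipids on a
#' grid in two leaflets (heads out, chains in), C-H bonds oriented at the
#' fixed polar angle realizing prescribed order parameters per fragment,
#' pseudo-water atoms filling the space outside the slab with a bulk-like
#' electron density, and a box whose lateral area realizes a prescribed area
#' per lipid. Not a physical membrane: an oracle carrying exact targets for
#' area per lipid, approximate targets for thickness and order parameters,
#' and a slab-like form factor.
#'
#' @param n_lipids total number of lipids (both leaflets; should be even
#'   with a square per-leaflet grid).
#' @param apl target area per lipid, Angstrom^2 (exact by construction).
#' @param thickness target bilayer thickness, nm (slab half-width used for
#'   atom placement and water exclusion).
#' @param S_chain,S_head target order parameters of chain and headgroup
#'   bonds.
#' @param n_frames,dt frames and spacing (ns).
#' @param water_height water layer height on each side, nm.
#' @param jitter positional noise amplitude, nm.
#' @param jitter_tau correlation time of the positional noise, ns
#'   (0 = white); slow noise mimics poorly sampled conformations and raises
#'   tau_rel.
#' @param seed integer seed.
#' @return list with \code{traj}, \code{mapping}
#'   (\linkS4class{MappingTable}), \code{n_lipids}, targets (\code{apl},
#'   \code{thickness}, \code{S_chain}, \code{S_head}) and \code{water_e}
#'   (electrons per pseudo-water).
#' @export
makeSyntheticBilayer <- function(n_lipids = 32, apl = 64, thickness = 4,
                                 S_chain = -0.18, S_head = -0.05,
                                 n_frames = 60, dt = 1, water_height = 1,
                                 jitter = 0.02, jitter_tau = 0, seed = 1) {
  set.seed(seed)
  per_leaf <- n_lipids / 2
  grid_n <- ceiling(sqrt(per_leaf))
  L <- sqrt(per_leaf * apl) / 10                     # nm
  Lz <- thickness + 2 * water_height
  half <- thickness / 2
  la <- .toy_lipid_atoms
  n_la <- nrow(la)
  heavy <- la$universal_atom[!grepl("H[0-9]*$", la$universal_atom) |
                               grepl("^H", la$universal_atom)]

  ## static head positions of each lipid
  lipid_xy <- cbind(((seq_len(per_leaf) - 1) %% grid_n + 0.5) * L / grid_n,
                    ((seq_len(per_leaf) - 1) %/% grid_n + 0.5) * L / grid_n)
  lipid_xy <- rbind(lipid_xy, lipid_xy)
  leaflet <- rep(c(1, -1), each = per_leaf)

  n_wat <- max(20L, 4L * n_lipids)
  water_e <- 0.333 * (L * L * 100) * (water_height * 10) * 2 / n_wat
  n_atoms <- n_lipids * n_la + n_wat
  coords <- array(0, dim = c(n_frames, n_atoms, 3))

  cos_t <- function(S) sqrt((2 * S + 1) / 3)
  bond_len <- 0.109
  S_of <- stats::setNames(
    ifelse(la$fragment == "headgroup", S_head,
           ifelse(la$fragment == "glycerol backbone", S_head, S_chain)),
    la$universal_atom)

  ## temporally correlated positional noise, independent per heavy atom
  n_heavy <- length(.toy_depth)
  noise <- array(stats::rnorm(n_frames * n_lipids * n_heavy * 3, 0, jitter),
                 dim = c(n_frames, n_lipids, n_heavy, 3))
  if (jitter_tau > 0) {
    phi <- exp(-dt / jitter_tau)
    for (f in 2:n_frames)
      noise[f, , , ] <- phi * noise[f - 1, , , ] +
        sqrt(1 - phi^2) * noise[f, , , ]
  }

  for (li in seq_len(n_lipids)) {
    base_idx <- (li - 1L) * n_la
    zsurf <- leaflet[li] * half
    for (f in seq_len(n_frames)) {
      heavy_pos <- list()
      for (a in seq_len(n_la)) {
        nm <- la$universal_atom[a]
        if (nm %in% names(.toy_depth)) {
          hi <- match(nm, names(.toy_depth))
          z <- zsurf - leaflet[li] * .toy_depth[[nm]] * half
          p <- c(lipid_xy[li, 1] + .toy_offset[nm, 1] + noise[f, li, hi, 1],
                 lipid_xy[li, 2] + .toy_offset[nm, 2] + noise[f, li, hi, 2],
                 z + noise[f, li, hi, 3])
          heavy_pos[[nm]] <- p
          coords[f, base_idx + a, ] <- p
        } else {
          carbon <- sub("H[0-9]*$", "", nm)
          ct <- cos_t(S_of[[nm]])
          phi_a <- stats::runif(1, 0, 2 * pi)
          dir <- c(sqrt(1 - ct^2) * cos(phi_a), sqrt(1 - ct^2) * sin(phi_a),
                   ct)
          coords[f, base_idx + a, ] <- heavy_pos[[carbon]] + bond_len * dir
        }
      }
    }
  }

  ## pseudo-water fills |z| in (half, Lz/2)
  wat0 <- n_lipids * n_la
  for (w in seq_len(n_wat)) {
    sgn <- if (w %% 2L == 0L) 1 else -1
    coords[, wat0 + w, 1] <- stats::runif(n_frames, 0, L)
    coords[, wat0 + w, 2] <- stats::runif(n_frames, 0, L)
    coords[, wat0 + w, 3] <- sgn * stats::runif(n_frames, half + 0.02,
                                                Lz / 2 - 0.02)
  }

  atoms <- rbind(
    data.frame(molecule = "POPC",
               resid = rep(seq_len(n_lipids), each = n_la),
               name = rep(la$universal_atom, n_lipids),
               electrons = rep(la$electrons, n_lipids),
               stringsAsFactors = FALSE),
    data.frame(molecule = "SOL", resid = n_lipids + seq_len(n_wat),
               name = "OW", electrons = water_e, stringsAsFactors = FALSE))

  traj <- FrameEnsemble(coords, box = c(L, L, Lz),
                        times = (seq_len(n_frames) - 1) * dt, atoms = atoms)
  list(traj = traj, mapping = toyLipidMapping(), n_lipids = n_lipids,
       apl = apl, thickness = thickness, S_chain = S_chain, S_head = S_head,
       water_e = water_e)
}
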