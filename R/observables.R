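## Basic per-simulation membrane observables.

#' C-H bond order parameters
#'
#' Computes S_CH = 1/2 <3 cos^2(theta) - 1> for each C-H bond, where theta is
#' the angle between the bond vector and the membrane normal (z axis). The
#' order parameter is first averaged over frames separately for each lipid,
#' and the mean, variance and standard error of the mean are then taken over
#' the per-lipid values, so the error estimate reflects the number of
#' independent lipids rather than correlated frames.
#'
#' @param traj a \linkS4class{FrameEnsemble} with explicit hydrogens.
#' @param bonds data.frame with columns \code{carbon} and \code{hydrogen}
#'   (universal atom names within one lipid type), e.g. from
#'   \code{\link{bondsFromMapping}}.
#' @param molecule universal molecule name whose bonds are analysed.
#' @return An \linkS4class{OrderParameterSet}.
#' @export
orderParameters <- function(traj, bonds, molecule) {
  atoms <- traj@atoms
  sel <- atoms$molecule == molecule
  resids <- sort(unique(atoms$resid[sel]))
  if (!length(resids)) stop("input error: no atoms of molecule ", molecule)
  co <- traj@coords
  rows <- lapply(seq_len(nrow(bonds)), function(b) {
    c_idx <- vapply(resids, function(r) {
      i <- which(sel & atoms$resid == r & atoms$name == bonds$carbon[b])
      if (length(i) != 1L) NA_integer_ else i
    }, integer(1))
    h_idx <- vapply(resids, function(r) {
      i <- which(sel & atoms$resid == r & atoms$name == bonds$hydrogen[b])
      if (length(i) != 1L) NA_integer_ else i
    }, integer(1))
    if (anyNA(h_idx))
      stop("unsupported-topology error: hydrogen '", bonds$hydrogen[b],
           "' missing for molecule ", molecule,
           " (united-atom trajectories are not supported)")
    if (anyNA(c_idx))
      stop("input error: carbon '", bonds$carbon[b], "' missing for molecule ",
           molecule)
    ## [n_frames, n_lipids] matrices of bond vector components
    dx <- co[, h_idx, 1, drop = FALSE] - co[, c_idx, 1, drop = FALSE]
    dy <- co[, h_idx, 2, drop = FALSE] - co[, c_idx, 2, drop = FALSE]
    dz <- co[, h_idx, 3, drop = FALSE] - co[, c_idx, 3, drop = FALSE]
    cos2 <- dz^2 / (dx^2 + dy^2 + dz^2)
    per_lipid <- colMeans(0.5 * (3 * cos2 - 1))   # average frames first
    n <- length(per_lipid)
    s <- if (n > 1) stats::var(per_lipid) else 0
    data.frame(bond = paste(bonds$carbon[b], bonds$hydrogen[b]),
               carbon = bonds$carbon[b], hydrogen = bonds$hydrogen[b],
               S_mean = mean(per_lipid), s = s, n = n,
               sem = sqrt(s) / sqrt(n), stringsAsFactors = FALSE)
  })
  new("OrderParameterSet", data = do.call(rbind, rows))
}

#' Electron density profile across the bilayer
#'
#' Histograms electron-weighted atom positions along z with a 1/3 Angstrom
#' bin width, after centring each frame on the electron-weighted centre of
#' the lipid selection (so the profile is invariant under rigid translations
#' of the system) and wrapping positions into the box. The per-frame
#' histograms are averaged over frames. The solvent-subtracted contrast
#' delta_rho is the total density minus the solvent density completed to its
#' bulk plateau: the plateau is estimated from the outer 20\% of the box and
#' the solvent profile is raised to it inside the membrane core, which makes
#' delta_rho vanish in bulk by construction.
#'
#' @param traj a \linkS4class{FrameEnsemble}.
#' @param lipid_selection,solvent_selection logical or integer atom indices;
#'   the lipid selection defines the centring, the solvent selection the
#'   subtracted background. \code{solvent_selection} may be empty, in which
#'   case no background is subtracted.
#' @param bin_width histogram bin width, Angstrom (default 1/3).
#' @return An \linkS4class{ElectronDensityProfile} (z in Angstrom, densities
#'   in e/Angstrom^3).
#' @export
electronDensityProfile <- function(traj, lipid_selection,
                                   solvent_selection = integer(0),
                                   bin_width = 1/3) {
  atoms <- traj@atoms
  lip <- .as_index(lipid_selection, nrow(atoms))
  sol <- .as_index(solvent_selection, nrow(atoms))
  if (!length(lip)) stop("input error: empty lipid selection")
  co <- traj@coords
  nf <- dim(co)[1]
  Lz <- mean(traj@box[, 3]) * 10                       # Angstrom
  nbins <- max(1L, round(Lz / bin_width))
  edges <- seq(-Lz / 2, Lz / 2, length.out = nbins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  el <- atoms$electrons
  tot <- matrix(0, nf, nbins); solv <- matrix(0, nf, nbins)
  for (f in seq_len(nf)) {
    z <- co[f, , 3] * 10                                # Angstrom
    zc <- if (sum(el[lip]) > 0) sum(z[lip] * el[lip]) / sum(el[lip])
          else mean(z[lip])
    zrel <- (z - zc + Lz / 2) %% Lz - Lz / 2            # wrap into [-Lz/2, Lz/2)
    area <- traj@box[f, 1] * traj@box[f, 2] * 100       # Angstrom^2
    vol <- area * (Lz / nbins)
    bin <- pmin(pmax(findInterval(zrel, edges, rightmost.closed = TRUE), 1L),
                nbins)
    tot[f, ] <- as.numeric(tapply(el, factor(bin, levels = seq_len(nbins)),
                                  sum, default = 0)) / vol
    if (length(sol))
      solv[f, ] <- as.numeric(tapply(
        el[sol] * 1, factor(bin[sol], levels = seq_len(nbins)), sum,
        default = 0)) / vol
  }
  rho_tot <- colMeans(tot)
  rho_sol <- colMeans(solv)
  if (length(sol)) {
    outer <- centers < min(centers) + 0.1 * Lz | centers > max(centers) - 0.1 * Lz
    plateau <- mean(rho_sol[outer])
    completed <- pmax(rho_sol, plateau)
  } else completed <- rho_sol
  new("ElectronDensityProfile", binCenters = centers, rhoTotal = rho_tot,
      rhoSolvent = rho_sol, deltaRho = rho_tot - completed,
      binWidth = Lz / nbins)
}

.as_index <- function(sel, n) {
  if (is.logical(sel)) which(sel) else as.integer(sel)
}

#' X-ray scattering form factor from a density profile
#'
#' Computes F(q) = | integral of delta_rho(z) exp(i q z) dz | by the midpoint
#' rule on the histogram grid. No symmetry of the membrane is assumed: real
#' and imaginary parts are accumulated separately and the modulus returned.
#'
#' @param profile an \linkS4class{ElectronDensityProfile}.
#' @param q_max upper end of the q grid, 1/Angstrom (default 1).
#' @param dq q grid spacing, 1/Angstrom (default 0.005).
#' @return A \linkS4class{FormFactorCurve} (|F| in e/Angstrom^2).
#' @export
formFactor <- function(profile, q_max = 1, dq = 0.005) {
  q <- seq(0, q_max, by = dq)
  z <- profile@binCenters
  w <- profile@deltaRho * profile@binWidth
  re <- vapply(q, function(qi) sum(w * cos(qi * z)), numeric(1))
  im <- vapply(q, function(qi) sum(w * sin(qi * z)), numeric(1))
  new("FormFactorCurve", q = q, F = sqrt(re^2 + im^2))
}

#' Area per lipid
#'
#' Time-averaged lateral box area divided by the number of membrane molecules
#' per leaflet: APL = 2 <Lx Ly> / N, with N the total number of lipid and
#' surfactant molecules in the simulation. The per-leaflet convention
#' reproduces the conventional 40-75 Angstrom^2 scale of fluid bilayers.
#'
#' @param traj a \linkS4class{FrameEnsemble}.
#' @param n_membrane_molecules total number of membrane molecules (both
#'   leaflets); defaults to the count of distinct membrane molecules in the
#'   atom table.
#' @return Numeric scalar, Angstrom^2.
#' @export
areaPerLipid <- function(traj, n_membrane_molecules = NULL) {
  if (is.null(n_membrane_molecules)) {
    a <- traj@atoms
    memb <- unique(a[isMembraneMolecule(a$molecule), c("molecule", "resid")])
    n_membrane_molecules <- nrow(memb)
  }
  if (!isTRUE(n_membrane_molecules > 0))
    stop("input error: number of membrane molecules must be > 0")
  mean_area <- mean(traj@box[, 1] * traj@box[, 2]) * 100   # Angstrom^2
  2 * mean_area / n_membrane_molecules
}

#' Bilayer thickness from density-profile intersections
#'
#' The thickness is the distance between the two z positions where the lipid
#' and water electron densities cross, one on each side of the membrane,
#' located by linear interpolation between histogram bins. With noisy
#' profiles showing multiple sign changes per side, the outermost crossing on
#' each side is used.
#'
#' @param lipid_profile,water_profile numeric density vectors on a shared
#'   grid, or \linkS4class{ElectronDensityProfile} objects (total and solvent
#'   densities are then taken from the first argument).
#' @param z bin centres in Angstrom (ignored when profiles are S4 objects).
#' @return Thickness in nm.
#' @export
bilayerThickness <- function(lipid_profile, water_profile = NULL, z = NULL) {
  if (is(lipid_profile, "ElectronDensityProfile")) {
    z <- lipid_profile@binCenters
    lip <- lipid_profile@rhoTotal - lipid_profile@rhoSolvent
    wat <- lipid_profile@rhoSolvent
  } else {
    lip <- lipid_profile; wat <- water_profile
  }
  d <- lip - wat
  sgn <- sign(d)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0 |
                (sgn[-length(sgn)] != 0 & sgn[-1] == 0))
  cross_z <- vapply(ch, function(i)
    z[i] + (z[i + 1] - z[i]) * d[i] / (d[i] - d[i + 1]), numeric(1))
  left <- cross_z[cross_z < 0]; right <- cross_z[cross_z > 0]
  if (!length(left) || !length(right))
    stop("thickness-undefined error: no lipid/water density crossing on ",
         if (!length(left)) "the lower side" else "the upper side")
  (max(right) - min(left)) / 10                            # nm
}
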