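#' @import methods
NULL

## Central containers of the package. Coordinates are stored in nm, times in
## ns, electron-density grids in Angstrom; functions state their units.

#' FrameEnsemble: a time series of atom coordinates with box vectors
#'
#' Holds per-frame Cartesian coordinates (nm) of all atoms, per-frame
#' orthorhombic box dimensions (nm), frame timestamps (ns), and an atom table
#' carrying the molecule identity, residue instance, universal atom name and
#' electron count of each atom. The membrane normal is the z axis by
#' convention.
#'
#' @slot coords numeric array \code{[n_frames, n_atoms, 3]}, nm.
#' @slot box numeric matrix \code{[n_frames, 3]} of (Lx, Ly, Lz), nm.
#' @slot times numeric vector of frame times, ns.
#' @slot atoms data.frame with columns \code{molecule} (universal molecule
#'   name), \code{resid} (integer molecule instance), \code{name} (atom name)
#'   and \code{electrons} (number of electrons, >= 0).
#' @exportClass FrameEnsemble
setClass("FrameEnsemble",
  representation(coords = "array", box = "matrix", times = "numeric",
                 atoms = "data.frame"))

setValidity("FrameEnsemble", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an [n_frames, n_atoms, 3] array")
  else {
    if (nrow(object@box) != d[1] || ncol(object@box) != 3L)
      msg <- c(msg, "box must be an [n_frames, 3] matrix")
    if (length(object@times) != d[1])
      msg <- c(msg, "times must have one entry per frame")
    if (nrow(object@atoms) != d[2])
      msg <- c(msg, "atom table must have one row per atom")
  }
  req <- c("molecule", "resid", "name", "electrons")
  if (!all(req %in% names(object@atoms)))
    msg <- c(msg, paste("atom table needs columns:", paste(req, collapse = ", ")))
  else if (any(object@atoms$electrons < 0))
    msg <- c(msg, "electron counts must be >= 0")
  if (any(object@box <= 0)) msg <- c(msg, "box dimensions must be positive")
  if (length(msg)) msg else TRUE
})

#' SimulationEntry: metadata of one databank simulation
#'
#' The in-memory form of a README.yaml databank entry: raw-data link, file
#' names, software and force field, thermodynamic conditions, the molecular
#' composition with force-field residue names and mapping-table associations,
#' and the user-declared equilibration period to discard. Unknown YAML keys
#' are preserved in \code{extras} so that an evolving on-disk schema
#' round-trips unchanged.
#'
#' @slot entryId character, hash-derived identifier (may be \code{NA} until
#'   computed from the raw files).
#' @slot rawDataLink DOI or URL of the raw data.
#' @slot trajectoryName,topologyName file names of the raw data.
#' @slot software,forceField character.
#' @slot temperature numeric, K.
#' @slot composition data.frame with columns \code{molecule} (universal name),
#'   \code{ff_name}, \code{mapping}, \code{count}.
#' @slot counterions character or \code{NA}.
#' @slot trajectoryLength numeric, ns.
#' @slot equilibrationDiscard numeric, ns (the TIMELEFTOUT of the entry).
#' @slot waterPerLipid numeric, molar water-to-lipid ratio.
#' @slot extras list of preserved unknown keys.
#' @exportClass SimulationEntry
setClass("SimulationEntry",
  representation(entryId = "character", rawDataLink = "character",
                 trajectoryName = "character", topologyName = "character",
                 software = "character", forceField = "character",
                 temperature = "numeric", composition = "data.frame",
                 counterions = "character", trajectoryLength = "numeric",
                 equilibrationDiscard = "numeric", waterPerLipid = "numeric",
                 extras = "list"))

setValidity("SimulationEntry", function(object) {
  msg <- character()
  comp <- object@composition
  req <- c("molecule", "ff_name", "mapping", "count")
  if (!all(req %in% names(comp)))
    msg <- c(msg, paste("composition needs columns:", paste(req, collapse = ", ")))
  else {
    if (any(comp$count < 0)) msg <- c(msg, "composition counts must be >= 0")
    unknown <- setdiff(comp$molecule, knownMolecules())
    if (length(unknown))
      msg <- c(msg, paste("unknown universal molecule name(s):",
                          paste(unknown, collapse = ", ")))
  }
  if (!isTRUE(object@temperature > 0)) msg <- c(msg, "temperature must be > 0 K")
  if (is.finite(object@trajectoryLength) &&
      !isTRUE(object@equilibrationDiscard < object@trajectoryLength))
    msg <- c(msg, "equilibration discard must be shorter than the trajectory")
  if (length(msg)) msg else TRUE
})

#' MappingTable: force-field to universal atom-name translation
#'
#' Associates force-field-specific atom names with universal atom names and
#' assigns each atom to a molecular fragment (headgroup, glycerol backbone,
#' acyl chains, other).
#'
#' @slot id character mapping-table identifier.
#' @slot rows data.frame with columns \code{universal_atom}, \code{ff_atom},
#'   \code{fragment}.
#' @exportClass MappingTable
setClass("MappingTable",
  representation(id = "character", rows = "data.frame"))

.fragments <- c("headgroup", "glycerol backbone", "acyl chain sn-1",
                "acyl chain sn-2", "other")

setValidity("MappingTable", function(object) {
  msg <- character()
  req <- c("universal_atom", "ff_atom", "fragment")
  if (!all(req %in% names(object@rows)))
    msg <- c(msg, paste("rows needs columns:", paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(object@rows$universal_atom))
      msg <- c(msg, "universal atom names must be unique within a table")
    bad <- setdiff(unique(object@rows$fragment), .fragments)
    if (length(bad))
      msg <- c(msg, paste("unknown fragment label(s):", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ExperimentEntry: one experimental data set
#'
#' Either a set of NMR C-H bond order parameters or an X-ray scattering form
#' factor, with the measurement conditions needed for simulation matching.
#'
#' @slot kind \code{"NMR-order-parameters"} or \code{"X-ray-form-factor"}.
#' @slot conditions list with elements \code{composition} (named molar
#'   percentages over membrane molecules), \code{counterions},
#'   \code{temperature} (K) and \code{waterPerLipid}.
#' @slot opData data.frame (\code{bond}, \code{S_exp}, \code{dS_exp}); empty
#'   for form-factor entries.
#' @slot ffData data.frame (\code{q} in 1/Angstrom, \code{F}, \code{dF},
#'   relative intensity); empty for NMR entries.
#' @exportClass ExperimentEntry
setClass("ExperimentEntry",
  representation(kind = "character", conditions = "list",
                 opData = "data.frame", ffData = "data.frame"))

setValidity("ExperimentEntry", function(object) {
  msg <- character()
  if (!object@kind %in% c("NMR-order-parameters", "X-ray-form-factor"))
    msg <- c(msg, "kind must be 'NMR-order-parameters' or 'X-ray-form-factor'")
  if (nrow(object@opData) && any(object@opData$dS_exp <= 0))
    msg <- c(msg, "experimental order-parameter errors must be > 0")
  if (nrow(object@ffData) > 1 && any(diff(object@ffData$q) <= 0))
    msg <- c(msg, "experimental q grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' OrderParameterSet: per-bond C-H order parameters with lipid statistics
#'
#' One row per C-H bond: the mean order parameter over lipids and frames, the
#' variance of the per-lipid means, the number of lipids, and the standard
#' error of the mean over lipids.
#'
#' @slot data data.frame with columns \code{bond}, \code{carbon},
#'   \code{hydrogen}, \code{S_mean}, \code{s} (variance over lipids),
#'   \code{n}, \code{sem}.
#' @exportClass OrderParameterSet
setClass("OrderParameterSet", representation(data = "data.frame"))

setValidity("OrderParameterSet", function(object) {
  d <- object@data
  msg <- character()
  req <- c("bond", "carbon", "hydrogen", "S_mean", "s", "n", "sem")
  if (!all(req %in% names(d)))
    msg <- c(msg, paste("data needs columns:", paste(req, collapse = ", ")))
  else {
    if (any(d$S_mean < -0.5 - 1e-9 | d$S_mean > 1 + 1e-9))
      msg <- c(msg, "order parameters must lie in [-0.5, 1]")
    if (any(d$n < 1)) msg <- c(msg, "n must be >= 1")
    if (any(d$sem < 0)) msg <- c(msg, "sem must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' ElectronDensityProfile: z-resolved electron densities across the bilayer
#'
#' Histograms of electron density along the membrane normal on a uniform
#' 1/3-Angstrom grid, centred on the lipid centre of mass: total density,
#' solvent density, and the solvent-subtracted contrast used for the form
#' factor.
#'
#' @slot binCenters numeric, z in Angstrom (uniform grid).
#' @slot rhoTotal,rhoSolvent,deltaRho numeric, e/Angstrom^3.
#' @slot binWidth numeric, Angstrom.
#' @exportClass ElectronDensityProfile
setClass("ElectronDensityProfile",
  representation(binCenters = "numeric", rhoTotal = "numeric",
                 rhoSolvent = "numeric", deltaRho = "numeric",
                 binWidth = "numeric"))

setValidity("ElectronDensityProfile", function(object) {
  msg <- character()
  n <- length(object@binCenters)
  if (length(object@rhoTotal) != n || length(object@rhoSolvent) != n ||
      length(object@deltaRho) != n)
    msg <- c(msg, "all profiles must share the bin grid")
  if (n > 1) {
    dz <- diff(object@binCenters)
    if (max(abs(dz - dz[1])) > 1e-8 * abs(dz[1]))
      msg <- c(msg, "bins must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' FormFactorCurve: X-ray scattering form factor |F(q)|
#'
#' @slot q numeric, scattering vector in 1/Angstrom, increasing.
#' @slot F numeric, |F(q)| in e/Angstrom^2, >= 0.
#' @exportClass FormFactorCurve
setClass("FormFactorCurve", representation(q = "numeric", F = "numeric"))

setValidity("FormFactorCurve", function(object) {
  msg <- character()
  if (length(object@q) != length(object@F))
    msg <- c(msg, "q and F must have equal length")
  if (length(object@q) > 1 && any(diff(object@q) <= 0))
    msg <- c(msg, "q grid must be increasing")
  if (any(object@F < -1e-12)) msg <- c(msg, "|F| must be >= 0")
  if (length(msg)) msg else TRUE
})

#' EquilibrationReport: conformational-sampling convergence of a lipid type
#'
#' Stores the autocorrelation decay time of the first principal component,
#' the derived distribution-convergence time (k times the decay time, with the
#' empirical calibration k = 49), the analysed simulation length, and their
#' ratio tau_rel. tau_rel > 1 signals that individual lipids may not have
#' sampled their conformational ensemble.
#'
#' @slot tauAuto,tauConvergence,tauSim numeric, ns.
#' @slot tauRel numeric, dimensionless.
#' @slot k numeric calibration constant (49).
#' @slot converged logical; FALSE when the autocorrelation never decayed
#'   below 1/e within the series.
#' @exportClass EquilibrationReport
setClass("EquilibrationReport",
  representation(tauAuto = "numeric", tauConvergence = "numeric",
                 tauSim = "numeric", tauRel = "numeric", k = "numeric",
                 converged = "logical"))

setValidity("EquilibrationReport", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@tauConvergence, object@k * object@tauAuto)))
    msg <- c(msg, "tauConvergence must equal k * tauAuto")
  if (object@tauSim > 0 &&
      !isTRUE(all.equal(object@tauRel, object@tauConvergence / object@tauSim)))
    msg <- c(msg, "tauRel must equal tauConvergence / tauSim")
  if (length(msg)) msg else TRUE
})
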