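#' Construct a FrameEnsemble
#'
#' @param coords array \code{[n_frames, n_atoms, 3]}, nm.
#' @param box matrix \code{[n_frames, 3]} (nm) or a length-3 vector recycled
#'   to all frames.
#' @param times numeric frame times (ns); defaults to 0, 1, ... frames.
#' @param atoms data.frame with \code{molecule}, \code{resid}, \code{name},
#'   \code{electrons}.
#' @return A \linkS4class{FrameEnsemble}.
#' @export
FrameEnsemble <- function(coords, box, times = NULL, atoms) {
  nf <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- seq_len(nf) - 1
  new("FrameEnsemble", coords = coords, box = box, times = as.numeric(times),
      atoms = as.data.frame(atoms, stringsAsFactors = FALSE))
}

#' @rdname FrameEnsemble
#' @param object,x a FrameEnsemble.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname FrameEnsemble
#' @export
setMethod("nFrames", "FrameEnsemble", function(x) dim(x@coords)[1])

#' @rdname FrameEnsemble
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname FrameEnsemble
#' @export
setMethod("nAtoms", "FrameEnsemble", function(x) dim(x@coords)[2])

#' @rdname FrameEnsemble
#' @export
setGeneric("frameCoords", function(x) standardGeneric("frameCoords"))
#' @rdname FrameEnsemble
#' @export
setMethod("frameCoords", "FrameEnsemble", function(x) x@coords)

#' @rdname FrameEnsemble
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))
#' @rdname FrameEnsemble
#' @export
setMethod("boxDims", "FrameEnsemble", function(x) x@box)

#' @rdname FrameEnsemble
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname FrameEnsemble
#' @export
setMethod("frameTimes", "FrameEnsemble", function(x) x@times)

#' @rdname FrameEnsemble
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname FrameEnsemble
#' @export
setMethod("atomData", "FrameEnsemble", function(x) x@atoms)

setMethod("show", "FrameEnsemble", function(object) {
  cat("FrameEnsemble:", nFrames(object), "frames,", nAtoms(object), "atoms\n")
  cat("  molecules:",
      paste(sprintf("%s(%d)", names(tb <- table(unique(
        object@atoms[, c("molecule", "resid")])$molecule)), tb),
        collapse = ", "), "\n")
  cat("  mean box [nm]:",
      paste(sprintf("%.2f", colMeans(object@box)), collapse = " x "), "\n")
  cat("  time span [ns]:", min(object@times), "-", max(object@times), "\n")
})

#' Accessors for OrderParameterSet
#'
#' @param x an \linkS4class{OrderParameterSet}.
#' @return \code{opData()} returns the underlying data.frame with one row per
#'   C-H bond (\code{S_mean}, variance \code{s}, \code{n}, \code{sem}).
#' @export
setGeneric("opData", function(x) standardGeneric("opData"))
#' @rdname opData
#' @export
setMethod("opData", "OrderParameterSet", function(x) x@data)

setMethod("show", "OrderParameterSet", function(object) {
  cat("OrderParameterSet:", nrow(object@data), "C-H bonds,",
      "n =", object@data$n[1], "lipids\n")
  print(utils::head(object@data, 8), row.names = FALSE)
  if (nrow(object@data) > 8) cat("  ...\n")
})

setMethod("show", "SimulationEntry", function(object) {
  cat("SimulationEntry", object@entryId, "\n")
  cat("  ", object@software, "/", object@forceField, "at",
      object@temperature, "K\n")
  cat("  composition:",
      paste(sprintf("%s(%d)", object@composition$molecule,
                    object@composition$count), collapse = ", "), "\n")
  cat("  trajectory:", object@trajectoryLength, "ns (discard",
      object@equilibrationDiscard, "ns)\n")
})

setMethod("show", "MappingTable", function(object) {
  cat("MappingTable", object@id, ":", nrow(object@rows), "atoms\n")
})

setMethod("show", "ExperimentEntry", function(object) {
  cat("ExperimentEntry [", object@kind, "] at",
      object@conditions$temperature, "K\n")
  cat("  composition:",
      paste(sprintf("%s(%.1f%%)", names(object@conditions$composition),
                    object@conditions$composition), collapse = ", "), "\n")
})

setMethod("show", "ElectronDensityProfile", function(object) {
  cat("ElectronDensityProfile:", length(object@binCenters),
      sprintf("bins of %.4f A over [%.1f, %.1f] A\n", object@binWidth,
              min(object@binCenters), max(object@binCenters)))
})

setMethod("show", "FormFactorCurve", function(object) {
  cat("FormFactorCurve:", length(object@q),
      sprintf("points, q in [%.3f, %.3f] 1/A, max |F| = %.3f e/A^2\n",
              min(object@q), max(object@q), max(object@F)))
})

setMethod("show", "EquilibrationReport", function(object) {
  cat(sprintf("EquilibrationReport: tau_auto = %.3g ns, tau_conv = %.3g ns (k = %g)\n",
              object@tauAuto, object@tauConvergence, object@k))
  cat(sprintf("  tau_sim = %.3g ns  ->  tau_rel = %.3g%s\n", object@tauSim,
              object@tauRel, if (object@converged) "" else " [not converged]"))
})

#' Form-factor curve accessors
#'
#' @param x a \linkS4class{FormFactorCurve}.
#' @return \code{ffQ()} the q grid (1/Angstrom); \code{ffAbs()} |F(q)|.
#' @export
setGeneric("ffQ", function(x) standardGeneric("ffQ"))
#' @rdname ffQ
#' @export
setMethod("ffQ", "FormFactorCurve", function(x) x@q)
#' @rdname ffQ
#' @export
setGeneric("ffAbs", function(x) standardGeneric("ffAbs"))
#' @rdname ffQ
#' @export
setMethod("ffAbs", "FormFactorCurve", function(x) x@F)

#' Density-profile accessors
#'
#' @param x an \linkS4class{ElectronDensityProfile}.
#' @return \code{profileZ()} bin centres (Angstrom); \code{profileDelta()} the
#'   solvent-subtracted contrast; \code{profileTotal()}, \code{profileSolvent()}
#'   the raw densities (e/Angstrom^3).
#' @export
setGeneric("profileZ", function(x) standardGeneric("profileZ"))
#' @rdname profileZ
#' @export
setMethod("profileZ", "ElectronDensityProfile", function(x) x@binCenters)
#' @rdname profileZ
#' @export
setGeneric("profileDelta", function(x) standardGeneric("profileDelta"))
#' @rdname profileZ
#' @export
setMethod("profileDelta", "ElectronDensityProfile", function(x) x@deltaRho)
#' @rdname profileZ
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))
#' @rdname profileZ
#' @export
setMethod("profileTotal", "ElectronDensityProfile", function(x) x@rhoTotal)
#' @rdname profileZ
#' @export
setGeneric("profileSolvent", function(x) standardGeneric("profileSolvent"))
#' @rdname profileZ
#' @export
setMethod("profileSolvent", "ElectronDensityProfile", function(x) x@rhoSolvent)

#' Simulation-entry accessors
#'
#' @param x a \linkS4class{SimulationEntry}.
#' @return \code{entryId()} the hash-derived identifier;
#'   \code{entryComposition()} the composition table;
#'   \code{entryTemperature()} the temperature in K.
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))
#' @rdname entryId
#' @export
setMethod("entryId", "SimulationEntry", function(x) x@entryId)
#' @rdname entryId
#' @export
setGeneric("entryComposition", function(x) standardGeneric("entryComposition"))
#' @rdname entryId
#' @export
setMethod("entryComposition", "SimulationEntry", function(x) x@composition)
#' @rdname entryId
#' @export
setGeneric("entryTemperature", function(x) standardGeneric("entryTemperature"))
#' @rdname entryId
#' @export
setMethod("entryTemperature", "SimulationEntry", function(x) x@temperature)

#' Equilibration-report accessor
#'
#' @param x an \linkS4class{EquilibrationReport}.
#' @return \code{tauRel()} the dimensionless convergence-to-length ratio.
#' @export
setGeneric("tauRel", function(x) standardGeneric("tauRel"))
#' @rdname tauRel
#' @export
setMethod("tauRel", "EquilibrationReport", function(x) x@tauRel)
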