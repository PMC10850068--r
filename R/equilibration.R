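## Conformational-sampling convergence of lipids via PCA of aligned
## heavy-atom coordinates.

#' Superpose lipid conformations onto their average structure
#'
#' Removes translation (centroid) and rotation (optimal least-squares
#' superposition via singular value decomposition) from each configuration in
#' a two-pass procedure: all configurations are superposed onto the initial
#' mean structure, the mean is recomputed from the aligned set, and the
#' configurations are superposed again onto the refined mean.
#'
#' @param configs numeric array \code{[n_config, n_atoms, 3]} of heavy-atom
#'   coordinates (one configuration per lipid per frame).
#' @return list with \code{aligned} (array of the same shape) and
#'   \code{mean} (matrix \code{[n_atoms, 3]}).
#' @export
alignConformations <- function(configs) {
  d <- dim(configs)
  if (length(d) != 3L || d[3] != 3L)
    stop("configs must be an [n_config, n_atoms, 3] array")
  if (d[1] < 2L) stop("at least 2 configurations are required")
  center <- function(m) sweep(m, 2, colMeans(m))
  mats <- lapply(seq_len(d[1]), function(i) center(configs[i, , , drop = TRUE]))
  ref <- center(Reduce(`+`, mats) / d[1])
  if (svd(ref)$d[2] < 1e-8 * max(svd(ref)$d[1], 1))
    stop("alignment error: degenerate (collinear) mean structure")
  pass <- function(mats, ref) lapply(mats, function(m) m %*% .kabsch(m, ref))
  aligned <- pass(mats, ref)
  ref2 <- center(Reduce(`+`, aligned) / d[1])
  aligned <- pass(mats, ref2)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) out[i, , ] <- aligned[[i]]
  list(aligned = out, mean = center(Reduce(`+`, aligned) / d[1]))
}

## Optimal rotation R (3x3) minimising ||P %*% R - Q|| for centred P, Q.
.kabsch <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Principal components of aligned lipid conformations
#'
#' Flattens the aligned configurations to a \code{[n_config, 3 n_atoms]}
#' matrix, pools all lipids of the type into one covariance, and returns the
#' components sorted by decreasing variance together with the centred
#' projection of every configuration on the first (slowest) component.
#'
#' @param aligned array \code{[n_config, n_atoms, 3]} from
#'   \code{\link{alignConformations}}, or the list it returns.
#' @param lipid integer vector assigning each configuration to a lipid
#'   instance; when supplied, per-lipid PC1 projection series are returned.
#' @return list with \code{sdev} (component standard deviations),
#'   \code{rotation}, \code{projection} (centred PC1 scores, one per
#'   configuration) and, when \code{lipid} is given, \code{series} (matrix
#'   \code{[n_lipids, n_frames]} of PC1 projections).
#' @export
principalComponents <- function(aligned, lipid = NULL) {
  if (is.list(aligned)) aligned <- aligned$aligned
  d <- dim(aligned)
  X <- matrix(aligned, nrow = d[1])       # columns: atom-major xyz blocks
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  proj <- pc$x[, 1]
  out <- list(sdev = pc$sdev, rotation = pc$rotation, projection = proj)
  if (!is.null(lipid)) {
    ids <- sort(unique(lipid))
    out$series <- t(vapply(ids, function(l) proj[lipid == l],
                           numeric(sum(lipid == ids[1]))))
  }
  out
}

#' Autocorrelation decay time of projection series
#'
#' Computes the normalized autocorrelation function of the PC1 projection of
#' each lipid, averages the functions over lipids, and returns the first lag
#' at which the averaged autocorrelation drops below 1/e, linearly
#' interpolated between lags. When the autocorrelation never decays below
#' 1/e within the series, the series duration is returned with
#' \code{converged = FALSE}.
#'
#' @param series numeric vector, or matrix \code{[n_lipids, n_frames]} with
#'   one projection series per lipid.
#' @param dt frame spacing, ns.
#' @return list with \code{tau} (ns) and \code{converged} (logical).
#' @export
acfDecayTime <- function(series, dt) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  n <- ncol(series)
  if (n < 10L) stop("series must have at least 10 samples")
  ok <- apply(series, 1, stats::sd) > 0
  if (!any(ok)) return(list(tau = n * dt, converged = FALSE))
  series <- series[ok, , drop = FALSE]
  target <- exp(-1)
  lag_max <- min(n - 1L, 64L)
  repeat {
    acfs <- apply(series, 1, function(x)
      stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1])
    m <- rowMeans(acfs)                 # averaged ACF, lags 0..lag_max
    below <- which(m < target)
    if (length(below)) {
      k <- below[1]                     # index into lags 0..lag_max (1-based)
      a1 <- m[k - 1]; a2 <- m[k]
      lag <- (k - 2) + (a1 - target) / (a1 - a2)
      return(list(tau = lag * dt, converged = TRUE))
    }
    if (lag_max >= n - 1L) return(list(tau = n * dt, converged = FALSE))
    lag_max <- min(n - 1L, lag_max * 4L)
  }
}

#' Relative equilibration of a lipid type
#'
#' Converts the autocorrelation decay time of the slowest principal component
#' into a distribution-convergence time using the empirical calibration
#' tau_convergence = k * tau_autocorrelation with k = 49 (fixed; determined
#' from long reference trajectories and insensitive to the force field), and
#' reports tau_rel = tau_convergence / tau_sim. Values above 1 flag
#' trajectories too short for individual lipids to sample their
#' conformational ensemble.
#'
#' @param tau_auto autocorrelation decay time, ns.
#' @param tau_sim analysed trajectory length, ns.
#' @param k calibration constant (default 49).
#' @param converged logical from \code{\link{acfDecayTime}}.
#' @return An \linkS4class{EquilibrationReport}.
#' @export
relativeEquilibration <- function(tau_auto, tau_sim, k = 49, converged = TRUE) {
  if (!isTRUE(tau_sim > 0)) stop("tau_sim must be > 0")
  new("EquilibrationReport", tauAuto = tau_auto,
      tauConvergence = k * tau_auto, tauSim = tau_sim,
      tauRel = k * tau_auto / tau_sim, k = k, converged = converged)
}

#' Equilibration analysis of a lipid type in a trajectory
#'
#' Convenience pipeline: extracts the heavy atoms of each lipid of the given
#' type, aligns all configurations to the average structure, projects on the
#' first principal component, and derives tau_rel. Rigid molecules (sterols
#' by default) are excluded upstream by \code{rigid_blacklist}.
#'
#' @param traj a \linkS4class{FrameEnsemble}.
#' @param molecule universal molecule name.
#' @param rigid_blacklist universal names to refuse (default sterols).
#' @return An \linkS4class{EquilibrationReport}.
#' @export
estimateEquilibration <- function(traj, molecule,
                                  rigid_blacklist = c("CHOL", "DCHOL")) {
  if (molecule %in% rigid_blacklist)
    stop("molecule ", molecule, " is rigid; excluded from PCA equilibration")
  atoms <- traj@atoms
  sel <- atoms$molecule == molecule & atoms$electrons > 1   # heavy atoms
  resids <- sort(unique(atoms$resid[sel]))
  nf <- nFrames(traj)
  idx_by_lipid <- lapply(resids, function(r) which(sel & atoms$resid == r))
  na <- length(idx_by_lipid[[1]])
  configs <- array(0, dim = c(length(resids) * nf, na, 3))
  lipid <- integer(length(resids) * nf)
  k <- 1L
  for (li in seq_along(resids)) for (f in seq_len(nf)) {
    configs[k, , ] <- traj@coords[f, idx_by_lipid[[li]], ]
    lipid[k] <- li
    k <- k + 1L
  }
  al <- alignConformations(configs)
  pcs <- principalComponents(al, lipid = lipid)
  dt <- if (nf > 1) diff(traj@times[1:2]) else 1
  dec <- acfDecayTime(pcs$series, dt)
  relativeEquilibration(dec$tau, tau_sim = nf * dt, converged = dec$converged)
}
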