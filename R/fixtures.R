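## Seeded synthetic-fixture generators with analytically known ground truth.
## These are first-class oracles for the analysis code: each generator's
## target quantity is computed in closed form, never by the code under test.

#' Oriented C-H bond ensemble with a prescribed order parameter
#'
#' Builds a \linkS4class{FrameEnsemble} of carbon-hydrogen pairs whose bonds
#' all make the fixed polar angle theta = arccos(sqrt((2 S + 1)/3)) with the
#' membrane normal, with uniformly random azimuth, so the analytic order
#' parameter of the ensemble is exactly the target S. With
#' \code{mode = "uniform"}, bond directions are drawn uniformly on the sphere
#' instead (analytic S = 0 in expectation).
#'
#' @param S target order parameter in [-0.5, 1].
#' @param n_lipids,n_frames ensemble size.
#' @param seed integer seed.
#' @param mode \code{"fixed"} polar angle or \code{"uniform"} sphere.
#' @param bond_length C-H bond length, nm (default 0.109).
#' @return list with \code{traj} (FrameEnsemble), \code{bonds} (data.frame
#'   carbon/hydrogen) and \code{S_analytic}.
#' @export
makeOrientedBondEnsemble <- function(S, n_lipids = 32, n_frames = 50,
                                     seed = 1, mode = c("fixed", "uniform"),
                                     bond_length = 0.109) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (S < -0.5 || S > 1))
    stop("target S must lie in [-0.5, 1]")
  set.seed(seed)
  na <- 2L * n_lipids
  coords <- array(0, dim = c(n_frames, na, 3))
  c_idx <- seq(1L, na, by = 2L)
  base <- matrix(stats::runif(n_lipids * 3, 1, 4), n_lipids, 3)
  for (f in seq_len(n_frames)) {
    if (mode == "fixed") {
      cos_t <- sqrt((2 * S + 1) / 3)
      phi <- stats::runif(n_lipids, 0, 2 * pi)
      dir <- cbind(sqrt(1 - cos_t^2) * cos(phi),
                   sqrt(1 - cos_t^2) * sin(phi),
                   rep(cos_t, n_lipids))
    } else {
      u <- stats::runif(n_lipids, -1, 1)          # cos(theta) uniform
      phi <- stats::runif(n_lipids, 0, 2 * pi)
      dir <- cbind(sqrt(1 - u^2) * cos(phi), sqrt(1 - u^2) * sin(phi), u)
    }
    coords[f, c_idx, ] <- base
    coords[f, c_idx + 1L, ] <- base + bond_length * dir
  }
  atoms <- data.frame(
    molecule = "POPC",
    resid = rep(seq_len(n_lipids), each = 2L),
    name = rep(c("C1", "C1H1"), n_lipids),
    electrons = rep(c(6, 1), n_lipids), stringsAsFactors = FALSE)
  traj <- FrameEnsemble(coords, box = c(5, 5, 5),
                        times = (seq_len(n_frames) - 1) * 0.1, atoms = atoms)
  list(traj = traj,
       bonds = data.frame(carbon = "C1", hydrogen = "C1H1",
                          stringsAsFactors = FALSE),
       S_analytic = if (mode == "fixed") S else 0)
}

#' Slab density profile with an analytic form factor
#'
#' A uniform contrast slab of width d centred at z = 0 inside a box of
#' height D, on the 1/3 Angstrom histogram grid. Its exact form factor is
#' |F(q)| = |2 contrast sin(q d / 2) / q|, with the first zero at q = 2 pi/d.
#'
#' @param d slab width, Angstrom (should be a multiple of the bin width for
#'   the profile to represent it exactly).
#' @param contrast electron density contrast, e/Angstrom^3.
#' @param box_D box height, Angstrom.
#' @param bin_width grid spacing, Angstrom (default 1/3).
#' @return list with \code{profile} (\linkS4class{ElectronDensityProfile}),
#'   \code{F_analytic} (function of q) and \code{first_zero} (2 pi / d).
#' @export
makeSlabProfile <- function(d, contrast = 0.1, box_D = 240, bin_width = 1/3) {
  if (d >= box_D) stop("slab must fit inside the box")
  nbins <- round(box_D / bin_width)
  edges <- seq(-box_D / 2, box_D / 2, length.out = nbins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  delta <- ifelse(abs(centers) < d / 2, contrast, 0)
  profile <- new("ElectronDensityProfile", binCenters = centers,
                 rhoTotal = delta + 0.333, rhoSolvent = rep(0.333, nbins),
                 deltaRho = delta, binWidth = box_D / nbins)
  list(profile = profile,
       F_analytic = function(q) ifelse(q == 0, contrast * d,
                                       abs(2 * contrast * sin(q * d / 2) / q)),
       first_zero = 2 * pi / d)
}

#' Scripted leaflet z-series for flip-flop tests
#'
#' Builds headgroup z trajectories realizing an exact list of crossing
#' attempts: each molecule starts in the upper leaflet at +z_rest, and each
#' scripted event descends through the midplane zone to -z_rest, dwells for
#' the scripted number of frames, then returns. Under the detector rules
#' (midplane cutoff, residence cutoff) an attempt with dwell >= frame_cutoff
#' is one flip-flop; shorter dwells produce none.
#'
#' @param n_frames series length.
#' @param events data.frame with columns \code{molecule}, \code{start}
#'   (frame the descent begins), \code{dwell} (frames spent at -z_rest;
#'   \code{Inf} = stays).
#' @param n_molecules number of molecules (default max molecule id).
#' @param z_rest resting distance from the midplane, nm (default 2).
#' @param transit frames spent crossing the zone each way (default 4).
#' @return matrix \code{[n_molecules, n_frames]} of z positions, nm.
#' @export
makeLeafletScript <- function(n_frames, events,
                              n_molecules = max(events$molecule),
                              z_rest = 2, transit = 4) {
  z <- matrix(z_rest, n_molecules, n_frames)
  for (i in seq_len(nrow(events))) {
    m <- events$molecule[i]; f0 <- events$start[i]; dw <- events$dwell[i]
    down <- seq(z_rest, -z_rest, length.out = transit + 2L)
    f <- f0
    for (v in down) { if (f <= n_frames) z[m, f] <- v; f <- f + 1L }
    stay_end <- if (is.finite(dw)) min(f + dw - 1L, n_frames) else n_frames
    if (f <= stay_end) { z[m, f:stay_end] <- -z_rest; f <- stay_end + 1L }
    if (is.finite(dw)) {
      for (v in rev(down)) { if (f <= n_frames) z[m, f] <- v; f <- f + 1L }
      if (f <= n_frames) z[m, f:n_frames] <- z_rest
    }
  }
  z
}

#' Scripted water z-series for permeation tests
#'
#' Builds walker trajectories with an exact number of full membrane
#' traversals and rebounds. Walkers rest in the lower bulk at -z_bulk; a
#' traversal moves linearly to +z_bulk (and stays until the next scripted
#' move), a rebound enters the slab and returns.
#'
#' @param n_frames series length.
#' @param moves data.frame with columns \code{walker}, \code{start},
#'   \code{kind} ("cross" or "rebound").
#' @param n_walkers number of walkers.
#' @param z_bulk resting |z|, nm; the membrane slab is |z| < z_slab.
#' @param z_slab slab half-width, nm (default 2).
#' @param transit frames per directed passage (default 6).
#' @return list with \code{z} (matrix \code{[n_walkers, n_frames]}),
#'   \code{lower}, \code{upper} (slab bounds), \code{n_cross},
#'   \code{n_rebound}.
#' @export
makePermeationScript <- function(n_frames, moves,
                                 n_walkers = max(moves$walker),
                                 z_bulk = 4, z_slab = 2, transit = 6) {
  z <- matrix(NA_real_, n_walkers, n_frames)
  side <- rep(-1, n_walkers)
  pos <- rep(-z_bulk, n_walkers)
  for (w in seq_len(n_walkers)) z[w, ] <- -z_bulk
  moves <- moves[order(moves$start), , drop = FALSE]
  for (i in seq_len(nrow(moves))) {
    w <- moves$walker[i]; f0 <- moves$start[i]
    from <- side[w] * z_bulk
    if (moves$kind[i] == "cross") {
      to <- -side[w] * z_bulk
      path <- seq(from, to, length.out = transit + 2L)
      side[w] <- -side[w]
    } else {
      mid <- -side[w] * 0.5 * z_slab      # into the slab past the midplane
      path <- c(seq(from, mid, length.out = transit + 1L),
                rev(seq(from, mid, length.out = transit + 1L))[-1])
      to <- from
    }
    f <- f0
    for (v in path) { if (f <= n_frames) z[w, f] <- v; f <- f + 1L }
    if (f <= n_frames) z[w, f:n_frames] <- to
  }
  list(z = z, lower = -z_slab, upper = z_slab,
       n_cross = sum(moves$kind == "cross"),
       n_rebound = sum(moves$kind == "rebound"))
}

#' Ornstein-Uhlenbeck series with known correlation time
#'
#' Exact discretization x_{t+1} = phi x_t + sqrt(1 - phi^2) sigma eps,
#' phi = exp(-dt/tau), stationary start. The analytic autocorrelation is
#' exp(-lag/tau).
#'
#' @param tau correlation time, ns.
#' @param n number of steps.
#' @param dt time step, ns.
#' @param seed integer seed.
#' @param sigma stationary standard deviation (default 1).
#' @param n_series number of independent series (default 1).
#' @return numeric vector, or matrix \code{[n_series, n]}.
#' @export
makeOUSeries <- function(tau, n, dt, seed = 1, sigma = 1, n_series = 1) {
  if (!isTRUE(tau > 0) || !isTRUE(dt > 0)) stop("tau and dt must be > 0")
  set.seed(seed)
  phi <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - phi^2)
  out <- matrix(0, n_series, n)
  for (s in seq_len(n_series)) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sigma)
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) x[t] <- phi * x[t - 1] + eps[t - 1]
    out[s, ] <- x
  }
  if (n_series == 1) drop(out) else out
}

#' Brownian walkers with known diffusion coefficient
#'
#' Independent 2-D random walks with Gaussian increments of variance
#' 2 D dt per axis, so the analytic MSD is 4 D t.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param n_steps,n_walkers series size.
#' @param dt time step, ns.
#' @param seed integer seed.
#' @return array \code{[n_steps, n_walkers, 2]} of positions, nm.
#' @export
makeBrownianWalkers <- function(D, n_steps, n_walkers = 10, dt = 0.01,
                                seed = 1) {
  set.seed(seed)
  D_nm <- D * 1e9                         # nm^2/ns
  sd_step <- sqrt(2 * D_nm * dt)
  xy <- array(0, dim = c(n_steps, n_walkers, 2))
  for (ax in 1:2)
    xy[, , ax] <- apply(matrix(stats::rnorm((n_steps - 1) * n_walkers,
                                            0, sd_step),
                               n_steps - 1, n_walkers), 2,
                        function(v) c(0, cumsum(v)))
  xy
}

#' Synthetic composition -> property regression dataset
#'
#' Random compositions over the eight feature classes (sparse Dirichlet-like
#' draws) with targets generated from known linear coefficients plus
#' Gaussian noise.
#'
#' @param coefficients named numeric vector over the feature classes
#'   (per-class property values; the target of a mixture is the
#'   fraction-weighted sum).
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param n number of rows.
#' @param seed integer seed.
#' @param target name of the target column (default \code{"apl"}).
#' @return data.frame with the eight class columns and the target.
#' @export
makeRegressionDataset <- function(coefficients, noise_sd = 0, n = 100,
                                  seed = 1, target = "apl") {
  classes <- .feature_classes
  beta <- stats::setNames(numeric(length(classes)), classes)
  beta[names(coefficients)] <- coefficients
  set.seed(seed)
  X <- t(vapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)                       # components in the mixture
    present <- sample(classes, k)
    w <- stats::setNames(numeric(length(classes)), classes)
    w[present] <- stats::rgamma(k, shape = 1.5)
    w / sum(w)
  }, numeric(length(classes))))
  colnames(X) <- classes
  y <- drop(X %*% beta) + stats::rnorm(n, 0, noise_sd)
  out <- as.data.frame(X)
  out[[target]] <- y
  out
}
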