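## Rare-event and transport analyses: lipid flip-flops, water permeation and
## permeability, lateral diffusion and the Tanner-equation anisotropy.

#' Assign molecules to bilayer leaflets
#'
#' Labels each molecule at each frame as upper or lower leaflet from the z
#' position of its headgroup atoms relative to the bilayer midplane. Within
#' the midplane zone (|z - z_mid| < cutoff) the previous confirmed label is
#' retained, so brief excursions towards the centre do not flip the label.
#'
#' @param headgroup_z matrix \code{[n_molecules, n_frames]} of headgroup z
#'   positions, nm.
#' @param midplane_z numeric midplane position per frame (default 0; the
#'   membrane is expected to be centred on the lipid centre of mass).
#' @param midplane_cutoff half-width of the midplane zone, nm (default 1).
#' @return list with \code{labels} (character matrix "upper"/"lower"),
#'   \code{side} (integer matrix: +1 upper, -1 lower, 0 midplane zone) and
#'   the parameters used.
#' @export
assignLeaflets <- function(headgroup_z, midplane_z = 0, midplane_cutoff = 1) {
  z <- as.matrix(headgroup_z)
  nm <- nrow(z); nf <- ncol(z)
  mid <- rep_len(midplane_z, nf)
  rel <- sweep(z, 2, mid)
  side <- matrix(0L, nm, nf)
  side[rel >= midplane_cutoff] <- 1L
  side[rel <= -midplane_cutoff] <- -1L
  lab <- side
  for (m in seq_len(nm)) {
    cur <- side[m, which(side[m, ] != 0L)[1]]       # first confirmed side
    for (f in seq_len(nf)) {
      if (side[m, f] != 0L) cur <- side[m, f]
      lab[m, f] <- cur
    }
  }
  list(labels = ifelse(lab > 0, "upper", "lower"), side = side,
       retained = lab, midplane_cutoff = midplane_cutoff)
}

#' Detect lipid flip-flop events
#'
#' A flip-flop is a confirmed translocation between leaflets: after entering
#' the midplane zone, the molecule must reside in the opposite leaflet for at
#' least \code{frame_cutoff} frames (midplane-zone frames retain the current
#' label and do not interrupt the residence). Shorter excursions to the
#' opposite side are rejected, in either direction, so a crossing that
#' returns before the cutoff contributes no event at all.
#'
#' @param trace result of \code{\link{assignLeaflets}}.
#' @param frame_cutoff minimum residence in the new leaflet, frames
#'   (default 100).
#' @return data.frame of events with columns \code{molecule},
#'   \code{start_frame} (first frame of the confirmed residence) and
#'   \code{end_frame} (frame at which the residence reached the cutoff).
#' @export
detectFlipFlops <- function(trace, frame_cutoff = 100) {
  lab <- trace$retained
  nm <- nrow(lab); nf <- ncol(lab)
  if (nf <= frame_cutoff)
    stop("trace must be longer than frame_cutoff")
  ev <- list()
  for (m in seq_len(nm)) {
    r <- rle(lab[m, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    confirmed <- r$values[1]
    for (j in seq_along(r$values)[-1]) {
      if (r$values[j] != confirmed && r$lengths[j] >= frame_cutoff) {
        ev[[length(ev) + 1L]] <- data.frame(
          molecule = m, start_frame = starts[j],
          end_frame = starts[j] + frame_cutoff - 1L)
        confirmed <- r$values[j]
      }
    }
  }
  if (length(ev)) do.call(rbind, ev) else
    data.frame(molecule = integer(), start_frame = integer(),
               end_frame = integer())
}

#' Flip-flop rate
#'
#' Rate per molecule per time: n_events / (n_molecules * analyzed_time).
#' With zero events the reciprocal of the total observation,
#' 1 / (n_molecules * analyzed_time), is reported as an upper limit for the
#' rate.
#'
#' @param events data.frame from \code{\link{detectFlipFlops}}, or an event
#'   count.
#' @param n_molecules number of molecules of the species observed.
#' @param analyzed_time analysed trajectory time, microseconds.
#' @return list with \code{rate} (1/us), \code{n_events} and
#'   \code{upper_limit} (1/us; NA unless zero events).
#' @export
flipFlopRate <- function(events, n_molecules, analyzed_time) {
  if (!isTRUE(analyzed_time > 0)) stop("analyzed_time must be > 0")
  n_ev <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  rate <- n_ev / (n_molecules * analyzed_time)
  list(rate = rate, n_events = n_ev,
       upper_limit = if (n_ev == 0) 1 / (n_molecules * analyzed_time)
                     else NA_real_)
}

#' Count water permeation events
#'
#' Counts complete membrane traversals of solvent molecules: a molecule that
#' leaves one bulk region, passes through the membrane slab, and reaches the
#' opposite bulk region scores one event; a molecule that enters the slab and
#' rebounds to the same side scores none. In a periodic multilamellar
#' geometry both bulk regions belong to the same water slab, so direct
#' transitions between them across the periodic boundary (without passing
#' through the membrane) are movement within bulk, not permeation.
#'
#' @param water_z matrix \code{[n_molecules, n_frames]} of z positions, nm
#'   (unwrapped or folded into the box; only region membership is used).
#' @param lower,upper membrane slab bounds, nm: scalars or per-frame vectors.
#' @return Integer event count.
#' @export
countPermeationEvents <- function(water_z, lower, upper) {
  z <- as.matrix(water_z)
  nf <- ncol(z)
  lo <- rep_len(lower, nf); up <- rep_len(upper, nf)
  total <- 0L
  for (m in seq_len(nrow(z))) {
    reg <- ifelse(z[m, ] < lo, -1L, ifelse(z[m, ] > up, 1L, 0L))
    state <- 0L           # last confirmed bulk side
    through <- FALSE      # passed the slab since leaving that side
    for (f in seq_len(nf)) {
      r <- reg[f]
      if (r == 0L) { through <- TRUE; next }
      if (state == 0L) { state <- r; through <- FALSE; next }
      if (r == state) { through <- FALSE; next }
      ## opposite bulk region
      if (through) total <- total + 1L
      state <- r
      through <- FALSE
    }
  }
  total
}

#' Water permeability from event counting
#'
#' P = r / (2 c_w), with r the permeation event rate per time and area and
#' c_w = 33.3679 nm^-3 the bulk water concentration. The factor 2 accounts
#' for events crossing in both directions at equilibrium.
#'
#' @param n_events number of complete traversals.
#' @param time analysed time, ns.
#' @param area lateral membrane area, nm^2.
#' @param c_w bulk water concentration, nm^-3 (default 33.3679).
#' @return list with \code{P} (um/s), \code{r} (events/(ns nm^2)).
#' @export
permeability <- function(n_events, time, area, c_w = 33.3679) {
  if (!isTRUE(time > 0) || !isTRUE(area > 0))
    stop("time and area must be > 0")
  r <- n_events / (time * area)          # 1/(ns nm^2)
  P_nm_ns <- r / (2 * c_w)               # nm/ns = m/s
  list(P = P_nm_ns * 1e6, r = r)         # um/s
}

#' Lateral diffusion coefficient from the Einstein relation
#'
#' D_parallel = slope/4 of the lateral mean-squared displacement versus lag
#' time, fitted over lags between 10\% and 50\% of the trajectory length to
#' avoid the short-time and poorly sampled long-time regimes. A poor linear
#' fit (R^2 < 0.9, e.g. ballistic motion) flags the result.
#'
#' @param xy array \code{[n_frames, n_walkers, 2]} (or a \code{[n_frames, 2]}
#'   matrix for a single walker), positions in nm, unwrapped.
#' @param dt frame spacing, ns.
#' @param n_lags number of lag points sampled in the fit window (default 40).
#' @return list with \code{D} (m^2/s), \code{r_squared}, \code{flagged},
#'   \code{msd} (data.frame lag_ns, msd_nm2).
#' @export
lateralDiffusion <- function(xy, dt, n_lags = 40) {
  if (length(dim(xy)) == 2L) xy <- array(xy, dim = c(dim(xy)[1], 1L, 2L))
  nf <- dim(xy)[1]
  if (nf < 100L) stop("at least 100 frames are required")
  lags <- unique(round(seq(max(1, 0.1 * nf), 0.5 * nf, length.out = n_lags)))
  msd <- vapply(lags, function(L) {
    d1 <- xy[(L + 1):nf, , 1, drop = FALSE] - xy[1:(nf - L), , 1, drop = FALSE]
    d2 <- xy[(L + 1):nf, , 2, drop = FALSE] - xy[1:(nf - L), , 2, drop = FALSE]
    mean(d1^2 + d2^2)
  }, numeric(1))
  t_lag <- lags * dt
  if (all(msd == 0))
    return(list(D = 0, r_squared = NA_real_, flagged = FALSE,
                msd = data.frame(lag_ns = t_lag, msd_nm2 = msd)))
  fit <- stats::lm(msd ~ t_lag)
  slope <- stats::coef(fit)[["t_lag"]]
  r2 <- suppressWarnings(summary(fit)$r.squared)
  curv <- stats::lm(msd ~ t_lag + I(t_lag^2))
  nonlinear <- r2 < 0.9 ||
    suppressWarnings(summary(curv)$r.squared) - r2 > 0.02
  list(D = max(slope, 0) / 4 * 1e-9,      # nm^2/ns -> m^2/s
       r_squared = r2, flagged = nonlinear,
       msd = data.frame(lag_ns = t_lag, msd_nm2 = msd))
}

#' Perpendicular water diffusion via the Tanner equation
#'
#' In a multilamellar stack, diffusion across the membranes is rate-limited
#' by permeation; the Tanner relation combines the two transport channels
#' harmonically: D_perp = D_par * P * z_w / (D_par + P * z_w), with z_w the
#' water layer thickness (box height minus bilayer thickness).
#'
#' @param D_par lateral diffusion coefficient, m^2/s.
#' @param P membrane permeability, um/s.
#' @param z_w water layer thickness, nm.
#' @return list with \code{D_perp} (m^2/s), \code{D_par}, \code{ratio}
#'   (D_perp/D_par), \code{P}, \code{z_w}.
#' @export
perpendicularDiffusion <- function(D_par, P, z_w) {
  if (!isTRUE(z_w > 0)) stop("geometry error: water layer thickness must be > 0")
  if (D_par < 0 || P < 0) stop("inputs must be >= 0")
  Pz <- (P * 1e-6) * (z_w * 1e-9)        # m^2/s
  D_perp <- if (D_par + Pz == 0) 0 else D_par * Pz / (D_par + Pz)
  list(D_perp = D_perp, D_par = D_par,
       ratio = if (D_par > 0) D_perp / D_par else NA_real_, P = P, z_w = z_w)
}

#' Activation energy from an Arrhenius plot of permeability
#'
#' Least-squares fit of ln(P) against 1/T; the slope is -E_a/k_B in Kelvin.
#' The energy is reported in units of k_B * T_ref with T_ref = 310 K, the
#' physiological reference.
#'
#' @param P permeabilities (> 0), any consistent unit.
#' @param T temperatures, K (>= 3 distinct values).
#' @param T_ref reference temperature for the energy unit, K (default 310).
#' @return list with \code{E_a} (in k_B T_ref units), \code{se} (standard
#'   error, same units), \code{slope} (K).
#' @export
arrheniusActivation <- function(P, T, T_ref = 310) {
  if (length(P) < 3 || length(unique(T)) < 3)
    stop("fit error: at least 3 temperatures are required")
  if (any(P <= 0)) stop("fit error: permeabilities must be > 0")
  x <- 1 / T
  fit <- stats::lm(log(P) ~ x)
  slope <- stats::coef(fit)[["x"]]
  se <- suppressWarnings(summary(fit)$coefficients["x", "Std. Error"])
  list(E_a = -slope / T_ref, se = se / T_ref, slope = slope)
}

#' Weighted binned summary of simulation observables
#'
#' Bins values by a membrane property and reports per-bin means weighted by
#' the simulation lengths, with weighted standard errors. Bins whose total
#' weight does not exceed \code{min_weight} are dropped (for permeation
#' statistics only bins with more than one microsecond of data are kept).
#'
#' @param values observable per simulation.
#' @param weights weights (simulation lengths); default equal.
#' @param by binning variable per simulation.
#' @param breaks bin breaks passed to \code{cut}.
#' @param min_weight minimum total bin weight (default 0).
#' @return data.frame with \code{bin}, \code{center}, \code{mean}, \code{sem},
#'   \code{n}, \code{weight}.
#' @export
binnedSummary <- function(values, weights = NULL, by, breaks, min_weight = 0) {
  if (is.null(weights)) weights <- rep(1, length(values))
  bins <- cut(by, breaks, include.lowest = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- lapply(seq_along(levels(bins)), function(b) {
    i <- which(as.integer(bins) == b & !is.na(values))
    if (!length(i)) return(NULL)
    w <- weights[i]; v <- values[i]
    if (sum(w) <= min_weight) return(NULL)
    m <- sum(w * v) / sum(w)
    sem <- if (length(i) > 1)
      sqrt(sum(w * (v - m)^2) / sum(w)) / sqrt(length(i)) else NA_real_
    data.frame(bin = levels(bins)[b], center = mids[b], mean = m, sem = sem,
               n = length(i), weight = sum(w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    data.frame(bin = character(), center = numeric(), mean = numeric(),
               sem = numeric(), n = integer(), weight = numeric())
  else out
}
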