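## Quality evaluation of simulations against NMR order parameters and X-ray
## scattering form factors.

#' Quality of one C-H bond order parameter against experiment
#'
#' Probability for the simulated order parameter to lie within the
#' experimental error bars. Treating the per-lipid means as independent
#' samples, (S_mean - mu) / (sqrt(s)/sqrt(n)) follows a Student
#' t-distribution; the heavy-tailed 1-degree-of-freedom form (Cauchy) is used
#' by default so that simulations far from experiment retain numerically
#' representable probabilities. The probability is the CDF mass of the
#' interval [S_exp - dS_exp, S_exp + dS_exp]:
#' P = F((S_exp + dS - S_mean)/sem) - F((S_exp - dS - S_mean)/sem).
#' Bonds whose simulation error exceeds the experimental error
#' (sem > dS_exp) are excluded: artificially slow dynamics widens the
#' distribution and would inflate the probability.
#'
#' @param S_mean simulated mean order parameter.
#' @param s variance of per-lipid means.
#' @param n number of lipids (>= 2).
#' @param S_exp experimental value.
#' @param dS_exp experimental error (default 0.02).
#' @param df degrees of freedom of the t-distribution (default 1).
#' @return list with \code{P} (NA when excluded), \code{excluded} and
#'   \code{sem}.
#' @export
bondQuality <- function(S_mean, s, n, S_exp, dS_exp = 0.02, df = 1) {
  if (n < 2) stop("insufficient-sample error: n must be >= 2")
  if (s < 0) stop("variance must be >= 0")
  sem <- sqrt(s) / sqrt(n)
  if (sem > dS_exp) return(list(P = NA_real_, excluded = TRUE, sem = sem))
  P <- if (sem == 0) {
    dev <- abs(S_mean - S_exp)
    if (dev < dS_exp) 1 else if (dev == dS_exp) 0.5 else 0
  } else {
    stats::pt((S_exp + dS_exp - S_mean) / sem, df) -
      stats::pt((S_exp - dS_exp - S_mean) / sem, df)
  }
  list(P = P, excluded = FALSE, sem = sem)
}

#' Fragment-averaged order parameter quality of one lipid
#'
#' P_frag = <P>_frag * F_frag, where <P>_frag is the average of the available
#' per-bond probabilities within the fragment and F_frag the fraction of the
#' fragment's bonds for which a quality is available (bonds excluded for
#' large simulation error, or without a matched experimental value, count
#' against the denominator). Fragments without any available bond have no
#' quality (NA), not zero.
#'
#' @param bond_table data.frame with columns \code{fragment} and \code{P}
#'   (NA = quality unavailable), one row per bond of the lipid.
#' @param fragment \code{"sn-1"}, \code{"sn-2"}, \code{"headgroup"} or
#'   \code{"total"} (all bonds of the molecule).
#' @return list with \code{P_frag}, \code{F_frag}, \code{n_bonds},
#'   \code{n_available}.
#' @export
fragmentQuality <- function(bond_table, fragment = "total") {
  frag_map <- c("acyl chain sn-1" = "sn-1", "acyl chain sn-2" = "sn-2",
                "headgroup" = "headgroup", "glycerol backbone" = "glycerol",
                "other" = "other")
  tags <- ifelse(bond_table$fragment %in% names(frag_map),
                 frag_map[bond_table$fragment], bond_table$fragment)
  rows <- if (fragment == "total") rep(TRUE, nrow(bond_table)) else
    tags == fragment
  sub <- bond_table[rows, , drop = FALSE]
  n_bonds <- nrow(sub)
  n_avail <- sum(!is.na(sub$P))
  if (n_bonds == 0L || n_avail == 0L)
    return(list(P_frag = NA_real_, F_frag = if (n_bonds) 0 else NA_real_,
                n_bonds = n_bonds, n_available = n_avail))
  F_frag <- n_avail / n_bonds
  list(P_frag = mean(sub$P, na.rm = TRUE) * F_frag, F_frag = F_frag,
       n_bonds = n_bonds, n_available = n_avail)
}

#' System-level order parameter quality
#'
#' Molar-fraction-weighted average of per-lipid fragment qualities,
#' P^frag = sum_lipid chi_lipid P^frag[lipid], with the fractions
#' renormalized over the scored lipids. The 'tails' fragment is the average
#' of the sn-1 and sn-2 acyl-chain qualities of each lipid.
#'
#' @param lipid_qualities data.frame with columns \code{lipid},
#'   \code{P_sn1}, \code{P_sn2}, \code{P_hg}, \code{P_total} (NA allowed).
#' @param fractions named numeric molar fractions of the lipids.
#' @return list with \code{tails}, \code{headgroup}, \code{total}
#'   (NA when no lipid is scored for that fragment).
#' @export
systemQuality <- function(lipid_qualities, fractions) {
  lq <- as.data.frame(lipid_qualities)
  chi <- fractions[lq$lipid]
  wavg <- function(v) {
    ok <- !is.na(v) & !is.na(chi)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * chi[ok]) / sum(chi[ok])
  }
  tails_per_lipid <- rowMeans(cbind(lq$P_sn1, lq$P_sn2), na.rm = TRUE)
  tails_per_lipid[is.nan(tails_per_lipid)] <- NA_real_
  list(tails = wavg(tails_per_lipid), headgroup = wavg(lq$P_hg),
       total = wavg(lq$P_total))
}

#' Scale experimental form-factor intensities to the simulation
#'
#' Experiments measure |F(q)| on a relative scale only. The scaling
#' coefficient applied to the experimental intensities is the weighted
#' least-squares solution
#' k_e = sum(|F_s||F_e|/dF^2) / sum(|F_e|^2/dF^2),
#' with the simulated curve interpolated onto the experimental q grid.
#'
#' @param sim a \linkS4class{FormFactorCurve} (or list with \code{q},
#'   \code{F}).
#' @param q_exp,F_exp,dF_exp experimental grid, intensities and errors.
#' @return list with \code{k_e}, the shared grid \code{q}, the interpolated
#'   simulated curve \code{F_sim} and the scaled experimental curve
#'   \code{F_exp_scaled}.
#' @export
scaleFormFactor <- function(sim, q_exp, F_exp, dF_exp) {
  qs <- if (is(sim, "FormFactorCurve")) sim@q else sim$q
  Fs <- if (is(sim, "FormFactorCurve")) sim@F else sim$F
  keep <- q_exp >= min(qs) & q_exp <= max(qs)
  q <- q_exp[keep]; Fe <- abs(F_exp[keep]); dF <- dF_exp[keep]
  if (all(Fe == 0)) stop("degenerate-scaling error: experimental curve is zero")
  Fsim <- stats::approx(qs, Fs, xout = q)$y
  w <- 1 / dF^2
  k_e <- sum(abs(Fsim) * Fe * w) / sum(Fe^2 * w)
  list(k_e = k_e, q = q, F_sim = Fsim, F_exp_scaled = k_e * Fe)
}

#' Locate the first form-factor minimum
#'
#' Smooths |F(q)| with a Savitzky-Golay filter (default window 31 points,
#' polynomial order 1) and scans upward from \code{q_min} for the first
#' strict local minimum, refined to sub-grid resolution by a parabola through
#' the three surrounding points. Lobe heights of simulated form factors
#' depend on the simulation box size, but the minima locations do not, which
#' is why the quality measure is built on them.
#'
#' @param q,F form-factor curve.
#' @param q_min lower bound of the search, 1/Angstrom (default 0.1).
#' @param window filter window length in points (odd; default 31, truncated
#'   for short curves).
#' @param order filter polynomial order (default 1).
#' @param resample_dq grid spacing the curve is linearly resampled to before
#'   filtering, 1/Angstrom (default 0.001). The point-count window implies a
#'   fixed q resolution; resampling makes the filter width independent of
#'   the input grid. \code{NULL} disables resampling.
#' @return q location of the first minimum (1/Angstrom), or NA with a
#'   \code{"diagnostic"} attribute when no minimum lies in range.
#' @export
firstFormFactorMinimum <- function(q, F, q_min = 0.1, window = 31, order = 1,
                                   resample_dq = 0.001) {
  if (!is.null(resample_dq) && length(q) > 1) {
    qd <- seq(min(q), max(q), by = resample_dq)
    F <- stats::approx(q, F, xout = qd)$y
    q <- qd
  }
  n <- length(F)
  w <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  Fs <- if (w > order + 1) signal::sgolayfilt(F, p = order, n = w) else F
  i0 <- which(q > q_min)[1]
  if (is.na(i0)) {
    out <- NA_real_; attr(out, "diagnostic") <- "no points above q_min"
    return(out)
  }
  for (i in seq(max(i0, 2L), n - 1L)) {
    if (Fs[i] < Fs[i - 1] && Fs[i] <= Fs[i + 1]) {
      a <- Fs[i - 1]; b <- Fs[i]; cc <- Fs[i + 1]
      denom <- a - 2 * b + cc
      delta <- if (denom > 0) 0.5 * (a - cc) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      return(q[i] + delta * (q[i + 1] - q[i]))
    }
  }
  out <- NA_real_
  attr(out, "diagnostic") <- "no local minimum found above q_min"
  out
}

#' Form-factor quality of a simulation against experiment
#'
#' FF_q = |q_min_sim - q_min_exp| * 100: one hundred times the distance (in
#' 1/Angstrom) between the locations of the first minima of the simulated
#' and the scaled experimental |F(q)|, both located after Savitzky-Golay
#' smoothing at q > 0.1 1/Angstrom. The best possible quality is 0.
#'
#' @param sim a \linkS4class{FormFactorCurve} or list with \code{q},
#'   \code{F}.
#' @param q_exp,F_exp experimental grid and (scaled or unscaled; scaling does
#'   not move minima) intensities.
#' @param dF_exp optional experimental errors, used to compute the reported
#'   scaling coefficient \code{k_e}.
#' @param ... passed to \code{\link{firstFormFactorMinimum}}.
#' @return list with \code{FF_q}, \code{q_min_sim}, \code{q_min_exp} and
#'   \code{k_e} (NA when no errors supplied). \code{FF_q} is NA with a
#'   diagnostic when either minimum cannot be located.
#' @export
formFactorQuality <- function(sim, q_exp, F_exp, dF_exp = NULL, ...) {
  qs <- if (is(sim, "FormFactorCurve")) sim@q else sim$q
  Fs <- if (is(sim, "FormFactorCurve")) sim@F else sim$F
  k_e <- if (!is.null(dF_exp))
    scaleFormFactor(sim, q_exp, F_exp, dF_exp)$k_e else NA_real_
  m_sim <- firstFormFactorMinimum(qs, Fs, ...)
  m_exp <- firstFormFactorMinimum(q_exp, abs(F_exp), ...)
  if (is.na(m_sim) || is.na(m_exp)) {
    diag <- c(if (is.na(m_sim)) "simulation: no first minimum located",
              if (is.na(m_exp)) "experiment: no first minimum located")
    return(list(FF_q = NA_real_, q_min_sim = as.numeric(m_sim),
                q_min_exp = as.numeric(m_exp), k_e = k_e, diagnostic = diag))
  }
  list(FF_q = abs(m_sim - m_exp) * 100, q_min_sim = as.numeric(m_sim),
       q_min_exp = as.numeric(m_exp), k_e = k_e)
}

#' Full order-parameter quality evaluation of one lipid
#'
#' Joins a simulated \linkS4class{OrderParameterSet} with an experimental
#' order-parameter table, scores every bond with \code{\link{bondQuality}},
#' and aggregates fragment qualities. Bonds without an experimental value are
#' unavailable and count against F_frag.
#'
#' @param ops an \linkS4class{OrderParameterSet}.
#' @param bonds_fragments data.frame \code{carbon}, \code{hydrogen},
#'   \code{fragment} (from \code{\link{bondsFromMapping}}).
#' @param experiment an \linkS4class{ExperimentEntry} of kind
#'   NMR-order-parameters (its \code{opData$bond} uses "carbon hydrogen"
#'   naming).
#' @param dS_exp default experimental error when the experiment table has
#'   none.
#' @return list with \code{bonds} (per-bond table incl. P), and fragment
#'   qualities \code{P_sn1}, \code{P_sn2}, \code{P_hg}, \code{P_total}.
#' @export
evaluateOrderParameterQuality <- function(ops, bonds_fragments, experiment,
                                          dS_exp = 0.02) {
  d <- ops@data
  d$fragment <- bonds_fragments$fragment[
    match(paste(d$carbon, d$hydrogen),
          paste(bonds_fragments$carbon, bonds_fragments$hydrogen))]
  ed <- experiment@opData
  d$S_exp <- ed$S_exp[match(d$bond, ed$bond)]
  d$dS_exp <- ed$dS_exp[match(d$bond, ed$bond)]
  d$dS_exp[is.na(d$dS_exp) & !is.na(d$S_exp)] <- dS_exp
  d$P <- NA_real_
  for (i in seq_len(nrow(d))) {
    if (is.na(d$S_exp[i])) next
    bq <- bondQuality(d$S_mean[i], d$s[i], d$n[i], d$S_exp[i], d$dS_exp[i])
    d$P[i] <- bq$P
  }
  list(bonds = d,
       P_sn1 = fragmentQuality(d, "sn-1")$P_frag,
       P_sn2 = fragmentQuality(d, "sn-2")$P_frag,
       P_hg = fragmentQuality(d, "headgroup")$P_frag,
       P_total = fragmentQuality(d, "total")$P_frag)
}
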