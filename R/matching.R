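## Simulation-experiment matching and quality-based ranking.

#' Molar composition of a simulation entry
#'
#' Molar percentages over membrane molecules (water and ions excluded; the
#' hydration level is handled by the separate fully-hydrated rule in
#' \code{\link{matchExperiments}}).
#'
#' @param entry a \linkS4class{SimulationEntry}.
#' @return Named numeric vector of molar percentages summing to 100.
#' @export
molarComposition <- function(entry) {
  comp <- entry@composition
  memb <- comp[isMembraneMolecule(comp$molecule), , drop = FALSE]
  agg <- tapply(memb$count, memb$molecule, sum)
  100 * agg / sum(agg)
}

#' Match a simulation against experimental data sets
#'
#' An experiment matches a simulation when every membrane molecule's molar
#' percentage agrees within \code{comp_tol} percentage units (molecules absent
#' from one side count as 0\%), charged lipids have identical counterions,
#' temperatures agree within \code{temp_tol} K, and the hydration level is
#' compatible: systems with molar water-to-lipid ratio of at least
#' \code{full_hydration} on both sides are considered fully hydrated,
#' otherwise the water percentage (over all molecules including water) must
#' agree within \code{comp_tol} units.
#'
#' @param sim a \linkS4class{SimulationEntry}.
#' @param experiments list of \linkS4class{ExperimentEntry} objects.
#' @param comp_tol composition tolerance, percentage units (default 3).
#' @param temp_tol temperature tolerance, K (default 2).
#' @param full_hydration water-per-lipid ratio above which a system is
#'   treated as fully hydrated (default 25).
#' @return The matching subset of \code{experiments} (possibly empty).
#' @export
matchExperiments <- function(sim, experiments, comp_tol = 3, temp_tol = 2,
                             full_hydration = 25) {
  sim_frac <- molarComposition(sim)
  sim_T <- sim@temperature
  sim_wl <- sim@waterPerLipid
  keep <- vapply(experiments, function(exp) {
    cond <- exp@conditions
    if (abs(cond$temperature - sim_T) > temp_tol) return(FALSE)
    exp_frac <- cond$composition
    mols <- union(names(sim_frac), names(exp_frac))
    s <- ifelse(mols %in% names(sim_frac), sim_frac[mols], 0)
    e <- ifelse(mols %in% names(exp_frac), exp_frac[mols], 0)
    if (any(abs(s - e) > comp_tol)) return(FALSE)
    if (any(mols[s > 0 | e > 0] %in% .charged_lipids)) {
      ci_s <- sim@counterions
      ci_e <- if (is.null(cond$counterions)) NA_character_ else cond$counterions
      if (!identical(is.na(ci_s), is.na(ci_e))) return(FALSE)
      if (!is.na(ci_s) && ci_s != ci_e) return(FALSE)
    }
    exp_wl <- if (is.null(cond$waterPerLipid)) Inf else cond$waterPerLipid
    sim_wl_eff <- if (is.na(sim_wl)) Inf else sim_wl
    if (sim_wl_eff < full_hydration || exp_wl < full_hydration) {
      ## percentage of water over all molecules, compared like a composition
      wpct <- function(wl) if (is.infinite(wl)) 100 * full_hydration /
        (full_hydration + 1) else 100 * wl / (wl + 1)
      if (abs(wpct(sim_wl_eff) - wpct(exp_wl)) > comp_tol) return(FALSE)
    }
    TRUE
  }, logical(1))
  experiments[keep]
}
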