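## End-to-end databank pipeline over a directory tree: analyse every
## simulation entry, evaluate qualities against matching experiments, rank.
## Artifact file names follow the databank conventions: apl.json,
## thickness.json, FormFactor.json, eq_times.json,
## [lipid]OrderParameters.json, [lipid]_OrderParameters_quality.json,
## [lipid]_FragmentQuality.json, system_quality.json, FormFactorQuality.json.

#' Parse an experimental data set directory
#'
#' An experiment folder holds a README.yaml (KIND, TEMPERATURE, COMPOSITION
#' as a molecule -> molar-percentage map, optional COUNTERIONS and
#' WATER_PER_LIPID, DATAFILE) plus the data CSV: columns \code{bond},
#' \code{S_exp}, \code{dS_exp} for NMR order parameters, or \code{q},
#' \code{F}, \code{dF} for X-ray form factors.
#'
#' @param dir experiment folder.
#' @return An \linkS4class{ExperimentEntry}.
#' @export
readExperimentEntry <- function(dir) {
  doc <- yaml::read_yaml(file.path(dir, "README.yaml"))
  data <- utils::read.csv(file.path(dir, doc$DATAFILE),
                          stringsAsFactors = FALSE)
  kind <- doc$KIND
  new("ExperimentEntry", kind = kind,
      conditions = list(
        composition = unlist(doc$COMPOSITION),
        counterions = if (!is.null(doc$COUNTERIONS)) doc$COUNTERIONS else NULL,
        temperature = as.numeric(doc$TEMPERATURE),
        waterPerLipid = if (!is.null(doc$WATER_PER_LIPID))
          as.numeric(doc$WATER_PER_LIPID) else NULL),
      opData = if (kind == "NMR-order-parameters") data else
        data.frame(bond = character(), S_exp = numeric(),
                   dS_exp = numeric()),
      ffData = if (kind == "X-ray-form-factor") data else
        data.frame(q = numeric(), F = numeric(), dF = numeric()))
}

#' @rdname readExperimentEntry
#' @param root directory whose subfolders (recursively) contain experiment
#'   README.yaml files.
#' @export
readExperimentEntries <- function(root) {
  files <- list.files(root, pattern = "^README\\.yaml$", recursive = TRUE,
                      full.names = TRUE)
  lapply(dirname(files), readExperimentEntry)
}

#' Analyse one simulation folder
#'
#' Loads the entry metadata and trajectory, discards the declared
#' equilibration period, and writes the five basic observables next to the
#' README.yaml: area per lipid (\code{apl.json}), bilayer thickness
#' (\code{thickness.json}), the X-ray form factor (\code{FormFactor.json}),
#' C-H bond order parameters per lipid
#' (\code{[lipid]OrderParameters.json}) and PCA equilibration times
#' (\code{eq_times.json}).
#'
#' @param sim_dir folder with README.yaml, trajectory.csv, topology.csv.
#' @param mappings named list of \linkS4class{MappingTable}s keyed by
#'   mapping id.
#' @return Invisibly, a list of the computed observables.
#' @export
analyzeSimulation <- function(sim_dir, mappings) {
  entry <- parseSimulationEntry(file.path(sim_dir, "README.yaml"),
                                file = TRUE)
  traj <- readFrameEnsembleCSV(file.path(sim_dir, entry@trajectoryName),
                               file.path(sim_dir, entry@topologyName))
  keep <- traj@times >= entry@equilibrationDiscard
  traj <- FrameEnsemble(traj@coords[keep, , , drop = FALSE],
                        box = traj@box[keep, , drop = FALSE],
                        times = traj@times[keep], atoms = traj@atoms)
  atoms <- traj@atoms
  comp <- entry@composition
  lipids <- comp$molecule[isMembraneMolecule(comp$molecule)]

  apl <- areaPerLipid(traj, sum(comp$count[comp$molecule %in% lipids]))
  writeDatabankJSON(list(apl = apl), file.path(sim_dir, "apl.json"))

  lip_sel <- atoms$molecule %in% lipids
  sol_sel <- atoms$molecule %in% .water_names
  prof <- electronDensityProfile(traj, lip_sel, which(sol_sel))
  thick <- tryCatch(
    bilayerThickness(prof@rhoTotal - prof@rhoSolvent, prof@rhoSolvent,
                     z = prof@binCenters),
    error = function(e) NA_real_)
  writeDatabankJSON(list(thickness = thick),
                    file.path(sim_dir, "thickness.json"))

  ff <- formFactor(prof)
  writeDatabankJSON(lapply(seq_along(ff@q), function(i) c(ff@q[i], ff@F[i])),
                    file.path(sim_dir, "FormFactor.json"))

  ops <- list(); eq <- list()
  for (lip in lipids) {
    map <- mappings[[comp$mapping[match(lip, comp$molecule)]]]
    bonds <- bondsFromMapping(map)
    op <- orderParameters(traj, bonds, lip)
    ops[[lip]] <- op
    d <- op@data
    writeDatabankJSON(
      stats::setNames(lapply(seq_len(nrow(d)), function(i)
        c(d$S_mean[i], d$sem[i], d$n[i])), d$bond),
      file.path(sim_dir, paste0(lip, "OrderParameters.json")))
    eq[[lip]] <- if (lip %in% .sterol_names) NA_real_ else
      tauRel(estimateEquilibration(traj, lip))
  }
  writeDatabankJSON(eq, file.path(sim_dir, "eq_times.json"))
  invisible(list(entry = entry, apl = apl, thickness = thick, ff = ff,
                 ops = ops, eq_times = eq, profile = prof))
}

#' Evaluate one simulation folder against experiments
#'
#' Matches the entry against the experiment collection, scores order
#' parameter qualities per bond, fragment and system, and the form-factor
#' quality, writing the databank-named artifacts into the folder. Requires
#' \code{\link{analyzeSimulation}} outputs to exist.
#'
#' @param sim_dir simulation folder.
#' @param experiments list of \linkS4class{ExperimentEntry}.
#' @param mappings named list of \linkS4class{MappingTable}s.
#' @return Invisibly, the quality report list (fragment qualities per lipid,
#'   system quality, FF quality) or NULL when nothing matches.
#' @export
evaluateQuality <- function(sim_dir, experiments, mappings) {
  entry <- parseSimulationEntry(file.path(sim_dir, "README.yaml"),
                                file = TRUE)
  matched <- matchExperiments(entry, experiments)
  if (!length(matched)) return(invisible(NULL))
  comp <- entry@composition
  lipids <- comp$molecule[isMembraneMolecule(comp$molecule)]
  frac <- molarComposition(entry) / 100

  lipid_rows <- list()
  for (lip in lipids) {
    opfile <- file.path(sim_dir, paste0(lip, "OrderParameters.json"))
    if (!file.exists(opfile)) next
    nmr <- Filter(function(e) e@kind == "NMR-order-parameters", matched)
    if (!length(nmr)) next
    raw <- jsonlite::read_json(opfile, simplifyVector = TRUE)
    map <- mappings[[comp$mapping[match(lip, comp$molecule)]]]
    bonds <- bondsFromMapping(map)
    d <- data.frame(bond = names(raw),
                    S_mean = vapply(raw, `[`, numeric(1), 1),
                    sem = vapply(raw, `[`, numeric(1), 2),
                    n = vapply(raw, `[`, numeric(1), 3),
                    stringsAsFactors = FALSE)
    d$carbon <- vapply(strsplit(d$bond, " "), `[`, character(1), 1)
    d$hydrogen <- vapply(strsplit(d$bond, " "), `[`, character(1), 2)
    d$s <- d$sem^2 * d$n
    opset <- new("OrderParameterSet",
                 data = d[, c("bond", "carbon", "hydrogen", "S_mean", "s",
                              "n", "sem")])
    q <- evaluateOrderParameterQuality(opset, bonds, nmr[[1]])
    writeDatabankJSON(
      stats::setNames(as.list(q$bonds$P), q$bonds$bond),
      file.path(sim_dir, paste0(lip, "_OrderParameters_quality.json")))
    writeDatabankJSON(list(`sn-1` = q$P_sn1, `sn-2` = q$P_sn2,
                           headgroup = q$P_hg, total = q$P_total),
                      file.path(sim_dir, paste0(lip, "_FragmentQuality.json")))
    lipid_rows[[lip]] <- data.frame(lipid = lip, P_sn1 = q$P_sn1,
                                    P_sn2 = q$P_sn2, P_hg = q$P_hg,
                                    P_total = q$P_total,
                                    stringsAsFactors = FALSE)
  }
  sysq <- NULL
  if (length(lipid_rows)) {
    sysq <- systemQuality(do.call(rbind, lipid_rows), frac)
    writeDatabankJSON(sysq, file.path(sim_dir, "system_quality.json"))
  }

  ffq <- NULL
  xray <- Filter(function(e) e@kind == "X-ray-form-factor", matched)
  ff_file <- file.path(sim_dir, "FormFactor.json")
  if (length(xray) && file.exists(ff_file)) {
    raw <- jsonlite::read_json(ff_file, simplifyVector = TRUE)
    sim_ff <- list(q = vapply(seq_len(nrow(raw)), function(i) raw[i, 1],
                              numeric(1)),
                   F = vapply(seq_len(nrow(raw)), function(i) raw[i, 2],
                              numeric(1)))
    ed <- xray[[1]]@ffData
    ffq <- formFactorQuality(sim_ff, ed$q, ed$F, ed$dF)
    writeDatabankJSON(list(FFQuality = ffq$FF_q, k_e = ffq$k_e,
                           q_min_sim = ffq$q_min_sim,
                           q_min_exp = ffq$q_min_exp),
                      file.path(sim_dir, "FormFactorQuality.json"))
  }
  invisible(list(lipids = lipid_rows, system = sysq, ff = ffq))
}

#' Run the full pipeline over a databank tree and rank the entries
#'
#' Analyses every simulation folder under \code{root/Simulations}, evaluates
#' qualities against the experiments under \code{root/experiments}, and
#' writes ranked lists (one per sort key) under \code{root/Ranking}.
#'
#' @param root databank root (as produced by
#'   \code{\link{buildMiniDatabank}}).
#' @param sort_keys quality keys to rank by.
#' @return Invisibly, a named list of ranking data.frames.
#' @export
runDatabankPipeline <- function(root,
                                sort_keys = c("P_sn1", "P_total", "FF_q")) {
  map_files <- list.files(file.path(root, "mapping_files"),
                          pattern = "\\.csv$", full.names = TRUE)
  mappings <- stats::setNames(lapply(map_files, readMappingTable),
                              sub("\\.csv$", "", basename(map_files)))
  sim_dirs <- list.dirs(file.path(root, "Simulations"), recursive = FALSE)
  experiments <- readExperimentEntries(file.path(root, "experiments"))
  for (d in sim_dirs) analyzeSimulation(d, mappings)
  for (d in sim_dirs) evaluateQuality(d, experiments, mappings)

  reports <- do.call(rbind, lapply(sim_dirs, function(d) {
    sq_file <- file.path(d, "system_quality.json")
    eq_file <- file.path(d, "eq_times.json")
    entry <- parseSimulationEntry(file.path(d, "README.yaml"), file = TRUE)
    sq <- if (file.exists(sq_file))
      jsonlite::read_json(sq_file, simplifyVector = TRUE) else list()
    eq <- if (file.exists(eq_file))
      jsonlite::read_json(eq_file, simplifyVector = TRUE) else list()
    fq_files <- list.files(d, pattern = "_FragmentQuality\\.json$",
                           full.names = TRUE)
    fq <- if (length(fq_files))
      jsonlite::read_json(fq_files[1], simplifyVector = TRUE) else list()
    ffq_file <- file.path(d, "FormFactorQuality.json")
    ffq <- if (file.exists(ffq_file))
      jsonlite::read_json(ffq_file, simplifyVector = TRUE) else list()
    num <- function(x) if (is.null(x) || !length(x) || is.na(x)) NA_real_
      else as.numeric(x)
    data.frame(entry_id = basename(d),
               P_sn1 = num(fq[["sn-1"]]), P_sn2 = num(fq[["sn-2"]]),
               P_hg = num(fq[["headgroup"]]), P_total = num(fq[["total"]]),
               FF_q = num(ffq[["FFQuality"]]),
               tau_rel = if (length(eq)) suppressWarnings(
                 max(unlist(eq), na.rm = TRUE)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  dir.create(file.path(root, "Ranking"), showWarnings = FALSE)
  out <- list()
  for (key in sort_keys) {
    rk <- rankSimulations(reports, key)
    writeDatabankJSON(rk, file.path(root, "Ranking",
                                    paste0("ranking_", key, ".json")))
    out[[key]] <- rk
  }
  invisible(out)
}

#' Build a synthetic mini-databank tree
#'
#' Writes a small, fully self-contained databank exercising the whole
#' pipeline: simulation folders (README.yaml + CSV trajectory/topology with
#' hash-derived folder names), a shared mapping table, and synthetic NMR and
#' X-ray experiment entries whose values bracket the simulated ones. One
#' entry is generated with slow conformational noise so that its tau_rel
#' exceeds the ranking discard threshold.
#'
#' @param root output directory (created).
#' @param seed integer seed.
#' @param n_entries number of simulation entries (default 3).
#' @return The root path, invisibly; folder names are the entry ids.
#' @export
buildMiniDatabank <- function(root, seed = 1, n_entries = 3) {
  dir.create(file.path(root, "Simulations"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(root, "mapping_files"), showWarnings = FALSE)
  writeMappingTable(toyLipidMapping(),
                    file.path(root, "mapping_files", "POPC_toy.csv"))

  S_chains <- c(-0.18, -0.15, -0.21)[seq_len(n_entries)]
  jitter_taus <- c(0, 0, 8)[seq_len(n_entries)]
  for (i in seq_len(n_entries)) {
    bl <- makeSyntheticBilayer(S_chain = S_chains[i],
                               jitter_tau = jitter_taus[i],
                               seed = seed + i)
    tmp <- tempfile(); tmp2 <- tempfile()
    writeFrameEnsembleCSV(bl$traj, tmp, tmp2)
    id <- computeEntryId(tmp, tmp2, files = TRUE)
    sim_dir <- file.path(root, "Simulations", id)
    dir.create(sim_dir, showWarnings = FALSE)
    file.copy(tmp, file.path(sim_dir, "trajectory.csv"))
    file.copy(tmp2, file.path(sim_dir, "topology.csv"))
    unlink(c(tmp, tmp2))
    entry <- new("SimulationEntry", entryId = id,
                 rawDataLink = "10.5281/zenodo.000000",
                 trajectoryName = "trajectory.csv",
                 topologyName = "topology.csv",
                 software = "synthetic", forceField = "toy",
                 temperature = 310,
                 composition = data.frame(
                   molecule = c("POPC", "SOL"),
                   ff_name = c("POPC", "SOL"),
                   mapping = c("POPC_toy", "POPC_toy"),
                   count = c(bl$n_lipids, 40 * bl$n_lipids),
                   stringsAsFactors = FALSE),
                 counterions = NA_character_,
                 trajectoryLength = max(frameTimes(bl$traj)),
                 equilibrationDiscard = 0, waterPerLipid = 40,
                 extras = list())
    writeSimulationEntry(entry, file.path(sim_dir, "README.yaml"))
  }

  ## synthetic experiments: NMR order parameters near the first entry's
  ## targets, and a slab-like X-ray form factor
  exp_nmr <- file.path(root, "experiments", "nmr", "POPC_310")
  dir.create(exp_nmr, recursive = TRUE, showWarnings = FALSE)
  bonds <- bondsFromMapping(toyLipidMapping())
  S_exp <- ifelse(bonds$fragment %in% c("headgroup", "glycerol backbone"),
                  -0.05, -0.18)
  utils::write.csv(data.frame(bond = paste(bonds$carbon, bonds$hydrogen),
                              S_exp = S_exp, dS_exp = 0.02),
                   file.path(exp_nmr, "order_parameters.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(yaml::as.yaml(list(KIND = "NMR-order-parameters",
                                TEMPERATURE = 310,
                                COMPOSITION = list(POPC = 100),
                                WATER_PER_LIPID = 40,
                                DATAFILE = "order_parameters.csv")),
             file.path(exp_nmr, "README.yaml"))

  exp_ff <- file.path(root, "experiments", "formfactor", "POPC_310")
  dir.create(exp_ff, recursive = TRUE, showWarnings = FALSE)
  slab <- makeSlabProfile(d = 40, contrast = 0.1)
  qgrid <- seq(0.02, 1, by = 0.002)
  utils::write.csv(data.frame(q = qgrid, F = slab$F_analytic(qgrid),
                              dF = 0.02),
                   file.path(exp_ff, "form_factor.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(yaml::as.yaml(list(KIND = "X-ray-form-factor",
                                TEMPERATURE = 310,
                                COMPOSITION = list(POPC = 100),
                                WATER_PER_LIPID = 40,
                                DATAFILE = "form_factor.csv")),
             file.path(exp_ff, "README.yaml"))
  invisible(root)
}
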