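## Metadata layer: universal molecule registry, README.yaml parsing and
## serialization, hash-derived entry identifiers.

.lipidbank <- new.env(parent = emptyenv())

.default_molecules <- c(
  ## phospholipids
  "POPC", "POPE", "POPG", "POPS", "POPI", "DPPC", "DOPC", "DMPC", "DLPC",
  ## sterols and diacylglycerols
  "CHOL", "DCHOL", "DOG", "SDG",
  ## sphingolipids and cardiolipins
  "PSM", "SSM", "CER", "TOCL", "TMCL",
  ## solvent and ions
  "SOL", "SOD", "CLA", "POT", "CAL")

.water_names <- "SOL"
.ion_names <- c("SOD", "CLA", "POT", "CAL")
.sterol_names <- c("CHOL", "DCHOL")
.charged_lipids <- c("POPG", "POPS", "POPI", "TOCL", "TMCL")

#' Universal molecule names known to the databank layer
#'
#' The registry of universal molecule abbreviations accepted in simulation
#' entries. \code{registerMolecules()} extends it (the naming convention grows
#' as new lipids are contributed).
#'
#' @return Character vector of universal names.
#' @export
knownMolecules <- function() {
  extra <- get0("molecules", envir = .lipidbank, ifnotfound = character())
  unique(c(.default_molecules, extra))
}

#' @rdname knownMolecules
#' @param names character vector of new universal names to accept.
#' @export
registerMolecules <- function(names) {
  extra <- get0("molecules", envir = .lipidbank, ifnotfound = character())
  assign("molecules", unique(c(extra, names)), envir = .lipidbank)
  invisible(knownMolecules())
}

#' Is a universal molecule name a membrane component?
#'
#' Water and monatomic ions are not membrane components; lipids, sterols,
#' diacylglycerols, sphingolipids and cardiolipins are.
#'
#' @param molecule character vector of universal names.
#' @return logical vector.
#' @export
isMembraneMolecule <- function(molecule) {
  !(molecule %in% c(.water_names, .ion_names))
}

.required_keys <- c("DOI", "TRJ", "TPR", "SOFTWARE", "TEMPERATURE",
                    "COMPOSITION", "TRJLENGTH", "TIMELEFTOUT")

#' Parse a README.yaml simulation entry
#'
#' Reads the databank README.yaml dialect into a
#' \linkS4class{SimulationEntry}. Required keys are \code{DOI}, \code{TRJ},
#' \code{TPR}, \code{SOFTWARE}, \code{TEMPERATURE}, \code{COMPOSITION} (one
#' block per molecule with \code{NAME}, \code{MAPPING}, \code{COUNT}),
#' \code{TRJLENGTH} (ns) and \code{TIMELEFTOUT} (ns, the equilibration period
#' discarded from all analyses). Unknown keys are preserved as opaque extras
#' and written back verbatim by \code{writeSimulationEntry()}.
#'
#' @param yaml_text character scalar of YAML text, or a file path when
#'   \code{file = TRUE}.
#' @param file logical; treat \code{yaml_text} as a path.
#' @return A \linkS4class{SimulationEntry}.
#' @export
parseSimulationEntry <- function(yaml_text, file = FALSE) {
  doc <- if (file) yaml::read_yaml(yaml_text) else yaml::yaml.load(yaml_text)
  if (!is.list(doc)) stop("entry is not a YAML mapping")
  missing <- setdiff(.required_keys, names(doc))
  if (length(missing))
    stop("schema error: missing required key(s): ",
         paste(missing, collapse = ", "))
  comp_raw <- doc$COMPOSITION
  comp <- do.call(rbind, lapply(names(comp_raw), function(m) {
    blk <- comp_raw[[m]]
    for (k in c("NAME", "MAPPING", "COUNT"))
      if (is.null(blk[[k]]))
        stop("schema error: COMPOSITION entry '", m, "' missing key: ", k)
    data.frame(molecule = m, ff_name = as.character(blk$NAME),
               mapping = as.character(blk$MAPPING),
               count = as.integer(blk$COUNT), stringsAsFactors = FALSE)
  }))
  unknown <- setdiff(comp$molecule, knownMolecules())
  if (length(unknown))
    stop("naming error: unknown universal molecule name(s): ",
         paste(unknown, collapse = ", "))
  n_water <- sum(comp$count[comp$molecule %in% .water_names])
  n_lipid <- sum(comp$count[isMembraneMolecule(comp$molecule)])
  wpl <- if (!is.null(doc$WATER_PER_LIPID)) as.numeric(doc$WATER_PER_LIPID)
         else if (n_lipid > 0) n_water / n_lipid else NA_real_
  extras <- doc[setdiff(names(doc),
                        c(.required_keys, "ID", "FF", "COUNTERIONS",
                          "WATER_PER_LIPID"))]
  new("SimulationEntry",
      entryId = if (!is.null(doc$ID)) as.character(doc$ID) else NA_character_,
      rawDataLink = as.character(doc$DOI),
      trajectoryName = as.character(doc$TRJ),
      topologyName = as.character(doc$TPR),
      software = as.character(doc$SOFTWARE),
      forceField = if (!is.null(doc$FF)) as.character(doc$FF) else NA_character_,
      temperature = as.numeric(doc$TEMPERATURE),
      composition = comp,
      counterions = if (!is.null(doc$COUNTERIONS)) as.character(doc$COUNTERIONS)
                    else NA_character_,
      trajectoryLength = as.numeric(doc$TRJLENGTH),
      equilibrationDiscard = as.numeric(doc$TIMELEFTOUT),
      waterPerLipid = wpl,
      extras = extras)
}

#' @rdname parseSimulationEntry
#' @param entry a \linkS4class{SimulationEntry}.
#' @param path optional file to write; when \code{NULL} the YAML text is
#'   returned.
#' @export
writeSimulationEntry <- function(entry, path = NULL) {
  comp <- entry@composition
  comp_list <- stats::setNames(lapply(seq_len(nrow(comp)), function(i)
    list(NAME = comp$ff_name[i], MAPPING = comp$mapping[i],
         COUNT = comp$count[i])), comp$molecule)
  doc <- c(list(DOI = entry@rawDataLink, TRJ = entry@trajectoryName,
                TPR = entry@topologyName, SOFTWARE = entry@software,
                TEMPERATURE = entry@temperature, COMPOSITION = comp_list,
                TRJLENGTH = entry@trajectoryLength,
                TIMELEFTOUT = entry@equilibrationDiscard),
           if (!is.na(entry@forceField)) list(FF = entry@forceField),
           if (!is.na(entry@waterPerLipid))
             list(WATER_PER_LIPID = entry@waterPerLipid),
           if (!is.na(entry@counterions)) list(COUNTERIONS = entry@counterions),
           if (!is.na(entry@entryId)) list(ID = entry@entryId),
           entry@extras)
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) txt else { writeLines(txt, path); invisible(path) }
}

#' Read all README.yaml entries under a directory
#'
#' @param dir directory scanned recursively for files named README.yaml.
#' @return Named list of \linkS4class{SimulationEntry} objects (names are the
#'   containing folder names).
#' @export
readSimulationEntries <- function(dir) {
  files <- list.files(dir, pattern = "^README\\.yaml$", recursive = TRUE,
                      full.names = TRUE)
  entries <- lapply(files, parseSimulationEntry, file = TRUE)
  names(entries) <- basename(dirname(files))
  entries
}

#' Hash-derived identifier for a simulation entry
#'
#' Computes the unique folder name of an entry from the raw topology and
#' trajectory byte streams: an md5 digest of the concatenation of the
#' topology digest and the trajectory digest (order fixed, so swapping the
#' two files changes the identifier).
#'
#' @param trajectory,topology raw vectors, or file paths when
#'   \code{files = TRUE}.
#' @param files logical; treat arguments as paths.
#' @return Character scalar (32 hex digits).
#' @export
computeEntryId <- function(trajectory, topology, files = FALSE) {
  if (files) {
    trajectory <- readBin(trajectory, "raw", file.size(trajectory))
    topology <- readBin(topology, "raw", file.size(topology))
  }
  if (!length(trajectory) || !length(topology))
    stop("input error: empty trajectory or topology byte stream")
  h <- paste0(.md5raw(topology), .md5raw(trajectory))
  .md5raw(charToRaw(h))
}

.md5raw <- function(bytes) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(bytes, tf)
  unname(tools::md5sum(tf))
}
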