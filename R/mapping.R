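## Universal naming: mapping tables and atom resolution.

#' Construct or read a mapping table
#'
#' A mapping table translates force-field-specific atom names into universal
#' atom names and assigns every atom to a fragment (headgroup, glycerol
#' backbone, acyl chain sn-1/sn-2, other).
#'
#' @param id mapping-table identifier.
#' @param rows data.frame with columns \code{universal_atom}, \code{ff_atom},
#'   \code{fragment}.
#' @return A \linkS4class{MappingTable}.
#' @export
MappingTable <- function(id, rows) {
  new("MappingTable", id = id,
      rows = as.data.frame(rows, stringsAsFactors = FALSE))
}

#' @rdname MappingTable
#' @param path CSV file with the three mapping columns; the id defaults to the
#'   file name.
#' @export
readMappingTable <- function(path, id = basename(path)) {
  MappingTable(id, utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname MappingTable
#' @param table a MappingTable to write.
#' @export
writeMappingTable <- function(table, path) {
  utils::write.csv(table@rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve a force-field atom name to its universal name and fragment
#'
#' @param entry a \linkS4class{SimulationEntry}.
#' @param molecule universal molecule name present in the entry composition.
#' @param ff_atom force-field atom name.
#' @param tables named list of \linkS4class{MappingTable} objects, keyed by
#'   mapping-table id.
#' @return list with \code{universal_atom} and \code{fragment}.
#' @export
resolveAtom <- function(entry, molecule, ff_atom, tables) {
  comp <- entry@composition
  i <- match(molecule, comp$molecule)
  if (is.na(i)) stop("molecule '", molecule, "' not in entry composition")
  tab <- tables[[comp$mapping[i]]]
  if (is.null(tab)) stop("mapping table '", comp$mapping[i], "' not loaded")
  j <- match(ff_atom, tab@rows$ff_atom)
  if (is.na(j))
    stop("unmapped-atom error: atom '", ff_atom, "' absent from mapping '",
         tab@id, "'")
  list(universal_atom = tab@rows$universal_atom[j],
       fragment = tab@rows$fragment[j])
}

#' C-H bond list of a mapping table
#'
#' Enumerates (carbon, hydrogen) universal-atom pairs from a mapping table.
#' Hydrogens are recognised by universal names containing "H" directly after
#' the carbon label they hang on (convention: hydrogen names are the carbon
#' name with an H suffix block, e.g. C12 / C12H1). Used to drive the order
#' parameter calculation from the metadata alone.
#'
#' @param table a \linkS4class{MappingTable}.
#' @return data.frame with columns \code{carbon}, \code{hydrogen},
#'   \code{fragment}.
#' @export
bondsFromMapping <- function(table) {
  rows <- table@rows
  hyd <- grepl("H[0-9]*$", rows$universal_atom) &
    !grepl("^H", rows$universal_atom)
  out <- lapply(which(hyd), function(j) {
    carbon <- sub("H[0-9]*$", "", rows$universal_atom[j])
    i <- match(carbon, rows$universal_atom)
    if (is.na(i)) return(NULL)
    data.frame(carbon = carbon, hydrogen = rows$universal_atom[j],
               fragment = rows$fragment[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(carbon = character(), hydrogen = character(),
               fragment = character(), stringsAsFactors = FALSE)
  else out
}
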