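## Bondi (1964) van der Waals radii by element; the working set for protein
## heavy atoms plus hydrogen and halogens. Unknown elements fall back to
## 1.8 A with a warning.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, CL = 1.75, SE = 1.90, BR = 1.85, I = 1.98)

VDW_DEFAULT <- 1.8

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

vdwRadius <- function(element) {
  el <- toupper(trimws(element))
  r <- VDW_RADII[el]
  unknown <- is.na(r) | el == ""
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using default radius ", VDW_DEFAULT, " A")
    r[unknown] <- VDW_DEFAULT
  }
  unname(r)
}

## Derive an element symbol from a PDB atom name when the element column is
## absent (first alphabetic character, two-letter check against the table).
elementFromName <- function(elety) {
  nm <- toupper(gsub("[^A-Z]", "", toupper(elety)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% names(VDW_RADII) & !substr(nm, 1, 1) %in% c("C", "N", "O",
                                                              "H", "S", "P"),
         two, substr(nm, 1, 1))
}

#' Load a complex structure as a StructureModel
#'
#' Parses a PDB or mmCIF file, keeps polymer protein chains only (waters,
#' ions, glycans and other hetero groups are dropped), resolves alternate
#' locations by keeping the highest-occupancy conformer (ties broken by
#' altloc identifier order), and assigns each atom a van der Waals radius
#' from a fixed element table (Bondi); unknown elements get 1.8 A with a
#' warning.
#'
#' @param path path to the structure file.
#' @param format \code{"pdb"}, \code{"mmcif"}, or \code{"auto"} (by file
#'   extension; \code{.cif} means mmCIF).
#' @param sourceId identifier recorded in the model; defaults to the file
#'   base name.
#' @return a \linkS4class{StructureModel}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' tc <- generateToyComplex(10, 4, 3.3, c(5, 8), seed = 1)
#' writeModelPdb(tc$model, pdb)
#' loadStructure(pdb)
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          sourceId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- obj$atom
  at <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no polymer residues in '", path, "' after filtering")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  ## altloc: highest occupancy wins, ties by altloc id order
  if (any(at$alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -occ, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                         unique(paste(at$chain, at$resno, at$insert,
                                      sep = "\r")))), , drop = FALSE]
  }
  element <- if ("elesy" %in% names(at) && !all(is.na(at$elesy)) &&
                 !all(trimws(at$elesy) == "")) {
    ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
           elementFromName(at$elety), toupper(trimws(at$elesy)))
  } else elementFromName(at$elety)
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = as.character(at$insert), resid = as.character(at$resid),
    elety = as.character(at$elety), element = element,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    radius = vdwRadius(element), stringsAsFactors = FALSE)
  if (is.null(sourceId))
    sourceId <- sub("\\.[^.]*$", "", basename(path))
  new("StructureModel", sourceId = sourceId, atoms = atoms)
}

#' Construct a StructureModel from an atom table
#'
#' Low-level constructor used by the synthetic-data generator and tests.
#'
#' @param atoms data.frame with the columns documented in
#'   \linkS4class{StructureModel}; \code{radius} may be omitted, in which
#'   case it is assigned from the element table.
#' @param sourceId identifier.
#' @export
structureModel <- function(atoms, sourceId = "model") {
  if (is.null(atoms$radius)) atoms$radius <- vdwRadius(atoms$element)
  if (is.null(atoms$insert)) atoms$insert <- ""
  new("StructureModel", sourceId = sourceId,
      atoms = as.data.frame(atoms, stringsAsFactors = FALSE))
}

#' Define the antigen/partner chain partition of a complex
#'
#' @param targetChains chain ids of the donor antigen.
#' @param partnerChains chain ids of the binding partner.
#' @export
chainPartition <- function(targetChains, partnerChains) {
  new("ChainPartition", targetChains = as.character(targetChains),
      partnerChains = as.character(partnerChains))
}

## Subset a model to a set of chains, keeping atom order.
subsetChains <- function(model, chains) {
  a <- model@atoms
  a <- a[a$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms in chains ", paste(chains, collapse = ","))
  new("StructureModel", sourceId = model@sourceId, atoms = a)
}

checkPartition <- function(model, partition) {
  present <- chainIds(model)
  missing <- setdiff(c(partition@targetChains, partition@partnerChains),
                     present)
  if (length(missing))
    stop("partition chain(s) missing from model: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

## Residue table of a model: one row per residue, in atom order.
residueTable <- function(model, chains = NULL) {
  a <- model@atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  a[!duplicated(paste(a$chain, a$resno, a$insert, sep = "\r")),
    c("chain", "resno", "insert", "resid")]
}

#' Extract the one-letter sequence of a chain
#'
#' Residues in file order; non-standard names become \code{X}.
#'
#' @param model a StructureModel.
#' @param chain a chain id.
#' @export
chainSequence <- function(model, chain) {
  res <- residueTable(model, chain)
  if (nrow(res) == 0L) stop("chain ", chain, " not in model")
  aa <- bio3d::aa321(res$resid)
  aa[is.na(aa) | aa == ""] <- "X"
  paste(aa, collapse = "")
}

#' Write a StructureModel as minimal PDB
#'
#' Emits plain ATOM records (serial, name, residue, chain, coordinates,
#' occupancy 1.00, element). Used to round-trip synthetic fixtures through
#' the real reader.
#'
#' @param model a StructureModel.
#' @param path output path.
#' @export
writeModelPdb <- function(model, path) {
  a <- model@atoms
  name <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, 1, 0,
    toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
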