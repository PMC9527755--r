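## Incoherent cross-section calculator: sum of tabulated atomic incoherent
## cross sections over the atoms of a protein, from a PDB file or a
## residue-composition table.  A cross-check utility: the shipped species
## defaults use the constants computed by the original study.

#' Atomic incoherent neutron cross sections
#'
#' Bound-atom incoherent cross sections (barn) from the standard neutron
#' data table (Sears 1992), bundled as a versioned CSV in
#' \code{inst/extdata/atomic_incoherent_xsec.csv}.
#'
#' @return data.frame with columns \code{element}, \code{sigma_inc_barn}.
#' @export
atomic_xsec_table <- function() {
  path <- system.file("extdata", "atomic_incoherent_xsec.csv",
                      package = "biqens", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## internal: named lookup vector element -> sigma_inc
atomic_xsec_lookup <- function() {
  tab <- atomic_xsec_table()
  stats::setNames(tab$sigma_inc_barn, toupper(tab$element))
}

## In-chain residue elemental compositions (free amino acid minus H2O),
## neutral protonation states.  n_H counts every hydrogen; n_H_labile the
## O/N/S-bound (exchangeable) ones, including the backbone amide H.
residue_compositions <- function() {
  # residue  C  H  N  O  S  labileH
  m <- rbind(
    ALA = c(3, 5, 1, 1, 0, 1),  ARG = c(6, 12, 4, 1, 0, 5),
    ASN = c(4, 6, 2, 2, 0, 3),  ASP = c(4, 5, 1, 3, 0, 2),
    CYS = c(3, 5, 1, 1, 1, 2),  GLN = c(5, 8, 2, 2, 0, 3),
    GLU = c(5, 7, 1, 3, 0, 2),  GLY = c(2, 3, 1, 1, 0, 1),
    HIS = c(6, 7, 3, 1, 0, 2),  ILE = c(6, 11, 1, 1, 0, 1),
    LEU = c(6, 11, 1, 1, 0, 1), LYS = c(6, 12, 2, 1, 0, 3),
    MET = c(5, 9, 1, 1, 1, 1),  PHE = c(9, 9, 1, 1, 0, 1),
    PRO = c(5, 7, 1, 1, 0, 0),  SER = c(3, 5, 1, 2, 0, 2),
    THR = c(4, 7, 1, 2, 0, 2),  TRP = c(11, 10, 2, 1, 0, 2),
    TYR = c(9, 9, 1, 2, 0, 2),  VAL = c(5, 9, 1, 1, 0, 1))
  colnames(m) <- c("C", "H", "N", "O", "S", "H_labile")
  m
}

#' Parse ATOM/HETATM records of a PDB file
#'
#' Minimal fixed-column PDB reader (no installed R package reads PDB).
#'
#' @param path PDB file path.
#' @return data.frame with columns \code{atom}, \code{element},
#'   \code{residue}, \code{chain}.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines))
    return(data.frame(atom = character(), element = character(),
                      residue = character(), chain = character()))
  atom <- trimws(substr(lines, 13, 16))
  residue <- trimws(substr(lines, 18, 20))
  chain <- trimws(substr(lines, 22, 22))
  element <- toupper(trimws(substr(lines, 77, 78)))
  # fall back to the atom-name convention when the element column is blank
  blank <- element == ""
  element[blank] <- toupper(substr(sub("^[0-9]*", "", atom[blank]), 1, 1))
  data.frame(atom = atom, element = element, residue = residue,
             chain = chain, stringsAsFactors = FALSE)
}

#' Incoherent cross section of a protein
#'
#' Sums tabulated atomic incoherent cross sections over all atoms of a
#' structure.  Input is either a PDB file (when hydrogens are absent from
#' the coordinates they are added per residue template) or a
#' residue-composition table.  Under \code{exchange = "labile-D"} the
#' O/N/S-bound hydrogens are counted as deuterium (fully exchanged in
#' D2O); \code{"all-H"} counts every hydrogen as protium.
#'
#' Note: the constants printed by the original study (464377.95 barn for
#' BSA, 1011495.41 barn for Ig) are not the plain all-H Sears-table sums
#' over the sequence hydrogens; the hydrogen convention used there is not
#' stated.  This calculator is a transparent cross-check, not the source
#' of the shipped defaults.
#'
#' @param pdb path to a PDB file, or \code{NULL}.
#' @param residues alternatively, a named vector of residue counts
#'   (three-letter codes), e.g. \code{c(GLY = 10, ALA = 5)}.
#' @param exchange \code{"all-H"} (default) or \code{"labile-D"}.
#' @return list with \code{sigma_inc} (barn), \code{by_element} (named
#'   vector of barn per element), \code{n_atoms} (named counts).
#' @export
pdb_cross_section <- function(pdb = NULL, residues = NULL,
                              exchange = c("all-H", "labile-D")) {
  exchange <- match.arg(exchange)
  comp <- residue_compositions()
  if (!is.null(pdb)) {
    at <- read_pdb_atoms(pdb)
    if (nrow(at) == 0) {
      counts <- numeric(0)
    } else if (any(at$element == "H")) {
      # hydrogens present: count elements as given
      counts <- table(at$element)
      counts <- stats::setNames(as.numeric(counts), names(counts))
      if (exchange == "labile-D") {
        # labile hydrogens are identified via residue templates
        counts <- swap_labile(counts, at, comp)
      }
    } else {
      # heavy atoms only: rebuild compositions from residue templates,
      # counting one residue per CA atom
      ca <- at[at$atom == "CA", ]
      unknown <- setdiff(unique(ca$residue), rownames(comp))
      if (length(unknown))
        stop("unknown residue(s): ", paste(unknown, collapse = ", "))
      rc <- table(ca$residue)
      counts <- residue_counts_to_elements(
        stats::setNames(as.numeric(rc), names(rc)), comp, exchange)
    }
  } else if (!is.null(residues)) {
    unknown <- setdiff(names(residues), rownames(comp))
    if (length(unknown))
      stop("unknown residue(s): ", paste(unknown, collapse = ", "))
    counts <- residue_counts_to_elements(residues, comp, exchange)
  } else stop("provide either a pdb path or a residue table")

  lut <- atomic_xsec_lookup()
  if (length(counts) == 0)
    return(list(sigma_inc = 0, by_element = numeric(0), n_atoms = numeric(0)))
  missing_el <- setdiff(names(counts), names(lut))
  if (length(missing_el))
    stop("no tabulated cross section for element(s): ",
         paste(missing_el, collapse = ", "))
  by_el <- counts * lut[names(counts)]
  list(sigma_inc = sum(by_el), by_element = by_el, n_atoms = counts)
}

## internal: residue counts -> element counts under an exchange model
residue_counts_to_elements <- function(residues, comp, exchange) {
  res <- comp[names(residues), , drop = FALSE]
  tot <- colSums(res * as.numeric(residues))
  counts <- c(C = tot[["C"]], H = tot[["H"]], N = tot[["N"]],
              O = tot[["O"]], S = tot[["S"]])
  if (exchange == "labile-D") {
    lab <- tot[["H_labile"]]
    counts["H"] <- counts["H"] - lab
    counts <- c(counts, D = lab)
  }
  counts[counts > 0]
}

## internal: move template labile hydrogens from H to D for explicit-H input
swap_labile <- function(counts, at, comp) {
  ca <- at[at$atom == "CA", ]
  known <- intersect(unique(ca$residue), rownames(comp))
  rc <- table(ca$residue[ca$residue %in% known])
  lab <- sum(comp[names(rc), "H_labile"] * as.numeric(rc))
  lab <- min(lab, counts["H"])
  counts["H"] <- counts["H"] - lab
  counts <- c(counts, D = unname(lab))
  counts
}
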