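# three-letter -> one-letter residue codes
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Parse a PDB-format structure
#'
#' Fixed-column parsing of ATOM/HETATM records. Alternate locations other
#' than blank or 'A' are excluded (with a warning); insertion codes are
#' preserved inside residue identifiers. TER/END/remark lines are ignored.
#'
#' @param pdb_text PDB text (single string or character vector of lines), or
#'   a path to a PDB file.
#' @return list of class `protein_structure` with an `atoms` data.frame
#'   (serial, name, altloc, resname, chain, resseq, icode, resid, x, y, z).
#' @export
read_structure <- function(pdb_text) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    lines <- readLines(pdb_text, warn = FALSE)
  } else if (length(pdb_text) == 1L) {
    lines <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- pdb_text
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM records found", call. = FALSE)
  idx <- which(is_atom)
  al <- lines[idx]
  f <- function(from, to) trimws(substr(al, from, to))
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  serial <- suppressWarnings(as.integer(f(7, 11)))
  resseq <- suppressWarnings(as.integer(f(23, 26)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resseq))
  if (length(bad) > 0L) {
    stop("malformed ATOM record at line ", idx[bad[1]], ": ",
         al[bad[1]], call. = FALSE)
  }
  altloc <- substr(al, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  if (!all(keep)) {
    warning(sum(!keep), " atoms with non-'A' altloc excluded", call. = FALSE)
  }
  atoms <- data.frame(serial = serial,
                      name = f(13, 16),
                      altloc = trimws(altloc),
                      resname = f(18, 20),
                      chain = substr(al, 22, 22),
                      resseq = resseq,
                      icode = trimws(substr(al, 27, 27)),
                      x = x, y = y, z = z,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  atoms$resid <- paste0(atoms$chain, atoms$resseq,
                        ifelse(atoms$icode == "", "", atoms$icode))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resid)), "residues, chains:",
      paste(unique(x$atoms$chain), collapse = ","), "\n")
  invisible(x)
}

atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}
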