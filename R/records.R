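#' @importFrom stats runif rnorm setNames cov
#' @importFrom utils head tail write.table read.table
NULL

# The 20 standard amino-acid one-letter codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default hydrophobic amino-acid set
#'
#' The lid and tunnel hydrophobicity statistics count residues belonging to a
#' configurable set of one-letter codes. The default, \{A, V, L, I, M, F, W,
#' P\}, is the aliphatic/aromatic apolar set commonly used for lipase lid
#' composition and is the calibration choice under which the packaged
#' reference panel reproduces the canonical Lip2 > Lip3 > Lip1 lid ordering
#' (12, 10, 8 hydrophobic residues).
#'
#' @param letters character vector of one-letter residue codes.
#' @return A validated character vector of class `hydrophobic_set`.
#' @export
#' @examples
#' hydrophobic_set()
hydrophobic_set <- function(letters = c("A", "V", "L", "I", "M", "F", "W", "P")) {
  letters <- toupper(unique(as.character(letters)))
  if (length(letters) == 0L) {
    stop("hydrophobic set must be non-empty", call. = FALSE)
  }
  bad <- setdiff(letters, AA20)
  if (length(bad) > 0L) {
    stop("hydrophobic set contains non-standard letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(letters, class = "hydrophobic_set")
}

#' Read a protein FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]; full header lines are
#' kept as names so that free-text descriptions remain searchable.
#'
#' @param path path to a (possibly multi-record) protein FASTA file.
#' @return An [Biostrings::AAStringSet] with headers as names.
#' @export
read_proteins <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' Write protein records as FASTA
#'
#' @param records an [Biostrings::AAStringSet].
#' @param path output path.
#' @param width line-wrap width in residues (default 60).
#' @export
write_proteins <- function(records, path, width = 60L) {
  Biostrings::writeXStringSet(records, filepath = path, width = width)
  invisible(path)
}

# First whitespace-delimited token of each header.
record_ids <- function(records) {
  sub("\\s.*$", "", names(records))
}

# Header text after the id token ("" when absent).
record_descriptions <- function(records) {
  d <- sub("^\\S+\\s*", "", names(records))
  d[d == names(records)] <- ""
  d
}

# Extract `key=value` fields from headers; NA where the key is absent.
header_field <- function(records, key) {
  pat <- paste0("(^|\\s)", key, "=([^\\s]+)")
  m <- regmatches(names(records), regexpr(pat, names(records), perl = TRUE))
  out <- rep(NA_character_, length(records))
  hit <- grepl(pat, names(records), perl = TRUE)
  out[hit] <- sub(pat, "\\2", regmatches(names(records),
                                         regexpr(pat, names(records), perl = TRUE)),
                  perl = TRUE)
  out
}

as_aa_set <- function(records) {
  if (inherits(records, "AAStringSet")) return(records)
  if (is.character(records)) {
    if (is.null(names(records))) {
      names(records) <- paste0("seq", seq_along(records))
    }
    return(Biostrings::AAStringSet(records))
  }
  stop("records must be an AAStringSet or a named character vector",
       call. = FALSE)
}

# Sample `n` residues from a probability vector over AA20, optionally
# excluding letters (probabilities renormalised).
sample_residues <- function(n, freqs, exclude = character(0)) {
  stopifnot(length(freqs) == 20L)
  names(freqs) <- AA20
  if (length(exclude) > 0L) freqs[exclude] <- 0
  freqs <- freqs / sum(freqs)
  sample(AA20, n, replace = TRUE, prob = freqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
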