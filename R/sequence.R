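#' @keywords internal
"_PACKAGE"

#' @useDynLib fibrilMC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# the nine residue types treated as hydrophobic (epsilon_{a,solv} > 0)
HYDROPHOBIC_SET <- c("C", "F", "L", "W", "V", "I", "M", "Y", "A")

#' Peptide sequence with hydrophobicity flags
#'
#' @param residues A single string (e.g. `"TFTFTFT"`) or a character vector of
#'   one-letter amino-acid codes; lowercase input is normalised to uppercase.
#' @return An object of class `peptide_sequence`: a list with `residues`
#'   (character vector) and `hydrophobic` (logical vector flagging membership
#'   of the hydrophobic set C, F, L, W, V, I, M, Y, A).
#' @examples
#' s <- peptide_sequence("TFTFTFT")
#' sum(s$hydrophobic)  # 3 phenylalanines
#' @export
peptide_sequence <- function(residues) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  if (length(residues) < 1L)
    stop("sequence must contain at least one residue", call. = FALSE)
  bad <- !(residues %in% AA_ALPHABET)
  if (any(bad))
    stop(sprintf("unknown residue code '%s' at position %d",
                 residues[which(bad)[1]], which(bad)[1]), call. = FALSE)
  structure(list(residues = residues,
                 hydrophobic = residues %in% HYDROPHOBIC_SET),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("Peptide %s (%d residues, %d hydrophobic)\n",
              paste(x$residues, collapse = ""), length(x$residues),
              sum(x$hydrophobic)))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) length(x$residues)

#' Is each residue of a sequence hydrophobic?
#'
#' @param sequence A [peptide_sequence()].
#' @return Logical vector, one entry per residue.
#' @export
is_hydrophobic <- function(sequence) {
  stopifnot(inherits(sequence, "peptide_sequence"))
  sequence$hydrophobic
}

aa_index0 <- function(residues) match(residues, AA_ALPHABET) - 1L

#' Read peptide sequences from a FASTA file
#'
#' Thin wrapper around [seqinr::read.fasta()] returning a named list of
#' [peptide_sequence()] objects; lowercase residues are normalised.
#'
#' @param path Path to an (uncompressed) FASTA file of amino-acid sequences.
#' @return Named list of `peptide_sequence` objects.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  out <- lapply(fa, function(s) peptide_sequence(toupper(as.character(s))))
  names(out) <- names(fa)
  out
}
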