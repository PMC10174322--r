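# Sequence utilities. All sequences are handled in memory as RNA
# (A/C/G/U) character strings, 5'->3'; FASTA readers accept DNA (T) and
# convert on input.

RNA_BASES <- c("A", "C", "G", "U")

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements, 5'->3'.
#' @export
rna_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (!all(b %in% names(comp))) stop("non-RNA letter in sequence")
    paste(rev(unname(comp[b])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Read sequences from FASTA as RNA
#'
#' Thin wrapper around [Biostrings::readBStringSet()]; `T` is converted to
#' `U` so DNA-convention files are accepted.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-ACGU/T letters in sequences: ",
         paste(utils::head(names(seqs)[bad], 3L), collapse = ", "))
  seqs
}

#' Write RNA sequences to FASTA
#'
#' @param seqs named character vector of RNA sequences (written with U).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_rna <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# validate an RNA alphabet, used by the target-prediction entry points
check_rna <- function(x, what = "sequence") {
  if (any(grepl("[^ACGU]", x)))
    stop(what, " contains letters outside the RNA alphabet A/C/G/U")
  invisible(x)
}
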