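#' Reference sequence
#'
#' Light container for a linear DNA reference against which variant calls are
#' described. Positions are 1-based, following the EMPOP / rCRS convention.
#' The mitochondrial genome's circularity is ignored: the reference is treated
#' as a linear string.
#'
#' @param bases A single string over A/C/G/T (case is normalized to upper).
#' @param name Sequence name.
#' @return An object of class `reference_sequence` with fields `name`,
#'   `bases` and `length`.
#' @examples
#' ref <- reference_sequence("AACAAGT")
#' ref$length
#' @export
reference_sequence <- function(bases, name = "ref") {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  if (nchar(bases) == 0L) {
    stop("reference sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", bases)) {
    stop("reference sequence may only contain A/C/G/T", call. = FALSE)
  }
  structure(
    list(name = as.character(name), bases = bases, length = nchar(bases)),
    class = "reference_sequence"
  )
}

#' @export
print.reference_sequence <- function(x, ...) {
  shown <- if (x$length > 60L) paste0(substr(x$bases, 1L, 57L), "...") else x$bases
  cat("<reference_sequence> ", x$name, " (", x$length, " bp)\n", shown, "\n", sep = "")
  invisible(x)
}

#' Read a reference sequence from a FASTA file
#'
#' The first record is used; additional records are ignored with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [reference_sequence()].
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path, call. = FALSE)
  if (length(seqs) > 1L) {
    warning("FASTA contains ", length(seqs), " records; using the first only")
  }
  reference_sequence(as.character(seqs[[1L]]), name = names(seqs)[1L])
}

# base at a 1-based position (internal)
ref_base <- function(reference, position) {
  substring(reference$bases, position, position)
}

as_reference <- function(x) {
  if (inherits(x, "reference_sequence")) x else reference_sequence(x)
}
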