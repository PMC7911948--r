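.iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> code
.iupac_rev <- local({
  keys <- vapply(.iupac_table, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.iupac_table), keys)
})

#' Expand an IUPAC ambiguity code into its base set
#'
#' @param code A single IUPAC nucleotide letter (case-insensitive).
#' @return Character vector of bases, e.g. `expand_iupac("W")` is `c("A","T")`.
#' @examples
#' expand_iupac("W")  # A T
#' expand_iupac("M")  # A C
#' @export
expand_iupac <- function(code) {
  stopifnot(length(code) == 1L)
  code <- toupper(code)
  bases <- .iupac_table[[code]]
  if (is.null(bases)) {
    stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  bases
}

#' Collapse a base set into its IUPAC code
#'
#' Inverse of [expand_iupac()].
#'
#' @param bases Character vector of bases (subset of A/C/G/T, non-empty).
#' @return A single IUPAC letter.
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- .iupac_rev[[key]]
  if (is.null(code)) stop("not a valid base set: ", key, call. = FALSE)
  unname(code)
}
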