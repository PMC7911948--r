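# Haplotype database I/O: flat TSV with columns sample_id / population /
# variants (an EMPOP-style variant string per single-source haplotype).

#' Read and write a haplotype database
#'
#' The on-disk format is UTF-8 tab-separated text with columns `sample_id`,
#' `population`, `variants`; lines starting with `#` are comments and the
#' header row is optional. Variant strings must be single-allele (no IUPAC
#' ambiguity codes): these are single-source haplotypes.
#'
#' @param path File path.
#' @param db A database tibble.
#' @return `read_haplotype_db()` returns a tibble with the three columns;
#'   `write_haplotype_db()` returns `path` invisibly.
#' @export
read_haplotype_db <- function(path) {
  cols <- c("sample_id", "population", "variants")
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  body <- head_lines[!startsWith(head_lines, "#") & nzchar(head_lines)]
  has_header <- length(body) > 0L && startsWith(body[1L], "sample_id")
  db <- readr::read_tsv(
    path, comment = "#",
    col_names = if (has_header) TRUE else cols,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(cols %in% names(db))) {
    stop("haplotype database must have columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  db$variants[is.na(db$variants)] <- ""
  if (anyDuplicated(db$sample_id)) {
    stop("duplicated sample_id in haplotype database", call. = FALSE)
  }
  tibble::as_tibble(db[, cols])
}

#' @rdname read_haplotype_db
#' @export
write_haplotype_db <- function(db, path) {
  readr::write_tsv(db[, c("sample_id", "population", "variants")], path,
                   progress = FALSE)
  invisible(path)
}

#' Decode database haplotypes against a reference
#'
#' Parses each record's variant string, keeps the normalized calls and adds
#' the decoded DNA `sequence` column used by the match statistics. Decoding
#' once up front makes repeated [rmne()]/[gbc_likelihood()] calls over the
#' same database cheap.
#'
#' @param db A haplotype database tibble.
#' @param reference A [reference_sequence()].
#' @return `db` with list-column `calls` and character column `sequence`;
#'   the reference is attached as attribute `"reference"`.
#' @export
decode_db <- function(db, reference) {
  reference <- as_reference(reference)
  profs <- purrr::map(db$variants, parse_variants, reference = reference)
  db$calls <- purrr::map(profs, "calls")
  db$sequence <- purrr::map_chr(profs, decode_haplotype,
                                reference = reference)
  attr(db, "reference") <- reference
  db
}
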