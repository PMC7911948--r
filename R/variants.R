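#' @importFrom tibble tibble as_tibble
NULL

# canonical empty call table
empty_calls <- function() {
  tibble(
    kind = character(),
    position = integer(),
    insert_index = integer(),
    end_position = integer(),
    alleles = list(),
    reference_retained = logical()
  )
}

#' Construct individual variant calls
#'
#' Low-level constructors for the three difference operations against the
#' reference: substitution, insertion (after a base), and deletion (of a span
#' of bases). Each returns a one-row call table; bind rows and pass to
#' [mixture_profile()] for validation and normalization.
#'
#' For indels, `fixed = TRUE` means the indel is carried by *all* contributors
#' to the mixture (the reference state is absent); the default `FALSE` means
#' some contributor retains the reference state, which is the usual mixture
#' reading of a plain EMPOP token.
#'
#' @param position 1-based reference position (for insertions: the base after
#'   which the insertion occurs; for deletions: the first deleted base).
#' @param alleles Character vector of observed bases at a substituted site.
#' @param sequence Inserted sequence (one string, length >= 1).
#' @param index Insertion index (the `.1` in `4.1T`).
#' @param end Last deleted position (deletions; defaults to `position`).
#' @param fixed Logical; indel present in all contributors (no reference
#'   state left in the mixture).
#' @return A one-row tibble of calls.
#' @name variant-calls
NULL

#' @rdname variant-calls
#' @export
call_substitution <- function(position, alleles) {
  alleles <- toupper(alleles)
  if (length(alleles) == 0L || !all(alleles %in% c("A", "C", "G", "T"))) {
    stop("substitution alleles must be a non-empty subset of A/C/G/T", call. = FALSE)
  }
  tibble(
    kind = "substitution", position = as.integer(position),
    insert_index = NA_integer_, end_position = NA_integer_,
    alleles = list(sort(unique(alleles))), reference_retained = NA
  )
}

#' @rdname variant-calls
#' @export
call_insertion <- function(position, sequence, index = 1L, fixed = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L || grepl("[^ACGT]", sequence)) {
    stop("inserted sequence must be a non-empty A/C/G/T string", call. = FALSE)
  }
  tibble(
    kind = "insertion", position = as.integer(position),
    insert_index = as.integer(index), end_position = NA_integer_,
    alleles = list(sequence), reference_retained = !fixed
  )
}

#' @rdname variant-calls
#' @export
call_deletion <- function(position, end = position, fixed = FALSE) {
  tibble(
    kind = "deletion", position = as.integer(position),
    insert_index = NA_integer_, end_position = as.integer(end),
    alleles = list(character()), reference_retained = !fixed
  )
}

#' Mixture profile: a normalized set of variant calls plus the reference
#'
#' Validates and normalizes a call table against a reference:
#' * substitution calls at one position are merged (allele union) and
#'   `reference_retained` is recomputed as "reference base among the alleles";
#'   substitutions whose allele set is exactly the reference base are no-ops
#'   and are dropped;
#' * insertion calls at the same anchor are merged in index order into one
#'   inserted string; same-anchor insertions that conflict are rejected;
#' * adjacent or identical deletions are merged into maximal runs; partially
#'   overlapping non-identical deletions are rejected.
#'
#' @param reference A [reference_sequence()] (or plain string).
#' @param calls A call table (rows from [call_substitution()] and friends),
#'   or `NULL` for the pure-reference profile.
#' @return An object of class `mixture_profile` with fields `reference` and
#'   `calls` (a normalized tibble).
#' @export
mixture_profile <- function(reference, calls = NULL) {
  reference <- as_reference(reference)
  if (is.null(calls) || nrow(calls) == 0L) {
    return(structure(list(reference = reference, calls = empty_calls()),
                     class = "mixture_profile"))
  }
  calls <- as_tibble(calls)
  L <- reference$length

  bad <- calls$position < 1L | calls$position > L
  del <- calls$kind == "deletion"
  bad[del] <- bad[del] | calls$end_position[del] > L |
    calls$end_position[del] < calls$position[del]
  if (any(bad)) {
    stop("variant position out of reference range (1..", L, "): position ",
         paste(calls$position[bad], collapse = ", "), call. = FALSE)
  }

  subs <- normalize_substitutions(calls[calls$kind == "substitution", ], reference)
  ins  <- normalize_insertions(calls[calls$kind == "insertion", ])
  dels <- normalize_deletions(calls[calls$kind == "deletion", ])

  out <- dplyr::bind_rows(subs, dels, ins)
  rank <- c(substitution = 0L, deletion = 1L, insertion = 2L)
  out <- out[order(out$position, rank[out$kind], out$insert_index,
                   na.last = TRUE), , drop = FALSE]
  structure(list(reference = reference, calls = out), class = "mixture_profile")
}

normalize_substitutions <- function(subs, reference) {
  if (nrow(subs) == 0L) return(empty_calls())
  merged <- lapply(split(seq_len(nrow(subs)), subs$position), function(i) {
    pos <- subs$position[i[1L]]
    alle <- sort(unique(unlist(subs$alleles[i])))
    rb <- ref_base(reference, pos)
    tibble(
      kind = "substitution", position = pos,
      insert_index = NA_integer_, end_position = NA_integer_,
      alleles = list(alle), reference_retained = rb %in% alle,
      .drop = identical(alle, rb)
    )
  })
  merged <- dplyr::bind_rows(merged)
  merged <- merged[!merged$.drop, setdiff(names(merged), ".drop"), drop = FALSE]
  merged
}

normalize_insertions <- function(ins) {
  if (nrow(ins) == 0L) return(empty_calls())
  merged <- lapply(split(seq_len(nrow(ins)), ins$position), function(i) {
    pos <- ins$position[i[1L]]
    idx <- ins$insert_index[i]
    seqs <- unlist(ins$alleles[i])
    keep <- !duplicated(paste(idx, seqs))
    idx <- idx[keep]; seqs <- seqs[keep]; i <- i[keep]
    if (anyDuplicated(idx)) {
      stop("conflicting insertions at anchor ", pos,
           ": same index, different sequence", call. = FALSE)
    }
    o <- order(idx)
    tibble(
      kind = "insertion", position = pos,
      insert_index = 1L, end_position = NA_integer_,
      alleles = list(paste(seqs[o], collapse = "")),
      reference_retained = all(ins$reference_retained[i])
    )
  })
  dplyr::bind_rows(merged)
}

normalize_deletions <- function(dels) {
  if (nrow(dels) == 0L) return(empty_calls())
  o <- order(dels$position, dels$end_position)
  pos <- dels$position[o]; end <- dels$end_position[o]
  ret <- dels$reference_retained[o]
  out_pos <- integer(); out_end <- integer(); out_ret <- logical()
  cp <- pos[1L]; ce <- end[1L]; cr <- ret[1L]
  for (k in seq_along(pos)[-1L]) {
    if (pos[k] == cp && end[k] == ce) {          # identical span: merge flags
      cr <- cr || ret[k]
    } else if (pos[k] <= ce) {                   # overlap, not identical
      stop("partially overlapping deletions: ", cp, "..", ce, " vs ",
           pos[k], "..", end[k], call. = FALSE)
    } else if (pos[k] == ce + 1L) {              # adjacent: same variant
      ce <- end[k]; cr <- cr || ret[k]
    } else {
      out_pos <- c(out_pos, cp); out_end <- c(out_end, ce); out_ret <- c(out_ret, cr)
      cp <- pos[k]; ce <- end[k]; cr <- ret[k]
    }
  }
  out_pos <- c(out_pos, cp); out_end <- c(out_end, ce); out_ret <- c(out_ret, cr)
  tibble(
    kind = "deletion", position = out_pos,
    insert_index = NA_integer_, end_position = out_end,
    alleles = rep(list(character()), length(out_pos)),
    reference_retained = out_ret
  )
}

#' @export
print.mixture_profile <- function(x, ...) {
  cat("<mixture_profile> on ", x$reference$name, " (", x$reference$length,
      " bp), ", nrow(x$calls), " call(s)\n", sep = "")
  if (nrow(x$calls) > 0L) cat("  ", format_variants(x), "\n", sep = "")
  invisible(x)
}

#' Parse an EMPOP-style variant string into a mixture profile
#'
#' Accepted tokens (whitespace-separated; `#` starts a comment):
#' * `73G`, `154W` — substitution at a position, IUPAC ambiguity codes
#'   expanded into allele sets (`reference_retained` is true when the
#'   reference base is part of the expansion);
#' * `4.1T`, `4.1TC` — insertion after a base; per-index forms
#'   (`4.1T 4.2C`) are merged in index order;
#' * `5 del`, `5-` — deletion of a base; adjacent deletions merge into one
#'   span;
#' * a trailing `!` on an indel token (`4.1T!`, `5 del!`, `5-!`) marks the
#'   indel as *fixed*: carried by every contributor, so the reference state
#'   is absent from the mixture. Plain indel tokens keep the reference state
#'   available (mixture semantics).
#'
#' @param text One profile as a string of tokens; `""` gives the
#'   pure-reference profile.
#' @param reference A [reference_sequence()] (or plain string).
#' @return A [mixture_profile()].
#' @examples
#' ref <- reference_sequence(strrep("A", 200))
#' parse_variants("73G 154W 178M", ref)
#' @export
parse_variants <- function(text, reference) {
  reference <- as_reference(reference)
  text <- sub("#.*$", "", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(mixture_profile(reference))

  rows <- list()
  i <- 1L
  while (i <= length(tokens)) {
    tok <- toupper(tokens[i])
    nxt <- if (i < length(tokens)) toupper(tokens[i + 1L]) else ""
    if (grepl("^[0-9]+$", tok) && nxt %in% c("DEL", "DEL!")) {
      rows[[length(rows) + 1L]] <-
        call_deletion(as.integer(tok), fixed = nxt == "DEL!")
      i <- i + 2L
    } else if (grepl("^[0-9]+-!?$", tok)) {
      pos <- as.integer(sub("-!?$", "", tok))
      rows[[length(rows) + 1L]] <-
        call_deletion(pos, fixed = grepl("!$", tok))
      i <- i + 1L
    } else if (grepl("^[0-9]+\\.[0-9]+[ACGT]+!?$", tok)) {
      m <- regmatches(tok, regexec("^([0-9]+)\\.([0-9]+)([ACGT]+)(!?)$", tok))[[1L]]
      rows[[length(rows) + 1L]] <- call_insertion(
        as.integer(m[2L]), m[4L], index = as.integer(m[3L]),
        fixed = m[5L] == "!"
      )
      i <- i + 1L
    } else if (grepl("^[0-9]+[A-Z]$", tok)) {
      pos <- as.integer(sub("[A-Z]$", "", tok))
      code <- sub("^[0-9]+", "", tok)
      alleles <- tryCatch(expand_iupac(code), error = function(e) {
        stop("cannot parse variant token '", tokens[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
      rows[[length(rows) + 1L]] <- call_substitution(pos, alleles)
      i <- i + 1L
    } else {
      stop("cannot parse variant token '", tokens[i], "'", call. = FALSE)
    }
  }
  mixture_profile(reference, dplyr::bind_rows(rows))
}

#' Format a profile (or call table) back into an EMPOP-style string
#'
#' The canonical form: multi-allele substitutions as IUPAC codes, insertions
#' as `pos.1SEQ`, deletions as per-position `pos-` tokens, fixed indels with a
#' trailing `!`. `parse_variants(format_variants(p), ref)` round-trips.
#'
#' @param x A [mixture_profile()] or a call tibble.
#' @return A single string (empty for the pure-reference profile).
#' @export
format_variants <- function(x) {
  calls <- if (inherits(x, "mixture_profile")) x$calls else as_tibble(x)
  if (nrow(calls) == 0L) return("")
  toks <- character(0)
  ordk <- c(substitution = 0L, deletion = 1L, insertion = 2L)
  calls <- calls[order(calls$position, ordk[calls$kind]), , drop = FALSE]
  for (k in seq_len(nrow(calls))) {
    kind <- calls$kind[k]
    if (kind == "substitution") {
      toks <- c(toks, paste0(calls$position[k], iupac_code(calls$alleles[[k]])))
    } else if (kind == "insertion") {
      toks <- c(toks, paste0(calls$position[k], ".", calls$insert_index[k],
                             calls$alleles[[k]],
                             if (!calls$reference_retained[k]) "!" else ""))
    } else {
      sufx <- if (!calls$reference_retained[k]) "!" else ""
      toks <- c(toks, paste0(seq(calls$position[k], calls$end_position[k]),
                             "-", sufx))
    }
  }
  paste(toks, collapse = " ")
}

#' Decode a single-source haplotype from its variant calls
#'
#' Applies the difference operations (substitute, insert, delete) to the
#' reference and returns the resulting DNA string. Every substitution must
#' carry exactly one allele (single-source calls cannot be ambiguous).
#' Equivalent encodings — e.g. deleting either A of an AA homopolymer —
#' decode to identical strings.
#'
#' @param reference A [reference_sequence()] (or plain string).
#' @param calls A call tibble or [mixture_profile()]; `NULL`/empty decodes to
#'   the reference itself.
#' @return A DNA string.
#' @examples
#' ref <- reference_sequence("AACAAGT")
#' decode_haplotype(ref, call_deletion(4))  # AACAGT
#' decode_haplotype(ref, call_deletion(5))  # AACAGT (equivalent encoding)
#' @export
decode_haplotype <- function(reference, calls = NULL) {
  reference <- as_reference(reference)
  if (inherits(calls, "mixture_profile")) {
    prof <- calls
  } else {
    prof <- mixture_profile(reference, calls)
  }
  calls <- prof$calls
  L <- reference$length
  chars <- strsplit(reference$bases, "", fixed = TRUE)[[1L]]
  keep <- rep(TRUE, L)
  ins_after <- rep("", L + 1L)  # ins_after[p + 1] = string inserted after base p

  for (k in seq_len(nrow(calls))) {
    kind <- calls$kind[k]
    if (kind == "substitution") {
      alle <- calls$alleles[[k]]
      if (length(alle) != 1L) {
        stop("cannot decode: ambiguous substitution at position ",
             calls$position[k], " (", paste(alle, collapse = "/"),
             "); single-source calls must be single-allele", call. = FALSE)
      }
      chars[calls$position[k]] <- alle
    } else if (kind == "deletion") {
      keep[calls$position[k]:calls$end_position[k]] <- FALSE
    } else {
      ins_after[calls$position[k] + 1L] <- calls$alleles[[k]]
    }
  }
  body <- chars
  body[!keep] <- ""
  paste0(ins_after[1L], paste0(body, ins_after[-1L], collapse = ""))
}

#' Mask intervals
#'
#' Intervals on the reference, 1-based inclusive, normalized (sorted, merged,
#' non-overlapping). Use [read_mask_bed()] for on-disk BED input (0-based
#' half-open; converted on read).
#'
#' @param start,end Integer vectors of interval bounds (1-based, inclusive).
#' @return A tibble with columns `start`, `end`, of class `mask_intervals`.
#' @export
mask_intervals <- function(start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("mask intervals must have end >= start", call. = FALSE)
  if (length(start) > 1L) {
    o <- order(start, end)
    start <- start[o]; end <- end[o]
    ms <- start[1L]; me <- end[1L]; os <- integer(); oe <- integer()
    for (k in seq_along(start)[-1L]) {
      if (start[k] <= me + 1L) me <- max(me, end[k])
      else { os <- c(os, ms); oe <- c(oe, me); ms <- start[k]; me <- end[k] }
    }
    start <- c(os, ms); end <- c(oe, me)
  }
  structure(tibble(start = start, end = end),
            class = c("mask_intervals", class(tibble())))
}

#' Read mask intervals from a BED file
#'
#' BED is 0-based, half-open on disk; intervals are converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' @param path Path to a BED file.
#' @return A [mask_intervals()] tibble.
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  # GRanges is already 1-based inclusive after import
  mask_intervals(BiocGenerics::start(gr), BiocGenerics::end(gr))
}

#' Remove variant calls that fall inside mask intervals
#'
#' A call is removed when its reference footprint intersects any interval:
#' the substituted position, the insertion anchor, or any part of a deletion
#' span. Applied identically to mixture profiles and to database haplotype
#' calls, so masked comparisons stay like-with-like. An empty mask is the
#' identity.
#'
#' @param x A [mixture_profile()] or a call tibble.
#' @param mask A [mask_intervals()] tibble (or anything with `start`/`end`).
#' @return Same type as `x`, with masked calls removed.
#' @export
mask_profile <- function(x, mask) {
  is_prof <- inherits(x, "mixture_profile")
  calls <- if (is_prof) x$calls else as_tibble(x)
  if (nrow(calls) > 0L && nrow(mask) > 0L) {
    foot_end <- ifelse(calls$kind == "deletion", calls$end_position, calls$position)
    hit <- rep(FALSE, nrow(calls))
    for (k in seq_len(nrow(mask))) {
      hit <- hit | (calls$position <= mask$end[k] & foot_end >= mask$start[k])
    }
    calls <- calls[!hit, , drop = FALSE]
  }
  if (is_prof) mixture_profile(x$reference, calls) else calls
}

#' @rdname mask_profile
#' @export
mask_calls <- function(x, mask) mask_profile(x, mask)
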