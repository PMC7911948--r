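# Matching: consistency (non-exclusion), accepting paths, explanation.

#' Is a haplotype consistent with a mixture graph?
#'
#' A haplotype is consistent (not excluded) when some source-to-sink path
#' spells it; epsilon nodes consume no characters. Decided by NFA-style
#' dynamic programming over node sets with epsilon closure, so the cost is
#' linear in haplotype length times the active frontier, never in the number
#' of generated sequences. Vectorized over haplotypes: checking a whole
#' database column is a single call.
#'
#' @param graph A `variant_graph`.
#' @param haplotype Character vector of A/C/G/T haplotype strings.
#' @return Logical vector, one verdict per haplotype.
#' @examples
#' g <- build_mixture_graph(parse_variants("3Y 4Y", reference_sequence("AACCT")))
#' is_consistent(g, c("AATCT", "AACCT", "AAGGT"))
#' @export
is_consistent <- function(graph, haplotype) {
  gi <- graph_index(graph)
  cpp_consistent(
    length(gi$ids), gi$is_base, gi$label,
    gi$from - 1L, gi$to - 1L, gi$source - 1L, gi$sink - 1L,
    toupper(haplotype)
  )
}

#' All accepting paths of a haplotype through a graph
#'
#' One string may trace several paths (e.g. a deletion in a homopolymer run
#' where both placements were encoded); the explanation test quantifies over
#' these choices, so the full set is enumerated. Paths are found by
#' deterministic backtracking (lexicographic in node id) over the
#' forward/backward-pruned product of graph nodes and prefix lengths.
#'
#' @param graph A `variant_graph`.
#' @param haplotype A single haplotype string.
#' @param cap Maximum number of paths to return; more flags `truncated`.
#' @return A list of class `accepting_paths`: `haplotype`, `paths` (each a
#'   character vector of node ids, source to sink), `truncated`.
#' @export
accepting_paths <- function(graph, haplotype, cap = 1000L) {
  stopifnot(length(haplotype) == 1L, cap >= 1)
  gi <- graph_index(graph)
  res <- cpp_accepting_paths(
    length(gi$ids), gi$is_base, gi$label,
    gi$from - 1L, gi$to - 1L, gi$source - 1L, gi$sink - 1L,
    toupper(haplotype), as.integer(cap)
  )
  structure(
    list(
      haplotype = toupper(haplotype),
      paths = lapply(res$paths, function(p) gi$ids[p]),
      truncated = res$truncated
    ),
    class = "accepting_paths"
  )
}

#' @export
print.accepting_paths <- function(x, ...) {
  cat("<accepting_paths> ", length(x$paths), " path(s) for ", x$haplotype,
      if (x$truncated) " [truncated]", "\n", sep = "")
  invisible(x)
}

# integer coverage machinery shared by explains() and feasible_pairs().
# Elements are nodes (1..n) then edges (n+1..n+m); returns a logical
# coverage vector for one path given as integer node indices.
path_cover <- function(path_idx, n_nodes, edge_lookup) {
  len <- length(path_idx)
  cov <- logical(n_nodes + length(edge_lookup))
  cov[path_idx] <- TRUE
  if (len > 1L) {
    keys <- paste(path_idx[-len], path_idx[-1L])
    cov[n_nodes + match(keys, names(edge_lookup))] <- TRUE
  }
  cov
}

# accepting paths for one haplotype, as integer node indices into gi$ids
paths_idx <- function(gi, haplotype, cap) {
  cpp_accepting_paths(
    length(gi$ids), gi$is_base, gi$label,
    gi$from - 1L, gi$to - 1L, gi$source - 1L, gi$sink - 1L,
    toupper(haplotype), as.integer(cap)
  )
}

#' Can a set of haplotypes explain a mixture graph?
#'
#' A haplotype multiset explains a mixture when every haplotype is
#' individually consistent *and* some choice of one accepting path per
#' haplotype jointly covers every node and every edge of the graph. Node
#' coverage alone is not enough: a mixture of reference and an insertion is
#' node-covered by two insertion carriers, yet neither carries the reference
#' state — the uncovered skip edge is what rejects that set. Duplicate
#' haplotypes are allowed and may take different accepting paths.
#'
#' The search over path choices is exhaustive with pruning on the still
#' coverable element set; `cap_paths` bounds paths per haplotype and
#' `cap_assignments` bounds explored path assignments, beyond which the
#' verdict is flagged approximate (a `FALSE` may then be a lower bound).
#'
#' @param graph A `variant_graph`.
#' @param haplotypes Character vector (multiset) of haplotype strings.
#' @param cap_paths Per-haplotype accepting-path cap.
#' @param cap_assignments Total path-assignment cap.
#' @return A list of class `mito_explanation`: `explained`, `consistent`
#'   (per-haplotype), `uncovered_nodes`, `uncovered_edges`, `witness` (one
#'   covering path per haplotype when explained), `approximate`.
#' @examples
#' g <- build_mixture_graph(parse_variants("3Y 4Y", reference_sequence("AACCT")))
#' explains(g, c("AATTT", "AACCT"))$explained  # TRUE: all alleles covered
#' explains(g, c("AATCT", "AACCT"))$explained  # FALSE: 4T never covered
#' @export
explains <- function(graph, haplotypes, cap_paths = 1000L,
                     cap_assignments = 1e6) {
  stopifnot(length(haplotypes) >= 1L)
  gi <- graph_index(graph)
  n <- length(gi$ids)
  edge_lookup <- stats::setNames(seq_along(gi$from), paste(gi$from, gi$to))
  n_elem <- n + length(gi$from)
  elem_names <- c(gi$ids, paste0(gi$ids[gi$from], " -> ", gi$ids[gi$to]))

  H <- length(haplotypes)
  masks <- vector("list", H)   # per hap: list of coverage vectors
  hpaths <- vector("list", H)  # per hap: list of integer node paths
  approximate <- FALSE
  consistent <- logical(H)
  for (h in seq_len(H)) {
    pr <- paths_idx(gi, haplotypes[h], cap_paths)
    if (pr$truncated) approximate <- TRUE
    consistent[h] <- length(pr$paths) > 0L
    hpaths[[h]] <- pr$paths
    masks[[h]] <- lapply(pr$paths, path_cover, n_nodes = n,
                         edge_lookup = edge_lookup)
  }

  result <- function(expl, best_cov, witness) {
    unc <- which(!best_cov)
    structure(
      list(
        explained = expl,
        consistent = consistent,
        uncovered_nodes = elem_names[unc[unc <= n]],
        uncovered_edges = elem_names[unc[unc > n]],
        witness = witness,
        approximate = approximate
      ),
      class = "mito_explanation"
    )
  }

  if (!all(consistent)) {
    cov <- Reduce(`|`, unlist(masks, recursive = FALSE), logical(n_elem))
    return(result(FALSE, cov, NULL))
  }

  # union of every path of haplotypes h..H: upper bound on what the
  # remaining choices can still cover
  suffix_union <- vector("list", H + 1L)
  suffix_union[[H + 1L]] <- logical(n_elem)
  for (h in rev(seq_len(H))) {
    suffix_union[[h]] <- Reduce(`|`, masks[[h]], suffix_union[[h + 1L]])
  }
  if (!all(suffix_union[[1L]])) {
    return(result(FALSE, suffix_union[[1L]], NULL))
  }

  best <- new.env(parent = emptyenv())
  best$cov <- logical(n_elem)
  best$n <- -1L
  best$witness <- NULL
  best$explored <- 0
  best$done <- FALSE

  rec <- function(h, covered, picks) {
    if (best$done) return(invisible())
    if (h > H) {
      best$explored <- best$explored + 1
      nc <- sum(covered)
      if (nc > best$n) {
        best$n <- nc
        best$cov <- covered
        best$witness <- picks
        if (nc == n_elem) best$done <- TRUE
      }
      if (best$explored >= cap_assignments) {
        approximate <<- TRUE
        best$done <- TRUE
      }
      return(invisible())
    }
    if (!all(covered | suffix_union[[h]])) return(invisible())  # prune
    for (p in seq_along(masks[[h]])) {
      rec(h + 1L, covered | masks[[h]][[p]], c(picks, p))
      if (best$done) return(invisible())
    }
    invisible()
  }
  rec(1L, logical(n_elem), integer())

  witness <- NULL
  if (best$n == n_elem) {
    witness <- lapply(seq_len(H), function(h) {
      gi$ids[hpaths[[h]][[best$witness[h]]]]
    })
    names(witness) <- haplotypes
  }
  result(best$n == n_elem, best$cov, witness)
}

#' @export
print.mito_explanation <- function(x, ...) {
  cat("<mito_explanation> explained = ", x$explained,
      if (x$approximate) " (approximate)", "\n", sep = "")
  if (!x$explained) {
    cat("  uncovered: ", length(x$uncovered_nodes), " node(s), ",
        length(x$uncovered_edges), " edge(s)\n", sep = "")
  }
  invisible(x)
}

#' Enumerate feasible unordered haplotype pairs of a two-person mixture
#'
#' All unordered pairs drawn from the graph's generated set that jointly
#' explain the graph. A pair covers every node and edge exactly when some
#' accepting path of one member covers everything the other's path misses,
#' so the test reduces to disjointness of per-path missing-element sets
#' (computed for all pairs at once via a cross-product of missing-element
#' indicator vectors). For a mixture of k biallelic substitution sites this
#' yields the 2^(k-1) complementary pairs. Intended as a small-scale oracle,
#' not for production statistics on large k.
#'
#' @param graph A `variant_graph`.
#' @param cap Cap on generated sequences (enumeration is exhaustive below it).
#' @param cap_paths Per-sequence accepting-path cap.
#' @return A tibble with columns `hap1`, `hap2` (`hap1 <= hap2`), with
#'   attribute `truncated`.
#' @export
feasible_pairs <- function(graph, cap = 1e5, cap_paths = 100L) {
  gen <- enumerate_generated(graph, cap)
  seqs <- gen$sequences
  gi <- graph_index(graph)
  pe <- pairwise_explains(gi, seqs, cap_paths)
  idx <- which(upper.tri(pe$explained_pair, diag = TRUE) & pe$explained_pair,
               arr.ind = TRUE)
  out <- tibble(hap1 = seqs[idx[, 1L]], hap2 = seqs[idx[, 2L]])
  out <- out[order(out$hap1, out$hap2), , drop = FALSE]
  attr(out, "truncated") <- gen$truncated || pe$truncated
  out
}

# Symmetric matrix of two-haplotype explanation verdicts over a set of
# (individually consistent) sequences. A pair of paths jointly covers every
# element exactly when their missing-element sets are disjoint, so all pairs
# are decided at once from the cross-product of missing indicators.
pairwise_explains <- function(gi, seqs, cap_paths = 100L) {
  n <- length(gi$ids)
  edge_lookup <- stats::setNames(seq_along(gi$from), paste(gi$from, gi$to))
  m <- length(seqs)
  miss_rows <- list()
  row_seq <- integer()
  truncated <- FALSE
  for (s in seq_len(m)) {
    pr <- paths_idx(gi, seqs[s], cap_paths)
    if (pr$truncated) truncated <- TRUE
    for (p in pr$paths) {
      miss_rows[[length(miss_rows) + 1L]] <- !path_cover(p, n, edge_lookup)
      row_seq <- c(row_seq, s)
    }
  }
  expl <- matrix(FALSE, m, m)
  if (length(miss_rows) > 0L) {
    M <- do.call(rbind, miss_rows) * 1
    shared_miss <- tcrossprod(M)  # [i,j] = #elements missed by both paths
    ok <- shared_miss == 0
    for (i in seq_len(m)) {
      ri <- which(row_seq == i)
      if (length(ri) == 0L) next
      for (j in i:m) {
        rj <- which(row_seq == j)
        if (length(rj) > 0L && any(ok[ri, rj])) {
          expl[i, j] <- expl[j, i] <- TRUE
        }
      }
    }
  }
  list(explained_pair = expl, truncated = truncated)
}

#' Feasible-pair count by the path-counting route
#'
#' For a two-person mixture whose profile consists of biallelic substitution
#' sites only, the feasible unordered pairs are exactly the complementary
#' assignments of the k ambiguous sites: 2^(k-1) of them (1 when the mixture
#' has no ambiguity). The generated-sequence count N = 2^k is obtained by
#' dynamic programming ([count_generated()]), so the answer N/2 is available
#' even when N is in the billions. Cross-check against [feasible_pairs()] at
#' small k; the closed form does not hold for general indel mixtures.
#'
#' @param graph A `variant_graph` built from a biallelic substitution-only
#'   profile.
#' @return Numeric pair count.
#' @export
n_feasible_pairs <- function(graph) {
  N <- count_generated(graph)
  if (N <= 1) 1 else N / 2
}
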