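# Variation graphs with epsilon nodes.
#
# Internal representation is deliberately plain (parallel character vectors)
# so that per-mixture construction stays cheap inside simulation studies.
# Node id scheme (deterministic given the profile, so graphs from identical
# profiles compare equal):
#   "source", "sink"        terminal sentinels
#   "e:<p>"                 backbone epsilon after base p (p = 0..L)
#   "b:<p>:<X>"             base node, allele X at reference position p
#   "bi:<p>.<j>:<X>"        j-th inserted base of the insertion after p
#   "ei:<p>"                closing epsilon of the insertion after p

new_variant_graph <- function(nodes, edges, reference) {
  structure(
    list(nodes = nodes, edges = edges,
         source = "source", sink = "sink", reference = reference,
         substituted = integer()),
    class = "variant_graph"
  )
}

#' Build the linear epsilon-node graph of a reference sequence
#'
#' Produces `source -> e0 -> b1 -> e1 -> ... -> bL -> eL -> sink`: one base
#' node per reference position with a backbone epsilon (sequence-free) node
#' between each pair of bases and at both ends. Epsilon nodes consume no
#' characters on a path; they bottleneck paths between variable positions so
#' that every node and edge of a mixture graph is certainly present in the
#' mixture.
#'
#' @param reference A [reference_sequence()] (or plain string).
#' @return A `variant_graph`.
#' @export
build_reference_graph <- function(reference) {
  reference <- as_reference(reference)
  L <- reference$length
  bases <- strsplit(reference$bases, "", fixed = TRUE)[[1L]]
  eps_id <- paste0("e:", 0:L)
  base_id <- paste0("b:", 1:L, ":", bases)

  nodes <- list(
    id = c("source", "sink", eps_id, base_id),
    kind = c("source", "sink", rep("epsilon", L + 1L), rep("base", L)),
    label = c("", "", rep("", L + 1L), bases)
  )
  edges <- list(
    from = c("source", eps_id[1:L], base_id, eps_id[L + 1L]),
    to   = c(eps_id[1L], base_id, eps_id[2:(L + 1L)], "sink")
  )
  new_variant_graph(nodes, edges, reference)
}

vg_has_node <- function(graph, id) id %in% graph$nodes$id

vg_add_nodes <- function(graph, id, kind, label) {
  graph$nodes$id <- c(graph$nodes$id, id)
  graph$nodes$kind <- c(graph$nodes$kind, kind)
  graph$nodes$label <- c(graph$nodes$label, label)
  graph
}

vg_remove_nodes <- function(graph, ids) {
  keep <- !(graph$nodes$id %in% ids)
  graph$nodes$id <- graph$nodes$id[keep]
  graph$nodes$kind <- graph$nodes$kind[keep]
  graph$nodes$label <- graph$nodes$label[keep]
  ekeep <- !(graph$edges$from %in% ids | graph$edges$to %in% ids)
  graph$edges$from <- graph$edges$from[ekeep]
  graph$edges$to <- graph$edges$to[ekeep]
  graph
}

vg_add_edges <- function(graph, from, to) {
  key_old <- paste(graph$edges$from, graph$edges$to)
  key_new <- paste(from, to)
  fresh <- !(key_new %in% key_old) & !duplicated(key_new)
  graph$edges$from <- c(graph$edges$from, from[fresh])
  graph$edges$to <- c(graph$edges$to, to[fresh])
  graph
}

#' Apply a single variant call to a variation graph
#'
#' These are the elementary construction steps used by
#' [build_mixture_graph()]; they are exported for inspection and testing.
#'
#' * **Substitution**: the reference base node at the position is removed and
#'   one base node per observed allele is added in its place (the reference
#'   base is re-added like any other allele when it is part of the observed
#'   set). If the reference base was not observed, it is absent from the
#'   graph — and hence from every generated haplotype.
#' * **Insertion**: a chain of inserted base nodes followed by a new closing
#'   epsilon is attached after the backbone epsilon that follows the anchor
#'   base; the closing epsilon takes over the anchor epsilon's former
#'   outgoing edges. Unless the insertion is fixed in all contributors, a
#'   skip edge (epsilon to epsilon) preserves the insertion-free spelling.
#' * **Deletion**: a bypass edge is added from the epsilon preceding the
#'   first deleted base to the backbone epsilon after the last deleted base.
#'   A deletion fixed in all contributors instead removes the spanned base
#'   nodes entirely.
#'
#' @param graph A `variant_graph`.
#' @param call A one-row call tibble ([call_substitution()] and friends).
#' @return The modified `variant_graph`.
#' @name apply-variant
NULL

#' @rdname apply-variant
#' @export
apply_substitution <- function(graph, call) {
  pos <- call$position[1L]
  alleles <- call$alleles[[1L]]
  rb <- ref_base(graph$reference, pos)
  ref_node <- paste0("b:", pos, ":", rb)
  if (pos %in% graph$substituted || !vg_has_node(graph, ref_node)) {
    stop("position ", pos, " has already been modified in this graph",
         call. = FALSE)
  }
  graph$substituted <- c(graph$substituted, pos)
  preds <- graph$edges$from[graph$edges$to == ref_node]
  succs <- graph$edges$to[graph$edges$from == ref_node]
  graph <- vg_remove_nodes(graph, ref_node)
  new_ids <- paste0("b:", pos, ":", alleles)
  graph <- vg_add_nodes(graph, new_ids, rep("base", length(new_ids)), alleles)
  graph <- vg_add_edges(graph,
                        from = rep(preds, each = length(new_ids)),
                        to = rep(new_ids, times = length(preds)))
  vg_add_edges(graph,
               from = rep(new_ids, times = length(succs)),
               to = rep(succs, each = length(new_ids)))
}

#' @rdname apply-variant
#' @export
apply_insertion <- function(graph, call) {
  pos <- call$position[1L]
  seqn <- call$alleles[[1L]]
  retained <- call$reference_retained[1L]
  eps <- paste0("e:", pos)
  closing <- paste0("ei:", pos)
  if (vg_has_node(graph, closing)) {
    stop("conflicting insertion: anchor ", pos, " already carries an insertion",
         call. = FALSE)
  }
  if (!vg_has_node(graph, eps)) {
    stop("cannot insert after position ", pos, ": backbone epsilon absent",
         call. = FALSE)
  }
  chars <- strsplit(seqn, "", fixed = TRUE)[[1L]]
  chain <- paste0("bi:", pos, ".", seq_along(chars), ":", chars)

  # the closing epsilon takes over the anchor epsilon's outgoing edges
  move <- graph$edges$from == eps
  graph$edges$from[move] <- closing

  graph <- vg_add_nodes(graph,
                        id = c(chain, closing),
                        kind = c(rep("base", length(chain)), "epsilon"),
                        label = c(chars, ""))
  graph <- vg_add_edges(graph,
                        from = c(eps, chain),
                        to = c(chain, closing))
  if (isTRUE(retained)) graph <- vg_add_edges(graph, eps, closing)
  graph
}

#' @rdname apply-variant
#' @export
apply_deletion <- function(graph, call) {
  p <- call$position[1L]
  e <- call$end_position[1L]
  retained <- call$reference_retained[1L]
  first_bases <- graph$nodes$id[graph$nodes$kind == "base" &
                                  startsWith(graph$nodes$id, paste0("b:", p, ":"))]
  target <- paste0("e:", e)
  if (length(first_bases) == 0L || !vg_has_node(graph, target)) {
    stop("deletion ", p, "..", e,
         " overlaps a span already removed from the graph", call. = FALSE)
  }
  eps_before <- unique(graph$edges$from[graph$edges$to %in% first_bases])
  if (isTRUE(retained)) {
    return(vg_add_edges(graph, eps_before, rep(target, length(eps_before))))
  }
  # deletion fixed in all contributors: the spanned bases were never present
  inner <- if (e > p) p:(e - 1L) else integer()
  if (any(paste0("ei:", inner) %in% graph$nodes$id)) {
    stop("deletion ", p, "..", e, " fixed in all contributors spans an ",
         "insertion anchor; the encoding is contradictory", call. = FALSE)
  }
  doomed <- graph$nodes$id[
    (graph$nodes$kind == "base" &
       grepl(paste0("^b:(", paste(p:e, collapse = "|"), "):"), graph$nodes$id)) |
      graph$nodes$id %in% paste0("e:", inner)
  ]
  graph <- vg_remove_nodes(graph, doomed)
  vg_add_edges(graph, eps_before, rep(target, length(eps_before)))
}

#' Compile a mixture profile into its variation graph
#'
#' Starts from the reference backbone and applies every call in canonical
#' order (substitutions, then insertions, then deletions). The construction
#' never adds uncertain elements: every node and every edge of the result is
#' asserted present in the mixture, which is what makes the joint node+edge
#' coverage test ([explains()]) a valid explanation criterion.
#'
#' @param profile A [mixture_profile()].
#' @return A `variant_graph`. Node identifiers are deterministic functions of
#'   the profile, so equal profiles give identical graphs.
#' @examples
#' ref <- reference_sequence("AACCT")
#' g <- build_mixture_graph(parse_variants("3Y 4Y", ref))
#' enumerate_generated(g)$sequences
#' @export
build_mixture_graph <- function(profile) {
  stopifnot(inherits(profile, "mixture_profile"))
  graph <- build_reference_graph(profile$reference)
  calls <- profile$calls
  for (k in which(calls$kind == "substitution")) {
    graph <- apply_substitution(graph, calls[k, ])
  }
  for (k in which(calls$kind == "insertion")) {
    graph <- apply_insertion(graph, calls[k, ])
  }
  for (k in which(calls$kind == "deletion")) {
    graph <- apply_deletion(graph, calls[k, ])
  }
  graph
}

#' @export
print.variant_graph <- function(x, ...) {
  cat("<variant_graph> ", length(x$nodes$id), " nodes, ",
      length(x$edges$from), " edges (reference ", x$reference$name, ", ",
      x$reference$length, " bp)\n", sep = "")
  invisible(x)
}

# ---- generator / oracle operations ----------------------------------------

# integer-indexed view used by the matching kernels
graph_index <- function(graph) {
  ord <- order(graph$nodes$id, method = "radix")
  ids <- graph$nodes$id[ord]
  kind <- graph$nodes$kind[ord]
  label <- graph$nodes$label[ord]
  from <- match(graph$edges$from, ids)
  to <- match(graph$edges$to, ids)
  list(
    ids = ids,
    is_base = as.integer(kind == "base"),
    label = ifelse(kind == "base", label, ""),
    from = from, to = to,
    source = match(graph$source, ids),
    sink = match(graph$sink, ids)
  )
}

#' Enumerate every haplotype the graph can generate
#'
#' Exhaustively spells out all distinct source-to-sink paths (epsilon nodes
#' consume no characters), up to `cap` paths. This is the small-scale oracle
#' against which the matching operations are checked; it is never meant for
#' graphs with astronomically many spellings — use [count_generated()] for
#' those.
#'
#' @param graph A `variant_graph`.
#' @param cap Maximum number of paths to walk before giving up (the result
#'   is then flagged `truncated`).
#' @return A list of class `generated_set`: `sequences` (sorted, distinct),
#'   `count` (`length(sequences)`), `n_paths` (paths walked) and `truncated`.
#' @export
enumerate_generated <- function(graph, cap = 1e5) {
  stopifnot(cap >= 1)
  gi <- graph_index(graph)
  n <- length(gi$ids)
  adj <- vector("list", n)
  o <- order(gi$from, gi$to)
  adj_split <- split(gi$to[o], gi$from[o])
  adj[as.integer(names(adj_split))] <- adj_split

  seen <- new.env(hash = TRUE, parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$n_paths <- 0L
  state$truncated <- FALSE
  chars <- character(n + 16L)  # path character stack

  visit <- function(v, depth) {
    if (state$truncated) return(invisible())
    if (v == gi$sink) {
      state$n_paths <- state$n_paths + 1L
      if (state$n_paths > cap) {
        state$truncated <- TRUE
        state$n_paths <- cap
        return(invisible())
      }
      s <- paste(chars[seq_len(depth)], collapse = "")
      assign(s, TRUE, envir = seen)
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (gi$is_base[w] == 1L) {
        chars[depth + 1L] <<- gi$label[w]
        visit(w, depth + 1L)
      } else {
        visit(w, depth)
      }
    }
    invisible()
  }
  visit(gi$source, 0L)
  seqs <- sort(ls(seen))
  structure(
    list(sequences = seqs, count = length(seqs),
         n_paths = state$n_paths, truncated = state$truncated),
    class = "generated_set"
  )
}

#' @export
print.generated_set <- function(x, ...) {
  cat("<generated_set> ", x$count, " distinct sequence(s) from ", x$n_paths,
      " path(s)", if (x$truncated) " [truncated]", "\n", sep = "")
  invisible(x)
}

#' Count source-to-sink paths by dynamic programming
#'
#' Exact path count in time linear in the number of edges (topological-order
#' accumulation), usable where enumeration is hopeless (e.g. dozens of
#' ambiguous sites: k independent biallelic sites give 2^k paths). Paths are
#' counted as paths; the count equals the number of distinct spellings when
#' the graph has no indel-induced spelling ambiguity.
#'
#' @param graph A `variant_graph`.
#' @return A numeric path count (may exceed integer range).
#' @export
count_generated <- function(graph) {
  gi <- graph_index(graph)
  ig <- as_igraph_vg(graph)
  topo <- igraph::topo_sort(ig, mode = "out")
  rank <- match(gi$ids, names(topo))
  np <- numeric(length(gi$ids))
  np[gi$source] <- 1
  eo <- order(rank[gi$from])
  for (k in eo) {
    np[gi$to[k]] <- np[gi$to[k]] + np[gi$from[k]]
  }
  np[gi$sink]
}

as_igraph_vg <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$id, kind = graph$nodes$kind,
                          label = graph$nodes$label, stringsAsFactors = FALSE)
  )
}

#' Structural validation of a variation graph
#'
#' Asserts the construction invariants: the graph is a DAG; every node is
#' reachable from the source and co-reachable to the sink; and base-to-base
#' edges occur only inside a single insertion chain, so epsilon nodes
#' bottleneck every pair of adjacent variable positions.
#'
#' @param graph A `variant_graph`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_graph <- function(graph) {
  ig <- as_igraph_vg(graph)
  if (!igraph::is_dag(ig)) stop("variant graph contains a cycle", call. = FALSE)
  fwd <- igraph::subcomponent(ig, graph$source, mode = "out")
  bwd <- igraph::subcomponent(ig, graph$sink, mode = "in")
  if (length(fwd) != length(graph$nodes$id) ||
      length(bwd) != length(graph$nodes$id)) {
    stop("variant graph has nodes unreachable from source or sink", call. = FALSE)
  }
  kind <- stats::setNames(graph$nodes$kind, graph$nodes$id)
  bb <- kind[graph$edges$from] == "base" & kind[graph$edges$to] == "base"
  if (any(bb)) {
    anchor_of <- function(id) sub("^bi?:([0-9]+)[.:].*$", "\\1", id)
    f <- graph$edges$from[bb]; t <- graph$edges$to[bb]
    ok <- startsWith(f, "bi:") & startsWith(t, "bi:") &
      anchor_of(f) == anchor_of(t)
    if (!all(ok)) {
      stop("base-to-base edge crosses a position boundary without an epsilon",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- import / export -------------------------------------------------------

#' Export and import variation graphs
#'
#' `graph_to_json()`/`graph_from_json()` round-trip the full graph (nodes,
#' edges, reference) through a plain JSON document, for inspection and fixture
#' diffs. `graph_to_dot()` writes Graphviz DOT via igraph.
#'
#' @param graph A `variant_graph`.
#' @param path Output file path (for `graph_to_json()`, `NULL` returns the
#'   JSON string).
#' @return `graph_from_json()` returns a `variant_graph`; the writers return
#'   the path invisibly.
#' @name graph-io
NULL

#' @rdname graph-io
#' @export
graph_to_json <- function(graph, path = NULL) {
  doc <- list(
    reference = list(name = graph$reference$name, bases = graph$reference$bases),
    nodes = data.frame(id = graph$nodes$id, kind = graph$nodes$kind,
                       label = graph$nodes$label, stringsAsFactors = FALSE),
    edges = data.frame(from = graph$edges$from, to = graph$edges$to,
                       stringsAsFactors = FALSE)
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname graph-io
#' @export
graph_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  new_variant_graph(
    nodes = list(id = doc$nodes$id, kind = doc$nodes$kind,
                 label = ifelse(is.na(doc$nodes$label), "", doc$nodes$label)),
    edges = list(from = doc$edges$from, to = doc$edges$to),
    reference = reference_sequence(doc$reference$bases, doc$reference$name)
  )
}

#' @rdname graph-io
#' @export
graph_to_dot <- function(graph, path) {
  igraph::write_graph(as_igraph_vg(graph), path, format = "dot")
  invisible(path)
}
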