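# Synthetic haplotype databases and in silico two-person mixtures.
#
# Haplotypes are generated by independent per-site mutation on a reference
# (no phylogeny): the match statistics under test depend on haplotype
# diversity, not on realistic linkage, and the statistics themselves never
# see how the database was produced.

#' Population model for the synthetic database generator
#'
#' @param reference_length Reference length in bp (used when no reference is
#'   supplied to [simulate_database()]).
#' @param n_haplotypes Number of single-source haplotypes to generate.
#' @param substitution_rate Per-site substitution probability r per
#'   haplotype. Mean pairwise differences between two haplotypes scale as
#'   2Lr(1-r) (plus a small two-hit term), so r = 0.015 on a 1000 bp
#'   reference mimics the ~30 pairwise differences typical of European
#'   mitochondrial genomes; r = 0.0275 mimics the ~55 of African genomes.
#' @param indel_rate Per-site probability of starting an indel (insertion or
#'   deletion with equal probability); occasional, as in real mtDNA.
#' @param indel_max_len Maximum indel length (lengths are drawn with
#'   geometrically decaying weights).
#' @param population Population label stamped on every record.
#' @return A list of class `population_model`.
#' @export
population_model <- function(reference_length = 1000L, n_haplotypes = 100L,
                             substitution_rate = 0.015, indel_rate = 1e-4,
                             indel_max_len = 3L, population = "SYN") {
  stopifnot(
    reference_length >= 1L, n_haplotypes >= 1L,
    substitution_rate >= 0, substitution_rate <= 1,
    indel_rate >= 0, indel_rate <= 1, indel_max_len >= 1L
  )
  structure(
    list(reference_length = as.integer(reference_length),
         n_haplotypes = as.integer(n_haplotypes),
         substitution_rate = substitution_rate,
         indel_rate = indel_rate,
         indel_max_len = as.integer(indel_max_len),
         population = population),
    class = "population_model"
  )
}

#' Simulate a single-source haplotype database
#'
#' Generates `n_haplotypes` variant call sets against the reference:
#' independent per-site substitutions plus occasional indels (skipping
#' placements that would overlap or abut another indel in the same
#' haplotype, so each record is in canonical form). Fully deterministic
#' given `seed`.
#'
#' @param model A [population_model()].
#' @param seed Integer seed fixing the whole database.
#' @param reference Optional [reference_sequence()]; when `NULL` a random
#'   reference of `model$reference_length` bp is generated first.
#' @return A decoded database tibble (columns `sample_id`, `population`,
#'   `variants`, `calls`, `sequence`) with the reference attached as
#'   attribute `"reference"`.
#' @export
simulate_database <- function(model, seed = 1L, reference = NULL) {
  stopifnot(inherits(model, "population_model"))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  if (is.null(reference)) {
    reference <- reference_sequence(
      paste(sample(bases, model$reference_length, replace = TRUE),
            collapse = ""),
      name = paste0("synthetic_ref_", model$reference_length, "bp")
    )
  }
  reference <- as_reference(reference)
  L <- reference$length
  ref_chars <- strsplit(reference$bases, "", fixed = TRUE)[[1L]]

  # the three bases a reference base can mutate into
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  len_prob <- 0.7^seq_len(model$indel_max_len)

  calls_col <- vector("list", model$n_haplotypes)
  variants_col <- character(model$n_haplotypes)
  seq_col <- character(model$n_haplotypes)
  for (h in seq_len(model$n_haplotypes)) {
    sub_pos <- which(stats::runif(L) < model$substitution_rate)
    sub_allele <- alt[cbind(match(ref_chars[sub_pos], rownames(alt)),
                            sample.int(3L, length(sub_pos), replace = TRUE))]

    ind_pos <- which(stats::runif(L) < model$indel_rate)
    blocked <- integer()  # indel footprints (+/- 1) already used
    del_p <- integer(); del_e <- integer(); ins_p <- integer()
    ins_seq <- character()
    for (p in ind_pos) {
      len <- sample.int(model$indel_max_len, 1L, prob = len_prob)
      if (stats::runif(1L) < 0.5) {        # deletion of p..p+len-1
        e <- min(p + len - 1L, L)
        if (any(seq(p - 1L, e + 1L) %in% blocked)) next
        del_p <- c(del_p, p); del_e <- c(del_e, e)
        blocked <- c(blocked, (p - 1L):(e + 1L))
        sub_drop <- sub_pos >= p & sub_pos <= e   # variation under a deletion
        sub_pos <- sub_pos[!sub_drop]
        sub_allele <- sub_allele[!sub_drop]
      } else {                             # insertion after p
        if (any(p:(p + 1L) %in% blocked)) next
        ins_p <- c(ins_p, p)
        ins_seq <- c(ins_seq, paste(sample(bases, len, replace = TRUE),
                                    collapse = ""))
        blocked <- c(blocked, p, p + 1L)
      }
    }
    ns <- length(sub_pos); nd <- length(del_p); ni <- length(ins_p)
    calls <- tibble(
      kind = c(rep("substitution", ns), rep("deletion", nd),
               rep("insertion", ni)),
      position = c(sub_pos, del_p, ins_p),
      insert_index = c(rep(NA_integer_, ns + nd), rep(1L, ni)),
      end_position = c(rep(NA_integer_, ns), del_e, rep(NA_integer_, ni)),
      alleles = c(as.list(sub_allele), rep(list(character()), nd),
                  as.list(ins_seq)),
      reference_retained = c(rep(FALSE, ns), rep(TRUE, nd + ni))
    )
    rank <- c(substitution = 0L, deletion = 1L, insertion = 2L)
    calls <- calls[order(calls$position, rank[calls$kind]), , drop = FALSE]
    # already canonical (single-allele, non-adjacent indels): skip
    # renormalization and wrap directly
    prof <- structure(list(reference = reference, calls = calls),
                      class = "mixture_profile")
    calls_col[[h]] <- calls
    variants_col[h] <- format_variants(prof)
    seq_col[h] <- decode_haplotype(reference, prof)
  }
  db <- tibble(
    sample_id = sprintf("%s%05d", model$population,
                        seq_len(model$n_haplotypes)),
    population = model$population,
    variants = variants_col,
    calls = calls_col,
    sequence = seq_col
  )
  attr(db, "reference") <- reference
  db
}

#' Merge two single-source haplotypes into an in silico mixture
#'
#' Builds the mixture profile two error-free contributors would produce:
#' substitution allele sets are unioned (a contributor that carries the
#' reference at a site substituted in the other contributes the reference
#' allele, yielding an IUPAC ambiguity); an indel present in exactly one
#' contributor keeps the reference state available, while an indel shared
#' identically by both is marked fixed. Pairs are rejected — a typed
#' outcome, not an error — when the two haplotypes are identical (as
#' strings, so equivalent encodings count as identical) or when they carry
#' partially overlapping or abutting non-identical indels, whose merged
#' encoding would be ambiguous.
#'
#' @param h1,h2 One-row slices of a decoded database (needing `calls` and
#'   `sequence`), or lists with those fields.
#' @param reference The common [reference_sequence()].
#' @return A list of class `mixture_attempt`: `status` (`"ok"`,
#'   `"identical"` or `"indel_overlap"`), and for `"ok"` the merged
#'   `profile` plus the contributor `sequences`.
#' @export
make_mixture <- function(h1, h2, reference) {
  reference <- as_reference(reference)
  c1 <- h1$calls[[1L]]; c2 <- h2$calls[[1L]]
  s1 <- h1$sequence[[1L]]; s2 <- h2$sequence[[1L]]
  if (identical(s1, s2)) {
    return(structure(list(status = "identical"), class = "mixture_attempt"))
  }

  d1 <- c1[c1$kind == "deletion", ]; d2 <- c2[c2$kind == "deletion", ]
  i1 <- c1[c1$kind == "insertion", ]; i2 <- c2[c2$kind == "insertion", ]

  # cross-contributor indel compatibility
  del_key <- function(d) paste(d$position, d$end_position)
  shared_del <- intersect(del_key(d1), del_key(d2))
  for (a in seq_len(nrow(d1))) {
    for (b in seq_len(nrow(d2))) {
      if (del_key(d1[a, ]) == del_key(d2[b, ])) next
      if (d1$position[a] <= d2$end_position[b] + 1L &&
          d2$position[b] <= d1$end_position[a] + 1L) {
        return(structure(list(status = "indel_overlap"),
                         class = "mixture_attempt"))
      }
    }
  }
  ins_key <- function(i) paste0(i$position, ":", unlist(i$alleles))
  if (nrow(i1) > 0L && nrow(i2) > 0L) {
    anchors <- intersect(i1$position, i2$position)
    for (p in anchors) {
      if (!identical(i1$alleles[[which(i1$position == p)]],
                     i2$alleles[[which(i2$position == p)]])) {
        return(structure(list(status = "indel_overlap"),
                         class = "mixture_attempt"))
      }
    }
  }
  shared_ins <- intersect(ins_key(i1), ins_key(i2))

  # substitutions: union of observed alleles; the reference allele joins
  # only where that contributor actually carries the reference (site not
  # substituted nor under one of its deletions)
  carries_ref <- function(calls, dels, p) {
    if (nrow(dels) > 0L &&
        any(p >= dels$position & p <= dels$end_position)) return(FALSE)
    TRUE
  }
  sub1 <- c1[c1$kind == "substitution", ]; sub2 <- c2[c2$kind == "substitution", ]
  all_pos <- sort(unique(c(sub1$position, sub2$position)))
  sub_rows <- list()
  for (p in all_pos) {
    a1 <- if (p %in% sub1$position) {
      if (carries_ref(c1, d1, p)) sub1$alleles[[which(sub1$position == p)]]
      else character()
    } else if (carries_ref(c1, d1, p)) ref_base(reference, p) else character()
    a2 <- if (p %in% sub2$position) {
      if (carries_ref(c2, d2, p)) sub2$alleles[[which(sub2$position == p)]]
      else character()
    } else if (carries_ref(c2, d2, p)) ref_base(reference, p) else character()
    alle <- union(a1, a2)
    if (length(alle) == 0L || identical(sort(alle), ref_base(reference, p))) next
    sub_rows[[length(sub_rows) + 1L]] <- call_substitution(p, alle)
  }

  del_rows <- list()
  all_dels <- dplyr::bind_rows(d1, d2)
  all_dels <- all_dels[!duplicated(del_key(all_dels)), , drop = FALSE]
  for (k in seq_len(nrow(all_dels))) {
    del_rows[[length(del_rows) + 1L]] <- call_deletion(
      all_dels$position[k], all_dels$end_position[k],
      fixed = del_key(all_dels[k, ]) %in% shared_del
    )
  }
  ins_rows <- list()
  all_ins <- dplyr::bind_rows(i1, i2)
  all_ins <- all_ins[!duplicated(ins_key(all_ins)), , drop = FALSE]
  for (k in seq_len(nrow(all_ins))) {
    ins_rows[[length(ins_rows) + 1L]] <- call_insertion(
      all_ins$position[k], all_ins$alleles[[k]],
      fixed = ins_key(all_ins[k, ]) %in% shared_ins
    )
  }

  profile <- mixture_profile(
    reference, dplyr::bind_rows(c(sub_rows, del_rows, ins_rows))
  )
  structure(
    list(status = "ok", profile = profile, sequences = c(s1, s2)),
    class = "mixture_attempt"
  )
}

#' Run an in silico two-person mixture study
#'
#' Repeatedly samples two records from the database with replacement, builds
#' the mixture (rejecting identical haplotypes and incompatible indels, with
#' a fresh draw after each rejection), and computes the per-mixture match
#' statistics: the number of distinct haplotype pairs that explain the
#' mixture, the number of distinct haplotypes that cannot be excluded, the
#' record-level p(RMNE) with its Clopper-Pearson upper bound, and the GBC
#' likelihood treating the first-sampled contributor as known (u = 1).
#'
#' @param db A decoded database ([simulate_database()] or [decode_db()]).
#' @param n_mixtures Number of accepted mixtures sought.
#' @param seed Integer seed; the full study table is reproducible from it.
#' @param conf Confidence level for Clopper-Pearson upper bounds.
#' @param cap_paths Per-haplotype accepting-path cap in explanation tests.
#' @param max_attempts Bound on total draws (rejections included).
#' @return A tibble of class `mito_study`, one row per accepted mixture:
#'   contributor ids, the merged profile string, `n_explaining_pairs`,
#'   `n_consistent`, `generating_pair_explains`, `p_rmne`, `p_rmne_upper`,
#'   `gbc_proportion`, `gbc_upper` and their log10 columns. Rejection
#'   tallies are in `attr(, "rejections")`.
#' @export
run_study <- function(db, n_mixtures, seed = 1L, conf = 0.95,
                      cap_paths = 50L, max_attempts = 50L * n_mixtures) {
  reference <- attr(db, "reference")
  if (is.null(reference)) stop("db must carry a reference attribute ",
                               "(use simulate_database() or decode_db())",
                               call. = FALSE)
  if (!"sequence" %in% names(db)) stop("db must be decoded first", call. = FALSE)
  n <- nrow(db)
  if (length(unique(db$sequence)) < 2L) {
    stop("database has fewer than two distinct haplotypes; ",
         "every mixture would be rejected", call. = FALSE)
  }
  set.seed(seed)
  useq <- sort(unique(db$sequence))
  ucount <- as.numeric(table(db$sequence)[useq])

  rejections <- c(identical = 0L, indel_overlap = 0L)
  rows <- vector("list", n_mixtures)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_mixtures && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(n, 2L, replace = TRUE)
    mm <- make_mixture(db[ij[1L], ], db[ij[2L], ], reference)
    if (mm$status != "ok") {
      rejections[mm$status] <- rejections[mm$status] + 1L
      next
    }
    graph <- build_mixture_graph(mm$profile)
    gi <- graph_index(graph)
    cons <- as.logical(cpp_consistent(
      length(gi$ids), gi$is_base, gi$label,
      gi$from - 1L, gi$to - 1L, gi$source - 1L, gi$sink - 1L, useq
    ))
    cseq <- useq[cons]
    n_cons_records <- sum(ucount[cons])
    pe <- pairwise_explains(gi, cseq, cap_paths)
    n_pairs <- sum(pe$explained_pair[upper.tri(pe$explained_pair, diag = TRUE)])

    k1 <- match(mm$sequences[1L], cseq)
    k2 <- match(mm$sequences[2L], cseq)
    gen_explains <- !is.na(k1) && !is.na(k2) && pe$explained_pair[k1, k2]

    # GBC with the first-sampled contributor known, one unknown:
    # records whose haplotype pairs with the known to explain the mixture
    gbc_num <- sum(ucount[cons][pe$explained_pair[k1, ]])
    p_rmne <- n_cons_records / n
    gbc_prop <- gbc_num / n

    accepted <- accepted + 1L
    rows[[accepted]] <- tibble(
      id1 = db$sample_id[ij[1L]], id2 = db$sample_id[ij[2L]],
      profile = format_variants(mm$profile),
      n_explaining_pairs = n_pairs,
      n_consistent = length(cseq),
      generating_pair_explains = gen_explains,
      p_rmne = p_rmne,
      p_rmne_upper = clopper_pearson_upper(n_cons_records, n, conf),
      gbc_proportion = gbc_prop,
      gbc_upper = clopper_pearson_upper(gbc_num, n, conf),
      approximate = pe$truncated
    )
  }
  if (accepted == 0L) {
    stop("no mixture could be built: all ", attempts, " draws were rejected",
         call. = FALSE)
  }
  if (accepted < n_mixtures) {
    warning("sought ", n_mixtures, " mixtures but accepted only ", accepted,
            " in ", attempts, " draws")
  }
  out <- dplyr::bind_rows(rows[seq_len(accepted)])
  out$log10_p_rmne <- log10(out$p_rmne)
  out$log10_gbc <- log10(out$gbc_upper)
  class(out) <- c("mito_study", class(out))
  attr(out, "rejections") <- rejections
  attr(out, "seed") <- seed
  attr(out, "n_sought") <- n_mixtures
  out
}
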