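# Match statistics over a haplotype database.

#' Exact Clopper-Pearson upper confidence limit
#'
#' Upper limit of the exact two-sided binomial confidence interval at the
#' given confidence level: the (1 - alpha/2) quantile of the
#' Beta(successes + 1, trials - successes) distribution, with the limit equal
#' to 1 when all trials succeed. For zero successes it reduces to the closed
#' form `1 - (alpha/2)^(1/trials)`. Used throughout to correct proportions
#' (RMNE, explaining-combination fractions) estimated from a finite database.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1`. Vectorized.
#' @param conf Two-sided confidence level (default 0.95, i.e. a 97.5%
#'   one-sided upper bound).
#' @return Numeric vector of upper limits in (0, 1].
#' @examples
#' clopper_pearson_upper(0, 10)     # 1 - 0.025^(1/10)
#' clopper_pearson_upper(5, 10)
#' @export
clopper_pearson_upper <- function(successes, trials, conf = 0.95) {
  if (any(trials < 1)) stop("trials must be >= 1", call. = FALSE)
  if (any(successes < 0) || any(successes > trials)) {
    stop("successes must lie in 0..trials", call. = FALSE)
  }
  alpha <- 1 - conf
  ifelse(successes >= trials, 1,
         stats::qbeta(1 - alpha / 2, successes + 1, trials - successes))
}

#' Random man not excluded (RMNE) for a mixture graph
#'
#' A potential contributor is any individual whose haplotype traces a path
#' through the mixture graph. p(RMNE) is the proportion of database records
#' that are consistent in this sense, with an exact Clopper-Pearson upper
#' bound correcting for the finite database. The statistic applies to
#' arbitrarily complex mixtures and needs no assumed contributor count.
#'
#' @param db A haplotype database tibble (see [read_haplotype_db()]), with a
#'   `sequence` column (add one with [decode_db()]) or decodable `variants`.
#' @param graph The mixture's `variant_graph`. When `mask` is used, build the
#'   graph from the masked profile so mixture and database are filtered
#'   identically.
#' @param population Optional population label to restrict to.
#' @param mask Optional [mask_intervals()]; database haplotypes are re-decoded
#'   with masked calls.
#' @param conf Confidence level for the upper bound.
#' @return An object of class `rmne_result`; see [tidy.rmne_result()].
#' @export
rmne <- function(db, graph, population = NULL, mask = NULL, conf = 0.95) {
  db <- filter_population(db, population)
  seqs <- db_sequences(db, graph$reference, mask)
  cons <- is_consistent(graph, seqs)
  n <- length(seqs)
  k <- sum(cons)
  structure(
    list(
      population = population %||% "all",
      n_consistent = k, n = n,
      p_rmne = k / n,
      p_rmne_upper = clopper_pearson_upper(k, n, conf),
      conf = conf
    ),
    class = "rmne_result"
  )
}

#' @export
print.rmne_result <- function(x, ...) {
  cat("<rmne_result> ", x$n_consistent, "/", x$n, " consistent (",
      x$population, "); p(RMNE) = ", signif(x$p_rmne, 4),
      ", ", x$conf * 100, "% CP upper = ", signif(x$p_rmne_upper, 4),
      "\n", sep = "")
  invisible(x)
}

#' Naive likelihood of a set of unknown haplotypes
#'
#' `|U|! * prod(Pr(H_j))` for unknown haplotypes H_1..H_|U| with frequencies
#' Pr(H_j): the number of orderings of the unknowns times the product of
#' their frequencies.
#'
#' @param frequencies Numeric vector of haplotype frequencies in `[0, 1]`.
#' @return The likelihood.
#' @examples
#' naive_likelihood(c(0.1, 0.2))  # 2! * 0.1 * 0.2 = 0.04
#' @export
naive_likelihood <- function(frequencies) {
  stopifnot(length(frequencies) >= 1L)
  if (any(frequencies < 0 | frequencies > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  factorial(length(frequencies)) * prod(frequencies)
}

#' Total likelihood over all explaining unknown sets
#'
#' Sums the naive likelihood over the collection T of all u-sets of database
#' haplotypes that, together with the known contributors, explain the
#' mixture graph. Haplotype frequencies are relative frequencies in the
#' (population slice of the) database. Candidates are pre-filtered to
#' haplotypes not excluded by [is_consistent()], which cannot change the sum.
#' When no set explains the mixture the sum is empty and the likelihood 0,
#' flagged `empty_T` — the situation the GBC estimator is designed for.
#'
#' @inheritParams rmne
#' @param u Number of unknown contributors (>= 1).
#' @param knowns Character vector of known (conditioned-on) contributor
#'   sequences.
#' @return An object of class `total_likelihood_result` with fields
#'   `likelihood`, `n_sets`, `empty_T`, `u`.
#' @export
total_likelihood <- function(db, graph, u, knowns = character(),
                             population = NULL, conf = 0.95) {
  stopifnot(u >= 1)
  db <- filter_population(db, population)
  seqs <- db_sequences(db, graph$reference)
  n <- length(seqs)
  tab <- table(seqs)
  useq <- names(tab)
  cand <- useq[as.logical(is_consistent(graph, useq))]
  sets <- enumerate_multisets(length(cand), u)
  lik <- 0
  n_sets <- 0L
  for (s in sets) {
    U <- cand[s]
    if (explains(graph, c(knowns, U))$explained) {
      lik <- lik + naive_likelihood(as.numeric(tab[U]) / n)
      n_sets <- n_sets + 1L
    }
  }
  structure(
    list(likelihood = lik, n_sets = n_sets, empty_T = n_sets == 0L, u = u,
         knowns = knowns),
    class = "total_likelihood_result"
  )
}

#' @export
print.total_likelihood_result <- function(x, ...) {
  cat("<total_likelihood> L = ", format(x$likelihood), " over ", x$n_sets,
      " explaining set(s)", if (x$empty_T) " [empty T]", "\n", sep = "")
  invisible(x)
}

#' GBC likelihood: explaining-combination proportion with exact upper bound
#'
#' The likelihood of a mixture under u unknown contributors, estimated as
#' the proportion of u-combinations of database haplotypes that (with the
#' known contributors appended) explain the mixture, out of the
#' choose(n, u) ways of drawing u haplotypes from a database of size n
#' (n(n-1)/2 pairs for u = 2). A Clopper-Pearson upper bound corrects for
#' the finite database; in the common case where no combination explains the
#' mixture the estimate is the upper bound on 0 successes in choose(n, u)
#' trials, which keeps the likelihood well defined where the total
#' likelihood degenerates to an empty sum.
#'
#' The combination scan is restricted to haplotypes that are not formally
#' excluded (consistent with the graph), which leaves the count unchanged
#' since an explaining combination must be individually consistent.
#'
#' @inheritParams total_likelihood
#' @param with_replacement Draw unknowns as multisets with replacement
#'   (denominator `choose(n + u - 1, u)`) instead of the default
#'   combinations without replacement (denominator `choose(n, u)`).
#' @param include_knowns Also allow the known contributors to be drawn as
#'   unknowns by implicitly appending them to the database (denominator uses
#'   the enlarged n). Default `FALSE`: knowns are conditioned on, not drawn.
#' @return An object of class `gbc_result` with fields `n_explaining`,
#'   `denominator`, `proportion`, `upper_bound`, `u`, `n`.
#' @export
gbc_likelihood <- function(db, graph, u, knowns = character(),
                           population = NULL, conf = 0.95,
                           with_replacement = FALSE, include_knowns = FALSE) {
  stopifnot(u >= 1)
  db <- filter_population(db, population)
  seqs <- db_sequences(db, graph$reference)
  if (include_knowns) seqs <- c(seqs, toupper(knowns))
  n <- length(seqs)
  if (n < u && !with_replacement) stop("u exceeds database size", call. = FALSE)
  tab <- table(seqs)
  useq <- names(tab)
  cand <- useq[as.logical(is_consistent(graph, useq))]
  counts <- as.numeric(tab[cand])

  n_explaining <- 0
  for (s in enumerate_multisets(length(cand), u)) {
    mult <- tabulate(s, nbins = length(cand))
    ways <- if (with_replacement) {
      prod(choose(counts + mult - 1, mult)[mult > 0])
    } else {
      prod(choose(counts, mult)[mult > 0])
    }
    if (ways == 0) next
    if (explains(graph, c(knowns, cand[s]))$explained) {
      n_explaining <- n_explaining + ways
    }
  }
  denominator <- if (with_replacement) choose(n + u - 1, u) else choose(n, u)
  structure(
    list(
      n_explaining = n_explaining, denominator = denominator,
      proportion = n_explaining / denominator,
      upper_bound = clopper_pearson_upper(n_explaining, denominator, conf),
      u = u, n = n, conf = conf,
      with_replacement = with_replacement, include_knowns = include_knowns
    ),
    class = "gbc_result"
  )
}

#' @export
print.gbc_result <- function(x, ...) {
  cat("<gbc_result> ", x$n_explaining, "/", format(x$denominator),
      " explaining combination(s); proportion = ", signif(x$proportion, 4),
      ", CP upper = ", signif(x$upper_bound, 4), "\n", sep = "")
  invisible(x)
}

# all u-multisets of 1..m as sorted index vectors (m^u bounded by caller use;
# candidates are the consistent few, per the pre-filter)
enumerate_multisets <- function(m, u) {
  if (m == 0L) return(list())
  if (choose(m + u - 1, u) > 1e6) {
    stop("too many candidate haplotype combinations (", m, " candidates, u = ",
         u, "); tighten the mixture or mask first", call. = FALSE)
  }
  out <- list()
  rec <- function(start, left, acc) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (i in start:m) rec(i, left - 1L, c(acc, i))
  }
  rec(1L, as.integer(u), integer())
  out
}

filter_population <- function(db, population) {
  if (is.null(population)) return(db)
  hit <- db$population == population
  if (!any(hit)) {
    stop("no records for population '", population, "'; available: ",
         paste(sort(unique(db$population)), collapse = ", "), call. = FALSE)
  }
  db[hit, , drop = FALSE]
}

# sequences of a database slice, decoding (and optionally masking) on demand
db_sequences <- function(db, reference, mask = NULL) {
  if (nrow(db) == 0L) stop("empty haplotype database slice", call. = FALSE)
  if (is.null(mask)) {
    if (!is.null(db[["sequence"]])) return(db$sequence)
    return(vapply(db$variants, function(v) {
      decode_haplotype(reference, parse_variants(v, reference))
    }, character(1L), USE.NAMES = FALSE))
  }
  vapply(db$variants, function(v) {
    prof <- mask_profile(parse_variants(v, reference), mask)
    decode_haplotype(reference, prof)
  }, character(1L), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
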