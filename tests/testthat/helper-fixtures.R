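# Shared fixtures: references, toy databases, independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic reference with A forced at the given positions (no RNG)
ref_with_A <- function(positions, length = 200L) {
  chars <- rep(c("C", "G", "T", "C"), length.out = length)
  chars[positions] <- "A"
  reference_sequence(paste(chars, collapse = ""), name = "fixture")
}

# the three-site worked mixture: 73G 154W 178M on a reference with A at all
# three sites
worked_example <- function() {
  ref <- ref_with_A(c(73L, 154L, 178L))
  list(ref = ref, profile = parse_variants("73G 154W 178M", ref))
}

toy_db <- function(ref, variants, population = "EU",
                   ids = sprintf("s%02d", seq_along(variants))) {
  decode_db(
    tibble::tibble(sample_id = ids, population = population,
                   variants = variants),
    ref
  )
}

# independent Clopper-Pearson oracle: invert the binomial tail equality
# P(X <= x; n, p) = alpha/2 by bisection on p
cp_upper_oracle <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  if (x >= n) return(1)
  stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                 c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# brute-force explanation oracle over all unordered pairs of generated
# sequences, using explains() directly (no pairwise shortcut)
brute_force_pairs <- function(graph, cap = 1000) {
  seqs <- enumerate_generated(graph, cap)$sequences
  out <- list()
  for (i in seq_along(seqs)) {
    for (j in i:length(seqs)) {
      if (explains(graph, c(seqs[i], seqs[j]))$explained) {
        out[[length(out) + 1L]] <- sort(c(seqs[i], seqs[j]))
      }
    }
  }
  out
}

# profile with k independent biallelic substitution sites (ref allele kept)
biallelic_profile <- function(k, spacing = 3L) {
  positions <- spacing * seq_len(k)
  ref <- ref_with_A(positions, length = spacing * k + 2L)
  parse_variants(paste0(positions, "R", collapse = " "), ref)
}
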