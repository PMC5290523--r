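# Independent oracles. Each one recomputes a quantity the package computes,
# by a different route, and must never call the code path it checks.

# Minimum edit distance of `pattern` against any substring of `text` whose
# length lies within `max_errors` of the pattern length: an exhaustive
# O(n * m * k) scan over every (offset, window length) pair, with the edit
# distances delegated to utils::adist.
primer_scan_oracle <- function(text, pattern, max_errors) {
  n <- nchar(text)
  m <- nchar(pattern)
  best <- Inf
  for (L in max(1, m - max_errors):(m + max_errors)) {
    if (L > n) next
    windows <- substring(text, 1:(n - L + 1), L:n)
    best <- min(best, min(utils::adist(pattern, windows)))
  }
  best
}

# Score-only affine-gap Smith-Waterman, plain quadratic DP in R.
sw_score_oracle <- function(query, ref, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (q[i - 1] == r[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# The allelic-imbalance calling rule, re-stated from scratch as scalar
# branches: homozygous reference above the cut-off, homozygous alternative
# when the reference fraction is under the lower cut-off AND the alternative
# fraction clears the cut-off, heterozygous otherwise; below the depth floor
# nothing is called.
genotype_rule_oracle <- function(n_ref, n_alt, n_other,
                                 hom_cutoff = 0.75, het_lower = 0.25,
                                 min_depth = 20) {
  depth <- n_ref + n_alt + n_other
  if (depth < min_depth) return("no_call")
  ref_frac <- n_ref / depth
  alt_frac <- n_alt / depth
  if (ref_frac > hom_cutoff) return("hom_ref")
  if (ref_frac < het_lower && alt_frac > hom_cutoff) return("hom_alt")
  "het"
}

# Same DP, row-vectorized for larger batches. A left-gap state must start
# from a cell not itself ending in a left gap (merging two abutting gaps
# into one is never worse), so E follows from a prefix cummax over
# H0 = max(0, diagonal, F).
sw_score_oracle_vec <- function(query, ref, match = 1, mismatch = -1,
                                gap_open = -2, gap_extend = -1) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  js <- seq_len(m)
  H_prev <- numeric(m + 1)
  F_prev <- rep(-Inf, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    s <- ifelse(q[i] == r, match, mismatch)
    D <- H_prev[js] + s
    F_cur <- pmax(H_prev[js + 1] + gap_open + gap_extend,
                  F_prev[js + 1] + gap_extend)
    H0 <- pmax(0, D, F_cur)
    G <- H0 + gap_open - gap_extend * js
    E <- gap_extend * js + c(-Inf, cummax(G)[-m])
    H_cur <- pmax(H0, E)
    best <- max(best, H_cur)
    H_prev <- c(0, H_cur)
    F_prev <- c(-Inf, F_cur)
  }
  best
}

# Mutate a sequence with k random edits (substitutions, insertions,
# deletions), used to plant approximate primer occurrences.
mutate_edits <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  for (e in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1)
    pos <- sample(length(x), 1)
    if (op == "sub") x[pos] <- sample(setdiff(c("A", "C", "G", "T"), x[pos]), 1)
    else if (op == "ins") x <- append(x, sample(c("A", "C", "G", "T"), 1), pos)
    else if (length(x) > 1) x <- x[-pos]
  }
  paste(x, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
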