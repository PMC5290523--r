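#' Reverse complement DNA sequences
#'
#' Vectorized; `N` complements to itself.
#'
#' @param seq Character vector over the alphabet A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AACN")
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
         USE.NAMES = FALSE)
}

#' Find approximate primer matches in a read
#'
#' Scans a read for occurrences of a primer within a maximum edit distance
#' (Myers bit-parallel algorithm; or fixed-length Hamming windows in
#' `"substitution"` mode). Overlapping candidate matches are reduced to the
#' local best: lowest edit count, then leftmost start.
#'
#' @param read A sequence string, or a one-row reads `data.frame`.
#' @param primer Primer sequence (>= 10 nt, plain A/C/G/T).
#' @param max_errors Maximum edit distance; must be below half the primer
#'   length.
#' @param mode `"edit"` (default) or `"substitution"`.
#' @return `data.frame` with columns `start`, `end` (1-based, inclusive) and
#'   `edits`, sorted by `start`. Zero rows when there is no match.
#' @export
#' @examples
#' find_primer_matches("TTTTTACGTACGTACGTTTTT", "ACGTACGTACGT", 0)
find_primer_matches <- function(read, primer, max_errors = 3L,
                                mode = c("edit", "substitution")) {
  mode <- match.arg(mode)
  if (is.data.frame(read)) read <- read$sequence[1]
  stopifnot(is.character(read), length(read) == 1L)
  if (nchar(primer) < 10L)
    stop("primer must be at least 10 nt long", call. = FALSE)
  if (grepl("[^ACGT]", primer))
    stop("primer contains characters outside A/C/G/T", call. = FALSE)
  if (max_errors >= nchar(primer) / 2)
    stop("max_errors must be below half the primer length", call. = FALSE)
  cpp_primer_hits(read, primer, as.integer(max_errors),
                  mode == "substitution")
}

#' Excise amplicon subreads from concatemer reads
#'
#' Identifies amplicon occurrences inside each (possibly concatenated) read
#' by approximate matching of both primers on both strands, excises the
#' primer-inclusive span, reverse-complements minus-strand subreads into the
#' locus forward orientation, and keeps subreads whose length lies in
#' `[min_subread_len, max_subread_len]` (inclusive). Each forward-primer hit
#' is paired with the nearest compatible downstream reverse-primer hit;
#' competing overlapping excisions are resolved by total primer edit count,
#' then leftmost start, and a read base belongs to at most one subread.
#'
#' @param reads Reads `data.frame` from [read_fastq()] or [simulate_reads()].
#' @param panel Panel `data.frame` from [load_panel()] or [make_panel()].
#' @param cfg A [pipeline_config()].
#' @return `data.frame` with one row per subread: `parent_read_id`,
#'   `locus_id`, `strand` (`"+"`/`"-"`), `start`, `end` (span on the parent
#'   read, 1-based inclusive), `primer_edits`, `sequence` (forward
#'   orientation), `quality`.
#' @export
extract_subreads <- function(reads, panel, cfg = pipeline_config()) {
  cfg <- as_config_(cfg)
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  if (nrow(reads) == 0L) return(empty_subreads_())
  cand <- cpp_extract_candidates(
    reads$sequence,
    start_plus = panel$fwd_primer,
    end_plus = reverse_complement(panel$rev_primer),
    start_minus = panel$rev_primer,
    end_minus = reverse_complement(panel$fwd_primer),
    max_errors = cfg$max_primer_errors,
    subs_only = cfg$primer_match_mode == "substitution",
    min_len = cfg$min_subread_len, max_len = cfg$max_subread_len)
  if (nrow(cand) == 0L) return(empty_subreads_())
  seq <- substr(reads$sequence[cand$read_index], cand$start, cand$end)
  qual <- substr(reads$quality[cand$read_index], cand$start, cand$end)
  minus <- cand$strand < 0L
  if (any(minus)) {
    seq[minus] <- reverse_complement(seq[minus])
    qual[minus] <- vapply(qual[minus], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  data.frame(
    parent_read_id = reads$read_id[cand$read_index],
    locus_id = panel$locus_id[cand$locus_index],
    strand = ifelse(minus, "-", "+"),
    start = cand$start, end = cand$end,
    primer_edits = cand$edits,
    sequence = seq, quality = qual,
    stringsAsFactors = FALSE)
}

empty_subreads_ <- function() {
  data.frame(parent_read_id = character(), locus_id = character(),
             strand = character(), start = integer(), end = integer(),
             primer_edits = integer(), sequence = character(),
             quality = character(), stringsAsFactors = FALSE)
}

#' Randomly downsample reads
#'
#' Each read is kept independently with probability `fraction`, under a
#' fixed seed, so the same seed always selects the same subset. Used to
#' check profile stability at a fraction of the sequencing depth (e.g.
#' 1/100th of a run).
#'
#' @param reads Reads `data.frame`.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return The kept subset of `reads`, in the original order.
#' @export
downsample_reads <- function(reads, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(reads)
  keep <- with_seed_(seed, runif(nrow(reads)) < fraction)
  reads[keep, , drop = FALSE]
}
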