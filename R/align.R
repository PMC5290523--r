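#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman. A gap of length L scores
#' `gap_open + L * gap_extend`. Tie-breaking is deterministic: ungapped
#' (diagonal) moves are preferred over gaps, and among equal-scoring end
#' cells the one ending earliest on the reference wins.
#'
#' @param query,context Non-empty DNA strings.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param snp_pos Optional 1-based reference position whose aligned query
#'   base is reported (`"DELETED"` when a deletion spans it, `"UNCOVERED"`
#'   when the alignment does not reach it).
#' @return List with `score`, `cigar` (M/I/D; I consumes query only),
#'   `ref_start`, `ref_end`, `query_start`, `query_end` (1-based inclusive),
#'   `mismatches`, `indels` (total gapped bases), and `snp_observation`.
#' @export
#' @examples
#' ctx <- strrep("ACGT", 12)
#' align_local(ctx, ctx)$score
align_local <- function(query, context,
                        scoring = list(match = 1, mismatch = -1,
                                       gap_open = -2, gap_extend = -1),
                        snp_pos = 0L) {
  stopifnot(nzchar(query), nzchar(context))
  cpp_align_local(query, context, as.integer(scoring$match),
                  as.integer(scoring$mismatch), as.integer(scoring$gap_open),
                  as.integer(scoring$gap_extend), as.integer(snp_pos))
}

#' Map subreads to their locus reference contexts
#'
#' Each subread is aligned locally against two versions of its assigned
#' locus's 51-nt context — with the reference and with the alternative
#' allele at the central position — and the better-scoring alignment is
#' kept (reference wins ties). A subread is supposed to contain the whole
#' 51-nt context, so context columns the alignment fails to cover count as
#' errors alongside mismatches and indels: alignments whose
#' `(mismatches + indels + uncovered context columns) / context length`
#' exceeds `cfg$max_map_mismatch_frac` are excluded as `high_mismatch`
#' (this is also what rejects random sequence, whose best local alignment
#' is a short high-identity island); subreads producing no positive-scoring
#' alignment are excluded as `no_overlap`.
#' With `cfg$cross_locus_check`, a subread that does not beat every other
#' locus's context by `cfg$cross_locus_margin` is excluded as `ambiguous`.
#' The base observed at the SNP position is read off the alignment column
#' covering context position 26.
#'
#' @param subreads Subreads `data.frame` from [extract_subreads()].
#' @param panel Panel `data.frame`.
#' @param cfg A [pipeline_config()].
#' @return `data.frame`: the subread identity columns plus `score`, `cigar`,
#'   `ref_start`, `ref_end`, `mismatches`, `indels`, `status`
#'   (`"mapped"`/`"excluded"`), `exclusion_reason` (`high_mismatch`,
#'   `ambiguous`, `no_overlap` or `none`), and `snp_observation` (a base,
#'   `DELETED`, or `UNCOVERED`).
#' @export
map_subreads <- function(subreads, panel, cfg = pipeline_config()) {
  cfg <- as_config_(cfg)
  if (nrow(subreads) == 0L) return(empty_alignments_())
  unknown <- setdiff(unique(subreads$locus_id), panel$locus_id)
  if (length(unknown))
    stop("subread assigned to locus absent from panel: ", unknown[1],
         call. = FALSE)
  alt_ctx <- alt_context_(panel)
  pieces <- lapply(seq_len(nrow(panel)), function(i) {
    idx <- which(subreads$locus_id == panel$locus_id[i])
    if (!length(idx)) return(NULL)
    aln <- cpp_map_batch(subreads$sequence[idx], panel$context[i], alt_ctx[i],
                         26L, cfg$match, cfg$mismatch, cfg$gap_open,
                         cfg$gap_extend)
    aln$.row <- idx
    aln
  })
  aln <- do.call(rbind, pieces)
  aln <- aln[order(aln$.row), , drop = FALSE]
  seqs <- subreads$sequence[aln$.row]
  out <- cbind(subreads[aln$.row, c("parent_read_id", "locus_id", "strand",
                                    "start", "end"), drop = FALSE],
               aln[, c("score", "cigar", "ref_start", "ref_end", "mismatches",
                       "indels", "aligned_ref_len", "snp_observation"),
                   drop = FALSE])
  rownames(out) <- NULL
  status <- rep("mapped", nrow(out))
  reason <- rep("none", nrow(out))
  ctx_len <- nchar(panel$context[match(out$locus_id, panel$locus_id)])
  no_aln <- out$score <= 0 | out$aligned_ref_len == 0L
  bad <- !no_aln &
    (out$mismatches + out$indels + (ctx_len - out$aligned_ref_len)) /
      ctx_len > cfg$max_map_mismatch_frac
  status[no_aln] <- "excluded"; reason[no_aln] <- "no_overlap"
  status[bad] <- "excluded"; reason[bad] <- "high_mismatch"
  if (cfg$cross_locus_check && nrow(panel) > 1L) {
    for (k in which(status == "mapped")) {
      others <- panel$context[panel$locus_id != out$locus_id[k]]
      best_other <- max(cpp_score_batch(seqs[k], others, cfg$match,
                                        cfg$mismatch, cfg$gap_open,
                                        cfg$gap_extend))
      if (out$score[k] - best_other < cfg$cross_locus_margin) {
        status[k] <- "excluded"; reason[k] <- "ambiguous"
      }
    }
  }
  out$status <- status
  out$exclusion_reason <- reason
  out$snp_observation[status == "excluded"] <- NA_character_
  out
}

# context with the alternative allele substituted at the central position
alt_context_ <- function(panel) {
  ctx <- panel$context
  paste0(substr(ctx, 1, 25), panel$alt_allele, substr(ctx, 27, 51))
}

empty_alignments_ <- function() {
  data.frame(parent_read_id = character(), locus_id = character(),
             strand = character(), start = integer(), end = integer(),
             score = integer(), cigar = character(), ref_start = integer(),
             ref_end = integer(), mismatches = integer(), indels = integer(),
             aligned_ref_len = integer(), snp_observation = character(),
             status = character(), exclusion_reason = character(),
             stringsAsFactors = FALSE)
}

#' Map one subread
#'
#' Convenience wrapper around [map_subreads()] for a single subread row.
#'
#' @param subread One-row subreads `data.frame`.
#' @param locus One-row panel `data.frame` for the assigned locus.
#' @param cfg A [pipeline_config()].
#' @return One-row alignment `data.frame` (see [map_subreads()]).
#' @export
map_subread <- function(subread, locus, cfg = pipeline_config()) {
  map_subreads(subread[1, , drop = FALSE], locus[1, , drop = FALSE], cfg)
}

#' Mapping rate of a locus
#'
#' Fraction of extracted subreads that mapped. Defined as 0 for an empty
#' locus, which is flagged.
#'
#' @param alignments Alignment `data.frame` rows for one locus.
#' @return List with `rate`, `n_mapped`, `n_extracted`, `empty_locus`.
#' @export
#' @examples
#' mapping_rate(data.frame(status = c("mapped", "mapped", "excluded")))
mapping_rate <- function(alignments) {
  n <- nrow(alignments)
  m <- sum(alignments$status == "mapped")
  list(rate = if (n == 0L) 0 else m / n,
       n_mapped = m, n_extracted = n, empty_locus = n == 0L)
}
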