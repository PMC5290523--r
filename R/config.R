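#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis. Defaults follow the
#' published protocol where one exists: up to 3 errors per primer match,
#' subread length filter 50-150 nt (inclusive), homozygous call above 75%
#' reference fraction with the symmetric 25% lower heterozygote bound, and a
#' homopolymer screen for runs of four or more bases. Constants the protocol
#' leaves open (mapping exclusion threshold, minimum call depth, alignment
#' scoring) are package choices, documented in the methods vignette.
#'
#' @param max_primer_errors Maximum edit distance allowed per primer match.
#' @param min_subread_len,max_subread_len Inclusive subread length filter, nt.
#' @param hom_cutoff Reference (or alternative) fraction above which a locus
#'   is called homozygous.
#' @param het_lower_cutoff Lower allele-fraction bound of the heterozygote
#'   band; must satisfy `0 < het_lower_cutoff < hom_cutoff < 1`.
#' @param max_map_mismatch_frac Alignments with
#'   `(mismatches + indels + uncovered context columns) / context length`
#'   above this are excluded (see [map_subreads()]).
#' @param min_call_depth Loci with fewer informative observations are
#'   reported as `no_call`.
#' @param homopolymer_min_run Minimum run length (default 4) that triggers
#'   the homopolymer risk flag near the SNP.
#' @param rng_seed Seed used by seeded operations (e.g. downsampling) when
#'   none is given explicitly.
#' @param primer_match_mode `"edit"` (substitutions + indels; default, the
#'   permissive reading appropriate for indel-rich nanopore reads) or
#'   `"substitution"` (Hamming windows only).
#' @param match,mismatch,gap_open,gap_extend Local-alignment scores; a gap of
#'   length L scores `gap_open + L * gap_extend`.
#' @param cross_locus_check If `TRUE`, a mapped subread is additionally
#'   required to score at least `cross_locus_margin` better against its
#'   assigned locus than against any other locus context ("uniquely mapped");
#'   off by default because extraction already assigns loci by primer.
#' @param cross_locus_margin Minimum score margin for the uniqueness screen.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(min_call_depth = 10)
#' cfg$hom_cutoff
pipeline_config <- function(max_primer_errors = 3L,
                            min_subread_len = 50L,
                            max_subread_len = 150L,
                            hom_cutoff = 0.75,
                            het_lower_cutoff = 0.25,
                            max_map_mismatch_frac = 0.30,
                            min_call_depth = 20L,
                            homopolymer_min_run = 4L,
                            rng_seed = 1L,
                            primer_match_mode = c("edit", "substitution"),
                            match = 1L, mismatch = -1L,
                            gap_open = -2L, gap_extend = -1L,
                            cross_locus_check = FALSE,
                            cross_locus_margin = 2L) {
  primer_match_mode <- match.arg(primer_match_mode)
  cfg <- list(
    max_primer_errors = as.integer(max_primer_errors),
    min_subread_len = as.integer(min_subread_len),
    max_subread_len = as.integer(max_subread_len),
    hom_cutoff = hom_cutoff,
    het_lower_cutoff = het_lower_cutoff,
    max_map_mismatch_frac = max_map_mismatch_frac,
    min_call_depth = as.integer(min_call_depth),
    homopolymer_min_run = as.integer(homopolymer_min_run),
    rng_seed = as.integer(rng_seed),
    primer_match_mode = primer_match_mode,
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    cross_locus_check = isTRUE(cross_locus_check),
    cross_locus_margin = as.integer(cross_locus_margin)
  )
  if (cfg$max_primer_errors < 0L)
    stop("max_primer_errors must be >= 0", call. = FALSE)
  if (!(cfg$min_subread_len < cfg$max_subread_len))
    stop("min_subread_len must be < max_subread_len", call. = FALSE)
  if (!(0 < cfg$het_lower_cutoff && cfg$het_lower_cutoff < cfg$hom_cutoff &&
        cfg$hom_cutoff < 1))
    stop("need 0 < het_lower_cutoff < hom_cutoff < 1", call. = FALSE)
  if (cfg$max_map_mismatch_frac <= 0 || cfg$max_map_mismatch_frac >= 1)
    stop("max_map_mismatch_frac must be in (0, 1)", call. = FALSE)
  if (cfg$min_call_depth < 1L)
    stop("min_call_depth must be >= 1", call. = FALSE)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

as_config_ <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) return(cfg)
  if (is.null(cfg)) return(pipeline_config())
  stop("cfg must be a pipeline_config()", call. = FALSE)
}
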