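#' Tabulate allele observations at a locus
#'
#' Counts the SNP-position observations of the mapped subreads of one locus:
#' `n_ref` (reference allele), `n_alt` (alternative allele), and `n_other`
#' (any third base, `N`, or `DELETED`). `UNCOVERED` observations carry no
#' information about the SNP and are excluded from depth; excluded
#' alignments are ignored.
#'
#' @param alignments Alignment `data.frame` rows (see [map_subreads()]); all
#'   rows must belong to `locus`.
#' @param locus One-row panel `data.frame`.
#' @return One-row `data.frame`: `locus_id`, `n_ref`, `n_alt`, `n_other`,
#'   `depth` (= `n_ref + n_alt + n_other`).
#' @export
tabulate_alleles <- function(alignments, locus) {
  locus <- locus[1, , drop = FALSE]
  if (nrow(alignments) && any(alignments$locus_id != locus$locus_id))
    stop("alignment from a different locus than '", locus$locus_id, "'",
         call. = FALSE)
  obs <- alignments$snp_observation[alignments$status == "mapped"]
  obs <- obs[!is.na(obs) & obs != "UNCOVERED"]
  n_ref <- sum(obs == locus$ref_allele)
  n_alt <- sum(obs == locus$alt_allele)
  data.frame(locus_id = locus$locus_id, n_ref = n_ref, n_alt = n_alt,
             n_other = length(obs) - n_ref - n_alt, depth = length(obs),
             stringsAsFactors = FALSE)
}

#' Call genotypes from allele counts
#'
#' Applies the allelic-imbalance cut-off rule. With fractions computed over
#' the full informative depth (`n_ref + n_alt + n_other`):
#' * `depth < min_call_depth` gives `no_call`;
#' * reference fraction above `hom_cutoff` gives `hom_ref`;
#' * reference fraction below `het_lower_cutoff` with alternative fraction
#'   above `hom_cutoff` gives `hom_alt`;
#' * anything else is `het`.
#'
#' `imbalance_warning` is set for a heterozygous call whose major allele
#' fraction exceeds 0.65, and for a homozygous call whose minor informative
#' allele fraction exceeds 0.15 or whose remaining reads are not mainly the
#' other allele (`n_other` exceeds it); the call itself stands. `low_depth`
#' and `empty_locus` flag the no-call states.
#'
#' @param counts Allele-count `data.frame` (any number of rows) from
#'   [tabulate_alleles()].
#' @param cfg A [pipeline_config()].
#' @return `data.frame`, one row per input row: `locus_id`, `genotype`,
#'   `depth`, counts, `ref_fraction`, `alt_fraction`, `other_fraction`,
#'   `flags` (comma-separated, possibly empty).
#' @export
#' @examples
#' call_genotypes(data.frame(locus_id = "rs0", n_ref = 757, n_alt = 243,
#'                           n_other = 0, depth = 1000))
call_genotypes <- function(counts, cfg = pipeline_config()) {
  cfg <- as_config_(cfg)
  depth <- counts$n_ref + counts$n_alt + counts$n_other
  if (!is.null(counts$depth) && any(counts$depth != depth))
    stop("depth must equal n_ref + n_alt + n_other", call. = FALSE)
  rf <- ifelse(depth > 0, counts$n_ref / depth, 0)
  af <- ifelse(depth > 0, counts$n_alt / depth, 0)
  of <- ifelse(depth > 0, counts$n_other / depth, 0)
  genotype <- ifelse(
    depth < cfg$min_call_depth, "no_call",
    ifelse(rf > cfg$hom_cutoff, "hom_ref",
           ifelse(rf < cfg$het_lower_cutoff & af > cfg$hom_cutoff,
                  "hom_alt", "het")))
  warn <- (genotype == "het" & pmax(rf, af) > 0.65) |
    (genotype == "hom_ref" & (af > 0.15 | counts$n_other > counts$n_alt)) |
    (genotype == "hom_alt" & (rf > 0.15 | counts$n_other > counts$n_ref))
  flags <- mapply(function(g, w, d) {
    f <- character()
    if (g == "no_call") f <- c(f, if (d == 0L) "empty_locus" else "low_depth")
    if (w) f <- c(f, "imbalance_warning")
    paste(f, collapse = ",")
  }, genotype, warn, depth, USE.NAMES = FALSE)
  data.frame(locus_id = counts$locus_id, genotype = genotype, depth = depth,
             n_ref = counts$n_ref, n_alt = counts$n_alt,
             n_other = counts$n_other, ref_fraction = rf, alt_fraction = af,
             other_fraction = of, flags = flags, stringsAsFactors = FALSE)
}

#' Call the genotype of a single locus
#'
#' Single-row convenience wrapper around [call_genotypes()].
#'
#' @param counts One-row allele-count `data.frame`.
#' @param cfg A [pipeline_config()].
#' @return One-row genotype call `data.frame`.
#' @export
call_genotype <- function(counts, cfg = pipeline_config()) {
  call_genotypes(counts[1, , drop = FALSE], cfg)
}

#' Screen a locus for homopolymer-induced miscall risk
#'
#' Nanopore base calling mis-measures the length of homopolymer tracts,
#' producing false indels. A locus is flagged when, in either the
#' reference-allele or the alternative-allele version of its 51-nt context,
#' a run of `min_run` or more identical bases contains the SNP position
#' (26) or touches one of positions 25-27. The description names each
#' triggering run's base, length and position.
#'
#' @param locus One-row panel `data.frame` (or list with `context`,
#'   `ref_allele`, `alt_allele`).
#' @param min_run Minimum run length (default 4).
#' @return List with `flagged` (logical) and `description` (character,
#'   empty when not flagged).
#' @export
#' @examples
#' loc <- list(context = paste0(strrep("GT", 11), "AAACCCC", strrep("TG", 11)),
#'             ref_allele = "A", alt_allele = "C")
#' homopolymer_risk(loc)$flagged
homopolymer_risk <- function(locus, min_run = 4L) {
  ctx_ref <- locus$context[1]
  alt <- locus$alt_allele[1]
  ctx_alt <- paste0(substr(ctx_ref, 1, 25), alt, substr(ctx_ref, 27, 51))
  desc <- character()
  for (allele in c("ref", "alt")) {
    ctx <- if (allele == "ref") ctx_ref else ctx_alt
    r <- rle(strsplit(ctx, "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- r$lengths >= min_run & starts <= 27L & ends >= 25L
    if (any(hit))
      desc <- c(desc, sprintf("%s allele: %s-run of %d at %d-%d",
                              allele, r$values[hit], r$lengths[hit],
                              starts[hit], ends[hit]))
  }
  list(flagged = length(desc) > 0L, description = paste(desc, collapse = "; "))
}

#' Concordance with a reference genotype profile
#'
#' Counts exact genotype matches between a call set and a reference
#' profile; `no_call` always counts as discordant and is listed.
#'
#' @param calls Genotype call `data.frame` from [call_genotypes()].
#' @param reference Named character vector (locus_id -> genotype) from
#'   [load_reference_profile()].
#' @return List with `n_concordant`, `n_total`, `discordant` (locus ids).
#' @export
concordance <- function(calls, reference) {
  missing <- setdiff(calls$locus_id, names(reference))
  if (length(missing))
    stop("locus missing from reference profile: ", missing[1], call. = FALSE)
  expected <- unname(reference[calls$locus_id])
  ok <- calls$genotype == expected & calls$genotype != "no_call"
  list(n_concordant = sum(ok), n_total = nrow(calls),
       discordant = calls$locus_id[!ok])
}
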