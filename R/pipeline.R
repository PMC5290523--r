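#' Run the full genotyping pipeline
#'
#' Deterministic composition of the analysis stages: read ingestion, subread
#' excision, alignment to the SNP reference contexts, allele tabulation,
#' genotype calling with the allelic-imbalance cut-off, homopolymer risk
#' screening, per-locus statistics, and (optionally) concordance against a
#' reference profile. Stage counts are kept in the report so the analysis
#' funnel (reads, subreads, mapped subreads) is always recoverable.
#'
#' @param fastq Path to a FASTQ file, or a reads `data.frame`.
#' @param panel Path to a panel TSV, or a panel `data.frame`.
#' @param cfg A [pipeline_config()].
#' @param reference Optional path to a reference-profile TSV, or a named
#'   genotype vector, for concordance.
#' @param out_dir Optional directory; when given, `genotypes.tsv`,
#'   `genotypes.vcf`, `alignments.tsv` and `report.json` are written there.
#' @param hist_bin Read-length histogram bin width, bp.
#' @return A list of class `"nanoplex_report"`: `totals`, `locus_stats`,
#'   `summary`, `read_length_histogram`, `calls`, `concordance` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(fastq, panel, cfg = pipeline_config(),
                         reference = NULL, out_dir = NULL, hist_bin = 250L) {
  cfg <- as_config_(cfg)
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  panel <- if (is.character(panel)) load_panel(panel) else panel
  validate_panel(panel, strict = FALSE)
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)))
    reference <- load_reference_profile(reference)

  subreads <- extract_subreads(reads, panel, cfg)
  alignments <- map_subreads(subreads, panel, cfg)

  counts <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    tabulate_alleles(
      alignments[alignments$locus_id == panel$locus_id[i] &
                   alignments$status == "mapped", , drop = FALSE],
      panel[i, , drop = FALSE])
  }))
  calls <- call_genotypes(counts, cfg)
  risk <- lapply(seq_len(nrow(panel)), function(i)
    homopolymer_risk(panel[i, , drop = FALSE], cfg$homopolymer_min_run))
  flagged <- vapply(risk, `[[`, logical(1), "flagged")
  calls$flags <- ifelse(
    flagged, ifelse(nzchar(calls$flags),
                    paste0(calls$flags, ",homopolymer_risk"),
                    "homopolymer_risk"), calls$flags)
  calls$homopolymer_note <- vapply(risk, `[[`, character(1), "description")

  locus_stats <- locus_stats_(panel, subreads, alignments, calls)
  report <- structure(list(
    totals = list(n_reads = nrow(reads), n_subreads = nrow(subreads),
                  n_mapped = sum(alignments$status == "mapped")),
    locus_stats = locus_stats,
    summary = summarize_locus_stats(locus_stats),
    read_length_histogram = length_histogram_(nchar(reads$sequence),
                                              hist_bin),
    calls = calls,
    concordance = if (!is.null(reference)) concordance(calls, reference),
    config = unclass(cfg)), class = "nanoplex_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_table(calls, file.path(out_dir, "genotypes.tsv"))
    write_vcf(calls, panel, file.path(out_dir, "genotypes.vcf"))
    write.table(alignments[, setdiff(names(alignments), "quality")],
                file.path(out_dir, "alignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_run_report(report, file.path(out_dir, "report.json"))
  }
  report
}

locus_stats_ <- function(panel, subreads, alignments, calls) {
  n_extracted <- vapply(panel$locus_id, function(id)
    sum(subreads$locus_id == id), integer(1), USE.NAMES = FALSE)
  n_mapped <- vapply(panel$locus_id, function(id)
    sum(alignments$locus_id == id & alignments$status == "mapped"),
    integer(1), USE.NAMES = FALSE)
  data.frame(
    locus_id = panel$locus_id,
    n_extracted = n_extracted, n_mapped = n_mapped,
    mapping_rate = ifelse(n_extracted > 0L, n_mapped / pmax(n_extracted, 1L),
                          0),
    empty_locus = n_extracted == 0L,
    depth = calls$depth,
    ref_fraction = calls$ref_fraction, alt_fraction = calls$alt_fraction,
    other_fraction = calls$other_fraction, stringsAsFactors = FALSE)
}

# population standard deviation (divisor n), as reported in the summary
pop_sd_ <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize per-locus statistics
#'
#' Mean, population standard deviation, minimum and maximum of the
#' per-locus extracted subread counts and mapped depths, plus the mean
#' mapping rate.
#'
#' @param stats `locus_stats` `data.frame` from a pipeline report.
#' @return Named list of summary statistics.
#' @export
summarize_locus_stats <- function(stats) {
  if (nrow(stats) == 0L) stop("no locus statistics to summarize",
                              call. = FALSE)
  list(
    n_loci = nrow(stats),
    extracted_mean = mean(stats$n_extracted),
    extracted_sd = pop_sd_(stats$n_extracted),
    extracted_min = min(stats$n_extracted),
    extracted_max = max(stats$n_extracted),
    depth_mean = mean(stats$depth),
    depth_sd = pop_sd_(stats$depth),
    depth_min = min(stats$depth),
    depth_max = max(stats$depth),
    mapping_rate_mean = mean(stats$mapping_rate))
}

length_histogram_ <- function(lens, bin) {
  if (!length(lens))
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  top <- max(lens)
  breaks <- seq(0L, (top %/% bin + 1L) * bin, by = bin)
  cnt <- tabulate(findInterval(lens, breaks, left.open = TRUE),
                  nbins = length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)] + 1L,
             bin_end = breaks[-1L], count = cnt)
}

#' Write a run report as JSON
#'
#' @param report A `"nanoplex_report"` from [run_pipeline()].
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.nanoplex_report <- function(x, ...) {
  cat("nanoplex run report\n")
  cat(sprintf("  reads: %d   subreads: %d   mapped: %d\n",
              x$totals$n_reads, x$totals$n_subreads, x$totals$n_mapped))
  s <- x$summary
  cat(sprintf("  subreads/locus: mean %.1f (SD %.1f, min %d, max %d)\n",
              s$extracted_mean, s$extracted_sd, s$extracted_min,
              s$extracted_max))
  cat(sprintf("  depth/locus: mean %.1f (SD %.1f); mean mapping rate %.1f%%\n",
              s$depth_mean, s$depth_sd, 100 * s$mapping_rate_mean))
  tab <- table(factor(x$calls$genotype,
                      levels = c("hom_ref", "het", "hom_alt", "no_call")))
  cat(sprintf("  calls: %d hom_ref, %d het, %d hom_alt, %d no_call\n",
              tab["hom_ref"], tab["het"], tab["hom_alt"], tab["no_call"]))
  if (!is.null(x$concordance))
    cat(sprintf("  concordance: %d/%d%s\n", x$concordance$n_concordant,
                x$concordance$n_total,
                if (length(x$concordance$discordant))
                  paste0(" (discordant: ",
                         paste(x$concordance$discordant, collapse = ", "), ")")
                else ""))
  invisible(x)
}
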