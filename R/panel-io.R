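#' Load a SNP panel definition file
#'
#' The panel is a tab-separated file with a header row and one row per locus:
#' `locus_id`, `fwd_primer`, `rev_primer`, `context`, `ref_allele`,
#' `alt_allele`, and optionally `amplicon_length`. The context is the 51-nt
#' reference sequence with the SNP at its center (position 26, 1-based) and
#' 25 nt of flank on either side; the central base must equal `ref_allele`.
#' `rev_primer` is given as written on the amplicon's reverse strand, i.e. a
#' plus-strand amplicon reads `fwd_primer ... reverse_complement(rev_primer)`.
#' Primers must be plain A/C/G/T; IUPAC ambiguity codes are rejected.
#'
#' @param path Path to the panel TSV.
#' @param strict If `TRUE` (default) and an `amplicon_length` column is
#'   present, lengths must lie in 59-115 bp (the gel-purified amplicon range).
#' @return A `data.frame`, one row per locus, in file order.
#' @export
#' @examples
#' panel <- make_panel(simulation_config(n_loci = 2, n_hp_loci = 0, seed = 7))
#' f <- tempfile(fileext = ".tsv")
#' write_panel(panel, f)
#' load_panel(f)$locus_id
load_panel <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   stringsAsFactors = FALSE)
  required <- c("locus_id", "fwd_primer", "rev_primer", "context",
                "ref_allele", "alt_allele")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("panel file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if ("amplicon_length" %in% names(df))
    df$amplicon_length <- as.integer(df$amplicon_length)
  validate_panel(df, strict = strict)
  df
}

# Line-numbered invariant checks shared by the loader and the simulator.
validate_panel <- function(panel, strict = TRUE) {
  fail <- function(i, msg)
    stop(sprintf("panel row %d (locus '%s'): %s", i, panel$locus_id[i], msg),
         call. = FALSE)
  dup <- duplicated(panel$locus_id)
  if (any(dup)) fail(which(dup)[1], "duplicate locus_id")
  for (i in seq_len(nrow(panel))) {
    ctx <- panel$context[i]
    if (nchar(ctx) != 51L)
      fail(i, sprintf("context has length %d, expected 51", nchar(ctx)))
    if (grepl("[^ACGT]", ctx)) fail(i, "context contains non-ACGT characters")
    ref <- panel$ref_allele[i]; alt <- panel$alt_allele[i]
    if (!(ref %in% DNA_BASES)) fail(i, "ref_allele must be one of A/C/G/T")
    if (!(alt %in% DNA_BASES)) fail(i, "alt_allele must be one of A/C/G/T")
    if (ref == alt) fail(i, "ref_allele and alt_allele must differ")
    if (substr(ctx, 26, 26) != ref)
      fail(i, sprintf("context center '%s' does not equal ref_allele '%s'",
                      substr(ctx, 26, 26), ref))
    for (col in c("fwd_primer", "rev_primer")) {
      p <- panel[[col]][i]
      if (!nzchar(p)) fail(i, paste(col, "is empty"))
      if (grepl("[^ACGT]", p))
        fail(i, paste(col, "contains characters outside A/C/G/T",
                      "(IUPAC ambiguity codes are not supported)"))
    }
    if (strict && "amplicon_length" %in% names(panel)) {
      al <- panel$amplicon_length[i]
      if (!is.na(al) && (al < 59L || al > 115L))
        fail(i, sprintf("amplicon_length %d outside the 59-115 bp range", al))
    }
  }
  invisible(panel)
}

#' Write a panel definition file
#'
#' Writes the tab-separated panel format read by [load_panel()]. Extra
#' simulator bookkeeping columns are dropped.
#'
#' @param panel Panel `data.frame`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  keep <- intersect(c("locus_id", "fwd_primer", "rev_primer", "context",
                      "ref_allele", "alt_allele", "amplicon_length"),
                    names(panel))
  write.table(panel[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads standard 4-line FASTQ with Sanger Phred+33 qualities (the only
#' encoding supported; nothing is guessed). Truncated records, sequences with
#' characters outside A/C/G/T/N, and sequence/quality length disagreements
#' are errors.
#'
#' @param path Path to the FASTQ file.
#' @return A `data.frame` with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 string, same length as the sequence), in file order.
#' @seealso [write_fastq()], [phred_scores()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  validate_fastq_structure_(path)
  parsed <- tryCatch(suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path,
                                                   quality.scoring = "phred")
    list(seqs = as.character(x),
         quals = as.character(Biostrings::quality(x)),
         ids = names(x))
  }), error = function(e)
    stop("malformed FASTQ '", path, "': ", conditionMessage(e),
         call. = FALSE))
  seqs <- parsed$seqs
  quals <- parsed$quals
  ids <- parsed$ids
  if (is.null(ids)) ids <- character(length(seqs))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("FASTQ record %d ('%s'): sequence and quality lengths differ",
                 bad[1], ids[bad[1]]), call. = FALSE)
  nonacgt <- which(grepl("[^ACGTN]", seqs))
  if (length(nonacgt))
    stop(sprintf(
      "FASTQ record %d ('%s'): sequence contains characters outside A/C/G/T/N",
      nonacgt[1], ids[nonacgt[1]]), call. = FALSE)
  data.frame(read_id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

# 4-line record structure check. Needed because the delegate FASTQ parser
# does not reliably reject a quality line whose length disagrees with its
# sequence line (it can silently return a corrupt record instead).
validate_fastq_structure_ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record at line ",
         (n %/% 4L) * 4L + 1L, call. = FALSE)
  if (n == 0L) return(invisible())
  rec <- seq(1L, n, by = 4L)
  bad_hdr <- which(!startsWith(lines[rec], "@") |
                     !startsWith(lines[rec + 2L], "+"))
  if (length(bad_hdr))
    stop("malformed FASTQ '", path, "': record ", bad_hdr[1],
         " lacks the @/+ header lines", call. = FALSE)
  bad_len <- which(nchar(lines[rec + 1L]) != nchar(lines[rec + 3L]))
  if (length(bad_len))
    stop("malformed FASTQ '", path, "': record ", bad_len[1],
         " sequence and quality lengths differ", call. = FALSE)
  invisible()
}

#' Write reads to FASTQ
#'
#' @param reads `data.frame` with `read_id`, `sequence`, `quality` columns as
#'   returned by [read_fastq()] or [simulate_reads()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence and quality lengths differ", call. = FALSE)
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality Character vector of Phred+33 strings.
#' @return A list of integer vectors.
#' @export
#' @examples
#' phred_scores("IIII")[[1]]
phred_scores <- function(quality) {
  lapply(quality, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Load a reference genotype profile
#'
#' Tab-separated with header `locus_id`, `genotype`; genotypes must belong to
#' `hom_ref`, `het`, `hom_alt`.
#'
#' @param path Path to the profile TSV.
#' @return Named character vector, locus_id -> genotype.
#' @export
load_reference_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("locus_id", "genotype") %in% names(df)))
    stop("profile file must have columns locus_id and genotype", call. = FALSE)
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in reference profile", call. = FALSE)
  bad <- !df$genotype %in% c("hom_ref", "het", "hom_alt")
  if (any(bad))
    stop("invalid genotype '", df$genotype[which(bad)[1]],
         "' in reference profile (allowed: hom_ref, het, hom_alt)",
         call. = FALSE)
  setNames(df$genotype, df$locus_id)
}

#' Write a reference genotype profile
#'
#' @param genotypes Named character vector, locus_id -> genotype.
#' @param path Output path.
#' @export
write_reference_profile <- function(genotypes, path) {
  write.table(data.frame(locus_id = names(genotypes), genotype = genotypes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the genotype call table
#'
#' One TSV row per locus: genotype, depth, allele counts and fractions, and
#' the quality flags, in a deterministic column order.
#'
#' @param calls Genotype call `data.frame` from [call_genotypes()].
#' @param path Output path.
#' @export
write_genotype_table <- function(calls, path) {
  cols <- c("locus_id", "genotype", "depth", "n_ref", "n_alt", "n_other",
            "ref_fraction", "alt_fraction", "other_fraction", "flags")
  out <- calls[, cols]
  for (col in c("ref_fraction", "alt_fraction", "other_fraction"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype call table written by [write_genotype_table()]
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of calls.
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c(locus_id = "character", genotype = "character",
                                  flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Write genotype calls as VCF 4.2
#'
#' Each panel locus becomes one VCF record on its own contig (the 51-nt
#' reference context), POS 26 = the SNP. The single sample carries
#' `GT:DP:AD`; genotypes encode as `0/0`, `0/1`, `1/1` and `./.` for
#' `no_call`.
#'
#' @param calls Genotype call `data.frame` from [call_genotypes()].
#' @param panel Panel `data.frame` (defines record order and alleles).
#' @param path Output path.
#' @param sample_name Sample column name.
#' @export
write_vcf <- function(calls, panel, path, sample_name = "SAMPLE") {
  missing <- setdiff(calls$locus_id, panel$locus_id)
  if (length(missing))
    stop("call for locus absent from panel: ", missing[1], call. = FALSE)
  rows <- match(panel$locus_id, calls$locus_id)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               no_call = "./.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=nanoplex",
    sprintf("##contig=<ID=%s,length=51>", panel$locus_id),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Informative depth at the SNP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt observation counts\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")), con)
  for (i in seq_len(nrow(panel))) {
    cl <- calls[rows[i], ]
    writeLines(paste(
      panel$locus_id[i], "26", panel$locus_id[i], panel$ref_allele[i],
      panel$alt_allele[i], ".", "PASS", ".", "GT:DP:AD",
      sprintf("%s:%d:%d,%d", gt_code[[cl$genotype]], cl$depth, cl$n_ref,
              cl$n_alt),
      sep = "\t"), con)
  }
  invisible(path)
}
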