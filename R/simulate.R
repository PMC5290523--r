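#' Simulation configuration
#'
#' Describes the synthetic sequencing world: a multiplex of short SNP
#' amplicons (59-115 bp, gel-purified range), pooled and randomly ligated
#' into concatemer reads, sequenced with per-base substitution/indel errors
#' in which deletions inside a homopolymer run of length r are scaled by
#' `hp_del_multiplier * (r - 1)` — the mechanism behind nanopore's false
#' indels at homopolymer tracts. Defaults emulate a 52-locus forensic
#' multiplex read at ~625 bp concatemers (about 7 amplicons per read) with
#' error rates representative of high-quality two-directional nanopore
#' reads.
#'
#' @param n_loci Number of panel loci.
#' @param n_hp_loci Number of loci constructed with a homopolymer run
#'   adjacent to the SNP (the at-risk loci).
#' @param hp_run_length Length of the planted run (4-25).
#' @param het_prob Probability a locus's true genotype is heterozygous;
#'   the remainder splits evenly between the homozygous states.
#' @param amplicon_length_range Inclusive amplicon length range, bp.
#' @param primer_length_range Inclusive primer length range, nt.
#' @param depth Amplicon copies emitted per locus (before errors).
#' @param locus_weights Optional per-locus weights emulating representation
#'   bias; copies become `round(depth * w / mean(w))`.
#' @param mean_amplicons_per_read Mean number of ligated amplicons per read
#'   (`1 + Poisson(mean - 1)`).
#' @param p_sub,p_ins,p_del Per-base substitution/insertion/deletion
#'   probabilities.
#' @param hp_del_multiplier Homopolymer deletion scaling factor; must keep
#'   `p_del * hp_del_multiplier * hp_run_length < 1`.
#' @param orientation_prob Probability an amplicon ligates in reverse
#'   orientation.
#' @param quality_phred Constant placeholder Phred score written to FASTQ
#'   (qualities are never used for decisions).
#' @param max_primer_errors Extraction error budget the panel must tolerate:
#'   generated primers keep pairwise edit distance above twice this value.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_loci = 52L, n_hp_loci = 5L,
                              hp_run_length = 8L, het_prob = 0.5,
                              amplicon_length_range = c(59L, 115L),
                              primer_length_range = c(18L, 25L),
                              depth = 100L, locus_weights = NULL,
                              mean_amplicons_per_read = 7,
                              p_sub = 0.05, p_ins = 0.02, p_del = 0.02,
                              hp_del_multiplier = 5,
                              orientation_prob = 0.5,
                              quality_phred = 12L,
                              max_primer_errors = 3L,
                              seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci), n_hp_loci = as.integer(n_hp_loci),
              hp_run_length = as.integer(hp_run_length), het_prob = het_prob,
              amplicon_length_range = as.integer(amplicon_length_range),
              primer_length_range = as.integer(primer_length_range),
              depth = as.integer(depth), locus_weights = locus_weights,
              mean_amplicons_per_read = mean_amplicons_per_read,
              p_sub = p_sub, p_ins = p_ins, p_del = p_del,
              hp_del_multiplier = hp_del_multiplier,
              orientation_prob = orientation_prob,
              quality_phred = as.integer(quality_phred),
              max_primer_errors = as.integer(max_primer_errors),
              seed = as.integer(seed))
  if (cfg$n_loci < 1L) stop("n_loci must be >= 1", call. = FALSE)
  if (cfg$n_hp_loci < 0L || cfg$n_hp_loci > cfg$n_loci)
    stop("n_hp_loci must lie in [0, n_loci]", call. = FALSE)
  if (cfg$hp_run_length < 4L || cfg$hp_run_length > 25L)
    stop("hp_run_length must lie in [4, 25]", call. = FALSE)
  for (p in c("het_prob", "p_sub", "p_ins", "p_del", "orientation_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]", call. = FALSE)
  if (cfg$p_del * cfg$hp_del_multiplier * cfg$hp_run_length >= 1)
    stop("p_del * hp_del_multiplier * hp_run_length must stay below 1",
         call. = FALSE)
  if (cfg$amplicon_length_range[1] < 51L)
    stop("amplicons must be at least 51 bp to host the SNP context",
         call. = FALSE)
  if (diff(cfg$amplicon_length_range) < 0 || diff(cfg$primer_length_range) < 0)
    stop("length ranges must be non-decreasing", call. = FALSE)
  if (cfg$primer_length_range[1] < 10L || cfg$primer_length_range[2] > 64L)
    stop("primer lengths must lie in [10, 64]", call. = FALSE)
  if (cfg$mean_amplicons_per_read < 1)
    stop("mean_amplicons_per_read must be >= 1", call. = FALSE)
  if (!is.null(cfg$locus_weights) &&
      length(cfg$locus_weights) != cfg$n_loci)
    stop("locus_weights must have one weight per locus", call. = FALSE)
  class(cfg) <- c("simulation_config", "list")
  cfg
}

random_bases_ <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# sample() treats a scalar as 1:x; this always samples from the vector
sample1_ <- function(v) v[sample.int(length(v), 1L)]

#' Generate a synthetic SNP panel
#'
#' Draws, for each locus, a random amplicon of 59-115 bp whose ends are the
#' primers (18-25 nt) and whose SNP sits at least 25 nt from both ends so
#' the full 51-nt context exists. A configured subset of loci carries a
#' planted homopolymer run of the alternative-allele base immediately 3' of
#' the SNP (with two reference-allele bases 5' of it), the motif behind
#' real at-risk loci; the remaining loci are rejected and redrawn until
#' [homopolymer_risk()] does not flag them and the SNP's neighbours differ
#' from both alleles. All primers (and their reverse complements) keep
#' pairwise edit distance above `2 * max_primer_errors`, so approximate
#' primer matching cannot confuse loci.
#'
#' @param cfg A [simulation_config()].
#' @return Panel `data.frame` as read by [load_panel()], with simulator
#'   bookkeeping columns `amplicon_ref`, `amplicon_alt`, `snp_pos`,
#'   `is_homopolymer`.
#' @export
make_panel <- function(cfg = simulation_config()) {
  with_seed_(cfg$seed, make_panel_(cfg))
}

make_panel_ <- function(cfg) {
  n <- cfg$n_loci
  hp_idx <- if (cfg$n_hp_loci > 0L) sort(sample.int(n, cfg$n_hp_loci))
            else integer()
  sep <- 2L * cfg$max_primer_errors
  pool <- character()  # accepted primers and their reverse complements
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      L <- sample1_(seq(cfg$amplicon_length_range[1],
                        cfg$amplicon_length_range[2]))
      pl1 <- sample1_(seq(cfg$primer_length_range[1],
                          cfg$primer_length_range[2]))
      pl2 <- sample1_(seq(cfg$primer_length_range[1],
                          cfg$primer_length_range[2]))
      snp_pos <- sample1_(seq(26L, L - 25L))
      amp <- strsplit(random_bases_(L), "")[[1]]
      ref <- sample(DNA_BASES, 1L)
      alt <- sample(setdiff(DNA_BASES, ref), 1L)
      amp[snp_pos] <- ref
      if (i %in% hp_idx) {
        amp[snp_pos + seq_len(cfg$hp_run_length)] <- alt
        amp[snp_pos - (1:2)] <- ref
      } else {
        nb <- snp_pos + c(-1L, 1L)
        bad_nb <- amp[nb] %in% c(ref, alt)
        if (any(bad_nb))
          amp[nb[bad_nb]] <- vapply(which(bad_nb), function(k)
            sample(setdiff(DNA_BASES, c(ref, alt)), 1L), character(1))
      }
      ctx <- paste(amp[(snp_pos - 25L):(snp_pos + 25L)], collapse = "")
      risk <- homopolymer_risk(list(context = ctx, ref_allele = ref,
                                    alt_allele = alt))$flagged
      if (risk != (i %in% hp_idx)) next
      fwd <- paste(amp[1:pl1], collapse = "")
      rev_p <- reverse_complement(paste(amp[(L - pl2 + 1L):L], collapse = ""))
      cand <- unique(c(fwd, rev_p, reverse_complement(c(fwd, rev_p))))
      if (length(cand) < 4L) next  # palindromic primer, redraw
      if (min(utils::adist(cand)[upper.tri(diag(4))]) <= sep) next
      if (length(pool) && min(utils::adist(cand, pool)) <= sep) next
      pool <- c(pool, cand)
      amp_ref <- paste(amp, collapse = "")
      amp_alt <- paste(replace(amp, snp_pos, alt), collapse = "")
      rows[[i]] <- data.frame(
        locus_id = sprintf("snp%03d", i), fwd_primer = fwd,
        rev_primer = rev_p, context = ctx, ref_allele = ref,
        alt_allele = alt, amplicon_length = L, amplicon_ref = amp_ref,
        amplicon_alt = amp_alt, snp_pos = snp_pos,
        is_homopolymer = i %in% hp_idx, stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not satisfy the primer separation constraint for locus ",
           i, " after 500 attempts", call. = FALSE)
  }
  panel <- do.call(rbind, rows)
  validate_panel(panel)
  panel
}

#' Draw true genotypes for a panel
#'
#' Heterozygous with probability `het_prob`, otherwise homozygous for either
#' allele with equal probability; seeded from the simulation config.
#'
#' @param panel Panel `data.frame`.
#' @param cfg A [simulation_config()].
#' @return Named character vector, locus_id -> genotype.
#' @export
draw_genotypes <- function(panel, cfg = simulation_config()) {
  with_seed_(cfg$seed + 1L, {
    g <- sample(c("hom_ref", "het", "hom_alt"), nrow(panel), replace = TRUE,
                prob = c((1 - cfg$het_prob) / 2, cfg$het_prob,
                         (1 - cfg$het_prob) / 2))
    setNames(g, panel$locus_id)
  })
}

#' Simulate concatemer nanopore reads with truth bookkeeping
#'
#' Emits `depth` amplicon copies per locus (allele by fair coin for
#' heterozygous loci), flips each into reverse orientation with
#' `orientation_prob`, applies the per-base error model (substitutions,
#' insertions, and homopolymer-scaled deletions), and ligates the shuffled
#' pool into reads of `1 + Poisson(mean_amplicons_per_read - 1)` amplicons.
#' Truth records every amplicon's locus, allele, orientation, clean
#' (pre-error, forward-orientation) sequence and its span on the finished
#' read; spans tile each read exactly.
#'
#' @param panel Panel from [make_panel()] (bookkeeping columns required).
#' @param genotypes Named genotype vector, e.g. from [draw_genotypes()].
#' @param cfg A [simulation_config()].
#' @return List of class `"nanoplex_sim"`: `reads` (FASTQ-ready
#'   `data.frame`), `truth` (per-amplicon `data.frame`), `locus_counts`
#'   (per-locus emitted ref/alt amplicon counts), `genotypes`, `panel`,
#'   `config`.
#' @export
simulate_reads <- function(panel, genotypes, cfg = simulation_config()) {
  stopifnot(all(c("amplicon_ref", "amplicon_alt") %in% names(panel)))
  if (!all(panel$locus_id %in% names(genotypes)))
    stop("genotypes must cover every panel locus", call. = FALSE)
  with_seed_(cfg$seed + 2L, simulate_reads_(panel, genotypes, cfg))
}

simulate_reads_ <- function(panel, genotypes, cfg) {
  n_loci <- nrow(panel)
  copies <- if (is.null(cfg$locus_weights)) rep(cfg$depth, n_loci)
            else pmax(1L, as.integer(round(
              cfg$depth * cfg$locus_weights / mean(cfg$locus_weights))))
  locus <- rep(seq_len(n_loci), copies)
  gt <- genotypes[panel$locus_id[locus]]
  allele <- ifelse(gt == "hom_ref", "ref",
                   ifelse(gt == "hom_alt", "alt",
                          ifelse(rbinom(length(locus), 1L, 0.5) == 1L,
                                 "ref", "alt")))
  clean <- ifelse(allele == "ref", panel$amplicon_ref[locus],
                  panel$amplicon_alt[locus])
  minus <- runif(length(locus)) < cfg$orientation_prob
  oriented <- clean
  if (any(minus)) oriented[minus] <- reverse_complement(clean[minus])
  errored <- cpp_mutate_seqs(oriented, cfg$p_sub, cfg$p_ins, cfg$p_del,
                             cfg$hp_del_multiplier)
  ord <- sample.int(length(locus))
  k <- 1L + rpois(length(ord), cfg$mean_amplicons_per_read - 1)
  read_of <- rep(seq_along(k), k)[seq_along(ord)]
  read_ids <- sprintf("simread_%06d", seq_len(max(read_of)))
  elen <- nchar(errored)[ord]
  ends <- stats::ave(elen, read_of, FUN = cumsum)
  starts <- ends - elen + 1L
  truth <- data.frame(
    read_id = read_ids[read_of],
    slot = stats::ave(read_of, read_of, FUN = seq_along),
    locus_id = panel$locus_id[locus[ord]],
    allele = allele[ord],
    orientation = ifelse(minus[ord], "-", "+"),
    clean_sequence = clean[ord],
    start = starts, end = ends, stringsAsFactors = FALSE)
  seqs <- vapply(split(errored[ord], read_of), paste, character(1),
                 collapse = "")
  reads <- data.frame(
    read_id = read_ids, sequence = unname(seqs),
    quality = strrep(rawToChar(as.raw(33L + cfg$quality_phred)),
                     nchar(unname(seqs))),
    stringsAsFactors = FALSE)
  locus_counts <- data.frame(
    locus_id = panel$locus_id,
    n_ref_amplicons = vapply(seq_len(n_loci), function(i)
      sum(locus == i & allele == "ref"), integer(1)),
    n_alt_amplicons = vapply(seq_len(n_loci), function(i)
      sum(locus == i & allele == "alt"), integer(1)),
    stringsAsFactors = FALSE)
  locus_counts$n_total <- locus_counts$n_ref_amplicons +
    locus_counts$n_alt_amplicons
  structure(list(reads = reads, truth = truth, locus_counts = locus_counts,
                 genotypes = genotypes, panel = panel, config = cfg),
            class = "nanoplex_sim")
}

#' Write simulation artifacts to disk
#'
#' Writes `<prefix>.fastq`, `<prefix>.panel.tsv`, `<prefix>.truth.json` and
#' `<prefix>.profile.tsv` (the truth genotypes in reference-profile format).
#'
#' @param sim A `"nanoplex_sim"` object from [simulate_reads()].
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(fastq = paste0(prefix, ".fastq"),
             panel = paste0(prefix, ".panel.tsv"),
             truth = paste0(prefix, ".truth.json"),
             profile = paste0(prefix, ".profile.tsv"))
  write_fastq(sim$reads, paths["fastq"])
  write_panel(sim$panel, paths["panel"])
  jsonlite::write_json(list(truth = sim$truth,
                            locus_counts = sim$locus_counts),
                       paths["truth"], dataframe = "rows", digits = NA)
  write_reference_profile(sim$genotypes, paths["profile"])
  invisible(paths)
}
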