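test_that("load_panel accepts a minimal valid row and rejects invariant violations", {
  ctx <- paste0(strrep("G", 25), "A", strrep("T", 25))
  row <- data.frame(locus_id = "rs1", fwd_primer = "ACGTACGTACGTAC",
                    rev_primer = "TTGGCCAATTGGCC", context = ctx,
                    ref_allele = "A", alt_allele = "C")
  f <- tempfile(fileext = ".tsv")
  write.table(row, f, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- load_panel(f)
  expect_equal(nrow(panel), 1L)
  expect_equal(panel$locus_id, "rs1")

  variants <- list(
    list(context = substr(ctx, 1, 50), msg = "length 50"),
    list(context = paste0(strrep("G", 25), "C", strrep("T", 25)),
         msg = "does not equal ref_allele"),
    list(alt_allele = "A", msg = "must differ"),
    list(fwd_primer = "ACGTNCGTACGTAC", msg = "IUPAC"),
    list(rev_primer = "", msg = "empty"))
  for (v in variants) {
    bad <- row
    bad[[setdiff(names(v), "msg")]] <- v[[setdiff(names(v), "msg")]]
    write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(load_panel(f), v$msg)
  }

  dup <- rbind(row, row)
  write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(f), "duplicate")
})

test_that("errors name the offending panel row", {
  ctx <- paste0(strrep("G", 25), "A", strrep("T", 25))
  rows <- data.frame(locus_id = c("rs1", "rs2"),
                     fwd_primer = "ACGTACGTACGTAC",
                     rev_primer = "TTGGCCAATTGGCC",
                     context = c(ctx, substr(ctx, 1, 44)),
                     ref_allele = "A", alt_allele = "C")
  f <- tempfile(fileext = ".tsv")
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(f), "row 2 \\(locus 'rs2'\\).*length 44.*expected 51")
})

test_that("a simulator panel round-trips through the TSV format", {
  panel <- make_panel(simulation_config(n_loci = 52, n_hp_loci = 5,
                                        seed = 21))
  f <- tempfile(fileext = ".tsv")
  write_panel(panel, f)
  back <- load_panel(f)
  expect_equal(nrow(back), 52L)
  expect_false(anyDuplicated(back$locus_id) > 0)
  cols <- c("locus_id", "fwd_primer", "rev_primer", "context",
            "ref_allele", "alt_allele", "amplicon_length")
  expect_identical(back[, cols], panel[, cols], ignore_attr = TRUE)
})

test_that("FASTQ reading preserves order and enforces record consistency", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGT", "+", "IIII",
               "@b", "GGCC", "+", "!!!!",
               "@c", "ACGTN", "+", "IIIII"), f)
  reads <- read_fastq(f)
  expect_equal(reads$read_id, c("a", "b", "c"))
  expect_equal(reads$sequence, c("ACGT", "GGCC", "ACGTN"))
  expect_equal(phred_scores(reads$quality[2])[[1]], rep(0L, 4))

  writeLines(c("@a", "ACGTACGTAC", "+", "IIIIIIIII"), f)  # 10 nt vs 9 quals
  expect_error(read_fastq(f), "malformed|lengths differ")
  writeLines(c("@a", "ACGT", "+", "IIII", "@b", "ACGT"), f)  # truncated
  expect_error(read_fastq(f), "malformed")
})

test_that("simulated FASTQ round-trips byte-for-byte", {
  world <- small_sim(seed = 31, n_loci = 8, depth = 80,
                     p_sub = 0.05, p_ins = 0.02, p_del = 0.02)
  expect_gte(nrow(world$sim$reads), 400 / 8)
  f <- tempfile(fileext = ".fastq")
  write_fastq(world$sim$reads, f)
  back <- read_fastq(f)
  expect_identical(back$sequence, world$sim$reads$sequence)
  expect_identical(back$read_id, world$sim$reads$read_id)
  expect_identical(back$quality, world$sim$reads$quality)
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("genotype table and VCF encode calls deterministically", {
  panel <- make_panel(simulation_config(n_loci = 4, n_hp_loci = 0, seed = 5))
  counts <- data.frame(locus_id = panel$locus_id,
                       n_ref = c(100L, 50L, 2L, 0L),
                       n_alt = c(0L, 50L, 98L, 0L),
                       n_other = c(0L, 0L, 0L, 0L))
  calls <- call_genotypes(counts)
  expect_equal(calls$genotype, c("hom_ref", "het", "hom_alt", "no_call"))

  tsv <- tempfile(fileext = ".tsv")
  write_genotype_table(calls, tsv)
  back <- read_genotype_table(tsv)
  expect_equal(back$genotype, calls$genotype)
  expect_equal(back$depth, calls$depth)

  vcf <- tempfile(fileext = ".vcf")
  write_vcf(calls, panel, vcf)
  lines <- readLines(vcf)
  gt <- sub(":.*", "", vapply(strsplit(grep("^[^#]", lines, value = TRUE),
                                       "\t"), `[[`, character(1), 10))
  expect_equal(gt, c("0/0", "0/1", "1/1", "./."))
  expect_error(write_vcf(calls, panel[-1, ], vcf), "absent from panel")
})

test_that("VCF output round-trips through a standard VCF parser", {
  skip_if_not_installed("VariantAnnotation")
  panel <- make_panel(simulation_config(n_loci = 52, n_hp_loci = 5,
                                        seed = 13))
  counts <- with_seed(13, data.frame(
    locus_id = panel$locus_id,
    n_ref = rbinom(52, 200, 0.5), n_alt = 0L, n_other = 0L))
  counts$n_alt <- 200L - counts$n_ref
  calls <- call_genotypes(counts)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, panel, f)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(f))
  expect_equal(nrow(vcf), 52L)
  expect_equal(as.character(SummarizedExperiment::seqnames(
    SummarizedExperiment::rowRanges(vcf))), panel$locus_id)
  expect_equal(unname(as.character(
    SummarizedExperiment::rowRanges(vcf)$REF)), panel$ref_allele)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               no_call = "./.")
  expect_equal(unname(VariantAnnotation::geno(vcf)$GT[, 1]),
               unname(gt_code[calls$genotype]))
  expect_equal(unname(VariantAnnotation::geno(vcf)$DP[, 1]), calls$depth)
})

test_that("reference profiles validate and round-trip", {
  gts <- c(rs1 = "hom_ref", rs2 = "het", rs3 = "hom_alt")
  f <- tempfile(fileext = ".tsv")
  write_reference_profile(gts, f)
  expect_identical(load_reference_profile(f), gts)
  writeLines(c("locus_id\tgenotype", "rs1\thomref"), f)
  expect_error(load_reference_profile(f), "invalid genotype")
})
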