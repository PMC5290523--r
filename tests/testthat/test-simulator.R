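test_that("generated panels satisfy every declared constraint", {
  panel1 <- make_panel(simulation_config(n_loci = 1, n_hp_loci = 0,
                                         seed = 61))
  expect_equal(nrow(panel1), 1L)
  expect_equal(substr(panel1$context, 26, 26), panel1$ref_allele)

  scfg <- simulation_config(n_loci = 52, n_hp_loci = 5, seed = 62)
  panel <- make_panel(scfg)
  flagged <- vapply(seq_len(52), function(i)
    homopolymer_risk(panel[i, ])$flagged, logical(1))
  expect_equal(sum(flagged), 5L)
  expect_identical(flagged, panel$is_homopolymer)

  # brute-force pairwise separation of all primers and reverse complements
  prim <- c(panel$fwd_primer, panel$rev_primer,
            reverse_complement(panel$fwd_primer),
            reverse_complement(panel$rev_primer))
  d <- utils::adist(prim)
  expect_gt(min(d[upper.tri(d)]), 2 * scfg$max_primer_errors)

  # the amplicon really is primer + insert + revcomp(rev primer)
  expect_identical(substr(panel$amplicon_ref, 1, nchar(panel$fwd_primer)),
                   panel$fwd_primer)
  expect_identical(
    substr(panel$amplicon_ref,
           nchar(panel$amplicon_ref) - nchar(panel$rev_primer) + 1,
           nchar(panel$amplicon_ref)),
    reverse_complement(panel$rev_primer))
  expect_true(all(panel$amplicon_length >= 59 & panel$amplicon_length <= 115))
})

test_that("simulation is deterministic down to the written bytes", {
  scfg <- simulation_config(n_loci = 6, n_hp_loci = 1, depth = 25, seed = 77)
  one <- simulate_reads(make_panel(scfg), draw_genotypes(make_panel(scfg),
                                                         scfg), scfg)
  two <- simulate_reads(make_panel(scfg), draw_genotypes(make_panel(scfg),
                                                         scfg), scfg)
  expect_identical(one$reads, two$reads)
  expect_identical(one$truth, two$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_simulation(one, f1); write_simulation(two, f2)
  for (suffix in c(".fastq", ".panel.tsv", ".truth.json", ".profile.tsv"))
    expect_identical(readLines(paste0(f1, suffix)),
                     readLines(paste0(f2, suffix)))
})

test_that("error-free single-amplicon reads equal their truth exactly", {
  scfg <- simulation_config(n_loci = 4, n_hp_loci = 0, depth = 30,
                            p_sub = 0, p_ins = 0, p_del = 0,
                            mean_amplicons_per_read = 1, seed = 19)
  sim <- simulate_reads(make_panel(scfg), draw_genotypes(make_panel(scfg),
                                                         scfg), scfg)
  expect_equal(nrow(sim$reads), 120L)  # k is pinned at 1
  oriented <- ifelse(sim$truth$orientation == "-",
                     reverse_complement(sim$truth$clean_sequence),
                     sim$truth$clean_sequence)
  expect_identical(sim$reads$sequence[match(sim$truth$read_id,
                                            sim$reads$read_id)], oriented)
})

test_that("truth spans tile each read and per-locus counts add up", {
  world <- small_sim(seed = 37, n_loci = 6, depth = 40,
                     p_sub = 0.05, p_ins = 0.02, p_del = 0.02)
  truth <- world$sim$truth
  for (id in unique(truth$read_id)) {
    tr <- truth[truth$read_id == id, ]
    tr <- tr[order(tr$slot), ]
    expect_equal(tr$start[1], 1L)
    expect_equal(tr$end[nrow(tr)],
                 nchar(world$sim$reads$sequence[
                   world$sim$reads$read_id == id]))
    if (nrow(tr) > 1)
      expect_equal(tr$start[-1], tr$end[-nrow(tr)] + 1L)
  }
  agg <- table(truth$locus_id)
  expect_equal(as.integer(agg[world$sim$locus_counts$locus_id]),
               world$sim$locus_counts$n_total)
  expect_equal(sum(world$sim$locus_counts$n_total), 6L * 40L)
})

test_that("homopolymer deletions match the closed-form shortening rate", {
  # a 10-base run with p_del = 0.01 and multiplier 5: each base survives
  # independently, P(shortened) = 1 - (1 - p_del*m*(r-1))^10
  run <- strrep("A", 10)
  seq <- paste0("GCGCGT", run, "TGCGCG")
  n <- 5000
  p_eff <- 0.01 * 5 * (10 - 1)
  expected <- 1 - (1 - p_eff)^10
  out <- with_seed(101, nanoplex:::cpp_mutate_seqs(rep(seq, n), 0, 0, 0.01, 5))
  shortened <- !grepl(run, out, fixed = TRUE)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(shortened) - expected), 3 * se)
  # and with no errors the sequence is untouched
  expect_identical(unique(nanoplex:::cpp_mutate_seqs(rep(seq, 5), 0, 0, 0, 5)),
                   seq)
})

test_that("mean read length follows the concatenation arithmetic", {
  scfg <- simulation_config(n_loci = 10, n_hp_loci = 0, depth = 200,
                            p_sub = 0, p_ins = 0, p_del = 0,
                            mean_amplicons_per_read = 7, seed = 53)
  panel <- make_panel(scfg)
  sim <- simulate_reads(panel, draw_genotypes(panel, scfg), scfg)
  # 2000 amplicons; every base lands in exactly one read
  expect_equal(sum(nchar(sim$reads$sequence)),
               sum(nchar(sim$truth$clean_sequence)))
  mean_k <- nrow(sim$truth) / nrow(sim$reads)
  expect_lt(abs(mean_k - 7) / 7, 0.05)
  expect_lt(abs(mean(nchar(sim$reads$sequence)) -
                  mean_k * mean(nchar(panel$amplicon_ref))) /
              (mean_k * mean(nchar(panel$amplicon_ref))), 0.05)
})

test_that("raising the homopolymer multiplier raises the artifact dose", {
  other_frac <- vapply(c(1, 3, 5), function(m) {
    scfg <- simulation_config(n_loci = 8, n_hp_loci = 4, depth = 60,
                              hp_del_multiplier = m, seed = 88)
    panel <- make_panel(scfg)
    sim <- simulate_reads(panel, draw_genotypes(panel, scfg), scfg)
    rep <- run_pipeline(sim$reads, panel)
    mean(rep$locus_stats$other_fraction[panel$is_homopolymer])
  }, numeric(1))
  expect_true(all(diff(other_frac) > 0))
})
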