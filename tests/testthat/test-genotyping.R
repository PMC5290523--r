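test_that("allele observations are tallied with the informative-depth rule", {
  loc <- data.frame(locus_id = "rs9", context = paste0(strrep("G", 25), "A",
                                                       strrep("T", 25)),
                    ref_allele = "A", alt_allele = "C")
  aln <- data.frame(locus_id = "rs9", status = "mapped",
                    snp_observation = c("A", "A", "C", "DELETED"))
  counts <- tabulate_alleles(aln, loc)
  expect_equal(unlist(counts[, c("n_ref", "n_alt", "n_other", "depth")]),
               c(n_ref = 2, n_alt = 1, n_other = 1, depth = 4))

  # UNCOVERED drops out of depth; excluded rows are ignored
  aln2 <- rbind(aln,
                data.frame(locus_id = "rs9", status = "mapped",
                           snp_observation = "UNCOVERED"),
                data.frame(locus_id = "rs9", status = "excluded",
                           snp_observation = NA))
  expect_equal(tabulate_alleles(aln2, loc)$depth, 4L)

  empty <- tabulate_alleles(aln[0, ], loc)
  expect_equal(empty$depth, 0L)
  expect_error(
    tabulate_alleles(data.frame(locus_id = "other", status = "mapped",
                                snp_observation = "A"), loc),
    "different locus")
})

test_that("severe allelic imbalance still calls homozygous, with a warning", {
  # 75.7% / 24.3% splits at a real locus were called homozygous reference
  call <- call_genotype(data.frame(locus_id = "rs1493232", n_ref = 757,
                                   n_alt = 243, n_other = 0))
  expect_equal(call$genotype, "hom_ref")
  expect_match(call$flags, "imbalance_warning")
  expect_equal(call$ref_fraction, 0.757)

  clean <- call_genotype(data.frame(locus_id = "x", n_ref = 100, n_alt = 0,
                                    n_other = 0))
  expect_equal(clean$genotype, "hom_ref")
  expect_equal(clean$flags, "")
})

test_that("calling agrees with an independent restatement of the rule", {
  # exhaustive grid at depth 60 (the acceptance suite covers depth 200)
  grid <- expand.grid(n_ref = 0:60, n_alt = 0:60)
  grid <- grid[grid$n_ref + grid$n_alt <= 60, ]
  grid$n_other <- 60L - grid$n_ref - grid$n_alt
  grid$locus_id <- sprintf("g%05d", seq_len(nrow(grid)))
  calls <- call_genotypes(grid)
  oracle <- mapply(genotype_rule_oracle, grid$n_ref, grid$n_alt,
                   grid$n_other)
  expect_identical(calls$genotype, unname(oracle))
})

test_that("calling is scale-invariant and no_call is reachable", {
  set.seed(12)
  for (i in 1:50) {
    n <- c(sample(0:40, 2, replace = TRUE), sample(0:8, 1))
    base <- data.frame(locus_id = "s", n_ref = n[1], n_alt = n[2],
                       n_other = n[3])
    scaled <- base
    k <- sample(2:9, 1)
    scaled[, 2:4] <- scaled[, 2:4] * k
    if (sum(n) >= 20 && sum(n) * k >= 20)
      expect_identical(call_genotype(base)$genotype,
                       call_genotype(scaled)$genotype)
  }
  low <- call_genotype(data.frame(locus_id = "s", n_ref = 10, n_alt = 9,
                                  n_other = 0))
  expect_equal(low$genotype, "no_call")
  expect_match(low$flags, "low_depth")
  none <- call_genotype(data.frame(locus_id = "s", n_ref = 0, n_alt = 0,
                                   n_other = 0))
  expect_equal(none$genotype, "no_call")
  expect_match(none$flags, "empty_locus")
})

test_that("homopolymer screen flags runs touching the SNP on either allele", {
  # the AA[A/C]CCCC motif: flagged for both alleles
  ctx <- paste0(strrep("GT", 11), "TAA", "A", "CCCC", strrep("GA", 10), "G")
  expect_equal(nchar(ctx), 51L)
  expect_equal(substr(ctx, 26, 26), "A")
  risk <- homopolymer_risk(list(context = ctx, ref_allele = "A",
                                alt_allele = "C"))
  expect_true(risk$flagged)
  expect_match(risk$description, "ref allele")
  expect_match(risk$description, "alt allele")

  # a 10-base run in the flank touching the SNP
  ctx10 <- paste0(strrep("GT", 7), "C", strrep("A", 10), "C",
                  strrep("TG", 12), "T")
  expect_equal(nchar(ctx10), 51L)
  expect_equal(substr(ctx10, 26, 26), "C")
  risk10 <- homopolymer_risk(list(context = ctx10, ref_allele = "C",
                                  alt_allele = "T"))
  expect_true(risk10$flagged)
  expect_match(risk10$description, "A-run of 10")

  # no run of 4+ anywhere near the SNP: not flagged
  ctx_clean <- paste0(strrep("GT", 12), "ACA", strrep("TG", 12))
  risk_clean <- homopolymer_risk(list(context = ctx_clean, ref_allele = "C",
                                      alt_allele = "A"))
  expect_false(risk_clean$flagged)

  # a long run far from the SNP does not flag
  ctx_far <- paste0(strrep("A", 8), strrep("GT", 8), "C", "A",
                    strrep("TG", 12), "T")
  expect_equal(nchar(ctx_far), 51L)
  risk_far <- homopolymer_risk(list(context = ctx_far, ref_allele = "A",
                                    alt_allele = "C"))
  expect_false(risk_far$flagged)
})

test_that("concordance counts exact matches and lists discordances", {
  ref <- setNames(rep(c("hom_ref", "het", "hom_alt"), length.out = 52),
                  sprintf("rs%02d", 1:52))
  calls <- data.frame(locus_id = names(ref), genotype = unname(ref))
  expect_equal(concordance(calls, ref),
               list(n_concordant = 52L, n_total = 52L,
                    discordant = character()))

  calls$genotype[calls$locus_id == "rs07"] <- "het"
  one_off <- concordance(calls, ref)
  expect_equal(one_off$n_concordant, 51L)
  expect_equal(one_off$discordant, "rs07")

  calls$genotype[calls$locus_id == "rs07"] <- "no_call"
  expect_equal(concordance(calls, ref)$discordant, "rs07")
  expect_error(concordance(data.frame(locus_id = "nope", genotype = "het"),
                           ref), "missing from reference")
})
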