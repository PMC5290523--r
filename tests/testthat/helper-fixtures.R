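# Hand-built fixtures for constructed extraction/alignment cases. A toy
# locus is a plus-strand amplicon fwd_primer + insert + revcomp(rev_primer)
# with a syntactically valid (but arbitrary) 51-nt context.

toy_locus <- function(locus_id = "rs_toy",
                      fwd = "ACGGTCAGTTCAAGGCTA",
                      rev = "TGACCTGAAGTTCCGAGT",
                      insert_len = 44, ref = "A", alt = "C",
                      seed = 99) {
  insert <- with_seed(seed, random_dna(insert_len))
  amplicon <- paste0(fwd, insert, reverse_complement(rev))
  context <- paste0(strrep("G", 25), ref, strrep("T", 25))
  list(
    panel = data.frame(locus_id = locus_id, fwd_primer = fwd,
                       rev_primer = rev, context = context,
                       ref_allele = ref, alt_allele = alt,
                       stringsAsFactors = FALSE),
    amplicon = amplicon)
}

as_read <- function(sequence, read_id = "read1") {
  data.frame(read_id = read_id, sequence = sequence,
             quality = strrep("I", nchar(sequence)), stringsAsFactors = FALSE)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small ready-made simulated world shared by several tests
small_sim <- function(seed = 7, n_loci = 6, n_hp_loci = 0, depth = 40,
                      p_sub = 0, p_ins = 0, p_del = 0, ...) {
  scfg <- simulation_config(n_loci = n_loci, n_hp_loci = n_hp_loci,
                            depth = depth, p_sub = p_sub, p_ins = p_ins,
                            p_del = p_del, seed = seed, ...)
  panel <- make_panel(scfg)
  gts <- draw_genotypes(panel, scfg)
  list(cfg = scfg, panel = panel, genotypes = gts,
       sim = simulate_reads(panel, gts, scfg))
}
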