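---
title: "Genotyping forensic SNP panels from concatemer nanopore reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping forensic SNP panels from concatemer nanopore reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoplex)
```

## The analysis problem

Forensic SNP multiplexes amplify dozens of short loci (59–115 bp after gel
purification) in one reaction. Amplicons that short cannot be sequenced
directly on a nanopore device whose base caller enforces a minimum fragment
length, so the amplicons are pooled, end-polished, and blunt-ligated into
random concatemers several hundred bp long. Each sequenced read is therefore
a string of complete amplicons in random order and orientation, and the
per-locus evidence has to be recovered computationally:

1. **Subread excision.** Every locus is searched for by its two PCR primers,
   allowing up to 3 edits per primer match to absorb nanopore errors. A
   forward-primer hit is paired with the nearest compatible downstream
   reverse-primer hit; the primer-inclusive span is excised, minus-strand
   hits are reverse-complemented into locus orientation, and only subreads
   of 50–150 nt (inclusive) are kept.
2. **Mapping.** Each subread is aligned (affine-gap Smith–Waterman) against
   the 51-nt reference context of its locus — the SNP with 25 nt of flank on
   either side — in both allele versions; the better-scoring alignment is
   kept and poor alignments are excluded.
3. **Tabulation and calling.** The base aligned to the context's central
   column is tallied per locus into reference / alternative / other counts,
   and genotypes are called with an allelic-imbalance cut-off.
4. **Risk screening.** Loci whose SNP touches a homopolymer tract are
   flagged, because nanopore base calling mis-measures homopolymer lengths
   and manufactures indels there.

A seeded simulator generates panels, true genotypes, and concatemer reads
with a homopolymer-aware error model plus complete truth bookkeeping, so the
whole pipeline is testable end to end without any sequencing data.

## The calling rule

For a locus with counts $n_\mathrm{ref}$, $n_\mathrm{alt}$,
$n_\mathrm{other}$ and informative depth
$d = n_\mathrm{ref}+n_\mathrm{alt}+n_\mathrm{other}$, with fractions
$f_\bullet = n_\bullet/d$:

* $d < d_\min$ (default 20) → `no_call`;
* $f_\mathrm{ref} > c$ (default $c = 0.75$) → `hom_ref`;
* $f_\mathrm{ref} < 1 - c$ **and** $f_\mathrm{alt} > c$ → `hom_alt`;
* otherwise → `het`.

`other` observations (a third base, `N`, or a deletion spanning the SNP
column) stay in the denominator: they are genuine reads of the locus that
failed to show either allele, and at homopolymer loci they are exactly the
signal that makes a call suspect. Alignments that never reach the SNP
column (`UNCOVERED`) carry no allele information and are excluded from
depth.

Design points that the protocol left open, decided here once:

* **Lower heterozygote bound.** The published rule states only the $>75\%$
  homozygote cut-off; the lower bound is taken as its symmetric complement
  ($0.25$). Both are `pipeline_config()` knobs.
* **`hom_alt` needs both conditions.** A wording like ">75 % reference →
  homozygous" does not distinguish "<25 % reference" from ">75 %
  alternative" for the alternative homozygote (they differ only when
  `other` is large). We require both, the conservative reading: a locus
  with 20 % ref / 50 % alt / 30 % other is *het* (and warned), not
  `hom_alt`.
* **Imbalance warning.** A heterozygote whose major allele exceeds 0.65, or
  a homozygote whose minor informative allele exceeds 0.15 (or whose
  residual reads are mostly neither allele), keeps its call but is flagged
  `imbalance_warning` — mirroring how a 75.7 % / 24.3 % locus is still
  called homozygous but is plainly abnormal.
* **Minimum depth.** Real runs have thousands of reads per locus and the
  protocol never states a floor, but a `no_call` state must be reachable
  for empty or failed loci; 20 informative observations is the default
  floor, far below any usable sequencing run yet enough that the
  imbalance fractions are meaningful.

## Subread excision

Primer matching uses Myers' bit-parallel algorithm for edit distance
(substitutions + indels), the permissive reading of "mismatches"
appropriate for indel-rich nanopore reads; a substitutions-only Hamming
mode is available as `primer_match_mode = "substitution"`. Overlapping
candidate matches collapse to the local best (fewest edits, then leftmost).
Matches may not span read boundaries; a primer straddling a ligation
junction is not found, which costs at most the two flanking amplicons of a
junction.

Pairing and conflict resolution: every forward-primer hit is paired with
the nearest downstream reverse-primer hit that yields a span within the
length filter; the same machinery runs on the reverse strand via the
reverse-complemented patterns. Competing overlapping excisions are then
admitted by **total primer edit count first, then leftmost start**, and a
read base belongs to at most one subread. The edits-first priority matters:
a chance 3-edit primer match inside an insert can never displace an exact
amplicon match, which is what makes extracted counts equal the simulator's
truth counts exactly on error-free data. Length bounds are inclusive;
subreads include their primers (the gel-purified 59–115 bp amplicons are
primer-inclusive, and a 50-nt floor applied to inserts alone would reject
most loci).

## Mapping and exclusion

The local aligner scores match $+1$, mismatch $-1$, and a gap of length
$L$ at $-(2 + L)$ (open $-2$, extend $-1$); all four are configurable.
Tie-breaking is deterministic: ungapped moves are preferred during
traceback, and among equal-scoring end cells the alignment ending earliest
on the reference wins.

A subread is supposed to contain its whole 51-nt context, so the exclusion
metric counts context columns the alignment fails to cover as errors:

$$\frac{\text{mismatches} + \text{indels} + (51 - \text{covered columns})}{51} > t$$

excludes the subread as `high_mismatch` ($t$ = `max_map_mismatch_frac`,
default 0.30). Normalizing by covered columns alone would let random
sequence through: the best local alignment of a random 100-mer against a
51-nt context is typically a 12–18-nt high-identity island whose local
mismatch ratio is far below any sane threshold. With the covered-column
term, random sequence is reliably excluded while genuine subreads — which
cover the context nearly fully even at nanopore error rates — are
unaffected. The default 0.30 tolerates roughly one error in four over the
context, well above two-directional nanopore read error rates, while
rejecting junk; the qualitative pipeline behaviour is stable for
thresholds in 0.2–0.4.

A cross-locus uniqueness screen (`cross_locus_check`) can additionally
require the assigned locus to out-score every other context by a margin
(default 2); it is off by default because extraction already assigns loci
by primer, and the simulator builds panels whose primers are mutually
separated by more than twice the edit budget.

## Homopolymer risk screen

A locus is flagged when a run of `homopolymer_min_run` (default 4, "four
or more bases") identical bases contains the SNP position or touches the
SNP or either neighbour, evaluated on both allele versions of the context.
The motif behind real failures is a SNP sitting between or inside runs of
its own two alleles (e.g. `AA[A/C]CCCC`): length errors in the run then
surface exactly at the SNP column as spurious deletions or shifted bases,
inflating the `other` fraction and skewing the allele balance. The screen
is sequence-based and conservative: it flags vulnerability, it does not
adjudicate calls.

## The simulator's stated world

Defaults describe the emulated experiment once; they are not tuned per
test:

| parameter | default | rationale |
|---|---|---|
| `n_loci`, `n_hp_loci` | 52, 5 | a 52-plex in which 5 loci carry the risky homopolymer motif, the observed shape of the real panel |
| `amplicon_length_range` | 59–115 bp | the gel-purified amplicon range |
| `primer_length_range` | 18–25 nt | typical multiplex PCR primers |
| `mean_amplicons_per_read` | 7 | ~625 bp mean reads over ~87 bp mean amplicons |
| `depth` | 100 | amplicon copies per locus; desk-scale stand-in for the ~10^4 of a real run |
| `p_sub`, `p_ins`, `p_del` | 0.05, 0.02, 0.02 | representative of legacy two-directional nanopore reads (~9 % total) |
| `hp_del_multiplier` | 5 | deletion probability inside a run of length $r$ scales by $5(r-1)$ |
| `hp_run_length` | 8 | planted run length at risky loci, inside the observed 4–10 range |
| `orientation_prob` | 0.5 | blunt ligation has no strand preference |
| `quality_phred` | 12 | constant placeholder; qualities are never used for decisions |

Panels are drawn so that all primers (and their reverse complements) keep
pairwise edit distance above twice the primer error budget, making
extraction unambiguous by construction; risky loci get the planted
`ref,ref,[SNP],alt-run` motif, clean loci are redrawn until the risk screen
does not fire and the SNP's neighbours differ from both alleles (emulating
marker selection that avoids homopolymer contexts). True genotypes are
heterozygous with probability 0.5. Errors are applied per base,
independently, with deletions scaled inside homopolymer runs — the
simplest model that reproduces the qualitative artifact (false indels at
runs ≥ 4). Reads are otherwise clean concatemers: no junction-spanning
homopolymers, no chimeras, no signal-level effects, no quality-by-position
structure. A green end-to-end test therefore establishes that the
*pipeline logic* recovers what the stated world contains; it says nothing
about base-caller behaviour on real signal.

Two test-suite readings of this world are worth recording. The noisy
recovery and downsampling-stability checks run with `hp_del_multiplier =
1` (the baseline per-base model): those checks are about recovery and
sampling stability with homopolymer effects removed, and the multiplier
applied to the runs of 2–3 bases ubiquitous in random sequence would
otherwise dominate them; the multiplier is exercised by the dedicated
homopolymer checks. The downsampling check simulates 5 000 emitted copies
per locus rather than 10 000 to stay inside the test-time budget — the
1/100 subsample then still carries ≈ 40 informative observations per
locus, twice the call floor, so the genotype table must reproduce exactly.

## Numerical and convention choices

* Coordinates are 1-based and inclusive throughout (the R/Bioconductor
  convention); VCF positions are 1-based per that standard.
* FASTQ qualities are fixed Phred+33; nothing is guessed. A light
  structural pass validates the 4-line records before parsing, because the
  delegate parser does not reliably reject quality/sequence length
  disagreements.
* Genotype vocabulary is closed: `hom_ref`, `het`, `hom_alt`, `no_call`.
* Summary SDs are population SDs (divisor $n$); the read-length histogram
  uses 250-bp bins; both stated in the report.
* The empty locus is defined everywhere: mapping rate 0 with an
  `empty_locus` flag, depth 0 → `no_call`.
* Determinism: identical inputs and configuration produce byte-identical
  outputs; all randomness (downsampling, simulation) is seeded explicitly,
  and seeded helpers restore the caller's RNG state.

## Limitations

* The aligner is exhaustive Smith–Waterman over 51-nt contexts — exact and
  fast at panel scale, but not a read mapper; there is no indexing, no
  paired scoring against off-target genomic sequence, and no mapping
  quality.
* The exclusion threshold stands in for a read mapper's internal
  behaviour; the real experiment's exact exclusion rule is not recoverable
  and is declared here rather than inferred.
* Homopolymer risk is screened from sequence alone; a flagged locus is not
  automatically mis-called, and an unflagged locus is not guaranteed safe.
* Mixtures (multi-contributor samples), genotype likelihood models, and
  population-genetics match statistics are out of scope.
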