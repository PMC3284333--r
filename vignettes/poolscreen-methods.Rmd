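---
title: "Pooled-progeny mutation screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-progeny mutation screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

`poolscreen` implements a bulked-segregant screen for haploid fungal
progeny. A mutant is crossed, progeny are selected for the mutant
phenotype, and DNA from `n` single-spore isolates (default 40) is pooled
and sequenced. The genetics that the screen exploits is simple:

* the **causative** allele was selected for, so it is carried by all `n`
  isolates — its pooled allele frequency is 1.0;
* every **unlinked background** mutation segregates 1:1 through meiosis, so
  its carrier count is `Binomial(n, 1/2)` — pooled frequency ≈ 0.5;
* a **reference-assembly error** looks like a variant in *every* sequenced
  pool, including a re-sequenced wild type.

At the read level, "penetrance" of a site in a pool is the fraction of
covering reads carrying the variant allele. Classification of each site
across pools:

1. fully penetrant, with sufficient coverage, in **all** pools →
   `reference_error`;
2. fully penetrant exactly in the sample set expected for one lineage
   (where the design fixes that lineage), with at most `absence_max_alt`
   variant reads in every other covered pool → `pattern_candidate`;
3. pattern matches but a pattern pool fails the coverage rule →
   `low_coverage`; a pool that must lack the variant has no usable depth →
   `inconsistent` (absence cannot be asserted — the source publications do
   not state how uncovered positions were treated, so we refuse to assert);
4. variant present but sub-penetrant anywhere → `partial_penetrance`
   (segregating background or sequencing error);
5. anything else → `inconsistent`.

Sites are restricted to SNPs and indels of <4 bases; longer events belong
to the structural screen. Indels are left-aligned inside repeat context
before cross-pool merging so that identical events share one key (the
underlying reports are silent on normalization; without it the same
deletion called at different offsets in different pools would never match).
Depth at a deletion site includes the deletion-supporting reads themselves:
they cover the site even though they leave no base at it.

# Tunable parameters

All screen constants live in `screen_config()`:

| parameter | default | meaning |
|---|---|---|
| `coverage_fraction` | 0.4 | per-pool depth required, as a fraction of that pool's mean coverage |
| `penetrance_min` | 1.0 | minimum alt fraction counted as "full penetrance" |
| `absence_max_alt` | 0 | alt reads tolerated in a pool that must lack the variant |
| `min_absent_depth` | 1 | depth needed before a pool can assert absence |
| `homopolymer_min_run` | 3 | run length flagging 1-base indels as homopolymer-artifact suspects |
| `strict_all_samples` | FALSE | apply the coverage rule to all pools at the site, not only pattern pools |

The defaults are the literal published rules (40% of mean coverage, 100%
penetrance, zero reads elsewhere). **For error-prone reads they are too
literal**: with per-base substitution error `e` and depth `d`, the chance
that at least one read at a true causative site carries an error *at that
site* is `1-(1-e)^d` (≈ 22% at `e = 0.005`, `d = 50`), which breaks exact
1.0 penetrance; likewise a non-pattern pool shows ≥1 matching error read
with probability ≈ `d·e/3` (≈ 8%). The bundled simulated-study
configuration therefore uses `penetrance_min = 0.9` and
`absence_max_alt = 2`, chosen from this closed-form error analysis, not
fitted: both thresholds sit many binomial standard deviations away from
the segregating regime (frequency ≈ 0.5 at 40 isolates), so the
fixed/segregating separation is untouched. With clean reads the defaults
apply unchanged.

Mean coverage is computed over positions with depth ≥ 1 rather than the
whole genome: under incomplete mapping this matches "average coverage for
that sample" as a property of the sequenced, mappable fraction. It is a
deliberate, configurable choice (`mean_coverage(covered_only = FALSE)`).

# The simulator: what it emulates, and what it does not

`study_scenario()` builds the full study: a uniform-random genome (default
2 Mb — a deliberately small stand-in for a ~40-Mb fungal assembly), two
synthetic genes (one plus-strand two-intron gene for the splice-donor
lesion, one minus-strand gene whose `TGA` stop hosts the stop-loss lesion),
three lineages with EMS-style backgrounds (90% transitions, 10% sub-4-base
indels, 40 per lineage), and four pools wired like the published crossing
scheme. The pool design distinguishes four per-(pool, lineage) states:
`fixed`, `segregating`, `absent` (phenotype counter-selected: causative
absent, background still segregating — the wild-type pools) and `none`
(lineage never entered this cross). A three-state design cannot express a
wild-type pool, which is why `none` exists.

Reads: fragments of `Normal(2000, 200)` bases drawn uniformly across
isolate haplotypes, 76-base mates read inward from both ends,
substitution errors i.i.d. per base, and independent `N` injection
(default 0.001) whose only purpose is to exercise the read-cleaning stage.
Read names carry the true origin for oracle checks, and identical seeds
give byte-identical FASTQ.

Deliberately **not** modelled: linkage (no genetic map exists for the
organism; loci segregate independently, so the simulator cannot produce
the elevated background-allele frequencies that loci linked to the
causative site would show in real data), diploidy, base-quality profiles,
indel sequencing errors, PCR duplicates and jumping-library chimeras.
Passing tests therefore demonstrate the logic of the screen under the
stated error model, not robustness to every artifact of real libraries —
for real data the SAM import path and the relaxation knobs are the
intended entry points.

# Mapping

The internal mapper is a seed-and-extend, **ungapped**, unique-best
placer: exact 20-mer seeds at staggered offsets (pigeonhole guarantees a
clean seed for ≤3 mismatches on 76-base reads), XOR/popcount extension
over the 2-bit-packed reference, and rejection of any read whose best
mismatch count is attained at two or more placements. It exists so the
whole pipeline runs self-contained at desk scale; it is not a BWA
replacement. Two documented consequences:

* reads spanning small indels either fail placement or map with mismatch
  tails, so indel evidence from the internal mapper is indirect — gapped
  CIGARs from `import_sam()` are the first-class indel evidence path;
* multi-mapping reads are discarded rather than randomly placed, which is
  the conservative choice for a penetrance screen.

# Structural screen

Two detectors, by design complementary:

* `find_uncovered_regions()` reports maximal zero-depth runs (≥ 500 b by
  default, sub-50-b islands merged) in one pool that every other pool
  covers at ≥ 5×. Defaults were chosen so that a 1.1-kb event is safely
  detected while random coverage holes at ~40× are essentially impossible
  (`P(depth 0) ≈ e^-40` per position). Regions uncovered in all pools are
  unsequenceable, not deletions, and are never reported.
* `insert_size_anomalies()` bins properly-oriented pairs by leftmost
  coordinate into genomic windows about one library insert wide (minimum
  50 pairs) and flags windows whose **median** insert deviates from the
  library expectation by more than `6·sd/sqrt(n)` *and* by at least
  `min_shift` bases (default 2.5 library standard deviations, i.e. 500 b
  with the default library). The second floor is an event-size threshold,
  the insert-space analogue of the gap scan's `min_len`: with hundreds of
  pairs per window the standard error is a dozen bases, and without a
  floor the detector would report median shifts far below the kilobase
  event scale the screen targets — exactly the 100-300-b shifts that
  duplication edges induce (see below).

The window geometry is load-bearing. A true deletion shifts essentially
every pair that starts within one insert upstream of it, so insert-sized
windows are homogeneous (+deleted-length) and flag strongly. A *balanced
replacement* — the deleted interval occupied by duplicated copies of the
immediate flanks — scatters only the mates that land inside the copies,
and only by the copy-to-source distance; inside an insert-sized window
those are a minority in both directions, the median stays put, and no
call is made, while the coverage-gap detector still sees the deleted
interval. Quantitatively: the copy-landing mates are a ~40% minority of
an insert-sized window with shifts of roughly the copy-to-source
distances (hundreds of bases, both signs), which drags the window median
by only ~150-300 b — below `min_shift` — whereas a true kilobase deletion
moves ~90% of a window's pairs by the full deleted length. Same-strand
pairs (inverted-copy mates, chimeras) are dropped before binning; this is
orientation-dialect-agnostic since both paired-end and mate-pair
chemistry map mates to opposite strands. With narrow fixed-count windows
instead, the copy-mate clusters dominate whole windows and the balanced
lesion is flagged — that is why windows are insert-sized.

# Consequence annotation

Gene models are CDS exon chains (GFF3 in/out); introns are the gaps, with
the canonical `GT..AG` check a warning, not an error. Splice windows are
the first/last two intron bases. `splice_defect_transcripts()` emits the
intron-retention transcript and, when a cryptic donor coordinate is given
(cryptic donors are established experimentally, never predicted), the
cryptic-splice transcript; both are translated to locate premature stops
and the divergence point from the wild-type peptide.
`stop_loss_extension()` walks in-frame codons from the mutated stop to the
next in-frame stop; by the default `inclusive` convention the residue
encoded by the mutated stop codon counts and the new terminal stop does
not (`exclusive` differs by exactly 1 — the convention behind published
extension lengths is not stated, so both are available). The standard
nuclear code is assumed throughout.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based only at
  the SAM/VCF/GFF boundaries.
* Error injection draws a `Binomial(L, rate)` count and distinct uniform
  positions, which is exactly an i.i.d. per-base Bernoulli field.
* A read shorter than the seed length is unmapped, not an error; zero
  cleaned reads yield a zero summary row; an empty reference is an input
  error.
* Classification ties cannot occur: the rule order (reference error →
  pattern match → low coverage → partial penetrance → inconsistent) is a
  partition.
* Two lineages with identical expected patterns are a configuration error
  (their candidates would be indistinguishable).

# Validation scale

The packaged validation suites run the full screen at a 2-Mb genome,
four pools, 50× coverage and 0.5% error across ten seeded replicates,
the structural scenarios at 200-300 kb and 40×, and the oracle
equivalence checks (brute-force pileup recount, independent in-frame stop
scan, closed-form read-drop rate) at ≤50-kb instances. These sizes were
chosen as the smallest at which every rule of the screen — the 40%
coverage rule, penetrance separation at 40 isolates, gap/insert
complementarity — operates in its intended regime.

# Known limitations

* No linkage: real progeny show allele-frequency gradients around the
  causative locus; the screen does not use (and the simulator does not
  produce) them.
* The ungapped internal mapper under-detects planted indels at low
  coverage; import externally mapped SAM for indel-sensitive work.
* Balanced replacements built from *distant* template sequence would be
  insert-detectable (the copy-mates would map far away); only flank-copy
  replacements are insert-silent, matching the lesion type that motivated
  the complementarity design.
* The VCF-like output is a faithful column layout, not a validated VCF
  4.x file.
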