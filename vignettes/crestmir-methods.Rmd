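---
title: "crestmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crestmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crestmir` is a small RNA-seq analysis pipeline for profiling microRNAs in
embryonic explant experiments of the kind used to compare *Xenopus laevis*
neural crest (NC), neural, ectoderm and blastula tissue: twelve libraries
(three replicates of four tissue types) built with high-definition (HD)
adapters, sequenced with adapter run-through, and analysed by exact genome
mapping and homology-based hairpin annotation. Every stage is exercised on
synthetic data with planted ground truth, so the package also contains a
first-class simulator. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

# The synthetic data generator

`sim_config()` + `generate_genome()` + `simulate_library()` emulate the
statistical structure the analysis stages assume:

* **Read structure.** Each read is `[4 degenerate nt][insert]
  [4 degenerate nt][3' adapter starting TGGAATTC]`, truncated to a fixed
  50-nt read length. Real HiSeq small RNA runs read through the adapter;
  fixing 50 nt forces the trimmer to cut mid-read. The published protocol
  does not state the read length, so it is a configurable assumption.
* **Insert length structure.** miRNA arms are 23 nt (plus isomiR end
  offsets); the background class is drawn around 29 nt (clamped 25-33).
  This reproduces the bimodal redundant-read size distribution with modes
  at 23 and 29 nt, and a background-dominated (unimodal, 29-nt) blastula
  profile via a per-tissue background fraction (default 0.45/0.45/0.40
  for NC/neural/ectoderm and 0.80 for blastula).
* **Hairpin loci.** Each planted precursor is
  `flank(5) + arm5(23) + loop(15) + revcomp(arm5) with 2 transition
  substitutions + flank(5)` (71 nt; all lengths configurable). Transitions
  keep maximum-pairing folds stable while exercising the mismatch
  tolerance of the homology search. Arms containing the adapter octamer
  are resampled at generation time, because such inserts are unrecoverable
  by construction of the trimming chemistry -- chance octamer occurrences
  in background reads remain and are what the 99.9% trimming-recovery
  bound accounts for.
* **The tandem repeat.** One region of `repeat_copies` x 1.2 kb identical
  units, each carrying five isoform hairpins of a single family
  (`mir-427`), mirrors the genomic organisation that makes the dominant
  embryonic miRNA family massively multi-mapping. Desk-scale genomes host
  5 copies rather than hundreds; the multi-mapping structure (every read
  hits every copy) is preserved.
* **Expression model.** Per library, each hairpin's insert count is
  negative binomial with `var = m + alpha * m^2` (default
  `alpha = 0.1`), the same parameterisation the DE module fits, so
  parameter recovery is well-posed. The repeat family receives 67% of
  miRNA reads (74% in blastula); the ten most abundant known hairpins
  share 80% of the known non-repeat pool; remaining known and novel loci
  split the rest evenly. Planted differential expression multiplies a
  hairpin's tissue mean by `2^log2fc`; the defaults plant three NC-only
  effects, one NC+blastula shared effect and one neural effect on
  low-abundance hairpins, where a 4-fold change distorts the family
  fractions least.
* **Arm switching.** Each hairpin has a dominant arm (5p fraction 0.85 or
  0.15, chosen at genome generation); `arm_switch_spec` overrides this
  per tissue. The default plants the classic pattern on repeat isoform A:
  5p fraction 0.90 in blastula, 0.05 elsewhere.
* **isomiRs.** End offsets are drawn from an explicit distribution
  (default: canonical 0.70, 5' end +-1 at 0.06 each, 3' end +-1 at 0.09
  each), dominated by 5'-end variation. The canonical form has majority
  probability so that reference-arm assignment by most-abundant-read is
  identifiable, and the modal 5' end carries ~0.88 of arm reads so that
  genuine loci pass the novel predictor's 5'-homogeneity gate.
* **29-nt cluster locus and gene models.** A recorded 2-kb interval
  contributes 5% of background reads; the rest fall uniformly. Five
  3-exon genes on both strands provide the exon/intron annotation for the
  degradation and intron checks.

What the generator does **not** emulate: sequencing errors, quality-score
structure, ligation bias (only the HD read structure is modelled), 1U
bias of the planted cluster reads, and real genome repeat content beyond
the single planted tandem array. Passing tests therefore certify the
pipeline's algorithmic behaviour under the stated statistical model, not
its robustness to base-calling artefacts.

# Trimming and collapsing

The 3' adapter is located by a perfect match to its first 8 nt
(`TGGAATTC`); the leftmost occurrence wins, the conservative standard for
3' adapters. The 4-nt HD signatures are then removed from both ends of
the pre-adapter remainder, and inserts of 16-35 nt (closed interval) are
kept. Reads are discarded, with a per-library audited reason, when no
octamer occurs, when the remainder is shorter than `2*hd_len + 1` (no
insert base can exist), or when the insert contains an N -- downstream
mapping is exact, so Ns can never match. The audit satisfies exact
conservation: raw = kept + sum of discard reasons. Mature miRNAs printed
as RNA are normalised to DNA (U -> T) on input.

# Exact mapping

Mapping is exact, full-length, both strands, all loci reported (no
multi-hit cap: the repeat family is the central multi-mapping object).
The implementation hashes every 16-nt genome window (16 nt is the
minimum kept insert length) and verifies candidates by direct substring
comparison, so its correctness reduces to the hash lookup being
exhaustive; the test suite checks hit-set equality against a
position-by-position scan on random instances. Size-class profiles are
scaled to reads per million genome-matched reads (RPM); per-library
totals of genome-matched reads are the only normalisation denominator
used anywhere.

# Hairpin annotation ladder

Known-precursor queries are searched with a seed-and-extend local
aligner: exact 11-nt word seeds nominate candidate windows, which are
aligned gapped (match +1, mismatch -2, gap open -5, gap extend -2, via
`Biostrings::pairwiseAlignment`). E-values use the Karlin-Altschul form
`E = K m n exp(-lambda S)` with `n` twice the genome length (both
strands); `lambda` and `K` are fitted once per session by the method of
moments on simulated maximal local scores of random uniform-composition
sequences (the composition of shuffled queries), under a fixed internal
seed. Hits with `E < 1e-06` survive. Because a stem-loop is nearly its
own reverse complement, the same locus is frequently hit on both
strands; loci are deduplicated strand-agnostically with the best
E-value deciding the annotated strand.

The filter ladder then drops every hit of any query with >= 30 hits,
and every hit whose hairpin interval (the aligned interval extended
symmetrically to the query length) is <= 55 nt. Both filters are
evaluated on the input hit set, so they commute. Candidates are folded
and validated (below), read counts are attached, and hairpins with
< 100 reads summed over all samples are removed unless another member
of their family passes (family rescue). Finally each arm's reference
mature is the most abundant read fully contained on that side of the
terminal loop, ties resolved lexicographically.

The published analysis curated hairpin structures manually; the
automated criteria here are an explicit, testable stand-in, not a
reproduction of that curation.

# Folding and hairpin validation

Structures come from a Nussinov maximum base-pairing dynamic program
(Rcpp) with minimum loop 3 and G:U wobble allowed, deterministic
traceback (5' base pairs its smallest admissible partner). Maximum
pairing replaces thermodynamic folding deliberately: the validation
question -- "is this a single dominant stem-loop?" -- needs a
deterministic, dependency-free structure, not free energies.

Validation passes when (a) at least 40% of bases are paired, (b) among
stems carrying >= 4 pairs exactly one is innermost (one terminal loop;
small incidental helices do not count as branches), and (c) the dominant
stem carries >= 15 pairs. Stems are maximal runs of pairs advancing by
<= 3 nt on both sides, which absorbs the bulges created by the planted
transition mismatches.

# isomiR quantification and arm switching

Reads are assigned to the arm they overlap, provided they do not reach
into the opposite arm; reads touching both arms span the loop and count
for neither. Strict containment between fold-derived loop boundaries was
rejected during development: maximum-pairing loop boundaries wobble by a
few nucleotides, which silently discarded canonical matures. isomiR
offsets are signed end shifts relative to the reference mature in
precursor coordinates, capped at +-5.

Multi-mapping reads contribute their full count to every containing
hairpin (configurable fractional alternative), which matches per-hairpin
tallies of a tandem repeat family; family-level *fractions* are instead
computed read-level (each read once per family) so the repeat family's
share of miRNA reads is not inflated by its copy number.

Arm switching between two tissues is called when the replicate-mean 5p
ratio is >= 0.7 in one tissue and <= 0.3 in the other, with libraries
below 50 arm reads excluded; the thresholds are conventions (the
phenomenon is qualitative) and configurable.

# Differential expression

Size factors are median-of-ratios over all-positive rows. Each hairpin
is tested with an NB GLM (log link, group indicator, log size factors as
offsets) and a Wald z on the group coefficient at `padj < 0.01` after
Benjamini-Hochberg adjustment (`stats::p.adjust`).

The dispersion estimator deserves its own paragraph. A per-row
method-of-moments estimate with three replicates per group is so noisy
that any fixed-weight shrinkage toward the across-row centre leaves the
Wald statistic with heavy, t-like tails: in development, a 50/50 shrink
produced visibly non-uniform null p-values (2.5% of null rows below
p = 0.01). The shipped estimator instead calibrates itself by parametric
bootstrap: rows are simulated under the common dispersion at the
observed row means (fixed internal seed; the caller's RNG state is
restored), giving (i) a small-sample bias correction for the centre and
(ii) the sampling spread of the per-row estimator. The shrinkage weight
is the excess of the observed spread over that sampling spread (with a
1.2x deadband absorbing noise), so homogeneous-dispersion data shrink
fully to the bias-corrected common value and heterogeneous data retain
per-row signal. On the package's benchmarks this yields null p-values
that pass a Kolmogorov-Smirnov uniformity check, observed FDR ~ 0.013
at `padj < 0.01`, and power ~ 0.97 for 4-fold changes at means >= 100
with three replicates -- operating characteristics comparable to
DESeq2's on the same data.

One compositional property is worth knowing. Median-of-ratios size
factors anchor on the median row, and in this design the repeat family's
copies are the majority of rows; since that family's share of miRNA
reads differs between tissues (67% vs 74% in blastula) and the
background fraction differs too, normalisation effectively re-expresses
every other hairpin relative to the repeat family's profile. A planted
4-fold shared NC/blastula effect therefore appears as roughly a 2.8-fold
normalised change in the blastula-versus-ectoderm contrast, and its
recovery at `padj < 0.01` with three replicates is borderline —
seed-dependent at desk-scale depths. This is the honest behaviour of
compositional count normalisation under a dominant multi-copy family,
the same situation the real miR-427 family creates.

Enrichment sets use every-pairwise logic: a hairpin is focal-tissue
enriched when significantly up against each other tissue separately
(not against a pooled rest group, which would let one strong contrast
mask another); the shared NC/blastula set requires both tissues up
against neural and ectoderm and no NC-blastula difference.

# Novel miRNA prediction

Candidate stacks are clusters (gap <= 3 nt) of same-strand loci of
Dicer-sized reads (16-24 nt -- the size gate also keeps the ~29-nt
background class out of stack building), with >= 10 reads, span
<= 40 nt, and 5'-homogeneity >= 0.8. For each stack, candidate
precursors of 60-200 nt are excised anchored at the stack with the
opposite (star) flank on either side, folded, and validated; anchoring
matters, because maximum pairing over long random flanks fragments the
true stem into branched structures that fail validation, while the
excised precursor folds cleanly. Among passing windows containing the
dominant read inside one stem arm (+-4 nt slack for the fuzzy
maximum-pairing arm boundaries), the longest hairpin wins, ties to the
higher paired fraction. Star support is flagged for opposite-arm reads
whose duplex with the mature shows the Dicer-typical 2-nt 3' overhang
(+-1 nt). Predictions group by single linkage: identical matures, or
same-strand mature loci with both end offsets <= 2 nt.

# The 29-nt class

Cluster detection merges 25-33 nt read loci across strands with gaps
<= 500 nt, trims loosely attached terminal reads (> 100 nt from the
body), and keeps intervals with >= 50 reads AND read density >= 3x the
genome-wide density of same-length reads. The density criterion is what
makes this a cluster finder rather than a coverage segmenter: on a
desk-scale genome saturated with uniform 29-nt background no interval
is denser than background and no cluster is called -- which is itself
the biologically expected answer when the long-RNA class is not
genomically clustered. Reported cluster statistics (majority-strand
bias, 1U fraction, mean length) are descriptive piRNA signatures.

Degradation and intron checks compare the count-weighted fraction of
29-nt reads overlapping exons (or introns) against all other lengths
with a one-sided two-proportion z test; any-overlap (>= 1 nt,
strand-agnostic) is the simplest testable convention. The null
calibration of this test (uniform placement stays non-significant) is
part of the acceptance suite, because the scientific conclusion it
supports is a negative finding.

# Problem sizes and determinism

Default test and acceptance problem sizes: the main synthetic study is
4 tissues x 3 replicates; unit tests run at a few thousand reads per
library, the property checks at 1e5, and the end-to-end check at 2e5
reads per library. Annotation-recovery experiments use 20 precursors of
~96 nt at 10% query divergence; the cluster-recovery experiment uses a
1-Mb genome with ~400 reads per library so that the planted cluster is
the only interval denser than background (with ~50 kb genomes and deep
background the correct and expected output is "no cluster"). All
randomness derives from a single root seed split per stage, simulated
FASTQ is byte-reproducible, and pipeline data outputs are
byte-identical across re-runs (the run report additionally records
wall-clock timings and is excluded from that contract).

# Known limitations

* A few percent of genuinely planted stem-loops fail the automated
  structure validation (maximum pairing occasionally branches a true
  stem into two side-by-side helices, read as multiple terminal loops);
  the annotation-recovery guarantee is >= 95%, not 100%.
* Maximum pairing over-pairs random sequence; the validation thresholds
  (>= 15-pair stem, 40% paired, single loop) were chosen for
  miRNA-precursor-sized windows and are not meaningful above ~300 nt.
* The homology E-value calibration assumes uniform base composition;
  strongly skewed genomes would need re-fitting via `estimate_karlin()`.
* The annotation's manual-curation stage of the original analysis is
  approximated by explicit rules; concordance with expert curation is
  untested.
* Multi-mapping is resolved by full counting; differential expression on
  tandem-repeat families therefore tests family-level, not copy-level,
  signal.
* The simulator plants blunt-ended stems, so the star-overhang flag is
  exercised by constructed fixtures rather than by the default
  simulation.
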