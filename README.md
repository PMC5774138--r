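# crestmir

Small RNA-seq analysis of microRNAs in embryonic explants, built for the
study design used to profile *Xenopus laevis* neural crest (NC), neural,
ectoderm and blastula animal-cap tissue: twelve libraries (three
replicates of four tissue types) prepared with high-definition (HD)
adapters — adapters carrying four degenerate nucleotides at each ligating
end — and sequenced with 3′ adapter run-through.

The package implements the full analysis as tested, reusable R functions:

* **HD adapter trimming** — locate the 3′ adapter by perfect match to its
  first 8 nt (`TGGAATTC`), strip the 4-nt HD signatures from both ends,
  keep 16–35 nt inserts, collapse to distinct sequences with per-library
  counts and a full discard audit.
* **Exact genome mapping** — full-length, gap-free, mismatch-free, both
  strands, all loci reported; size-class profiles in reads per million
  genome-matched reads (RPM).
* **Hairpin annotation** — seed-and-extend homology search of known
  animal precursor hairpins against the genome with calibrated
  Karlin–Altschul E-values (`E = K·m·n·e^(−λS)`, threshold `E < 10⁻⁶`),
  the filter ladder (≥ 30-hit queries removed, hairpins ≤ 55 nt removed,
  < 100 reads over all samples removed with family rescue), maximum
  base-pairing (Nussinov) structure validation, and data-driven mature
  arm assignment.
* **isomiR and arm-switch quantification** — signed 5′/3′ end offsets
  against each reference mature, per-library 5p/(5p+3p) arm ratios, and
  tissue-dependent arm-switch calls; tissue profiling views (top-10
  families, family fractions, heatmap matrices).
* **Differential expression** — median-of-ratios size factors and a
  negative-binomial Wald test (`var = m + α·m²`) with
  bootstrap-calibrated empirical-Bayes dispersion shrinkage,
  Benjamini–Hochberg correction, calls at `padj < 0.01`, and the derived
  enrichment sets (NC-enriched; shared NC ∩ blastula).
* **Novel miRNA prediction** — read-stack detection on Dicer-sized
  reads, anchored precursor excision and folding, longest-passing-hairpin
  selection, star-overhang support, and single-linkage grouping by
  mature sequence.
* **29-nt class characterisation** — density-based cluster detection
  with piRNA-signature statistics (strand bias, 1U fraction), in-cluster
  fractions, and exon/intron enrichment checks for degradation-fragment
  hypotheses.
* **A synthetic-data generator** — plants a genome with known hairpins, a
  miR-427-like tandem repeat of ~1.2 kb units carrying five isoform
  hairpins, arm switching, negative-binomial replicate noise, planted
  differential expression, a 29-nt cluster locus and gene models, and
  writes FASTQ/FASTA/GFF3/JSON ground truth so every stage is testable
  without downloads.

## Worked example

Simulate a compact 12-library experiment and run the whole pipeline:

```r
library(crestmir)

cfg <- sim_config(seed = 7, genome_length = 40000, n_hairpin_loci = 15,
                  n_novel_loci = 2, repeat_copies = 2,
                  replicates_per_tissue = 3, depth_per_library = 30000)
sim <- simulate_experiment(cfg, tempdir())
res <- run_pipeline(run_config(
  genome = sim$paths$genome, precursors = sim$paths$precursors,
  annotation = sim$paths$gff, manifest = sim$paths$manifest,
  outdir = file.path(tempdir(), "out"), seed = 7))

res$reads
#> collapsed_reads: 138128 distinct sequences, 12 libraries, 378,093 kept reads

nrow(res$annotation$hairpins)        # known loci recovered (15 + 2 x 5 isoform copies... minus mirrors)
#> [1] 24

round(res$views$family_fraction["mir-427", ], 3)
#>       NC   neural ectoderm blastula
#>    0.561    0.665    0.689    0.692

sw <- res$arm_switches
head(sw[sw$status == "switched" & sw$tissue_b == "blastula", ], 2)
#>  hairpin    ratio_a   ratio_b   status tissue_a tissue_b
#>   hpl014 0.05468928 0.8822345 switched       NC blastula
#>   hpl019 0.05468928 0.8822345 switched       NC blastula

res$enrichment_sets
#> $nc_enriched
#> [1] "hpl001" "hpl002" "hpl012"
#> $shared_nc_blastula
#> [1] "hpl013"
```

Reading the output: the repeat (miR-427-like) family carries ~56–69% of
miRNA reads per tissue; the repeat's isoform-A copies switch arms between
blastula (5p ratio 0.88) and the other tissues (0.05), matching the
planted 0.90/0.05; the three planted NC-enriched hairpins and the one
planted NC∩blastula hairpin are recovered exactly by the `padj < 0.01`
enrichment-set logic; and the simulator's withheld loci come back as
novel predictions (5 predictions in 5 groups — one per expressed arm
that passed the structural rules).

Every intermediate is also written to `outdir` as plain TSV / FASTA /
GFF3 / BED / JSON, and re-running with the same configuration reproduces
those files byte for byte.

A thin command-line front end is installed with the package
(`inst/scripts/crestmir`): `crestmir simulate --config sim.yaml --outdir
DIR` and `crestmir run --config run.yaml`.

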