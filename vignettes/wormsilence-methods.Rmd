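---
title: "Methods: small-RNA silencing analysis in wormsilence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA silencing analysis in wormsilence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`wormsilence` re-implements, as a tested and reusable pipeline, the
computational analysis of a *C. elegans* piRNA-pathway silencing study:
small-RNA read processing with UMI-aware duplicate collapsing, exact-match
genome alignment, small-RNA class quantification (21U, 22G, 26G, miRNA),
21U-sensor and metagene 22G coverage profiling, differential 22G targeting
with gene-set overlap enrichment, zero-class transposon reversion-frequency
estimation, and two-channel germ-granule colocalization quantification.
Every stage is exercised end-to-end on synthetic data with machine-readable
ground truth, so the whole analysis is verifiable without any external
download.

# Read processing

Raw reads have the architecture

```
5'-UMI (4 nt) + insert (15-30 nt) + 3'-UMI (4 nt) + 3' adapter + tail
```

and are processed in a fixed five-step order:

1. **Adapter trimming** (`trim_adapter()`): the earliest exact occurrence of
   any configured adapter — a full internal match, or a read-terminal prefix
   of the adapter at least 5 nt long — and everything 3' of it are removed.
   Reads whose trimmed length falls outside 26–38 nt (a 15–30 nt insert plus
   two 4-nt UMIs) are discarded. Matching is exact: the generator writes
   adapters without sequencing errors, so error-tolerant matching would
   change nothing here; an error model is a documented non-goal.
2. **Quality filtering** (`quality_filter()`): a read is kept only if 100%
   of its bases are at Phred ≥ 20; the percentage is a parameter.
3. **UMI-aware duplicate collapsing** (`collapse_umi_duplicates()`): reads
   with byte-identical *full* sequence (UMIs still attached) collapse to one
   record carrying the multiplicity. Keying on the full read is the most
   conservative interpretation of UMI-based deduplication: two molecules
   sharing an insert still differ in their 8 random UMI bases.
4. **UMI trimming** and 5. **minimum-length filtering**
   (`extract_insert()`): the first and last 4 bases are stored as UMIs and
   inserts shorter than 15 nt are discarded.

The order matters and is asserted in the tests: collapsing *after* UMI
removal would merge distinct molecules that share an insert. Each stage
reports `n_in = n_kept + n_discarded`, and the pipeline report concatenates
these into a conservation ledger.

# Alignment

`map_reads()` performs exhaustive exact matching: all occurrences of the
insert (forward) and of its reverse complement (reported on the minus
strand, in genomic coordinates) across all contigs. The implementation
compiles all query inserts into one trusted-band Aho–Corasick dictionary
(band = shortest insert; tails verified exactly) and scans each contig and
its reverse complement, so occurrence completeness holds by construction;
the test suite additionally checks equality against a brute-force
position-by-position scan.

When an insert has several equally good placements, exactly one is reported,
chosen uniformly at random — the single-report multimapper policy of classic
short-read aligners — but from a *seeded* generator, so runs are
reproducible; `n_hits` records the true number of placements.

Structural-RNA removal (`filter_structural()`) drops an alignment iff a
structural feature (rRNA/tRNA/snoRNA/snRNA) *on the same strand* covers at
least 90% of the read's length, the fraction computed with respect to the
read interval. Counts are normalized to reads per million mapped
non-structural reads (RPM).

Internally, alignment tables use 0-based half-open coordinates; annotation
is handled as 1-based closed `GRanges` (GFF3 convention) and converted at
the boundary.

# Small-RNA classification

The class definitions are field convention rather than anything the figures
print, so they are explicit and configurable (`class_rules()`):

| class | length | 5' base | context |
|-------|--------|---------|---------|
| miRNA | 18–26 | any | sense overlap with a miRNA locus |
| 21U   | 21 | T | sense overlap with a piRNA locus |
| 22G   | 22 | G | antisense to an annotated gene (sensor included) |
| 26G   | 26 | G | antisense to an annotated gene |

The first matching rule in the order miRNA → 21U → 22G → 26G wins, so the
classes partition the reads; anything else is `other`. Per-gene antisense
22G counting increments the single gene a read is antisense to; a read
antisense to two or more overlapping genes increments none and is counted
as ambiguous (the toy annotation forbids gene overlaps, so this is an edge
guard).

# Coverage profiles

**Sensor windows.** Secondary 22G RNAs — those triggered directly at the
21U recognition site — are quantified as the summed RPM of reads
intersecting the 21-bp site padded by `pad` on each side; tertiary 22Gs are
reads intersecting the mCherry CDS but not the secondary window. The
original window coordinates are not published, so `pad` is a parameter
(default 50 bp) recorded in every output header; the windows must stay
disjoint after padding.

**Metagene curves.** Per gene, antisense 22G coverage is taken in transcript
orientation, cumulated with fractional assignment onto 100 equal
relative-position bins, and divided by the gene total, so every per-gene
curve rises from 0 to exactly 1 (resolution-independent; a minus-strand
gene with mirrored coverage yields the identical curve as its plus-strand
counterpart). The set curve is the mean over genes; the replicate SD is the
shading. For genotype comparison, per-gene normalized coverage is summed in
10 bins and compared bin-wise with a two-tailed unpaired t-test across
genes, Bonferroni-corrected by the number of bins.

**Site-centered profiles.** The anchor of a 21-nt 21U target site is the
genomic base pairing with position 10 of the 21U RNA, counted 1-based along
the 21U in target-transcript orientation (the Argonaute cleavage-site
convention). For each antisense 22G read the profile accumulates the signed
offset of its 5' end from the anchor (positive = 3' on the target
transcript), within ±50 bp. The 5'-end convention (rather than full
coverage) was chosen because 22G production positions are defined by their
5' ends; this is flagged as an interpretation choice.

# Differential 22G targeting

Counts are normalized by median-of-ratios size factors (`normalize_counts()`;
per-sample median over all-nonzero genes of the count over the gene's
geometric mean; total-count fallback when no gene is nonzero everywhere).
`test_differential()` then computes, per gene, the log2 fold change of
genotype means with a 0.5 pseudocount and a two-tailed location test on
`log2(normalized + 0.5)`, BH-adjusts over all tested genes, and calls genes
`up`/`down` at adjusted p < 0.05 and fold change > 2 — the conventional
volcano thresholds.

The default test statistic uses a **common log-scale variance** pooled over
all tested genes' residual sums of squares. At three replicates per
genotype a per-gene variance has only 4 degrees of freedom; its sampling
noise dominates the statistic and caps the power to recover even four-fold
effects at roughly 75–80% after multiplicity adjustment. Pooling is
justified here because on the log scale the NB variance `1/μ + φ` is nearly
constant across moderately-to-well-expressed genes with shared dispersion —
exactly the regime of per-gene 22G counts — and it leaves the null
calibration intact (raw p < 0.05 fraction ≈ 0.05 in null simulations).
This is a common-dispersion assumption, not per-gene empirical-Bayes
shrinkage (which stays out of scope); the classical per-gene t-test remains
available via `var_method = "per_gene"`.

Gene-set overlap enrichment (`gene_set_overlap()`) builds, for each set ×
direction over the annotated-gene universe, the 2×2 membership table, tests
it with Fisher's exact test (two-sided probability-ordering rule; the
"doubled one-tail" rule is available since conventions differ), adjusts
with BH across all cells, and reports the sample odds ratio ad/bc — the
association strength conventionally shown in overlap heat maps — with an
`ns` flag at adjusted p ≥ 0.05. The universe is all annotated
protein-coding genes.

# Reversion frequency

The transposon excision frequency per animal is estimated by the Poisson
zero-class method from plate counts: with `T` plates scored, `R` plates
showing revertants and `N` animals per plate,

$$ f = -\ln[(T - R)/T] / N. $$

`R = 0` gives `f = 0`; `R = T` leaves the zero class empty and the
frequency is not estimable (error, or a flagged `NA` in the table variant).
The default `N` is 10,000 animals, the population of a starved plate.
Consistency is verified by simulation: plates revert independently with
probability `1 − exp(−N f)`, and the median of 500 estimates at
`f = 1e-4`, `N = 10,000`, `T = 100` falls within a few percent of the
truth.

# Granule quantification

`segment_channel()` thresholds one channel (Otsu's method by default —
the original analysis adjusted thresholds manually, so a numeric override
is provided and the threshold used is recorded on the output), labels
connected components and keeps objects of 1–2,000 pixels (inclusive
bounds). Connectivity is 8 by default (the ImageJ convention) and
configurable; the labeling is an iterative minimum-label propagation, so
the result is scan-order independent. Centroids are unweighted pixel means,
areas are pixel counts, both also in micrometres via the pixel size.

`pair_distances()` reports, for every object in channel A, the Euclidean
center-to-center distance to its *nearest* channel-B object — the
center-distance measure of colocalization. The pairing is directional by
construction and the tests assert this on a counterexample.

`zp_ratio_test()` pools Z- and P-granule counts per genotype and compares
each genotype to the reference with a pooled two-proportion z-test on the
proportion Z/(Z+P) (a proportion test needs proportions; the figure-style
ratio Z/P is emitted alongside), Holm-adjusting across genotypes.
`area_compare()` gives box-plot summaries (median, IQR, 1.5·IQR whiskers
clipped to the data) and pairwise two-tailed unpaired t-tests.

Only single-z-slice 2D images are analyzed, matching the deconvolved
single-stack inputs of the original workflow; nucleus detection and 3D are
non-goals.

# The synthetic-data generator

`sim_config()` + `make_reference()` + `simulate_reads()` +
`simulate_images()` define the study conditions:

* **Genome**: one 200-kb autosome-like contig of i.i.d. random bases plus a
  5-kb sensor contig carrying an mCherry CDS (positions 1,000–2,000) and a
  21-bp 21U recognition site (2,100–2,121) inside a transcript annotated as
  a gene. 50 genes of 1 kb, 8 structural loci, 10 miRNA loci, 20 piRNA loci
  (built with a 5' T on their strand), and 21U target sites planted inside
  WAGO-1-set genes. Gene sets (Mutator, CSR-1, WAGO-1, ERGO-1, ALG-3/4,
  replicative histones) are drawn independently so they overlap, like the
  published lists they stand in for. This scale keeps a full six-sample run
  under a minute while leaving k-mers effectively unique.
* **Reads**: 50,000 per sample by default, class mix
  21U/22G/26G/miRNA = 0.15/0.55/0.10/0.20 plus 2% structural reads; 22G and
  26G reads are placed antisense with a genuine genomic 5'-G (positions are
  sampled from the subset of gene-body starts whose antisense read begins
  with G, approximately uniform over the body); sensor 22Gs are planted at
  an exact 10:1 secondary:tertiary count ratio (tertiary can be switched
  off to emulate a genotype that lost the amplified response); per-gene 22G
  abundance is scaled by `2^log2FC` in the mutant genotype (default: +2 on
  three genes, −2 on three). Qualities are Q40 except a 5% planted
  low-quality fraction (one base at Q15, placed inside the UMI+insert+UMI
  core so it survives trimming); 20% of reads are exact PCR copies.
  Molecule full sequences are forced unique by UMI re-draws so the
  pre-duplication multiset is exactly recoverable.
* **Images**: planted discs of configured center and radius on constant
  background, co-registered two-channel 16-bit TIFF, optional Gaussian
  noise; truth records planted centers and rendered pixel areas, and flags
  overlapping objects.

What the generator does **not** emulate: sequencing errors, genome-scale
repeat structure and mappability artifacts, ligation biases, gene-specific
NB dispersion, 3D point-spread functions, or uneven illumination. Passing
tests therefore demonstrate correctness of the computations under clean,
known-truth conditions — not robustness to every artifact of real data.

# Numerical choices and degenerate inputs

* Identical seeds give byte-identical outputs everywhere: every random draw
  derives from the configured seed, multimapper ties use a per-sample
  seeded RNG, and output files carry no timestamps (the GFF3 date pragma is
  stripped; provenance headers record package version, a parameter hash and
  the seed).
* Fisher's two-sided p uses the probability-ordering rule with a 1e-7
  relative tolerance on probability ties, matching the standard enumeration
  convention.
* `fisher_exact` odds ratio: ∞ when bc = 0 and ad > 0, `NA` when both
  products are 0; degenerate (empty-direction) overlap tables report p = 1.
* Zero-variance t-tests: t = 0, p = 1 when the groups are identical; `NA`
  when both groups are constant but different.
* Metagene: zero-coverage genes are excluded and counted; bins with fewer
  than two usable genes per genotype report `NA` p-values.
* `two_prop_z` is undefined at pooled proportions 0 or 1 and returns `NA`.
* Empty segmentation masks return empty object tables, not errors; a
  genotype with zero granules is dropped from the ratio test with a
  warning.

# Problem sizes used in the checks

The test suite and the acceptance script run, by the package's own choice
of scale: 10,000 random 15–30-nt inserts against the 205-kb toy genome for
the mapper/oracle comparison; one 50,000-read sample with 20% duplicates
and 5% low-quality reads for the processing ledger and class-mix recovery;
20,000-read noise-free samples for the sensor windows; 50 genes × 20
simulation runs for the metagene power check; 1,000 genes at 3v3 (NB mean
200, dispersion 0.05) for differential calibration and recovery; all 2×2
tables with n = 20 for the Fisher oracle; 500 replicate plate simulations
for the reversion estimator; and 9 planted discs across two channels for
granule recovery.

# Known limitations

* The mapper is exact-match only (`-v 0` semantics); it is not a general
  aligner and reports one placement per read, so multimapper-aware
  fractional counting is not available downstream.
* The differential module assumes a shared log-scale variance by default;
  for data with strongly gene-specific dispersion use
  `var_method = "per_gene"` and expect lower power, or an external
  count-model tool.
* Published headline gene counts of the original study depend on its
  deposited sequencing data and are not reproduced here; the package's
  acceptance surface is planted-effect recovery on synthetic data.
* Granule analysis is 2D, single-threshold, nearest-center pairing;
  object-boundary distances and 3D stacks are out of scope.
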