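---
title: "Calling and characterizing RNA-DNA differences with rddscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing RNA-DNA differences with rddscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddscope)
```

## The problem

A transcriptome is not a verbatim copy of its genome. At thousands of
positions the RNA base differs from the homozygous DNA genotype of the
same cells — RNA-DNA sequence differences (RDDs). The dominant class is
A-to-G: adenosine deaminases acting on RNA (ADAR1, ADAR2) convert
adenosine to inosine in double-stranded RNA, and sequencers read inosine
as guanosine. Because adjacent inverted Alu repeats fold into long RNA
duplexes, primate editing concentrates in Alu elements, often as dense
clusters ("hyperediting"). The remaining eleven substitution classes —
including transversions that deamination cannot produce — behave
differently in every respect and serve as an internal negative control.

rddscope re-implements, as a tested and reusable pipeline, the analysis
that detects these sites from matched DNA-seq and strand-specific
RNA-seq of the same cells, quantifies how each site responds to siRNA
knockdown of ADAR1/ADAR2, characterizes the sequence and genomic context
of the sites, and relates editing to gene expression.

## The calling model

The input is a pair of pileup tables per individual: for each covered
position, per-allele read counts for DNA and for RNA, the RNA strand of
origin from directional sequencing, and a flag for unique mapping (the
upstream aligners' concern; rddscope does not realign). A site is called
when every filter of a deliberately stringent cascade passes:

1. **DNA genotype** — a single allele carries at least
   `require_dna_concordance` (default 100%) of at least
   `min_dna_coverage` (default 10) DNA reads. Heterozygous positions can
   masquerade as RDDs through allelic imbalance and are never eligible.
2. **RNA coverage** — at least `min_rna_coverage` (default 10) RNA reads.
3. **RDD level** — the most frequent non-genotype RNA allele accounts
   for at least `min_rdd_level` (default 10%) of all RNA reads at the
   position. The level is the editing level for A-to-G sites.
4. **Unique mapping** on both molecules, when required.
5. **Cross-individual concordance** — the same site (position *and*
   type) must be called in every individual
   (`intersect_individuals()`). This is the strongest guard against
   alignment artifacts, which recur in one library but not in
   independent genomes.

Types are labeled on the transcribed strand: a reference-strand T-to-C
difference inside a minus-strand gene is an A-to-G editing event
(`classify_rdd_type()`). The strand comes from the overlapping gene
models; where transcripts on both strands overlap, the call keeps a
plus-strand label and a `strand_unknown` flag; intergenic sites fall
back to the RNA strand of origin recorded in the pileup.

Three conventions that the filter definitions leave open are fixed
here:

* *Coverage minimum* — "10 total reads" is read as ≥ 10 on **each**
  molecule. Ten combined reads could genotype on five DNA reads, which
  would make a 100%-concordance requirement nearly vacuous.
* *Variant choice* — with three possible variant alleles, the most
  frequent non-genotype allele wins; exact ties resolve by the fixed
  order A < C < G < T and carry a `tie` flag, so calling is
  deterministic.
* *Level denominator* — the RDD level divides by **all** RNA reads, not
  reference-plus-variant only; with a rare third allele the difference
  is below read-count resolution anyway.

## Knockdown response and the FDR bound

Editing that ADAR enzymes produce must shrink when the enzymes are
silenced. `compare_conditions()` re-measures every control site in the
knockdown RNA (no calling thresholds — an abolished site would never
re-pass the 10% filter, but its level of zero is still a measurement)
and classifies the response: `decreased_ge20` when the relative change
`(control − kd)/control` is at least 0.20 in **every** individual,
`increased_ge20` symmetrically, otherwise `unchanged`; `abolished` marks
sites whose knockdown level is exactly zero. The relative reading makes
"reduced to zero" the natural extreme of "decreased"; an
absolute-difference mode is available (`mode = "absolute"`). Sites
lacking ≥ 10 knockdown reads in each individual are `not_evaluable` and
excluded from denominators.

Because a true enzyme target must respond, the fraction of called
A-to-G sites that fail to respond bounds the false discovery rate from
above: `kd_fdr_bound()` returns
(evaluable − decreased)/evaluable. On the reported response counts
(6,258 decreased of 6,524) this is 4.1%; an orthogonal bound pools
validation assays by total counts — `combined_fdr()` on 24/25 Sanger
plus 5/6 ddPCR gives 2/31 ≈ 6.5%. Pooling, not averaging, is the right
aggregation: the per-method rates (4% and 16.7%) would average to 10.3%
and misrepresent the evidence.

`venn_partition()` splits responding sites into ADAR1-only, ADAR2-only
and shared targets; the three compartments sum to the responsive total
by construction, and the identity is asserted in the tests.

## Site features

* `neighbor_profile()` — base frequencies at offsets −10..+10 on the
  transcribed strand (minus-strand flanks are reverse-complemented). The
  A-to-G hallmark is guanosine depletion immediately 5′ and enrichment
  immediately 3′ of the edited adenosine.
* `cluster_fraction()` — fraction of sites with another site of the
  same set within 25 nt (center-to-center, inclusive; the boundary is
  parameterized since "within 25 nt" does not specify tie handling).
* `inverted_repeat_proximity()` — `within` / `near_lt_1kb` / `far`
  relative to repeat intervals annotated as inverted pairs; "near" is a
  strict `< 1000` nt from the interval edge, a literal reading of
  "< 1 kb", with adjacency counted as 1 nt.
* `assign_region()` — per overlapping transcript a site is CDS, 5′UTR,
  3′UTR or intron; unanimity across transcripts keeps the label,
  disagreement (or exons of non-coding transcripts, whose annotation is
  ambiguous) yields `Mixed`, no overlap yields `intergenic`. The six
  labels partition any call set.
* `detect_hyperedited()` — transcripts with strictly more than 50
  A-to-G sites in their span ("more than 50" is strict). Isoforms that
  share a span share the sites; all qualifying isoforms are reported.
* `scan_motifs()` / `motif_enrichment()` — fixed-pattern scanning of
  the AU-rich elements (the HuR motif `TA(T/A)TTTT` and the related
  `(U/A)UUUA`, `(U/C)UUUA`, `AUUU(U/C)` in DNA alphabet), counting
  overlapping matches via IUPAC-degenerate search, with a 1-df
  chi-square (and Fisher) test on the 2×2 presence table and a
  Haldane-corrected odds ratio. De-novo motif discovery is out of
  scope: downstream analyses consume the discovered motifs as fixed
  patterns, which is what is implemented.

## Expression

`compute_rpkm()` is the classical reads per kilobase per million.
Fold changes between conditions are computed on depth-normalized counts
with a 0.5 pseudocount guarding zeros; units classify as increased
(fold ≥ 2), decreased (≤ 0.5) or unchanged, at transcript and at gene
level (gene counts are isoform sums over the merged exonic length — a
sum of RPKMs would be wrong whenever isoform lengths differ).
`detect_isoform_switching()` reports genes where isoforms move
significantly in opposite directions while the gene total stays
unchanged, and `editing_expression_correlation()` tests the
independence of editing change and expression change per gene (Pearson,
with an explicit undefined result when either variable is degenerate).
No particular count-level significance test is canonical for this
filter-based design, so fold-change classification is
primary here and no count-level test is imposed.

## The synthetic-data generator

`simulate_dataset()` produces the full experimental design at desk scale, with
a ground-truth ledger for every planted site and transcript:

* a contig (default 500 kb) with 40 two-isoform genes on alternating
  strands; Alu-like 280-nt cassettes overwrite intronic/3′UTR sequence,
  about half of the first-intron cassettes as inverted pairs (copy plus
  nearby reverse complement);
* A-to-G sites in four enzyme classes (ADAR1-only, ADAR2-only, shared,
  hyperedited) planted on transcribed-strand adenosines, 85% inside
  Alu, confined to a 60% subset of "edited" genes so unedited
  transcripts exist as a contrast; placement prefers the 5′-non-G /
  3′-G context with probability 0.8; per-site editing levels are
  uniform on 1%–99%, matching the observed range;
* hyperedited transcripts receive 60 clustered sites each (above the
  >50 detection threshold);
* non-A-to-G RDDs placed in CDS/5′UTR compartments, untouched by
  knockdown — the negative control;
* reads are independent per-read draws: DNA at fixed depth 30 (a typical
  whole-genome coverage), RNA at Poisson depth 50, each read keeping its
  base with probability 1 − ε (ε = 0.001, a typical post-filter
  Illumina error) or landing uniformly on another base. This binomial
  model is the minimal one consistent with pileup counting; it ignores
  mapping bias, PCR duplicates and splice-junction artifacts, so
  passing recovery tests demonstrates correctness of the calling logic,
  not robustness to alignment pathology;
* knockdown scales true levels per class: ×0.1 under ADAR1 knockdown
  (strong silencing), ×0.5 under ADAR2 knockdown (the partial, ~25%
  mRNA reduction observed), with a +30% compensatory boost (capped at
  1) of ADAR1-class sites under ADAR2 knockdown — the magnitude is a
  labeled configuration choice, since the phenomenon is reported
  without a rate model;
* two individuals share the truth and re-draw read noise; a
  configurable fraction of individual-specific sites (default 0) models
  inter-individual differences;
* expression: log-normal base means, Poisson counts, ×2/×0.5
  perturbations on a planted subset and reciprocal multipliers on
  isoform-switch pairs with equal base means, which keeps the gene
  total at 1.25× — inside the 2-fold window, hence "unchanged" at gene
  level while both isoforms move.

Everything is deterministic given the config seed; per-stage streams
are derived from it, and byte-identical reruns are asserted in the
tests.

## Numerical and testing choices

* **Percentages** round half away from zero (`proportion()`), which
  reproduces the familiar 96/98/67 percentages from their printed
  numerators and denominators; base R's banker's rounding would not.
* **Caller verification** is exhaustive, not sampled: all
  ~1,820 × 1,820 DNA×RNA allele-count compositions with up to 12 reads
  per molecule are compared against an independently written
  brute-force filter.
* **Recovery conditions.** The recovery analyses run at read depth 50,
  ε = 0.001, planted levels ≥ 20%, on a 300-kb genome with ~260 planted
  sites. One subtlety is intrinsic: with per-read errors at rate ε, a
  depth-*d* DNA column is error-free with probability (1−ε)^d — 95.1%
  at d = 50 — so the strict 100%-concordance genotype filter discards
  ~5% of truly homozygous positions per individual (~10% after the
  two-individual intersection) regardless of implementation. That loss
  is a property of the strict filter itself, not a bug; measured strict-mode
  sensitivity (~0.945) matches the closed form. The recovery checks
  therefore use the caller's error-tolerance parameter
  (`require_dna_concordance = 0.96`, allowing ≤ 2 discordant reads of
  50 while still rejecting genuine heterozygotes), under which
  sensitivity and precision are ≥ 0.95/0.99.
* **Null behavior.** With no planted sites, a false call in one
  individual needs ≥ 2 identical-base errors among 20 reads
  (≈ 6×10⁻⁵ per position); requiring the same site in both individuals
  squares that, so a 10-kb null genome yields zero calls with
  probability near 1. The tests assert exactly zero.
* **Boundary effects.** Planted expression folds sit exactly at the
  2-fold classification boundary, and fixed-depth normalization shifts
  observed folds by the net composition change, so observed folds
  straddle the threshold; exact-recovery tests of the classifier use a
  margin below the planted effect rather than the boundary itself.
* **Problem sizes.** Test simulations use 120–300 kb genomes with
  12–30 genes and 50–260 planted sites — large enough for every
  structural property and small enough to keep the whole suite around a
  minute.

## Limitations

Alignment is out of scope: unique mapping arrives as a per-position
flag, and none of the artifacts that dominate real RDD false-positive
lists (paralog mismapping, splice-junction errors) are modeled. The
generator does not plant AU-rich elements, so motif enrichment over
simulated transcripts is null by construction and the enrichment code
is validated on constructed sequence sets instead. Hyperediting
detection counts sites per transcript span, so isoforms sharing outer
exons are reported together. The knockdown scale factors are global per
enzyme class; real per-site responses are heterogeneous.
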