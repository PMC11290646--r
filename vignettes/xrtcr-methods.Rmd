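---
title: "Models and methods behind xrtcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xrtcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xrtcr)
```

# Scope

`xrtcr` analyses excision-repair sequencing (XR-seq) of UV-induced CPD
damage to quantify transcription-coupled repair (TCR) and to detect
transcription — including intergenic, non-coding transcription — from the
repair signal itself. It operates downstream of alignment: inputs are
mapped-read intervals (BED-level), gene and ncRNA annotations, chromosome
sizes, optional genome sequence, epigenomic tracks (bedGraph) and a
chromatin-state segmentation. A synthetic-data generator reproduces the
statistical structure of the assays so that every stage of the pipeline is
exercised by tests with known ground truth.

# The repair model

Nucleotide excision repair releases a short single-stranded oligonucleotide
around the lesion. The generator and the read-composition profiler share
one geometric model:

* CPD damage occurs at TT dinucleotides only (the dominant photoproduct).
* Dual incision cuts ~19 nt 5′ and 6 nt 3′ of the 2-nt dimer, giving
  19 + 2 + 6 = 27-nt products. Jitter (default ±2 nt, binomially
  distributed with mode 0) is applied to the 5′ incision only.
* Library preparation shortens products to sequenced reads of 19–24 nt by
  trimming from the 5′ end only, so the 3′ geometry — exactly 6 nt between
  the dimer and the 3′ read end — is preserved at every read length. This
  5′-only trimming is a modelling choice: it is the simplest mechanism
  that reconciles ~27-nt excision products with 19–24-nt reads while
  keeping the observed fixed TT offset from the 3′ end.

**Position convention.** Reported dinucleotide positions are the number of
nucleotides strictly 3′ of the dinucleotide:

```
5'-N N N N N N N N N N N N N N N N T T x x x x x x-3'
                                   ^dimer          ^3' end
                                        <-- 6 nt -->
```

A dimer followed by six nucleotides is "6 nt from the 3′ end". This
convention is used identically by the generator
(`simulate_excision_products`) and the profiler (`positional_dinuc_freq`),
making the 3′-anchored TT maximum an internal consistency check of the
whole read-level model. (An alternative convention counts the dimer's 5′
base as the k-th base from the 3′ terminus; under the 19/2/6 geometry that
would place the maximum at 8, so it is not used.)

Two pathways generate damage-site samples:

* **TCR**: only on the template strand of transcribed loci (annotated
  genes plus the planted intergenic loci), with an exponential 5′→3′
  positional weight `exp(-d / decay)` (`decay_bp` = 1500 bp by default,
  normalised within each locus so locus read shares follow expression).
  The decay reproduces the qualitative TSS-proximal repair peak without
  claiming a quantitative profile.
* **Global repair**: TT sites drawn uniformly from both strands genome
  wide.

Genotype presets fix the pathway mixture: WT 0.6/0.4 TCR/global, `csb-1`
0/1, `xpc-1` 1/0. The per-gene statistic TS/(TS+NTS) then has expectation
1 for `xpc-1`, 0.5 for `csb-1`, and `p + (1-p)/2` for a mixture with TCR
weight `p` — the last identity assumes both pathways hit gene bodies with
equal probability, so the parameter-recovery test uses a gene-dense
configuration (genes covering ~90% of a small genome, no intergenic
transcription) where the identity holds to within ±0.015; on the default
sparse-gene genome the gene-conditional TCR share exceeds `p` and recovery
via this closed form would be biased upward.

Time dependence is a per-timepoint multiplier on the decay length
(1× at 5 min up to 12× at 48 h), flattening the TSS-proximal skew as
repair proceeds — a monotone ordered-trend device, not a kinetic ODE; no
kinetic model over the 5 min–48 h span is attempted.

# Counting conventions

* Coordinates are BED-style 0-based half-open at format boundaries and
  `GRanges` (1-based closed) internally; converters live only in the
  readers/writers.
* Gene-level read counting follows `bedtools intersect -c -wa -F 0.5`
  semantics: a read counts for a feature iff ≥ 50% of the *read* lies
  inside it (ties count), and a read may count for several features.
  Strand rule `-S` (opposite) defines transcribed-strand counting because
  genes are annotated on their coding strand; `-s` (same) gives the
  non-transcribed strand.
* Bin-level counting (intergenic discovery) uses ≥ 1 bp overlap,
  strand-blind; bins are unstranded and the half-read rule is reserved for
  gene/feature intersections.
* Gene QC retains genes with ≥ 10 TT dinucleotides on either strand *or*
  — combined by AND — ≥ 10 reads total across all XR samples; the
  read-QC chain applies deduplication (coordinates + strand identity
  only), mapping quality strictly > 20, chromosome whitelist, and length
  19–24 nt, in that order, reporting survivors per stage.
* The 2,142-gene-style profile selection keeps genes strictly longer than
  2 kb with ≥ 500 bp to the nearest neighbour on either side, any strand
  or biotype — the filter protects strand assignment from neighbouring
  genes, and a same-strand neighbour contaminates as much as an
  opposite-strand one.
* Metagene layout: 50 bins over [TSS−500, TSS+1000) and 50 bins over
  [TES−1000, TES+500), 30 bp each, in transcription orientation; exactly
  100 bins per gene always. Genes whose windows leave the chromosome are
  dropped and counted.
* TSS heatmaps deduplicate TSSs and keep a TSS iff ≥ 1 kb from the last
  kept one, scanning each chromosome in coordinate order (deterministic
  keep-first tie-break); rows are ranked by total signal, the
  "best-represented half" being the top 50%.
* Chromatin-state assignment gives each read to the state with the
  largest overlap, ties to the lowest state id. Epigenomic track scores
  are width-weighted means over the track intervals overlapping a region;
  regions without coverage are missing, not zero.
* Undefined TS fractions (0/0) propagate as `NA`, never 0, and are
  excluded from cohort means with the exclusion count recorded.

# Intergenic discovery

The detection-call rules mirror the three assay classes: XR requires a
non-zero timepoint-median adjusted count in both replicates (the median
over the six timepoints is the combined per-replicate value); RNA requires
both strains; capped requires either cap-size class. XR-unique bins are
classified by annotation overlap with the fixed priority piRNA >
pseudogene > protein_coding > eRNA > lincRNA > ncRNA > other (single-class
reporting needs a deterministic tie rule; the priority runs from the most
specific ncRNA class downward). Detection quality against the capped
ground truth is summarised as sensitivity, specificity and their geometric
mean.

# Repair dynamics

Per-gene time courses are fitted by continuous piecewise-linear least
squares over the ordered sample index 0–5 (the timepoints span three
orders of magnitude in clock time, so only their order is modelled; a
log-hours axis is a trivial substitution). Breakpoint candidates are the
midpoints between consecutive samples, guaranteeing at least one sample
per segment; the search over 0–2 breakpoints is exhaustive. The breakpoint
count is selected by BIC with 2 + 2k parameters (a slope change and a
location per breakpoint); residual sums of squares are floored at 1e-10 of
the series' total variation so exact fits tie toward the simpler model
instead of amplifying rounding noise.

The significance threshold is the 0.95 quantile of the pooled permuted-R²
distribution: each permutation shuffles the timepoint labels once, shared
across genes, and refits. The permuted statistic is the *selected-model*
R² — the same statistic scored on observed genes — so null and observed
values are exchangeable and the null exceedance rate matches 1 − quantile
(verified over 200 null matrices). Genes significant in both replicates
are clustered (correlation distance, average linkage, tree cut at two) and
the clade peaking earlier is labelled "early".

The planted-trend generator (`simulate_timecourse`) uses smooth unimodal
early/late archetypes with noise sd defaulting to 0.02 × the dynamic
range — the counting CV of per-gene totals of a few thousand reads; at
that noise ≥ 90% of planted trends exceed the permutation threshold.
Breakpoint-location recovery is tested separately at noise 0.05 × range,
where the fitted breakpoint lands within ±1 timepoint in ≥ 90% of series.

# What the generator does and does not emulate

Emulated: strand asymmetry by genotype; excision geometry and trimming;
TT-restricted damage against an i.i.d. AT-rich genome; expression-weighted
locus coverage with a 5′ bias; piRNA clustering on one chromosome with
28-nt precursors visible to long-cap but not short-cap libraries;
mostly-bidirectional eRNAs; poly(A)-restricted RNA-seq (with a small
TES read-through fraction) versus capped RNA-seq covering ncRNA loci;
promoter/enhancer-enriched accessibility and histone tracks over a
20-state segmentation; mapping-quality mixtures and duplicate reads.

Not emulated: sequencing errors and base qualities; real genome sequence
composition (no isochores, repeats or motif structure); UV dose–response;
kinetic repair rates; polymerase pausing. Consequently, passing tests
demonstrate the correctness and calibration of the *analysis* —
counting semantics, normalisation, call rules, statistical thresholds —
under a faithful generative model of the assays' structure; they do not
certify performance on real libraries, where alignment artefacts and
sequence biases add variance the generator does not contain.

# Problem sizes and runtime

Defaults are sized so the full pipeline runs in well under a minute on one
CPU: a 4.3-Mb six-chromosome genome, 150 genes, 300 piRNA / 60 eRNA / 15
lincRNA loci, 10⁵ reads per XR sample (12 samples for the xpc-1 time
course), 10⁵ reads per RNA/capped library, and 200-bp bins (~21,500
genome-wide). The test suite uses these plus a smaller shared fixture;
calibration checks use 200 null matrices (permutation threshold), 200 null
simulations (rank-sum size), and 500 planted series (breakpoint
recovery). A `chrom.sizes` preset with the real ce11 chromosome lengths
ships in `inst/extdata/` for full-scale tiling checks (501,436 bins at
200 bp).

# Known limitations

* `place_in_gaps` spreads loci by a stars-and-bars slack composition —
  near-uniform but not exactly uniform placement at high packing density.
* Random-region sampling for the track comparison excludes nothing by
  default (the comparison population is the entire genome); an `exclude`
  argument is available where a blacklist-aware null is wanted.
* The BAM world is out of scope: mapped reads enter as BED with mapping
  quality in the score column; bigWig tracks enter as bedGraph text.
* With six timepoints the permutation threshold is necessarily high
  (piecewise-linear fits are flexible on short series); power is adequate
  only for strong trends, which matches the intended use of the
  significance call as a conservative screen.
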