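---
title: "clipmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models,
the parameters that matter, what the simulators do and do not emulate,
and the places where the design was genuinely open and a choice had to
be made. It states no empirical result that the test suite does not
itself compute.

## The analysis problem

An iCLIP experiment yields sequencing reads whose 5' ends sit next to
protein–RNA cross-link sites. Three replicate experiments plus a
(shallower, antibody-free) control are typical. The companion
experiment is a knockdown RNA-seq: junction and intron-boundary counts
quantify cassette-exon inclusion (PSI) and intron retention (pir) with
and without the protein. The questions the package answers are: where
does the protein bind (peaks, their genomic context, their position
relative to splice sites and to the canonical exon junction complex
deposition point ~24 nt upstream of exon junctions), which introns are
bound (a read-count classification robust to diffuse binding that
never forms sharp peaks), and whether binding explains the splicing
changes seen on depletion (RNA maps, Δpir shifts, enrichment and
overlap statistics).

## Coordinates

Internally everything is 1-based, closed-interval `GRanges`/`IRanges`
— the Bioconductor convention — with BED and GTF conversion delegated
to rtracklayer, which is exact on the wire. The one deliberate
exception is `genomic_to_transcriptomic()`, which returns a 0-based
offset from the transcript 5' end, because an offset is a distance and
0 for "the first base" composes cleanly with the inverse mapping.
"5' end of an exon" always means the genomic start on the plus strand
and the genomic end on the minus strand.

The representative transcriptome keeps, per gene, the transcript with
the longest CDS. The tie-break (longer spliced length, then
lexicographically smallest transcript id) is our choice — any
deterministic rule would do, and determinism is required for testing.
Genes without an annotated CDS fall back to the longest spliced
transcript; in a protein-coding analysis this path is only a guard.

## Peak calling

The caller works on fixed-length reads (trim long reads with
`trim_reads()`, extend cross-link points with `extend_reads()`; 10 nt
default). Per gene span of width $W$ with $n$ reads:

1. Build the observed coverage profile.
2. Re-place the same $n$ reads (same lengths) uniformly at random in
   the span, `n_iter = 100` times; reads may overlap.
3. For each height $h$, estimate
   $\mathrm{FDR}(h) = \overline{N_{rand}(h)} / \max(1, N_{obs}(h))$,
   where $N(h)$ counts positions with coverage $\ge h$. The estimate is
   capped at 1 and monotonized with a running minimum — the raw ratio
   is not guaranteed non-increasing while the underlying quantity is,
   and the running minimum cannot change the threshold height.
4. Peaks are maximal runs of positions with coverage $\ge h^*$, the
   smallest height with FDR < α (default 0.01).

The exact "modified FDR" of the published caller is not restated in
the literature we re-implement; this positionwise ratio estimator is
the member of the randomization-FDR family that is exactly testable by
enumeration (on a 3-position toy gene with 2 unit reads the test suite
compares the Monte-Carlo table against all 9 placements).

**Summits.** With point-plus-extension reads, the position of maximal
*coverage* within a run is biased ~+4 nt from the cross-link (coverage
is an asymmetric 10-nt smoothing of the 5'-end profile). The summit is
therefore placed at the leftmost position of maximal read 5'-end
density within the run (`summit_on = "starts"`, the default);
`"coverage"` reproduces the naive definition. With this choice,
planted sites of strength 30 over a 0.01 reads/nt background are
recovered with mean summit error below the simulator's 2-nt jitter sd.

**Consensus.** Control peaks are subtracted per experiment *before*
consensus (≥1 nt same-strand overlap). Regions covered by peaks from
≥k of the experiment sets (interval-level overlap; whether the
published analysis used summit- or interval-level support is unknown,
interval is implemented) are merged with their contributing peaks, and
pooled reads intersecting the merged regions are re-called. The
re-call randomizes over the whole gene span (pass `spans`), not the
merged region: restricting the null to a region barely wider than the
peak makes the observed profile typical of the null and kills all
signal — a pitfall the test suite demonstrates indirectly by using
`spans` everywhere.

## Binding annotation

Summit categories use the precedence CDS exon > 5'UTR > 3'UTR >
intron, representative transcript first and then any isoform. The
precedence across overlapping isoforms is not documented for the
original analysis; ours favours exonic calls, is configurable in
effect (annotate against any `tx_annotation`), and sums to 1 over the
four categories after dropping intergenic summits.

The exon-end metaprofile's null re-draws each summit uniformly *within
its host exon*, holding the exon-length composition fixed; a
genome-wide null would confound composition with position. Profiles
are truncated at `max_dist` (distances beyond it are dropped, not
clamped); with `max_dist` below the minimal internal exon width the
null is flat up to Monte-Carlo noise, which is what the acceptance
criterion checks.

Motif scanning takes the 20-nt summit-centred window, already
sense-oriented (minus-strand windows are reverse-complemented), so the
reverse complement is never scanned separately. PWM matches use
Biostrings `matchPWM` at 80% of the maximal score by default; IUPAC
strings match degenerately.

## CLIP+/CLIP− introns

A read increments an intron when it overlaps it by ≥5 nt on the same
strand, and counts toward exactly one intron — the largest overlap,
leftmost on ties (with a single intron set per gene the case is rare
by construction). The per-experiment CLIP+ rule is
`count >= 5 * control` when the control has reads, else `count >= 5`;
CLIP+ requires the rule in ≥2 of 3 experiments (support 3 is reported
separately as the stringent stratum), CLIP− requires `count <= control`
in *every* experiment. Counts are compared raw, as published — the
rule has a depth confound when control libraries are much shallower,
and `control_scale` exposes a depth-corrected sensitivity analysis.
Whether the published rule compared pooled or per-experiment counts
before the 2-of-3 vote is ambiguous; per-experiment is implemented, as
written.

The expression filter drops introns of genes whose median-of-ratios
normalized count (the DESeq estimator, re-implemented and checked
against DESeq2 on random matrices) is below 1.

Splice-site strength is a pluggable scorer. The default trains
first-order PWMs on the annotation's own donor 9-mers (3 exonic + 6
intronic bases) and acceptor 23-mers (20 intronic + 3 exonic) with a
0.5 pseudocount against a uniform background, reported as log2-odds.
The published maximum-entropy parameterization can be supplied as any
function with the same signature; re-deriving it is out of scope.

## Splicing quantification

`psi = 100·ī/(ī+e)` with ī the mean of the two inclusion junction
counts; `pir = 100·b̄/(b̄+j)` with b̄ the mean of the two exon–intron
boundary counts and j the spliced junction count. A pir estimate is
flagged unreliable when total coverage is below `e` or the two
boundary counts are grossly unbalanced (ratio > 5; one empty boundary
against a non-empty one counts as infinite). The exact reliability
rule of the originating pipeline is unspecified; this balance rule is
our choice and is configurable. Intron-body reads are not used — only
boundary and spliced-junction reads.

The differential filter follows the −r/−m/−e contract: per condition,
replicate counts are pooled and the inclusion fraction given a
`Beta(supporting+1, opposing+1)` posterior; `prob_accept` is the
Monte-Carlo probability that the conditions differ by ≥ m percent
(default 10), and acceptance needs `prob_accept >= r` (default 0.95)
plus ≥ e (default 10) reads in every sample. The originating
pipeline's internal probability model is not public; the Beta
posterior on pooled counts is the simplest model satisfying the
quoted acceptance semantics, and swapping conditions provably negates
Δ while preserving `prob_accept`. Replicates are pooled rather than
hierarchically modelled — with planted effects the operating
characteristics (recall ≥ 0.9 at |Δ| = 20, depth 500; false acceptance
≤ 0.05 at Δ = 0) are met, which is the contract the tests enforce.

Direction bias per event class is a 1-df χ² goodness-of-fit of the two
direction counts against 50:50, no continuity correction.

## Integration

RNA maps partition accepted cassette calls into *enhanced* (more
skipped upon depletion — the factor enhances inclusion) and *silenced*
(more included), plus a control pool (reference PSI in [10, 90],
|Δpsi| < 5, ≥1 peak in the region); only events with ≥1 peak summit in
the region (upstream constitutive exon through downstream constitutive
exon, shortest flanking exons when several are annotated) enter any
group, and no event is in two groups. Exonic and intronic 50-nt
splice-site flanks are binned at 5 nt and normalized by the group's
event count; intron positions are also reported as relative position
(0 = 5' splice site, 1 = 3' splice site). Peaks are not matched to
events: all same-strand summits on the chromosome are profiled per
event, so overlapping neighbouring events can contribute stray counts
— visible, and accepted, in the recovery tests.

Rank-based group comparisons (Δpir CLIP+ vs CLIP−, feature contrasts)
use an exact mid-rank enumeration for ≤12 observations — where
`wilcox.test` would silently fall back to a normal approximation under
ties — and `wilcox.test` otherwise. Fisher tests are one-sided
(greater); no |Δpir| floor is applied before the CLIP+/− density
comparison.

## The simulators: what they emulate, what they do not

`sim_genome()` builds one chromosome of multi-exon genes (alternating
strands, one transcript per gene, CDS from mid-first-exon to
mid-last-exon) with two intron classes: *optimal* (log-normal length,
median 1500 nt; GC 0.40; consensus-strength splice sites) and
*suboptimal* (0.5× median length; GC 0.55; splice-site PWMs mixed 50:50
with uniform, GT..AG kept invariant), 30% suboptimal. These effect
sizes are the package's fixed "stated world": median human intron
length is in the low thousands, exons ~150 nt, and a 2-fold length /
0.15 GC contrast is the magnitude a bound-vs-unbound intron comparison
reports as strongly significant. `sim_binding_sites()` couples
intronic sites to suboptimal introns with probability 0.8, so the
feature contrast is recoverable by design.

`sim_iclip()` emits reads as single-nucleotide cross-link points
(Poisson per site, strength 30 by default, normal jitter sd 2 nt) over
a uniform 0.01 reads/nt background on gene spans; replicate depth
factors (1, 1, 0.5) exercise the 2-of-3 consensus, and the control
keeps the background, removes the sites, and runs at 0.2× depth —
the ~5× shallower control library of a typical iCLIP design.

`sim_splice_counts()` draws the two supporting counts and the opposing
count independently as Poisson with means `depth·p` and `depth·(1−p)`,
making the PSI/pir estimators consistent as depth grows (checked at
depths 10²–10⁶).

Not emulated: sequencing errors, mappability and fragment-length
biases, multi-isoform genes, overdispersion across replicates,
correlated background structure, and intron-body reads. A green
recovery test therefore establishes that the *algorithms* recover what
was planted under clean noise — not that any particular biological
dataset will behave as cleanly.

## Numerical notes and degenerate inputs

* Zero reads in a gene yield an empty peak set, not an error; a gene
  with no height reaching the FDR threshold likewise.
* All-zero splicing events quantify as `NA` and are excluded.
* Every stochastic function takes a `seed`; per-gene and per-stage
  seeds are derived from the global seed so results are independent of
  iteration order and reruns are byte-identical.
* `size_factors()` errors when no gene is nonzero in all samples —
  there is no defensible normalization in that case.
* Summit ties break leftmost; representative-transcript ties break as
  described above; both are arbitrary but fixed.

## Known limitations

The consensus re-call needs gene spans to be statistically sensible
(see above). The read-count CLIP+ rule inherits the published depth
confound. The RNA map profiles all peaks per event rather than
assigning each peak to one event. The Beta-posterior acceptance model
treats replicates as exchangeable pools. The default splice-site
scorer is a first-order PWM, weaker than a maximum-entropy model at
ranking near-consensus sites.
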