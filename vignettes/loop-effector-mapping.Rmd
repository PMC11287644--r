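---
title: "Mapping GWAS variants to effector genes through chromatin loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GWAS variants to effector genes through chromatin loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopGWAS)
```

## The problem and the model

Most risk variants for complex musculoskeletal disease lie in non-coding
DNA. A fine-mapped credible set tells us *where* the causal variant of a
GWAS signal is likely to be, but not *which gene* it acts on. Chromatin
loops measured by Hi-C supply a physical hypothesis: if the variant sits in
an active enhancer on one loop anchor, the genes with active promoters on
the contacted anchor are the natural effector candidates. loopGWAS encodes
that reasoning as a deterministic pipeline over standard file formats, plus
an approximate Bayes factor (ABF) colocalisation step that asks whether the
GWAS signal and a molecular QTL for the candidate gene share a single
causal variant.

All interval logic uses bedtools-style semantics: an overlap is at least
one shared base, with no distance slack. Internally coordinates follow the
GRanges convention (1-based, closed); BED/BEDPE input and output are
converted at the boundary, and 1-based variant positions are used as given.

## Loop integration

Loop callers disagree, both between algorithms and between the 5 kb and
10 kb resolutions of the same algorithm, with anchors jittered by roughly a
bin. We therefore merge loop calls whose forward anchors overlap *and*
whose reverse anchors overlap, taking the transitive closure of that
pairwise relation (connected components) and replacing each component by a
single loop whose anchors are the enclosing range of the member anchors.
The same operation merges resolutions within a caller and unions loops
across callers; the merged loop records its supporting caller set. Two
deliberate choices:

* **Merge criterion.** Reciprocal ≥ 1 bp overlap of both anchors is the
  simplest deterministic criterion; the test suite pins it against an
  independent union-find oracle. No merge distance parameter is introduced.
* **Self-overlap filter.** After union-anchor merging, a loop's two anchors
  can come to overlap each other; such loops are ambiguous (the "loop"
  would connect a region to itself) and are removed, with the count
  reported.

Anchor sides are positional — "forward" is the left anchor by coordinate —
and CTCF QC ignores motif strand, reporting the fraction of forward and
reverse anchors containing at least one motif. Whether published per-caller
CTCF ratios are strand-specific is not stated in the sources this design
follows; the positional reading is the conservative one and is what the QC
report documents. The same motif overlap, applied to TAD boundary
intervals, gives the boundary coverage metric.

## Activity classification

A candidate cis-regulatory element is called **active** from two kinds of
evidence: open chromatin (one consensus ATAC peak set, as typically
produced upstream by a k-of-n sample consensus — `consensusPeaks()` builds
one when per-replicate tracks are all that is available) and
replicate-thresholded histone marks. A promoter needs H3K4me3 and H3K27ac,
an enhancer H3K4me1 and H3K27ac, each in at least `chipMinReps` (default 2)
of the ChIP replicates. The rule is monotone: adding peaks can only turn
elements on, never off — a property the tests check alongside an exhaustive
truth-table enumeration of all evidence combinations.

ATAC overlap is required for enhancers as well as promoters, applied
uniformly to every element rather than only to the variant-harbouring
subset. Promoter-to-gene annotation searches a window 1500 bp upstream and
500 bp downstream of the promoter *element*; because an element has no
strand, the window is genomically left/right on the element, while the TSS
of each gene is strand-aware (transcript start for `+`, transcript end for
`-`) as recorded in the gene table. This reading is recorded in the run
metadata so users who prefer a gene-strand-oriented window can see exactly
what was done.

## Variant chaining

Credible-set variants are filtered at posterior probability **strictly
greater than** 0.03 (the ">3%" convention; a variant at exactly 0.03 is
dropped, and the threshold is configurable). A variant "hits" an anchor
when its single base lies inside the anchor interval — SNVs only; an indel
is represented by its first base. Wide anchors can contain a variant on
both sides of a loop; both hits are kept and chains are deduplicated by
(variant, enhancer, promoter, loop path).

* **1-hop chains**: variant in an active enhancer on one anchor, active
  promoter(s) on the opposite anchor of the same loop.
* **2-hop chains**: when the opposite anchor carries only active enhancers
  and *no* active promoter, every other loop touching that anchor is
  followed one further step; an active promoter on its far anchor closes
  the chain. Exactly one extra hop is allowed — no transitive closure —
  because each hop dilutes the physical-contact evidence.

Loops in which neither anchor overlaps any cCRE are screened separately:
an anchor that itself satisfies the enhancer evidence rule is reported as a
candidate novel regulatory region. QTL records join chains by rsid alone;
positional fallback is deliberately not attempted because rsid-keyed QTL
tables are the norm and positional joins silently mismatch assemblies.
Pairwise LD between lead and credible-set variants is the squared Pearson
correlation of genotype dosages (`ldR2`).

## Colocalisation

For each trait, the Wakefield log ABF of every shared variant is
`0.5 * log(1 - r) + 0.5 * r * z^2` with `r = W / (V + W)`, `V = se^2`,
`z = beta / se`, and prior effect variance `W`. The prior SD defaults to
0.15 for quantitative traits and 0.2 (log-odds) for case-control — the
standard defaults of the ABF method, since the method's published
applications rarely restate them — and both are configurable, as are the
hypothesis priors `p1 = p2 = 1e-4`, `p12 = 1e-5`. All hypothesis sums are
computed in log space; the H3 cross-term uses

    log(sum_{i != j} exp(L1_i + L2_j)) = logdiffexp(S1 + S2, S12)

with a guard returning −∞ when `S12 >= S1 + S2` within rounding (as in the
single-variant case, where no distinct pair exists and PP.H3 is exactly 0).
Posteriors are renormalised after exponentiation and sum to 1 within 1e-12
for any input. Where several phenotypes share a signal, the lead phenotype
is the panel whose lead variant has the smallest two-sided normal p-value
of beta/se, compared on |z| so that extreme signals do not tie at an
underflowed p = 0; remaining ties break lexicographically on the trait
label. Variants are matched by rsid only — allele harmonisation (strand
flips, effect-allele swaps) is out of scope, and real-data users must
harmonise panels beforehand.

## The synthetic scene and what it does (not) show

`generateScene()` plants a complete miniature study with unambiguous
ground truth. Its geometric defaults are fixed design choices:

* 2 chromosomes × 5 Mb, 200 loops, 20 signals, 4 callers — seconds-scale
  runtime with non-trivial multiplicity at every stage.
* Each loop occupies its own 50 kb block; anchors are 5 kb (or 10 kb at the
  coarser resolution), per-caller jitter is N(0, 500 bp) truncated at 2 kb
  so that all copies of a true loop still overlap and merge back to one.
* Planted elements are 800 bp, mutually non-overlapping and at least one
  anchor-width apart, so chain recovery has no tie-breaking ambiguity and
  precision = recall = 1 is the correct expectation, not a tolerance.
* Signals split into 1-hop chains (`frac_ep_loops`), 2-hop chains
  (`n_ee_chains`), inactive-enhancer and anchor-only negatives. Each signal
  also gets decoy variants that straddle the 3% filter: one above threshold
  inside the anchor but outside any cCRE, one above threshold outside all
  anchors, one at exactly 0.03 and one below. The funnel counts are thereby
  known exactly in advance.
* CTCF motifs are planted in 90% of forward and 85% of reverse anchors
  (real per-caller ratios of 75–96% motivate the range), and 38 of 40 TAD
  boundaries carry a motif.
* Association panels use `se = 1/sqrt(2 * maf * (1 - maf) * n)` — the
  standard quantitative-trait approximation — with causal |z| = 8 under the
  shared/distinct scenarios.

What passing on this scene does **not** show: the generator's panels are
LD-free, its loops are cleanly separated, its peaks are noise-free
rectangles, and element activity is binary by construction. Real data has
overlapping elements, correlated variants and borderline peaks; the tests
demonstrate algorithmic correctness under known truth, not robustness to
those ambiguities.

## Numerical and degenerate-input choices

* Merged-loop ids are a deterministic content hash of the sorted member
  ids, so re-runs and input permutations give identical output files.
* Zero loops yield CTCF ratios reported as 0; an empty TAD boundary set is
  an error (the coverage fraction is undefined).
* Outputs are byte-deterministic given inputs; the only timestamp lives in
  `run_metadata.json`.
* Problem sizes in the test suite — 10 kb mask-oracle chromosomes, 200-loop
  merge fixtures over 20 seeds, 100 colocalisation replicates of 500
  variants, 10 end-to-end seeds — were chosen as the smallest scales at
  which every stage still multiplexes (several chains per kind, several
  callers, several scenarios).

## Known limitations

Single-causal-variant colocalisation only (no SuSiE-style multi-signal
decomposition, no LD-aware extension); no allele harmonisation; no
liftover between genome builds (all inputs must share one assembly); loop
calling, peak calling and fine-mapping are consumed as inputs, never
re-done.
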