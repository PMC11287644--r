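# loopGWAS

Maps fine-mapped GWAS credible-set variants to candidate effector genes
through chromatin loops, and tests GWAS/molecular-QTL signal pairs for a
shared causal variant by approximate Bayes factor colocalisation.

Genome-wide association signals for complex diseases such as osteoarthritis
mostly fall in non-coding regulatory DNA, so the affected gene is rarely the
nearest one. Hi-C chromatin loops provide the missing link: a variant
sitting in an **active enhancer** on one loop anchor can regulate the gene
whose **active promoter** sits on the opposite anchor. This package
implements that mapping as a tested, reusable pipeline for anyone holding
loop calls (from one or more loop-calling algorithms), epigenomic peak
tracks, and fine-mapping output:

1. **Loop integration & QC** — per-caller merging of 5 kb and 10 kb loop
   calls, removal of loops whose two anchors overlap each other, CTCF-motif
   anchor QC ratios, TAD-boundary CTCF coverage, and a cross-caller union.
   Loops whose forward anchors overlap *and* whose reverse anchors overlap
   are grouped by transitive closure and replaced by one loop with
   union anchors.
2. **Activity classification** — a cCRE promoter is *active* when it lies
   in ATAC open chromatin and overlaps H3K4me3 and H3K27ac peaks in ≥ 2 of
   3 ChIP replicates; an enhancer likewise with H3K4me1 in place of
   H3K4me3. Active promoters are annotated to genes with a TSS within
   1500 bp upstream / 500 bp downstream of the promoter element.
3. **Variant chaining** — credible-set variants with posterior probability
   of causality > 3% are overlaid with loop anchors, then with active
   enhancers; enhancer–promoter (1-hop) and enhancer–enhancer–promoter
   (2-hop) chains yield candidate effector genes; cCRE-free anchors with
   full enhancer evidence are reported as candidate novel regulatory
   regions; molecular QTL records (eQTL/pQTL/methQTL) are joined by rsid.
4. **Colocalisation** — per-variant Wakefield log approximate Bayes
   factors; with V = se², W = prior SD², r = W/(V+W), z = β/se:

   log ABF = ½·log(1 − r) + ½·r·z²

   Hypothesis sums are carried in log space (H3's cross-term via
   log Σ_{i≠j} = logdiffexp(S1 + S2, S12)) and normalised to the posteriors
   PP.H0–PP.H4, with PP.H4 > 0.8 the conventional evidence for a shared
   causal variant. Default priors p1 = p2 = 1e-4, p12 = 1e-5.
5. **Synthetic data** — a seeded generator writes a complete miniature
   input bundle (BEDPE loops with per-caller anchor jitter, CTCF/TAD/cCRE/
   peak BEDs, credible-set, QTL and summary-statistic tables) with planted
   ground truth for every stage, so the whole pipeline is testable
   end-to-end with known answers.

## Worked example

```r
library(loopGWAS)

scene <- generateScene(sceneSpec(seed = 1), "scene")
res   <- runPipeline(runConfig("scene", "scene/out"))

res$table1
#>        caller loops  ctcf_fwd  ctcf_rev ep_loops ap ae snp
#> 1        fanc   196 0.8877551 0.8367347       23 51 81  13
#> 2 hicexplorer   196 0.8877551 0.8367347       23 51 81  13
#> 3    mustache   196 0.8877551 0.8367347       23 51 81  13
#> 4         sip   196 0.8877551 0.8367347       23 51 81  13

res$funnel
#>                 stage   n
#> 1      credible_total 100
#> 2       credible_pass  60
#> 3          in_anchors  40
#> 4 in_active_enhancers  13
#> 5      chain_variants  13
```

One row of `table1` per loop caller: retained loops after resolution
merging and the self-overlap filter, the fraction of forward/reverse
anchors containing a CTCF motif, enhancer-promoter loop count, active
promoters (AP) and enhancers (AE) on anchors, and active enhancers
containing a credible variant (SNP). The funnel shows the variant counts
narrowing from all credible-set variants, through the PP > 3% filter, to
variants in loop anchors and finally in active enhancers.

`res$chains` lists each variant → enhancer → (hop enhancer →) promoter →
gene chain with its joined QTL annotations, and `res$coloc` the posterior
hypothesis probabilities per QTL-supported signal, e.g.

```r
head(res$coloc[c("signal_id", "pp_h3", "pp_h4")], 3)
#>   signal_id        pp_h3        pp_h4
#> 1       S01 1.080025e-15 1.000000e+00
#> 2       S03 6.853978e-05 2.735035e-04
#> 3       S04 7.337280e-10 9.999999e-01
```

A thin command-line wrapper with `simulate`, `run`, `qc` and `coloc`
subcommands is installed at `inst/scripts/loopgwas.R`.

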