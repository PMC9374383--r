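# tilecrispr

Protein-domain-resolution analysis of Cas9 tiling screens, with matched
dual-fluorescence reporter statistics and a ground-truth simulator.

## The problem

A conventional CRISPR knockout screen asks whether a *gene* is essential. A
tiling ("domain scanning") screen asks *which parts of its protein* are: an
sgRNA library covering every NGG-PAM site in a coding sequence is transduced
into cells, and guide representation is sequenced at the start and end of a
growth competition. Frameshift alleles (about two thirds of Cas9 repair
outcomes) knock the gene out wherever they land, but small in-frame indels
impair fitness only when they disrupt an essential functional domain — so the
*position-dependent* component of guide dropout maps essential domains at
near-residue resolution. The approach identified the GTPase and ETF1-binding
regions of the translation termination factor GSPT1 as the parts of the
protein that leukemia cells cannot live without, and the same study
quantified the downstream phenotype — stop-codon readthrough — with
BFP–stop–GFP flow reporters.

`tilecrispr` implements that computational workflow end to end for R users
(Bioconductor idiom: S4 classes over `DataFrame`/`SummarizedExperiment`):

* **Library design** — `enumerateGuides()` finds every 20-nt protospacer with
  an NGG PAM on either strand of a CDS, assigns the blunt cut site (between
  protospacer positions 17|18, 3 nt 5′ of the PAM) a coding-strand coordinate
  and the first disrupted codon; `assembleLibrary()` adds essential-gene
  (positive) and nonessential (negative) control guides.
* **Dropout scoring** — for guide *g* and replicate *r*, the CRISPR score is
  the change in library frequency, *CS(g,r) = f(g, day 22, r) / f(g, day 0,
  r)*, so *CS = 0.1* means 10-fold depletion. Guides with day-0
  representation ≤ 5 % of the expected 1/N are removed, replicates are
  combined by median, and scores are anchored to the controls on the log10
  scale: *z = (x − m⁻) / (m⁻ − m⁺)*, where *m⁻*, *m⁺* are the
  negative-/positive-control medians — so nonessential controls sit at 0 and
  essential-gene controls at −1 by construction (`scoreScreen()`).
* **Domain calling** — `residueProfile()` averages z over guides cutting
  within a ±5-residue window of each amino acid, `callEssentialSegments()`
  extracts sub-threshold runs, and `annotateSegments()` reports
  overlap/Jaccard against known domain intervals, with GC-rich guides
  (potential off-target dropout, e.g. over a polyglycine repeat) flaggable
  via `flagGCArtifacts()`.
* **Reporter statistics** — `mfiRatio()` and `reporterFoldChanges()` compute
  GFP/BFP mean-fluorescence ratios and their fold change versus vehicle
  (readthrough: fold > 1; drug-induced degradation: fold < 1), with exact
  Wilcoxon rank-sum contrasts by dose/stop-codon/time and Kruskal–Wallis
  tests (`readthroughTests()`), plus the fluorescence-tracked competition
  assay (`competitionFoldChange()`).
* **Simulation** — `simulateScreenCounts()` draws multinomial (optionally
  Dirichlet-multinomial) read counts under a two-outcome growth model
  (frameshift vs in-frame lesion, each with its own selection coefficient)
  and `simulateReporterEvents()` generates per-cell flow events with known
  readthrough/degradation truth, so every stage of the pipeline can be
  validated against ground truth without any external data.

## Worked example

Simulate a screen of the study's shape — 260 tiling guides over a 499-codon
protein plus 22 essential and 41 nonessential controls, in triplicate at days
0 and 22 with 3.2 × 10⁶ reads per sample — with one 50-aa essential domain at
residues 200–249 (selection coefficient 0.8 against in-frame lesions), then
recover it:

```r
library(tilecrispr)

lib    <- simulateTilingLibrary(seed = 1)
truth  <- trueModel(data.frame(name = "GTPase-like",
                               start_aa = 200, end_aa = 249),
                    geneEssential = FALSE, aaLength = 499)
cfg    <- screenSimConfig(seed = 42)
counts <- simulateScreenCounts(lib, truth, cfg)

res <- runTilingPipeline(counts, lib,
                         zThreshold = expectedAnchoredZ(cfg) / 2)
anchorStats(res$scores)
#> $m_neg
#> [1] 0.03402108
#> $m_pos
#> [1] -0.4437005
#> $separation
#> [1] 78.13189

res$segments
#>   start_aa end_aa length_aa      min_z     mean_z
#> 1      204    253        50 -0.3798601 -0.3534776

annotateSegments(res$segments,
                 data.frame(name = "GTPase-like",
                            start_aa = 200, end_aa = 249))
#>   segment_start segment_end      domain domain_start domain_end overlap_aa
#> 1           204         253 GTPase-like          200        249         46
#>   domain_fraction   jaccard
#> 1            0.92 0.8518519
```

The controls separate cleanly (separation ≈ 78 on an SSMD-like scale), one
depleted segment is called, and it recovers the true domain at Jaccard 0.85.
Because this configuration isolates the in-frame signal (the gene is not
essential for frameshift), the calling threshold is set to half the
attainable in-frame depletion, `expectedAnchoredZ(cfg)/2` ≈ −0.18, rather
than the default −0.5 used when knockout signal is present; the methods
vignette (`vignettes/tiling-screen-methods.Rmd`) derives this.

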