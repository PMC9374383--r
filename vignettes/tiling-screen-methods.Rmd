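---
title: "Methods: domain-resolution tiling screens, reporter ratios, and the simulation model"
author: "tilecrispr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-resolution tiling screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilecrispr)
```

# Why tile a single gene

Frameshift alleles produced by Cas9 cutting inactivate a gene wherever they
occur, but roughly a third of repair outcomes are in-frame indels, and those
impair fitness only when they damage a functional domain. In a library that
tiles every NGG-PAM site of one coding sequence, *all* guides share the
frameshift component of dropout; the **position-dependent excess** dropout
localises essential domains. This vignette documents the models, parameter
choices and numerical conventions the package uses, and what its simulations
do and do not establish.

# Guide enumeration conventions

`enumerateGuides()` applies four explicit conventions where the experimental
description leaves room:

* **Containment.** The full 23-nt protospacer + PAM window must lie inside
  the CDS. A boundary rule has to be picked for reproducibility; requiring
  full containment is the strictest and simplest.
* **Both strands.** NGG sites are scanned on the coding strand and its
  reverse complement, the standard practice for Cas9 libraries. Minus-strand
  cut coordinates are re-expressed on the coding strand, so enumeration is
  reverse-complement symmetric (strands swap, `cut_nt` maps to `L − cut_nt`;
  this is property-tested).
* **Cut site.** The blunt SpCas9 cut falls between protospacer positions 17
  and 18 (3 nt 5′ of the PAM). `cut_nt` is the coding-strand nucleotide
  immediately 5′ of the cut, and the residue assignment is the codon
  containing `cut_nt + 1` — the first codon the cut disrupts:
  `cut_aa = floor(cut_nt / 3) + 1`.
* **Duplicates.** Identical protospacers are collapsed to one record by
  default (one sgRNA = one sequence in a pooled library), retaining all cut
  sites in `all_cut_nt`; the first site in coding order serves as the
  primary coordinate. Disable with `collapseDuplicates = FALSE` to study
  multi-site guides.

Correctness is established against a brute-force oracle — slide every 23-nt
window over the sequence and its reverse complement and keep windows ending
in GG — on hundreds of random sequences, rather than against any particular
published guide list, whose boundary and duplicate conventions are not
machine-checkable.

# Scoring model

For guide $g$ and replicate $r$, with read frequencies
$f(g, s) = (n_{gs} + c) / \sum_g (n_{gs} + c)$,

$$\mathrm{CS}(g, r) = \frac{f(g,\ \text{day }22,\ r)}{f(g,\ \text{day }0,\ r)},$$

so a score of 0.1 means a 10-fold depletion. Numerical conventions:

* **Pseudocount** $c = 1$ read by default. Guides in essential domains are
  *expected* to reach zero day-22 counts at lethal selection; a pseudocount
  keeps their scores finite while changing well-measured guides negligibly
  (day-0 counts are ~10⁴ at default depth). $c = 0$ reproduces raw ratios
  and errors informatively on division by zero.
* **QC** uses the day-0 samples as the representation baseline (they are
  sequenced per replicate, unlike the plasmid pool, which need not be
  available) with a *strict* inequality: pass iff mean day-0 frequency
  $> 0.05 / N$.
* **Replicate combination** is the median (robust to one failed replicate);
  mean is available by argument.
* **Scale.** z anchoring operates on $\log_{10} \mathrm{CS}$ by default:
  depletion and enrichment become symmetric and the 10-fold-depletion guide
  sits at $-1$ before anchoring. A linear mode is provided since z is
  invariant to any increasing affine transform of the chosen scale — the
  choice of scale only matters for how *intermediate* effects interpolate
  between the anchors.
* **Anchoring.** With $m^-$, $m^+$ the medians of the QC-passing negative
  (nonessential) and positive (essential-gene) controls,
  $z = (x - m^-)/(m^- - m^+)$. The control medians land exactly on 0 and
  $-1$ by construction — this is an identity, not a statistical estimate —
  and equal control medians are a hard error, since the scale is then
  undefined. QC-failing guides get no z and are excluded from the medians.
* **Day-12 samples** (or any intermediate timepoint) are carried in the
  container and ignored by default scoring, which compares day 22 to day 0.

# Control separation gating

Anchored z is a *relative* scale: it divides by $m^- - m^+$. If the two
control sets do not actually separate — a failed screen, or a simulation with
selection switched off — that denominator is pure sampling noise and z
explodes. `runTilingPipeline()` therefore computes an SSMD-like separation
statistic,

$$\mathrm{sep} = \frac{m^- - m^+}{\sqrt{\mathrm{MAD}^2_- + \mathrm{MAD}^2_+}},$$

and suppresses segment calling when it falls below 2, a conventional
"informative assay" cutoff for control-based screen QC. Selective screens at
default simulation settings sit near 80–90 on this scale; selection-free
screens near 0. Gating is a pipeline-level decision: `callEssentialSegments()`
itself remains a pure function of the profile so that thresholds can be
studied in isolation.

# Residue profiles and segment calling

`residueProfile()` averages z over guides with $|cut_{aa} - a| \le w$ for
each residue $a$. Defaults:

* `windowRadius = 5` residues. At the ~1 guide/8 bp density of a dense
  tiling library (one guide per ~2.7 codons), an 11-residue window averages
  roughly 4 guides — enough to suppress single-guide noise without blurring
  a 50-aa domain's boundaries by more than the window itself.
* The window statistic is the **mean**, not the median: with ~4 values per
  window the median is unstable and discards half the information.
* `callEssentialSegments()` reports maximal runs of at least `minRun = 5`
  consecutive *covered* residues with mean z at or below the threshold;
  uncovered residues (no guide within the window) break runs rather than
  being interpolated.
* `flagGCArtifacts()` flags guides with protospacer GC ≥ 0.8 (boundary
  inclusive, so a 92%-GC guide is flagged at a 0.92 threshold). Extremely
  GC-rich tracts such as polyglycine repeats invite off-target dropout;
  excluding flagged guides from the profile is optional because the flag
  marks *suspicion*, not established artifact.

## Choosing the calling threshold

The default `zThreshold = -0.5` is halfway from the neutral anchor (0) to
the essential-gene anchor ($-1$): appropriate when the dropout signal of
interest includes the knockout (frameshift) component.

When the analysis isolates the **in-frame** component — as the simulator's
recovery benchmark does by making the gene nonessential for frameshift —
there is a hard ceiling on attainable depletion. Under the two-outcome
model below, an in-frame-lethal domain guide retains a fraction $\phi$
(the frameshift probability) of neutral growth, while positive controls
retain $1 - \phi$; on the anchored scale the deepest reachable z is

$$z_{\max} = \frac{\log_{10} \phi}{-\log_{10}(1-\phi)} \approx -0.37
\quad (\phi = 2/3),$$

computed by `expectedAnchoredZ()`. A $-0.5$ threshold can never be reached
in this regime. The package therefore applies the same halfway logic to the
attainable anchor: recovery analyses call at `expectedAnchoredZ(cfg)/2`
(≈ $-0.18$ at defaults). This is a property of the effect-size model, derived
in closed form, not a fitted constant.

# Reporter quantification

* **MFI** is the arithmetic mean of live-gated intensities (geometric mean
  available, as flow conventions differ), and the readout is
  $\mathrm{MFI}_{GFP} / \mathrm{MFI}_{BFP}$ per condition, then fold change
  against the matched vehicle condition (same construct, stop codon, time
  and replicate). Fold changes are computed per replicate and summarised
  afterwards, never on pooled events.
* **Live gating** uses an explicit `live` flag; forward/side-scatter
  modelling is out of scope, so synthetic events carry the flag directly.
* **Tests.** Rank-sum contrasts (adjacent doses within codon × time; codon
  pairs within dose × time) use the exact two-sided distribution for group
  sizes up to 8 without ties, and the tie-corrected normal approximation
  otherwise; dose-response within a codon × time cell also gets a
  Kruskal–Wallis test. Raw p-values are reported at α = 0.05 with no
  multiplicity correction, matching how such reporter panels are usually
  reported.
* **Competition assay.** For a fluorescently tracked sgRNA population,
  $\mathrm{fold} = \frac{\%^+(\text{drug}, t)/\%^+(\text{drug}, 0)}
  {\%^+(\text{vehicle}, t)/\%^+(\text{vehicle}, 0)}$; per-gene summaries
  average over that gene's guides with a standard error.

# The simulation model

`simulateScreenCounts()` emulates the screen at the level that matters for
the statistics, not the biology of repair:

1. Plasmid abundances $a_g \sim \text{Lognormal}(0, \sigma)$, normalised
   ($\sigma = 0.5$: a typical oligo-pool spread, ~3-fold between quartile
   extremes).
2. Each edited cell is frameshift with probability $\phi = 2/3$ (the
   standard indel-outcome assumption; configurable) or in-frame otherwise.
3. Populations grow exponentially at $d$ doublings/day for $t$ days; guide
   $g$'s expected share at day $t$ is proportional to
   $a_g \left[\phi\, 2^{dt(1 - s_{ko,g})} + (1-\phi)\, 2^{dt(1 - s_{if,g})}\right]$
   with $s_{ko,g} = s_{ko}$ for positive controls and for target guides of
   an essential gene, and $s_{if,g} = s_{domain}$ for target guides cutting
   inside an essential domain; negative controls are neutral.
4. Counts are multinomial at the configured depth (default 3.2 × 10⁶
   reads/sample ≈ 2000× representation for 323 guides), independent per
   replicate; a Dirichlet-multinomial option adds overdispersion.

Defaults describe the emulated screen: triplicate, days 0 and 22, one
doubling per day (so ~4 × 10⁶-fold expansion, comfortably past the
10,000-fold the protocol guarantees), $s_{ko} = 1$ (knockout of an essential
gene is lethal), $s_{domain} = 0.8$ (in-frame damage to an essential domain
is strongly but not perfectly deleterious — the experimental literature gives
no measured value; this is a testability choice, *not* an estimate of any
real screen, and results should not be read as such).

`simulateTilingLibrary()` generates a GC-biased (62%) random CDS of 499
codons, enumerates its guides, evenly thins them to 260 and adds 22 + 41
random-sequence controls, reproducing the composition and ~1-guide/2.7-codon
density of the motivating library. `simulateReporterEvents()` draws BFP
lognormal and sets $GFP = r(1-\text{deg})\,k\,BFP\,\varepsilon$ with
multiplicative lognormal noise $\varepsilon$, so the expected MFI-ratio fold
change against an $r = 1$ vehicle is exactly $r$.

**What the simulations do not model:** indel spectra and allele dynamics
within a cell population, PCR jackpots, off-target cutting (GC flagging
exists precisely because real data have it and the simulator does not),
cell-cycle structure, scatter-based gating, compensation/spillover.
Passing recovery benchmarks therefore demonstrates that the *analysis*
is correct and well-calibrated under its stated model — not that the model
captures every failure mode of real screens.

# Reproducibility and problem sizes

All stochastic functions take explicit seeds, draw from a private RNG stream
and restore the caller's; fixed seed means byte-identical output, and the
scoring pipeline itself is deterministic. The validation suite exercises the
screen simulator at its default depth (3.2 × 10⁶ reads, 323 guides) across
50-seed ensembles for the domain-recovery and null-calibration benchmarks,
and the reporter estimator at 10⁴ events × 20 seeds — sizes chosen so the
Monte-Carlo error of each benchmark is far below its acceptance margin while
the whole suite stays interactive.

# Known limitations

* Segment calls carry no significance measure (no permutation p-values);
  the separation gate protects against uninformative screens, not against
  locally correlated noise in an informative one.
* Guide coverage gaps longer than the window radius split segments; with
  sparse libraries, increase `windowRadius` deliberately rather than
  relying on defaults.
* The enumeration targets SpCas9 NGG only; alternative PAMs, efficiency
  scores (on/off-target), and intron-aware genomic coordinates are out of
  scope.
* Reporter analysis starts from event tables; FCS parsing and compensation
  belong to upstream flow tooling.
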