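---
title: "Calling demethylase-sensitive methylation changes: methods and design"
author: "demethr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling demethylase-sensitive methylation changes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demethr)
```

## The scientific problem

Plant DNA glycosylases actively remove 5-methylcytosine. In maize seed the
endosperm is genome-wide hypomethylated relative to the embryo, and this
hypomethylation is concentrated on the maternal genome. `demethr`
implements the computational pipeline used to characterise such a system
from whole-genome bisulfite sequencing (WGBS), RNA-seq and DAP-seq data:
where does methylation rise when demethylases are knocked out, which of
those regions coincide with tissue hypomethylation (the operational
definition of a demethylase target), what happens to the expression of
nearby genes, to endosperm-specific genes, to imprinted genes, and to
transcription-factor binding.

Because real WGBS input at maize scale is far too large for unit testing,
the package ships a first-class synthetic-data module. Every analysis
stage can be exercised against data with *planted ground truth*, and the
test suite does exactly that.

## Weighted methylation level

All methylation summaries use the count-weighted level
$$m = \frac{\sum_i \text{meth}_i}{\sum_i \text{total}_i}$$
over a set of cytosines, not the mean of per-site ratios. The two agree
only at uniform coverage; weighting by counts makes pooled and
partition-then-pooled summaries identical, which the suite checks as an
invariant. The bisulfite conversion rate is one minus the weighted level
over the unmethylated control genome (the chloroplast), pooling all
contexts.

Per-cytosine input is accepted in a canonical six-column TSV or in BSMAP
methratio layout. In the methratio dialect the pre-computed ratio column
is deliberately ignored and levels are always recomputed from the raw
`C_count`/`CT_count` pair, so inconsistent upstream rounding can never
propagate. No effective-CT adjustment is applied: the canonical path uses
raw counts throughout.

## The DMR cascade

`call_dmrs()` contrasts two methylomes per sequence context through four
deterministic stages, with every threshold in `dmr_config()`:

1. **Window summaries.** Non-overlapping 100-bp windows; per window and
   context, the number of covered cytosines, mean coverage, and weighted
   level.
2. **Candidate windows.** Eligibility (≥ 6 sites with data, mean coverage
   ≥ 3×) is required in *both* samples — the conservative reading of the
   published rule, and the one its random-control description states
   explicitly ("in both WT and mutant"). Candidates need a level
   difference of ≥ 30% (CG, CHG) or ≥ 10% (CHH).
3. **Per-cytosine support.** Over cytosines covered in both samples, a
   site is differential when its ratio difference reaches 20% (CG/CHG) or
   10% (CHH) *and agrees in sign with the window difference*; windows
   keep going only when ≥ 80% of co-covered sites are differential. The
   sign condition is this package's design choice — the source rule
   states only a magnitude — because opposing-direction cytosines should
   not be allowed to support a region. Sites covered in only one sample
   enter neither numerator nor denominator.
4. **Merge and finalise.** Same-direction windows with an inter-window
   gap ≤ 100 bp merge; levels are recomputed by the weighted method over
   the merged span; regions of exactly one window must reach 60/50/20%
   (CG/CHG/CHH), longer regions 30/30/10%. Direction (`hyper` = sample B
   above sample A) comes from the recomputed difference.

Numerical conventions: all comparisons are `>=`/`<=` on unrounded
doubles; coordinates are 0-based half-open; a cytosine at 1-based
position $p$ belongs to window $\lfloor (p-1)/100 \rfloor$. Eligibility is
a window-stage property and is not re-checked after merging. Merging is
restricted to same-context, same-direction windows.

One caveat documented rather than hidden: "raising any threshold never
increases the DMR count" is not a theorem of the cascade — removing a
middle window can split one merged region into two that both pass the
single-window test. It holds on the isolated-DMR designs the acceptance
suite uses, and that is how the property is tested.

## Sensitive DMRs, annotation, and gene linking

A *demethylase-sensitive* DMR is a mutant-hyper DMR (mutant > WT in
endosperm) that overlaps (≥ 1 bp; no reciprocal fraction is stated in the
source method) an endosperm-hypo DMR (endosperm < embryo in WT).
Feature assignment uses the precedence genic > promoter/flank (within
2 kb of a gene) > TE > intergenic; the precedence is a package decision
for the undefined case of a TE inside a gene flank. Distances are
strand-ignorant bp gaps, 0 when overlapping. Gene linking uses the same
gap with the "within 2 kb" rule, boundary inclusive.

## Metaprofiles

Profiles span 80 bins: 20 upstream 100-bp bins, 40 body bins with the
body normalised to 4000 bp ($d/L \cdot 4000$ from the TSS), 20 downstream
bins. A window is anchored at its midpoint — the source method says
"distance between the 100-bp windows and TSS" without naming an anchor,
and the midpoint makes the profile exactly mirror-symmetric under genome
reversal (a tested invariant). Minus-strand features are mirrored so bin
0 is always farthest upstream of the 5′ end. Per feature and bin, counts
from the assigned windows are pooled by the weighted method; across
features the bin mean is unweighted, so a short high-coverage feature
counts as much as a long one. Nearest-feature ties break by smaller gap,
then lexicographic id. Features shorter than 40 bp still produce 40 body
bins (bins may share windows). Grouping by TE superfamily gives one
profile per family.

## Endosperm specificity and proportion tests

Per gene, each tissue is represented by its maximum over developmental
stages; the endosperm ratio divides that by the sum over *all* tissues in
the matrix (the source is ambiguous about the denominator; all-tissues is
the default and the set of tissues is whatever the matrix contains).
Classes: exclusive (≥ 0.90), preferential (> 0.50), non-specific
(< 0.30); genes in [0.30, 0.50] get the label `intermediate`, which the
source leaves unnamed. Count-proportion comparisons use the classical
two-sample chi-square with Yates continuity correction
(`two_proportion_test()`, mirroring `prop.test` defaults, with an
uncorrected option); the gradient view (`specificity_gradient()`) uses
decile bins by default since the original bin edges are not stated.

## Imprinting

Triploid endosperm carries two maternal genomes per paternal one, so the
null maternal read fraction is 2/3. The classifier takes pooled-replicate
allelic counts per gene and reciprocal cross; maternal identity always
comes from cross metadata, never column order. A gene is informative when
at least one allele has ≥ 10 reads in each reciprocal cross — the
"one allele" reading of an ambiguous rule, with `total` and `both` modes
exposed. MEG/PEG calls need ≥ 80% maternal (paternal) reads in *both*
reciprocal crosses. Candidate MEGs whose whole-seed expression is ≥ 3×
their endosperm expression are attributed to maternal-tissue
contamination and removed (zero endosperm with positive seed expression
counts as removed). `imprinting_shift()` flags a wild-type MEG as having
lost imprinting when its maternal fraction in the mutant-maternal cross
drops below the threshold, and symmetrically for PEGs.

Under the 2:1 null at depth 50, a false MEG needs ≥ 80% maternal reads in
two independent crosses; the suite verifies ≥ 29/30 planted recovery per
class with ≤ 1% false calls, and the occasional single null gene crossing
the threshold is expected, not a defect.

## DAP-seq peak tools

Two replicate peaks are *shared* when their overlap exceeds 90% of either
peak — equivalently of the smaller one — and the overlap region
represents the peak; overlapping emitted regions are merged, which makes
the operation symmetric in replicate order. Peak methylation is the
weighted level of contained context cytosines; the differential vs
non-differential comparison uses a two-sided Wilcoxon rank-sum test on
per-peak levels per context and group (the source figure names no test; a
sign-test alternative is exposed), with `NA` for groups under 3 peaks
with data.

## The synthetic world

`simulation_design()` states the world once; every generator is a pure
function of the design and replays byte-identically. Defaults, and why:

* **Genome**: one 1-Mb chromosome (10,000 windows) plus a 100-kb fully
  unmethylated control chromosome for conversion-rate estimation.
* **Cytosine density** 8/8/24 per 100 bp for CG/CHG/CHH — CHH most
  abundant, as in plant genomes; enough CG sites that most windows pass
  the 6-site rule.
* **Coverage** Poisson with mean 30 (20 in the null-design acceptance
  check, as stated there); Poisson rather than negative binomial for
  simplicity, with the design as the dispersion knob.
* **Baselines** CG 0.80, CHG 0.60, CHH 0.05 — typical maize gene-distal
  levels.
* **Planted DMRs** default 50 hyper + 50 hypo single-window CG DMRs at
  levels 0.05 vs 0.95 with exactly 10 sites each; background sites are
  excluded from planted intervals so the planted effect is not diluted.
* **Imprinting** 30 MEGs (f = 0.97), 30 PEGs (0.03), 940 nulls (2/3),
  depth 50; 10 MEGs shift to f = 0.5 in the mutant-female cross.
* **Context assignment** is drawn from the density model, not from a
  reference sequence — context is an input annotation throughout the
  pipeline, so sequence realism buys nothing for these tests.

What a green test therefore establishes: the cascade recovers planted
effects of the stated size at the stated coverage, and stays silent under
the null. What it does not establish: behaviour under non-Poisson
coverage dispersion, mapping artefacts, incomplete conversion, or
context misassignment — none of which the generator emulates.

## Known limitations

* No statistical DMR test (Fisher/beta-binomial) and no replicate
  handling: the design under study had one WGBS library per genotype and
  tissue, and the cascade is intentionally threshold-based.
* The DMR-count monotonicity property is empirical, not structural (see
  above).
* `read_methylome()` trusts the declared context; there is no
  FASTA-based re-derivation.
* Peak calling, differential-binding fitting and DEG model fitting are
  upstream tools' jobs; their outputs are consumed as tables.
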