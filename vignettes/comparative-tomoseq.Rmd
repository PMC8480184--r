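---
title: "Comparative spatial transcriptomics of nematodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative spatial transcriptomics of nematodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoevo)
```

# The measurement and the model

RNA tomography (tomo-seq) slices a straightened worm into ~40 cryosections
of 20 µm along the anterior–posterior (A–P) axis and sequences each slice,
yielding a gene × section matrix of transcript counts per specimen. The
sections are ordered by the physical cutting order, so the matrix is a
one-dimensional spatial transcriptome. `tomoevo` implements the comparative
analysis of such data across two nematode species: region segmentation,
regional-gene calling, one-to-one orthology and cross-species region
comparison, spatially resolved phylostratigraphy, and dN/dS summaries by
gene age and by region.

## Normalization and z-scores

Within a specimen, counts are normalized by the total transcript count of
their section,

$$x_{gs} = \frac{c_{gs}}{\sum_g c_{gs}},$$

so every retained section's normalized column sums to 1; sections with a
zero total (cryosection dropout) are dropped with a warning — the only
section-level quality filter applied by default, since anything stricter
would be a guess about upstream processing. Each gene's normalized profile
is then z-scored across that specimen's sections with the sample (n − 1)
standard deviation, the convention of `scale()`. A gene whose normalized
profile is constant has no defined z-score; its z row is `NA` and is
*excluded* from downstream medians rather than set to 0, because a constant
gene carries no evidence of regional enrichment in either direction and a
planted 0 would silently dilute pooled medians.

An important property of this normalization is that it is *compositional*:
a gene's normalized value is its share of the section, so genes strongly
expressed in one region depress every other gene's share there. At
realistic fold changes this coupling is far below the counting noise; in
the deterministic strong-fold limit it dominates and produces false
regional calls for flat genes (their tiny variance is purely the
compositional signal). The z > 1 rule therefore needs counting noise to be
the dominant variance source — which it is for real data — and the
synthetic validation at extreme folds checks the evaluator against
truth-derived profiles rather than asserting that the threshold rule is
immune to compositionality.

## Region segmentation by marker peaks

Regions are anchored on marker genes with punctuated spatial expression.
For a marker set, the signal is the per-section mean of the available
markers' z-scores, smoothed by a running median of width 3 (odd, configurable;
width 1 disables smoothing). Peaks are maximal runs of sections with
smoothed signal above `min_z = 1`; runs separated by a single
below-threshold section are bridged (`merge_gap = 1`), so one dropout
section inside an expression domain does not split it, while the canonical
two-peak case with a two-section gap stays split. The peak section is the
run's argmax, ties to the anterior.

Each marker-defined region is seeded by a configured *ordinal* peak of its
marker set — a sperm-marker family high in two separate regions defines the
anterior one as its first peak and the posterior one as its second. Seeds
must occur in configured A–P order. Sections between consecutive seeds go
to an indirect region configured between them ("the sections strictly
between the anchors") when one exists; otherwise the gap is split at its
midpoint, the extra section of an odd gap going anterior. The midpoint rule
is the least-informative apportionment of ambiguous sections and is the
package's choice where no rule is dictated by the biology; the anterior
tie-break makes it deterministic. The first region absorbs leading
sections, the last absorbs trailing ones, so every section is assigned and
each region is contiguous.

## Pooling, expressed and regional genes

Specimens are pooled per region: the pooled median z-score of gene $g$ in
region $r$ is the median over all sections of all specimens assigned to
$r$ (undefined z entries excluded). The gene universe is restricted to
genes detected (nonzero total) in at least `min_specimens` specimens —
all of them by default, the conservative reading of a
"detected in every animal" universe. Two independent flags are then called:

* **expressed** in $r$: pooled median normalized count > 0;
* **regional** in $r$: pooled median z-score strictly > 1.

`regional` does not imply `expressed` by construction (they are independent
criteria on different statistics); a strict mode ANDing them is available
behind a flag for users who want regional calls restricted to robustly
detected genes.

## Clustering

Sections (and regions, via ortholog profiles) are clustered with complete
linkage on the distance $1 - r$, $r$ the Pearson correlation over genes
with defined values in both objects. `hclust` is order-sensitive under
ties, so leaf labels are sorted lexicographically before clustering; the
result is deterministic and exportable as Newick.

## One-to-one orthology

Orthologs are called as reciprocal best hits from a combined-database hit
table: a gene's best cross-species hit is its lowest e-value hit below
0.001 (ties: higher bitscore, then lexicographic target id — the tie rules
are the package's own, chosen for determinism), self-hits excluded, and a
pair is emitted only when the relation is mutual. By default a gene whose
best within-species hit outranks its best cross-species hit is dropped
(`reject_if_within_species_hit_better`): this is what a combined-database
best-hit search does in the presence of recent inparalogs, and it prevents
spurious one-to-one calls between outparalogs. Full Inparanoid-style
clustering is deliberately out of scope.

## Overlap and domain overrepresentation tests

Cross-species region sharing is tested on the universe of ortholog pairs
expressed in both species: for regions $r_a, r_b$, the 2×2 table of
(regional in both, in $a$ only, in $b$ only, in neither) is tested with
Fisher's exact test; within-species analyses use each species' expressed
genes as the universe. Domain overrepresentation intersects each region's
regional genes with each protein-domain family against the background of
all expressed genes, reporting the member count, the sample odds ratio, and
the cumulative expression of the overlapping genes (sum of their median
normalized counts in the region). The exact test uses the standard
probability-ordering two-sided rule (summing hypergeometric probabilities
≤ the observed one, with a 1e-7 relative tie tolerance); two-sided is the
default and one-sided (greater) is available, since enrichment questions
are directional. All p-values of an analysis are adjusted together by
Benjamini–Hochberg; q < 0.05 is the reporting threshold.

## Phylostratigraphy

A ladder phylogeny assigns each focal gene an age class: stratum 1 is the
focal species, higher strata are older splits. A taxon carries homology
evidence for a gene if any protein hit targets it with e-value < 1e-3
*or* any nucleotide hit with e-value < 1e-5 — the union, because the
nucleotide search exists precisely to rescue genes whose annotated ORFs are
wrong; an intersection would defeat it. The gene's stratum is the maximum
stratum with evidence; genes with no qualifying hits are stratum 1
(no detectable homology = youngest). Thresholds are strict inequalities.
Age composition is reported per regional gene set next to the genome-wide
"Ref" distribution; by default Ref is computed over all annotated genes
(the full universe handed to the assignment), with restriction to expressed
genes available as a flag, since the choice between the two is a judgment
call the user should own. The young-fraction test is a one-sided Fisher
test per region (young ∩ regional vs the rest of the universe) with BH
adjustment across regions, plus each region's rank by young fraction — the
quantity behind the out-of-testis comparison.

## Evolutionary rates

Rates tables (one dN/dS per ortholog pair, model-0 style) are consumed, not
computed. Per focal gene, the partner with the lowest dS is selected as the
one-to-one ortholog (ties: lower ω, then lexicographic id — a documented
convention, since none is dictated); pairs with dS = 0 have undefined ω and
are excluded with a logged count. Group summaries report n, median and
quartiles with linear-interpolation (type-7) quantiles — stated explicitly
because boxplot conventions differ. Species pairs are matched by median dS
against a reference divergence, ties resolved toward the larger (more
conservative) divergence.

## Reference-isoform selection and ORFs

One representative isoform per gene is chosen by three cascading rules:
(1) a unique poly-A-tailed isoform (terminal run of ≥ 6 adenines — the run
must reach the 3′ end); (2) among several tailed isoforms, the one whose
best protein hit reaches furthest 3′, measured as the alignment end
*relative to transcript length* (absolute ends would favour long isoforms
for length alone; absolute mode is a flag); (3) otherwise the longest
isoform, ties lexicographic. The longest-ORF peptide is the longest
stop-free codon run over the three forward frames (the assembly is
strand-specific; a six-frame flag exists), start codon not required, codons
containing ambiguity letters translating to `X` without breaking the run,
ties to the most 5′ start and then the lowest frame.

# The synthetic experiment

`generate_experiment()` produces every input the pipeline consumes, with
full ground truth, from one seed; each component draws from a sub-seed
derived from it, so components regenerate independently and the whole
experiment is bit-reproducible.

The default parameters are the study conditions the pipeline targets: two
species, 4 specimens × 40 sections, 3,000 genes, 8 regions. Counts are
negative-binomial (dispersion 0.3, a typical bulk RNA-seq value) around
gene baselines drawn log-normal(log 5, 0.8) — section totals of ~20,000–
30,000 transcripts, matching the scale of real tomo-seq sections — times
per-section log-normal library factors (sdlog 0.2), the minimal model under
which normalization by section totals is actually necessary. A 30% regional
fraction at fold 4 plants the signal; markers get fold 10. The two
sperm-related regions are narrow (3 sections, spermatheca-like) and share a
single 12-member MSP-like marker family defining them as its first and
second peak: a two-peak marker's z plateau is mathematically capped near
1.7 when it is high in a quarter of the sections (it *saturates* in fold),
so only a family-sized average gives a usable signal — which is also the
realistic structure, real sperm regions expressing dozens of MSPs. One
region is defined indirectly between its neighbours. 30% of genes have a
one-to-one ortholog, conserved in regional identity with probability 0.8.

Gene ages follow a 5-stratum reference distribution
(0.25, 0.15, 0.15, 0.20, 0.25); genes regional in a sperm region draw from
the same distribution with young strata (I–III) boosted by a factor β = 3
(β = 1 is the null). Hit tables encode the ages: the defining stratum
always carries a qualifying hit (as a nucleotide-only rescue with
probability 0.2), intermediate strata often do, and decoy hits above the
thresholds point at older taxa. ω is Gamma(shape 3) with stratum means
(0.50, 0.35, 0.25, 0.18, 0.12) — younger genes under weaker purifying
selection; dS is log-normal and paralog cluster partners always receive
strictly larger dS than the true partner.

What the generator does *not* emulate: 3′-bias and gene-length effects of
the library chemistry, section-to-section bleed, correlated noise between
adjacent sections, gene families with correlated expression, inparalog hit
structure beyond the dominance flag, and homology-detection failure for
fast-evolving genes. Passing the synthetic suite therefore shows the
*procedures* are correct and well-calibrated under the stated noise model,
not that the thresholds are optimal for any particular real data set.

# Numerical choices and degenerate inputs

* Zero-total sections are dropped, not imputed; an all-zero matrix errors.
* Undefined z (constant genes) propagates as `NA` and is excluded from
  medians; a gene undefined in every pooled section is never regional there.
* Fisher tests on empty margins return p = 1 with odds ratio reported as 0.
* BH is the plain step-up with monotonicity enforcement, returned in input
  order.
* Dendrogram determinism comes from lexicographic leaf ordering, not from
  relying on `hclust` internals.
* Sections are 1-based in every report; regions are named from the config.
* All tie-breaks (best hits, peaks, isoforms, dS selection, species-pair
  matching) are documented deterministic rules.

# Validation problem sizes

The test suite validates the exact test against full hypergeometric
enumeration on every 2×2 table with total ≤ 60 plus 1,000 random tables
with margins up to 200; BH, phylostratum assignment, RBH and ORF extraction
against independent brute-force oracles on 1,000 (200 for RBH) random
instances; segmentation, regional-gene recovery, the out-of-testis
detection with its type-I control, and the ω-age trend on replicated
synthetic experiments at the default conditions (20, 10 + 10, 50 + 50 and
20 seeds respectively); and byte-identical reproducibility of a full
pipeline rerun. These sizes give stable pass/fail behaviour at the planted
effect sizes while keeping the suite fast.

# Known limitations

* The z > 1 regional rule is a fixed threshold; no attempt is made to model
  per-gene variance, and weakly expressed regional genes near the detection
  limit are the main source of missed calls (recall ~0.91–0.93 at the
  default fold of 4).
* Compositional coupling of total-count normalization (above) bounds the
  attainable precision when a few genes dominate a section.
* Strict RBH undercalls one-to-one orthologs in the presence of lineage-
  specific duplications — by design, as the point of the dominance filter.
* Phylostratigraphy inherits homology-detection failure: a fast-evolving
  ancient gene is dated young; the package reports, and cannot correct,
  this bias.
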