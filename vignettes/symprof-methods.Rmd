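---
title: "Methods: differential gene presence and symbiont community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential gene presence and symbiont community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symprof)
```

# The scientific problem

Lucinid bivalves host chemosynthetic, sulfur-oxidizing gill symbionts of the
candidate genus *Thiodiazotropha*. In a single host population, several
closely related symbiont lineages can co-occur: one lineage (here called
"lotti") and a second lineage ("luna") represented by two 16S sequence
variants that are only ever observed together. Two questions drive the
package:

1. **Which genes distinguish the lineages?** Shotgun reads from each host
   are mapped against a long-read assembly of the luna genome. A gene that
   is well covered in luna-dominant hosts but uncovered in lotti-dominant
   hosts is evidence of a luna-specific locus.
2. **How are the symbiont sequence types distributed across hosts and the
   surrounding seagrass habitat?** 16S amplicon (ASV) tables from host
   gills and from four environmental compartments (seagrass blades,
   roots/rhizomes, sediment, seawater) are filtered, normalized, and
   summarized into dominance, co-occurrence, richness, and shared-ASV
   reports.

Both analyses are implemented as reusable, deterministic building blocks,
with a synthetic-data generator that plants known truth so every stage can
be verified end to end without any external download.

# Coverage model

For each sample, primary mapped alignments (SAM flags 0x4, 0x100, 0x800
excluded) contribute depth along the reference: every reference-consuming
alignment-match CIGAR operation (`M`, `=`, `X`) adds one to each position it
covers, deletions (`D`) and skips (`N`) consume reference without adding
depth, and `I`/`S`/`H` consume none. This matches the semantics of standard
depth tools. From the per-base profile we compute, per gene interval
$[s, e)$:

* **breadth** $= |\{i \in [s,e) : d_i \ge 1\}| / (e - s)$, the fraction of
  covered positions;
* **mean depth** $= \sum_{i \in [s,e)} d_i / (e - s)$, in fold coverage;
* **normalized depth** $=$ mean depth divided by the sample's genome-wide
  mean depth (missing when the sample has no coverage at all; such samples
  are flagged).

All coordinates are held 0-based half-open internally (BED convention);
SAM's 1-based positions are converted exactly once at the parse boundary.
No MAPQ filter is applied by default (configurable). Depth is stored as
integers; derived means are kept at full precision and only rounded (to six
decimals) when written to TSV.

# Present / absent / unknown classification

Each gene in each sample is classified trinarily:

* **present** if breadth $\ge$ 0.65 **and** raw mean depth meets the
  group-specific threshold: $\ge 20\times$ in luna-dominant samples,
  $\ge 2\times$ in lotti-dominant samples. The two groups map at very
  different absolute abundances against the luna reference, so a single
  cutoff would be miscalibrated for one of them.
* **absent** if breadth $< 0.10$ **and** mean depth $< 1\times$. These
  absence cutoffs are package defaults, chosen to leave a wide "unknown"
  buffer between the present and absent regions; both are configurable and
  recorded in the run metadata.
* **unknown** otherwise; unknown cells are excluded from testing entirely.

Thresholding uses *raw* mean depth, not normalized depth: the presence
thresholds are stated in absolute fold coverage, while normalized depth
exists for cross-sample comparison and reporting. A configuration override
can switch the comparison basis by supplying different thresholds.

The threshold object enforces its own consistency (absence cutoffs strictly
below the presence cutoffs), which makes the present and absent regions
provably disjoint — classification is a total function on the valid domain.

# Differential presence testing

For each gene, present/absent calls are tabulated by symbiont group into a
2×2 table $(a, b; c, d)$ ($a$ = present in luna-dominant hosts). Genes with
an empty present+absent margin in either group are *untestable*: they are
reported but excluded before multiple-testing correction, so the number of
tests $m$ counts testable genes only.

The two-sided Fisher exact p-value is computed under the hypergeometric
null with all margins fixed, using point-probability ordering: the p-value
sums the probabilities of all tables whose point probability does not
exceed the observed one, with a relative tolerance of $1 + 10^{-7}$ for
floating-point ties (the dominant two-sided convention). The reported odds
ratio is the sample odds ratio $(ad)/(bc)$, infinite when $bc = 0 < ad$ and
missing when both products vanish. Benjamini–Hochberg step-up adjustment
(via `stats::p.adjust`) yields q-values; a gene is called lineage-specific
at $q < 0.05$ (configurable), with the direction taken from the two groups'
present-fractions rather than the odds-ratio sign, so infinite odds ratios
need no special-casing.

The implementation is verified against two independent oracles in the test
suite: exhaustive enumeration over fixed-margin tables with exact
binomial-coefficient arithmetic (all tables with total $\le 30$, agreement
to $10^{-12}$), and `stats::fisher.test` on random tables.

# Community analysis

ASV tables are processed in a fixed order that mirrors standard amplicon
practice: organelle/eukaryote ASV removal (case-insensitive lineage match
on *mitochondria*, *chloroplast*, *eukaryota*; "unclassified" is kept),
then removal of samples under 1000 reads (strict inequality: a sample at
exactly the threshold is kept), then cumulative sum scaling (CSS).

**CSS dialect.** Quantile dialects differ between implementations, so the
package states its rule exactly: for sample $j$ with $k$ positive counts,
$q_j$ is the value at index $\lceil l k \rceil$ of the sorted positive
counts (nearest rank, $l = 0.5$ by default), the scaling factor is
$s_j = \sum \{x : x \le q_j\}$, and normalized counts are
$x \cdot 1000 / s_j$. The adaptive quantile selection of the original CSS
method is intentionally out of scope. Worked example: counts
$(0,2,4,6,8)$ give $q = 4$, $s = 6$. CSS is invariant to per-sample
rescaling, and so are all downstream dominance calls.

**Dominance and co-occurrence.** The dominant symbiont of a host is the
focal ASV with the largest relative abundance among those detected (raw
count $\ge 1$ by default; the field data show abundances down to 0.006%,
so no abundance floor is imposed). Exact ties break to the
lexicographically smallest ASV id — a measure-zero event in real data,
fixed for determinism. Detection flags of the focal trio map to six
co-occurrence categories that partition the $2^3$ detection patterns;
two patterns (lotti with exactly one variant) collapse into one category,
as do the two single-variant patterns.

**Shared ASVs.** An ASV is shared when it is detected in at least one gill
sample and at least one environmental sample under the same id space; the
report gives per-compartment prevalence and mean relative abundance,
sorted by overall prevalence. Comparing tables with disjoint id spaces is
an error rather than a silent empty result.

Ordination, PERMANOVA, diversity indices beyond observed richness, and
phylogenetic-signal tests are out of scope: the module ends at the derived
tables such tests would consume.

# The synthetic-data generator

The generator is the package's test bed; its defaults encode the study
conditions rather than convenient values.

**Metagenome side.** The reference lays equal-length genes head-to-tail
with flanking spacers; a configurable number of gene ids (123 at the
default 4000-gene scale) is planted as lineage-specific truth. Reads are
*error-free truth placements*: per gene, the read count is Poisson with
mean $\mathrm{depth} \cdot L_\text{gene} / L_\text{read}$ and starts are
uniform such that reads never straddle gene boundaries. This makes the
per-gene expected depth exact and the recovery test sharp; sequencing
error and mapper behaviour are deliberately not modelled, because the
analysis under test begins at the alignment stage. Intergenic reads are an
optional separate stream (off by default; their length is truncated to the
spacer width when spacers are shorter than a read). Default depth regimes —
50× core and specific in luna-dominant samples; 5× core, 0× specific in
lotti-dominant samples — place core genes comfortably above both presence
thresholds and specific genes at exactly the absent pattern in the
lotti group. The cohort default is 43 + 43 samples, an even split of the
86-metagenome scale; per-group counts are not reported in the field data,
so the neutral even split is used and is configurable.

**Amplicon side.** Each host draws a co-occurrence category from the
renormalized probabilities $(0.238, 0.146, 0.25, 0.369)$ (the printed
values sum to 1.003 because one of them is approximate). The dominant
focal type's relative abundance is drawn uniformly within the observed
dominance ranges (68.3–98.7% for lotti, 48.4–98.1% for the luna
variants); a variant occurring at low abundance under lotti dominance uses
the observed 0.006–1.9% range; a non-dominant focal under variant
dominance uses 1–40% (not quantified in the field data; chosen to keep
variant pairs clearly co-detected). In the all-three category the dominant
type is drawn uniformly among the three. Hosts in the variants-only
category always carry both variants. Remaining mass is spread over 160
background ASVs by a symmetric Dirichlet (concentration 0.1, giving
realistically sparse per-sample communities); ten background gill ASVs
carry the focal genus lineage so genus-restricted richness is exercised,
and planted mitochondrial/eukaryote ASVs exercise the taxon filter.
Library sizes are log-normal with median 20 000; the low-library filter is
exercisable by raising the log-sd or lowering the median.

The environmental survey plants luna variant 1 in all four compartments
(~0.02% on roots/rhizomes) and a second shared ASV only on blades and
roots/rhizomes (~0.04% there), with ~60% of hosts carrying the second
shared ASV at low abundance in the gill — so the planted shared-ASV set
has exactly two members under defaults. Environment-only ASVs of the focal
genus are enriched on roots/rhizomes.

**What the generator does not emulate.** Sequencing error, chimeras,
paired-end structure, compositional correlations among background taxa,
site/date effects, and real taxonomic structure. Passing tests therefore
demonstrate the correctness of the computations under the stated
statistical structure, not robustness to artefacts of real sequencing.

# Numerical and design choices

* Determinism is byte-level: identical (parameters, seed) give identical
  outputs, including SAM and TSV files; reruns of the full pipeline are
  verified identical by checksum.
* Fisher p-values use `stats::dhyper` point masses in double precision;
  at cohort scale genes sharing a contingency table are tested once.
* Coverage uses run-length/interval machinery with an all-M fast path;
  both paths are checked bit-exactly against a per-base brute-force
  recount.
* Degenerate inputs have defined behaviour rather than crashes: empty
  alignment sets give all-zero profiles; a sample with no coverage gets
  missing normalized depth and a flag; a single-group cohort is refused
  with an explicit error; empty margins give untestable genes; an all-zero
  ASV sample is an error at CSS (it should have been filtered).
* Test problem sizes: the planted-recovery design uses 500 genes with 25
  planted specific genes and 20 samples per group over 20 seeds; the null
  design uses 100 replicates; the community recovery uses 10 000 hosts and
  100 survey seeds. These sizes give tight statistical bounds (binomial
  standard errors well under the asserted tolerances) at desk scale.

# Known limitations

* BAM/CRAM are not parsed (SAM text only), and FASTQ handling, mapping,
  assembly, and annotation are out of scope by design.
* The absence cutoffs below which a gene is called absent are package
  defaults (breadth < 0.10, depth < 1×); the field analysis states only
  that such cutoffs existed. They are surfaced in configuration and in the
  run metadata so any reanalysis states them explicitly.
* Whether presence thresholds should apply to raw or normalized depth is
  ambiguous in the field description; raw is the package default (see
  above), and both quantities are always reported.
* CSS here uses a fixed quantile; the adaptive quantile of the original
  CSS reference is not implemented.
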