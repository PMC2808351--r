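---
title: "Deriving a quiescent HSC signature: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a quiescent HSC signature: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemsig)
```

# Overview

`stemsig` implements a four-stage meta-analysis that extracts, from
three replicated two-color cDNA microarray comparisons, the set of genes
consistently enriched in quiescent hematopoietic stem cells (HSC)
relative to their differentiated (MPP), mobilized, and leukemic (LSC)
counterparts. This vignette explains each stage's model and assumptions,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

# The experimental design being modeled

Each comparison is a competitive two-channel hybridization: RNA from two
cell states is labeled with Cy3/Cy5 and co-hybridized, so every spot
yields one log~2~ intensity ratio. Three biological replicates are each
repeated with the dye labels exchanged ("dye swap"), giving six
replicate ratios per clone per comparison. After orientation correction
(flipping the sign of the swapped channels) all six columns share one
sign convention; in this package **positive means higher in the
perturbed state** (MPP / mobilized / leukemic), so quiescence-associated
genes appear as *down*.

Because the contrast lives inside each ratio, differential expression is
a **one-class** problem: under the null the six replicate ratios of a
clone are symmetric about zero.

# Stage 1: probe mapping

Spotted cDNA libraries are redundant — a gene is typically represented
by several clones — and not every clone can be assigned a gene. The
mapping table lists candidate (clone, gene, score) rows; resolution
keeps each clone's highest-scoring candidate. **Tie-break:** equal top
scores go to the lexicographically smallest gene id. The true
tie-breaking rule of any particular BLAST pipeline is unknowable from
summary tables alone; a deterministic convention is required for
reproducible analyses, and this is ours.

Clone lists collapse to gene lists by dropping unmapped clones and
deduplicating gene ids. Summary percentages display round-half-up (the
convention under which the canonical published funnels reproduce), while
full precision is retained in the object.

# Stage 2: one-class SAM

## Reproducibility filter

A clone enters the analysis only if its spot was present (above
background) in at least `min_present = 5` of the 6 replicates. Presence
is taken as given by the upstream image analysis — it arrives in the
data as the missing-value pattern — because no quantitative
above-background rule survives into the data we model.

## The statistic

For clone *i* with mean present-replicate log ratio $m_i$ and standard
error $s_i$,

$$d_i = \frac{m_i}{s_i + s_0}.$$

The exchangeability constant $s_0$ damps the explosive statistics of
clones with accidentally tiny variance. Two estimation strategies are
provided:

* `cv_minimization` (default): candidates are the percentiles
  $0, 5, \dots, 100$ of the $s_i$; clones are binned into ten
  equal-count windows by $s_i$, the MAD of $d$ within each window is
  computed, and the candidate minimizing the coefficient of variation of
  those MADs wins. This is the classic "make the scale of $d$
  independent of the error level" criterion.
* `median_s`: $s_0 = \mathrm{median}(s_i)$, used as a fallback below 20
  clones (too few for stable windowing) with a warning.

$s_0 = 0$ is permitted only when no clone has zero standard error.

## The permutation null

Under the one-class null the replicate signs are exchangeable, so every
assignment of $\pm 1$ to the six columns is equally likely. The null is
**exhaustive** by default: all $2^6 = 64$ assignments, recomputing means
*and* standard errors (partial flips change both). Exhaustive
enumeration is exact, cheap, and closed under global negation — which is
what makes the stage's sign antisymmetry (negating the matrix swaps the
up and down call sets exactly) hold to machine precision. Above 20
replicates exhaustive mode refuses and a seeded sampled mode must be
used.

## Delta selection and FDR

Observed order statistics $d_{(i)}$ are compared with their permutation
expectation $\bar d_{(i)}$ (mean of the sorted null vectors). For a
threshold $\delta$, candidate up-calls are ranks with
$d_{(i)} - \bar d_{(i)} > \delta$ and down-calls the mirror image; the
attained thresholds (smallest up-called $d$, largest down-called $d$)
become cutoffs, every clone beyond a cutoff is called, and the FDR
estimate is the median across sign assignments of the count of null $d$
beyond the cutoffs, divided by the number of calls. We use the median
(not a percentile variant) and apply no prior-fraction ($\pi_0$)
correction; both choices are recorded in the output provenance.

Raw per-$\delta$ FDR estimates are noisy and not automatically monotone.
We enforce monotonicity with a **conservative envelope**: each
$\delta$'s FDR is the maximum raw estimate over all thresholds at least
as large, so a loose threshold can never borrow a stringent threshold's
estimate, and the curve is non-increasing by construction. The smallest
$\delta$ whose envelope FDR meets the 10% target is selected; if none
does, the call set is empty with `fdr_achieved = NA`. The default
$\delta$ grid is 50 log-spaced values in $[0.01, 10]$ — wide enough that
its ends are never selected in practice, and recorded in the output.

On pure-noise inputs (1,000 clones × 6 replicates) this procedure calls
a vanishingly small fraction of clones (about 0.06% in the calibration
suite) and the achieved-FDR estimates of the non-empty call sets have
median 0 — the purpose of the calibration acceptance test.

# Stage 3: overlap meta-analysis

## The universe

All overlap probabilities condition on an explicit universe $U$: the
genes with at least one clone present in $\ge 5$ of 6 replicates in at
least one dataset. The universe is **global across datasets**, not
per-comparison — a gene detectable anywhere is a gene either list could
in principle have contained.

## Pairwise and trinary scores

For gene lists $G_i, G_j \subseteq U$ with overlap
$O_{ij} = |G_i \cap G_j|$, the overlap score is the hypergeometric upper
tail $P(X \ge O_{ij})$, computed through the survival function in log
space (`stats::phyper`) so that extreme significance never underflows.
The convention is one-sided — "this much overlap or more" — and
significance is strict inequality $p < \alpha$ with $\alpha = 0.001$.
The trinary indicator $T_{ijk}$ is true iff all three pairwise scores
are significant; it is symmetric in its arguments by construction. No
multiple-testing correction is applied across the pairwise tests: the
fixed $\alpha$ is itself the decision rule.

## Directions, conflicts, and the signature

A gene called up via one clone and down via another within the same
comparison is excluded from **both** directional lists and reported.
With redundant probes such conflicts are possible whenever the false
discovery rate is nonzero; exclusion prevents one gene from inflating
opposing lists. The signature is the gene-level intersection of the
three down lists; its clone-level size counts the unique clones, across
the three comparisons' down clone lists, whose gene lies in the
intersection — so the clone count is always at least the gene count.

# The synthetic-data generator

The generator emulates exactly the design above: a clone library with
zero-truncated-Poisson redundancy (mean 2.5 clones/gene; degenerate at
one clone/gene when the mean is 1), a configurable fraction of unmapped
clones (split between "no sequence" and "sequence but no match", so the
mapping funnel has all three levels), decoy second-best candidates on a
quarter of clones so best-match resolution is exercised, and per
comparison a clone × 6 matrix in which planted genes' clones are
$\mathcal{N}(\pm\text{effect}, \sigma^2)$ and null clones
$\mathcal{N}(0, \sigma^2)$, with independent Bernoulli per-spot
missingness. Dye swaps are sign-corrected at generation, matching data
that arrive orientation-consistent from the upstream database.

Planted truth is a set of disjoint gene subsets, one per Venn region and
direction. The defaults plant a strong down bias (1,093 down vs 89 up
genes across regions) and a 93-gene three-way-down region — the
signature the pipeline must recover. Down and up regions are globally
disjoint, so the planted truth itself contains no direction conflicts
(conflicts can still arise from false calls, which is what the exclusion
rule handles).

**Default calibration choices** (the source study reports no effect or
variance magnitudes, so these are modeling choices, made once): effect
size 1.5 log~2~ units, replicate noise SD 0.5, 5% missing spots, 10%
unmapped clones, 3,000 genes. At these values a planted clone's
$|d|$ is large but single-clone dropout still occurs, so recovery is
high (93–98% of the planted signature across seeds) without being
trivially perfect.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real arrays: spatial artifacts and
intensity-dependent (MA-curvature) bias, correlated missingness,
clone-specific variance heterogeneity beyond sampling noise,
cross-hybridization between paralogous clones, and any normalization
step (ratios are modeled as arriving normalized). Conclusions about the
pipeline's behavior under those failure modes require real data.

# Stage 4: cross-study comparison

External studies enter as (up list, tested list) pairs. Each comparison
is restricted to commonly tested genes: the signature and its universe
are intersected with the study's tested set, and — a choice the
published table format leaves open — the study's up list is **also**
intersected with the restricted universe before the hypergeometric
computation, because all four sets of a hypergeometric test must live in
one universe. p-values are computed in log space and reported as
$-\log_{10} p$ to four decimals. A study sharing no tested genes with
the signature is refused rather than reported as a vacuous zero.

# Numerical and scale choices

* Exact checks: the hypergeometric implementation is verified against
  term-by-term exact-rational enumeration for every instance with
  universe size ≤ 12, to 12 significant digits.
* Test-suite problem sizes: module tests run at 500 genes (~1,400
  clones); the end-to-end recovery check at the default 3,000 genes
  (~8,300 clones); the null calibration on 200 simulations of 1,000
  clones × 6 replicates. These sizes preserve every qualitative regime
  of the full-scale study (redundancy, filter attrition, FDR behavior)
  at a few seconds per check.
* All generator randomness flows from one config seed through fixed
  per-stage substreams (library, truth, ratios), so studies, manifests
  and TSV outputs are byte-identical across runs of the same config.
* Degenerate inputs: empty universes refuse overlap testing; empty call
  sets are valid results, not errors; clones with fewer than two present
  replicates are excluded from d computation with a warning; an
  all-equal-ratios clone with $s_0 = 0$ is caught by the positivity
  guard.

# Known limitations

* The one-class sign-flip null assumes symmetric replicate noise;
  heavy-tailed or skewed spot noise would distort the permutation FDR.
* With six replicates the null has only 64 assignments, so per-clone
  permutation p-values are coarse; the SAM quantile device works on the
  pooled order statistics and does not need finer resolution, but very
  small call sets inherit granular FDR estimates (0, 1/k, ...).
* The conservative FDR envelope can select a larger $\delta$ (fewer
  calls) than a raw-curve reading would; we prefer losing marginal calls
  to overstating confidence.
* Cross-study comparisons inherit each external study's own calling
  thresholds; the restriction to commonly tested genes equalizes
  opportunity, not stringency.
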