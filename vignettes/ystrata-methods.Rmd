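---
title: "Models and methods behind ystrata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ystrata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrata)
```

ystrata analyses male-lineage population structure from two kinds of data:
a **count matrix** of populations by Y-chromosomal haplogroups, and
**per-individual Y-STR haplotypes** (17 integer repeat counts per chromosome,
the Y-filer panel minus the multi-copy markers DYS385a/b). This vignette
explains the statistical models behind each module, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer would want to know about.

## The packaged survey fixture

The package ships a curated haplogroup frequency table for 31 endogamous
populations from Tamil Nadu (1680 Y chromosomes, 21 haplogroups), together
with the published per-population Nei gene diversities and the partitions of
the populations used by the structure analyses: seven subsistence-based
major population groups (MPG), the tribe/caste dichotomy, a caste-rank
hierarchy, and sampled districts. Integer counts are reconstructed from the
printed percentages by nearest-integer rounding and validated by three
layers of checksums (row sums against the printed sample sizes, pooled
member rows against the printed group rows, grand totals against the printed
total row). The provenance file shipped next to the CSV records how a
column-displacement artifact of the source transcription was resolved; the
test suite re-runs every checksum.

```{r fixture}
m <- tn_hg_counts()
m
```

## Diversity and enrichment

Nei's unbiased gene diversity over haplogroup classes is
$D = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, with its sampling variance
from Nei's classical formula. Lineage-class proportions (for example the
putatively autochthonous Indian lineages) carry binomial standard errors
$\sqrt{p(1-p)/n}$. The class sets are *configuration*, not constants
(`lineage_classes()`), because the autochthony assignment of several
haplogroups is debated and published pooled proportions cannot be reproduced
from any single fixed bipartition; keeping the sets as arguments makes every
reported proportion auditable.

Enrichment of a haplogroup in a group is tested at two levels. The
chromosome-level test is a two-sided Fisher exact test of haplogroup versus
all others, inside versus outside the group. The population-level test first
classifies each population as over-represented (by default: point-estimate
frequency strictly above the pooled overall frequency, the simplest rule
consistent with common practice; a per-population Fisher criterion is
selectable) and then applies a Fisher exact test to the counts of
over-represented populations inside and outside the group, reporting both
the two-sided and one-sided p-values since published analyses do not state
sidedness. No multiple-testing correction is applied: raw p-values are
reported, as in the analyses the package reproduces.

## Hierarchical AMOVA, R_ST and the grouping bootstrap

AMOVA partitions the total of squared inter-individual distances into
among-group, among-population-within-group, and within-population variance
components using the standard weighted coefficients for unequal sample
sizes; the fixation indices are the defining ratios $F_{CT} = V_a/V$,
$F_{SC} = V_b/(V_b+V_c)$, $F_{ST} = (V_a+V_b)/V$. Two metrics are built in:
**haplogroup identity** (distance 0/1, the "SNP" mode of published tables)
and **STR** (squared repeat differences summed over loci, the stepwise
convention under which $F_{ST}$ becomes Slatkin's $R_{ST}$). Negative
variance components are retained in the ratios by default, matching common
AMOVA practice; a clamping switch sets them to zero first. Permutation
p-values use the three standard nulls (populations among groups for
$F_{CT}$; individuals among populations within groups for $F_{SC}$;
individuals among populations for $F_{ST}$), switching to exhaustive
enumeration when fewer distinct population reassignments exist than
requested permutations.

Alternative groupings of the same populations are compared with a
multinomial bootstrap: each replicate resamples individuals with replacement
*within* each population (sizes preserved) and recomputes $F_{CT}$; the
median and 2.5/97.5 percentiles over 500 replicates summarize the sampling
uncertainty of the index under the study design. Within-population
resampling is the conservative reading of the published procedure (the
pooled alternative is available via `unit = "pooled"`). Two groupings are
declared ordered only when their 95% intervals are disjoint; touching
bounds count as overlap.

## Ordination

`hg_pca()` is covariance PCA — column-centered, **no** variance
normalization. Its default mode expands the count matrix to the
per-individual 0/1 haplogroup indicator matrix and takes the PCA over
individuals, the convention of individual-level genotype PCA; this is the
mode that reproduces the published two-component variance share for the
packaged survey (the population-frequency mode, also provided, concentrates
far more variance in two components because it removes the within-population
multinomial noise). A skree heuristic (components before the largest
successive eigenvalue drop) is advisory output only. `hg_nmds()` wraps
Kruskal's non-metric MDS (stress-1, monotone regression via iterative
majorization) with 20 random restarts by default, convergence when the
stress ratio changes by less than 1e-6, and reports stress in percent.
Negative $R_{ST}$ entries are floored at zero before embedding.

## Reduced-median haplotype networks

STR characters are ordered, so the coordinatewise median of three repeat
vectors equals the majority consensus of their binary "ladder" expansions;
the construction therefore works directly on repeat vectors. Locus weights
follow the inverse-variance convention: weight proportional to 1/variance of
the repeat counts at the locus, normalized to mean 10 and rounded to
integers of at least 1 (monomorphic loci get the maximum weight). Median
(Steiner) nodes are proposed from triples in the neighbourhood of the
current minimum spanning network and retained when they strictly shorten the
weighted spanning tree; the reduction coefficient `r` scales that comparison
(at the default 1.0 only strict improvements are kept). The final graph is
the union of all minimum spanning trees over the retained nodes; inferred
nodes that no longer shorten the tree are pruned. Published settings of the
original desktop program are not fully recoverable, so the tests target
structural invariants (connectivity, containment of all observed haplotypes,
total weighted length no greater than a spanning tree of the observations,
recovery of hand-built medians) rather than figures.

The `segregation_score()` — the fraction of adjacent observed-node pairs
sharing a majority population label, with a label-permutation null — is a
package-defined operationalization of the visual "population-specific
cluster" reading of published networks, and is flagged as such in its
output.

## STR-variance dating

Haplogroup ages use the effective-mutation-rate calibration: with `Var` the
mean over loci of the per-locus repeat variance (n−1 denominator) within a
haplogroup (and optionally a group), `age = Var / w × g` with defaults
`w = 6.9e-4` mutations per locus per generation and `g = 25` years. These
constants are configuration with documented defaults; they reproduce the
published variance/age tables to the 3-decimal rounding of the variances
(one printed cell is internally inconsistent by 3.5% and is flagged in the
tests). Cells with fewer than 5 complete records are excluded, mirroring
the published cutoff. The across-locus standard error of `Var` propagates
linearly to an age standard deviation; mutation-rate uncertainty is *not*
folded in.

## The synthetic-data generator

`simulate_haplotypes()` draws a structured-coalescent genealogy under a
dated population-split tree (lineages coalesce only within their current
population; populations merge backwards at the split times; constant haploid
size per deme) and lays mutations on branches as Poisson events per locus,
each a single ±1 repeat step (the strict SMM). Haplogroup labels are
modelled as perfectly linked markers inherited from the ancestral lineages
extant at the root split — no recurrent mutation. Defaults are 17 loci,
mutation rate 6.9e-4 per locus per generation (the same effective-rate
convention used for dating, so simulated variances and dated ages are
mutually consistent), generation length 25 years, ancestral repeat count 15.

What the generator does **not** emulate: multi-step mutations, allele range
constraints during evolution (values are clamped to the representable 5–50
band only on output), mutation-rate heterogeneity across loci, population
growth (the API accepts a growth rate but only constant size is
implemented), and any gene flow other than the explicit scenario
perturbations. Passing tests therefore certify the estimators under the
idealized stepwise model, not robustness to the rate heterogeneity and
homoplasy of real Y-STR panels.

Three perturbation scenarios probe sensitivity to unmodelled admixture:
`random_split` relabels one deme into two pseudo-demes by fair coin;
`symmetric_mixing` swaps the labels of exactly `round(m·n)` chromosomes each
way between two demes; `in_migration` replaces a fraction `m` of each target
deme by draws from a source deme.

## The split-time sampler

`sample_split_posterior()` is a reduced-scale coalescent MCMC in the spirit
of classical Y-STR divergence samplers: Metropolis–Hastings over the
genealogy (node-time slides and fixed-height subtree re-attachments), the
ranked population-merge topology (for 3–4 demes), the split times, a single
effective size, and a shared per-locus mutation rate, under the SMM
likelihood computed by Felsenstein pruning on a truncated integer lattice.
The displacement kernel along a branch of length $t$ is
$e^{-\mu t} I_{|d|}(\mu t)$ (modified Bessel function), truncated at 15
steps; the lattice spans the observed repeat range ±8 with a uniform root
distribution. Conditional likelihood vectors are cached per node and only
the changed root-ward path is recomputed.

Priors: gamma on the mutation rate with mean 6.9e-4 and shape 28 — matching
the quoted uncertainty of the effective rate (6.9 ± 1.3 × 10⁻⁴ per locus per
25-year generation). This choice matters: STR data identify only the product
of rate and time, so the rate prior anchors the time axis, and a diffuse
rate prior lets the whole chronology rescale. Effective size is lognormal
(median 2000, log-sd 1); split times are uniform below their parent with the
root uniform on (0, 100 Kya). A joint time-scale move multiplies all node
times, split times and the size by a common factor while dividing the rate
by it — the likelihood is exactly invariant along this ridge, and the move
lets the informative priors equilibrate quickly.

Model scope: no gene flow after a split, constant sizes, one shared rate.
Chains default to 40,000 iterations with 10,000 burn-in and thinning 10 —
sized so a two-deme run of ~100 chromosomes completes in about a minute on
one core; production analyses of this kind historically used chains two
orders of magnitude longer, and the effective-sample-size diagnostic flags
runs that need more. Convergence is advisory (`converged` field), never
silently enforced.

`modal_tree()` summarizes the sampled ranked topologies by highest
frequency, breaking ties by mean posterior density (recorded when it
happens). `tmrca_cluster()` provides the simple cluster-age estimators
(mean squared deviation or mean absolute step distance from a center,
per-locus, divided by the rate): closed-form companions to the sampler, not
replacements for it.

### What the admixture scenarios show

With labels swapped between two demes (`symmetric_mixing`), near-identical
chromosomes end up on both sides of the split, and the no-gene-flow model
can only accommodate them by collapsing the split time — a 10% swap more
than halves the estimate. A randomly split panmictic sample collapses to a
few hundred years. In-migration from a *divergent* source deme turns out to
behave the same way in this sampler once the chains converge: although most
migrant chromosomes found deep lineages, a migrant pair that happens to be
recently related within the source population will usually land on both
sides of the target split, and that single pair caps the split-time
parameter just as swapped natives do. Historical analyses of this scenario
reported much smaller perturbations (estimates "only slightly affected" up
to 40–50% in-migration); that robustness came from reading split times off
modal trees in which the migrant clade is identified and filtered by its
distinct haplogroup-defining markers — machinery that is out of scope here.
The scenario test records this divergence: in this package's direct
split-time posterior, in-migration at 20–40% reduces the estimate by more
than half, and the corresponding check documents the model-scope difference
rather than reproducing the published insensitivity.

## Problem sizes used by the checks

The packaged reproduction targets run on the full 31 × 21 fixture (1680
chromosomes). Simulation-based checks are sized for interactive use: the
stepwise-divergence calibration uses two demes of 25 over 60 replicates;
sampler coverage uses 12 replicates of 12 chromosomes per deme with 6,000
iteration chains; the scenario checks use demes of 40–60 with
12,000–30,000 iteration chains; the reproduction script runs the scenario
experiments (60 and 2 × 50 chromosomes) with 30,000–40,000 iteration
chains over 5 seeds. These sizes are the package's own reduced-scale
choices and are declared wherever results are reported.

## Known limitations

* The sampler supports 2–4 demes; analyses over more groups are composed
  from runs on subsets (pooling the remaining branches), as the historical
  composite-tree procedure did.
* Constant deme sizes; no growth, no gene flow, one shared mutation rate.
* The reduced-median construction is a principled re-implementation, not a
  byte-compatible port of the original desktop program.
* Dating uses the evolutionary (effective) rate convention throughout;
  pedigree-rate dating would give systematically younger ages and is not
  provided.
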