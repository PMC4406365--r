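---
title: "Methods: population genetics of the Hopscotch insertion at tb1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of the Hopscotch insertion at tb1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teopop)
```

# Scientific setting

The *teosinte branched1* (*tb1*) gene represses lateral organ growth in
*Zea mays*; the *Hopscotch* retrotransposon insertion in its distant
upstream control region enhances *tb1* expression and is the canonical
"maize allele" behind the unbranched architecture of domesticated
maize. The same insertion segregates in natural teosinte populations,
which raises three questions this package operationalises: how is the
insertion distributed across populations and subspecies; does sequence
variation near *tb1* look neutral or selected; and does the insertion
affect tillering in teosinte as it does in maize. Each analysis stage
below states the model, its assumptions, the tunable parameters, and
the numerical decisions taken where the procedure was genuinely open.

# Marker genotyping

The co-dominant assay runs two PCRs per plant: a flanking reaction
whose product is ~300 bp without the insertion and ~5 kb with it, and
an internal reaction that yields a ~1.1 kb product only when the
insertion is present (its reverse primer sits in the element's LTR).
`callGenotypeFromBands()` is a total, deterministic map from the
pattern vocabulary (flanking: `300bp`, `5kb`, `both`, `none`, `failed`;
internal: `1.1kb`, `none`, `failed`) to a call. Decisions:

* A reaction that *resolved with no band* (`none`) is distinct from one
  that *failed*. A flanking `none` is inconsistent with every genotype
  (both alleles amplify in that reaction) and is scored `missing`.
* When only one PCR resolved well, one allele is scored (`H_half` /
  `h_half`) rather than inferring the diploid genotype. When only the
  flanking PCR resolved and showed both bands, we score `H_half`: the
  5 kb product is direct evidence for the insertion allele, and a
  single-allele score is the conservative reading of a one-PCR call.
* Patterns in which the two PCRs contradict each other are scored
  `missing` with a logged reason, never half-called: a contradiction
  means at least one reaction did not resolve *well*.

Half-calls contribute exactly one chromosome to allele-frequency
denominators and are excluded from Hardy–Weinberg tests and from the
genotype-free variance components only through their single scored
chromosome — no diploid class exists for them. Missing calls keep
their record (explicit `missing`, never a dropped row) so denominators
stay auditable.

# Hardy–Weinberg test

`hweTest()` compares observed genotype counts with
$(N\hat p^2,\,2N\hat p\hat q,\,N\hat q^2)$ by a chi-square statistic
with 1 df (three classes, one estimated allele frequency). Monomorphic
samples are flagged undefined rather than returning a spurious zero.

# Hierarchical F-statistics

Differentiation is estimated by moment (ANOVA) variance components on
the three-level hierarchy taxon / population / chromosome, in the
Weir–Cockerham tradition. Working at the chromosome (allele) level —
a binary indicator per scored chromosome — lets half-calls contribute
naturally and avoids needing a heterozygosity term. For unequal sample
sizes the expected-mean-square coefficients are the standard nested
unbalanced-design ones; with taxa $i$, populations $j$, sizes
$n_{ij}$:

$$n_b = \frac{N - \sum_i \frac{\sum_j n_{ij}^2}{n_{i\cdot}}}{P - T},\quad
c_b = \frac{\sum_i \frac{\sum_j n_{ij}^2}{n_{i\cdot}} - \frac{\sum_{ij} n_{ij}^2}{N}}{T - 1},\quad
c_a = \frac{N - \frac{\sum_i n_{i\cdot}^2}{N}}{T - 1}.$$

From components $\sigma^2_a$ (taxa), $\sigma^2_b$ (populations within
taxa), $\sigma^2_w$ (within populations):
$F_{CT} = \sigma^2_a/\sigma^2_{tot}$,
$F_{SC} = \sigma^2_b/(\sigma^2_b + \sigma^2_w)$,
$F_{ST} = (\sigma^2_a + \sigma^2_b)/\sigma^2_{tot}$.

Decisions:

* **Population inclusion threshold.** `minChromosomes = 8` by default.
  Survey write-ups of this assay have used both "eight or more" and
  "sixteen or more" chromosomes for different summaries; eight is the
  default because it matches the larger reported population count, and
  the argument makes the alternative a one-keystroke override.
* **Negative estimates.** Moment components can go negative in finite
  samples; F values are reported raw *and* truncated at zero
  (`fct_trunc` etc.). A printed "F<sub>CT</sub> = 0" corresponds to
  the truncated form.
* **Pooled F<sub>ST</sub>.** Whether an "among all populations"
  F<sub>ST</sub> pools taxa (two-level) or is the three-level statistic
  is ambiguous in survey tables, so `hierFstats()` reports both
  (`fst` and `fst_pooled`).
* Pairwise `pairwiseFstMarker()` is the same machinery restricted to
  two populations (the two-population Weir–Cockerham estimator at the
  allele level), reported raw.

# Sequence diversity and Tajima's D

Statistics are computed per population alignment (the two ~600 bp
resequenced regions are the motivating case). Site filtering is the
main open choice; we use two explicit denominators:

* **Complete deletion** for segregating-site statistics: any column
  containing `-` or `N` in any sequence is dropped before counting S,
  haplotypes, and $\hat\theta_W = S/a_1$. This matches the default of
  the classic summary-statistic libraries.
* **Pairwise deletion** for $\hat\theta_\pi$ and p-distances: each
  sequence pair uses its own comparable-site count.

Sites with more than two states count once toward S; π counts all
pairwise mismatches. Tajima's D is computed entirely on the
complete-deletion columns at locus scale,
$D = (\hat\theta_\pi^{loc} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$, with
the usual $a_1,\dots,e_2$ constants; it is undefined (NA with a flag)
at $S = 0$ and requires $n \ge 4$. The sequence
$F_{ST} = 1 - \pi_w/\pi_b$ uses the unweighted mean of the two
within-population π values and is reported raw; note that this π-ratio
form has an $O(1/n)$ downward bias when the two samples are drawn from
one panmictic population, which the tests account for by averaging
over replicates. Several π-ratio variants exist in the literature;
published pairwise sequence F<sub>ST</sub> tables computed with other
estimators are therefore comparable only approximately.

# The coalescent null for D

Significance of D is judged against 10,000 (default) neutral coalescent
replicates simulated at the observed sample size with
$\theta = \hat\theta_W$ and, by default, $\rho = \theta$ — the
"identical population recombination rate" convention. The simulator is
a Hudson-style ancestral recombination graph: lineages carry ancestral
material as segments of $[0,1)$; coalescence occurs at rate
$k(k-1)/2$, recombination at rate $(\rho/2)\times$ span per lineage
(span = distance between a lineage's outermost ancestral endpoints);
mutations are Poisson at rate $\theta/2$ per unit of ancestral branch
length, placed uniformly under infinite sites; segments whose
descendant set reaches the full sample are dropped (local MRCA). Only
ancestral-material-bearing lineages are tracked. The engine is written
in C++ for speed and draws all randomness from R's RNG, so
`set.seed()` gives byte-identical replicate sets.

Decisions: replicates with $S = 0$ have undefined D and are excluded
from the quantile computation but reported (`reps_undefined`); the 95%
interval is equal-tailed via type-7 order-statistic interpolation;
$\theta$ is parameterised per locus, matching the classic simulators.
Correctness anchors: $E[S] = \theta a_1(n)$ and $E[\pi] = \theta$
(checked to 3 Monte-Carlo SE at 2,000 replicates), weak negative skew
of the neutral D distribution, variance of D decreasing in $\rho$, and
an empirical type-I error of ~5% when data are simulated under the
same null (200 outer replicates at 1,000 inner replicates — sizes
chosen to make the Monte-Carlo error a small fraction of the 5%
target).

# Linkage disequilibrium and haplotype blocks

r² is computed on *phased* haplotypes only (the motivating SNP panels
are phased upstream); no composite-LD fallback for unphased data is
offered, because none was used in the analysis this package
reproduces. For each unordered SNP pair, gamete counts over jointly
non-missing haplotypes give $D = p_{AB} - p_A p_B$ and
$r^2 = D^2/(p_A p_a p_B p_b)$, with $\chi^2 = n r^2$ on 1 df. Pairs
monomorphic among the jointly non-missing haplotypes are skipped and
counted. `mafFilter()` keeps SNPs with minor allele frequency **at
least** the threshold (boundary inclusive, default 0.1) and is
idempotent.

Region summaries classify a pair as "in region" only when *both* SNPs
fall in the half-open interval; pairs straddling the boundary belong to
neither mean and are counted separately — the partition is otherwise
ambiguous. Haplotype blocks tile the chromosome in fixed windows
anchored at multiples of the block size (default 5 kb, conservative
given teosinte's sub-5.5-kb LD decay); within a window each distinct
haplotype string becomes one dense integer allele code (0, 1, ... in
order of first appearance), and the code-to-string table is returned so
the recoding is lossless. The anchoring convention is our choice; block
definitions anchored at the first SNP instead would shift window
boundaries by less than one window.

# Neighbor-joining trees and bootstrap

Distances are uncorrected p-distances with pairwise deletion — at
~600 bp and within-species divergence a substitution correction changes
nothing detectable, and it keeps distances exactly reproducible from
the alignment. NJ follows Saitou–Nei with the Q-criterion; ties on Q
are broken by the lexicographically smallest pair of node
representatives (each node represented by its smallest descendant leaf
label), making the topology deterministic. Negative branch-length
estimates are clamped to zero with the deficit transferred to the
sister edge, preserving the pair's path length. Bootstrap supports
resample alignment columns with replacement, rebuild the tree, and
count each internal bipartition of the point-estimate tree; supports
are fractions in [0,1] stored as internal node labels, which is also
how they are written to Newick.

# Phenotype association

The tillering index is Σ tiller lengths / plant height (0 for an
untillered plant). Because the index is exactly 0 for untillered
plants, the log (Box–Cox $\lambda = 0$) transform needs an offset; we
use +1, i.e. $\log(1 + \text{index})$, and flag this prominently
because analyses that used $\lambda = 0$ on such data must have made
*some* offset choice without stating it.

`repeatedMeasuresAnova()` is a univariate split-plot decomposition:
between-subject factor genotype (hh/Hh/HH), within-subject factor day,
their interaction, with subject nested in genotype as the error stratum
for the genotype F-test. Genotype is the only term in its stratum, so
its sum of squares is unambiguous even with strongly unbalanced class
sizes (the motivating panel is 82/104/20); day and genotype × day are
tested against the within-subject residual. No sphericity correction is
applied by default — the decomposition is reported as-is, and the
null-size simulations below justify the working α. Plants with missing
time points are dropped listwise with a message; half-call genotypes
are excluded. Exact SAS GLM output on unbalanced data may differ in the
within-subject rows depending on its sums-of-squares options; the
genotype test, which carries the scientific conclusion, does not.

The one-way ANOVA (`onewayAnova()`) serves the independent control
trait, culm diameter, which is not expected to respond to *tb1*
variation.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the pipeline is
validated.

* **Island-model marker panels** (`simulateIslandGenotypes()`): taxon
  frequencies ~ Balding–Nichols around the ancestral frequency with
  parameter $F_{CT}$; population frequencies ~ Balding–Nichols around
  their taxon frequency with $F_{SC} = (F_{ST}-F_{CT})/(1-F_{CT})$,
  using the standard beta shapes $p(1-F)/F$, $(1-p)(1-F)/F$; genotypes
  binomial within populations. Defaults (2 taxa × 16 populations × 20
  individuals, $F_{ST} = 0.22$, $F_{CT} = 0$, 2% half-calls, 2%
  missing) mirror a genome-typical teosinte survey. Parameter-recovery
  tests average 20 seeds and require ±0.05 / ±0.03 agreement.
* **Sequence and SNP panels** come from the coalescent engine;
  alignments map the 0/1 infinite-sites matrix to nucleotides as
  derived = T, ancestral = A over a monomorphic C background, which
  keeps every diversity statistic and p-distance numerically identical
  to its 0/1 counterpart. Chromosome-scale panels are large-ρ runs with
  positions rescaled to bp.
* **Phenotypes** (`simulatePhenotypes()`): on the analysis (log) scale,
  response = day mean + genotype effect × H dosage + subject intercept
  + residual; tiller lengths are back-constructed so the tillering
  index reproduces the simulated response at the plant's height, and
  culm diameter is drawn independently of genotype. Default day means
  follow a growth curve with the index rising ~0.5 → 2.0, keeping the
  log-scale response away from the zero-tiller boundary (negative draws
  are clamped to an untillered plant; at the default SDs this affects
  well under 1% of records). Real greenhouse data differ in ways the
  generator does not model: many true zeros in early measurements,
  heteroscedastic measurement error, attrition, and correlated
  day-to-day residuals. Passing the null-size and power tests therefore
  shows the *procedure* is calibrated under its stated model, not that
  real tillering data satisfy that model.

# Problem sizes and numerical tolerances

The test suite runs the coalescent moment checks at 2,000 replicates
(3-SE agreement), the neutrality-test size check at 200 × 1,000
replicates (99% binomial envelope around 5%), the association size
check at 500 simulations and its power check at 100 simulations of 60
plants per genotype with a 1-residual-SD effect; dual-implementation
oracles require 1e−10 (Tajima's D), 1e−12 (π, r²) and exact-topology
(NJ on 50 random additive matrices) agreement. These sizes were chosen
so every stochastic assertion has Monte-Carlo error several times
smaller than the tolerance it checks.

# Known limitations

* F-statistics are single-locus moment estimates; no jackknife or
  bootstrap CIs are provided.
* The sequence F<sub>ST</sub> is the π-ratio form only.
* The neutral null has no demography (no bottlenecks, growth or
  migration) and no selection — it is the standard neutral model that
  the significance convention presumes.
* The split-plot ANOVA is not a mixed-model (REML) analysis; with
  severe unbalance and missing time points a mixed model would use the
  data more efficiently.
* Environmental-association and Bayesian admixture analyses around the
  locus are out of scope; phasing must happen upstream of the LD stage.
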