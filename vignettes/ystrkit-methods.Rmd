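---
title: "Methods: forensic Y-STR statistics, AMOVA Rst, and simulated panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic Y-STR statistics, AMOVA Rst, and simulated panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

ystrkit analyses Y-STR haplotype tables the way forensic population studies
do: direct-counting summary statistics, AMOVA-based pairwise Rst, and
distance-based structure views. This vignette records the models, the
parameter choices, and the numerical conventions, so that every number the
package produces can be traced to a stated rule.

## The data model

A *panel* is a tibble of male samples: `sample_id`, `population`, and one
list-column per locus holding the sorted allele multiset. Y-STR alleles are
repeat counts; microvariants (incomplete repeats) keep their conventional
decimal notation (`17.2` means 17 repeats plus 2 bases) and enter every
computation as the literal real value — no repeat-equivalence recoding is
applied, because none is standard.

Multi-copy loci (DYS385a/b-style duplicated markers) carry one multiset per
man. The multiset is stored sorted ascending and input order carries no
meaning: genotyping cannot phase which physical copy an allele came from,
so `13-14` and `14-13` are the same genotype. DYF387S1, DYS527 and DYF404S1
are modelled as expected-two-copy but *variable*: lineages with one or
three amplifiable copies are accepted unflagged, because published
population tables report such patterns as ordinary genotypes.

Quality flags are data, not errors. A missing genotype (markers `""`, `-`,
`N`, `null`, `NA`, case-insensitive) and a copy-number anomaly (a
single-copy locus showing two alleles, typically a duplication) are both
recorded per sample and locus. Flagged genotypes are excluded from that
locus's allele statistics and from Rst distances — the common
reference-database practice for intermediate or duplicated patterns — but
the sample stays in the panel, keeps its other loci, and an anomalous
genotype still participates in whole-haplotype identity with its literal
allele pattern. DYS389II is used exactly as typed; the kit reports it
without subtracting DYS389I and the package applies no transformation.

## Forensic statistics

All summary statistics are direct counts. For a frequency spectrum with
counts $c_i$, $n = \sum c_i$ and $P_i = c_i/n$:

* Gene diversity / haplotype diversity (Nei's unbiased estimator):
  $GD = \frac{n}{n-1}\left(1 - \sum_i P_i^2\right)$. It is 0 for a
  monomorphic locus and exactly 1 when all $n$ observations differ.
* Haplotype match probability: $HMP = \sum_i P_i^2$, the probability two
  men drawn with replacement share a haplotype.
* Discrimination capacity: $DC = k/n$ with $k$ the number of distinct
  haplotypes.

These are tied by the identity $HD = \frac{n}{n-1}(1 - HMP)$ and the
integer identity $DC \cdot n = k$; the test suite asserts both to machine
precision on random panels, plus agreement of HMP with a naive
pairwise-match count.

Multi-copy loci admit two allele spectra and the package exposes both: a
*pooled* spectrum over all copies ($n$ = samples × copies) and a
*combination* spectrum over sorted multisets ($n$ = samples). Per-locus GD
for multi-copy loci is computed on the combination spectrum, matching how
published tables report a single GD for "DYS385a/b"; the report emits both
allele-inventory counts since surveys are ambiguous about which they total.

**Reporting precision.** The API always returns full precision. Published
tables round to 4 decimals, but not uniformly: haplotype diversity values
are truncated (0.99995 prints as 0.9999) while match probabilities round
half-up (0.00255 prints as 0.0026). `round_down()` and `round_half_up()`
implement the two conventions explicitly (base `round()` is banker's
rounding), with a `1e-9` guard absorbing binary floating-point error on
exact decimal halves such as $408/160000 \times 10^4 = 25.5$.

## Pairwise Rst by AMOVA

The molecular distance between two complete haplotypes over a locus set is
$\delta^2 = \sum_\ell \sum_c (a_{\ell c} - b_{\ell c})^2$, copies paired
after ascending sort within each man. Sorted pairing is the only
well-defined pairing for unphased duplicated loci; when two men carry
*different* copy numbers at a variable locus, that locus is skipped for
that pair (no pairing exists) and the skip is counted in the result.

The two-level AMOVA on the matrix of $\delta^2$ gives, for $N$ samples in
$P$ populations of sizes $n_p$:

$$SSD_{total} = \tfrac1N \sum_{i<j} \delta^2_{ij}, \qquad
  SSD_{within} = \sum_p \tfrac1{n_p} \sum_{i<j \in p} \delta^2_{ij},$$

$MS_{among} = (SSD_{total}-SSD_{within})/(P-1)$,
$MS_{within} = SSD_{within}/(N-P)$,
$n_c = (N - \sum_p n_p^2/N)/(P-1)$, and the variance components
$\sigma^2_a = (MS_{among}-MS_{within})/n_c$, $\sigma^2_w = MS_{within}$,
from which $R_{st} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$.

Conventions:

* **Complete cases.** Samples flagged at any selected locus are dropped
  before the AMOVA rather than renormalising distances per pair.
* **Negative estimates.** $\sigma^2_a$ can be negative by sampling noise;
  the raw Rst is reported, and the value is clamped to 0 wherever it feeds
  a distance matrix (MDS and NJ require non-negativity). Zero total
  variance is reported as Rst 0 with a degenerate flag.
* **Locus subset.** Cross-population comparisons default to the
  Yfiler-Plus content (25 locus names; DYS385 and DYF387S1 carry two copies
  each, giving the customary count of 27 loci). Whether to include the
  multi-copy loci at all is selectable (`multi_copy = FALSE` restricts to
  single-copy loci); they are included by default since the 27-count is
  only reached with them.
* **Significance.** Permutation p-values shuffle individuals across the two
  population labels with group sizes preserved and use the add-one
  estimator $p = (1 + \#\{R_{perm} \ge R_{obs}\})/(n_{perm}+1)$, whose
  minimum is $1/(n_{perm}+1)$. Tests check null calibration by a
  Kolmogorov–Smirnov comparison with the uniform distribution.

The implementation is verified two ways: the hand-worked four-sample
instance (within-pair alleles {10,10} vs {12,14} at one locus gives
$R_{st} = 0.8$), and, on random small panels, an independent oracle that
never forms pairwise distances — classical one-way ANOVA sums of squares on
the repeat scores per locus, aggregated and converted to variance
components. The two routes agree to $10^{-9}$.

## MDS and neighbor-joining

**Classical (Torgerson) MDS.** Distances are squared, double-centered
($B = -\tfrac12 J D^{(2)} J$), and eigendecomposed; coordinates are
eigenvectors scaled by the square roots of the top positive eigenvalues.
Rst values are used as distances directly — no $R_{st}/(1-R_{st})$ or other
transform — since reference-database practice plots raw Rst. Negative
eigenvalues (Rst matrices are generally non-Euclidean) are excluded from
coordinates but reported, with `goodness` the captured share of
positive-eigenvalue mass. Two reproducibility conventions: each axis's sign
is fixed so its largest-magnitude loading is positive, and asking for more
dimensions than there are positive eigenvalues reduces the dimension with a
warning. On distances that are exactly Euclidean of dimension $d$, the
$d$-dimensional embedding reproduces every pairwise distance to $10^{-8}$
(tested, including against `stats::cmdscale`).

**Neighbor-joining.** Saitou–Nei agglomeration on the clamped Rst matrix:
repeatedly join the pair minimising
$Q(i,j) = (m-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, assign branch
lengths by the standard three-point formulas, and close the final three
nodes onto one internal vertex (two taxa yield the degenerate single-edge
tree). Ties in $Q$ break toward the smallest (row, column) pair in input
order; negative branch lengths are clamped to 0 without redistributing
length. Both rules are arbitrary where the literature is silent — desktop
phylogenetics programs do not document theirs — so exact replication of any
particular published figure's topology is not claimed. NJ is exact on
additive matrices, and the tests verify topology and branch lengths to
$10^{-9}$ on random 4–12 leaf additive trees, alongside agreement with
`ape::nj`. Trees are `ape::phylo` objects; Newick labels containing spaces
are single-quoted.

## The simulator: what it emulates, and what not

`simulate_panel()` is a forward-time haploid Wright–Fisher model with
single-step stepwise mutation (SMM): each generation every allele copy
mutates with its locus rate and steps ±1 repeat with equal probability,
reflecting at one repeat. A monomorphic founder (14 repeats by default, a
typical modal Y-STR allele) evolves for a burn-in of $4N$ generations —
roughly the coalescent depth of a haploid population, enough to approach
mutation–drift equilibrium — then splits star-fashion into `n_pops`
populations that drift independently for $T$ generations before sampling
without replacement. Multi-copy loci are `copy_number` linked,
independently mutating values. The default per-copy rate of 0.002 per
generation is a standard order of magnitude for Y-STR loci, between slow
markers (~5×10⁻⁴) and rapidly mutating ones (~10⁻²).

This reproduces the statistical structure the analysis assumes — haploidy,
no recombination, repeat-count variance growing with $\mu N$ and divergence
time — which is what the property tests need: diversity ranks with mutation
rate, and mean pairwise Rst increases with split time. It does *not*
emulate real Y-chromosome demography: no population growth, migration, or
social structure; no multi-step or length-biased mutation; no microvariant
creation (microvariants enter tests only through parsing fixtures); no
genotyping error. Passing tests therefore validate the estimators'
behaviour under a clean neutral model, not the historical realism of any
simulated panel.

Determinism: one master seed; per-population streams are derived from it
deterministically, so identical configurations give byte-identical panels.
Because the ancestral burn-in consumes the RNG before the split, two
configurations differing only in $T$ share their ancestral state under the
same seed — the divergence-monotonicity experiment exploits this pairing to
cut Monte-Carlo noise.

**Problem sizes.** The Monte-Carlo checks run at sizes chosen to give
clear signal quickly: divergence monotonicity uses $N = 100$, 36 loci at
rate 0.002, 40 sampled per population, 50 replicates per split time
$T \in \{20, 100, 500\}$; null calibration uses $T = 0$ splits with 12
loci and 199 permutations. The published-spectrum reconstructions
(400 samples, 392 singleton + 4 doubleton haplotypes) are exact, not
stochastic.

## Degenerate inputs and edge rules

* Diversity of a spectrum with $n < 2$ is undefined and raises an error.
* A single population skips the Rst/MDS/NJ pipeline stages with a logged
  notice; two populations skip only the tree.
* An all-zero distance matrix embeds to all-zero coordinates.
* Exact-count spectrum sampling reproduces the input spectrum exactly;
  multinomial mode is seeded.
* Frequency tables print at 4 decimals but always sum to 1 before
  rounding; the printed GD row uses the same convention.

## Known limitations

* Haplotype-frequency confidence intervals, reference-database surveying,
  and mutation-rate estimation are out of scope.
* Rst assumes the stepwise mutation model; for loci violating SMM (e.g.
  frequent multi-step changes) allele-identity measures like Fst behave
  differently and are not provided.
* The AMOVA is two-level (population/individual); hierarchical
  region-level designs are not implemented.
* NJ and MDS replicate the *method*, not any specific program's tie-break
  choices, so figure-level topology identity with desktop tools is not
  guaranteed on non-additive matrices.
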