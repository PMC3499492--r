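---
title: "Methods: organelle haplotype phylogeography with haplorigin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle haplotype phylogeography with haplorigin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(haplorigin)
```

`haplorigin` reimplements a complete organelle-DNA phylogeography
workflow for rice domestication: diversity statistics, group
differentiation, a median-joining haplotype network, a bootstrapped
neighbor-joining phylogeny, Bayesian admixture clustering, molecular-clock
dating, and haplotype-sharing progenitor identification. This vignette
explains the models, the tunable parameters, the numerical conventions,
and what the shipped synthetic-data generator does and does not emulate.

## Data model and masking

Input is a set of per-locus aligned FASTA files (six chloroplast and four
mitochondrial loci in the motivating design), a partition map assigning
each locus to an organelle, and a metadata table (species, subspecies,
tropical/subtropical group, province, decimal coordinates). Loci are
concatenated with contiguous 1-based offsets; all coordinates in reports
and outputs are 1-based inclusive.

Indels are excluded from every statistic. We apply *complete deletion*:
a concatenated column is dropped from the analysis mask if **any**
accession carries `-`, `N`, `?`, or an IUPAC ambiguity code there.
Ambiguity codes are conservatively treated as missing rather than as
partial information, since none of the downstream estimators can use a
fractional base call. One global mask, computed over the full accession
set including the outgroup, serves every downstream statistic, so numbers
computed on different scopes (cultivated vs wild, chloroplast vs
mitochondrial) refer to the same column set and stay comparable.
Per-scope re-masking exists behind `collapse_haplotypes(remask = TRUE)`
but is not the default. The chloroplast and mitochondrial views partition
the mask column-by-column, which makes segregating sites exactly additive
across organelles — a property the test suite asserts.

Haplotypes are equivalence classes of identical masked sequences. Labels
H1, H2, … are assigned by decreasing member count with ties broken by
first occurrence, purely so results are deterministic and testable; the
labels carry no meaning beyond that.

## Diversity estimators

For a scope of n sequences over L analyzed sites we report S (segregating
sites), h (haplotype count), and three classical estimators:

* Hd = n/(n−1) · (1 − Σᵢ pᵢ²), the unbiased haplotype diversity over
  haplotype frequencies pᵢ; with two haplotypes this is n/(n−1)·2pq.
* π = Σ_{i<j} d_ij / (C(n,2)·L), mean pairwise differences per site.
  Internally π is computed from haplotype frequencies
  (Σ n_i n_j k_ij terms), which the tests verify agrees with the
  all-pairs definition to 1×10⁻¹².
* θ_w = S / (a·L) with a = Σ_{k=1}^{n−1} 1/k.

θ_w uses the **full masked length** L, not a silent-site length. Tables
formatted by `write_diversity_table()` report π and θ_w ×10³ at two
decimals, the conventional scale for organelle data. Estimators refuse
n < 2.

## Differentiation: AMOVA Φ_ST

Between two groups we use the distance-based AMOVA with pairwise
nucleotide differences as squared distances — the estimator desktop
Arlequin applies to haplotype sequence data:

    SSD_WP = Σ_p (1/n_p) Σ_{i<j∈p} d_ij        SSD_T = (1/n) Σ_{i<j} d_ij
    σ²_w = SSD_WP/(n−2)                         n' = n − Σ_p n_p²/n
    σ²_a = (SSD_T − SSD_WP − σ²_w)/n'           Φ_ST = σ²_a/(σ²_a + σ²_w)

Conventions: when the total sum of squared distances is zero (both groups
monomorphic for one haplotype) Φ_ST is defined as 0; negative σ²_a is
clamped so Φ_ST ∈ [0, 1], with the raw ratio kept in `phi_st_raw`. A
Hudson-style 1 − H_w/H_b variant (`estimator = "hudson"`) is provided for
sensitivity analysis, and a seeded label-permutation test
(`fst_permutation_test`, default 1000 permutations) gives informational
p-values. Under panmixia the raw estimator is mean-zero only when group
labels are independent of the genealogy; the null test therefore
randomizes the split per replicate.

## Median-joining network

`build_mj_network()` follows the classical two-phase construction:

1. **ε-relaxed minimum spanning network.** Edge (u, v) is admitted when
   its Hamming weight is at most the weight at which the components of u
   and v merge during Kruskal agglomeration, plus ε. At ε = 0 this is the
   union of all minimum spanning trees; over a fixed node set the link
   set is monotone in ε. The default ε = 0 matches common practice when
   no relaxation is specified. Kruskal ties are broken by
   (weight, lexicographic node pair) for determinism.
2. **Median insertion.** For every mutually linked triplet, the
   column-wise majority consensus is computed; a triplet contributes no
   median if any column shows three distinct states (the conservative
   multistate treatment — we do not fall back to the first node's state).
   Novel consensus signatures join the node set as median vectors mv1,
   mv2, …, and the network is rebuilt until no new median arises.

Finally, median vectors of degree ≤ 2 whose removal does not raise the
minimum spanning cost of the remaining nodes are pruned iteratively.
Both loops carry a 100-iteration cap and abort on non-convergence rather
than returning a partial network. Every edge is labelled with the Hamming
distance between its endpoints; adding medians can only keep the spanning
cost at or below the sampled-haplotype MST cost, which the tests verify
against a spanning-tree enumeration oracle on small inputs.
`medians = FALSE` yields the plain ε-MSN when inferred intermediates are
not wanted.

## Phylogeny

Distances between haplotypes use Kimura's two-parameter model,
d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q), with transition and transversion
proportions computed over the masked columns (invariant columns count in
the denominator, so d is per analyzed site). Saturated pairs — logarithm
domain violations — abort with the offending pair named; we deliberately
do not substitute an arbitrary large distance. The matrix is cross-checked
in the tests against an independent K80 implementation.

Trees are built over haplotypes (alleles), not over all accessions, since
organelle genomes are inherited as units; an accession-level tree is just
the haplotype tree with tips duplicated. Neighbor-joining uses the
standard Q-criterion agglomeration; negative branch lengths are clamped
to zero with the raw values kept in an attribute. Bootstrap resampling
draws columns with replacement from the full masked concatenation (not
per locus), matching a single combined analysis; support is the
percentage of replicate trees containing each internal bipartition, and
the whole procedure is seeded. Rooting places the root at the midpoint of
the outgroup's pendant edge, preserving all leaf-to-leaf path lengths.

## Bayesian clustering

The clustering model is a haploid admixture model with independent allele
frequencies: individual i carries allele x_il at locus l; its latent
origin z_il is Categorical(q_i); cluster k's allele frequencies p_kl have
a symmetric Dirichlet(λ) prior, and admixture proportions q_i a symmetric
Dirichlet(α) prior. Gibbs sweeps update z, p, q from their conjugate
conditionals (z via a vectorized Gumbel-max draw). α is fixed, not
sampled, and defaults to 1, as does λ; both are configurable. Model
evidence per K is approximated as Ln P(D) = mean(lnL) − var(lnL)/2 over
retained sweeps, with lnL the mixture log-likelihood at the sweep's
(q, p); `select_k` takes the argmax with ties to the smaller K, and hard
assignment requires a membership proportion strictly above 0.6.

Two caveats are worth stating prominently. First, the ten organelle loci
are physically linked in reality — they share one genealogy — yet the
model treats them as conditionally independent markers given z, exactly
as the desktop STRUCTURE analysis of such data does; the clustering is
therefore a descriptive summary of haplotype structure, not an inference
about recombining loci. Second, cluster labels are arbitrary:
`align_clusters()` performs greedy maximal-overlap matching across runs
for reporting only.

Paper-faithful MCMC sizes (100,000 burn-in + 100,000 sweeps, thinning 10)
are the defaults; the test suite uses desk-scale runs (hundreds to a few
thousand sweeps), which the strongly informative test fixtures mix well
under — the sampler's own tests verify two-population recovery,
aligned-membership recovery from model-simulated data (mean absolute
error < 0.1), and selection of K = 5 on a five-population fixture in at
least 8 of 10 seeded runs.

## Molecular-clock dating

Sites at which all indica share one state and all japonica a different
one (fixed differences, no frequency threshold) are counted per organelle
view. The divergence time applies the printed organelle clock exactly:
T = 3N/(Lµ) for chloroplast and T = 12N/(Lµ) for mitochondrial loci,
with µ = 7.16×10⁻⁹ substitutions/site/yr (the rice nuclear-gene rate) and
the 1:3:12 mt:cp:nuclear rate ratio supplying the multipliers. All three
constants are configurable via `clock_params()`.

The ratio admits a second reading — as organelle *rates*
r_org = µ·ratio/12 with the standard divergence formula T = N/(2Lr) —
which gives different times (2N/(Lµ) for chloroplast, 6N/(Lµ) for
mitochondria). `divergence_time()` reports this alternative in an
`alternatives` attribute rather than silently choosing: only the formula
arithmetic itself is treated as testable, and linearity in N and 1/L is
asserted by the tests.

## Phylogeography

A wild accession is a candidate progenitor when its combined haplotype is
carried by at least one cultivated accession; it is flagged for the
subspecies carrying that haplotype, and a haplotype carried by both
subspecies raises a `conflict` flag. The Tropic of Cancer (23.5° N)
separates tropical from subtropical; the boundary latitude itself is
classed subtropical (strict `<` for tropical), a choice consistent with
progenitors "near the TOC on the south side" being tropical. Regional
haplotype numbers count presence (≥ 1 accession), not frequency, and
percentages are reported integer-rounded alongside the raw ratios. The
latitude-range summary flags `indica_lower` when both the minimum and the
maximum of the indica-progenitor range lie below japonica's — the ranges
may still overlap, as they do in the motivating data, so "entirely
disjoint" would be the wrong criterion.

## The synthetic-data generator

Because the analysis needs realistic inputs without any external
download, `simulate_organelle()` generates the full dataset from a seeded
scenario whose defaults are the study conditions: 27 indica + 23 japonica
cultivars, 73 tropical + 46 subtropical wild accessions, one outgroup,
ten loci totalling 9161 bp (5420 chloroplast + 3741 mitochondrial,
inside the printed 9089–9233 range; per-locus lengths are plausible
reconstructions).

The generative model, in order:

1. A random root sequence; two wild clades (indica-like, japonica-like)
   separated by forced diagnostic substitutions on the clade stems —
   10 chloroplast and 3 mitochondrial by default, alternating stems so
   the outgroup sits between the clades. Stem substitutions are specified
   exactly (not Poisson), so diagnostic-site counts are reproduced
   exactly.
2. Clade founder haplotypes sit at the clade ancestors. The japonica
   founder (J1) and the first indica founder (I1) are the ancestors; the
   second indica founder (I2) is offset by one chloroplast substitution,
   making the two indica haplotypes mitochondrially identical — hence the
   cultivated mitochondrial partition is exactly two haplotypes split
   27/23.
3. Derived wild haplotypes arise on per-clade coalescent genealogies
   (`ape::rcoal`), with infinite-sites mutations dropped as a Poisson
   process at rate (θ_cp·L_cp + θ_mt·L_mt)/2 per branch-length unit and
   assigned to organelles proportionally to θ·L. Pendant branches are
   conditioned on at least one mutation (`distinct_haplotypes = TRUE`),
   so the realized wild haplotype count equals the design (15). The
   default per-site rates θ_cp = 1.5×10⁻⁴ and θ_mt = 5×10⁻⁵ keep the
   3:1 chloroplast:mitochondrial ratio and put wild polymorphism at the
   study's scale; the 15-distinct-haplotype and 13-diagnostic design
   imposes a floor of 26 wild segregating sites, so the fixture sits
   slightly above the printed wild S.
4. Wild accessions are placed on haplotypes, provinces and latitude
   groups by an explicit sampling-design table
   (`default_wild_design()`): the japonica-like clade is subtropical with
   J1 also reaching tropical sites near the TOC; the indica-like clade is
   tropical; one haplotype (J6) is confined outside Southern China, so 14
   of 15 wild haplotypes (93 %) occur there. Latitudes are drawn
   uniformly within illustrative per-province bounding boxes clipped by
   group, with the founder range endpoints pinned (japonica progenitors
   22.25–26.8° N, indica progenitors 18.25–23.3° N). Coordinates are
   illustrative, not sourced survey data.
5. Cultivars replicate the founder haplotypes to the design counts
   (japonica 23×J1; indica 25×I1 + 2×I2, reproducing the printed
   cultivated haplotype-frequency spectrum); the outgroup receives 25
   substitutions on its own stem.

A truth record (per-accession clade/haplotype/progenitor labels and
per-column mutation placements) accompanies every dataset.

What the generator does **not** emulate: recurrent mutation (an
infinite-sites discipline is enforced; a saturation mode would need a
finite-sites model), recombination and wild–cultivated introgression,
within-haplotype sequence variation among accessions sharing a haplotype
(accessions are exact copies of their haplotype, as organelle data make
possible), and accession-level coalescent frequencies (membership counts
follow the design table rather than an evolving frequency spectrum).
Passing tests on these fixtures therefore demonstrate correctness of the
estimators and algorithms under the study's design — not robustness to
introgression, sequencing error, or model misspecification in real
surveys.

`simulate_coalescent()` exposes the bare single-population
infinite-sites process; under it E[S] = θ·L·Σ 1/k, and the suite checks
over 200 seeded replicates that the mean of θ̂_w falls within three
standard errors of the simulated θ — the calibration link between
generator and estimator.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes data → diversity → Φ_ST → network → tree →
clustering → dating → geography, writing plain TSV/GraphML/newick/JSON
outputs. One base seed fans out through fixed offsets (bootstrap:
seed + 1, clustering: seed + 2, per-K Gibbs runs: config seed + K), so
toggling one stage never shifts another stage's random stream; the
manifest records the seed and a parameter hash, and contains no
timestamps, making identical configurations byte-identical end to end.

The test suite runs everything at desk scale, chosen as the smallest
sizes at which each property is cleanly decidable: oracle-equivalence
loops on 6–10 sequences × 25–40 columns; bootstrap checks at 30–100
replicates on the study-scale fixture; Gibbs recovery at 2000 + 2000
sweeps (n = 90, 20 markers) and K-selection at 800 + 800 sweeps over
K = 2–7 × 10 seeds (n = 100, 10 markers); generator calibration at 200
replicates of n = 20 × 1000 bp; and two full pipeline runs at reduced
bootstrap/MCMC sizes for the determinism check. Paper-faithful sizes
(1000 bootstrap replicates, K = 2–10, 10⁵ + 10⁵ sweeps) remain the
function defaults.

## Known limitations

* Φ_ST here is the distance-based two-group AMOVA; Arlequin's
  haplotype-frequency variants and multi-level AMOVA are out of scope,
  and printed non-zero Φ_ST values from the motivating study are treated
  as qualitative patterns (which the fixture reproduces), not as exact
  reproduction targets.
* The clustering model ignores linkage between organelle loci by
  construction (see above).
* The clock's printed formula and its rate-ratio reading disagree; both
  are reported, neither is adjudicated.
* The median-joining implementation targets the small haplotype counts of
  organelle surveys (tens of nodes); its triplet scan is cubic in the
  node count and is not intended for thousands of haplotypes.
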