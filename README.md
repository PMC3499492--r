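# haplorigin

Organelle-DNA phylogeography of rice domestication, as a tested, reusable
R pipeline.

## The problem

Asian cultivated rice (*Oryza sativa*) comprises two subspecies, indica
and japonica, domesticated from common wild rice (*O. rufipogon*). Two
questions are still argued for China: *where* was rice domesticated, and
*how many times*? Chloroplast and mitochondrial DNA are well suited to
these questions — uniparentally inherited, non-recombining, and slowly
evolving — so a wild accession whose combined organelle haplotype is
identical to a cultivated haplotype is a candidate direct progenitor, and
the geography of those progenitors localizes domestication.

`haplorigin` implements the complete analysis for this design: partitioned
multi-locus organelle alignments (six chloroplast + four mitochondrial
loci) for cultivated, wild and outgroup accessions, with sample metadata
(species, subspecies, tropical/subtropical group split at the Tropic of
Cancer, province, coordinates). It is aimed at population geneticists and
crop-domestication researchers who want each stage as a composable,
tibble-first function rather than a chain of desktop programs (DnaSP,
Arlequin, NETWORK, PAUP*, STRUCTURE).

## What it computes

* **Data model** — per-locus aligned FASTA + partition map + metadata TSV
  are concatenated with 1-based locus offsets; the *analysis mask* keeps
  only columns where every accession has an unambiguous base (complete
  deletion of indel/missing/ambiguous columns). Identical masked sequences
  collapse into haplotypes H1, H2, … labelled by decreasing frequency.
* **Diversity** (`diversity_stats`, `diversity_table`) — segregating sites
  S; haplotype number h; unbiased haplotype diversity
  Hd = n/(n−1)·(1 − Σ pᵢ²); nucleotide diversity
  π = Σ_{i<j} d_ij / (C(n,2)·L); Watterson's θ_w = S/(a·L) with
  a = Σ_{k=1}^{n−1} 1/k.
* **Differentiation** (`pairwise_fst`, `fst_matrix`) — distance-based
  AMOVA Φ_ST on pairwise nucleotide differences (the Arlequin-style
  estimator for haplotype sequence data), with variance components σ²_a,
  σ²_w, the zero-total-variance convention Φ_ST = 0, a seeded permutation
  test, and a Hudson 1 − H_w/H_b variant for sensitivity analysis.
* **Haplotype network** (`build_mj_network`) — median-joining network:
  ε-relaxed minimum spanning network, iterative insertion of median
  (Steiner) vectors from mutually linked triplets, pruning of obsolete
  medians; edges weighted by mutational steps; GraphML/DOT/TSV export and
  an `autoplot()` method.
* **Phylogeny** (`k2p_matrix`, `nj_tree`, `bootstrap_support`,
  `root_with_outgroup`) — Kimura two-parameter distances
  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q), neighbor-joining over haplotypes,
  nonparametric bootstrap over the masked concatenation, outgroup rooting
  on the *O. barthii* allele.
* **Bayesian clustering** (`run_structure`) — haploid admixture model with
  independent allele frequencies fitted by Gibbs sampling (STRUCTURE-style);
  model choice by Ln P(D) = mean(lnL) − var(lnL)/2 across K; hard
  assignment by the strict >60 % membership rule.
* **Molecular dating** (`clock_table`) — substitutions fixed between
  indica and japonica (diagnostic sites N) converted with the organelle
  clock T = 3N/(Lµ) (chloroplast) and T = 12N/(Lµ) (mitochondria), µ the
  rice nuclear rate 7.16×10⁻⁹ /site/yr, from the 1:3:12
  mt:cp:nuclear rate ratio.
* **Phylogeography** (`identify_ancestors`, `region_distribution`,
  `latitude_ranges`, `toc_classify`) — progenitor identification by
  haplotype sharing, haplotype-by-province distributions, the
  Southern-China (Guangdong + Guangxi + Hainan) share of wild haplotype
  diversity, the domestication bottleneck retention ratio, and progenitor
  latitude ranges around the Tropic of Cancer (23.5° N).
* **Synthetic data** (`simulate_organelle`, `paper_scenario`) — a seeded
  generator that emulates the study's sampling design (27 indica + 23
  japonica cultivars, 73 tropical + 46 subtropical wild accessions, one
  outgroup, ten loci totalling 9161 bp, two diverged wild clades, a
  3-of-15 haplotype bottleneck) with a machine-readable truth record, so
  every stage is testable without any external download.
* **Pipeline** (`run_pipeline`, `pipeline_report`) — config-driven
  end-to-end run with TSV outputs, a deterministic manifest, and a
  collated plain-text report.

## Worked example

```r
library(haplorigin)

sim <- simulate_organelle(paper_scenario())   # seeded study-scale dataset
cfg <- pipeline_config(scenario = paper_scenario(), out_dir = "run",
                       bootstrap_reps = 200, k_range = 2:3,
                       mcmc_steps = 500, burn_in = 500, thinning = 5,
                       seed = 7)
bundle <- run_pipeline(cfg)
writeLines(pipeline_report(bundle))
```

The report prints (abridged):

```
Diversity summary:
     scope     organelle   n  S  h    Hd   pi theta_w    L
    sativa   chloroplast  50 11  3 0.548 0.95    0.45 5420
 rufipogon   chloroplast 119 24 15 0.912 1.24    0.83 5420
    sativa mitochondrial  50  3  2 0.507 0.41    0.18 3741
 rufipogon mitochondrial 119  8  6 0.746 0.60    0.40 3741
    sativa      combined  50 14  3 0.548 0.73    0.34 9161
 rufipogon      combined 119 32 15 0.912 0.98    0.65 9161

Diagnostic-site dating:
     organelle  N    L   T_years T_Myr
   chloroplast 10 5420  773052.4  0.77
 mitochondrial  3 3741 1344007.7  1.34

Wild progenitor accessions: 49
Progenitor latitude ranges:
 progenitor_of  n lat_min lat_max
        indica 26   18.25    23.3
      japonica 23   22.25    26.8

Southern-China haplotypes: 14 of 15 (93%); cultivated retention: 20%
```

Reading this: cultivated rice carries far fewer haplotypes (3 vs 15) and
lower θ_w than wild rice — the domestication bottleneck retained ~20 % of
wild haplotype diversity. π and θ_w are reported ×10³. The wild accessions
sharing cultivated haplotypes (the inferred progenitors) split cleanly:
indica's progenitors lie south of the Tropic of Cancer (18.25–23.3° N),
japonica's sit higher (22.25–26.8° N), and 14 of the 15 wild haplotypes
occur in Southern China — the diversity center. The dating rows apply the
printed clock formula to the 10 chloroplast + 3 mitochondrial diagnostic
substitutions.

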