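---
title: "Methods: genomic parentage inference for clonal hybrid cultivars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic parentage inference for clonal hybrid cultivars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriseek)
```

## The inference problem

Many perennial crop cultivars — clonally propagated citrus being the textbook
case — descend from a single historical hybridization event and have since
been maintained as a clone group differing only by somatic mutations.
Identifying the two parents of such a cultivar from modern germplasm is a
parentage-inference problem with an unusual structure: the "offspring" is a
clone group, candidate parents are themselves living cultivars (possibly
admixed between two progenitor species, e.g. mandarin and pummelo), and the
decisive evidence comes from several partly independent genomic signals.

`hybriseek` implements the four signals this kind of study rests on, plus a
synthetic-data generator that emulates the population structure so every
stage can be validated against known truth:

1. **Diagnostic-SNP genome painting** — classify fixed-width windows of each
   accession's genome as homozygous species-A (`MM`), homozygous species-B
   (`PP`), heterozygous (`MP`) or `unknown`, using SNPs (near-)fixed for
   opposite alleles in two pure reference panels.
2. **Method-of-moments IBD** — PLINK-style Z0/Z1/Z2 estimates per pair;
   a parent–offspring pair shows Z1 ≈ 1 and zero opposing homozygotes.
3. **Haplotype copying** — a deterministic minimal-cost segmentation of each
   recipient haplotype into donor-copied fragments; per-donor fragment
   counts ("copying vectors") rank relatives.
4. **Trio coincidence probability** — the decisive statistic: the percentage
   of SNPs at which the putative offspring's genotype is Mendelian-compatible
   with a candidate parent pair — with exhaustive ranking over all candidate
   pairs, and chloroplast p-distances to orient the winning pair into seed
   (maternal) and pollen parent.

## The trio statistic

For genotype dosages $g_O, g_A, g_B \in \{0,1,2\}$, the gamete sets are
$\{0\}$, $\{0,1\}$ and $\{1\}$, so the offspring dosages reachable from a
parent pair form the contiguous range

$$\big[\,(g_A{=}2) + (g_B{=}2),\; (g_A{\geq}1) + (g_B{\geq}1)\,\big].$$

The coincidence probability of a trio is $100\times$ the fraction of
evaluated sites whose offspring dosage lies in that range. Sites with any
missing call in the trio are skipped. Two denominators are reported:

* `informative_only = TRUE` (default) excludes sites where *both* parents are
  heterozygous, because every offspring genotype is compatible there — such
  sites can only dilute the contrast between true and false pairs;
* `informative_only = FALSE` keeps every called site.

Both modes are first-class outputs because the field reports such statistics
without always specifying the denominator. The quoted "±" dispersion is the
standard deviation over per-chromosome coincidence values (nine values for
citrus); a leave-one-chromosome-out jackknife standard error is available via
`dispersion = "jackknife"`. Genotypes are treated as unphased dosages, so a
*de novo* or somatic mutation in the offspring counts as an incompatibility —
relevant for clone groups, which carry somatic mutations by definition; this
is why even a true trio scores slightly below 100 at non-zero genotyping
error, and why the statistic is used as a *ranking*, not an absolute test.

Candidate-pair ranking scores every unordered pair, sorting by coincidence,
then informative-site count, then lexical ids — a total order, so reruns are
reproducible.

## IBD estimation and its frequency assumption

The IBD module equates observed IBS0/1/2 site counts with their expectations
under site allele frequencies $p$:

$$P(\mathrm{IBS0}\mid Z_0)=2p^2q^2,\quad
  P(\mathrm{IBS1}\mid Z_0)=4pq(p^2+q^2),\quad
  P(\mathrm{IBS1}\mid Z_1)=2pq,\ \ldots$$

solving sequentially for $Z_0, Z_1, Z_2$, truncating negative estimates to
zero and renormalizing (the standard practice for this estimator family;
PLINK's finite-sample correction factors are not applied). $\hat\pi =
Z_2 + Z_1/2$.

The estimator assumes genotypes drawn from one population with known
frequencies. In a structured cohort (pure species panels plus admixed
cultivars) frequencies estimated from the pooled cohort are badly biased: at
species-diagnostic sites the pooled frequency is intermediate while a
mandarin parent–offspring pair is monomorphic, which deflates Z1 by on the
order of 0.1–0.2 in our simulations. `ibd_moments()` therefore accepts an
explicit frequency vector, and every calibration in this package estimates
frequencies from the pure species-A reference panel (20 accessions by
default). The pipeline does the same. Users analysing real data should pass
frequencies from a panel matching the pair's population.

## Haplotype copying without MCMC

Probabilistic chromosome-painting models (ChromoPainter-style) estimate how
much of each recipient haplotype is copied from each donor. This package
substitutes a deterministic minimal-cost copying model solved exactly by
dynamic programming: copying a mismatched allele costs `mismatch_cost`
(default 0.5), changing donor haplotype between adjacent sites costs
`switch_cost` (default 1.0), uniformly along the genome (no genetic map).
Ties break toward staying with the current donor and then toward the
lowest-index donor, so output is deterministic; optimality is verified in the
test suite against exhaustive path enumeration on small instances.

The per-donor *fragment counts* are the working quantity: true parents and
co-clones receive the most fragments. Absolute counts depend on marker
density and the cost settings and are **not** comparable across datasets or
to counts from probabilistic painters; only their ranking is used. Recipient
missing sites are skipped; a missing donor allele costs `mismatch_cost / 2`
(an even bet), keeping the segmentation deterministic under missingness.

## Chloroplast orientation

The chloroplast is maternally inherited, so the seed parent of a cross is the
candidate whose cp haplotype is nearest the query. Distances are p-distances
over shared called sites on effectively haploid calls (heterozygous cp calls
are dropped with a logged count; haploid VCF GT fields are folded to
homozygous dosages on reading). A neighbor-joining tree (textbook iterative
Q-matrix; negative branch lengths clamped to zero with a log; the final edge
split at its midpoint, which preserves all leaf-to-leaf path lengths) is
emitted in Newick for visual inspection. `decide_origin()` combines the
evidence deterministically and never silently overrides a conflict: if the
cp-nearest candidate is not in the best-scoring pair the orientation is
reported `"unresolved"`; absent cp data it is `"undetermined"`.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates:

* two diverged founder pools sharing one site set: a fraction of sites
  (default 0.3) carries a fixed allelic difference (frequencies 0 vs 1); all
  other sites share a single ancestral frequency drawn from Beta(0.5, 0.5).
  With `fixed_diff_fraction = 0` the species labels are exchangeable by
  construction;
* pure reference panels (default 20 + 20 accessions — a desk-scale analogue
  of the panel-rich cohorts real studies assemble, and large enough to
  estimate panel frequencies for the IBD module);
* admixed cultivars: species-B blocks with exponential lengths (mean 5 Mb)
  spliced into a species-A background by an alternating renewal process, per
  haplotype; 20 candidates with introgression fractions 0–0.20, the
  designated seed parent fully mandarin-like (fraction 0) and the pollen
  parent at 0.10;
* one F1 from the designated cross: one recombinant gamete per parent,
  crossovers Poisson(1.5 per chromosome), uniform placement, no
  interference (no published genetic map is assumed);
* a clone group (default 5) derived from the F1 at somatic rate $10^{-4}$
  per site per clone, each mutation flipping one haplotype allele;
* symmetric genotype error (default 0.005) and missingness (default 0.02)
  applied to hard genotypes — no allele-balance or depth model, because the
  pipeline consumes hard genotypes only. Corruption would break the
  haplotype-sum invariant, so corrupted sites are re-phased canonically
  (0 → 0|0, 1 → 0|1, 2 → 1|1); downstream haplotype analyses are robust to
  this because corrupted sites are a small minority;
* maternally inherited chloroplast haplotypes (default 200 sites; founders
  independent, offspring = mother + Poisson mutations).

Defaults: nine chromosomes of 30 Mb with 5556 sites each (~5 × 10⁴ sites
genome-wide). Ground truth (pedigree, per-sample ancestry blocks, clone
lineage, cp maternal lines, gamete sources) is emitted alongside the data.

Deliberately **not** modelled: coalescent-exact founder histories, linkage
disequilibrium within founder pools (sites are independent given the
frequencies), crossover interference, indels/SVs, selection, and read-level
sequencing artefacts. Consequently, passing tests demonstrate that the
estimators are correctly implemented and calibrated under their own
assumptions — not that those assumptions hold in any particular real
dataset. In particular the within-pool site independence makes LD pruning
nearly a no-op on synthetic data (it is exercised by dedicated tests), and
makes candidate ranking somewhat easier than with real haplotype structure.

## Numerical and design choices

* **Windows**: painting uses non-overlapping 500 kb windows, at least 10
  classified diagnostic calls per called window, and a 0.8 majority-vote
  threshold; windows below threshold are `unknown`. No HMM smoothing — the
  four-colour landscape this emulates is coarse, and a majority vote is
  transparent and monotone (raising `min_sites` can only turn calls into
  `unknown`). Window size is a free parameter exposed in the configuration.
* **Ascertainment**: diagnostic sites require ≥ 3 called samples per panel
  and alt frequency ≤ 0.05 in one panel and ≥ 0.95 in the other; near-fixed
  rather than strictly fixed, which is robust at small panel sizes.
* **Site filters**: defaults `max_missing = 0.2`, `min_maf = 0.01`;
  LD pruning at genotype-dosage r² > 0.9 in 50-site windows stepping by 5,
  pairwise-complete over missing data, keeping the earlier site on conflict;
  monomorphic sites (undefined r²) are never pruned on r² grounds. With
  `min_maf = 0` the MAF bound is not applied at all, so the filter at
  `max_missing = 1` is the identity.
* **PCA**: mean imputation per site, centering at 2p and scaling by
  √(2p(1−p)), constant sites dropped with a log; component signs fixed so
  the largest-magnitude entry is positive.
* **Degenerate inputs**: trios with zero evaluable sites, empty panels,
  pairs with no shared called cp sites, and cyclic cp pedigrees are errors,
  not silent results; a pair with fewer than 100 informative sites is
  flagged `low_confidence`.

## Validation problem sizes

The test suite validates each stage against independent oracles (gamete
enumeration for the trio statistic, exhaustive path enumeration for the
copying DP, naive per-site recounts for IBS and site filters, closed-form
3-taxon formulas and `ape::nj` for neighbor joining) and then checks the
calibrated end-to-end properties at the generator's study conditions:
50 seeded replicates at ~5 × 10⁴ sites for parent-pair recovery, a full-size
error-free cohort for IBD calibration (with full-sib expectations averaged
over eight independent sib pairs, since realized IBD per pair fluctuates
widely with nine chromosomes), 20 replicates at ~1.35 × 10⁴ sites for donor
ranking, and 20 chloroplast pedigrees for maternal assignment. The bundled
demo (`run_demo()`) runs the entire pipeline on a 9 × 700-site cohort in
well under a minute.

## Known limitations

* The trio statistic has no genotyping-error model (no CERVUS-style
  likelihood); its absolute value depends on the error rate and on the
  `informative_only` denominator, so compare pairs within one dataset only.
* IBD estimates inherit the frequency-cohort caveat above; in strongly
  structured cohorts without a clean reference panel, both Z1 and PI_HAT are
  biased.
* The copying model is deliberately simpler than probabilistic painters: no
  recombination-map-aware switch costs, no per-donor copying proportions
  normalization, no MCMC uncertainty.
* Chloroplast assignment assumes the true seed parent (or a maternal-line
  relative) is among the candidates; the nearest candidate is reported even
  when all distances are large, so inspect the emitted distances and NJ
  tree.
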