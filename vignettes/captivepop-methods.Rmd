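---
title: "Simulating and analysing genomic diversity in captive breeding programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing genomic diversity in captive breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captivepop)
```

# The problem

Captive breeding programs hold small, closed populations for many
generations before reintroduction. Three forces erode the genomic
diversity (GD) those programs exist to preserve: inbreeding, genetic
drift, and selection — both deliberate (e.g. breeding for docile
behaviour) and inadvertent (adaptation to captivity). `captivepop`
provides a forward-in-time simulator of such colonies under the three
breeder-selection protocols used in practice, and the statistical
machinery to analyse SNP panels and pedigrees from them:

* pedigree kinship $f$, inbreeding $F$, and mean kinship $mk$, with a
  gene-dropping Monte Carlo oracle;
* a simulation-based neutrality test that flags SNPs whose
  allele-frequency change is inconsistent with drift under the matched
  breeding protocol;
* D′-based linkage grouping of unphased genotypes and resampled
  multilocus heterozygosity (MLH);
* effective population size from heterozygosity loss;
* permutation-tested heterozygosity–fitness correlations (HFCs).

A synthetic-data generator emulates the full study design (20 wild
founders in 10 pairs, replicate colonies at 20 pairs per generation for
20 generations, block-structured genotypes, a heritable docility trait,
inbreeding depression on fitness traits), so every stage runs and is
testable with no external data.

# The breeding model

Generations are discrete and non-overlapping; pairs are monogamous.
Each generation:

1. **Breeder selection** from the living cohort, by protocol:
   * **MK** — the ranked mean-kinship procedure. Mean kinship
     $mk_i = \frac{1}{n}\sum_j f_{ij}$ is computed over the living
     cohort; the single individual with the highest $mk$ (whose sex
     still has surplus candidates) is removed; mean kinships are
     recalculated; this repeats until exactly $n_\text{pairs}$ males
     and females remain. Ties are broken by a seeded uniform draw.
     A batch-removal variant (all tied-top individuals at once) exists
     but is off by default.
   * **RAN** — uniform random choice of breeders.
   * **DOC** — the $n_\text{pairs}$ lowest-scoring (most sedentary)
     individuals of each sex on an additive docility trait. The default
     architecture is 10 loci of equal effect with environmental noise
     scaled for $h^2 \approx 0.5$ in the founders; the trait model is
     configurable because only its additive form, not its architecture,
     is identified by the study design. A null variant that selects DOC
     breeders randomly is available; trait-based selection is the
     default reading.
2. **Pairing under the close-kin rule**: a proposed pair is admissible
   only if its kinship does not exceed the mean pairwise kinship of the
   living cohort. Males are matched most-constrained-first (fewest
   admissible partners) and receive a uniformly chosen admissible
   female; if none is admissible the minimum-kinship female is used and
   the relaxation is logged. (A naive redraw-until-admissible scheme
   cannot guarantee that a male related to all but one female ends up
   with that female; most-constrained-first does.)
3. **Reproduction**: per-pair litter sizes are drawn from the
   offspring-count distribution — by default a negative binomial with
   mean 4 and dispersion 2, truncated at 12, standing in for the
   observed distribution of offspring weaned per pair. Each offspring
   receives one uniformly chosen allele per parent per locus and is
   assigned male/female with probability 0.5.

The kinship matrix is grown generation-by-generation with the tabular
recursion $f_{ij} = \tfrac12(f_{s_i j} + f_{d_i j})$,
$f_{ii} = \tfrac12(1 + f_{s_i d_i})$, with founders unrelated and
non-inbred; an unknown single parent is treated as a unique unrelated
founder. Since parents always precede offspring and generations do not
overlap, the extension is a handful of dense matrix operations per
generation, which is what makes thousands of replicate colonies
tractable in R.

**Extinction.** With 20 pairs and the default litter distribution, a
colony fails when fewer than 20 candidates of either sex remain; this
happens in roughly a fifth of 20-generation runs (the real design lost
one of six colonies). Null-distribution replicates that go extinct are
re-drawn on a fresh sub-seed and the count is logged; analyses that
need a surviving colony condition on survival the same way.

**Viability selection.** The generator can place `selection_loci`
under selection at coefficient $s$: relative pre-weaning fitness is
$w = (1-s)^g$ with $g$ the number of founder-minor alleles at those
loci, and a conceived offspring survives to weaning with probability
$\min(1, w/\bar w)$, where $\bar w$ is the mean fitness of that
generation's conceived cohort. Two considerations force the
normalization. Unnormalized multiplicative survival compounds across
loci — at $s = 0.2$ on 20 loci mean survival is $\approx 0.09$ and
every colony dies immediately, contradicting both the observed
colonies and the litter-size distribution being the *observed weaned
counts*. But selection confined within litters (resampling gametes at
fixed litter sizes) removes between-family fitness variance entirely,
and that variance is the channel through which mean-kinship management
— which equalizes family contributions — damps the response to
selection relative to random mating. Cohort-normalized thinning keeps
both: demography close to the configured distribution, and
family-level selection differentials.

# The neutrality test

For each locus the *minor allele is fixed once*, from the generation-1
founder-offspring genotypes (the earliest genotyped cohort; wild
founders were not genotypable), and the same allele is tracked at every
generation; ties at frequency 0.5 break toward the alphabetically first
allele. The null model is the colony itself: `n_reps` (default 100)
whole-colony replicates are simulated from the same founder state under
the matched protocol with no selection; all loci ride the same pedigree
within a replicate. The p-value of an observed frequency $q$ at the
evaluated generation is the proportion of replicate frequencies
strictly more extreme, i.e. strictly closer to a boundary:
$$p = \frac{\#\{\min(q_\text{sim}, 1-q_\text{sim}) <
\min(q, 1-q)\}}{R}.$$
Benjamini–Hochberg adjustment is applied across loci and a locus is
called *nonneutral* when the adjusted p falls below `fdr_alpha`
(default 0.05). For reporting, results aggregate over linkage units: a
group is flagged iff any member is, and the count is flagged singletons
plus flagged groups.

**Calibration and the boundary atom.** With 100 replicates the p
resolution is 0.01. Among loci still segregating at the evaluated
generation the p-value is calibrated to conservative (the package's
null-calibration check measures a raw-p < 0.05 fraction of ~0.02 among
segregating loci, averaged over sampled generations). But the strict
inequality means a locus *fixed or lost* in the observed colony always
gets p = 0 — no simulated frequency can be strictly closer to the
boundary than the boundary — even when the null loses the locus at the
same rate. In a strongly drifting colony (fitted drift $N_e \approx
31$ here, the range pedigree methods give for 20-pair mouse colonies) a
substantial fraction of null loci is lost by generation 19, all
auto-flagged: the same check measures an overall raw-p < 0.05 fraction
of ~0.15. At late generations "nonneutral" therefore increasingly
means "fixed", which also inverts the expected protocol ordering of
the neutral-minus-nonneutral MLH difference (the flagged set has
heterozygosity ~0 under every protocol, so the difference just tracks
neutral-side heterozygosity — highest under MK). The strict reading is
the faithful one ("closer to either 0 or 1 *than*"), so it is the
default;
`empirical_pvalue(mode = "tie_inclusive")` counts equally-extreme
replicates and restores boundary calibration for users who want a
calibrated test rather than the original procedure. An
`add_one` mode gives the conservative $(b+1)/(R+1)$ variant. This
behaviour is exactly why the package's null-calibration check reports
the raw-p fraction both overall and among segregating loci.

# Linkage grouping and resampled MLH

D′ between two loci is estimated from unphased genotypes by a two-locus
EM (only the double heterozygote is phase-ambiguous), started from
linkage-equilibrium frequencies, tolerance $10^{-8}$, at most 1000
iterations — the two-locus likelihood is well behaved so multiple
restarts are unnecessary; |D| is used and normalized by the standard
$D_\text{max}$. Monomorphic loci and empty overlaps yield `NA`
(unlinked). Grouping connects loci with D′ above the threshold
(default 0.8); candidate groups are maximal cliques; a SNP occurring in
more than one clique is excluded; surviving cliques of two or more are
the putative groups, everything else a singleton. Maximal cliques are
the only reading under which a SNP can "occur in more than one group" —
connected components are disjoint by construction. Note two
consequences users should expect on real data: D′ is inflated toward 1
for rare alleles, so low-MAF panels produce spurious edges; and raising
the threshold is *not* guaranteed to shrink the grouped-SNP count,
because splitting an overlapping clique pair can release excluded loci
back into groups.

Individual MLH is the heterozygous fraction of scorable calls.
Resampled MLH averages, over `n_mlh_replicates` (default 100) draws of
"all singletons plus one random SNP per group", the MLH on that subset
— de-weighting linked blocks without discarding them.

# Diversity, Ne, and HFCs

Group summaries report mean ± SE (sample SD/√n) over individuals per
population × generation. The within-individual partition difference
$d_i = \text{MLH}_\text{neutral} - \text{MLH}_\text{nonneutral}$ is
summarized per protocol as mean ± 1 SE (the "standard error interval").
Effective population size inverts the Wright–Fisher decay
$H_t = H_0(1 - 1/(2N_e))^t$, with $H$ the mean individual
heterozygosity; the default span is $t = 18$ (generation-1 founder
offspring to generation 19) and is configurable because the elapsed-
generation count is genuinely ambiguous (18 vs 19) in the study design.

HFC analysis crosses each diversity measure (all-SNP, neutral,
nonneutral MLH, pedigree F) with each trait in each stratum (females,
males, combined), reporting tie-aware Spearman r and a permutation p
from `n_permutations` (default 1000) permutations of the diversity
vector. The default test is two-sided on |r| — the conservative choice
when correlations of either sign would be reported as findings — with
one-sided alternatives available, and an
exact-enumeration mode for n ≤ 8. Missing values are deleted pairwise
per cell. Note that the SNP-vs-pedigree concordance (MLH vs F) draws
most of its signal from between-generation F spread: within a single
generation F barely varies and the correlation is weak.

# The synthetic world

The generator's defaults state the emulated design: 20 founders in 10
fixed pairs; 6 generation-1 offspring per pair per colony (enough that
a 20-pair colony can start; real founder pairs produced multiple
litters); 500 SNPs of which 40 linkage blocks (sizes 2–5, two to a few
dozen in real data) built from 4 ancestral haplotypes per block with
symmetric-Dirichlet(5) haplotype weights — extreme weights would let
block loci escape the configured founder minor-allele-frequency range
(uniform on [0.05, 0.5]); uniform genotype missingness of 2% (GBS
panels are typically filtered to ≥95% call rate); sampled generations
1, 6, 12, 19 at 15 individuals. Fitness traits are
$\text{baseline} + \text{additive value} - \text{slope}\cdot F +
\text{noise}$ with mouse-scale baselines (weaning weight 8 g, tail
65 mm, ear 16 mm, hind foot 20 mm, 4 offspring weaned) and depression
slopes of a few noise-SDs per unit F, so HFC signs are known by
construction. What the generator does *not* emulate: read-level
genotyping artifacts (allele dropout, depth), age structure,
overlapping generations, mutation, and recombination within blocks
(blocks are few-haplotype systems, sufficient to exercise D′ grouping).
A green test on synthetic data therefore establishes the machinery and
the direction of built-in effects, not any real colony's empirical
values.

# Numerical choices

* All randomness flows from one seed per run; replicate r uses a
  deterministic sub-stream. Seeded functions restore the caller's RNG
  state.
* Kinship is tabular (no path counting): exact, $O(n^2)$, and
  deterministic. The gene-dropping oracle is the independent check, not
  the implementation.
* BH adjustment is the explicit step-up formula (min over $j \ge i$ of
  $m p_{(j)}/j$, capped at 1), cross-checked in tests against
  `p.adjust`.
* The two-way ANOVA on nonneutral counts is `protocol + generation`
  without interaction, with Tukey HSD on generation means, via
  `stats::aov`/`TukeyHSD`.
* Mean kinship includes the self term by default (studbook-software
  convention; the flag `include_self = FALSE` exposes the other
  convention — rankings barely differ in realistic cohorts).
* Degenerate inputs: zero-variance rank vectors, singleton cohorts,
  single-level ANOVA factors, monomorphic loci, and extinct colonies
  all return flagged/NA results rather than errors, except where the
  input contract is violated.

# Known limitations

* The neutrality test inherits the boundary-atom anticonservatism of
  its strict definition (above); at late generations in small colonies
  "nonneutral" increasingly means "fixed".
* D′ grouping semantics (clique + exclusion) can discard a large
  fraction of loci in dense LD, and estimating D′ on individuals
  pooled across populations or generations inflates it (admixture LD);
  estimate within cohorts.
* Pedigree-based F ignores Mendelian sampling variance; its
  correlation with marker heterozygosity weakens as pedigrees deepen —
  visible in the simulator output.
* The simulator is monogamous with non-overlapping generations and no
  re-pairing after failure; none of these relaxations is attempted.
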