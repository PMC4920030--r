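---
title: "Region-based rare-variant testing in case-parent trios with conADA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based rare-variant testing in case-parent trios with conADA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conada)
```

## The problem

Rare-variant association studies aggregate many low-frequency variants in
a gene or small chromosomal region because no single rare variant carries
enough information to be tested on its own. In case-parent trio designs
(an affected child plus both genotyped parents) the transmission
disequilibrium framework conditions on parental genotypes, which makes
the inference immune to population stratification: subpopulations that
differ in both allele frequencies and disease risk cannot confound a
statistic that only compares transmitted against non-transmitted parental
alleles. The cost of conditioning is power; the cost of aggregating whole
regions is dilution by neutral variants.

conADA addresses both. Per-variant transmission P-values are combined by
a *truncated weighted Fisher* rule that adaptively discards variants with
large P-values (likely neutral), with the truncation threshold itself
selected by permutation so that the threshold search is corrected for.
When unrelated population controls are available they contribute through
per-variant *weights* only — never through the statistic's null
distribution — so validity under stratification is preserved even when
the controls come from a different population mix than the trios.

## Per-variant statistic

Let $c_{il}, f_{il}, m_{il} \in \{0,1,2\}$ be the minor-allele counts of
child, father and mother of trio $i$ at variant $l$. Conditional on the
parents, Mendelian transmission gives
$E(c_{il}) = (f_{il}+m_{il})/2$ and
$\mathrm{Var}(c_{il}) = f_{il}(2-f_{il})/4 + m_{il}(2-m_{il})/4$
(a quarter per heterozygous parent). The region test starts from the
conditional score statistic

$$T_l \;=\; \frac{\bigl[\sum_i (c_{il} - e_{il})\bigr]^2}
                 {\sum_i \mathrm{Var}(c_{il}\mid f_{il},m_{il})},$$

which is asymptotically $\chi^2_1$ under the null and reduces exactly to
the classic TDT $(b-c)^2/(b+c)$ when tallied over heterozygous parents
(`variant_statistic()`; the identity is asserted against a direct
transmission tally in the test suite). Zero-variance loci (no informative
parent) are kept with $p_l = 1$ rather than dropped, so the P-value and
weight vectors stay aligned across permutations. Because the final
inference is permutation-based, the asymptotic tail only needs to order
datasets sensibly; no continuity correction is applied.

A trio-locus with any missing member contributes nothing at that locus
and stays missing under permutation. Mendelian inconsistencies are a hard
error by default (`check_mendelian()`), because the permutation flip
formula below presupposes compatibility; `mendelian_policy =
"set-missing"` converts offending trio-loci to missing instead.

## Weights

Two schemes, both functions of parents and controls only (hence constant
across permutations):

* **MAF** (`maf_weights()`): $w_l = \mathrm{Beta}(\widehat{MAF}_l; 1, 25)
  = 25(1-\widehat{MAF}_l)^{24}$, the rare-variant up-weighting shared by
  SKAT, SKAT-O, pedgene and MAF-weighted rvTDT, with the frequency
  estimated from parental genotypes. Used when no controls exist.
* **PC** (`pc_weights()`): the Cochran–Armitage trend chi-square
  comparing the genotype distribution of trio parents against population
  controls with scores (0, 1, 2). The weight is large exactly when the
  two distributions differ, which is how external controls inform the
  test. The statistic-versus-square-root convention is a free choice
  (rank-based inference is invariant to common rescaling but not to the
  relative re-weighting); the chi-square form is the default, `form =
  "z"` gives the square root.

A zero weight removes a variant from every score identically, which is
equivalent to exclusion and accepted as such. Frequencies above 0.5 can
arise in subsets after founder-based orientation; weights use the
frequency as computed, keeping them consistent with the statistic's
coding.

## Adaptive combination and the min-P adjustment

For truncation thresholds $\theta_1 < \dots < \theta_J$ (default
$0.10, 0.11, \dots, 0.20$; a 0.05–0.25 grid of 21 is available and
behaves very similarly) the significance score is

$$S_j = \sum_l w_l \,(-\ln p_l)\, I[p_l \le \theta_j].$$

Each $S_j$ is converted to a rank P-value against $B$ permuted samples,
counting ties inclusively and including the row itself in the pool of
$B+1$, so every rank P-value is at least $1/(B+1)$ and the procedure can
never report zero. The minimum over thresholds, MinP, is adjusted for the
threshold search by comparing the observed MinP with the permuted MinP
values from the same single permutation pool (no second permutation
layer): $P_{adj} = (1 + \#\{b: MinP^{(b)} \le MinP_{obs}\})/(B+1)$.
Exact zeros among the $p_l$ are clamped to the smallest positive double
before taking logs.

## Permutation by diplotype flipping

Within a small region no recombination is assumed, so each parental
haplotype behaves as one allele. The null permutation assigns each child,
by an independent fair coin, either its observed diplotype or the two
non-transmitted parental haplotypes; at the genotype-score level the
flipped child is $f + m - c$ jointly across loci. The flip is an
involution, preserves Mendelian compatibility, and leaves parents,
controls, expectations and weights untouched. For $n$ trios there are
$2^n$ flip patterns; `enumerate_null()` evaluates all of them (guarded at
$n \le 20$) and serves as the exact oracle for the Monte Carlo path in
the test suite.

### Sequential Monte Carlo stopping

Permutations are drawn in batches (default 100). After each batch beyond
$B_{min}$ the engine counts permuted MinP values at or below the observed
MinP; once the count reaches $h = \lceil 1/c^2 \rceil$ (16 at the default
$c = 0.25$, i.e. a relative standard error of about 25% for the adjusted
P-value) it stops and reports the Besag–Clifford estimate $h/B^*$, where
$B^*$ is the permutation index at which the $h$-th exceedance occurred —
recovered from the current pool's ranks at the checkpoint. Using $B^*$
rather than the checkpoint $B$ makes the rule well-defined under
batching and handles the fully degenerate case correctly: when every
score ties (for example all weights zero), the $h$-th exceedance is
permutation $h$ itself and the reported adjusted P-value is 1. Without
early stopping the add-one estimate $(1+\text{count})/(1+B_{max})$ is
reported. Sampling never stops before $B_{min}$ (default 100) nor runs
past $B_{max}$ (default 10000). How MinP ranks interact with sequential
stopping is otherwise an open design point; checkpointed re-ranking
against the growing pool is the documented choice here, and it is cheap
because only the child scores change across permutations (the permuted
numerator is a single matrix product over the coin matrix).

All randomness flows from one seed; results are reproducible
bit-for-bit.

## The synthetic stratified-study generator

`generate_study()` emulates a two-subpopulation exome-like region study:

* **Founder pools** (`build_founder_pools()`): ancestral frequencies are
  drawn from Beta(0.15, 2) truncated to (0, 0.05] — a rare-skewed
  spectrum in which most sites fall below 1% — and diverged into
  "EUR-like" and "AFR-like" subpopulation frequencies by a
  Balding–Nichols construction with differentiation $F_{st} = 0.1$ by
  default, on the order of continental human differentiation. Each pool
  holds 10,000 binary haplotypes. Finite pools induce within-region
  linkage disequilibrium through haplotype reuse. This construction is a
  deliberate stand-in for coalescent-simulated haplotypes: it reproduces
  the statistical structure the method is sensitive to (stratified
  frequencies, rare spectrum, within-region LD, no recombination) but
  not the empirical LD patterns of real human populations, so power
  numbers here should be read as internally comparative, not as
  forecasts for real data.
* **Disease model**: logistic penetrance
  $P(\text{affected}) = \mathrm{expit}(\beta_{0s} + \beta^\top G)$ with
  $\beta_{0s} = \mathrm{logit}(K_s)$ fixing baseline prevalences
  $K_{EUR} = 0.05$, $K_{AFR} = 0.01$. Because the genetic terms also
  contribute, the realized prevalence slightly exceeds $K_s$ under causal
  designs; at the rare frequencies used the discrepancy is small and the
  generator reports rather than corrects it.
* **Effect sizes** (`paf_to_beta()`): each causal locus gets
  $\beta = \ln(1 + \eta/((1-\eta) f))$ from inverting
  $PAF = f(RR-1)/[1+f(RR-1)]$ at its frequency, so rarer causal variants
  carry larger effects for the same per-locus attributable fraction
  $\eta$ (defaults 0.01, or 0.02 for mixed-direction designs). The
  exposure frequency is the allele frequency by default;
  `paf_exposure = "carrier"` uses the carrier frequency instead, and the
  two bracket the plausible readings of the attributable-fraction
  calibration.
* **Ascertainment**: trios are rejection-sampled on an affected child;
  controls are rejection-sampled unaffected by default
  (`control_ascertainment = "random"` gives pure population draws — the
  difference is minor at these prevalences). The causal set is a
  configurable fraction (0.25 or 0.75 in the headline designs) of loci
  with pooled founder MAF ≤ 0.01; the analysis marker set keeps loci
  with pooled founder MAF ≤ 0.05.

## Experiment scale and what the checks show

The replicated experiments shipped with the package (`conada_power()`,
the test suite and `scripts/acceptance.R`) run at desk scale: 1,000 null
studies of 100 trios + 100 controls with 30 requested sites and
$B_{min}=10$, $B_{max}=1000$ for type-I error at 0.05 and 0.01; 500
replicates for the mismatched-mixture robustness check (trios 80:20
EUR:AFR against controls 20:80); 300 replicates for the power contrast
(75% causal, all deleterious, $\eta = 0.01$). These sizes keep each
experiment within minutes on one CPU while leaving the binomial
uncertainty of a rejection proportion at a few tenths of a percent to a
couple of percent.

Two caveats follow from the scale, not the method. First, with 100 trios
most rare sites have only a handful of informative (heterozygous)
parents, so per-variant P-values — and hence the significance scores —
live on a coarse lattice. The permutation procedure remains exactly
valid (ties are counted inclusively, the add-one convention is used),
but exact tests on heavily discrete data are conservative: empirical
rejection under the null sits somewhat below the nominal level,
noticeably at 0.05, and individual 1,000-replicate measurements scatter
around that already-conservative rate. Second, the MinP adjusted P-value
can never undercut $1/(B+1)$, so $B_{max}$ bounds the resolution at the
strict significance levels.

## Known limitations

* Only trios plus unrelated controls; no general pedigrees, imputation,
  phasing, X-chromosome handling or covariate adjustment.
* Two-sided inference only (the squared statistic).
* Founder pools do not reproduce empirical human LD; admixed individuals
  are not simulated.
* Within-region recombination is assumed absent, as appropriate for
  gene-scale regions; applying the flip permutation across recombining
  distances would break the diplotype argument.
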