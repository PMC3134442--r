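---
title: "Mapping cotranslational chaperone specificity from RNC immunopurification profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cotranslational chaperone specificity from RNC immunopurification profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnctools)
```

## The biological setting

Ribosome-nascent-chain (RNC) immunopurification identifies the substrates
of factors that act on proteins *while they are being synthesized*. A
tagged factor — a ribosomal protein, the signal recognition particle
(SRP), a subunit of the nascent-chain-associated complex (NAC), or a
membrane fraction — is affinity-purified together with the translating
ribosomes it engages, and the co-purifying mRNAs are quantified against
total RNA on two-color arrays. Each gene in each biological replicate
yields one log2(IP/reference) ratio; genes reproducibly shifted above
zero are the factor's cotranslational interactome.

Comparing interactomes across baits and strains then becomes set
algebra: joint SRP/membrane classification separates cotranslational
ER-targeting routes; comparing SRP's targets between wild-type and
NAC-deletion cells partitions them into NAC-independent, NAC-dependent
and off-target classes; overlaps among the NAC subunits Egd2 (alpha),
Egd1 and Btt1 (betas) assign substrates to the possible dimers.

## The enrichment model

For gene $i$ with replicate ratios $x_{i1},\dots,x_{iR}$ the moderated
one-class statistic is

$$d_i = \frac{\bar{x}_i}{s_i + s_0},$$

where $s_i$ is the standard error of the replicate mean and $s_0 \ge 0$
is an exchangeability constant that prevents genes with accidentally
tiny variance from dominating the ranking.

**Null distribution.** The only assumption on the null is symmetry of
the replicate ratios around zero. Sign-flip permutations realize it: one
sign pattern $\epsilon \in \{-1,+1\}^R$ per permutation is applied to
*all* genes, preserving gene-gene correlation. With $R$ replicates there
are only $2^R$ distinct patterns, so whenever $2^R$ is within the
permutation budget (default 800) the null is enumerated exactly —
at the study's 3–4 replicates the test is deterministic and
seed-independent; random patterns are drawn only for $R \ge 10$.

**q-values.** At the threshold set by gene $i$,

$$q_i = 100 \cdot \frac{\mathrm{median}_b\, \#\{g : |d^{(b)}_g| \ge |d_i|\}}
                       {\#\{g : |d_g| \ge |d_i|\}},$$

capped at 100. Because a raw ratio of counts need not be monotone, each
gene then inherits the smallest ratio attained by any larger calling
set that contains it (a cumulative minimum along the $|d|$-sorted list;
ties in $|d|$ are ordered by gene id for reproducibility). A target set
is the genes with $q \le 1$ and $d > 0$: the calling language of this
assay is *enrichment*, so depleted genes are excluded by default
(`sign = "both"` lifts this).

**Choice of $s_0$.** Among the 0th–100th percentiles (step 5) of the
$s_i$ distribution, $s_0$ is the candidate minimizing the coefficient of
variation of median $|d|$ across ten $s$-quantile bins — the standard
recipe that makes $|d|$'s scale approximately independent of $s$. Tests
that compare against hand-computable enumeration pin `s0 = 0`.

**Missing values.** Spot-quality filtering (regression correlation
strictly > 0.6 *and* signal over background strictly > 2.5) and array
normalization leave missing cells; genes missing two or more replicate
values are removed (`filter_features()`, `max_missing = 1`). For the
cells that remain missing, the default policy is 10-nearest-neighbour
imputation before testing (`impute = "knn"`). This is deliberate, and
worth spelling out: with available-case statistics, a gene missing
replicate $j$ has its observed $d$ reproduced *exactly* by every sign
pattern whose only flips touch column $j$ — four patterns out of
sixteen at $R = 4$ rather than the two global-identity ones. Genes that
carry true signal therefore leak their full $|d|$ into the permutation
null, and the estimated false-discovery ratio at the boundary of the
true-positive block is inflated right at the calling threshold, making
target calling unstable from seed to seed. KNN imputation (the standard
preprocessing step in the SAM lineage of microarray tools) removes the
degeneracy. `impute = "none"` restores available-case semantics, under
which a gene's $d$ is invariant to the positions of its missing cells;
the test suite exercises both.

## The synthetic study

`simulate_study()` generates the full experimental design with known
ground truth. Its defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | genome size (scaled down from a yeast-sized genome for test-time tractability) |
| `n_replicates` | 4 | biological replicates per bait |
| `effect_size` | 2 | mean log2 shift of planted targets |
| `noise_sd` | 0.5 | replicate noise (log2 units), i.e. effect/sd = 4 |
| `missing_rate` | 0.02 | per-cell missingness, missing completely at random |
| `translatome_fraction` | 0.85 | genes engaged by the ribosomal baits |
| `srp_fraction` | 0.15 | SRP target-set size |
| `srp_sstm_share` | 0.70 | SS/TM share of wild-type SRP targets |
| `nac_dependent_fraction` | 0.30 | lowest-abundance share of SRP targets lost in the NAC deletion |
| `off_target_fraction` | 0.60 | abundant cytosolic genes gained in the deletion, relative to the wild-type set |
| `mem_fraction` | 0.40 | membrane-associated set size |

The covariate structure encodes the biology the classifiers must
recover: SRP targets are drawn so that 70% carry SS/TM flags (the
wild-type share characteristic of this interactome; an explicit share is
used rather than a sampling weight, because weighted sampling without
replacement depletes the SS/TM pool and undershoots the intended
composition); NAC-dependent targets are the lowest-abundance wild-type
targets; off-targets are abundance-weighted cytosolic genes, sized so
the deletion-strain interactome's SS/TM share falls to roughly 40%;
Egd1's set nearly coincides with Egd2's while Btt1's is small and
mitochondrially biased. Abundance and translation rate are correlated
log-normals (rho = 0.5 on the log scale). Per-bait random streams are
derived from the master seed and the bait name, so the roster can change
without perturbing existing baits.

Synthetic proteins use a low-hydropathy background alphabet
(S, T, N, Q, G, P, D, E, K, R — all Kyte-Doolittle scores ≤ −0.4), so a
window-7 mean can never cross the stretch threshold of 1 by chance, and
planted hydrophobic runs (N-terminal for SS, interior for TM) are the
only detectable stretches. Planted-stretch tests are therefore exact.

**What the generator does not emulate.** No probe-level intensities, dye
bias, print-tip effects or spatially structured missingness; replicates
are independent (no shared batch structure) and noise is Gaussian;
protein sequences have no realistic composition outside the planted
stretches. Passing tests demonstrate that the statistical machinery
recovers truth under the stated noise model — not that the model
captures every failure mode of real arrays.

## Sequence features

Hydropathy profiles average Kyte-Doolittle residue scores over sliding
windows (no terminal padding: length $L$ gives $L - w + 1$ values), with
window 7 for stretch detection and window 11 over the first 50 residues
for N-terminal hydrophobicity. A hydrophobic stretch is a maximal run of
at least 5 profile values strictly greater than 1. Coordinates are
reported in profile space (window starts), with residue-space bounds
(`res_start`, `res_end = end + window − 1`) alongside, since "a run of
$k$ window values" and "a run of $k$ residues" differ by $w - 1$.
Unknown residues `X` score 0 with a warning; any other non-standard
letter is an error; sequences shorter than the window are errors rather
than degenerate profiles.

## Set algebra and tables

Quadrant and NAC-dependence labels partition a universe of genes, by
default the translatome (the ribosomal-bait target set) in the pipeline;
classifiers accept any universe. Dimer assignment follows subunit
overlaps (Egd1∩Egd2 → Egd1/Egd2; Egd2∩Btt1 minus Egd1 → Btt1/Egd2;
unique to Egd2 or Btt1 → homodimer). Two edge cases the overlap rules do
not determine are fixed and documented: genes in all three sets take the
Egd1/Egd2 label with all consistent dimers recorded, and genes in Egd1
and Btt1 but not Egd2 (no shared alpha partner) take Btt1-homodimer.

Category tables count target genes per annotation term, each gene once
per term it carries (so counts can exceed the total), with percentages
rounded half-up to one decimal — the convention that reproduces printed
percentage tables exactly from their counts and totals.

Annotation enrichment uses the exact hypergeometric tail, summed in log
space; significance defaults to raw p < 0.01 (the convention of
classical GO term finders), with Bonferroni and Benjamini-Hochberg
available as clearly labelled extensions. When the annotated background
fills the whole universe, an under-representation tail below the
attainable support is reported as exactly 0 — the true probability of an
impossible event.

## Numerical and descriptive conventions

* Quartiles use linear interpolation of order statistics (quantile
  type 7); whiskers are the most extreme points within 1.5 IQR of the
  quartiles.
* Correlations are pairwise-complete Pearson with a minimum overlap of
  3; clustering runs average linkage on 1 − r, with items sorted by id
  first so equal-distance merges resolve to the lexicographically
  smallest pair and the tree is invariant to input order.
* Column median-centering (a stand-in for database-level array
  normalization) is available behind the `center` flag of
  `sam_one_class()` and off by default: the synthetic ratios are already
  centered by construction.
* The Fig-style threshold ambiguity between "1% FDR" and "p < 0.01" for
  class definitions is not resolved; both the q threshold and alpha are
  parameters.

## Test-time problem sizes

The suite verifies SAM against an independent exhaustive sign-flip
oracle on 6–8 gene fixtures (3–4 replicates), hydropathy and stretch
detection against brute-force oracles on 1000 random sequences,
hypergeometric tails against combinatorial enumeration for all
backgrounds up to 30 genes, and recovery/false-discovery behaviour on
1000-gene simulations (10 recovery seeds, 20 null seeds, one full
default study for the classifiers). These sizes were chosen so the whole
suite runs in a few minutes while keeping every Monte-Carlo bound
comfortably away from its tolerance.

## Known limitations

* On pure-null data the median-count q-value occasionally assigns q = 0
  to the single strongest gene (whenever more than half of the sign
  patterns produce a smaller maximum |d| than observed), so roughly one
  null run in ten yields one spurious call at q ≤ 1. The false-discovery
  *rate* criterion is unaffected (the median realized false-positive
  proportion over seeds is 0), but "every null run is empty" is not a
  guarantee this estimator can make.
* With many strongly enriched genes the sign-flip null is contaminated
  by partial flips of true targets; the q-values near the boundary of a
  large target block are accordingly conservative. This is inherent to
  one-class permutation FDR, not a defect of the implementation.
* Two-class and time-course designs, local FDR, GO-graph propagation,
  and probe-level normalization are out of scope.
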