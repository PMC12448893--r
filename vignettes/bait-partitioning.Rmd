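---
title: "Partitioning a shared deacetylase among its complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning a shared deacetylase among its complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Class-I histone deacetylases such as HDAC1/2 are catalytic subunits shared
by several distinct corepressor complexes (SIN3, NuRD, CoREST, MiDAC, MIER,
RERE).  An affinity purification of a tagged bait (e.g. HDAC1-Flag) pulls
down a mixture of all of them, and the question this package answers is
quantitative: *what fraction of the bait resides in each complex, and how do
point mutations on the bait surface redistribute it?*

`baitquant` implements the full analysis path from a label-free
protein-groups table to per-complex proportions, subunit stoichiometry
ratios, a bait mass balance, enrichment/differential-binding statistics, and
acetyl-site-level quantification of derivatized histones, together with a
synthetic-data generator that makes every stage testable against a known
ground truth.

# The model

## iBAQ as a molar proxy

For protein $p$ with raw intensity $I_p$ and $N_p$ theoretically observable
peptides,

$$\mathrm{iBAQ}_p = I_p / N_p,$$

which is proportional to the molar amount of $p$ in the sample because
summed intensity scales with both abundance and the number of peptides a
protein can contribute.  $N_p$ is computed by in-silico digestion:
fully-cleaved peptides (no missed cleavages) of 6–30 residues, the
conventional iBAQ window.  The search-engine settings used for
*identification* (trypsin/P with 3 missed cleavages; 5 for propionylated
histones) are exposed in the same digestion interface but deliberately do
not default into the iBAQ denominator, which models *observability*, not
the search space.  `countObservablePeptides()` counts distinct peptide
*sequences* in the window; `digestProtein()` itself reports every span.

Two cleavage chemistries are modelled.  `trypsin_p` cuts C-terminal of Lys
and Arg regardless of a following Pro.  `argc_propionyl` cuts after Arg
only: chemical propionylation of free lysines in histone workflows blocks
tryptic cleavage at Lys, which is what produces the classic intact histone
tail peptides (H3 9–17, H3 18–26, H4 4–17, ...).

## Partitioning the bait

Each complex engages the bait through one (or a few interchangeable)
*direct binders* — the ELM2–SANT or SIN3-family proteins — in a 1:1
stoichiometry with the bait.  Under that model the molar amount of complex
$c$ equals the summed molar amount of its direct binders, so

$$\pi_c \;=\; \frac{\sum_{b \in \mathrm{direct}(c)} \mathrm{iBAQ}_b}
                   {\sum_{c'} \sum_{b \in \mathrm{direct}(c')} \mathrm{iBAQ}_b}.$$

The denominator runs over catalog complexes only: the pie partitions
*complexed* bait.  Free or unassigned bait is captured separately by the
mass balance

$$\mathrm{MB} = \frac{\sum_c \sum_{b \in \mathrm{direct}(c)} \mathrm{iBAQ}_b}
                     {\mathrm{iBAQ}_\mathrm{bait}},$$

which is close to 1 when the 1:1 model accounts for essentially all
recovered bait, and is flagged (not truncated) when it exceeds 1.
Interchangeable direct binders within a complex (MTA1-3, RCOR1-3,
MIDEAS/TRERF1) are summed; undetected direct binders contribute zero and
are listed in the report, since absence of one paralogue is informative
rather than an error.

Subunit ratios (`subunitRatio()`) are plain quotients of mean iBAQ,
formatted `"R:1"`.  Because the observable-peptide normalization cancels
sequence-length bias, the noise-free simulation recovers copy-number ratios
exactly (tested to 1e-9).

## The label-free testing path

The enrichment/differential-binding statistic follows the standard
label-free workflow, implemented rather than delegated:

1. remove reverse hits, potential contaminants, and proteins only
   identified by site;
2. $\log_2$ transform (zero = missing);
3. per-sample median subtraction;
4. keep proteins with $\ge$ 3 valid values in at least one group;
5. impute each missing cell from $N(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2)$,
   with $\mu_j, \sigma_j$ the present-value moments of that sample $j$;
6. two-sided pooled-variance (Student's) $t$-tests with permutation-based
   FDR at 0.05.

The downshifted Gaussian expresses the missing-not-at-random structure of
label-free data: measurements are censored preferentially at low intensity,
so imputed values belong in the lower tail.  Imputation is per-column by
default because each run has its own intensity distribution; a whole-matrix
mode exists.  Draws are keyed to row names so that reordering rows permutes
the imputed cells identically, and all randomness flows from one seed
through named substreams (sequences, noise, dropout, imputation,
permutations), so adding a stage never perturbs another stage's draws.

### Permutation FDR conventions

The test statistic is $d_i = \Delta_i / (s_i + s_0)$ with $s_i$ the pooled
standard error and $s_0 = 0$ by default (the SAM fudge constant is
supported but not presumed).  Group labels are permuted: all
$\binom{n}{n_1} - 1$ distinct non-identity assignments when there are at
most `nPermutations` (default 250) of them, otherwise that many distinct
random non-identity assignments.  The identity is excluded because it
reproduces the observed statistics into the null; the complementary
assignment is kept, as in standard balanced-relabeling practice.  For a
threshold at each observed $|d_i|$,

$$\widehat{\mathrm{FDR}}(|d_i|) =
  \frac{\text{mean permuted count of } |d^*| \ge |d_i|}
       {\text{observed count of } |d| \ge |d_i|},$$

capped at 1 and monotonized by a running minimum from the least significant
statistic upward, so q-values never decrease as $|d|$ shrinks.  Zero pooled
variance yields $d = \pm\infty$ (p = 0) by convention, or $d = 0$ (p = 1)
when the difference is also zero; infinities order correctly through the
exceedance counts.

### A caveat on median normalization with asymmetric content

When one group contains many proteins the other lacks entirely (a bait
pulldown versus a no-bait control), the per-sample median shifts by the
content difference, which imparts a small systematic *negative* difference
to proteins present in both groups.  The permuted null mixes the groups and
does not reproduce that shift, so depleted-direction calls on shared
background should be interpreted as normalization artifacts; enrichment
screens count the positive side, as does the planted-interactor validation
below.

## Histone acetyl-site quantification

`mapPeptidesToSites()` aggregates modified-peptide records to
site-combination keys in mature-protein (initiator-Met-clipped) numbering,
the community convention behind labels like "H3 K18ac".  A peptide
acetylated at two lysines contributes to its combination key
(`"H3 K18ac+K23ac"`) only — never double-counted into single sites — and
records sharing a key are summed, so total accepted intensity is conserved.
Records that do not match the reference at the stated position are rejected
with a reason, not silently dropped.  `relativeAcetylationChange()` then
reuses the testing path above on the site table.  Only relative (log2)
changes are reported; acetylation stoichiometry would require the
unmodified-form normalization that the relative design does not need.
Median normalization of site intensities is the default; normalization to
total signal is available because the choice is genuinely open for histone
tables.

# The synthetic-data generator

The generator *defines* the conditions under which the pipeline is
validated:

* **Ground truth** (`generateGroundTruth()`): complexes with direct-binder
  copy numbers summing to `proportion × baitAmount × occupancy`; occupancy
  defaults to 0.91 so that simulated pulldowns exhibit the near-complete
  1:1 mass balance typical of this bait, with the slack modelling free
  bait.  Non-direct members get log-uniform stoichiometry multipliers in
  [0.25, 2], so sub- and super-stoichiometric subunits both occur
  (an RBBP4-like twice-present subunit is within the default range).
  Background contaminants draw log-normal copy numbers
  (meanlog `log(0.5)`, sdlog 2) spanning the dropout regime.
* **Sequences** (`generateSequences()`): random 20-letter chains of
  200–1500 residues with a combined K+R frequency of 0.11 and P at 0.05,
  typical proteome values; verified by a law-of-large-numbers test.
* **Measurements** (`simulatePulldown()`): expected intensity
  `copies × observable peptides × responseFactor` (a single global
  response factor — iBAQ's peptide-count normalization is the quantity
  under test, not ionization physics); multiplicative log-normal noise of
  0.2 in log2 units (≈ 15 % CV, a typical label-free replicate spread);
  dropout with probability `plogis(-steepness · (log2 I - midpoint))`,
  midpoint 20 and steepness 1 by default, i.e. mild missingness
  concentrated in low-abundance background.  Controls contain background
  only, at the same expected intensity as in the bait group; interactors
  and bait are absent from them.  Four bait and four control replicates by
  default; the control arm is assumed symmetric because nothing in the
  modelled design says otherwise, and the count is configurable.
* **Histone tables** (`simulateHistonePeptides()`): occupancies per
  site-combination and group placed on the packaged mature H3/H4/H2B
  reference tails, with the residual occupancy as the fully propionylated
  form, so an occupancy ratio propagates exactly to a noise-free intensity
  ratio.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: peptide-level ionization differences,
retention-time or charge-state structure, cross-sample LFQ normalization
(the simulated LFQ columns mirror the raw columns), ragged/shared protein
groups, and correlated (batch) noise.  Conclusions about those belong to
the upstream search engine, not to this package.

# Validation at a glance

The test suite closes the loop end to end, at problem sizes chosen to make
the checks sharp but quick:

* noise-free simulations recover the generating proportions, copy-number
  ratios and the 0.91 mass balance to 1e-9;
* with default noise (0.2 log2, 4 + 4 replicates, mild dropout), estimated
  proportions fall within ±5 percentage points of truth in ≥ 95 of 100
  seeded runs;
* digestion agrees with an exhaustive independent enumeration: all
  {A,K,R,P} sequences to length 6 (verifying residue classification in
  every local context, including Lys-Pro and blocked lysines), all
  cleavage-site patterns to length 12 via two-letter alphabets (the only
  structure digestion depends on beyond residue class), and seeded random
  full-alphabet sequences of length 7–12;
* 10,000 imputed cells in a column with mean 20 and sd 1 average
  18.2 ± 0.05 with sd 0.30 ± 0.03, the stated law;
* permutation q-values equal a brute-force oracle (independent code path
  via `stats::t.test` and explicit loops) on 3 vs 3 and 4 vs 4 designs,
  and on pure-null 1000 × (4 vs 4) matrices the mean false-discovery
  proportion at q ≤ 0.05 stays below 0.05 across 50 seeds;
* a planted screen of 148 strong interactors among 1000 background
  proteins is fully recovered at q ≤ 0.05 with no false enrichment calls.

`scripts/acceptance.R` re-runs these end-to-end quantities from scratch
against the installed package.

# Numerical and design decisions

* **Raw vs LFQ for iBAQ.**  The enrichment path consumes LFQ intensities;
  iBAQ conventionally uses raw intensities and does so by default.  Both
  are supported (`which=`) because upstream tools differ.
* **Replicate aggregation.**  `ibaqMean` averages over *detected*
  replicates (zeros are missingness, not abundance); summing is available
  (`aggregate = "sum"`), and proportions are invariant to that choice up
  to detection asymmetries.
* **Order of operations.**  Per-replicate iBAQ is averaged and then summed
  over direct binders; averaging intensities first is equivalent in the
  noise-free limit and nearly so under log-normal noise.
* **Degenerate inputs.**  Empty columns fail median normalization
  explicitly; zero-variance columns fail imputation explicitly; a protein
  with no observable peptide gets `NA` iBAQ (flagged), never a division by
  zero; an undetected ratio denominator yields a flagged `NA`, not
  infinity; an empty post-filter matrix is an error, not an empty result.
* **Rounding.**  Percentages are reported rounded to integers for display
  alongside full-precision values in files, matching how such proportions
  are conventionally quoted.
* **N-terminal methionine.**  Pulldown sequences are digested as given (no
  Met-clipped variant is generated); histone coordinates, by contrast, use
  mature numbering because that is how sites are named.

# Limitations

The catalog is user-curated: the package partitions bait among the
complexes it is told about and cannot discover a missing complex (a large
mass-balance shortfall is the symptom to watch).  The 1:1 direct-binder
model is an assumption, not an inference; a complex engaging the bait
through two simultaneous direct binders would be double-counted.  Protein
groups are treated as single proteins via their primary accession.  And
the permutation FDR needs enough samples to be meaningful — with 3 vs 3
designs only 19 non-identity relabelings exist, so q-value resolution is
coarse.
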