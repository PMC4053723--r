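---
title: "Calling X-inactivation status from allelic imbalance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling X-inactivation status from allelic imbalance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciscan)
library(dplyr)
```

## The problem

In female cells one of the two X chromosomes is transcriptionally silenced
(X-chromosome inactivation, XCI). Which X is inactivated is decided early in
development and inherited clonally, so a bulk sample is a mixture of two cell
types: those with the maternal X active and those with the paternal X active.
A gene fully subject to XCI is expressed from only the active X (Xa) in every
cell; a gene that *escapes* XCI is also expressed from the inactive X (Xi),
typically at a fraction of the Xa level.

At a heterozygous expressed SNP the two alleles can be distinguished, and the
allelic imbalance

$$\mathrm{AI} = \left|\,f - 0.5\,\right|, \qquad f = \text{allele-1 fraction}$$

ranges from 0 (balanced bi-allelic expression) to 0.5 (mono-allelic
expression). In a female whose XCI is *skewed* — a fraction $s > 0.5$ of
cells share the same Xi — the AI of an X-linked gene carries information
about its expression from the Xi. `xciscan` turns that information into
per-gene, per-female XCI statuses and cohort-level summaries.

## The forward model

Normalise Xa expression to 1 and let $e \ge 0$ be the Xi expression level as
a fraction of Xa (we report it as %Xi). With a fraction $s$ of "type 1"
cells (majority Xi) and $1 - s$ of "type 2" cells, the allele-1 expression
fraction at a heterozygous site is

$$f(s, e) \;=\; \frac{s + e\,(1 - s)}{1 + e},
\qquad \mathrm{AI}(s, e) \;=\; |f - 0.5|
\;=\; \frac{|s - 0.5|\,|1 - e|}{1 + e}.$$

`expected_ai()` implements this map and `xi_from_ai()` its inverse,

$$e \;=\; \frac{s - f}{f + s - 1}, \qquad f = 0.5 + \mathrm{AI},$$

clamped below at 0: an AI larger than $s - 0.5$ has no non-negative solution
and arises when the skew estimate is itself biased low (see below), so it is
reported as 0% Xi. Three limits anchor intuition:

* $e = 0$ (fully silenced): $\mathrm{AI} = s - 0.5$. Averaging this over a
  *subject training set* of genes known to be silenced estimates the
  female's skew as $s = 0.5 + \overline{\mathrm{AI}}$
  (`skew_from_subject_ai()`). A female averaging 0.3891 is 88.91% skewed.
* $e = 1$ (Xi expresses at the Xa level): $\mathrm{AI} = 0$ at any skew.
* $s = 0.5$ (random XCI): $\mathrm{AI} = 0$ at any $e$ — AI carries no
  information about XCI in such females, which is why they are excluded
  from calling (group R below).

```{r forward}
skew_from_subject_ai(0.3891)
expected_ai(0.8891, 0.10)   # AI at the 10%-Xi cutoff for this female
xi_from_ai(0.3184, 0.8891)  # and back
```

**Identifiability.** Because AI is an absolute deviation, $e$ and its mirror
$e'$ with $(1-e')/(1+e') = (e-1)/(1+e)$ produce identical AI; expression
*above* the Xa level ($e > 1$) cannot be distinguished from expression below
it. `xi_from_ai()` therefore returns the branch $e \le 1$, and round-trip
guarantees hold exactly on $e \in [0, 1]$ and in AI space everywhere. In
practice Xi expression above the Xa level is not expected biologically.

**Skew underestimation.** If subject-training genes leak a little Xi
expression, the estimated skew is slightly below the truth, which pushes
some converted %Xi values negative. Clamping to zero inside `xi_from_ai()`
(rather than at the reporting layer) keeps every downstream consumer on the
meaningful scale.

## Probe quality control

Three exclusion rules precede any calling.

**Intensity threshold (Tau).** Homozygous ("uninformative") probes should
show AI 0, but at low total cDNA intensity hybridisation noise inflates
their apparent AI. For each sample set we fit, by nonlinear least squares
(`minpack.lm`), the one-phase decay

$$\mathrm{AI}(I) = \mathrm{plateau} + (y_0 - \mathrm{plateau})\,
e^{-I/\tau},$$

to homozygous-probe AI against intensity, and use the fitted $\tau$ as the
minimum intensity: only measurements with intensity strictly greater than
the sample set's Tau are kept. For homozygous probes the stored allele
fraction sits near 0 or 1, so their apparent AI is computed as
$\min(f, 1-f)$, the deviation from the mono-allelic pole — the quantity
that is nominally 0 and rises with noise. Starting values are data-driven
(decile means for $y_0$ and the plateau, the half-decay intensity for
$\tau$), which also makes the fit scale-equivariant: doubling all
intensities doubles the fitted Tau.

**Genomic-DNA ratio.** A probe whose genomic-DNA (1:1 by construction)
allele ratio exceeds 0.7 in at least 50% of informative females of any one
sample set has a hybridisation bias that mimics mono-allelic expression; it
is removed from *all* sample sets. The rule uses
$\max(r, 1-r) > 0.7$ so it cannot depend on the arbitrary allele labelling.

**Two-probe concordance.** For genes with exactly two surviving probes we
record, per female, whether the probes agree on the subject-vs-escape call
at that female's boundary, and test each gene's discordant count against
the cohort-wide discordance rate (one-sample chi-square). No numeric
definition of "concordant" is universal, so an alternative
$|\Delta \mathrm{AI}| < 0.1$ definition is selectable and the definition
used is carried in the result object.

## Female grouping

Calling requires skew. Per sample set, the AI below which 90%, 95% and
99.5% of informative *autosomal* probes fall calibrates what "balanced"
looks like (autosomes host a ~10% minority of genuinely cis-imbalanced
loci, which these quantiles absorb).

* **Group 1** — average subject-training AI strictly above the autosomal
  99.5% quantile: strongly skewed, called directly.
* **Group 2** — remaining females whose per-gene AI regresses significantly
  (slope test, $p \le 0.05$) on the group-1 mean per-gene AI over genes
  with a consistent group-1 call (subject or escape only): partially
  skewed, callable after rescaling. Note that under the forward model
  $\mathrm{AI}(s, e) = (s - 0.5)\,\frac{1-e}{1+e}$ for $e \le 1$, so
  across genes two females' AIs are *exactly* proportional with slope
  $(s_2 - 0.5)/(s_1 - 0.5)$ — the linear regression is not an
  approximation but the model's own structure, which is why mapping the
  group-1 boundaries through the fitted line is the right rescaling.
* **Group R** — everything else: effectively random XCI, excluded from XCI
  calls but reused for the imprinting screen.

The per-gene AI is always the unweighted mean of probe $|f - 0.5|$ over the
gene's informative probes, and a gene needs at least two informative probes
in a female to count.

## Status boundaries and calling

For a group-1 female the four-level status is cut at three AI boundaries:
E1:E2 at the autosomal 90% quantile, E2:E3 at the 95% quantile, and E3:S at
`expected_ai(skew, 0.10)` — the AI corresponding to exactly 10% Xi
expression for that female. For group 2 all three are mapped through the
regression line; the group-1-level E3:S reference is evaluated at the mean
group-1 skew of the sample set, since the regression covariate is the
group-1 mean AI. Boundaries are clipped to $[0, 0.5]$ and re-ordered (with
a warning) in the rare case a fitted line inverts them.

Lower AI means more Xi expression, so calls run E1 (most escape) through S:
a gene is **subject** in a female when its AI is at or above the E3:S
boundary, i.e. when its Xi expression is below 10% of Xa. A boundary tie
maps to S, keeping "escape requires *more than* 10% Xi expression"
consistent in AI space.

Genic aggregation uses the informative-female escape fraction with the
exact rationals 7/9 and 2/9 (not rounded percentages): escape when at least
7/9 of females escape, subject when at most 2/9 do, variable escape in
between — so that 7-of-9 reproduces the classical somatic-cell-hybrid rule
the cutoffs descend from. Variable-escape genes are subtyped:

* **bimodal** — at least 75% of calls are E1 or S, with both present
  (silenced in some females, strong escape in others);
* **borderline** — every call is S or E3 (Xi expression hovering around the
  10% cutoff);
* **heterogeneous** — anything else (a genuine continuum).

Finally, escape genes are split by whether their mean %Xi reaches the range
spanned by PAR1 genes (which escape by construction, being X/Y-identical),
and subject genes at 5% Xi (inclusive above), yielding the four expression
classes used in the chromatin analysis.

## Downstream analyses

**Adjacency clustering.** Excluding PAR1, genes are ordered by position and
unordered status pairs of consecutive genes counted. Because the published
expected counts for this test are not derivable from any stated method, the
package computes expectations by permuting statuses over positions
(`permutation_expected()`, default 1000 permutations), which is the natural
exchangeability null; user-supplied expected counts are also accepted so
published tables can be re-analysed as printed. Per pair we report the
chi-square component $(O-E)^2/E$ and standardized residual
$(O-E)/\sqrt{E}$; the total statistic is referred to a chi-square
distribution with (pairs − 1) degrees of freedom by default
(configurable), alongside the permutation p-value, which we regard as the
primary one.

**Cross-sample-set comparison.** Per sample set with at least five
informative females, genic statuses are compared: all informative sets
agreeing gives `consistent_*`; the two same-cell-type (LCL) populations
disagreeing gives `population_specific`, unless the third set disagrees
with both (`population_and_cell_line`); LCL sets agreeing against the
fibroblast set gives `cell_line_specific`. When only one LCL set and the
fibroblast set are informative and they disagree, population and cell-line
effects are confounded and the gene is `inconsistent`.

**Group-R imprinting screen.** In random-XCI females every X gene should be
bi-allelic regardless of XCI status; mono-allelic expression there (mean AI
above the autosomal 99.5% quantile) suggests imprinting. A one-sided Grubbs
test (maximum normed residual, toward high AI) first removes females whose
average AI contradicts their group-R label. Genic categories reuse the
7/9–2/9 fraction rule on the bi-allelic fraction.

**Histone ChIP AI.** Allelic imbalance measured after chromatin
immunoprecipitation reflects allele-differential chromatin. Probes are
assigned to the promoter (±1 kb of the strand-resolved TSS) and gene body
(TSS–TES), and mean |AI| compared across the four expression classes with
all pairwise two-tailed t-tests, Holm-corrected within each mark × region
family (Bonferroni/BH selectable). Holm was chosen as the default because
it controls the family-wise error rate without the independence
assumptions Bonferroni shares but dominates.

## The synthetic cohort

`simulate_cohort()` generates the full probe-table structure the pipeline
consumes, plus ground truth, so every stage is testable without array data.
Defaults describe the study conditions the package targets:

* three sample sets (two LCL populations, one fibroblast set) × 20 females;
* per-female skew from a mixture: 35% highly skewed (uniform 0.85–0.98),
  40% moderately skewed (0.68–0.85), 25% effectively random (0.50–0.52) —
  spanning random to near-complete skewing;
* 200 X-linked genes in positional runs (a PAR1 block at the tip, escape
  blocks, variable-escape blocks of all three subtypes, subject blocks, one
  planted imprinted gene), so adjacency clustering has signal: 100
  subject-training genes (mostly fully silenced, a minority leaking up to
  ~7% Xi), 30 escape-training genes (8 PAR1 at 49–75% Xi, the rest
  25–75%), 24 variable-escape genes (8 per subtype: bimodal draws
  per-female xi from {0, 1}, borderline from a normal centred at the 10%
  cutoff, heterogeneous from a broad mixture), 33 further subject genes,
  12 further escape genes, 1 imprinted gene (mono-allelic in every female);
* 1–10 (default 2–8) probes per gene, heterozygous per female at rate 0.35;
* log-normal intensity (meanlog `log(8000)`, sdlog 0.8) and allele-fraction
  noise with standard deviation $0.02 + 0.15\,e^{-I/2000}$ — the same
  one-phase-decay shape the QC stage fits, so the Tau filter is exercised
  meaningfully and surviving probes carry ≈0.02 noise;
* 2000 autosomal probes, 10% of them cis-imbalanced with excess AI
  $0.05 + \mathrm{Exp}(0.08)$ (capped at 0.45), which places the 90/95/99.5%
  quantiles near 0.05/0.11/0.29 — comparable to array cohorts;
* 2% of probes carry a genomic-DNA ratio artifact (ratio ≈ 0.85) in one
  sample set;
* ChIP AI per expression class with means 0.40/0.32/0.22/0.12 from silenced
  to PAR1-range escape and spread 0.08, gene bodies receiving 40× the
  promoter probe count.

All randomness flows from one root seed; the same seed and configuration
reproduce the probe table bit for bit, and the generator restores the
caller's RNG state.

What the generator does *not* emulate: raw two-channel fluorescence and its
polynomial normalisation, linkage between neighbouring probes, expression-
level differences between genes beyond the intensity model, population
allele-frequency structure in heterozygosity, and read-count (binomial)
noise. Passing recovery tests on this cohort therefore demonstrates the
inference logic is correct under the stated noise model, not that the
thresholds are optimal for any particular array platform.

## Numerical choices and problem sizes

* Round-trip and inversion tolerances are 1e-9 absolute; comparisons
  against printed values use the printed precision (4 decimals for AI,
  1 decimal for chi-square components).
* Ties: group 1 requires AI *strictly above* the 99.5% quantile; intensity
  must be *strictly above* Tau; AI exactly at E3:S is S; subject genes
  with exactly 5% Xi are `subject_ge5`; escape fractions use inclusive
  7/9 and 2/9.
* Degenerate inputs: a flat AI–intensity relationship is a degeneracy
  error, not a fit; a zero-variance Grubbs sample has Z defined as 0 and
  no outlier; sets without group-1 females fall back to group R with a
  warning; pairs with zero expected adjacency count are excluded with a
  warning.
* Test and validation problem sizes — a 3 × 20-female, 200-gene cohort
  with 2000 autosomal probes for recovery checks; 2000 genes for the
  concordance null; 20 replicates for the ChIP null; 5000 probes for Tau
  recovery; 1000 permutations (100–200 in fast paths) for adjacency —
  were chosen so the full suite runs in about a minute while leaving the
  stochastic assertions comfortable margins.

## Known limitations

* Skew is estimated from expression itself; any Xi leakage in the subject
  training set biases skew low and %Xi estimates low (clamped at 0). An
  orthogonal skew assay can replace the estimate wherever a
  `female_profiles` table is accepted.
* Group-2 rescaling assumes the regression line transfers the boundary
  geometry; with few consistent genes the slope is noisy, and the package
  refuses the regression below 10 shared genes rather than guess.
* The cross-set decision tree identifies population and cell-line axes
  only when the informative pattern allows it; with two informative sets
  spanning both axes the call is `inconsistent` by design.
* Per-transcript (isoform-level) statuses are out of scope; discordant
  probes within a gene are treated as noise via the concordance screen,
  not as splice-specific XCI.
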