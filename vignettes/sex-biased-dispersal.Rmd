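---
title: "Inferring sex-biased dispersal from assignment indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-biased dispersal from assignment indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersalkit)
```

This vignette documents the models implemented in `dispersalkit`, the
assumptions behind them, the tunable parameters and their defaults, and the
design decisions taken where the methodology was genuinely open. The setting
is a fragmented amphibian metapopulation: adults of both sexes are sampled on
land-bridge islands, genotyped at codominant microsatellite loci, and the
question is whether one sex disperses between islands more than the other,
and which island attributes predict that asymmetry.

## The assignment-index model

The corrected assignment index treats each island as a population with its
own allele frequencies. For individual $i$ on island $s$, each scored locus
contributes its expected genotype frequency under random mating,
$p^2$ for a homozygote and $2pq$ for a heterozygote, computed from the
allele frequencies of $s$ itself. The multilocus likelihood is the product
over scored loci (missing calls are simply skipped, with no imputation), and

$$\mathrm{AIc}_i \;=\; \log_{10} L_i \;-\;
\overline{\log_{10} L}_{\,s} .$$

AIc is exactly mean-zero per island, which removes the island-level
differences in overall genotype probability (driven by diversity and sample
size) and leaves a within-island ranking: individuals with strongly negative
AIc carry genotypes atypical of their island and are the most likely
immigrants.

Assumptions worth stating explicitly:

* **HWE form of the genotype frequency.** The $2pq$ form is used even where
  a locus departs from Hardy–Weinberg proportions in that island. This
  mirrors the classical assignment-test methodology; departures inflate the
  likelihoods of heterozygotes slightly but do so for both sexes alike, and
  the inference only ever compares sexes within islands.
* **Base of the logarithm** is 10 (the convention of the widely used
  spreadsheet implementation). Any base would merely rescale AIc; one is
  fixed for reproducibility.
* **Leave-one-out** (removing the focal individual's two allele copies
  before forming its frequencies) defaults to *off*, because the plain
  population-frequency description is the canonical one; the option exists
  (`leave_one_out = TRUE`) since the best-known implementation offers it.
  With it on, an allele can have frequency zero; such alleles are replaced
  by `zero_freq` (default 0.01, a Paetkau-style floor) before the product.

The disparity statistic is $d\mathrm{AIc} = \overline{\mathrm{AIc}}_M -
\overline{\mathrm{AIc}}_F$. Since dispersers score negative, $d\mathrm{AIc} >
0$ means females are the more immigrant-like sex (female-biased dispersal)
and $d\mathrm{AIc} < 0$ the reverse. Per-island comparisons use two-sided
Mann–Whitney U tests: the exact null distribution when both sexes have at
most 8 individuals and there are no ties, otherwise the normal approximation
with continuity and tie corrections. P-values are Benjamini–Hochberg
corrected across the tested islands (the family is the set of per-island
tests). The pooled variant keeps AIc centered within islands but compares
all males against all females in one test.

## Population-genetic diagnostics

**Diversity.** Mean allelic richness is the raw mean number of distinct
alleles per locus per island — *not* rarefied. Published per-island values up
to 9.00 with ten loci are consistent with raw counts from the standard
parentage software, and raw counts are what the summary reproduces; a
rarefaction option (`rarefy_n`) exists for cross-study comparisons where
sample sizes differ badly. Expected heterozygosity uses Nei's unbiased
correction $\frac{2n}{2n-1}(1 - \sum_k p_k^2)$ by default, which converges to
the plain gene diversity as $n \to \infty$ (the suite checks agreement to
$10^{-3}$ at $n = 10^4$).

**Hardy–Weinberg exact tests.** Conditional on the allele counts, the
probability of a genotype array is Levene's

$$P(\{n_{kl}\}) \;=\; \frac{n!\, 2^{h} \prod_k a_k!}{(2n)! \prod_{k \le l}
n_{kl}!},$$

with $h$ the number of heterozygotes. The p-value is two-sided in the
probability-ordering sense: the total probability of arrays no more probable
than the observed one. Arrays are enumerated completely when a cheap
composition bound guarantees the count fits under `enum_cap` (default
$10^6$); otherwise the same probability is estimated by Monte Carlo, by
randomly re-pairing the $2n$ gene copies (which samples the Levene
distribution exactly) for `mc_iter` iterations under a caller-supplied seed.
Monomorphic or nearly empty cells are untestable and reported as $p = 1$
with a flag rather than dropped silently.

**Genotypic linkage disequilibrium.** For each island and locus pair the
association between single-locus *genotypes* is measured by the
log-likelihood-ratio $G$ statistic on the genotype-by-genotype contingency
table. The permutation scheme shuffles one locus's genotype column among the
island's individuals — this preserves both marginal genotype distributions,
which is the correct null for a genotypic (not gametic) test — and the
p-value uses the $+1/+1$ correction, so $p \ge 1/(B+1)$ by construction.

**AMOVA.** The two-level analysis partitions the total sum of squares
computed from the pairwise squared-distance matrix,
$SS = \sum_{i<j} d^2_{ij}/n$, into among- and within-island components.
The default distance counts allele mismatches per locus (0, 1 or 2; the
multiset mismatch of the two allele pairs) summed over loci — the
"number of different alleles", $F_{ST}$-like choice, which is conservative
when mutation is not strictly stepwise. An $R_{ST}$-like squared-size
distance is available (`distance = "rst"`) since microsatellite repeat
counts carry size information. When a locus is missing in either individual
it is dropped from that pair and the distance rescaled by the number of
compared loci; a pair sharing no scored locus is an error rather than a
guess. Variance components come from the expected mean squares with the
usual unequal-$n$ coefficient $n_0$; negative components are reported raw
and clamped to zero only for percentages (the convention of the standard
AMOVA software). Significance of $\Phi_{ST}$ is by permutation of
individuals among islands.

## The landscape layer

Per-island $d\mathrm{AIc}$ is regressed on six island attributes: area $A$
(stored in hectares for fidelity with published tables, converted to m²
internally — the conversion is what makes the published PAR and SI columns
mutually consistent, verified on the first survey row), isolation $I$ (m to
the mainland shore), $\mathrm{PAR} = P/A$ (m⁻¹),
$\mathrm{SI} = P / (2\sqrt{\pi A})$ (1 for a circle, flagged as inconsistent
geometry if below 1), sex ratio (males/females of the sampled adults) and
breeding sites per transect. Sex-ratio deviations from 1:1 are tested
per island with a 1-df goodness-of-fit chi-square *without* continuity
correction — $(11, 30)$ gives $\chi^2 = 361/41 = 8.805$, which matches the
published value only without the correction.

Predictors are screened at VIF < 10 ($\mathrm{VIF}_j = 1/(1-R^2_j)$ from
regressing predictor $j$ on the rest), then a backward stepwise search drops
whichever predictor lowers AICc most, stopping when no removal lowers it;
dropped predictors never re-enter, and the full trace is emitted. AICc uses
$K = k + 2$ (slope count plus intercept plus error variance):

$$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2K + \frac{2K(K+1)}{n-K-1}.$$

Two design notes on small-sample behaviour, established with the exhaustive
all-subsets audit (`exhaustive_aicc()`):

* With $n = 14$ islands and six candidates, backward search finds the
  global AICc minimum in about 98–99% of strongly signalled simulated
  data sets.
* Min-AICc itself admits one spurious predictor alongside two true strong
  ones in roughly a quarter of replicates at $n = 14$ — an intrinsic
  property of the criterion (the chance that some noise predictor reduces
  RSS enough to beat the ~5-point penalty), not of the search path. Exact
  recovery of the true predictor *set* therefore plateaus near 75% no
  matter how strong the effects are, while the true predictors themselves
  are essentially always retained. Tests assert the computed rates.

The final model's $R^2$ is decomposed over the top two retained predictors by
commonality analysis: unique fractions $R^2_{12} - R^2_{2}$ and $R^2_{12} -
R^2_{1}$ and the shared fraction $R^2_1 + R^2_2 - R^2_{12}$, which can be
negative under suppression and is then flagged rather than truncated.

## The simulator: what it emulates and what it does not

`simulate_islands()` is a discrete-generation, non-overlapping forward-time
island model: 14 island demes (capacities of a few dozen adults) plus one
mainland deme 50× the mean island capacity, random mating within demes,
offspring sexes balanced 1:1, microsatellite mutation at $5\times10^{-4}$
per transmitted allele (stepwise ±1 repeat by default, reflected at the
bounds; a k-allele option exists), and 25 generations — the approximate
number of 2-year frog generations since the reservoir that created the
islands was impounded.

Migration is modelled from the **recipient side**: each new adult on island
$j$ is an immigrant with probability
$m_{\mathrm{sex}} \cdot e^{-I_j/\lambda}$ (males additionally
$\times(1 + \beta_{BS} \cdot BS_j)$, off by default), and an immigrant's
parents are drawn from a source deme chosen with weight proportional to
census size times $e^{-D/\lambda}$, with $\lambda$ = `isolation_effect`
(default 1500 m) and inter-island distances proxied by the sum of the two
islands' mainland-isolation values (only island-to-mainland distances are
surveyed). The recipient-side formulation was chosen over per-capita forward
emigration deliberately: with a 50× mainland, per-capita emigration would
deliver several times an island's capacity in immigrants per generation to
near islands, destroying the interpretability of $m_f$ and $m_m$ as
immigrant fractions. As implemented, the realized immigrant fraction among
sampled females tracks $m_f e^{-I_j/\lambda}$ directly, which is what the
parameter-recovery tests rely on; the simulator records every sampled
adult's natal deme as ground truth.

What the simulator does **not** emulate: overlapping generations and age
structure (real frogs breed over several seasons), genotyping artefacts
(null alleles, allelic dropout, scoring error — upstream filters in real
data), within-island spatial structure, breeding-site competition beyond the
male settlement weight, and non-equilibrium colonization history. Passing
parameter-recovery tests therefore shows the *inference machinery* is
correct under its own model; it does not certify power or calibration on
real data with those complications.

A survey-shaped fixture (`make_survey_fixture()`) pins the per-island sampled
male/female counts to the published survey exactly (382 adults on 14
islands), carries the published area/isolation/PAR/SI columns, and fills the
unpublished per-island breeding-site counts with a fixed synthetic integer
set matching the published mean, spread and range (25–167, mean 62.9);
those values are labelled synthetic wherever they appear.

## Numerical and calibration choices

* Tolerances: AIc mean-centering and AMOVA sum-of-squares identities are
  exact to $10^{-9}$; permutation p-values use $\ge$ comparisons with a
  $10^{-12}$ slack so ties with the observed statistic count as extreme.
* Permutation and Monte-Carlo defaults (999 AMOVA permutations, 1000 LD
  permutations, $10^4$ HWE Monte-Carlo iterations) follow common practice;
  the pipeline exposes all of them, and every stochastic stage takes a seed
  derived deterministically from the single run seed.
* The Mann–Whitney test is discrete: at nominal $\alpha = 0.05$ and 10+10
  individuals per island its realized size is about 0.045, slightly
  conservative by construction. The suite's null-calibration check (500
  simulator replicates under $m_f = m_m$) verifies the realized type-I rate
  sits within a 99% binomial band around 0.05 computed over the replicates.
* Test-suite problem sizes — e.g. 200 replicates for the LD null
  calibration, 100 for the stepwise-vs-exhaustive audit, 50 for
  female-biased recovery, 500 for the type-I check — were chosen once as
  the smallest sizes at which the binomial bands are informative, and the
  vignette's claims are limited to what those runs compute.

## Known limitations

* The HWE genotype-frequency form inside the assignment likelihood assumes
  random mating within islands; islands in strong disequilibrium weaken the
  likelihood model for both sexes simultaneously.
* dAIc regression at $n = 14$ islands is unavoidably small-sample; AICc and
  the reported $R^2$ behave accordingly, and the stepwise trace should be
  read alongside the exhaustive audit.
* AMOVA assumes the allele-mismatch (or squared-size) distance captures the
  mutation process; neither is exactly right for compound or interrupted
  microsatellite motifs.
* The package does not estimate null-allele frequencies or other genotyping
  artefacts; loci failing upstream reliability screens should be removed
  with `exclude_loci()` before analysis.
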