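# dispersalkit

Tools for detecting and explaining **sex-biased dispersal** in fragmented
amphibian populations from codominant microsatellite genotypes.

In many vertebrates one sex disperses from its natal site while the other is
philopatric. Genetically, recent immigrants carry multilocus genotypes that
are atypical of the population in which they were sampled, so dispersal can be
inferred from assignment indices without observing movement. `dispersalkit`
implements the full workflow used in land-bridge-island studies of frogs
(e.g. *Odorrana schmackeri* in Thousand Island Lake, China): population
diagnostics, corrected assignment indices, per-island and pooled sex
comparisons, and a landscape-regression layer that asks which island
attributes predict the strength and direction of the bias. Its intended users
are molecular ecologists working with GenePop-formatted microsatellite data
plus a sample metadata table carrying sex labels.

## The statistics at the core

For individual *i* in population *s*, the expected genotype frequency at
locus *l* is `p^2` (homozygote) or `2pq` (heterozygote) from the allele
frequencies of *s*; the multilocus likelihood is the product over scored
loci. The **corrected assignment index** is

    AIc_i = log10 L_i − mean_{j in s}( log10 L_j )

so AIc averages zero within every population and negative values mark likely
immigrants. The per-island disparity statistic is

    dAIc = mean(AIc male) − mean(AIc female)

with dAIc > 0 indicating female-biased dispersal (females score lower) and
dAIc < 0 male-biased dispersal. Per-island male/female comparisons use
two-sided Mann–Whitney U tests with Benjamini–Hochberg FDR correction.

The landscape layer fits

    dAIc = a + bA + cI + dPAR + eSI + fSR + gBS

(A area, I isolation, PAR perimeter/area ratio, SI shape index
`P/(2·sqrt(pi·A))`, SR sex ratio, BS breeding-site count), after screening
predictors at VIF < 10, selects a model by backward stepwise search under
AICc (`K = k + 2` parameters), and partitions the final R² into unique and
shared predictor contributions.

Supporting diagnostics: per-population allelic richness, observed and Nei's
unbiased expected heterozygosity; exact Hardy–Weinberg tests on the Levene
conditional distribution (complete enumeration with a Monte-Carlo fallback);
genotypic linkage-disequilibrium permutation G-tests; and a two-level AMOVA
(Excoffier sums of squares, Phi_ST, permutation p).

Because the original study's raw genotypes were never deposited, the package
ships a forward-time island-model **simulator** with sex-specific migration,
stepwise/k-allele microsatellite mutation, isolation-damped immigration and
exact ground truth (natal island of every sampled adult), so every stage is
testable by parameter recovery.

## Worked example

Simulate a 14-island metapopulation in which only females migrate
(`m_f = 0.3`, `m_m = 0`), then run the dispersal inference:

```r
library(dispersalkit)

sim <- simulate_islands(sim_config(m_f = 0.3, m_m = 0, seed = 42))
tab <- sim$table
tab
#> genotype_table: 280 individuals, 10 loci, 14 islands
#>   sex: 140M / 140F
#>   missing calls: 0.0%

rec <- assignment_index(tab)          # per-individual AIc
sb  <- sex_bias_test(rec)             # per-island Mann-Whitney + FDR
head(sb[c("island", "n_male", "n_female", "daic", "u", "p_raw", "p_fdr",
          "direction")], 5)
#>   island n_male n_female    daic  u p_raw p_fdr     direction
#> 1     01     10       10  0.3731 52 0.910 0.970 female-biased
#> 2     02     10       10  0.5893 56 0.678 0.970 female-biased
#> 3     03     10       10  0.4279 52 0.910 0.970 female-biased
#> 4     04     10       10 -1.0639 32 0.186 0.867   male-biased
#> 5     05     10       10 -0.0133 52 0.910 0.970   male-biased

dd <- daic(rec)
sprintf("pooled dAIc = %+.4f (p = %.3f)", dd$pooled$daic, dd$pooled$p)
#> "pooled dAIc = +0.2329 (p = 0.470)"

amova_two_level(tab, permutations = 200, seed = 1)
#> Two-level AMOVA (allele_mismatch distance)
#>   Among islands : SS =   259.479  df =  13  sigma2 =   0.6971   10.38%
#>   Within islands: SS =  1600.650  df = 266  sigma2 =   6.0175   89.62%
#>   Phi_ST = 0.1038   permutation p = 0.004975
```

The pooled dAIc is positive — males score higher than females on average,
i.e. female genotypes are less typical of their islands — which is exactly
the signature the simulator planted (one third of each island's females are
immigrants each generation, no males are). With only 280 individuals a single
replicate is rarely significant per island; rates across replicates are what
the test suite checks.

The full pipeline (diversity → HWE/LD → AMOVA → AIc → sex-bias → landscape
model) runs from one configuration and writes per-stage TSVs plus a text
report:

```r
paths <- make_survey_fixture("fx", seed = 7)   # survey-shaped synthetic data
run_all(run_config(paths[["genepop"]], paths[["sidecar"]], paths[["attrs"]],
                   out_dir = "out", seed = 11))
```

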