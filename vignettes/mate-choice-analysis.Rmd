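---
title: "Genetic-benefit mate choice in double-breeding birds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-benefit mate choice in double-breeding birds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

In facultatively double-brooded passerines such as the great tit (*Parus
major*), a minority of pairs initiate a second clutch after fledging a first
brood. Two non-exclusive hypotheses describe the genetic benefit a female may
seek when forming the social bond behind such a demanding season: **good
genes** (choose males whose intrinsic quality — ornament size, body size, song
repertoire, individual heterozygosity, low inbreeding — is high) and **genetic
compatibility** (choose males genetically dissimilar to yourself, i.e. of low
pairwise relatedness). `broodmate` implements the full analysis by which these
hypotheses are tested from codominant microsatellite genotypes and breeding
records: marker quality control, moment estimation of relatedness and
inbreeding, standardized heterozygosity, year-stratified dyadic randomization
tests, and binomial-logit mixed-model selection by AICc.

Because raw field datasets of this kind are typically available only on
request, the package carries a first-class synthetic-data generator
(`simulate_breeding_population()`) that reproduces the statistical structure
the analysis assumes, so that every stage is tested end-to-end without any
download.

# Estimators

## Ritland moment estimators

For a locus with $n_l$ alleles at reference frequencies $p_i$, write
$P_{xi} \in \{0, \tfrac12, 1\}$ for individual $x$'s dosage of allele $i$.
The pairwise relatedness estimate at that locus is

$$\hat r_l = \frac{2}{n_l - 1}\left(\sum_i \frac{P_{xi}P_{yi}}{p_i} - 1\right),$$

and the individual inbreeding estimate is

$$\hat F_l = \frac{1}{n_l - 1}\left(\sum_i \frac{\delta_i}{p_i} - 1\right),$$

with $\delta_i$ the indicator that the individual is homozygous for allele
$i$. Multilocus values are weighted means over loci with information weights
$w_l = n_l - 1$; a locus missing in either member of a dyad simply drops out
of that dyad's weighted mean (per-locus pairwise deletion — the handling of
missing genotypes is not otherwise identifiable from a published analysis).
Both estimators are unbiased (their expectations equal the true kinship
coefficient and inbreeding coefficient), but individual estimates are noisy
with 8 microsatellites and routinely fall outside $[-1, 1]$; negative values
simply mean "less similar than a random pair under the reference
frequencies". The package tests unbiasedness by Mendelian gene-dropping:
10,000 simulated dyads per relationship class must recover means of 0, 0.25
and 0.5 within three Monte-Carlo standard errors.

Reference frequencies matter: relatedness between pair members is computed
with frequencies from **paired adults only**, while individual $F$ and
standardized heterozygosity use **all genotyped birds** (adults plus
offspring), mirroring the reference sets of the original analysis.

## Standardized heterozygosity

$H_s$ is the proportion of an individual's *typed* loci that are heterozygous
divided by the mean population observed heterozygosity of exactly those loci.
An individual typed at loci of population-average heterozygosity scores about
1; the standardization removes the bias that arises when individuals are
typed at different locus subsets. Note that a raw heterozygous-locus
proportion (mean near the population $H_o$, e.g. 0.72) and the standardized
score (mean near 1) differ by that factor; effect sizes on the two scales
differ correspondingly.

# Locus quality control

Markers are screened the way microsatellite panels conventionally are before
relatedness work:

* **Hardy–Weinberg**: a Monte-Carlo exact test. Conditioning on the observed
  allele counts, the $2n$ alleles are re-dealt into $n$ genotypes (the Levene
  distribution); the p-value is the proportion of shuffles whose conditional
  table probability is at most the observed one, with the add-one correction
  $(1 + \#\{P_\text{sim} \le P_\text{obs}\})/(n_\text{mc}+1)$. The test is
  validated against exhaustive enumeration at small $n$ and holds its nominal
  type-I error under simulated equilibrium data (slightly conservatively, as
  exact tests do).
* **Null alleles**: two closed-form estimators of the frequency of a
  non-amplifying allele, Chakraborty's $(H_e-H_o)/(H_e+H_o)$ and Brookfield's
  $(H_e-H_o)/(1+H_e)$, bracketing the maximum-likelihood estimate that
  genotyping software reports. Loci at or above the 0.20 threshold are
  flagged but **not** dropped — in the motivating study all retained loci
  fell below 0.20, and the threshold is a report, not a filter.
* **Linkage disequilibrium**: a genotypic log-likelihood-ratio $G$ statistic
  on the two-locus genotype table, with the null built by permuting one
  locus's genotypes across individuals. Validated for calibration against
  uniformity on independent loci.

`filter_loci()` drops HWE failures at level $\alpha$ (default 0.05, raw; a
Bonferroni switch exists because the original analysis does not state any
correction), then resolves significant LD pairs greedily — repeatedly
dropping the locus involved in the most significant pairs, ties broken
lexicographically — until no significant pair remains. Expected heterozygosity
uses the small-sample unbiased form $(2n/(2n-1))(1-\sum_i p_i^2)$, which
matters at sample sizes near 73.

# Randomization tests

The dyadic null asks: if each double-breeding female had taken a male at
random from her year's full male pool, what would the mean pair relatedness
look like? Per iteration, males are assigned without replacement within each
year (a male holds one social bond per season) and the mean over all
assigned dyads, pooled over years, is recorded; 10,000 iterations give the
null distribution, whose 2.5% and 97.5% empirical quantiles (type-7 linear
interpolation, stated for reproducibility) are the critical values. The
decision is two-tailed; an add-one two-tailed empirical p-value is also
reported, though the decision rule itself uses only the critical values.
Trait nulls (male heterozygosity, stripe width) draw the observed number of
double-breeding males per year from the year pools and record the pooled
mean.

Two readings of "all other pair combinations possible in each year" exist:
the default null pool contains **all** males present in the year (including
the observed mates); `exclude_observed_mate = TRUE` implements the stricter
reading. Years are pooled after averaging across all assigned dyads of an
iteration (a single pooled mean per iteration), the simpler of the two
possible poolings. Both choices are recorded here because the source text
does not resolve them.

The machinery is validated three ways: exhaustive enumeration on pools small
enough to enumerate ($\le 4\times4$), bit-reproducibility under a fixed seed
(R's Mersenne-Twister generator, seed recorded in every result object), and
type-I error: when double-breeding labels are assigned with no trait or
genetic effect, the two-tailed decision rejects in about 5% of replicate
populations.

# Models and selection

Double breeding (0/1) is modelled with binomial-logit GLMMs with random
intercepts for male identity (pseudo-replication across years) and year
(annual incidence differences), fitted by Laplace-approximated maximum
likelihood via `lme4::glmer` — mixed-model internals are deliberately
delegated; the wrapper exposes log-likelihood, AIC, deviance and the
parameter count $k$ = intercept + fixed effects + one variance component per
random effect, matching the "np" convention of published selection tables.
With one observation per male, the male variance component typically sits on
the boundary (zero); such singular fits are flagged, not rejected, and the
wrapper is tested to coincide with a plain logistic fit in exactly that case.
Data that (quasi-)separate the response produce an informative error naming
the predictors, since no maximum-likelihood fit exists there.

Three hypothesis models are compared by AIC: good genes (individual $F$,
$H_s$, stripe width, tarsus length, repertoire size), compatibility (pair
relatedness), and their union. All-subsets selection over the six predictors
($2^6 = 64$ models, including the intercept-only model) is ranked by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, with Akaike weights
normalized over the full candidate set and models within $\Delta\mathrm{AICc}
< 4$ of the best retained. Collinearity is screened with VIFs
($1/(1-R^2_j)$), thresholds 4 for the female-quality model and 2 for the
mate-choice model, as in the source analysis.

Group contrasts use the Welch (unpooled) $t$ from group means and standard
errors — the form that reproduces the published $t$ statistics — and a
two-sample rank-sum test (exact by enumeration for $n_1+n_2 \le 12$ without
ties, normal approximation with midranks and tie correction otherwise). The
statistic reported as $W$ is the rank sum of the first sample; the
Mann–Whitney $U = W - n_1(n_1+1)/2$ is returned alongside because published
"W" values are often wilcox.test's $U$. The source text names signed-rank
tests but applies them to independent unequal-size groups, for which only
the rank-sum test is defined; the package implements the latter.

# The synthetic-data generator

`sim_config()` defaults define the study conditions: 8 loci with 6 alleles
each (frequencies Dirichlet(1) per locus), three years with 29/23/21 socially
monogamous pairs (73 in total), a target double-breeding incidence of 0.30,
trait distributions calibrated to published great tit summaries (stripe
width ~ N(9.9, 1.8²) mm, tarsus ~ N(21.5, 1.3²) mm, repertoire ~ N(3.7,
1.1²) rounded to integers ≥ 1, first-egg date ~ N(19.5, 5.5²) days with
April 1 = day 1), first broods of ~11.7 and second broods of ~8.0 nestlings,
and a 2% missing-call rate. Founders are unrelated Hardy–Weinberg draws
(optionally inbred via identical-by-descent copying at rate `founder_f`);
offspring are generated by Mendelian gene dropping. Null alleles, when
enabled, are modelled mechanistically as a segregating non-amplifying allele:
visible/null heterozygotes surface as false homozygotes and null/null
genotypes as missing data — exactly the mechanism the Chakraborty/Brookfield
estimators assume.

Double-breeding labels come from
$P(\text{double}) = \mathrm{logit}^{-1}(\beta_0 + \beta_s\,\text{stripe} +
\beta_h H_s + \beta_r r)$, computed from the *true* genotypes and generating
frequencies. The intercept is centred numerically so the population mean
probability equals the target incidence. The published study reports no
effect sizes, so the slope defaults were fixed once by pilot simulation with
two anchors: the double-vs-single group contrasts they induce at study size
match the published group summaries (stripe ≈ +1.4 mm vs the published 1.31,
relatedness ≈ −0.16 vs −0.166, $H_s$ ≈ +0.14 standardized), and a
study-sized dataset reproduces the qualitative result pattern — the combined
model winning the three-way AIC comparison, stripe and relatedness present
in the retained model set, and the dyadic randomization test rejecting low —
in the large majority of replicates. The defaults are
`beta = c(stripe = 1.4, Hs = 9, r = -28)`. The slope for relatedness is
large in per-unit terms only because the relatedness covariate has tiny
variance (σ ≈ 0.17 with 8 loci); per standard deviation the three effects
are comparable (roughly 2.5, 1.8 and −2.4 logit units per SD). One honest caveat: the published critical bands of the
randomization tests are narrower than the stated procedure (2.5% quantiles
of 10,000 simulated means) can produce at these sample sizes, so simultaneous
rejection of all three trait tests in a single replicate occurs in most but
not all replicates at these effect sizes; pushing slopes high enough to force
it produces quasi-separated datasets that no logistic fit supports.

What the generator does *not* emulate: extra-pair paternity (all offspring
are within-pair), age structure and return rates (every pair is new), allele
mutation, spatial territory structure, and any trait–trait correlation
beyond what the shared selection step induces. Passing tests therefore show
the machinery is correct and calibrated under the stated model, not that
real data satisfy that model.

# Numerical and design choices

* Quantiles everywhere are type-7 (R's default interpolation), stated
  explicitly because critical values move at the third decimal across types.
* Monte-Carlo p-values use add-one corrections, so they are never exactly 0.
* HWE and LD tests compare log table probabilities with a `1e-9` tie
  tolerance so that ties count as "at least as extreme".
* Allele labels are opaque strings ordered lexicographically (microsatellite
  codes are sizes, not ordinals); genotypes are stored with the smaller label
  first, making allele order irrelevant throughout.
* `aicc()` refuses $n \le k+1$; model ranking refuses candidate sets with no
  converged member; empty locus sets after QC are an error rather than a
  silent fallback.
* The GLMM integration setting `nAGQ = 0` (penalized-likelihood step only) is
  used in the large simulation studies for speed; at the boundary fits these
  data produce it agrees with full Laplace, and the test suite checks the
  reduction against `glm` at machine-level tolerance. Published-style single
  analyses default to `nAGQ = 1`.
* Test and acceptance problem sizes: 10,000 dyads per relationship class for
  estimator unbiasedness, 1,000 zero-effect replicates (inner nulls of 1,000
  iterations) for randomization calibration, 1,000 Hardy–Weinberg replicates
  for HWE type-I error, and 200 study-sized replicates for the
  model-selection pattern.

# Known limitations

* The Ritland estimators take reference frequencies as known; estimating them
  from the same sample that contains the dyad introduces $O(1/n)$ bias that
  is visible only at very small reference samples.
* The null-allele estimators assume the heterozygote deficit is caused by
  null alleles alone; inbreeding or substructure inflate them.
* `compare_hypotheses()` fits the three models as specified with both random
  intercepts even where a variance component is unidentifiable (one
  observation per male); the boundary fits are flagged and are the expected
  behaviour at this design, not an error.
* Model-averaged coefficients are deliberately out of scope: the selection
  table reports per-model weights, and coefficient tables are reported for
  the global and best models.
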