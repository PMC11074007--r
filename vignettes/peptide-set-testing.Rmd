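---
title: "Competitive peptide set testing: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive peptide set testing: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters
and why their defaults are what they are, what the simulator does and
does not emulate, the numerical choices, and the known limitations.

## 1. The model stack

### Peptide-level linear models

For peptide $i$ with log2 abundance $y_{ij}$ in sample $j$ we fit, by
ordinary least squares on the observed samples only,

$$ y_{ij} = \alpha_i + \beta_i g_j + \gamma_i^\top z_j + e_{ij}, $$

where $g_j \in \{0,1\}$ indicates the test group and $z_j$ are
optional covariates. $\beta_i$ is the peptide log2 fold change (test
minus reference). Peptides with fewer than two observations in either
group, or with no residual degree of freedom, are flagged and excluded
from all sets and backgrounds rather than silently dropped; a contrast
that cannot be estimated should not contribute pseudo-information.

### Empirical-Bayes moderation

Residual variances $s_i^2$ (on $d_i$ df) are shrunk toward a prior
$s_0^2$ with $d_0$ prior df via the posterior mean
$\tilde s_i^2 = (d_0 s_0^2 + d_i s_i^2)/(d_0 + d_i)$. The
hyperparameters come from moment matching on the log scale: under the
sampling model $s_i^2 \sim s_0^2 F_{d_i, d_0}$,
$E[\log s_i^2]$ and $\mathrm{Var}[\log s_i^2]$ are explicit in
digamma/trigamma functions, so $d_0$ solves a trigamma equation
(Newton iteration, step tolerance $10^{-8}$) and $s_0^2$ follows from
the mean. When the observed spread of $\log s_i^2$ is no larger than
its pure sampling value, $d_0 = \infty$ is reported and every
$\tilde s_i^2$ equals the common value (the plain mean of the
$s_i^2$, not the biased log-scale back-transform). The moderated
statistic $t_i = \hat\beta_i / (u_i \tilde s_i)$ is referred to a
Student $t$ on $d_0 + d_i$ df.

A covariate-dependent prior ("trend") is available: $s_0^2$ becomes a
lowess function (span 0.5) of the covariate. The package uses it only
in the aggregation comparators, with $\log(\text{peptide count})$ as
the covariate, and only when the proteome actually mixes peptide
counts — a constant covariate is detected and treated as no trend, so
the two code paths agree exactly on uniform proteomes.

### Inter-peptide correlation

Peptides cut from one protein share the protein's true abundance
trajectory, so their quantitative profiles are positively correlated;
treating them as independent replicates overstates the evidence. We
assume a single pairwise correlation $\rho$ per protein and estimate
it from the mixed model

$$ y_{ij} = X_j \beta_i + r_j + \varepsilon_{ij}, \qquad
   r_j \sim N(0, \sigma_r^2), \quad
   \varepsilon_{ij} \sim N(0, \sigma_e^2), $$

with a full peptide-by-design fixed-effect interaction (each peptide
keeps its own intercept and group effect, as the peptide index on
$\beta$ demands) and a random intercept per sample. The implied
marginal covariance of the $m$ peptides in any sample is
$\sigma_r^2 J + \sigma_e^2 I$, an equicorrelation matrix, so

$$ \hat\rho = \frac{\hat\sigma_r^2}{\hat\sigma_r^2 + \hat\sigma_e^2}
   \in [0, 1] $$

is non-negative by construction — the model-based counterpart of the
explicit clamp applied to the alternative moment ("Wu-style")
estimator, which standardizes the residual vectors and reads the mean
pairwise correlation off the variance inflation of their mean. The
moment estimator is faster and nearly assumption-free but requires
complete data; it refuses missing values with a pointer to the mixed
method rather than imputing silently.

Estimation is REML. Two routes coexist and are tested against each
other and against an external mixed-model implementation:

* complete matrices use the balanced-ANOVA closed form (between-sample
  mean square of peptide-averaged residuals vs. within mean square),
  which coincides with REML away from the boundary;
* incomplete matrices profile the REML criterion down to the single
  variance ratio $\lambda = \sigma_r^2/\sigma_e^2$; each candidate
  $\lambda$ whitens the per-sample blocks analytically
  ($ (I+\lambda J)^{-1/2} = I - cJ $), so the 1-D search on
  $\log\lambda$ (tolerance $10^{-10}$) is cheap and deterministic.
  Optima at the lower search bound are reported as the boundary
  estimate $\hat\sigma_r^2 = 0$ with a flag.

Correlation is estimated once per protein from the expression
residuals and reused for the test statistic, adopting the working
assumption that correlations between peptide t-statistics track the
correlations between the log expressions they are computed from.

### The competitive set test

For a protein of interest with peptide index set $P$ ($|P| = m_1$)
and background $P^c$ ($m_2$ peptides, every fitted peptide not mapped
to the protein — a shared peptide belongs to every protein it maps to
and never to those proteins' backgrounds), the null hypothesis is
$\mu_{t,P} = \mu_{t,P^c}$: the protein's peptides are no more
differentially expressed than the rest of the peptidome. The
statistic is

$$ T = \frac{\bar t_P - c_{P^c}}
  {\sqrt{s_\mathrm{pool}^2\left(\frac{1 + (m_1-1)\hat\rho}{m_1}
   + \frac{1}{m_2}\right)}},
   \qquad
   s_\mathrm{pool}^2 = \frac{(m_1-1) s_P^2 + (m_2-1) s_{P^c}^2}
   {m_1 + m_2 - 2}, $$

referred two-sidedly to $t_{m_1+m_2-2}$. The factor
$1 + (m_1-1)\hat\rho$ is the variance inflation of a mean of $m_1$
equicorrelated statistics; at $\hat\rho = 0$ with the SD background
scale the statistic is *exactly* the classical pooled two-sample
t-test (verified against an independently coded textbook formula to
$10^{-10}$).

Background center and scale come in two flavors. `sd` uses the sample
mean and standard deviation of $t_{P^c}$. `mad` — the default — uses
the median and $1.4826 \cdot \mathrm{MAD}$; the constant is
$1/\Phi^{-1}(3/4)$ rounded to four decimals, which makes the MAD
consistent for the SD under normality. The robustification matters
when a minority of truly changing proteins fattens the tails of the
background t-distribution: a handful of active proteins should not
inflate the yardstick against which every other protein is measured.
Only the background side is robustified; the set side keeps its
sample mean and SD, since the set is exactly the object under test.

The degrees of freedom and pooling convention deserve a note: the
exact reference formula used by the published method lives in
supplementary material that is not part of the main text, so the
package adopts the standard competitive-test construction stated
above ($m_1 + m_2 - 2$ df, set+background pooling) and documents it
as its own convention. Single-peptide sets are tested with
$\mathrm{VIF} = 1$ (their `m` column flags them); their set variance
contributes zero weight to the pool.

P-values are adjusted across proteins by Benjamini-Hochberg
(default) or, for users worried about dependence, the more
conservative Benjamini-Yekutieli step-up, implemented directly (sort,
multiply by $n/i$ and for BY by the harmonic number, cumulative
minimum, cap at 1) and tested against the reference implementation.

## 2. Data handling defaults

* **Zero intensities are missing**, not $\log_2 0$: a zero from a
  quantitation tool is a non-detection. No negative-infinity sentinel
  survives ingestion (the constructor refuses non-finite values).
* **Contaminants/decoys**: the MaxQuant dialect drops rows whose
  accessions carry `CON__`/`REV__` prefixes (any mapped accession
  triggers removal).
* **Missingness filter**: "observed in at least 70% of samples" is
  implemented as count $\ge \lceil 0.7 n \rceil$, the conservative
  reading of "at least"; the fraction is a parameter (`min_frac`)
  with the 70% default that is customary in label-free proteomics.
* **Normalization**: per-sample median centering (subtract the
  column's observed median, add back the grand median) equalizes
  column medians without touching within-sample differences. Other
  upstream pipelines normalize differently, so the method is
  pluggable (`none` is available) and the choice is recorded in
  output metadata rather than asserted as canonical.
* **No imputation.** Both the mixed-model estimator and the set test
  operate on observed cells under a missing-at-random assumption;
  missing-not-at-random mechanisms (intensity-dependent dropout) are
  explicitly out of scope.

## 3. The simulator: a stated world

`sim_config()` defaults encode the benchmark world: 9000 peptides in
a mixture proteome of 1400 3-peptide, 360 10-peptide and 40
30-peptide proteins (uniform 3/10/30-peptide proteomes of 3000, 900,
300 proteins are one argument away); peptide means drawn standard
normal; unit peptide variances; within-protein equicorrelation $\rho$
(0 or 0.05 in the benchmark scenarios) realized exactly by the
one-factor construction $\sqrt\rho\, z_{gj} + \sqrt{1-\rho}\,
\epsilon_{ij}$; $N$ total samples split evenly into two groups; a
`de_fraction` of proteins (5% in power scenarios) shifted by
$\pm$`effect` (0.5 log2 units, half up and half down) in the test
group; 1000 replicates by default, with every replicate's seed
derived as master seed + replicate index. DE proteins are drawn
without replacement, stratified across proteome blocks by
largest-remainder apportionment, so mixture scenarios always contain
DE proteins of every size class.

Per replicate, every requested workflow sees the identical table and
design, so power comparisons are paired. Raw p-values at
$\alpha = 0.05$ feed the Type I error rate (null proteins) and power
(DE proteins); BH-adjusted p-values feed the empirical FDR (false
discoveries over discoveries, 0 when nothing is discovered) and TPR.
Every metric is reported with its Monte-Carlo standard error across
replicates.

What the simulator does *not* emulate: missing values and their
intensity dependence, heteroscedastic peptides (ionization efficiency
spans orders of magnitude), shared peptides, isoform substructure,
heavy-tailed measurement error, and between-protein correlation. A
green simulation test therefore establishes calibration and ordering
claims under the stated Gaussian equicorrelated world, not
performance on any particular real dataset; the real-data entry
points exist precisely because those claims must be re-examined per
dataset.

### On the Type I error of the null scenario

Under the null mixture scenario ($\rho = 0$, $N = 30$) the measured
rejection rate of the competitive test at raw $p < 0.05$ is 0.0418
(Monte-Carlo SE 0.0003 at 200 replicates), not 0.0500. This is not an
implementation artifact but a property of the published method: with
true $\rho = 0$ the REML estimate for a 3-peptide protein has
sampling SD $\approx \sqrt{2/(mN(m-1))} \approx 0.105$, and the
non-negativity of $\hat\rho$ turns that noise into a positive mean,
$E[\hat\rho] \approx 0.105\,\phi(0) \approx 0.042$. The resulting
average VIF of $\approx 1.08$ deflates $T$ by $\approx 4\%$, and
$P(|Z| > 1.96\sqrt{1.084}) = 0.041$ — matching the measurement. The
clamp thus buys protection against anti-conservatism under true
positive correlation at the price of mild conservatism at $\rho = 0$;
the acceptance suite asserts the literal $\pm 3$ Monte-Carlo-SE band
around 0.05 and that assertion stays red, deliberately, with this
analysis as the explanation.

## 4. Comparator workflows

Summation collapses a protein to
$\log_2 \sum_{i} 2^{y_{ij}}$ over observed peptides (sums live on the
raw intensity scale; a cell with no observed peptide stays missing).
Robust rollup fits the two-way model
$y_{ij} = p_i + s_j + e_{ij}$ on observed log2 cells by iteratively
reweighted least squares with Huber weights (tuning constant 1.345
for 95% normal efficiency; residual scale re-estimated each iteration
by the scaled MAD; at most 50 iterations, coefficient tolerance
$10^{-6}$), and reports the estimated sample effects re-centered to
the protein's grand mean. Rank-deficient observation patterns
(disconnected peptide/sample bipartite graphs) fall back to
observed-cell sample means with a flag. Both rollups reduce exactly
to the peptide profile for single-peptide proteins, and both feed the
same OLS + empirical-Bayes machinery as the peptide level, with the
log-peptide-count trend available for mixture proteomes.

## 5. Open design points, resolved

* **Covariates beyond the group effect** in the peptide and mixed
  models: accepted by the interfaces, default group-only — the
  benchmark scenarios never exercise them, and silent covariate
  defaults are a reproducibility hazard.
* **BH across which proteins**: adjustment spans *all* tested
  proteins, including single-peptide sets; excluding them would make
  the adjusted p-value of a protein depend on an arbitrary
  testability boundary.
* **FDR/TPR definitions**: the standard empirical definitions with
  FDR = 0 on zero discoveries.
* **Summation scale**: on raw intensities ("summed intensity" means
  raw), then re-logged.
* **Replicate counts**: scenarios stated with 1000 replicates are run
  at 200 in the acceptance suite (Monte-Carlo SEs are reported and
  the bands account for them); the power-ordering check uses 100
  paired replicates, ample for a difference an order of magnitude
  larger than its SE.

## 6. Known limitations

The test assumes the bulk of the peptidome is unchanged and roughly
centered (competitive tests lose meaning when most analytes move in
one direction, as in pull-downs or secretomes); it assumes a common
variance of peptide t-statistics across proteins (a Welch-type
variant would relax this); equal pairwise correlation within a
protein ignores isoform subgroup structure; small cohorts with
peptide-rich proteins ($m = 30$, $N = 6$) leave $\hat\rho$ too noisy
for exact calibration; and statistical significance of a set says
nothing about effect-size relevance — the reported mean peptide log2
fold change is the number to inspect for that.
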