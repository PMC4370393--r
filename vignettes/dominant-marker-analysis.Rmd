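---
title: "Population-genetic analysis of dominant marker data with dompop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of dominant marker data with dompop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dompop)
```

## The data model

Dominant fingerprinting markers (ISSR, RAPD, AFLP) score each individual at
each locus as band **present** (1) or **absent** (0). A band is present
whenever at least one copy of the amplifiable allele is carried, so the
heterozygote is indistinguishable from the dominant homozygote and only the
null homozygote is observed directly. Everything in this package flows from
that masking: with band frequency $f_b$ at a locus and Hardy–Weinberg
proportions, the band-absence class has frequency $q^2$, which forces the
**square-root estimator**

$$\hat q = \sqrt{1 - f_b}, \qquad \hat p = 1 - \hat q.$$

(The widely circulated one-line variant "$q = (1-f_b)/2$" is not consistent
with Hardy–Weinberg dominance and is not used.)

The central container is the `BandMatrix` class, a
`SummarizedExperiment` with loci as rows, individuals as columns, a
`population` column and an optional per-locus `primer` assignment. The
`calls` assay admits 0, 1 and `NA`; validity enforces binary calls, unique
labels, a complete population map, and at least two individuals.

## Marker informativeness

Per locus, `picDominant()` computes $PIC = 1 - p^2 - q^2 = 2pq$ (maximum
0.5 at $f_b = 0.75$), and `shannonBand()` the two-state entropy
$-p\ln p - (1-p)\ln(1-p)$, bounded by $\ln 2$. The one-term form
$-p \ln p$ cannot exceed $1/e \approx 0.368$, while published primer tables
for this marker class report values near 0.386, so the two-state entropy is
the only consistent reading and is the one implemented. `primerReport()`
aggregates per primer; the marker index is the exact product
$MI = \overline{PIC} \times$ (number of polymorphic loci), and a locus
counts as polymorphic when its pooled band frequency lies strictly inside
$(0,1)$ (an optional 95%/99% criterion flag exists but is off by default,
since reports with a 100% polymorphism class imply the strict rule).
Percent-polymorphic columns are *truncated* to one decimal — the convention
of the classic report tables this mirrors (21/22 prints as 95.4) — whereas
the LD percentage below is rounded.

## Within-population diversity

`populationDiversity()` averages per-locus statistics over **all** loci
(monomorphic loci contribute zeros rather than being dropped, the
POPGENE-style convention): observed alleles $N_a \in \{1,2\}$, Nei's gene
diversity $h = 2pq$, effective alleles $N_e = 1/(1-h)$, Shannon's
$I = -p\ln p - q\ln q$, and a band-state expected heterozygosity
$H_e = \frac{n}{n-1}(1 - f_b^2 - (1-f_b)^2)$ computed on the phenotype
states under haploid coding with the small-sample correction. $H_e$ and $h$
measure different things: their ratio is $q(1+q)\cdot n/(n-1)$, so band-state
diversity exceeds allele-based diversity exactly where
$f_b \le (\sqrt5 - 1)/2$; panels rich in low- and mid-frequency bands
therefore show $\bar H_e > \bar h$. The pooled ("Species") row always
dominates the mean within-population $h$ (a Wahlund-type inequality the
test suite checks on simulated data).

## Differentiation

* `gstDominant()` — per-locus $H_t = 2\bar p\bar q$ on unweighted mean
  frequencies, $H_s = \overline{2p_kq_k}$, combined as the ratio of sums
  $\sum_l (H_t - H_s) / \sum_l H_t$ (the stable Weir-style choice among the
  equally defensible averaging orders).
* `amova()` — one-level AMOVA with the squared Euclidean distance between
  band vectors (= mismatch count), SSD partition, variance components from
  expected mean squares with the unequal-$n$ coefficient $n_0$, and
  $\Phi_{st} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Significance comes
  from permuting individuals across populations with the observed statistic
  included in numerator and denominator, so $p \ge 1/(B+1)$ and the test is
  exact-level. A zero total SSD flags $\Phi_{st}$ as undefined instead of
  inventing a number.
* `pairwiseFst()` — two-population $\Phi_{st}$ per pair, the pairwise-Fst
  convention of distance-based AMOVA software. Note that $\Phi_{st}$ on
  band vectors quantifies differentiation of the *band states*: under
  dominance it sits above the allele-level $\theta$ that generated the
  data (≈0.26 band-state for $\theta = 0.2$ at mid-range frequencies).
  Recovery tests therefore compare it with the band-level differentiation
  computed from the simulation truth, not with $\theta$ itself.
* `geneFlow()` — Wright's island-model inversion $N_m = (1-F_{st})/(4F_{st})$.
* `ldScreen()` — two-sided Fisher's exact test per locus pair on the joint
  presence/absence table, pooled over populations (one genome-wide
  percentage is reported). Unordered pairs $\binom{L}{2}$ are the default;
  an "ordered" flag reproduces the $L^2$ denominator some reports print.
  Fisher's test is conservative on discrete tables, so the realised
  false-positive rate sits slightly below $\alpha$.

## Distances, trees, ordination

`neiDistance()` implements Nei's (1978) small-sample-unbiased distance on
the dominant-marker allele-frequency estimates, with per-locus sample sizes
taken from non-missing call counts. `upgma()` is average-linkage
agglomeration with node height = merge distance / 2; exact ties break on
the lexicographically smallest pair of cluster labels (a cluster is
labelled by its alphabetically first leaf). The tie rule matters in
practice: the embedded reference distance table contains a near-tie
(0.03345 vs 0.0335) that decides a merge order, and the documented rule
makes the outcome reproducible. `pcoa()` performs Gower double-centering of
$-d^2/2$ with percentages over positive eigenvalues only; `mantelTest()`
correlates distance triangles with a joint row/column permutation null,
enumerated exhaustively when $n \le 7$ ($n! \le 5040$) and sampled
otherwise; `geographicDistance()` uses the haversine formula (mean Earth
radius 6371.0088 km) via geosphere on coordinates parsed from
degrees–minutes–seconds by `parseDMS()`.

"PCA on pairwise genetic distances", as popularised by GenAlEx-style
workflows, is a principal-coordinates analysis, which is why the package
exposes `pcoa()` rather than a covariance PCA. Pearson's $r$ in the Mantel
test is invariant to linear rescaling of either matrix, but different
geographic metrics can still shift permutation p-values slightly, so exact
reproduction of any one published isolation-by-distance $r$ is not claimed.

## The Bayesian hierarchical model

`fitHickory()` estimates differentiation and inbreeding from phenotype
counts alone. Per locus $\pi_l \sim U(0,1)$; per population the null-allele
frequency $q_{kl} \sim \mathrm{Beta}$ with mean $1-\pi_l$ and dispersion
$\theta_B$ (shapes scaled by $(1-\theta_B)/\theta_B$, so that the
among-population variance of frequencies is $\theta_B\,\pi(1-\pi)$); the
likelihood of the band-absent class is $q^2 + f q(1-q)$ with
$f \sim U(0,1)$. Updates are Metropolis-within-Gibbs with reflected
Gaussian proposals; proposal widths adapt toward ~35% acceptance during
burn-in only and are frozen afterwards, keeping the retained chain valid.
Each retained draw records

$$\theta_I = \frac{\sum_l \mathrm{var}_k(p_{kl})}{\sum_l \bar p_l (1 - \bar p_l)},$$

the variance-based $F_{st}$ analog of the sampled frequencies (ratio of
sums across loci, the numerically stable choice), plus $\theta_B$, $f$, the
per-population panmictic heterozygosity $h_s = \overline{2pq}$ and the
deviance. DIC uses the Spiegelhalter decomposition
$\bar D + p_D$ with $p_D = \bar D - D(\hat q, \hat f)$.

Variants: **full** (both $\theta_B$ and $f$ estimated), **f0** ($f \equiv 0$),
**theta0** ($\theta_B \equiv 0$, i.e. all populations share $1 - \pi_l$;
$\theta_I$ is then identically 0 — the variant exists to be *beaten* in DIC
comparisons when real differentiation is present), and **ffree** ($f$
redrawn from its prior each sweep, ignoring the data — a device for showing
how little dominant data inform $f$ directly). `compareModels()` ranks by
DIC with name-stable ties.

Chain lengths: the conventional long-run defaults (burn-in 50 000, 250 000
sweeps, thin 50) are the method defaults; the test suite and calibration
studies use 2 000 / 10 000 / 10 on study-sized data (8 populations of
19–23, 180 loci), where the posterior is already stable to well under the
reporting precision.

## Admixture clustering and $\Delta K$

`fitAdmixture()` runs a Gibbs sampler for the admixture model on
haploid-coded bands: cluster frequencies Beta(1,1), ancestries
Dirichlet(1), and a latent cluster of origin per individual–locus call,
sampled by the Gumbel-max trick. The "correlated allele frequencies" prior
of genotype-based samplers is deliberately simplified to independent
Beta(1,1) frequencies: under dominance and at these panel sizes the
correlated-prior parameters are effectively unidentifiable, and nothing
downstream (recovery on separable data, $\Delta K$ mechanics, the
assignment rule) depends on the prior correlation. The run-level
$\widehat{\ln P}(X|K) = \bar{\ln L} - \mathrm{var}(\ln L)/2$ is the
standard heuristic estimate used for model choice. `evannoDeltaK()`
computes $\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)|/sd(L(K))$
from replicate runs, leaving the endpoints undefined rather than
extrapolating, and `assignIndividuals()` applies the inclusive $\ge 0.8$
rule, labelling everything else "admixed".

## The simulator and what passing tests mean

`simulateDominant()` is the generative mirror of the hierarchical model:
$p_{kl} \sim \mathrm{Beta}(\pi_l(1-\theta)/\theta,\,(1-\pi_l)(1-\theta)/\theta)$,
band absence with probability $q^2 + fq(1-q)$. `studyLikeDataset()` fixes
the reference study design — 8 populations of (20, 23, 20, 23, 23, 21, 19,
23) individuals, 180 loci in primer groups of (19, 22, 18, 18, 16, 17, 20,
10, 19, 21), $\theta = 0.19$, $f = 0.14$, $\pi \sim U(0.05, 0.95)$. The
$\theta$ and $f$ defaults are that study's own estimates, chosen so
parameter-recovery tests run under realistic conditions; $U(0.05, 0.95)$
keeps loci away from monomorphism, as marker panels are ascertained to do.

The simulator draws loci independently (no linkage, no clonal structure,
no mutation history) and populations exchangeably (no geography in the
frequencies). Passing recovery tests therefore shows the estimators are
correct *under the model they assume*; it cannot show robustness to
linkage, clonality or isolation-by-distance patterns in real data, which
is why the LD screen is tested on explicitly constructed correlated
columns instead.

## Numerical choices and limitations

- Permutation p-values always include the observed statistic (+1
  convention); seeds are mandatory in the API and derived deterministically
  per stage in `runPipeline()`.
- Probabilities inside likelihoods are clamped to $[10^{-12}, 1-10^{-12}]$
  before logs; Beta proposals reflect at the (0,1) boundary, preserving
  symmetry.
- Rounding happens only in reporting helpers (`percentPolymorphic()`
  truncates, `ldPercent()` rounds); all machine-readable outputs carry full
  precision.
- Negative AMOVA variance components are reported as computed (they carry
  information about the design) rather than truncated.
- The Bayesian $f$ is weakly identified from dominant phenotypes; expect
  wide posteriors, and use the `ffree` variant plus DIC to judge how much
  the data actually say about it.
- AMOVA here is strictly one-level (within/among populations); no
  region/population hierarchy.

## A worked run

```{r example, eval = FALSE}
sim <- studyLikeDataset(seed = 1)
m <- sim$matrix

primerReport(m)[, c("primer", "n_polymorphic", "mean_pic", "mi")]
populationDiversity(m)
res <- amova(m, n_perm = 999, seed = 2)
res
geneFlow(phiST(res))
tree <- upgma(neiDistance(m))
cutTree(tree, 3)
fit <- fitHickory(m, "full", burn_in = 2000, samples = 10000, thin = 10,
                  seed = 3)
posteriorSummary(fit, "thetaI")
```

The whole workflow, driven by one YAML config with per-stage seeds and
provenance headers, is available as `runPipeline()`; see `?runPipeline`.
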