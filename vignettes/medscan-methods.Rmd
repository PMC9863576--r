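---
title: "Methods: association scans and QTL hotspots in structured landrace panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association scans and QTL hotspots in structured landrace panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medscan)
```

## The problem

Landrace collections carry adaptive variation shaped by centuries of local
selection. Three complementary association scans expose different layers of
that variation:

* **Phenology GWAS** (class P): heading, anthesis and maturity dates from
  replicated-check augmented field trials, adjusted to per-accession BLUPs.
* **Environmental GWAS** (class C): long-term climate normals of each
  accession's country of origin used directly as phenotypes, so that loci
  associated with the climate of origin mark putatively adaptive variants.
* **eigenGWAS** (class E): eigenvectors of the genetic similarity
  decomposition used as phenotypes, so that loci with outlying
  differentiation between subpopulations surface without any phenotype at
  all.

Because a single locus can answer to several of these scans, the package's
final products are *QTL hotspots*: genomic regions where the density of
marker--trait associations (MTAs), pooled over all scans, is exceptional.

## Phenotype adjustment

Field trials follow a non-replicated augmented design: each test accession
is sown once per season, with two replicated check cultivars interleaved at
roughly one check per five test plots. Trait values are fitted per
environment (year) with the linear mixed model

$$ y = X\beta + Z\gamma + \varepsilon, $$

where the fixed effects $\beta$ are the intercept and check-cultivar
effects and the random effects $\gamma$ comprise independent row, column
and accession terms. `reml_blup()` fits this model by REML with
`lme4::lmer()` and returns the accession BLUPs, averaged across years by
default (`combine = "per_year"` preserves per-environment values; how years
should be combined is genuinely open, and the arithmetic mean is the
package's choice). The test suite verifies the fit against an independent
dense solve of Henderson's mixed-model equations at the same variance
components (agreement to 1e-8), and checks the defining shrinkage property
of BLUPs directly.

Climate phenotypes are simpler: `climate_phenotype()` assigns every
accession the long-term value of one variable (Tmax, Tmin, Tmean, Rh,
Sunshine, Rad, ET0, Rain) in one growth window of its country of origin.
The two windows are fixed calendar ranges for Mediterranean wheat --- SA
(sowing to anthesis), 20 November--31 March, and AM (anthesis to maturity),
1 April--30 June. `window_average()` averages daily series over the window,
except rainfall, which is accumulated: published long-term rain figures for
such windows are totals in mm, not daily means, and the packaged climate
table follows that convention (e.g. window totals of several hundred mm).

## The mixed-model association engine

All three scan families use one engine: the P+K (PCA + kinship) mixed
linear model. For a phenotype $y$,

$$ y = X\beta + g_j m_j + u + \varepsilon,\qquad
   u \sim N(0, \sigma_g^2 K),\quad \varepsilon \sim N(0, \sigma_e^2 I), $$

with $X$ an intercept plus the top principal components of the dosage
matrix (6 by default), $m_j$ the mean-imputed 0/1/2 dosage of marker $j$,
and $K$ the genomic kinship (column-centered cross-product by default,
VanRaden's scaling as an option). `fit_null_mlm()` estimates
$(\sigma_g^2, \sigma_e^2)$ by REML through a single eigen-decomposition of
$K$ and one-dimensional profiling of the restricted likelihood over the
variance ratio $\delta = \sigma_g^2/\sigma_e^2$ (grid scan over
$\log\delta \in [-10, 10]$ followed by golden-section refinement at
tolerance 1e-8). Under the default P3D mode the null components are reused
for every marker; `scan_markers()` then whitens the model with
$V^{-1/2}$ in the eigenbasis and performs an exact F-test per marker by
projecting out the fixed covariates once --- the whole scan is three matrix
products plus column sums, so $10^4$ markers on 150 accessions take well
under a second. Exact per-marker REML is available behind `p3d = FALSE`.

Reported quantities per association: $-\log_{10} p$, the allele
substitution estimate, and $r^2$, defined as the squared partial
correlation between whitened marker and whitened phenotype given the
covariates ($F/(F + \mathrm{df})$). This definition is bounded, monotone in
the signal-to-noise ratio (tested on a noise ladder) and reproducible,
which is why it is preferred over fractions of raw phenotypic variance.

MTAs are retained above a fixed $-\log_{10} p > 3$ convention; no
multiple-testing correction is applied, deliberately, because the
downstream hotspot stage is itself an aggregation device and the threshold
matches common practice in wheat landrace panels.

Two engine-specific choices deserve note:

* **eigenGWAS collinearity guard.** When the phenotype is `eigenk`, the
  $k$-th fixed PC is dropped (`drop_collinear_pc_for_eigen = TRUE`),
  otherwise the covariate absorbs the very axis under test and the scan is
  blind by construction. The guard is configurable because either design
  can be argued.
* **Compression.** `assoc_config(compression = g)` clusters accessions on
  kinship into `g` groups and fits at group level. It is off by default:
  the "optimum" level is panel-specific and not operationally defined, and
  the uncompressed model is exact.

## Population structure

`kinship()`, `ibs_distance()` and `pcoa()` provide the structure layer.
PCoA is classical metric scaling of the allele-sharing distance
$D = 1 - \mathrm{IBS}$ (proportion of shared alleles among pairwise
non-missing markers): double-centering of $-D^2/2$ and
eigen-decomposition, axes scaled by $\sqrt{\lambda}$, percentages of
variance relative to the sum of positive eigenvalues. Eigenvectors are
sign-ambiguous; each axis is oriented so its first non-zero score is
non-negative, and tests compare axes up to sign. `eigen_phenotypes()` turns
the top 5 axes (default) into the class-E trait table.

## From MTAs to hotspots

Each MTA is standardized to a Gaussian density on the genetic map. The
95% width of the Gaussian equals the chromosome's LD-decay extent CI (in
cM), i.e. $\sigma = \mathrm{CI}/3.92$ with $3.92 = 2 \times 1.96$. The
per-cM *overview index* at integer position $x$ is

$$ U(x) = \frac{1}{nbE} \sum_{\text{MTAs } i} \phi(x;\, c_i, \sigma_{chr(i)}^2), $$

where $nbE$ is the number of experiments (trait--scan combinations
contributing MTAs) and $c_i$ the MTA position. $U$ integrates to
$nbQTL/nbE$ over the map; the test suite checks this mass conservation to
1% away from chromosome ends (Gaussian mass beyond the ends is not
reflected --- a small, documented edge bias). Two thresholds are derived:
the *mean* threshold $nbQTL/(nbE \times \text{map length})$, the value a
uniform spread of the same mass would take everywhere, and a *high*
threshold at `high_multiplier` (default 5) times the mean. The multiplier
is a config knob because the exact factor behind published high thresholds
of this kind is not derivable from first principles.

`detect_peaks()` reports maximal runs of consecutive integer-cM positions
strictly above the threshold (one peak per run, at the leftmost argmax).
`build_hotspots()` dilates each peak by half the chromosome's LD extent,
merges overlapping cM intervals, unions the trait classes of the MTAs
inside, and anchors the interval physically at the mapped markers nearest
to each end. Hotspots are named `chromosome.ordinal` in cM order.
`physical_interval()` computes the CI in Mb (order-insensitive absolute
width, rounded to 2 decimals); `select_hotspots()` retains regions with CI
at most 20 Mb --- wider regions make candidate-gene mining uninformative
--- and `merge_overlapping()` unions same-chromosome regions whose
physical intervals intersect (1-based inclusive coordinates: touching
endpoints merge, a 1-bp gap does not), concatenating ordinals in the
merged name (`1B.1-2`).

## Differentiation patterns and candidate genes

Within eigen-associated hotspots, `group_allele_frequencies()` tabulates
subpopulation allele frequencies (allele counting: 2 per homozygote, 1 per
heterozygote; admixed accessions can be excluded by passing them an `NA`
group label) and `classify_differentiation()` labels each subpopulation
pair at each marker: *robust* when the two majority alleles differ and both
majority frequencies reach 80%, *moderate* when both reach 60% without
qualifying as robust, *none* otherwise. The rule is symmetric in the pair
and invariant to allele labelling, and raising the robust threshold can
only shrink the robust set (both tested).

`genes_in_hotspot()` extracts gene models whose intervals intersect the
hotspot's physical interval (any overlap, inclusive bounds --- strict
containment is ill-defined at flanking-marker edges, so the laxer rule is
declared and used consistently). `deg_filter()` implements the candidate
filter: a gene is kept for a tissue when stress tpm exceeds control tpm by
strictly more than 2 (a delta of exactly 2.0 is excluded; downregulation
never qualifies), in at least one study when several stress studies are
present.

## The synthetic-data generator

`simulate_population()` draws a structured panel under the Balding--Nichols
model: ancestral frequency $p \sim U(0.1, 0.9)$ per marker, subpopulation
frequencies $\sim \mathrm{Beta}(p(1-F_{st})/F_{st},\,
(1-p)(1-F_{st})/F_{st})$, genotypes binomial. Defaults mirror the panel the
pipeline is designed for: 153 accessions, 3 subpopulations (West, North
and East Mediterranean, with 23 countries split 7/8/8 across them), ~10^4
SNPs on 21 chromosomes of 175 cM each (~3675 cM total, ~4 Mb/cM), and a
20% admixed fraction drawn as 50/50 two-subpopulation mixtures --- the
admixture level of real panels is rarely published, so 0.2 is a
calibration choice that places the top-5 PCoA axes in the empirically
typical 10--40% band of explained variance. Realized differentiation is
validated against an independent Weir--Cockerham estimator
($|\hat\theta - F_{st}| < 0.02$ at 5000 markers).

What the generator deliberately does **not** emulate: linkage
disequilibrium between markers (markers are independent; LD only enters
through the per-chromosome CI used for standardization), coalescent
ancestry, genotyping-chip missingness patterns, and genotype--environment
interaction. Passing tests therefore demonstrate the statistical machinery
under the stated model, not robustness to every property of real panels.

`simulate_phenology()` produces augmented-design plot records (year, row,
column effects, planted additive QTLs, residual scaled to a target
heritability; check plots are rounded up to an even count so both named
checks are always replicated). `simulate_climate()` gives countries of the
same subpopulation a shared mean plus country noise.
`simulate_structured_null()` produces the canonical confounded null: a
phenotype whose mean follows ancestry (admixed accessions get the mixture
mean of their two components' shifts) with unit noise. The ancestry
weighting matters: a shift attached to the discrete subpopulation *label*
is not a function of genome-wide ancestry, so no structure correction could
remove it, and it would measure the wrong thing.
`simulate_annotation_expression()` plants a known subset of
stress-upregulated genes with deltas above the 2-tpm filter margin.

## Validation problem sizes

The shipped validation suite runs the pipeline at these scales, chosen to
make the statistical checks sharp while keeping a full run in minutes:

* oracle equivalence: 20 random instances, $n \in [20, 50]$,
  $m \in [30, 100]$, p-values vs a dense whitened-GLS oracle at 1e-8
  relative;
* type-I calibration: 20 replicates of $n = 150$, $m = 5000$,
  $F_{st} = 0.1$ structured nulls; the exceedance rate at
  $-\log_{10} p = 3$ must fall in the 99% binomial envelope around
  $10^{-3}$ with the P+K correction, and exceed it without;
* parameter recovery: 50 replicates of $n = 150$, $m = 1000$ with three
  QTLs planted within a few cM on chromosome 3B at $h^2 = 0.6$; planted
  markers whose realized share of trait variance is at least 10% must be
  detected in at least 80% of cases, and the resulting hotspot must contain
  the true position in at least 90% of replicates with all three MTAs
  found.

## Known limitations

* The overview index is evaluated on an integer-cM grid; sub-cM structure
  is smoothed over, and peaks at chromosome ends lose Gaussian mass.
* P3D holds variance components fixed across markers; for markers with
  very large effects the exact per-marker REML (available via
  `p3d = FALSE`) gives slightly different p-values.
* The per-environment BLUP / across-year mean pathway ignores
  genotype-by-year interaction; a multi-environment fit is out of scope.
* Duplicate-pattern QC keeps the first marker by input order; permuting
  input order changes which representative survives (never how many).
* The differentiation classifier reads frequencies at face value; it
  applies no sampling-error correction, matching its role as a descriptive
  screen rather than a formal selection test.
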