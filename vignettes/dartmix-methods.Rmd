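---
title: "Models and methods behind dartmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dartmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dartmix analyses dominant marker panels — loci scored as band present (1),
absent (0) or missing (?) by hybridization platforms such as Diversity
Arrays Technology (DArT) — through the classic diversity workflow: marker
informativeness, similarity-based ordination and trees, model-based
admixture clustering with delta-K model selection, variance partitioning,
and mixed-model trait–marker association. This vignette states the models,
the assumptions behind them, the numerical choices, and what the simulated
test bed does and does not establish.

## The data model

The central object is a `DartSet`, a `SummarizedExperiment` with a ternary
`calls` assay (markers in rows, genotypes in columns) and an optional
`intensity` assay holding the continuous hybridization level behind each
call. A dominant marker cannot distinguish the heterozygote from the
band-present homozygote, so every method in the package works directly on
the band state rather than on inferred allele dosages. Per-marker missing
fractions are computed at construction; markers above the cap (default
0.28, the upper end of what a well-behaved DArT panel shows) are flagged
and optionally dropped. Identifier matching between call, intensity and
trait tables is by id, case-sensitively, never by row order.

## Marker informativeness

For band-present frequency $p$ over non-missing calls, the polymorphic
information content is $\mathrm{PIC} = 1 - p^2 - (1-p)^2$, applied
directly to the dominant score. No dominant-to-allelic correction (such as
estimating the recessive allele frequency by a square root) is attempted:
the band state is the observable, and correcting it would change the
statistic silently. The intensity-based quality $Q$ is the one-way ANOVA
$R^2$ of the hybridization level against the present/absent call, computed
with population ($1/n$) variances so that $Q \in [0, 1]$ exactly;
single-call clusters are allowed, empty clusters or zero total variance
leave $Q$ undefined.

## Similarity, ordination, trees

Jaccard similarity counts only informative states:
$s = n_{11}/(n_{11} + n_{10} + n_{01})$, with joint absences excluded from
numerator and denominator, and markers missing in either genotype removed
pairwise (pairwise deletion maximises data use; the effective marker count
per pair is reported). A pair with a zero denominator — both genotypes
band-free over their shared observed loci — is undefined and errors by
default; `zeroDenominator = "one"` treats such identical empty profiles as
similarity 1, the coherent limit, which is needed for boundary
constructions such as a fully band-absent population. Distances are
$d = 1 - s$.

Principal coordinate analysis is classical metric scaling. Negative
eigenvalues (expected, since Jaccard distances are generally not
Euclidean) are reported but never used for coordinates, and no
Cailliez/Lingoes correction is applied — the per-axis variance shares are
relative to the positive eigenvalue mass only. Trees are Saitou–Nei
neighbour joining (via ape), exact on additive metrics; negative branch
lengths on non-additive input are clamped to zero with a message, which
can be disabled.

## The admixture model

Band states are modelled as haploid Bernoulli observations:

$$X_{il} \mid z_{il} \sim \mathrm{Bernoulli}(p_{z_{il},l}), \quad
  z_{il} \mid q_i \sim \mathrm{Categorical}(q_i), \quad
  q_i \sim \mathrm{Dirichlet}(\alpha \mathbf{1}_K), \quad
  p_{kl} \sim \mathrm{Beta}(\lambda, \lambda).$$

This is the major modelling simplification relative to a full diploid
admixture model: dominant scores carry no dosage information, so treating
each band state as one draw from the cluster's band frequency keeps every
conditional conjugate and the Gibbs sweep exact. Missing cells are skipped
in all likelihood terms. Defaults are $\alpha = 1/K$ and $\lambda = 1$; a
"correlated frequencies" alternative centres each locus prior on the
observed overall band frequency with drift parameter $F$
(an empirical-Bayes hierarchical Beta prior), since practice varies
between the two prior families.

The sampler is compiled code driven by R's RNG, so a `set.seed()` call
fully determines a chain. Within-chain label switching is handled by
greedily aligning each post-burn-in sweep's $Q$ columns to the running
posterior mean before averaging; across replicate chains, labels are
aligned by the same greedy matching (`alignClusters`). The
model-comparison quantity is
$\ln P(D) \approx \bar{\ell} - \mathrm{Var}(\ell)/2$ over the per-sweep
observed-data log-likelihood $\ell$ — the estimator the delta-K method
expects — rather than a raw harmonic mean, which is numerically unstable.

Delta-K uses the means and standard deviations of $\ln P(D)$ over
replicate chains per $K$: $L'(K) = L(K) - L(K-1)$,
$L''(K) = L'(K+1) - L'(K)$, $\Delta K = |L''(K)| / S[L(K)]$, defined only
for interior $K$ with at least two replicates and positive SD; the best
$K$ is the argmax. Five replicates per $K$ is the default. Full-scale
MCMC settings (burn-in 50000, 100000 retained sweeps, $K$ up to 15)
are the defaults of `fitAdmixture`; the pipeline exposes them so that
desk-scale analyses can run shorter chains. Between-cluster divergence is
the net squared difference of band-frequency vectors,
$\delta_{ab} = \tfrac{1}{L}\sum_l (p_{al} - p_{bl})^2$, fed to neighbour
joining for the population tree. Hard assignments take the argmax of each
genotype's admixture row, ties to the lowest index.

## Variance partitioning and diversity

AMOVA uses the squared-distance sums of squares
($SS_\mathrm{total} = \sum_{i<j} d_{ij}^2 / n$, within-population terms
scaled by population size), with $V_b = MS_\mathrm{within}$ and
$V_a = (MS_\mathrm{among} - MS_\mathrm{within})/n_0$. Significance is by
label permutation with the $(b+1)/(m+1)$ estimator, which cannot return a
zero p-value. Pairwise $\Phi_{st} = V_a/(V_a + V_b)$ is computed on each
population pair's union; negative raw values (sampling noise around zero
differentiation) are clamped to 0 for reporting with the raw value
retained. The package accepts any population assignment — model-based
hard assignments or an external file — since assignments from different
upstream analyses (ordination-derived versus model-based groupings) are
used interchangeably in this literature without a canonical resolution.

Shannon diversity per population is the sum over loci of the binary
entropy of the within-population band frequency (non-missing calls only,
$0\ln 0 \equiv 0$). This per-locus reading is a deliberate, testable
choice: it is additive over loci, bounded by $L\ln 2$, and supports the
Hutcheson-style variance
$\sum_l \{[p(\ln p)^2 + q(\ln q)^2] - [p\ln p + q\ln q]^2\}/N_l +
1/(2N_l^2)$ ("Bowman's method"), plus a bootstrap variance over genotype
resamples within the population. Published per-population values computed
with other tools on other definitions are not directly comparable, and the
package makes no claim of matching any specific historical table. The
t-test between two populations uses
$t = (H'_1 - H'_2)/\sqrt{V_1 + V_2}$ with Hutcheson degrees of freedom.

## Trait–marker association

Relative kinship is identity-by-state centred by the mean off-diagonal
similarity, truncated at zero, diagonal 1. The mixed model per trait is
$y = X\beta + u + e$, $u \sim N(0, \sigma_g^2 K_r)$, with
$X = [\mathbf{1}, Q_{1..K-1}]$ (the last admixture column is dropped:
rows of $Q$ sum to one). Variance components are estimated once per trait
by REML through a single spectral decomposition of $K_r$ and reused for
every marker (the P3D/EMMA strategy); each marker then enters as a 0/1
fixed covariate tested by GLS F-test, with missing calls mean-imputed for
the design matrix only — never for diversity statistics. Marker $R^2$ is
the incremental explained proportion on the whitened scale, invariant to
affine rescaling of the trait. With $K_r = I$ and no $Q$ the scan is
algebraically ordinary least squares, which the tests verify to 1e-8.
Under a structured null the scan is mildly conservative (empirical type-I
error a little under the nominal 0.05) — the familiar behaviour of Q+K
models whose kinship is estimated from the tested markers themselves.

The permutation scans (GLM with continuous $Q$ covariates, SA with hard
population membership) permute raw trait values across genotypes with
covariates fixed and adjust each marker by the max-over-markers F
distribution, again with the $(b+1)/(m+1)$ correction. Permuting raw
traits rather than residuals is slightly anti-conservative under strong
structure; it is retained as the straightforward reading of standard
practice and noted here. The two-stage report ranks markers significant
in the MLM at $\alpha_1 = 0.05$ and flags them confirmed when the GLM or
SA adjusted p also reaches $\alpha_1$; counts are reported at 0.05 and
0.01. No additional false-discovery layer is applied on top — the
two-stage rule *is* the multiple-testing stance.

## Trait statistics

Coefficients of variation are SD/mean (flagged above 0.5); correlation
counts use the exact t transform of the Pearson r with pairwise-complete
n. The rotated PCA retains correlation-matrix components with eigenvalue
strictly greater than 1 (so two exactly uncorrelated standardised traits
retain nothing — the boundary is deliberate and warned about), varimax
with Kaiser row normalization rotates the retained loadings, and each
trait is assigned to its largest absolute rotated loading. Genotype
clustering standardises traits, takes Pearson similarity between trait
profiles, and applies unweighted average linkage (UPGMA), the common
default of spreadsheet AHC tools; cutting at similarity levels 0.75 and
0.9 yields nested groups by construction.

## The synthetic-data generator

The generator is the package's test bed and emulates the cohort design the
package targets: 111 genotypes, 191 polymorphic dominant loci with
per-marker missing rates uniform on [0, 0.28], 10 latent clusters, and 38
traits. Loci follow the Balding–Nichols construction — ancestral frequency
$p_l \sim U(0.1, 0.9)$, cluster frequency
$p_{kl} \sim \mathrm{Beta}(p_l(1-F)/F, (1-p_l)(1-F)/F)$ with drift
$F = 0.2$ by default — with Dirichlet($\alpha = 0.2$) admixture, Bernoulli
band calls, and intensities $N(0, 0.25^2)$ / $N(1, 0.25^2)$ for
absent/present (giving marker quality around 0.8, a high-quality assay
regime). Phenotypes are marker effects plus a population effect plus
Gaussian noise, with traits in a block sharing causal markers to create
correlated trait families; effect sizes default to a regime in which
single-marker $R^2$ lands in the 0.05–0.25 range typical of small
association panels, since no ground-truth effect sizes exist for the real
cohort. Missingness is injected completely at random per marker; there is
no genotype-level missingness structure, no linkage, and no selection or
demography beyond the single divergence parameter — passing tests
therefore establish correctness of the estimators under this generative
model, not robustness to LD, genotyping batch effects or informative
missingness in real panels.

## Problem sizes and numerical choices

The test-suite runs its recovery experiment at 90 genotypes, 150 loci,
$K_{true} = 3$, $F = 0.3$, five replicate chains per $K \in 2..5$ with
2000 burn-in and 5000 retained sweeps — small enough to run routinely,
large enough that delta-K selects the true $K$ and posterior admixture
recovers truth to a mean absolute error under 0.1. Calibration checks use
roughly 2000–3000 marker tests. Symmetry is validated at 1e-10 when
writing square matrices; PCoA eigenvalues below 1e-9 count as
non-positive; Newick branch lengths are written at 6 significant digits
and square matrices at 12. Ties are broken deterministically everywhere
(lowest index; lexicographic pair choice in NJ via ape) so that equal
seeds give bit-identical outputs, which the pipeline test asserts.

## Known limitations

The admixture model is haploid-Bernoulli, not a full dominant-diploid
likelihood; its $\ln P(D)$ is an approximation adequate for delta-K
comparison rather than an exact marginal likelihood. AMOVA is
single-level (no region > population hierarchy). The permutation scans
require complete trait vectors. The Shannon index is a per-locus
definition, deliberately not comparable to collection-level definitions.
Real DArT array formats, call-rate/reproducibility scoring from array
replicates, and linkage-map integration are out of scope; map positions
for markers, where available, are pass-through annotations.
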