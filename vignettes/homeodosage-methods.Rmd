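---
title: "Models and methods behind homeodosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homeodosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`homeodosage` analyses how the three homoeologous copies of a gene are
dosed against each other in an allohexaploid population, and how that
dosage is wired genetically. This vignette is the package's own account
of its models: what each estimator assumes, which tunable parameters
matter, what the synthetic cohort generator does and does not emulate,
and the numerical choices that a maintainer would otherwise have to
reverse-engineer.

## The synthetic cohort generator

Every downstream method is validated against cohorts from
`simulate_cohort()`, which emulates a diploidized allohexaploid panel of
inbred accessions. Its defaults are the package's reference study
conditions; they were fixed once, on biological grounds, and the test
suite runs against them.

**Genotypes.** Three subgenomes (A, B, D) with a configurable number of
chromosomes; SNPs every 10 kb with allele frequencies uniform on
[0.05, 0.5]. Haplotypes come from a latent Gaussian AR(1) process along
each chromosome, thresholded at the allele-frequency quantile, giving
geometrically decaying linkage disequilibrium with a default length
scale of 1 Mb (`ld_decay_bp`) — selfing crop panels show LD over
megabases, and without it subgenome relationship matrices of unrelated
individuals degenerate towards the identity and cannot be told apart.
Population structure defaults to a 3-pool admixture with Balding–Nichols
allele-frequency drift (F = 0.1), so that covariate correction and
inflation diagnostics face a realistic confounder. Accessions are fully
inbred (dosages 0/2); thresholding preserves each SNP's marginal allele
frequency exactly.

**Expression.** Each homoeolog group draws a baseline log2 TPM (mean 3,
sd 1) shared by its members up to a small deviation
(`baseline_member_sd = 0.25`): homoeologs descend from one ancestral
gene and tend to similar abundance. On the log2 scale the model adds
planted *cis* effects (per-gene probability 0.5, effect sd 0.6 per
dosage unit, SNP within ±1 Mb), *trans* effects (per-triplet probability
0.3, shared across members with probability 0.5, SNP on another
chromosome), hidden factors (2 factors, loading sd 0.2) and noise
(sd 0.3); TPM is the exponential. Effects act multiplicatively on TPM,
matching the log2 analysis scale.

**Silencing and compensation.** A fraction of triplets
(`silencing_prob`, default 0.1) carries a silencing allele on one random
member: a dedicated cis SNP whose homozygous class multiplies the
member's TPM by `silencing_depth` (default 0.02, i.e. ~2% residual
output), at population frequency `silencing_freq` (default 0.3). A
fraction `compensation` (c, default 0.7) of the lost TPM is redistributed
equally to the surviving members. With equal baselines this makes the
expected total-expression ratio between silenced and unsilenced
accessions 1 − (1 − c)/3: exactly 2/3 at c = 0 and 1 at c = 1, which is
what `compensation_analysis()` estimates.

**Traits.** Each trait is a linear combination of the true
silencing burden (count of silenced homoeolog copies per accession),
optional direct SNP effects, and Gaussian noise.

**What the generator does not emulate:** read-level noise and mapping
bias, recombination maps calibrated to a real genome, multi-tissue
expression, and epistasis. Passing tests therefore demonstrate that the
estimators recover the generative model they assume — not that real
wheat data satisfy that model.

### Isolation in recovery experiments

The planted-signal recovery tests (compensation ratios, silencing
recall) switch the *competing* variance sources off — no cis/trans
effects, no hidden factors, matched member baselines — so that the
planted mechanism is the only systematic signal. With the full
architecture on, silenced-pair correlations are diluted by independent
regulatory variance and recall drops to roughly 50–88%; that dilution
measures the cohort's heterogeneity, not the detector. The same
convention is used for the false-discovery experiment (below).

## Normalization and the eQTL phenotype

Transcripts are kept when expressed (TPM > 0.5) in at least 3 accessions
with sd > 0.5. Values become log2(1 + TPM) and are quantile-normalized
across accessions (each accession's order statistics replaced by the
cross-accession means; ties get the mean of the quantiles they span, via
limma). Hidden confounders are removed by regressing each transcript on
the top-k principal factors of the accession × transcript matrix
(default k = 15, configurable; k is not critical for the synthetic
cohorts, which plant few factors). This PCA residualization is the
package's deterministic latent-factor correction — it plays the role
that PEER-style factor models play in population transcriptomics, with
exactly reproducible output. Residuals are exactly mean-zero and
orthogonal to the removed factors.

One caveat found while validating: quantile normalization across only a
few hundred genes lets a very large planted effect in one gene leak into
the values of other genes in the same accession (the per-accession
quantile map is too coarse). At transcriptome scale (tens of thousands
of transcripts) the effect is negligible. The scan-calibration
experiments therefore plant phenotypes directly on the log2 scale.

## Variance partitioning

GRMs are built from per-SNP standardized dosages (empirical sample
variance, missing to the mean), thinned to one SNP per 100-kb window to
neutralize SNP-density differences between subgenomes. Empirical
standardization is used rather than 2p(1−p) because the panel is inbred
(0/2 coding); the empirical form is correct for either coding.

`reml_varcomp()` maximizes the restricted likelihood of
y = Σ_c u_c + e with Var(y) = Σ σ²_c G_c + σ²_e I by
average-information REML: an EM first step, then AI updates with step
halving when a proposal leaves the parameter space, projection of
stragglers onto a small positive floor (1e-8 × var(y)), and an
active-set rule that holds components pinned at the floor with negative
score fixed — without it the EM fallback crawls for hundreds of
iterations when the GRMs are nearly collinear. Convergence is an
absolute restricted log-likelihood change below 1e-8 (default), at most
200 iterations; a singular variance structure returns a non-converged
result rather than an error. Fractions are invariant to positive
rescaling of y. A Haseman–Elston regression (`he_varcomp()`) is provided
as an independent moment-based cross-check; it is unconstrained and
noisier, and is used in tests only.

cis-genic/trans-genic windows anchor at the gene midpoint, the cis
window (±1 Mb) is boundary-inclusive, and SNPs in the 1–5 Mb annulus are
excluded from both components. Recovery experiments simulate phenotypes
from the same (thinned) SNP sets used to build the fitted GRMs, so that
Var(y) matches the model exactly and the experiment measures estimator
quality rather than tagging attenuation.

## Association scanning and eQTL calling

The scan is ordinary least squares of each residualized transcript on
each dosage with the top 3 genotype principal components as covariates,
computed by projecting both sides onto the orthogonal complement of the
covariates (Frisch–Waugh) and forming all transcript × SNP slopes by
matrix products. Missing dosages are mean-imputed for the scan only;
monomorphic SNPs are skipped. BH q-values are computed over the full
scan jointly; FDR < 1e-5 defines significance.

Significant SNPs merge into an eQTL interval when LD r² > 0.2 **and**
distance < 100 kb (read conjunctively), closed under single linkage;
the lead SNP is the minimum p, ties broken by smaller position then
snp_id. Leads within ±1 Mb of the gene are cis; a different chromosome
is trans (the conservative definition); same-chromosome leads beyond
1 Mb are "other" and excluded from trans analyses.

Permutation calibration shuffles accession labels of the whole residual
matrix (preserving the expression correlation structure), repeats the
scan, and reports mean permuted count / observed count — the
false-positive proportion. The genomic inflation factor is the median
1-df chi-square quantile of a gene's p-values divided by 0.4549.

In the false-discovery recovery experiment, a discovery is scored true
when its SNP tags (r² > 0.05) a planted causal SNP of that gene: a SNP
in LD with a causal variant genuinely violates the null hypothesis the
p-value tests, and the LD-merging step treats it as the same locus.

## SMR and HEIDI

At the top eQTL SNP, b_xy = b_GWAS/b_eQTL estimates the expression →
trait effect, and T_SMR = z²_GWAS z²_eQTL / (z²_GWAS + z²_eQTL) is
referred to χ²₁. T_SMR is bounded by both z² values, and the test is
invariant to simultaneous allele flips. Instruments require an eQTL p
below 5e-8 and allele-frequency agreement within 0.2 between the two
summary sets; candidate reporting follows SMR p < 1e-4 with HEIDI pass
at p ≥ 0.05, cis window 10 Mb and trans window 5 Mb.

HEIDI asks whether SNPs in LD with the instrument give the same b_xy.
Eligible SNPs have r² to the top SNP in (0.05, 0.9), at most 20 ranked
by eQTL significance, at least 3 to test. The covariance of
d_i = b_xy(i) − b_xy(top) uses the first-order delta-method
approximation cov(b_xy,i, b_xy,j) ≈ b_xy,i b_xy,j (r_ij/(z_y,i z_y,j) +
r_ij/(z_x,i z_x,j)). The statistic is the whitened quadratic form
d′V_d⁻¹d (eigenvalue decomposition, components below 1e-8 of the top
eigenvalue dropped) on rank(V_d) degrees of freedom — the d_i share the
top SNP and are strongly correlated, so a sum of marginally standardized
d²_i is not chi-square calibrated, while the whitened form holds its
size under the single-causal-variant null. Under pleiotropy (one variant
driving both expression and trait) rejection at 0.05 stays near nominal;
with two causal variants at r² = 0.5 and opposite-sign effects the b_xy
profile is heterogeneous and the test rejects in a majority of
replicates, provided the instrument is strong — the validation scenarios
use cohorts of 1000 with |z| of the causal associations around 6–9,
mirroring SMR practice of instrumenting genome-wide-significant hits.

## Networks and trait prediction

Regulatory edges connect a cis-eGene to a trans-eGene sharing a
significant SNP when their residual |SCC| exceeds 0.6, signed by the
SCC. Module detection uses deterministic fast-greedy modularity followed
by a deterministic single-node local-moving refinement (the plain
agglomerative pass can end a few hundredths below the optimum on small
graphs); Louvain is available behind a flag.

Ridge prediction (`glmnet`, alpha = 0) uses 10 outer folds with the
penalty chosen by 5-fold inner cross-validation over 50 lambdas
log-spaced on [1e-3, 1e3], predictors centered and standardized within
training folds. The intercept is fixed at the cohort trait mean rather
than refit per training fold: a refit intercept equals the training-fold
mean, which is anti-correlated with the held-out observations by
construction, and that fold-mean artifact biases the null prediction
accuracy to about −0.15 at n = 200 — an uninformative gene set should
score zero. Accuracy is the Spearman correlation between concatenated
held-out predictions and observations, compared against random gene sets
of equal size.

## Numerical choices and degenerate inputs

- Spearman correlations use mid-ranks for ties and return missing for
  constant vectors or fewer than 3 complete pairs; LD is computed over
  pairwise-complete accessions with no imputation.
- The sample (n−1) standard deviation is used in the low-expression
  rule (TPM < 3 and TPM < mean − sd), on the raw TPM scale.
- Heterozygotes in the inbred panel count as dosage 1 and toward the
  heterozygosity filter (default cap 3%).
- Duplets are evaluated by the strong-threshold rule only and reported
  separately from triplets; the two-partner rule is undefined for them.
- Empty cis-genic SNP sets fall back to a single-component fit with the
  cis fraction recorded as 0; windows with no SNPs contribute 0 to
  diversity, and windows whose SNPs are all uncallable return missing.
- All stochastic steps (cohort generation, permutations, random-pair and
  random-gene-set nulls) take explicit seeds; the generator derives
  per-stage sub-seeds so each stage is reproducible in isolation, and
  identical configurations produce byte-identical output files.

## Problem sizes used in validation

The test suite exercises cohorts of 60–200 accessions, up to 500
triplets, and up to ~20,000 SNPs; the REML recovery uses 50 phenotypes
on a 20,000-SNP hexaploid layout; SMR/HEIDI discrimination uses 100
replicates of 20-SNP regions with 1000 individuals; ridge prediction
uses 200 accessions × 300 genes with 100-set nulls. These sizes were
chosen so the full suite characterizes every estimator on a single CPU
in a few minutes while keeping each experiment's Monte-Carlo error well
inside the asserted margins.

## Known limitations

- The PCA residualization is a deterministic surrogate for richer
  latent-factor models; it removes linear factor structure only.
- The scan is fixed-effects OLS + PCs; a mixed-model scan would give
  better calibration under extreme, unmodelled relatedness.
- Standard errors of variance components are not computed.
- Quantile normalization is the standard variant with mid-tie handling;
  "robust" refinements differing in tail treatment would change little
  at transcriptome scale but are not implemented.
- The trans-eQTL definition is conservative (different chromosome);
  same-chromosome distal regulation lands in the "other" class.
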