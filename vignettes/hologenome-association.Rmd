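---
title: "Hologenome-wide association: models, kernels and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hologenome-wide association: models, kernels and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hologwas)
```

## The models

`hologwas` tests per-SNP fixed effects on a quantitative trait under four
linear mixed models that differ only in their random-effect structure.
Writing $y$ for the $n$-vector of trait values, $X$ for the fixed-effect
design (intercept, optional covariates and genotype principal
components) and $z_j$ for the dosage vector of SNP $j$:

$$y = X\beta + z_j\gamma_j + u + e, \qquad e \sim N(0, \sigma_e^2 I),$$

with the polygenic term $u$ depending on the model:

* **GWAS** — $u = g$, $g \sim N(0, G\sigma_g^2)$, where
  $G = X_S X_S'/(q-1)$ is the genomic relationship matrix built from the
  standardized $n \times q$ genotype matrix $X_S$;
* **M-GWAS** — $u = m$, $m \sim N(0, M\sigma_m^2)$, where $M = RR'/p$ is
  the microbial relationship matrix built from the $n \times p$ matrix
  $R$ of log-transformed OTU relative abundances;
* **HWAS-CG** — $u = g + m + h_c$, adding a genome–microbiome
  *covariance* kernel $h_c = L_M L_G' + (L_M L_G')'$, with $L_G, L_M$
  the lower Cholesky factors of $G$ and $M$;
* **HWAS-H** — $u = g + m + h$, adding the Hadamard *interaction* kernel
  $h_{hp} = G \circ M$ (entrywise product).

The null hypothesis $\gamma_j = 0$ is assessed with the Wald statistic
$W = \hat\gamma_j^2 / \mathrm{var}(\hat\gamma_j)$ referred to
$\chi^2_1$.

### Assumptions

The models assume an additive polygenic architecture on the genotype
side, a linear effect of log relative abundances on the microbial side,
Gaussian residuals, and — for the scan — that the variance components
estimated once under the no-SNP null describe the covariance of $y$ well
enough for every SNP (the EMMAX/P3D approximation, discussed below).
Relative abundances are compositional; the log transform plus
column-centering treats them as a Euclidean embedding, which is the
convention the microbial-kernel construction expects, not a full
compositional-data treatment.

## Kernel constructions

**Genotype standardization.** Column $j$ of $X_S$ is
$(x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$ with $p_j$ the alt-allele frequency
computed from non-missing calls (VanRaden-style; unit variance under
Hardy–Weinberg equilibrium). Because no formula is canonical for
"standardized" we fixed the observed-frequency HWE form and expose the
frequencies on the object so users can audit them. Missing dosages are
kept missing in storage and mean-imputed only at standardization/test
time, so raw data are never silently modified.

**OTU log transform.** Zeros are ubiquitous in relative-abundance
tables, and $\log 0$ is undefined, so a pseudocount is required; the
default (`"auto"`) is half the smallest nonzero relative abundance in
the table, a standard heuristic that keeps the imputed values below
everything observed. Columns are mean-centered by default: $RR'$ on
uncentered log abundances is dominated by the compositional mean, while
the centered version plays the covariance-like role the model intends.
Both choices are flags.

**The covariance kernel `h_c`.** The symmetrized product of Cholesky
factors is *not* in general positive semi-definite — it is a
cross-covariance term, and its REML coefficient is correspondingly
treated as an unconstrained covariance parameter, while all other
coefficients are constrained nonnegative. Cholesky factorization
requires strictly positive-definite inputs, so rank-deficient kernels
are jittered ($\varepsilon \cdot \overline{\mathrm{diag}}$ added to the
diagonal, $\varepsilon$ escalating tenfold from $10^{-8}$ to at most
$10^{-2}$); any jitter applied is recorded in the kernel's metadata.
The operand order ($L_M$ on the left) follows the defining equation
literally; since the result is symmetrized the choice only affects
intermediate values.

**The Hadamard kernel `h_hp`.** Entrywise $G \circ M$; positive
semi-definite whenever both factors are (Schur product theorem), so its
coefficient stays constrained. A practical consequence worth knowing:
off-diagonal entries of $G$ and $M$ are small in magnitude for unrelated
individuals, so their product is nearly zero and $G \circ M$ is close to
a diagonal matrix. The interaction variance is therefore weakly
identified against the residual at moderate sample sizes — point
estimates of $\sigma^2_{h}$ and $\sigma^2_e$ can trade off within a
replicate while their sum, and all p-values, stay stable. The recovery
experiments below quantify this.

Kernels are not rescaled to unit mean diagonal by default (no such
normalization is part of the definitions); a flag-level rescaling exists
for cross-kernel comparability, and the *simulator* does rescale its
generating kernels so that variance fractions are interpretable as
shares of phenotypic variance.

## REML and the fast scan

Variance components maximize the restricted likelihood of
$y \sim N(X\beta,\ \sum_k \sigma_k K_k + \sigma_e^2 I)$ via
average-information (AI) updates with an EM fallback whenever an AI step
fails to improve the objective, starting from equal shares of the
phenotypic variance (covariance terms at zero). Parameters pinned at the
zero boundary with negative scores are frozen per iteration (active-set
projection); convergence is $|\Delta \ell_R| < 10^{-6}$ or 100
iterations. If the converged $\hat V$ is not positive definite — possible
only through the unconstrained `h_c` coefficient — that coefficient is
shrunk toward zero until the smallest eigenvalue clears
$10^{-8} \cdot \overline{\mathrm{diag}}(\hat V)$.

The scan eigendecomposes the *fitted* $\hat V = UDU'$ once per
trait-model pair and whitens: $y^* = D^{-1/2}U'y$, likewise $X$ and each
dosage column. Generalized least squares under $\hat V$ is then ordinary
least squares on whitened data. With several kernels no rotation can
diagonalize each kernel separately, so decomposing the fitted $\hat V$
is the only exact single-rotation scheme. Standard errors come from the
whitened design alone ($\mathrm{se}^2 = 1/(s^{*\prime} M_{X^*} s^*)$,
unit whitened residual variance): $\hat V$ already carries the full
phenotypic covariance, and this known-variance form is what makes
$W \sim \chi^2_1$ exact given $\hat V$ — re-estimating a residual scale
per SNP would double-count. Degenerate (constant) SNP columns are
flagged and reported with missing p-values rather than failing the scan.

**The P3D approximation.** Variance components are estimated once under
the null and reused for every SNP. The exact alternative
(`exact_per_snp = TRUE`) re-runs REML per SNP with the SNP as a fixed
covariate. The two agree closely across the bulk of a scan (median
$|\Delta(-\log_{10}p)| < 0.02$ in our checks at $n = 150$, $q = 300$)
and preserve ranking essentially perfectly, but for the handful of most
strongly (chance-)associated SNPs the per-SNP refit visibly moves the
variance components — an $O(1/n)$ effect that vanishes asymptotically
but is material in small samples. A uniform closeness bound is therefore
not a property small-sample users should expect; the test suite checks
bulk agreement and rank preservation instead, and verifies the fixed-V
scan itself against explicit-inverse GLS oracles to $10^{-8}$.

## Significance regimes

Four regimes are summarized per scan: the arbitrary threshold
$p \le 0.05$ (boundary inclusive; the descriptive convention is fixed
once and logged), Benjamini–Hochberg FDR (via `stats::p.adjust`),
Bonferroni $\alpha/n_\mathrm{tested}$, and a genome-wide significance
threshold (GWST). The GWST is implemented as a seeded permutation
family-wise threshold: whitened trait residuals are permuted
(Freedman–Lane style, re-projected off the covariates), the fast scan is
re-run per permutation, and the empirical $\alpha$-quantile of the
minimum-p distribution is the cutoff (default $T = 1000$; a fixed
user-supplied threshold mode also exists). A permutation definition was
chosen because it is the standard family-wise-calibrated construction
that is strictly more stringent than Bonferroni in the presence of
dependence, matching how GWST is used alongside the other regimes; the
exact construction used elsewhere in the literature varies. By
construction the regimes nest on any scan:
BC-significant ⊆ BH-significant ⊆ arbitrary-significant at equal
$\alpha$.

Genomic inflation is $\lambda = \mathrm{median}(W)/0.4549$ (the
$\chi^2_1$ median); $\lambda \approx 1$ on null data indicates a
calibrated scan.

## SNP-to-gene annotation

A SNP is treated as a point and annotated with every gene intersecting
the window $[\mathrm{pos} - w, \mathrm{pos} + w]$ (default
$w = 100$ kb), classified as `within_gene` (SNP inside the gene,
distance 0), `within_window` (gene entirely inside the window) or
`overlaps_window` (partial intersection). Boundaries are inclusive: a
gap of exactly $w$ still reports. Strand is ignored — upstream and
downstream are treated symmetrically. Nearest-gene reporting breaks ties
deterministically by distance, then smaller start coordinate, then
lexicographic gene ID; the window criteria are phrased gene-side in
common usage, and the SNP-centered reading implemented here is the
symmetric interpretation, documented so results are reproducible.

## The synthetic-data generator

The generator emulates the post-QC data the models consume:

* **Genotypes** — per SNP, MAF $\sim U(0.05, 0.5)$ and dosages
  $\mathrm{Bin}(2, \mathrm{MAF})$ i.i.d. across individuals
  (Hardy–Weinberg, linkage equilibrium); finite-sample monomorphic
  columns are redrawn so standardization is always defined.
* **Microbiome** — logistic-normal compositions: latent log abundances
  $L = \sqrt{f}\,\mathrm{scale}(X_S B) + \sqrt{1-f}\,E$ with $B, E$
  standard normal and $f$ the genotype-driven share (default 0.3),
  mapped through a per-row softmax. $f > 0$ induces the
  genome–microbiome covariance the hologenome kernels exist to model.
* **Phenotypes** — $y = X\beta + \sum_c z_c\gamma_c + u$ with
  $u \sim N(0, V_\mathrm{true})$ drawn through the Cholesky factor of
  $V_\mathrm{true} = \sum_k f_k K_k + f_e I$; generating kernels are
  rescaled to mean diagonal 1 so the $f_k$ are variance shares. Default
  fractions are genomic 0.3, microbial 0.2, hologenome 0.1, residual
  0.4 — a moderately heritable production trait with substantial
  microbiability, the regime these models target. For the
  covariance-kernel architecture the generator adds
  $\rho_{gm} h_c$ and halves $\rho_{gm}$ (logged) if it breaks positive
  definiteness, which keeps the draw well-defined for any requested
  covariance.

What the generator does **not** emulate: linkage disequilibrium and
population structure on the genotype side, phylogenetic or
count-sampling structure on the microbiome side, non-Gaussian traits.
Passing calibration and recovery tests on these data therefore
demonstrates correctness of the estimators under the generating model,
not robustness to the full messiness of real livestock data.

## Experiment scale and numerical choices

The packaged experiments run at desk scale, chosen so the whole suite
completes in minutes on one core while keeping Monte Carlo error small
relative to the tolerances checked: null calibration uses 100 replicate
scans per model at $n = 300$, $q = 2000$, $p = 200$ (pooled rejection
rate at $\alpha = 0.05$ checked against its 95% binomial interval; mean
$\lambda$ within $[0.85, 1.15]$), and variance-fraction recovery uses
50 replicates at $n = 500$ against truth $(0.3, 0.2, 0.1, 0.4)$ with a
$\pm 0.1$ mean-error band — wide enough to absorb the
Hadamard-vs-residual identifiability trade-off described above, tight
enough to catch scale errors in any kernel. Full-size runs are config
changes only.

Numerical details fixed by design: QC comparisons are inclusive on the
keep side; the OTU "prevalence" filter counts nonzero entries (an
abundance-threshold mode is provided, since prevalence- and
abundance-based readings of such filters both occur in practice);
kernels are symmetrized exactly ($\tfrac12(K + K')$) on construction;
eigenvector sign follows the largest-magnitude-loading-positive
convention; permutation thresholds take the $\lfloor \alpha T \rfloor$-th
smallest minimum p-value; all seeds derive from a single master seed via
a fixed linear-congruential map, so every pipeline product is a pure
function of (config, seed).

## Known limitations

* The Hadamard interaction variance is weakly identified at
  $n \lesssim 500$ (near-diagonal kernel); interpret its point estimate
  with its replicate spread, not alone.
* The covariance coefficient on `h_c` makes $\hat V$ indefinite in
  principle; the shrink-to-PD safeguard biases extreme negative
  covariances toward zero rather than failing.
* P3D p-values for the strongest hits are mildly conservative relative
  to per-SNP REML in small samples (see above); re-check top hits with
  `exact_per_snp = TRUE` when $n$ is small.
* Derived traits assume nonzero daily gain; feed conversion is
  undefined otherwise and raises an error rather than returning
  infinity.
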