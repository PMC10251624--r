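---
title: "Single-step genomic evaluation and indirect candidate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation and indirect candidate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgblup)
```

## The model

`ssgblup` implements single-step genomic BLUP for a univariate animal
model

$$ y = Xb + W u + e, \qquad u \sim N(0, H\sigma_u^2), \qquad
   e \sim N(0, I\sigma_e^2), $$

where $u$ collects the additive genetic effects of all pedigree animals,
genotyped ($u_g$) and non-genotyped ($u_n$). The inverse covariance
structure combines the sparse pedigree inverse $A^{-1}$ with a genomic
correction on the genotyped block,

$$ H^{-1} = A^{-1} +
   \begin{bmatrix} 0 & 0 \\ 0 & G_C^{-1} - A_{gg}^{-1} \end{bmatrix},
   \qquad G_C = ZBZ' + C, $$

with $Z = M - 2\,\mathbf{1}p'$ the centered allele counts, $B$ the
VanRaden scaling ($B = I(1-w)/k$, $k = 2\sum_i p_i(1-p_i)$, when
$C = wA_{gg}$; $B = I/k$ when $C = \varepsilon I$), and $C$ a
regularization: either a small ridge $\varepsilon I$ or the residual
polygenic (RPG) form $wA_{gg}$, in which a proportion $w$ of the
additive variance is not attributed to markers.

Two equivalent formulations of the mixed model equations are provided:

* **ssGTBLUP** keeps the equations of the classical single-step system
  and applies $G_C^{-1}$ through the Woodbury identity
  $G_C^{-1} = C^{-1} - C^{-1}ZK^{-1}Z'C^{-1}$ with
  $K = Z'C^{-1}Z + B^{-1}$, an $m \times m$ matrix factored once
  ($K = LL'$). The *component-wise* strategy nests products around two
  triangular solves so only $L$ and the packed genotypes are needed; the
  *original* strategy precomputes $T = L^{-1}Z'C^{-1}$ and applies
  $(C^{-1} - T'T)$.
* **ssSNPBLUP** appends the $m$ SNP-effect equations explicitly, with
  coupling blocks $-C^{-1}Z\lambda$ and $K\lambda$ on the marker block;
  the $K$ action is computed per iteration as $Z'(C^{-1}(Zv)) + B^{-1}v$
  so $K$ never has to be inverted inside the solver.

Both are solved matrix-free with preconditioned conjugate gradient
(PCG). The preconditioner is a dense Cholesky factor of
$P_{ff} = X'X + \mathrm{diag}(X'X)\cdot 10^{-4}$ on the fixed block and
the coefficient-matrix diagonal on the random blocks; the SNP diagonal
can be the exact $\lambda\,\mathrm{diag}(K)$ or the cheap approximation
$2p_i(1-p_i)n$ scaled by $1/w$ (or $1/\varepsilon$). Convergence is
declared when the relative residual
$C_r = \lVert C_{\mathrm{MME}} s - r \rVert / \lVert r \rVert$
drops below $10^{-7}$. The Lanczos tridiagonal implied by the PCG
scalars yields estimates of the extreme effective eigenvalues of the
preconditioned system, reported as a diagnostic only — the estimator
behind published effective-eigenvalue figures is not specified, so no
numerical agreement is claimed.

A *J-factor* — a fixed covariate equal to $-1$ for genotyped animals and
$-(A_{ng}A_{gg}^{-1}\mathbf{1})_i$ otherwise — absorbs the mean
difference between the pedigree base and the genomic base. Reported
GEBV are $\hat u_i + J_i\hat\mu$ so genotyped and non-genotyped animals
share a base.

## Indirect prediction of selection candidates

A genotyped selection candidate has no own phenotype and no progeny in
the latest evaluation. Its GEBV decomposes as
$\hat u_{j,c} = -\hat\mu + Z_c\hat g + \hat d_c$: the J term, the direct
genomic value, and the candidate's RPG effect. The package computes:

* $\hat g = K^{-1}Z'C^{-1}\hat u_g$ by two triangular solves
  (equivalently $BZ'G_C^{-1}\hat u_g$; the two routes agree to 1e-8 in
  the test suite);
* $\hat d_g = \hat u_g - Z\hat g$ for the evaluation's genotyped
  animals (equal to $wA_{gg}G_C^{-1}\hat u_g$ by the Woodbury identity);
* $\hat d_c = A_{cg}A_{gg}^{-1}\hat d_g$ by two routes that agree to
  1e-8: a dense $A_{gg}$ solve followed by one Colleau full-pedigree
  product, or the sparse ancestor system plus a parent-average sweep.

Four predictors are exposed: **PA** (mean of parent GEBV), **DGV**
($Z_c\hat g$ alone), **REG** ($-\hat\mu + Z_c\hat g + \tilde d_c$ with
the RPG parent average using a regression $\hat d_g = \hat a +
\hat b\hat u_g$ for non-genotyped parents), and **GRV** (the exact
decomposition). Candidate genotypes are always centered with the
*prior evaluation's* allele frequencies, because $\hat g$ lives on that
scale. PA treats an unknown parent as contributing the base mean 0; the
REG recursion likewise scores unknown ancestors 0.

## The synthetic study

`simConfig()`/`simulateStudy()` generate the two-evaluation study: a
discrete-generation pedigree (560 founders, six generations, full-sib
families of two, a final candidate generation of one offspring per
mating, about 3,080 animals), 1,000 unlinked biallelic markers
gene-dropped from founder frequencies drawn uniformly on (0.05, 0.95),
true values $u = Za + d$ with i.i.d. marker effects at variance
$(1-w)\sigma_u^2/k$ and a pedigree-correlated RPG component at
proportion $w = 0.20$, phenotypes at heritability $h^2 = 0.3$ (one
record per non-candidate animal from generation two on), and partial
genotyping: all candidates plus 70% of the three preceding generations,
so the reduced set keeps about four fifths of the genotypes — the
proportion routine full/reduced evaluations operate at. Sizes were
chosen as the desk-scale realization of that design (about 3,000
animals, about 1,500 genotypes); the package solves them in seconds.

Choices worth stating explicitly:

* **No linkage.** Markers are gene-dropped independently. The method's
  algebra does not rely on LD, and unlinked loci keep the moment-based
  checks on the generator exact. Real marker panels carry LD, so
  absolute accuracies here do not transfer to real data; the
  full-versus-indirect comparisons do, because both sides see the same
  genomes.
* **No selection.** Matings are random; the pedigree-vs-genomic base
  difference that the J-factor absorbs is instead induced directly, by
  adding `jfactorShift` (0.3 genetic SD) to the true values of all
  descendants of a designated founder half. This exercises $\hat\mu$
  without bringing selection machinery into scope.
* **Variances are fixed** at $\sigma_u^2 = 1$ so level biases read
  directly in genetic-SD units; the comparison report uses the true
  $\sigma_u$, since no genetic-SD estimator is part of the model.
* **Unknown parents** are base animals everywhere (no genetic groups,
  no metafounders).

## Numerical choices and degenerate inputs

* $K$ is factored once per evaluation; $K^{-1}x$ is always the forward
  solve with $L$ followed by the backward solve with $L'$. A
  non-positive-definite $K$ (duplicated genotypes with a vanishing
  ridge) is reported with advice rather than silently regularized.
* Solves against $A_{gg}$ go through a cached dense Cholesky factor —
  at desk scale this is safer than forming $A_{gg}^{-1}$ sparsely.
* PCG starts from zero for reproducibility; $C_r$ is evaluated every
  iteration (it is free, being the maintained residual norm over the
  right-hand-side norm).
* The stored diagonal of the random block is exact by default,
  including the Woodbury low-rank part of $G_C^{-1} - A_{gg}^{-1}$;
  `omitCorrectionDiag = TRUE` reproduces production set-ups that skip
  those terms.
* Fixed-effect class levels are indexed in sorted label order with the
  first level absorbed, so solution files are byte-reproducible.
* Monomorphic markers are dropped at read time; missing genotype codes
  either fail loudly (default) or are mean-imputed with a warning.
* With observed-frequency centering $Z'\mathbf{1} = 0$, so as
  $w \to 0$ the RPG effects do not vanish but converge to the rank-one
  base term $A_{gg}\mathbf{1}\,(\mathbf{1}'\hat u_g)/
  (\mathbf{1}'A_{gg}\mathbf{1})$ — the common mean the markers cannot
  carry. The test suite pins this limit.

## What the tests do and do not show

The exact-identity and oracle suites (Woodbury products against dense
inverses, backsolving against the dense $BZ'G_C^{-1}$ route, the RPG
identities, pedigree algebra against the tabular relationship matrix,
PCG against direct solves) hold at tolerances of 1e-7 to 1e-12 and
establish the implementation is the algebra it claims to be.

The study-level checks are scale-limited. On the default study the two
formulations agree essentially exactly (correlation and slope 1.000 at
$C_r < 10^{-7}$), and full-versus-reduced GEBV for the animals present
in both evaluations correlate above 0.998. The GRV indirect predictions
correlate with full-data candidate GEBV at about 0.98: with roughly
1,100 phenotyped genotyped animals informing 1,000 marker effects,
removing the candidate genotypes moves $\hat g$ noticeably more than in
a population with millions of genotypes, and at this scale the
regression approximation (REG), which borrows the non-genotyped
parents' own solutions, can edge out the exact projection (GRV), which
conditions on the genotyped set alone. Both effects shrink as the
reference grows; neither reflects a defect in the decomposition, whose
internal identities hold to machine precision.

## Session-scale example

```{r example, eval = FALSE}
study <- simulateStudy(simConfig(), seed = 1)
model <- ssModel(h2 = 0.3, w = 0.20)
reduced <- singleStepSolve(study$ped, study$genoReduced,
                           study$phenotypes, model)
pred <- predictIndirect(reduced, study$ped, study$genoCandidates)
full <- singleStepSolve(study$ped, study$genoFull, study$phenotypes, model)
fullCand <- setNames(gebv(full)[study$candIdx],
                     animalIds(study$ped)[study$candIdx])
compareIndirect(pred, fullCand)
```
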