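---
title: "Pedigree and single-step genomic evaluation of full-sib families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and single-step genomic evaluation of full-sib families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgblup)
```

## The problem

Embryo transfer lets a single donor cow produce many full sibs. When such
animals are evaluated before slaughter they have no phenotype of their own,
and under pedigree BLUP their expected relationships are all the pedigree can
see: every pair of full sibs from non-inbred, unrelated parents has
numerator relationship exactly 0.5, so all members of a family receive the
same estimated breeding value (EBV). Selection within a family is then
impossible. Single-step genomic BLUP (ssGBLUP) replaces the expected
relationship with the realized genomic one: full sibs share half their
genome *on average*, but Mendelian sampling spreads the realized sharing
around 0.5, so each sib gets an individual genomic EBV (GEBV), typically
with higher accuracy. This package implements both evaluations, a
variance-component estimator, and a simulator of this population structure,
so the contrast can be reproduced and stress-tested at desk scale.

## Model

Both methods fit the single-trait animal model

$$y = X\beta + Zu + e, \qquad
\operatorname{Var}\!\begin{pmatrix} u \\ e \end{pmatrix} =
\begin{pmatrix} K^{-1}\sigma_a^2 & 0 \\ 0 & I\sigma_e^2 \end{pmatrix},$$

where $K = A^{-1}$ (PBLUP) or $K = H^{-1}$ (ssGBLUP). Solutions come from
Henderson's mixed-model equations with the variance ratio
$\alpha = \sigma_e^2/\sigma_a^2$ multiplying $K$:

$$\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \alpha K \end{pmatrix}
\begin{pmatrix} \hat\beta \\ \hat u \end{pmatrix} =
\begin{pmatrix} X'y \\ Z'y \end{pmatrix}.$$

A note on $\alpha$: some write-ups describe the multiplier of $H^{-1}$
loosely as "the additive genetic variance"; dimensionally the equations
only work with the ratio, which is what this package uses.

* **A** is built by the tabular method with inbreeding
  ($a_{ii} = 1 + \tfrac12 a_{s d}$), and its sparse inverse directly by
  Henderson's rules with Meuwissen–Luo inbreeding coefficients — dense
  inversion appears only as a test oracle.
* **G** is the VanRaden matrix $Z_c Z_c'/(2\sum_j p_j(1-p_j))$ with
  $Z_c = M - P$, $M \in \{-1,0,1\}$ and row $j$ of $P$ equal to
  $2(p_j - 0.5)$. By default $p_j$ are observed frequencies of the pooled
  genotyped set (test + reference, as the data were pooled before
  analysis); base-population frequencies can be supplied instead, and the
  simulator's tests use its known founder frequencies for exactly this
  reason — centering a handful of related families at their own observed
  frequencies biases the level of G.
* **H⁻¹** is $A^{-1}$ plus the genotyped-block correction
  $(G^*)^{-1} - A_{22}^{-1}$ with $G^* = w\,G + (1-w)A_{22}$, default
  $w = 0.95$. The minus sign is forced by the identity that $H^{-1}$ must
  reduce to $A^{-1}$ when $G = A_{22}$ (a plus sign fails this trivially);
  the blend is the field-standard invertibility guard, configurable up to
  $w = 1$. No $\tau$–$\omega$ scaling is applied.

Accuracy is reported, by default, with the printed evaluation formula
$\mathrm{Acc} = 1 - \mathrm{PEV}/\sigma_a^2$, where PEV is
$C^{uu}_{ii}\sigma_e^2$ from the inverted coefficient matrix. In standard
terminology this quantity is the *reliability*; `mode = "sqrt"` gives its
square root, the conventional accuracy. Both are exposed because published
tables using the first form are reproduced as written. PEV can exceed
$\sigma_a^2$ for animals whose only tie to the data passes through poorly
estimated fixed effects; accuracy is then clamped to zero with a warning
rather than reported negative.

## Variance components

`em_reml()` implements EM-REML on the mixed-model equations:

$$\sigma_a^{2\,(t+1)} = \frac{\hat u' K \hat u +
  \sigma_e^{2\,(t)}\,\mathrm{tr}(K C^{uu})}{q}, \qquad
\sigma_e^{2\,(t+1)} = \frac{y'(y - X\hat\beta - Z\hat u)}{N - r(X)}.$$

Rather than inverting the coefficient matrix each iteration, the package
absorbs the fixed effects once ($W = Z'SZ$), factors $K = R'R$, and
eigendecomposes $R^{-T} W R^{-1}$; every EM quantity then becomes an
$O(q)$ sum over eigenvalues, and the iterates are algebraically identical
to the naive algorithm (the test suite checks the two trajectories agree to
near machine precision). This is what makes a 2,000-animal parameter
recovery experiment affordable on one CPU. Convergence is declared when the
larger relative component change drops below `1e-8` (cap 500 iterations,
both configurable); the restricted log-likelihood is tracked and must not
decrease. EM approaches boundary optima ($h^2 \to 0$ or $1$) very slowly;
the toy example used to check against a likelihood grid search was chosen
with an interior optimum for that reason.

Heritability is always $h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)$.

## Fixed effects

Birth year, birth month and slaughter place enter as class effects
(corner-point constraint: first level zero, so solutions are comparable
across runs) and age at slaughter as a linear covariate. The evaluated
population recorded these four; their kinds are the conventional
carcass-model choice and are configurable. Records with slaughter age
outside 26–36 months (bounds retained) are removed before modeling, as are
records outside optional per-trait plausibility bounds.

## The simulator: a stated world

The generator emulates the structure of the motivating study, scaled to a
desk: 16 full-sib families of 10 genotyped, phenotype-less test animals,
produced by 16 sire-by-donor-dam matings that re-use 5 sires and 14 dams
(so several families are paternal or maternal half sibs of one another,
mirroring the published mating table); a reference tier of 2,000 genotyped,
phenotyped animals in paternal half-sib groups of 20 with dams re-used
twice; 2,000 biallelic SNPs with founder frequencies uniform on
[0.05, 0.5], dropped through the pedigree locus-by-locus without linkage;
and one additive trait with $h^2 = 0.4$ (the middle of the study's
0.2–0.5 range) on a carcass-weight-like scale ($\sigma_p^2 = 2000$, mean
440). Test-family sires are drawn from the reference sires so the test
families are genetically connected to the reference data. Class-effect
sizes (year/month/place effect SDs of 0.15/0.10/0.10 of a phenotypic SD)
and an age slope of 0.10 phenotypic SD per month are plausibility choices,
stated once here; none of these values were tuned against any test outcome.

True breeding values come either from the SNP effects themselves (`genic`
mode, the default: normal effects scaled so the realized TBV variance is
$\sigma_a^2$) or from the parent-average recursion
$TBV = \tfrac12 TBV_{sire} + \tfrac12 TBV_{dam} + m$ with the
Mendelian-sampling draw $m \sim N(0, \sigma_a^2(0.5 - 0.25(F_s + F_d)))$.
A `zero_mendelian` switch produces the degenerate control in which full
sibs are genuinely identical.

What the simulator does **not** emulate: linkage and recombination maps
(loci segregate independently, so realized-relationship spread at a given
SNP count is slightly narrower than with linked loci), selection across
generations, genotyping error, population structure beyond the two tiers,
and non-additive genetic effects. A green test therefore establishes that
the algorithms reproduce the structural contrast (identical EBVs, spread
GEBVs, higher genomic accuracy) under Mendelian inheritance — not that any
particular published accuracy value is recovered, which would require the
original, undeposited data.

## Numerical choices

* Topological renumbering breaks ties by input order; all randomness in the
  simulator flows from one integer seed through R's Mersenne–Twister with
  pinned normal/sample kinds, so identical configs give byte-identical
  outputs.
* Unknown parents are unrelated, non-inbred base animals; no genetic
  groups or metafounders.
* Relationship strata: RT3 = both recorded parents shared, RT2 = exactly
  one, RT1 = otherwise. An unknown parent never counts as shared — the
  published strata came from a fully recorded pedigree, so this convention
  is ours and is stated rather than silent.
* Marker QC removes MAF < 0.01, missingness ≥ 0.10, and exact-test HWE
  p < 1e-6 (chi-square available); surviving missing calls are
  mean-imputed to $2p_j$, standing in for the external phasing/imputation
  pipeline used on the real data, which is out of scope.
* The MME left-hand side is solved by Cholesky when possible; confounded
  fixed effects beyond the corner constraint trigger a warning and a
  generalized-inverse path. PEV uses the explicit inverse (desk scale; no
  approximation algorithms).
* Per-family report tables give both animal-weighted and family-weighted
  overall means: printed per-family means in the motivating report do not
  average to its overall row under equal weights, so the package defines
  both explicitly.

## Limitations

Single trait only (no multi-trait REML or genetic correlations); no
unknown-parent groups; no weighted or APY variants of ssGBLUP; dense
algebra throughout, intended for up to a few thousand animals. The
published real-data values that depend on the undeposited phenotypes and
genotypes (absolute variance components, accuracies, per-family values)
are inputs to arithmetic worked examples in the acceptance suite, not
quantities this package claims to reproduce.
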