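---
title: "Approximating ssGBLUP reliabilities with the APY inverse: methods and design"
author: "apyrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating ssGBLUP reliabilities with the APY inverse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apyrel)
```

## The problem

Genetic evaluations report, next to each estimated breeding value (EBV), a
reliability: the squared correlation between the true and estimated breeding
value, computed as `rel = 1 - PEV / sigma_u2` where PEV is the prediction
error variance.  Exact PEVs are diagonal elements of the inverted
coefficient matrix of Henderson's mixed model equations (MME), a computation
whose cost grows cubically with the number of equations and which is
infeasible for national-scale single-step genomic BLUP (ssGBLUP)
evaluations with millions of animals and hundreds of thousands of
genotypes.

`apyrel` approximates these reliabilities for single- and multiple-trait
animal models in which the genomic relationship matrix G is represented
through the Algorithm for Proven and Young (APY).  The package combines one
*exact* ingredient — a block-sparse extraction of the inverse diagonal of
the genomic system, possible because the APY inverse of G is sparse — with
*approximate* ingredients on the pedigree side, and validates the whole
against dense MME inversion on simulated populations.

## Model

The single-trait animal model is

    y = X b + W u + e,   Var(u) = G_APY * sigma_u2,   Var(e) = I * sigma_e2

with `b` cross-classified fixed effects (contemporary group, sex, ...), `u`
breeding values and `alpha = sigma_e2 / sigma_u2`.  For genotyped animals
the PEVs (up to `sigma_e2`) are the diagonal of

    (D + alpha * G_APY^-1)^-1

where `D` is the diagonal of record information left after absorbing the
fixed-effect equations, `D ~ W'(I - X(X'X)^- X')W`.

### The APY structure

APY partitions the genotyped animals into `nc` core and `nn` noncore
animals and models each noncore breeding value as a regression on the core
ones plus an independent residual.  With `Pnc = Gnc Gcc^-1` and
`Mnn = diag(Gnn - Gnc Gcc^-1 Gcn)`, the inverse is block-sparse:

    G_APY^-1 = [ Gcc^-1 + Pnc' Mnn^-1 Pnc ,  -Pnc' Mnn^-1 ]
               [ -Mnn^-1 Pnc              ,   Mnn^-1      ]

a dense `nc x nc` block, a dense `nc x nn` strip, and a *diagonal*
`nn x nn` block.  `build_apy_decomposition()` forms these blocks, computing
each `Mnn_i` row by row so that no `nn x nn` object is ever allocated.

### Exact block-sparse PEV extraction

Adding `D` preserves the structure: `Kcc` (dense core), `Kcn` (dense
strip), `knn` (positive diagonal).  Writing `U = Kcn diag(knn)^-1`, the
Schur complement `T^-1 = Kcc - U Kcn'` is `nc x nc`; `block_sparse_pev()`
inverts it by Cholesky and reads off

* core diagonal: `diag(T)`;
* noncore diagonal: `1/knn_i + u_i' T u_i`, with `u_i` the i-th column of `U`.

This is algebraically exact — the only expensive steps are two
`nc^2 * nn` multiplications and one `nc^3` inversion, so cost grows
linearly in the number of noncore animals at fixed core size.  The test
suite checks every entry against dense inversion to 1e-8 relative
(typically agreeing to near machine precision).

## Approximations on the pedigree side

### Record information D

`approx_record_information()` uses two passes over the records.  Pass one
counts records per fixed-effect level (per trait, among records observed
for that trait); pass two weights each record by
`max(0, 1 - sum_effects 1/n_level)` and accumulates weights per animal.
This is exact for a single cross-classified effect (one record per animal)
and a close approximation for crossed effects.  All cross-classified
effects are absorbed, not only the largest one; covariates are outside the
model class and are dropped with a warning.  The clamp at zero keeps D a
valid information diagonal when many small levels would drive the weight
negative.

### Pedigree reliabilities in effective record contributions

Information is carried in *effective record contributions* (ERC): `q`
record-equivalents give reliability `rel = q/(q + alpha)` and conversely
`q = alpha * rel/(1 - rel)`.  `approx_pedigree_reliability()` tracks three
sources per animal — own records `q_own` (fixed), parents `q_par`, progeny
`q_prog` — and iterates:

1. **Parents to progeny** (pedigree order): the parent average carries
   `rel_PA = (rel*_s + rel*_d)/4`, each parent's reliability taken
   *excluding* the contribution it previously received from this animal.
2. **Progeny to parents** (reverse order): a progeny with own-plus-progeny
   information `q_p` and a mate of reliability `rel_m` contributes source
   reliability

        r_src = 0.25 / (0.75 + 0.25 * (1 - rel_m) + alpha / q_p)

   converted to ERC and summed over progeny.
3. Combine: `rel = rel_from_erc(q_own + q_par + q_prog)`.

Every coefficient follows from exact absorption of a two-generation MME.
For a parent with one single-record progeny and an unknown mate the
contribution is exactly `0.25 * alpha / (0.75 + alpha)`; a progeny with
unlimited records and a perfectly known mate contributes source reliability
exactly 1/3.  The per-edge exclusion bookkeeping (subtracting last round's
sent contribution before using a relative as a source) limits double
counting of information that merely echoes back.  Iteration stops when the
largest reliability change is below `tol` (default 1e-5, default
`max_rounds = 20`; convergence is typically reached in 5–8 rounds).  Own
records contribute for all sexes.

The scheme is validated against dense inversion of `diag(D) + alpha A^-1`:
on simulated multi-generation pedigrees of about 2,000 animals the
correlation exceeds 0.99 and the mean absolute difference is below 0.01.

### The non-inbred relationship convention

`build_a_inverse()` uses Henderson's rules with Mendelian-sampling
precisions 2, 4/3 and 1 (both/one/no parents known), i.e. inbreeding is
ignored in the Mendelian variances.  For the oracle algebra to be exact the
tabular A of `build_a()` follows the *same* convention,
`A = T D T'` with `D_ii` in {1/2, 3/4, 1}, so its diagonal is
`0.25 (a_ss + 2 a_sd + a_dd) + D_ii` rather than the inbreeding-adjusted
textbook value.  The two functions are exact inverses on any pedigree,
related matings included.  Reliabilities are normalised as
`1 - PEV / sigma_u2` throughout; an inbreeding-adjusted normalisation
(`1 - PEV / (a_ii sigma_u2)`) is deliberately not offered because the
relationship machinery is non-inbred end to end.

## The single-step pipeline

`ssgblup_rel()` executes, per trait:

1. pedigree reliabilities from D; conversion to ERCs;
2. genomic step: block-sparse PEV of `diag(ERC) + alpha G_APY^-1` for
   genotyped animals;
3. "A22" step: the pedigree approximation rerun with own-information equal
   to the ERCs for genotyped animals and zero elsewhere — the reliability
   their information would reach through pedigree relationships alone;
4. combination by ERC additivity:
   `q_final = max(0, q_ped + q_gblup - q_a22)`.  The A22 subtraction
   removes what the genomic step re-counts through relationships already
   present in the pedigree; the clamp handles the (rare) negative net;
5. propagation: for each genotyped animal, Steffensen's derivative-free
   iteration back-solves the own-information `q*` that reproduces its
   combined reliability with all other animals' pedigree-stage states
   frozen (a single outer pass keeps the cost linear); the pedigree
   approximation is rerun with these `q*` to read off non-genotyped
   reliabilities.

Steffensen's method (`backsolve_erc_steffensen()`) was chosen because the
forward map is cheap but derivative-free, and near the root the transformed
iteration converges quadratically; a bisection fallback with a doubling
upper bound covers denominator underflow.  Targets below the
no-own-information reliability clamp to `q* = 0`.

### Multiple traits

Per-trait single-trait reliabilities are adjusted for cross-trait
information using the genetic (`G0`) and residual (`R0`) covariance
matrices.  Per animal, a working prediction-error matrix of trait dimension
is inverted:

    W = ( O^1/2 R0~^-1 O^1/2  +  G0^-1  +  sum_j m_j B )^-1
    B = (1/3) G0^-1 - (2/3) G0^-1 ((4/3) G0^-1 + (Q R0 Q)^-)^-1 (2/3) G0^-1

and `rel_j = 1 - W_jj / G0_jj`.  Design choices worth recording:

* **Effective observations.** `O_jj = rel_j R0_jj / ((1 - rel_j) G0_jj)`
  is the unique diagonal for which the formula returns the single-trait
  reliability exactly when there is one trait and no progeny term — the
  collapse property the implementation enforces to 1e-12.  Consistency
  then requires the own-record term to be the *information* matrix
  `O^1/2 R0~^-1 O^1/2` (effective observations scaling the residual
  precision); the scalar case makes the two conventions easy to confuse,
  but only this one has the collapse property for arbitrary `G0`, `R0`.
* **Missing traits.** `R0~^-1` is the inverse of `R0` restricted to traits
  with `O_jj > 0`, zero elsewhere; likewise `(Q R0 Q)^-` restricts to
  non-missing traits.  These masked inverses are the natural limits of the
  full formula as information for a trait goes to zero and keep W defined
  for animals with arbitrary missing-trait patterns.
* **Progeny term.** `B` is the exact per-progeny precision a parent gains
  from one recorded progeny with an unknown mate (in the single-trait
  scalar case it reduces to `1 / (4 R0 + 3 G0)`).  `m_j` counts progeny
  with a record for trait j; `Q` is taken from the animal's own record
  pattern.  The summation index runs over traits inside one working matrix
  used for all traits of the animal.

With diagonal `G0` and `R0` and no progeny term the adjustment is the
identity map on single-trait reliabilities, which the tests assert to
1e-12.

## The synthetic population generator

`simulate_population()` emulates the data shape of a livestock evaluation:

* discrete, non-overlapping generations with random mating; a configurable
  fraction of males used as sires (default 10%, the polygynous shape of
  cattle breeding);
* true breeding values by the recursion `u = 0.5 u_s + 0.5 u_d + phi`,
  `Var(phi) = 0.5 G0` (founders `G0`) — multi-trait via the Cholesky factor
  of `G0`;
* genotypes by gene drop: founder haplotypes drawn at allele frequencies
  Uniform(0.05, 0.95), transmitted with free recombination; the genotyped
  subset is taken from the most recent generations first, as in practice;
* phenotypes `y = mu + cg + sex + u + e` with contemporary groups nested in
  generation (group effects N(0, 0.5^2) on a unit phenotypic variance) and
  per-trait missingness masks;
* founders carry no records by default (unrecorded base population).

Defaults are a single trait of heritability 0.3 on unit phenotypic
variance; the three-trait configurations used in validation have
heritabilities 0.4/0.3/0.3, genetic correlations 0.35–0.55 and residual
correlations 0.15–0.30, typical of growth traits in beef cattle, with
missing-trait probabilities 0.1/0.2/0.3.

What the generator does *not* emulate — and hence what passing validation
does not demonstrate — includes linkage and LD structure (markers segregate
independently, so realized relationships are slightly less variable than
with real chromosomes), directional selection and assortative mating,
overlapping generations, maternal effects and heterogeneous residual
variances.  The validation targets the *reliability algebra* — agreement of
the approximation with exact inversion of the same relationship structures
— which does not require markers to be causal; true breeding values are
therefore simulated from the pedigree, not from the markers.

## Validation design and problem sizes

Because the algebra being approximated is only tractable densely at desk
scale, the package validates against dense oracles (straight-line code,
sharing nothing with the production paths):

* `exact_gblup_pev()` — dense inversion of the shifted (APY) system;
* `exact_ssgblup_reliability()` — the full MME with
  `H^-1 = A^-1 + [0 0; 0 G_APY^-1 - A22^-1]`, inverted densely.

The shipped validation uses: exactness of the block solver on instances of
200–500 genotyped animals (10–20% core); end-to-end agreement on simulated
populations of roughly 5,000 animals with 1,000 genotyped (200 core) for
the single-trait model, and roughly 3,700 animals with 400 genotyped (210
core) for the three-trait model.  Observed agreement — correlations at or
above 0.97 for genotyped and non-genotyped animals separately, mean
absolute differences below 0.03, regression slopes of exact on approximate
within 0.90–1.10 — is computed afresh by the test suite and by
`scripts/acceptance.R`, not quoted from elsewhere.  The mild downward slope
for genotyped animals (about 0.94) reflects a small systematic
overstatement by the ERC-additivity combination: information circulating
between close relatives is re-counted slightly differently through G than
through A22, and the effect grows with the density of sibships.

## Numerical choices and degenerate inputs

* Blending: `G` is blended as `0.95 G + 0.05 A22` (identity if no pedigree)
  before the APY factorisation, guaranteeing a positive-definite core
  block; `beta` is user-settable in (0, 1].
* Missing dosages impute to the rounded expectation `2 * freq`, keeping
  the dosage domain {0, 1, 2}.
* `Mnn_i <= 0` aborts with advice to blend or enlarge the core.
* Steffensen tolerances: 1e-8 on the reliability residual, 50 iterations,
  bisection fallback; pedigree iteration: 1e-5, 20 rounds, with a warning
  (not an error) on non-convergence.
* Reliabilities are clamped to [0, 1) on output; the combination clamp at
  `q_final = 0` covers pathological negative net information.
* Ties in core selection do not arise: the random draw is uniform without
  replacement under a private RNG stream, so caller RNG state is untouched
  and the partition is reproducible from the seed alone.

## Known limitations

* Non-inbred relationship rules only; deep closed pedigrees with
  substantial inbreeding will see A (and hence reliabilities of older
  animals) slightly misstated.
* The D approximation covers cross-classified effects only.
* The combination step assumes ERC additivity; no damping of the genomic
  minus A22 difference is applied.
* `exact_ssgblup_reliability()` is intentionally dense and guarded at
  6,000 animals; it is a validation oracle, not a production path.
* Reliability of EBVs, not EBVs themselves: the package never solves the
  MME for breeding values.
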