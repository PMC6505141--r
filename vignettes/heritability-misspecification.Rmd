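---
title: "Heritability estimation under mis-specified genetic correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability estimation under mis-specified genetic correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinherit)
```

## The model

`kinherit` works with the two-component polygenic model for a quantitative
trait measured on N individuals clustered in mutually independent pedigrees:

$$ y = g + e, \qquad g \sim N(0, \sigma_g^2 G), \qquad e \sim N(0, \sigma_e^2 I), $$

parameterized as $\theta = (h^2, \sigma^2)$ with total variance
$\sigma^2 = \sigma_g^2 + \sigma_e^2$ and heritability
$h^2 = \sigma_g^2/\sigma^2$, so that
$y \sim N(0, [h^2 G + (1-h^2) I]\sigma^2)$. Fixed effects are assumed to have
been adjusted out beforehand; the package has no covariate machinery.

The genetic correlation matrix $G$ is twice a kinship matrix, and the central
question is what happens when the matrix used for fitting, $G_f$, differs
from the matrix $G_t$ that actually generated the trait. The package supports
three families of kinship measures, in increasing order of variability around
the pedigree expectation:

* **pedigree kinship** $2\Psi$ (`pedigree_kinship`): the expectation of
  genome sharing over descent, a deterministic function of the relationship;
* **realized kinship** $2\Phi$ (`simulate_descent` + `realized_kinship`): the
  actual proportion of genome shared identical by descent, in genetic
  distance, for one realization of inheritance — genome-wide, or $2\Phi^*$
  on a chromosome subset where the relative variability is larger;
* **marker-based estimates** $2\hat\Phi_c$ (`classic_grm`): the classic
  genomic relationship matrix, an unbiased but noisy identity-by-state
  estimator of $2\Phi$ (an LD-weighted or other improved estimator can be
  registered through `grm_plugin`; none is shipped).

## Fitting: the eigen-transformation

Because there are only two variance components, each pedigree block of $G_f$
can be diagonalized, $G_f = T D T^\top$, and the rotated trait
$y^* = T^\top y$ has diagonal covariance
$[h^2 D + (1-h^2) I]\sigma^2$ under the fitted model. The log-likelihood
(without its additive constant) is then a sum over scalar channels,

$$ \ell(h^2, \sigma^2; y^*) = -\tfrac12\Big[N\ln\sigma^2 +
   \sum_i \ln v_i + \frac{1}{\sigma^2}\sum_i \frac{y_i^{*2}}{v_i}\Big],
   \qquad v_i = h^2\lambda_i + 1 - h^2. $$

`fit_mle` profiles $\sigma^2$ in closed form,
$\hat\sigma^2(h^2) = N^{-1}\sum_i y_i^{*2}/v_i$, and maximizes the profile
over $h^2$ by Brent search on several overlapping subintervals of $[0,1]$
with the best result retained, plus an explicit comparison against the
boundary values; the parameter tolerance is $10^{-9}$. Boundary solutions
are flagged. If all eigenvalues are equal the likelihood does not depend on
$h^2$ at all and the fit is flagged unidentifiable rather than returning an
arbitrary number.

Numerical choices worth knowing about:

* eigenvalues within $10^{-10}$ (relative to the largest) below zero are
  treated as rounding noise and clipped to 0;
* a fitted matrix may be genuinely indefinite — a diagonal-constrained GRM
  is the practical case — and is accepted as such: the negative eigenvalues
  are kept and the $h^2$ search is restricted to the region where every
  variance channel $v_i$ stays positive, which is exactly where the
  likelihood is defined. Trait *simulation* in contrast requires a true
  covariance matrix that is PSD beyond the clipping tolerance and errors
  otherwise;
* at $h^2 = 1$ a zero eigenvalue makes the likelihood $-\infty$; the search
  domain is clamped at $1 - 10^{-12}$.

## Sampling variance under correct specification

When $G_f = G_t$ the asymptotic sampling variance of $\hat h^2$ is the
closed form implemented in `asv_correct`,

$$ \mathrm{ASV}(\hat h^2) = \frac{2}{\sum_i \frac{(\lambda_i-1)^2}{v_i^2} -
   \frac1N \big[\sum_i \frac{\lambda_i-1}{v_i}\big]^2 }, $$

which depends on the design only through the eigenvalues of the correlation
matrix. The per-eigenvalue summand $(\lambda-1)^2/v^2$ (`asv_summand`) is
V-shaped with minimum at $\lambda = 1$: eigenvalues far from 1 are what make
a design informative about heritability. This is why realized kinship on a
single short chromosome ($2\Phi^*$), whose eigenvalues spread far beyond the
two point masses of $2\Psi$, gives visibly smaller sampling error under
correct specification. For 100 sibships of 14 at $h^2 = 0.5$ the 2$\Psi$
eigenvalues are 7.5 (multiplicity 100) and 0.5 (multiplicity 1300) and the
formula evaluates to an asymptotic standard error of 0.067.

## Mis-specification: pseudo-true limits and sandwich covariance

When $G_f \neq G_t$, write $\Delta = G_t - G_f$. The rotated trait is really
distributed with covariance
$[h_0^2 D + (1-h_0^2)I]\sigma_0^2 + h_0^2\sigma_0^2\, T^\top \Delta T$,
whose diagonal $a_i$ is all the Kullback-Leibler objective sees:

$$ (h_1^2, \sigma_1^2) = \arg\min \; \tfrac12\ln\sigma^2 +
   \frac{1}{2N}\sum_i\Big[\ln v_i + \frac{a_i}{v_i\,\sigma^2}\Big]. $$

`pseudo_true` solves this for the given finite sample of blocks, again with
$\sigma^2$ profiled and a Brent search in $h^2$. The MLE converges to this
pseudo-true point, and `sandwich_acov` provides its sampling covariance
$J^{-1} K (J^{-1})^\top / N$, where $J$ is the expected Hessian of the
per-observation log-likelihood at $\theta_1$ under the true distribution and
$K$ the covariance of the per-observation score. Both are computed in closed
form from Gaussian quadratic-form identities
($E[y^\top A y] = \mathrm{tr}(AC)$,
$\mathrm{Cov}(y^\top A y, y^\top B y) = 2\,\mathrm{tr}(ACBC)$) applied block
by block to the full transformed covariance $C = T^\top \Sigma_t T$ — the
off-diagonal of $C$ matters for $K$ even though only its diagonal enters the
pseudo-true objective. Under $\Delta = 0$ the information identity $K = -J$
holds and the $h^2$ entry of the sandwich reduces exactly to the closed-form
ASV above; the test suite verifies this to $10^{-6}$ relative, checks the
$(h^2,h^2)$ element of $J$ against its printed closed form, checks all of
$J$ against numerical differentiation of the expected log-likelihood, and
checks $K$ against the Monte-Carlo covariance of simulated scores.

A practically important special case: when $G_f = 2\Psi$ is fitted while the
truth is realized kinship, $\Delta$ has mean zero over descent and enters
only through quadratic forms $t_j^\top(\sum_b \Delta_b/m)t_j$ that vanish as
the number of pedigrees grows. Fitting pedigree kinship is therefore
consistent whatever the causal genome, with the same asymptotic variance as
under correct specification with $2\Psi$
(`consistency_check_pedigree_fit` tracks both convergences). Fitting a
*more* variable measure than the truth (e.g. $G_f = 2\Phi^*$ under
$G_t = 2\Phi$ or $2\Psi$, or a noisy GRM under $G_t = 2\Phi$) biases
$\hat h^2$ downward; fitting a broader (less variable) matrix causes little
bias. The cousinship study (`run_cousinship_study`) shows the downward bias
grows with the remoteness of the relationship — the mechanism by which
GRM-based population designs can contribute to "missing heritability".

## The gene-drop simulator

`simulate_descent` drops founder genomes through each pedigree along a
genetic map. Crossovers are a homogeneous Poisson process at 1 event per
100 cM per meiosis (Haldane model, no interference) and the starting
parental haplotype of each chromosome is a fair coin; coordinates are cM,
0-based, half-open. The reference this package's studies were compared
against does not state its crossover model; Poisson/Haldane is the standard
choice and matches the expectation properties the theory uses
($E[\Phi] = \Psi$, verified by Monte Carlo in the tests). The default map
has 22 human-like autosomes totalling 3539 cM with chromosome 22 at 74 cM;
any map can be supplied as two-column text. Because the published
chromosome-22 analyses depend on an unpublished map, chromosome-22 results
computed here can differ from published values by a small systematic amount
(of order 0.01 in the pseudo-true heritability); the acceptance checks carry
that allowance explicitly.

Realized kinship from a descent realization is computed exactly (segment
intersection in C++, no marker grid): $\phi(i,j)$ averages, over the four
ordered haplotype pairs, the genetic length carrying the same founder label,
divided by the selected map length. It is linear in chromosome length by
construction, positive semi-definite, and has unit diagonal for outbred
individuals.

## The synthetic marker generator

`simulate_founder_haplotypes` is a synthetic stand-in for a reference
haplotype panel (the published studies used 1000 Genomes Phase 3 haplotypes
and a 169,751-marker panel; neither is redistributable here, and marker
counts are scaled down). Allele frequencies follow a symmetric Beta(0.5,
0.5) spectrum truncated at a minor-allele-frequency floor (default 0.05);
local LD comes from a first-order Markov Gaussian-copula latent process
whose correlation decays geometrically with genetic distance (latent
correlation `ld^d` at d cM, default `ld = 0.5`), which keeps marginal
frequencies exact and makes denser panels increasingly redundant — the
mechanism behind the observation that additional markers do not improve the
classic GRM without limit. What this generator does **not** emulate:
recombination-hotspot LD structure, allele-frequency differences between
populations, and genotyping error. Tests that pass with this
generator therefore validate the estimator algebra and the qualitative bias
mechanisms, not the magnitude of GRM noise on any particular real panel;
this is also why the cousinship bias curves are asserted as orderings
(third worse than second cousins, reverse direction nearly unbiased) rather
than as numbers.

`drop_genotypes` populates genotypes deterministically through the IBD
mosaic — IBD segments are identical by state without error — and
`classic_grm` uses the generating ("known") allele frequencies, computed
within pedigree blocks, optionally with the diagonal constrained to 1.

## Study conditions and problem sizes

The simulation harness defaults reproduce the main study conditions: 100
independent sibships of 14 (N = 1400), $\sigma_0^2 = 1$,
$h_0^2 \in \{0.2, 0.5, 0.8\}$, 500 replicates per scenario
(`scenario_config`), and a fixed total sample of 2000 for the cousinship
grid. Within each replicate descent is simulated afresh, $G_t$ and $G_f$
are built from the same realization, a trait is drawn under $G_t$, and the
model is fitted with $G_f$; empirical means and standard deviations of
$\hat h^2$ are reported next to the pseudo-true limit and sandwich standard
error computed from the same $(G_t, G_f)$ — the "analytical" values are
averages of the finite-sample (finite-m) solutions over descent
realizations, which is the natural reading of solving the KL objective "for
any finite N". The unit tests and the smaller demonstrations in this
vignette scale the replicate counts down (tens of replicates, blocks of a
few hundred individuals); the chosen sizes keep every Monte-Carlo
comparison inside 3 standard errors of its target, which is the criterion
used throughout the test suite.

Master seeds: every stochastic routine takes one integer seed; per-pedigree
streams are derived deterministically from it by pedigree index, so block
$b$ of a simulation does not change when more blocks are appended, and every
result table is bitwise reproducible from its configuration.

## A worked example

```{r example, eval = FALSE}
ped  <- build_pedigree("sibship", size = 14)
psi2 <- rep_kinship(pedigree_kinship(ped), 100)   # 2 Psi, N = 1400

# closed-form ASE under correct specification with 2 Psi
sqrt(asv_correct(eigen_transform(psi2)$lambda, h2 = 0.5))
#> [1] 0.06682816

# one descent realization; pseudo-true limit of fitting 2 Phi under 2 Psi
dr   <- simulate_descent(ped, m = 100, seed = 1)
phi  <- realized_kinship(dr)
pseudo_true(misspec_problem(psi2, phi, h2_0 = 0.5))$h2
#> [1] 0.4532427

# sandwich standard error for the same mis-specification
sandwich_acov(misspec_problem(psi2, phi, h2_0 = 0.5))$ase_h2
#> [1] 0.05529087

# a small empirical check: 50 replicates of the full loop at Gt = Gf = 2 Phi
res <- run_scenario(scenario_config(reps = 50, seed = 3))
res$summary[, c("h2_emp_mean", "h2_emp_sd", "h2_analytical", "se_analytical")]
#>   h2_emp_mean  h2_emp_sd h2_analytical se_analytical
#> 1   0.4959829 0.06210997           0.5    0.06159626
```

## Known limitations

* Only two variance components: no shared-environment term, no multiple
  genetic components; the eigen-trick does not extend beyond two.
* Maximum likelihood, not REML, and no fixed-effect estimation.
* No confidence intervals or tests for $h^2$; the sandwich output is the
  asymptotic covariance only.
* Sex-averaged maps without interference; no X chromosome; inbreeding is
  handled by the kinship recursion but the canonical structures are outbred
  except for the documented 14-member inbred pedigree.
* The exact topologies of the two 14-member canonical pedigrees are
  documented defaults (a three-generation family and an inbred
  double-first-cousin structure); any exact topology can be supplied as a
  FAM file.
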