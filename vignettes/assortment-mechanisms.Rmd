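---
title: "Inferring assortative-mating mechanisms from partner, sibling, and in-law correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring assortative-mating mechanisms from partner, sibling, and in-law correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadassort)
```

## The problem

Partners resemble each other in education and in mental and somatic health.
That resemblance can arise from at least four processes:

* **direct assortment** — selection on the observed phenotype itself;
* **indirect assortment** — selection on a correlated trait, possibly latent
  (general attractiveness, vulnerability to psychopathology, an imperfectly
  measured version of the phenotype);
* **social stratification** — partners meet inside environmental strata that
  also shape the phenotype;
* **convergence** — partners become more similar after couple formation,
  through mutual influence or shared environments.

The processes have different consequences for children, for genetic studies,
and for how one should adjust for assortment, but they are indistinguishable
from a couple correlation alone. Data on one full sibling of each partner
("family quads") separate them: each mechanism implies a distinct pattern for
the partner correlation $r_{partner}$, the sibling correlation $r_{sibling}$,
and the sibling-in-law correlation $r_{inlaw}$.

Path tracing with co-paths gives, per mechanism (unit variances assumed):

| mechanism | $r_{partner}$ | $r_{sibling}$ | $r_{inlaw}$ | IIF |
|---|---|---|---|---|
| direct (copath $m$, sibling corr. $r_s$) | $m$ | $r_s$ | $m r_s$ | $1$ |
| indirect (loading $a$, copath $\mu$, $r_m$, $E=(1-a^2)r_e$) | $a^2\mu$ | $a^2 r_m + E$ | $a^2\mu r_m$ | $1/(a^2 + E/r_m)$ |
| stratification (loading $q$) | $q^2$ | $q^2$ | $q^2$ | $1/q^2$ |

where the **in-law inflation factor** is
$$\mathrm{IIF} = \frac{r_{inlaw}}{r_{sibling} \cdot r_{partner}}.$$

Under direct assortment the in-law correlation is exactly the product of the
two correlations that connect the in-laws, so IIF $= 1$. Indirect assortment
with small residual sibling similarity pushes IIF toward $1/a^2 > 1$; with
$r_e = r_m$ the inflation cancels exactly, and $r_e > r_m$ can push it below
1. Stratification gives $1/q^2 > 1$. Convergence adds to the partner
correlation (shared couple environment $n^2$; mutual influence $2xa$) far
more than to the in-law correlation ($x r_m a$), driving IIF *below* its
base value — which is why similarity should be measured before couples form.
An elevated IIF therefore rules out direct assortment but cannot by itself
distinguish indirect assortment from stratification; that requires
additional data.

`quadassort` implements the full chain: liability-threshold correlation
estimation, the quad model with the IIF and its likelihood-ratio test,
mechanism simulators, descriptive and logistic-regression checks, and a
pipeline that sequences them.

## Estimation under the liability-threshold model

Diagnoses enter as binary indicators (1 = affected). We model each as the
exceedance of a threshold $\tau$ by a latent standard-normal liability, and
estimate latent correlations by full-information maximum likelihood (FIML):

* **tetrachoric** (binary–binary): each complete pair contributes its 2×2
  cell probability, built from the bivariate-normal upper-orthant kernel
  $P(Z_1>\tau_1, Z_2>\tau_2; r)$;
* **polyserial** (continuous–binary): normal density of the continuous
  member times the conditional probit probability of the binary member;
* **Pearson** (continuous–continuous): bivariate-normal FIML, which with
  complete data and no covariates *is* the sample correlation and is
  computed in closed form.

Pairs with one member missing contribute that member's marginal likelihood,
so incomplete rows still inform thresholds and means. Covariates act as
*definition variables*: they shift thresholds (binary) or means (continuous)
linearly, with estimated slopes, while the correlation itself is
covariate-free. Education adjustment uses both partners' education as
definition variables on both sides of a pair; a trait is never adjusted for
itself.

Numerical choices, in one place:

* the correlation is optimized as $z=\tanh^{-1} r$, keeping the search off
  the $\pm 1$ boundary; estimates with $|\hat r| > 0.999$ are flagged
  (`boundary = TRUE`, `converged = FALSE`) because tetrachoric likelihoods
  flatten near the boundary;
* the orthant kernel is a 48-node Gauss–Legendre rule on the
  arcsine-substituted correlation integral of the bivariate normal CDF,
  vectorized over thresholds (agreement with deterministic rectangle
  quadrature is at the $10^{-10}$ level in the tests);
* optimization uses `nlminb` with a relative tolerance of $10^{-10}$,
  followed by restarts from the solution; a restart that cannot improve the
  objective certifies stationarity, which guards against spurious
  "false convergence" labels from finite-difference gradients on large-$n$
  objectives;
* standard errors come from the observed information (numerical Hessian);
  confidence intervals are computed on the $z$ scale and back-transformed;
* cell probabilities are clamped at $10^{-12}$ before logging;
* a fast two-stage mode (thresholds by probit inversion of the margins,
  then a 1-D profile for $r$) is available for the covariate-free
  tetrachoric; joint FIML is the default.

## The quad model and the test of direct assortment

`fit_quad_model()` fits the joint 4-person structure with one partner
correlation, one sibling correlation shared by the two sides of the family,
one in-law correlation shared by the two sides, and a free
co-sibling-in-law correlation. Continuous traits use the multivariate
normal likelihood, grouped by missingness pattern (quads with one sibling
contribute trivariate marginals; couples without siblings, bivariate ones).
Binary traits use 2–4 dimensional rectangle probabilities computed by
deterministic Miwa quadrature, so log-likelihoods are reproducible run to
run. Proposals whose correlation matrix fails a Cholesky factorization are
rejected with a barrier value, so a non-positive-definite structure is never
returned. Sex adjustment enters means or thresholds only.

The constrained (direct-assortment) model sets
$r_{inlaw} = r_{partner} \cdot r_{sibling}$ *by reparameterization* — the
in-law correlation is computed, not estimated — which guarantees exact
nesting. `lrt_direct_assortment()` compares the two fits with a 1-df
chi-square statistic and attaches the IIF from the free fit; across traits
the p-values are Benjamini–Hochberg adjusted (one FDR family per output
table; IIFs with zero-product denominators are reported missing and
excluded from the family). Equality of two correlation sets across
observation windows is tested by maximizing summed *profile* likelihoods
over a common correlation, one degree of freedom per constraint.

## What the simulator emulates — and what it does not

`simulate_quads()` constructs liabilities by conditional Gaussian sampling
along the family chain: the index person and their sibling first, the
partner through the mechanism's copath, then the partner's sibling. This
reproduces the path-traced expected correlations *exactly*, without the
finite-pool distortion a rank-matching mating market would introduce.
Mate formation via an explicit dating market, preference heterogeneity, and
age-structured cohorts are deliberately out of scope.

Defaults are fixed at the study conditions the package is designed around:
93,963 couples; a sibling observed for $156{,}335/187{,}926 \approx 83.2\%$
of members on each side (independent thinning — coverage counts are known
but no missingness mechanism is, so independence is the neutral choice);
binary traits dichotomized at registry-style prevalences (bundled in
`condition_prevalences()`, e.g. substance use 1.6%, depressive disorder
9.09%); and a within-person correlation of 0.66 between the two
education measures as the multitrait calibration anchor. Simulated data are
missing-at-random by construction and carry none of the participation
biases, diagnostic-coding noise, or cohort trends of real registries — so
green tests certify the *inferential machinery*, not the registry estimates.

`overlay_convergence()` adds a couple-shared environment (variance $n^2$)
and symmetric mutual influence ($x$) *after* quad formation, then
re-standardizes, so reported correlations stay on the unit-variance scale.
The overlay's exact variance bookkeeping is the reference; the additive path
expressions ($n^2 + 2xa$ and $x r_m a$) in
`expected_relative_correlations()` ignore re-standardization and should be
read as first-order sums. The mutual-influence term is implemented as one
symmetric linear mixing step; a sequential-influence reading would differ at
higher order in $x$.

## Skewed liabilities and the product identity

The direct-assortment test rests on a product identity
$r_{ab} r_{bc} = r_{ac}$, and tetrachoric correlations assume normal
liabilities. `skewed_liability()` probes robustness with two constructions:

* **marginal transform** (default): a monotone sinh–arcsinh transform of
  each member's chain liability. Because dichotomizing a monotone transform
  at a fixed quantile is dichotomizing the underlying chain, tetrachorics
  recover the chain correlations and the product identity holds — even
  though each tetrachoric *overestimates* the Pearson correlation of the
  observed skewed liabilities (by +0.01 to +0.03 at skewness $\approx -1.2$
  in the acceptance simulation, several SEs at $n = 200{,}000$).
* **innovation skewing** (`skew_innovations = TRUE`): the chain's
  independent innovations are skewed before linear mixing. Pearson
  correlations then satisfy the identity exactly while the copula is
  non-Gaussian; the tetrachorics acquire *pair-specific* biases and the
  product identity degrades as skew grows (at skewness $-1.2$ the deviation
  is about 0.03, outside Monte-Carlo error).

The contrast is scientifically useful: the robustness claim is a statement
about dichotomized monotone distortions of a shared latent scale, not about
arbitrary non-Gaussian dependence. Both variants are exposed so users can
decide which threat model fits their trait.

## The logistic-regression check

`logistic_adjusted_or()` regresses the index person's diagnosis on the
partner's and the sibling-in-law's phenotypes jointly. If assortment acts on
the *observed* phenotype, the sibling-in-law adds nothing once the partner
is in the model. One subtlety the test suite makes explicit: when assortment
acts on a continuous liability and only its dichotomization is observed,
conditioning on the partner's binary indicator is incomplete and a residual
sibling-in-law association remains even under direct assortment on the
liability — the binary indicator is then an imperfect proxy, which is
itself a form of indirect assortment for the indicator. Separation is
detected (divergent coefficients or non-convergence) and flagged.

## Open design choices

Where the analysis conventions were genuinely open, the package fixes them
as follows: correlations are estimated in separate bivariate models per
trait pair (not jointly across relationship types); both `birth_year` and
derived age are exposed as covariates, with `birth_year` used by the
pipeline's adjustment arm; couples where neither partner has a sibling
enter the quad likelihood through their bivariate marginal; and the
prospective-versus-established-couples contrast is realized as two
observation windows of one simulated population, the second after a
convergence overlay.

## Problem sizes and runtime

The test suite estimates on populations of 20,000–200,000 quads, sizes at
which Monte-Carlo error is small relative to the tolerances being checked
while the full suite stays inexpensive: the null distribution of the
direct-assortment LRT uses 500 replicates of 1,500 quads, the size check
100 replicates of 20,000, and the mechanism identities single populations
of 200,000. The acceptance script re-simulates each mechanism at 200,000
quads and finishes in well under a minute on one core.

## Limitations

Estimates of the IIF are ratios and become unstable when
$r_{partner} \cdot r_{sibling}$ is near zero; such cells are reported
missing rather than tested. The binary quad likelihood supports
low-cardinality (categorical) covariates only, since thresholds are shared
within covariate cells. The equality LRT treats the two windows as
independent samples; with overlapping couples it is anti-conservative. And
the simulators' Gaussian (or monotone-transformed Gaussian) liabilities
cannot represent traits whose dependence structure is itself non-Gaussian —
the innovation-skewed variant exists precisely to show where that matters.
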