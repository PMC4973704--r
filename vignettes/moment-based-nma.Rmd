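---
title: "Moment-based network meta-analysis with random inconsistency effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based network meta-analysis with random inconsistency effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlnma)
```

## The model

`dlnma` analyses contrast-level network meta-analysis data. A *design* is the
set of treatments a trial compares; all studies with the same treatment set
share a design. Study $i$ of design $d$ contributes a vector
$\mathbf{Y}_{di}$ of $c_d$ estimated effects (log odds ratios, standardized
mean differences, ...) of the design's non-baseline treatments relative to
its baseline (we take the lexicographically first treatment of each design as
its baseline, and the lexicographically first treatment in the network, $A$,
as the global reference). The model is

$$
\mathbf{Y}_{di} = \boldsymbol\delta_d + \mathbf{B}_{di} + \boldsymbol\Omega_d
  + \boldsymbol\varepsilon_{di},
$$

where $\boldsymbol\delta_d$ collects linear combinations of the $c$ *basic
parameters* $\delta^{AB}, \delta^{AC}, \dots$ (so consistency is assumed for
the *average* effects), and the three random components are independent with

* $\mathbf{B}_{di} \sim N(\mathbf{0},\ \tau_\beta^2 \mathbf{P}_{c_d})$ —
  study-level heterogeneity,
* $\boldsymbol\Omega_{d} \sim N(\mathbf{0},\ \tau_\omega^2 \mathbf{P}_{c_d})$ —
  a design-level *inconsistency* random effect shared by all studies of the
  design,
* $\boldsymbol\varepsilon_{di} \sim N(\mathbf{0},\ \mathbf{S}_{di})$ — the
  within-study error, with $\mathbf{S}_{di}$ fixed and known.

$\mathbf{P}_{c_d} = \mathbf{I} + (\mathbf{J}-\mathbf{I})/2$ (unit diagonal,
halves off-diagonal) encodes a common variance for every pairwise comparison.
Stacking all studies gives the marginal model
$\mathbf{Y} \sim N(\mathbf{X}\boldsymbol\delta,\
\mathbf{S} + \tau_\beta^2\mathbf{P}_1 + \tau_\omega^2\mathbf{P}_2)$, where
$\mathbf{P}_1$ is block diagonal by study and $\mathbf{P}_2$ block diagonal
by design ($1$ for two rows estimating the same contrast, $1/2$ for
different contrasts of the same design, $0$ across designs).

Inconsistency is thus treated as a second source of random variation; the
network is *consistent* exactly when $\tau_\omega^2 = 0$.

## Estimation

Both variance components are estimated non-iteratively by the method of
moments, from the decomposition of Cochran's network Q statistic

$$ Q^{net} = \sum_d Q_d^{het} + Q^{inc}, $$

where $Q^{net}$ is the weighted (weights $\mathbf{S}^{-1}$) residual sum of
squares about the GLS fit of the consistency mean structure, $Q_d^{het}$ is
the same statistic computed within design $d$, and $Q^{inc}$ is obtained by
subtraction (it is non-negative because the within-design fits nest the
network fit). Matching the two independent quadratic forms to their
expectations gives two linear estimating equations:

$$
\sum_d Q_d^{het} = \sum_d (n_d - 1) c_d + \hat\tau_\beta^2 \sum_d K_d,
\qquad
Q^{net} = \sum_d n_d c_d - c + \hat\tau_\beta^2\,\mathrm{tr}(\mathbf{BP}_1)
          + \hat\tau_\omega^2\,\mathrm{tr}(\mathbf{BP}_2),
$$

with $K_d = \mathrm{tr}\{\mathbf{B}_d(\mathbf{I}_{n_d} \otimes
\mathbf{P}_{c_d})\}$ and $\mathbf{B}$ (resp. $\mathbf{B}_d$) the usual
weighted-projection residual matrix. The first equation is solved for an
*untruncated* $\hat\tau_\beta^2$; that untruncated value is substituted into
the second, which is solved for an untruncated $\hat\tau_\omega^2$. The
untruncated estimators are exactly unbiased; for inference both are truncated
at zero (introducing a positive bias), the total variance
$\mathbf{V} = \mathbf{S} + \hat\tau_\beta^2\mathbf{P}_1 +
\hat\tau_\omega^2\mathbf{P}_2$ is treated as known, and

$$
\hat{\boldsymbol\delta} =
 (\mathbf{X}^T\mathbf{V}^{-1}\mathbf{X})^{-1}\mathbf{X}^T\mathbf{V}^{-1}
 \mathbf{Y},
\qquad
\mathrm{Var}(\hat{\boldsymbol\delta}) =
 (\mathbf{X}^T\mathbf{V}^{-1}\mathbf{X})^{-1}.
$$

When every study is a two-arm trial of a single design, the first estimating
equation is exactly the classical DerSimonian–Laird equation, so the
procedure is a strict extension of that method; the test suite verifies the
reduction to machine precision against an independently coded oracle and
against `metafor::rma(method = "DL")`.

### Model families and design choices

* **RI** (`nma_fit(net, model = "ri")`): both components estimated as above.
* **RC** (`model = "rc"`): consistency imposed, $\hat\tau_\omega^2 \equiv 0$.
  Two heterogeneity estimators are exposed. The default (`rc_estimator =
  "qnet"`) solves the network-level equation with
  $\hat\tau_\omega^2 = 0$, attributing the inconsistency sum of squares to
  heterogeneity — more precise when consistency really holds. The
  alternative `"qhet"` reuses the within-design equation, which makes an RI
  fit with $\hat\tau_\omega^2 = 0$ collapse exactly onto the RC fit; users
  who want that collapse property can opt into it.
* **CC** (`model = "cc"`): both components fixed at zero,
  $\mathbf{V} = \mathbf{S}$.
* **Loop-restricted inconsistency**: `p2_override` replaces $\mathbf{P}_2$
  (entries may only be zeroed, never invented across designs), restricting
  which designs share inconsistency effects; the fit reports the ratio
  $\hat\tau_\omega^2/\hat\tau_\beta^2$ for assessing its magnitude.

Other deliberate choices:

* *Truncation order.* Both equations are solved with untruncated values; the
  untruncated $\hat\tau_\beta^2$ is substituted into the second equation even
  when negative, and truncation happens only when $\mathbf{V}$ is formed.
* *Degenerate networks.* If every design has a single study
  ($\sum K_d = 0$) the heterogeneity variance is not identifiable and the RI
  fit stops with an identifiability error. If
  $\mathrm{tr}(\mathbf{BP}_2) = 0$ — exactly the case for single-design
  networks, where $\mathbf{P}_2$ lies in the span of the mean structure —
  the inconsistency variance is inestimable; the fit warns, flags
  `omega_inestimable`, sets it to zero and so degrades gracefully to a
  DerSimonian–Laird analysis.
* *Numerics.* All inversions go through Cholesky factorizations
  (`chol`/`backsolve`/`chol2inv`); an indefinite within-study covariance
  matrix fails loudly naming the study. Networks in this field are small
  (tens of contrasts), so the global matrices are dense; clarity is preferred
  over sparsity.
* *Normal quantiles.* Confidence intervals use standard normal quantiles
  throughout: the simulation engine's excess-kurtosis output shows both
  positive and negative values across the grid, so switching to a t
  distribution would not improve calibration uniformly.
* *Baselines and ordering.* Lexicographic byte order (C collation,
  locale-independent) defines treatment ordering, design baselines and the
  reference; studies supplied against a non-canonical baseline are
  re-expressed by the exact linear transform of `y` and `S`, which leaves all
  Q statistics and fits invariant (tested). A different reference may be
  requested; the basic parameters are then expressed against it directly.

## Further inference

* `generics::tidy()` / `generics::glance()` give the coefficient table and
  the one-row model summary; `nma_contrast()` propagates covariance to any
  linear combination of basic parameters.
* `nma_rank()` draws effect vectors from
  $N(\hat{\boldsymbol\delta}, \mathrm{Var}(\hat{\boldsymbol\delta}))$ with
  the reference effect pinned at exactly zero and tallies the full rank
  distribution. `direction` has no default because the beneficial sign
  differs by outcome; a silent default could invert every ranking.
* `nma_i2()` compares nested fits through
  $R = |\mathbf{C}_{num}\mathbf{C}_{den}^{-1}|^{1/2c}$, the $c$-th root of
  the confidence-region volume ratio, and
  $I^2 = (R^2-1)/R^2 \times 100\%$: RI vs RC isolates the impact of
  inconsistency, RC vs CC that of heterogeneity, RI vs CC their joint
  impact. Subsets of basic parameters use the corresponding submatrices with
  the reduced dimension.

Uncertainty intervals *for the variance components themselves* are out of
scope, as is REML/likelihood estimation; the method deliberately mirrors the
simplicity of the original two-step moment procedure.

## The simulation engine and what it emulates

`simulate_network()` and `run_simulation_study()` generate data exactly from
the model above:

* within-study variances are independent draws of $0.25\chi^2_1$
  rejection-sampled into $[0.009, 0.6]$ (inclusive bounds; the distinction
  is measure-zero) — the classic generator for log-odds-ratio sampling
  variances; $\mathbf{S}_{di} = \sigma^2_{di}\mathbf{P}_{c_d}$, i.e. equal
  variances and within-study correlation $1/2$, reflecting equal allocation;
* effects are drawn from the marginal model with true $\boldsymbol\delta =
  \mathbf{0}$ by default (variance estimation is location-invariant, which
  the tests verify);
* three built-in layouts over treatments A–D: `run1` (2 studies of each of
  ABC, ABD, AB, AC, AD; 14 effects), `run2` (10 of each; 70 effects) and
  `run3` (5 studies of each of all ten 2- and 3-arm designs; 70 effects);
* the grid $\tau_\beta^2, \tau_\omega^2 \in \{0, 0.024, 0.168\}$ spans none,
  mild and severe heterogeneity/inconsistency. Through the generator's
  Higgins–Thompson *typical* within-study variance
  ($\bar s^2 = (k{-}1)\sum w_i / \{(\sum w_i)^2 - \sum w_i^2\} \approx
  0.056$), the three $\tau_\beta^2$ values correspond to RC-vs-CC
  $I^2 \approx 0\%, 30\%, 75\%$. Note this correspondence is a statement
  about the typical variance: on networks whose $\sigma^2_{di}$ vary across
  studies, the volume-ratio $I^2$ converges instead to the
  information-weighted ratio $1 - E[1/(\sigma^2+\tau^2)]/E[1/\sigma^2]$,
  which is larger (about 45% and 80% at the two nonzero grid values).

One master seed spawns an independent sub-seed per grid cell, so any cell is
reproducible in isolation. Replicates whose fit fails are counted
(`n_failed`), never silently dropped.

The generator emulates the randomized-trial summary-data setting the model
assumes: normal within-study errors with *known* covariances, a common
heterogeneity variance for all comparisons, and design-level exchangeable
inconsistency. Real data violate all of these to some degree — estimated
(not known) within-study variances correlated with effect sizes, unequal
allocation, comparison-specific heterogeneity, and inconsistency
concentrated in particular loops — so passing operating-characteristic
checks demonstrate correctness of the implementation under the model, not
robustness of the method on arbitrary real networks. In particular the
method is known to understate uncertainty in small, highly inconsistent
networks because the variance components are treated as known.

### Problem sizes used by the packaged checks

The packaged operating-characteristic checks reproduce single grid cells at
the reference scale of 3000 replicates (mid-range coverage cells use
10000–12000 replicates so that the check's own binomial Monte Carlo error is
small against its tolerance), the full-grid unbiasedness check runs the
nine run-1 cells at 3000 replicates, moment-identity regressions use 600
replicates per grid point at fixed within-study covariances, and the I²
calibration uses ten networks of 100 studies per design. A single run-1
grid cell at 3000 replicates takes a few seconds on one CPU; the complete
27-cell study at full scale remains well within an hour.

## Known limitations

* Arm-based likelihoods (e.g. exact binomial) are not supported; normal
  approximations can dilute effect estimates when studies are small.
* No uncertainty statements for $\hat\tau_\beta^2, \hat\tau_\omega^2$
  (bootstrap is a practical route, not implemented here).
* Multi-arm studies that include the same treatment category twice are
  rejected rather than approximated.
* The ranking is for the average effects across all designs; ranking in a
  new study or design would need a predictive covariance that is not
  specified here.
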