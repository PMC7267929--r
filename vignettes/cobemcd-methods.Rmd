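---
title: "Methods: common-component extraction and maximal-dissimilarity subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: common-component extraction and maximal-dissimilarity subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cobemcd)
```

## The decomposition

Each run of a subject's resting-state scan is a parcellated matrix
$R_n \in \mathbb{R}^{P \times T}$ (regions × timepoints). The model is

$$R_n = \bar A \bar Y_n^\top + \hat A_n \hat Y_n^\top,$$

with $\bar A$ ($P \times C$, orthonormal columns) shared by all runs and
the second term run-specific. `cobemcd` solves this deterministically:

1. each (optionally row-demeaned) run is reduced to an orthonormal basis
   $Q_n$ of its leading column space, with the rank set per block either
   explicitly or by a squared-singular-value energy fraction;
2. the common directions are the leading eigenvectors of
   $M = \sum_n Q_n Q_n^\top$, obtained by one dense symmetric
   eigendecomposition. Column $c$ maximizes
   $\sum_n \lVert Q_n^\top a\rVert^2$ among unit vectors orthogonal to
   the earlier columns; the *fit score* $\lambda_c / N \in [0,1]$ equals
   1 exactly when the direction lies inside every run's retained
   subspace.

Because the solver is a dense eigendecomposition there is no random
initialization and no convergence failure mode; `tol` and `max_iter` in
`cobe_config()` exist for interface compatibility, with `tol` also used
for rank and tie decisions. Eigenvalue ties (e.g. several directions
common to all blocks) are reported via `eigen_gap_tied`, not an error:
the returned basis of the tied subspace is the solver's deterministic
choice. Run time courses are the least-squares coefficients
$\bar Y_n = R_n^\top \bar A$ computed from the *raw* runs, so
$R_n = \bar A \bar Y_n^\top + \text{residual}_n$ reconstructs exactly and
the squared Frobenius norms satisfy the Pythagorean identity; demeaning
(default on) affects only the estimation of the basis. Signs are fixed by
flipping each column so its largest-magnitude weight is positive —
between-subject correlations of components are sign-sensitive, so a
convention is mandatory.

### Tunable parameters

* `rank_policy` — default `energy = 0.99` per block. A full-rank block
  would make the common subspace degenerate (every direction "common"),
  so truncation is mandatory; 0.99 keeps band-limited structure while
  discarding the flattest noise directions. A `fixed = r` override
  exists; requests beyond the block's numerical rank are capped.
* `demean_rows` — default `TRUE`; components should reflect temporal
  covariation, not baseline offsets.
* `n_components` — C is user-specified, 1 by default (the analysis
  operates on first components). Asking for more components than the
  rank of $M$ names the achievable maximum in the error.

### Sequential extraction

Extracting $C=1$, deflating every run by the found direction
(`deflate_stack()`), and extracting $C=1$ again reproduces the one-shot
$C=2$ answer. This holds *for data that actually share a common
subspace*; for unstructured noise blocks the re-computed block bases
after deflation need not relate to the original ones and the property
fails by a wide margin. The tests therefore check it on instances drawn
from the decomposition's own model (a planted 2-dimensional common
subspace, block-specific components, light noise), which is its domain
of validity.

## Dissimilarity selection

The first common components of $S$ subjects are correlated (Pearson over
the $P$ weights) into an $S \times S$ matrix. `grow_dissimilar_set()`
seeds a set with a uniformly drawn pair with $|r| < \tau$ (strict, default
$\tau = 0.75$) and adds uniformly drawn qualifying subjects until none
qualify — so every returned set is maximal. `select_mcd()` repeats this
(default 1,000 restarts, one seeded RNG stream) and keeps the set with
the smallest within-set maximum $|r|$; ties go to the larger set, then
the lexicographically smallest id list, making results fully
deterministic under a seed. "Smallest maximum absolute correlation" is
interpreted within-set — the only reading consistent with per-set
construction. The CS group is the exact complement. Exhaustive
enumeration (feasible at $S \le 12$) is used as the test oracle for both
maximality and the min-max optimum; exact optimality at cohort scale is
not claimed (the problem has maximum-independent-set flavor).

## Group contrasts

Component weights are averaged per parcellation label (17 cortical
networks, hemispheres merged; 19 separate subcortical ROIs) and compared
between MCD and CS with a two-sided Welch t test per label, Bonferroni
over the number of labels present (36 by default). The behavioral
battery uses the same machinery over 69 measures. Welch was chosen
because the groups are strongly unbalanced and the reference analysis
reports mean ± SE (a mean comparison); a Mann–Whitney option exists for
ordinal purists. The sex contrast is a Pearson chi-square without
continuity correction (expected counts are large in the intended use;
Yates correction available). Degenerate labels/measures (both groups
constant and equal) return statistic 0, p = 1 with a warning flag rather
than an error. The RSSM control re-tests the flagged measures against a
uniformly drawn sex-matched CS subset; `n_draws > 1` additionally
reports the per-measure median p over draws.

## The synthetic world

The generator is a stated world, not a dial:

* **Maps.** A unit-norm template with elevated default-mode weights.
  Majority subjects get the template plus jitter (scale 0.1,
  renormalized); subgroup subjects get the template with its
  DMN-A-analog weights reduced by $\delta = 0.15$ plus a large
  idiosyncratic perturbation (scale 0.5, renormalized), making subgroup
  maps mutually dissimilar — the reference analysis observes
  dissimilarity but does not model its source, so idiosyncratic
  high-variance perturbation is this package's choice.
* **Template calibration.** Renormalization couples the planted effects:
  a subgroup map loses norm to the DMN-A reduction and gains norm from
  scatter, and any mismatch rescales *every* label's mean, leaking the
  effect outside DMN-A. The template height on DMN-A regions is
  therefore set in closed form so the two effects cancel at the default
  geometry: $2\delta n_A h - n_A\delta^2 = s^2 - j^2$, giving
  $h = ((s^2 - j^2)/n_A + \delta^2)/(2\delta) \approx 0.235$ at
  $P = 100$, with the remaining mass spread as a flat baseline (DMN-B/C
  at 1.4× baseline). Without this identity the stated property "the
  groups differ only in DMN-A" is unattainable for any non-sparse
  template. The template is fixed per parcellation and does not track
  configuration changes.
* **Runs.** $R_n = \sqrt P\, a y_n^\top + \sum_{j=1}^{k} \sqrt P\, b_{nj}
  u_{nj}^\top + \sigma E_n$ with $y, u$ zero-mean AR(1) time courses
  ($\phi = 0.9$, emulating the smoothness of band-pass-filtered BOLD
  without implementing the filter — what matters to the decomposition is
  rank structure, not spectra), $b_{nj}$ random unit vectors
  orthogonalized against $a$, and $E_n$ white noise. The $\sqrt P$
  amplitude gives component matrices entries of order one, so
  $\sigma = 0.5$ is directly the per-entry noise-to-component ratio. At
  these defaults the retained (0.99-energy) rank is ≈ 56 of 100, and the
  planted direction — the only one shared by all four runs — is
  recovered with $|\cos| > 0.95$ for ≥ 95% of subjects (measured ≈ 100%).
* **Behaviors.** Five planted measures carry the substance-use and
  antisocial group means reported for similarity/dissimilarity subgroups
  in large healthy cohorts (4.84 vs 10.11; 5.97 vs 18.05; 1.35 vs 4.59;
  0.53 vs 2.19; plus a small antisocial shift); the other 64 have equal
  means. The reported standard errors at the original cohort scale
  (n = 681/107) imply population sds under which these effects are
  statistically invisible at the desk-scale default cohort (16 vs 104,
  Bonferroni α/69). Since the stated world requires the planted effects
  to be detectable at defaults, sds were chosen once for that scale
  (standardized effects d ≈ 2.5–2.8) while keeping the planted means.
  Count-like measures are clipped at zero (simple and documented, not a
  zero-inflation model); clipping slightly skews low-mean null measures,
  which stays within the familywise Monte-Carlo envelope. Sex is drawn
  with the reported group-conditional male fractions (74/107 and
  323/681). An optional per-measure `sex_delta` builds sex-confounded
  scenarios for the RSSM control tests.
* **Determinism.** Each subject's map and runs come from
  subject-specific derived seeds, so a subject's data are invariant to
  cohort size and order; regenerating with the same config and seed is
  byte-identical.

What a green test does *not* establish: the generator has no
hemodynamics, motion artifacts, censoring gaps, spatial autocorrelation
within networks, or realistic behavioral distributions; majority maps
are exchangeable draws around one template rather than a continuum of
individual differences. Green tests establish that the machinery —
decomposition, selection, contrasts, control — behaves as specified on a
world with known truth, not that the scientific findings replicate.

## Numerical choices

* Orthonormality and reconstruction tolerances: 1e-8 / 1e-10 (relative).
* Rank decisions discard singular values below `1e-12 ×` the largest;
  the energy threshold is applied with a 1-ulp-scale slack so exact
  fractions (e.g. `energy = 1`) are not defeated by round-off.
* Correlation matrices are symmetrized and their diagonal pinned to 1
  after `stats::cor` (and after file round trips).
* Strict inequality $|r| < \tau$ throughout, matching "less than a
  threshold".
* Matrix text files are written at `%.17g`, so write/read round trips
  are lossless.
* RNG: Mersenne-Twister with inversion; functions that seed internally
  (`select_mcd`, `draw_rssm`, `generate_dataset`) save and restore the
  ambient RNG state.

## Null calibration

The familywise-error checks use the exchangeable null: $\delta = 0$
*and* subgroup scatter equal to majority jitter, so group labels carry no
information. ($\delta = 0$ alone leaves a variance difference between
groups — a different, non-null world.) Calibration batteries run on the
generator's true maps rather than re-extracted components: they test the
comparison machinery, and recovery is covered by its own criteria.

## Known limitations

* Exact min-max subset selection is not attempted at cohort scale;
  optimality is only verified against enumeration at small S.
* The per-block rank and demeaning conventions of the original analysis
  are unknown; energy 0.99 and row-demeaning are this package's defaults
  (both configurable).
* The 419-region lookup is a synthetic stand-in with even allocation of
  parcels to networks, not the real cortical parcellation.
* The dissimilarity-versus-behavior auxiliary analysis uses the mean
  absolute correlation to all other subjects as its per-subject
  "variation" proxy, and is labelled as such.
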