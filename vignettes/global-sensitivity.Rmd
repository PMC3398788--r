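---
title: "Global sensitivity analysis of kinetic signalling models with SignalGSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global sensitivity analysis of kinetic signalling models with SignalGSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SignalGSA)
```

## The problem

Kinetic models of cancer-related signalling pathways are chronically
under-determined: dozens of rate constants and protein abundances are fitted
to a handful of phospho-protein time courses, leaving many parameters poorly
identifiable, and the cells the conclusions are meant for vary biologically
around any fitted point. Local sensitivity analysis — derivatives at one
nominal parameter set — inherits both problems. Global sensitivity analysis
(GSA) instead perturbs all parameters simultaneously across a bounded space
and asks which of them *consistently* control a biologically meaningful
output across the whole ensemble of plausible network implementations.

SignalGSA implements one specific GSA pipeline for that purpose: Sobol
sampling of the parameter hypercube, paired no-drug/drug ensemble
simulation, an area-under-curve readout metric, partial rank correlation
coefficient (PRCC) profiles, a rank-concordance check of sample-size
adequacy, and rule-based interpretation of the paired profiles.

## The readout metric

A readout is a composite phospho-protein fraction
$y(t) = \sum_s x_s(t) / Y_{tot}$ — for the bundled fixture, phosphorylated
Akt over total Akt. Each simulated parameter set is summarised by

$$S_y = \int_0^T y(t)\,dt, \qquad S_{y,n} = S_y / S_y^{max}, \quad
S_y^{max} = T,$$

so $S_{y,n} \in [0,1]$ is the fraction of the theoretical maximum signal
(all protein phosphorylated for the whole window) actually produced — a
measure of total signalling exposure that is robust to the shape details
(dips, peaks, speed) of individual trajectories. The horizon defaults to
$T = 60$ min, long enough for a receptor-stimulated phospho-response to
develop fully; it is a `SimulationSettings` field, not a constant.

$S_y$ is computed by augmenting the ODE system with an auxiliary state
$dS/dt = y(t)$ integrated jointly with the model. The alternative —
quadrature on a fixed output grid — silently loses accuracy whenever a
sampled parameter set produces kinetics faster than the grid; with joint
integration the error tracks the solver tolerances instead, which is why
the acceptance checks can hold the AUC to $10^{-6}$ relative against closed
forms across three decades of time constants.

## The hypercube and its sampling

`buildParameterSpace()` encodes the standard boundary rules:

* kinetic constants: $[P/f,\; f\,P]$ around nominal with fold $f = 10$
  (an effective 100-fold range) — wide enough to imitate strong drug
  inhibition or activating/deactivating mutations;
* protein totals: an absolute 10–1000 nM window, the range into which most
  abundance estimates for receptor-pathway proteins fall;
* external compound doses (ligand, inhibitor) are excluded from the
  hypercube: they are controlled by the paired `Condition` objects;
* explicit per-parameter overrides win over both rules.

Within ranges, sampling is **log-uniform** (`u ↦ lower·(upper/lower)^u`).
This was a genuinely open design point: fold-symmetric ranges are symmetric
in log space, and a linear-uniform rule would put 90% of the sampling mass
in the upper decade, biasing the analysis towards high parameter values.
Rank-based statistics downstream are invariant to this choice *per
parameter marginal*, but the joint coverage is not, so the choice is made
once and documented here.

Points come from the deterministic (unscrambled) Sobol sequence, generated
with the Gray-code construction over Joe–Kuo direction numbers. The bundled
direction-number table covers 128 dimensions — several times the largest
model shipped with the package; larger models would simply need a longer
copy of the published table. The all-zeros first point is skipped by
default so no parameter starts exactly on its lower bound. An optional
randomisation for uncertainty replicates applies a seeded random digital
(XOR) shift per dimension, which preserves the base-2 net structure; full
nested (Owen) scrambling is deliberately not implemented, since the
replicates are used only to probe the stability of significance calls, not
to build randomised QMC error estimates.

## PRCC and its significance

For parameter $j$, all parameter columns and the metric are rank
transformed (average ties); $\hat P_j$ is regressed on all other
$\hat P_l$, $\hat S_{y,n}$ on the same set, and the PRCC is the Pearson
correlation of the two residual vectors. This removes the (rank-linear)
influence of every other parameter, so the coefficient isolates the
monotone association of one parameter with the output. Signs matter: a
positive pole parameter pushes the signal up, a negative pole parameter is
a brake.

The regressions use QR decompositions; constant columns are reported as
undefined (NA) with a warning and excluded as predictors rather than left
to produce rank-deficient designs. The implementation is checked in the
test suite against an independent algebraic route — partial correlation via
the inverse of the rank-correlation matrix — to $10^{-10}$.

Significance uses the standard $t$ approximation for a partial correlation
with $k-1$ controlled variables, $t = r\sqrt{df/(1-r^2)}$ on
$df = N - 2 - (k-1)$ degrees of freedom. At ensemble sizes of $10^5$ this
is far more permissive than a fixed $|r| > 0.05$ display cutoff; the
package reports computed p-values and leaves any magnitude cutoff
(`min_abs_prcc`) as explicit configuration of the classification step.
Raw p-values are reported by default; a Benjamini–Hochberg flag exists but
is off, since the method's interpretation step already imposes a magnitude
threshold.

PRCC presumes monotone parameter–output relationships.
`monotonicityCheck()` replaces visual scatterplot inspection with a
quantitative rule: metric ranks are averaged within ten quantile bins per
parameter, and a parameter is flagged when the bin-mean sequence shows both
a significant rise and a significant fall (successive-difference z-scores
beyond ±3). The z threshold trades sensitivity against false alarms from
binning noise; 3 standard errors keeps the false-flag rate negligible at
the ensemble sizes used here.

## Sample-size adequacy

Whether $N$ samples suffice is judged by ranking parameters by $|PRCC|$ at
successive sample sizes and computing the top-down coefficient of
concordance (TDCC) between consecutive rankings: Savage scores
$SS(r) = \sum_{i=r}^{n} 1/i$ weight the top of the ranking heavily, and the
TDCC is the Pearson correlation of the two Savage-score vectors (tied items
share the mean of the scores their positions span — the exact formula for
the two-ranking case is reconstructed here from the Savage-score
definition, and its properties are verified exhaustively for small $n$ in
the tests). Because the Sobol sequence is deterministic, each larger run
extends the smaller ones, so the whole scan costs one ensemble at the
largest $N$. The default scan sequence is the full-scale one
(5000 … 120,000); the desk-scale fixture scan uses 512–4096, where the
TDCC already saturates above 0.99.

## Interpretation rules

Given a no-drug profile and a drug profile, `classifyTargets()` applies
fixed rules with explicit thresholds (significance level $\alpha$, minimum
$|PRCC|$, and a $\Delta$ threshold on $|PRCC|$ gain, default 0.1):
drug targets are significant-positive without drug; susceptibility
biomarkers significant of either sign without drug; resistance biomarkers
significant-negative under drug; combination candidates
significant-positive under drug; acquired sensitivity is a $|PRCC|$ gain of
at least $\Delta$. The "upper part of the spectrum" and "poles" of a
colour-coded profile are thus operationalised as reproducible predicates
instead of visual judgement; 0.1 for $\Delta$ marks a shift clearly above
the sampling noise of the coefficients at the ensemble sizes used.

## Local sensitivity for comparison

`lsaSpectrum()` computes the classical one-at-a-time spectrum at the
nominal point: $C_i = [S(P_i + dP_i) - S(P_i - dP_i)]\,P_i\,/\,[2\,dP_i\,
S(P_i)]$ with $dP_i = 0.01\,P_i$, the normalised central difference
approximating $d\log S / d\log P_i$. The 1% step balances truncation
against solver-noise error; the acceptance checks verify the second-order
convergence (halving the step shrinks the error ~4×) and $10^{-4}$
agreement with symbolic derivatives on a closed-form model. Comparing LSA
and GSA spectra on the fixture shows the expected divergence: both agree on
the phosphoinositide pool and phosphatase totals, while receptor-level
parameters matter far more under the inhibitor in both views.

## What the fixture emulates — and what it does not

`makeReducedErbbModel()` is a 12-species, 28-parameter reduction of an
ErbB2/3-type network: ligand–receptor binding, inhibitor-blocked
dimerisation (the inhibitor competitively sequesters the ErbB2-like
receptor, mirroring an antibody mechanism), dimer-driven PI3K activation, a
PIP2/PIP3 cycle with Michaelis–Menten PI3K and PTEN arms, PIP3-dependent
Akt membrane recruitment, and PDK1/PP2A control of Akt phosphorylation.
Amounts are nM, times minutes; five conserved pools (both receptors, PI3K,
phosphoinositides, Akt) are declared and checked to $10^{-6}$ relative
along trajectories.

Its nominal values are design choices, tuned once so that construction
constraints hold: totals within the 10–1000 nM sampling window, a no-drug
pAkt fraction of ~0.34 at 60 min (inside the required (0.2, 0.8) band), a
drug-to-no-drug AUC ratio well under 0.8 at 100 nM inhibitor, silence
without ligand, and monotone AUC response to each protein total across its
10-fold range. They are *not* estimates for any cell line, and the fixture
deliberately omits the MAPK branch (whose parameters contribute little to
pAkt sensitivity in full-scale models of this family) — so Akt→Raf
crosstalk and any Erk readout are untestable here. Passing the fixture
pipeline therefore demonstrates that the machinery recovers a known
monotone sensitivity structure; it says nothing about fit to experimental
trajectories, which is out of scope for this package.

Analytic companions serve as oracles: `makeMonotoneBenchmark()` builds
closed-form monotone test functions with declared signs and a dummy
coordinate (default noise 0; the acceptance checks use noise 0.2, a
realistic output-noise scale relative to unit-scale effects);
`makeAnalyticAucModel()` provides one- and two-state models whose AUC and
logarithmic gains have closed forms.

## Numerical choices and degenerate inputs

* Solver: `deSolve::lsoda` with rtol $10^{-6}$, atol $10^{-9}$ nM —
  100-fold rate-constant spreads make parts of every ensemble stiff.
* Solver failures (non-convergence, non-finite states, non-finite
  parameters) are flagged per record, never raised; a sample with a failure
  in *either* condition is dropped entirely (complete-case rule), and the
  counts are reported in the table metadata. How the original full-scale
  analyses handled such failures is unstated in the literature this follows;
  complete-case exclusion with reporting keeps the PRCC inputs consistent.
* Negative states beyond $100 \times$ atol mark a run failed rather than
  being clamped — clamping would silently bias AUC metrics.
* The plausibility filter (default threshold 0.01 on the no-drug
  $S_{y,n}$) is evaluated on the reference condition only; drug-condition
  records of accepted samples are always retained.
* Ties: average ranks everywhere, including Savage scores; profile sorting
  breaks ties by input order so reports are byte-reproducible.
* SBML: the supported subset is a plain reaction ODE system — single unit
  compartment, species, global parameters, initial assignments, kinetic
  laws in arithmetic MathML; local parameters are promoted to prefixed
  globals, boundary/constant species become parameters. Events, rules,
  constraints and function definitions are rejected by name. Declared
  compartment sizes other than 1 are rejected rather than converted, since
  amount/concentration conversion is not implemented.

## Problem sizes

The bundled analyses use desk-scale sizes chosen once: ensembles of
$N = 4096$ Sobol points ($\times$ 2 conditions) for the fixture profiles
and target calls, a 512–4096 scan for TDCC saturation, $N = 2000, k = 6$
random instances for the PRCC oracle comparison, and 20 scrambled
replicates for significance-stability checks. Full-scale signalling studies
use the default scan sequence up to 120,000 points; nothing in the
implementation is specific to the small sizes.

## Known limitations

* PRCC is blind to non-monotone control; the monotonicity diagnostic flags
  such parameters but the pipeline offers no variance-based fallback.
* The fixture's inhibitor acts purely by receptor sequestration; drugs with
  intracellular mechanisms would need their own condition definitions.
* The t-approximation p-values assume approximately independent sampled
  columns; the Sobol design satisfies this well for the marginals used
  here, but strongly correlated (constrained) parameter spaces would need
  a permutation-based significance assessment.
* SBML import covers the subset above; models relying on events, rules or
  non-unit compartments are rejected rather than approximated.
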