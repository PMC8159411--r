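---
title: "Predicting chemoselectivity from conceptual-DFT reactivity indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chemoselectivity from conceptual-DFT reactivity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosel)
```

## Scope and model

NHC-catalyzed functionalizations of carbonyl compounds proceed through a
small set of interconverting active intermediates whose polarity the
additives (base, oxidant, protic media) can invert.  Each intermediate
opens a competing channel — amidation/ketolation, [2+n] cycloaddition,
[3+n] annulation — and `chemosel` predicts which channel dominates from
three ingredients, all of which are *inputs* (tables of orbital energies,
spin populations and relative Gibbs energies); no electronic-structure
calculation is ever run by this package.

1. **Global reactivity indices.**  For a species with frontier energies
   $E_H$, $E_L$: chemical potential $\mu = (E_H + E_L)/2$, hardness
   $\eta = E_L - E_H$, electrophilicity $\omega = \mu^2/2\eta$, and
   nucleophilicity $N = E_H - E_H(\mathrm{TCNE})$ with the
   tetracyanoethylene HOMO at $-0.38586$ hartree as the conventional
   zero.  All indices are reported in eV whatever the input unit, because
   that is how the field prints them.

2. **The $\omega + N$ barrier predictor.**  For a nucleophile/electrophile
   pair, stronger combined reactivity means a lower addition barrier.  The
   shipped calibration
   $\Delta G^\ddagger_p = 51.8 - 5.9\,(\omega + N)$ ($\omega+N$ in eV,
   $\Delta G^\ddagger_p$ in kcal/mol) is treated as an authoritative
   constant: the three calibration points behind it are not fully
   tabulated anywhere we can reach, so `published_model()` cannot be
   re-derived, only re-applied.  `fit_lfer()` exists for users
   calibrating their own reaction families.

3. **Profile ranking.**  Multi-step pathways are compared by an effective
   barrier and by product stability (details below).

## Interpretation choices that were genuinely open

**The predictor's unit annotation.**  The calibration is sometimes
written with an ambiguous "eV/23.1 kcal/mol" tag that could be read as a
division.  We read it as a unit annotation — $\omega+N$ in eV, the
predicted barrier in kcal/mol — because only that reading reproduces every
tabulated prediction (8.9, 6.7, 11.0, 14.7, 19.8 kcal/mol at sums 7.27,
7.65, 6.92, 6.28, 5.42 eV).

**Effective barriers are span-style.**  Tabulated pathway barriers
$\Delta G^\ddagger_{total}$ (31.0, 28.0, 24.5, 9.9 kcal/mol for the
flagship four channels) exceed the corresponding single-step barriers
(e.g. 24.5 vs 11.5 kcal/mol for the [3+2] channel), so they must
accumulate climbs from an upstream resting state.  We therefore define

$$\Delta G^\ddagger_{total} = \max_{\mathrm{TS}\ t}\Big[G(t) -
\min_{\mathrm{minima}\ m \prec t} G(m)\Big],$$

the energetic-span-style "worst climb out of any preceding resting
state", and record the maximizing (TS, minimum) pair.  The exact
resting-state convention behind the tabulated values cannot be confirmed
from available data; this definition is our documented interpretation,
and tests compare it only against its own brute-force enumeration oracle
and use the tabulated values in rank-based checks.

**Irreversibility.**  The product-selection rule needs a cutoff for "the
product lies far enough below the entry that re-crossing is negligible at
room temperature".  We default to 10 kcal/mol, boundary inclusive,
configurable in `classify_reversibility()` and `run_rank()`; the flagship
product at $-23.7$ kcal/mol and the reversible side wells are insensitive
to any cutoff in the 5–20 kcal/mol range.

**Temperature.**  Room temperature is implied but never stated by the
benchmark study; 298.15 K reproduces both of its ee conversions
(2.4 kcal/mol $\to$ 96.6% ee; 0.8 kcal/mol $\to$ 58.8 $\to$ 59% ee), so
298.15 K is the package default everywhere.

**Constants and rounding.**  Full-precision conversion constants
(27.211386 eV/hartree, 23.060548 kcal/mol/eV, $R = 1.98720425 \times
10^{-3}$ kcal/(mol K)) are used internally; the rounded 23.1 kcal/mol/eV
seen in print cannot reproduce the printed ee arithmetic.  Literature
comparisons round half-up (`round_half_up()`) to the printed precision —
one decimal for barriers and high ee values, integers for low ee values —
because R's default banker's rounding disagrees with how chemistry tables
are typeset.

**Parr-function conventions.**  $P^-_k$ comes from the vertical radical
*cation*'s atomic spin density, $P^+_k$ from the radical *anion*'s — the
standard definition.  The spin-population flavor (Mulliken vs NPA) is not
distinguished: the input simply carries `spin_density`.  Negative partial
spin densities are accepted; renormalization divides by the algebraic sum
(tolerance 0.05 on $|\Sigma - 1|$ before a provenance note/warning), and
`reactive_site()` takes the signed maximum, ties broken toward the lowest
atom index and flagged.

**Open-shell species.**  The package takes whatever $E_H/E_L$ the user
supplies and validates only gap positivity; it imposes no SOMO
convention, since none is established for the anionic intermediates in
this chemistry.

## The synthetic generator

Because no deposited orbital energies exist for these systems, the test
inputs come from a pi-only Hückel model: $H = \alpha I + \beta A$ over
the conjugated skeleton's adjacency matrix, defaults $\alpha = -11$ eV,
$\beta = -2.7$ eV (typical literature magnitudes), chosen once so that
synthetic $\omega$ and $N$ values span the realistic 0–8 eV window of the
real intermediates.  Neutral, even-atom, closed-shell systems give a
HOMO/LUMO pair; squared coefficients of the singly occupied orbital of a
vertical radical ion give exactly-normalized synthetic spin densities.
The random-skeleton generator draws labelled trees and optionally closes
one even ring, so every generated skeleton is alternant (bipartite) and
the pairing theorem and trace identity serve as independent oracles.

What this emulates: the *shape* of the data a quantum-chemistry run would
deliver (orbital ladders, normalized spin distributions, realistic index
ranges).  What it does not: real DFT orbital energies, heteroatom and
solvent effects, or any quantitative property of the actual NHC
intermediates.  Passing tests therefore certify the algebra and the
workflow, not agreement with real electronic structure — the benchmark
DFT energetics enter the suite only as fixed reference tables
(`reference_values()`), and every check against them is identity- or
rank-based.

## Numerical notes

- Profile validation enforces strict minimum/TS alternation, entry
  minimum at 0 (tolerance $10^{-9}$ kcal/mol), and a shared entry label
  across compared pathways.
- A profile without any transition state reports a zero effective barrier
  with a `barrierless` flag rather than an error.
- `fit_lfer()` requires $\ge 2$ non-excluded points with distinct
  abscissae, warns if the recovered slope has the "wrong" (positive)
  sign, and stores the slope as a magnitude under the subtraction
  convention $a - b(\omega+N)$ because that is how the calibrated line is
  written.  Excluded points must carry a reason (the precedent being a
  ring-strain-dominated four-membered-ring transition state) and are
  reported but never fitted.
- Predictions outside the shipped calibration window
  ($\approx$ 5.3–7.7 eV) are allowed but flagged `extrapolated`.
- Ranking ties (equal predicted barriers, e.g. two channels sharing an
  index sum) keep input order and are flagged rather than broken
  arbitrarily.

## Problem sizes in the test suite

Property-style tests use 200 random orbital pairs, 100 random alternant
skeletons of up to 14 atoms, 500 random alternating profiles of up to 15
stationary points, and a 50-point noisy calibration at $\sigma = 0.3$
kcal/mol — sizes at which the independent oracles (closed forms,
exhaustive enumeration, normal equations) are exact and the whole suite
runs in seconds.

## The command-line wrapper

The spec-level workflow (indices $\to$ predictor $\to$ ranking $\to$
product call) is scriptable via the thin Rscript at
`inst/cli/chemosel` with subcommands `indices`, `parr`, `fit`, `predict`,
`ee`, `rank`, `huckel`, `fixtures`.  Configuration is flags-only: with
every option already a flag and reports echoing their full configuration,
a separate YAML layer added surface without adding auditability, so it
was dropped.  Diagnostics go to stderr, results to stdout or files; exit
codes distinguish argument errors (2), validation errors (3) and partial
per-row failures (4).  Reports are versioned (`schema_version`) and
deterministic — identical inputs yield byte-identical JSON.

## Known limitations

- The single-gap ee model ignores Curtin–Hammett averaging over
  transition-state conformers and any temperature dependence of
  $\Delta\Delta G^\ddagger$.
- The LFER is a two-parameter empirical line calibrated within one
  reaction family; it knows nothing about ring strain (its one documented
  failure mode), sterics, or solvent, and extrapolation is flagged, not
  forbidden.
- Effective barriers assume pre-equilibrium access to every upstream
  minimum; a microkinetic treatment (out of scope) could disagree for
  profiles with slow early steps.
- The Hückel generator is a single-($\alpha,\beta$) homoatomic model —
  adequate as a data generator, not as chemistry.
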