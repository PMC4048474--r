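---
title: "Modelling telomere shortening, senescence and Werner's syndrome with telosim"
author: "telosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling telomere shortening with telosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosim)
```

## The model

Somatic cells lose telomeric DNA every time they divide: DNA polymerase
cannot complete the 5' end of each newly synthesized strand, so one end of
every fresh strand is `y` basepairs shorter than its template (the
end-replication problem).  When any telomere of any chromosome falls below
a critical length, the cell permanently stops dividing — it is senescent.
telosim is a Monte Carlo simulator of this process at two levels:

* a **chromosome model**, in which individual chromosomes divide
  independently, and
* a **cell model**, in which each cell carries `N = 46` chromosomes that
  replicate synchronously; the *shortest* telomere in the cell gates
  division, so cells senesce earlier and with much longer average
  telomeres than free chromosomes.

### State

A chromosome is a quartet of telomere lengths, one per strand end, written
`(top_left, top_right / bottom_left, bottom_right)`.  The row convention
carries strand orientation: the complement synthesized on the top strand
is incomplete at the *right* end, the complement of the bottom strand at
the *left* end.  A chromosome whose last replication eroded the right end
is in the canonical state `(m, n / m, n - y)`.

### Replication

One division of a non-senescent chromosome produces two daughters, each
keeping one parent strand as template:

* the daughter keeping the **top** template is
  `(tl, tr / tl, tr - y(tr))` — for a canonical parent this is *identical*
  to the parent;
* the daughter keeping the **bottom** template is
  `(bl - y(bl), br / bl, br)` — for a canonical parent, *shorter* by `y`
  at each newly copied end (quartet sums `S` and `S - 2y`).

A subtlety worth stating: iterating the canonical one-line rule literally
("copy the parent; erode the bottom-left entry") has a fixed point at
`(m - y, n - y / m, n - y)` and would stall erosion on that lineage
forever.  The strand-template form above is the physically consistent
iteration — it is the same rule applied after rotating the quartet 180°,
the two ends eroding in alternate generations — and it is what telosim
implements.  One consequence used in the tests: each division leaves
exactly one daughter equal to its parent, and the population mean telomere
length falls by `y/4` per generation while everything divides.

The per-replication loss and the division probability may depend on
telomere length:

```
y(n)     = y0 + y1 * n
P_div(n) = (a + b * n)^alpha ,   0 <= alpha <= 1
```

with the base clamped at zero before exponentiation and the result clamped
to `[0, 1]`.  `alpha = 0` gives case A (divide whenever possible);
`alpha > 0` gives case B, where cells that could have divided but drew not
to are classified "potential" rather than senescent.  `preset_case()`
carries the ten standard parameterizations (A1, A2, B1.1–B1.4, B2.1–B2.4),
all calibrated so that the expected loss `P_div(n) y(n)` is roughly 200 bp
per replication half-way to senescence (`n = 2975`), plus `zhang_fit`, a
cell-level parameterization fitted to published fibroblast data
(`y(n) = 10 + 0.043 n`, `P_div = (n/12200 - 0.03)^0.25`, starting from
12,200 bp; we start that preset from an all-12,200 quartet since only the
starting length is reported).

### Werner's syndrome

Werner's syndrome is modelled as an extra deletion of `x` basepairs that
occurs with probability `p_w` per chromosome replication, at one of four
strand/end positions chosen uniformly (right or left end of either
daughter; the left-end deletion of the shorter daughter compounds with the
end-replication loss).  `preset_werner()` holds the standard pairs — `p_w`
in 0.2–1 against `x` in 1000–200 — chosen so the expected extra loss
`x * p_w` is 200 bp per replication.  A deletion that would leave any
telomere at the deleted end below the feasibility floor is infeasible: the
chromosome, and with it the whole cell, does not divide that generation
(it is classified "potential" and may try again).  Two of the four
variants are infeasible for a chromosome whose eroding end has reached the
critical region, so such a chromosome fails to divide with conditional
probability 1/2 per Werner event.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 200 bp | senescence when any telomere is strictly below it |
| `werner_floor` | = threshold | feasibility floor for the extra deletions |
| `initial_quartet` | (6000, 6000, 6000, 5800) | starting state, mean 5950 bp |
| `chromosomes` | 1 / 46 | chromosome vs cell model |
| `passage_cap` | 200 cells | tracked sample after passaging |
| `max_generations` | 500 | generation budget per run |

Two readings of the critical length appear in the source material: a
threshold of zero (lengths measured above an absolute floor) and 200 bp.
Both are supported; 200 bp is the default, and the senescence test is
strict (`min < threshold`), so a telomere exactly at the critical length
may still replicate.  The feasibility floor for Werner deletions defaults
to the senescence threshold — "loss below the threshold blocks
replication" — which reduces to the absolute floor 0 exactly when the
threshold is 0; `replicate_werner()` exposes the floor directly for
boundary-state analysis.

## Simulation procedure

Each generation every tracked cell is classified: senescent cells are
retained unchanged; each non-senescent cell draws a uniform variate
against `P_div` of its mean telomere length; a cell that attempts division
samples one replication event per chromosome, divides only if every
chromosome's event is feasible, and allocates each chromosome's two
daughter quartets to the two daughter cells independently at random
(2^N allocations).  The tracked sample is then passaged: when it exceeds
200 cells a uniform subsample of 200 is kept, mimicking cell-culture
passaging.  Alongside the tracked sample a *notional* population size is
propagated as `N(g+1) = (1 + phi_div(g)) N(g)` from the sampled dividing
fraction, and population doublings are `pd = log2(N(g)/N(0))`; `pd`
equals `g` exactly while every cell divides, and saturates as divisions
cease.

A run stops when the tracked sample is fully senescent or the generation
budget is exhausted (runs are flagged `censored`, never silently
truncated).  Full senescence of the *chromosome* model is ultimately
sampling-driven: because every division leaves one daughter identical to
its parent, a small pool of dividing lineages persists until passaging
happens to drop them, which can take several hundred generations after
the bulk of the population has senesced.  The default budget of 500
generations covers the standard cases at default parameters; the slowest
Werner ensembles (`p_w = 0.6`) are run with a larger budget where full
senescence is required.  With `p_w = 1` and the threshold floor the last
lineages can become permanently division-blocked while every telomere is
still at or above the critical length; such runs reach a doubling plateau
(divisions cease) without ever satisfying the full-senescence criterion,
and are reported as censored with the plateau visible in the trajectory.

Reproducibility: one R RNG stream per run, seeded explicitly; replicate
`i` of an ensemble uses `base_seed + i - 1`.  Identical configuration and
seed give byte-identical output files.

## Ensembles and summaries

`run_ensemble()` aligns replicate trajectories on generation number
(extending senescent plateaus by their last value) and returns
per-generation ensemble means and standard deviations, a per-replicate
senescence table and its ensemble summary: the pd at which the first
senescent cell appears in the tracked sample (per-replicate
first-appearance, then averaged), the final pd at full senescence, and the
tracked-sample mean telomere length at that generation.
`ensemble_on_pd()` re-indexes trajectories on a common population-doubling
grid by interpolation, for doubling-indexed plots.  `telomere_histogram()`
bins per-cell mean or per-cell shortest telomere lengths (100 bp bins on
0–6000 by default — a reporting choice, not part of the model), and
`histogram_modes()` operationalizes "bimodal" as at least two
plateau-merged local maxima after zeroing bins holding fewer than two
cells.  `gompertz_fit()` fits the saturating growth law
`N = a exp(-b e^{-c t})` to population sizes by Levenberg–Marquardt least
squares on the log scale, with starting values from the linearization
`log log(a0/N) = log b - c t`.

## What the defaults emulate — and what they do not

The default configurations are the study conditions of the underlying
models: initial quartet (6000, 6000, 6000, 5800) bp (mean 5950; the
all-equal variant is selectable), constant loss 200 bp (case A1) or the
length-dependent variants of the preset table, threshold 200 bp, cap 200,
Werner pairs with `x p_w = 200`.  The simulator reproduces the qualitative
biology these models target — linear early decline of mean length at
`y0/4` per generation, a sharp transition to senescence in case A versus
a smooth one in case B, earlier senescence at much longer mean telomere
length in the 46-chromosome cell model, accelerated senescence with wider
length distributions under Werner deletions, and Gompertzian growth of
total cell number.  It does not model telomerase elongation,
recombination, cell death, asynchronous division, or sequence-level
detail; passing tests therefore say nothing about those processes in real
cells.

## Numerical choices

Telomere lengths are real-valued; nothing is rounded in state (length-
dependent losses like `n/30` are not integers), only at serialization
(6 significant digits).  Normal-aging losses clamp at zero; Werner
deletions never clamp — an infeasible deletion blocks the division
instead.  Ties and boundaries: senescence is strict (`<`), feasibility is
non-strict (`>=` the floor), and an exponent of zero yields division
probability 1 for any non-senescent cell.  The Gompertz fit requires at
least four positive sizes and reports non-convergence as an error rather
than returning a spurious optimum.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run reduced but structurally
identical versions of the reference experiments: 200-replicate
chromosome-level ensembles (against 2000-replicate reference curves) and
50-replicate cell-level ensembles (against 1000), sizes at which the
ensemble standard errors of the reported summaries are well under the
tolerances being checked.

## Known limitations

* The sampling-driven extinction of the last dividing chromosome lineages
  makes "time to full senescence" and the population composition at that
  moment sensitive to the passaging rule; the reference experiments used a
  passaging procedure whose details are not fully specified, and our
  uniform-without-replacement subsampling reproduces final doubling counts
  well while yielding a longer senescent tail (and hence a lower tracked
  mean length at the extinction generation) for the chromosome model.
* First-appearance times of senescent cells are reported per replicate and
  averaged; reading them instead as the departure point of ensemble-mean
  fraction curves gives systematically earlier values.
* The `p_w = 1` Werner regime ends in division-blocked rather than
  senescent populations under the threshold feasibility floor (see above).
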