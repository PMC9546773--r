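---
title: "Fitting sequence-recognition models to selection-and-sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting sequence-recognition models to selection-and-sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probefit)
```

# The generative model

`probefit` treats an affinity-selection experiment as three stacked
layers.

**Binding layer.** A probe is a variable region between constant flanks.
Each binding mode `a` (one protein species) slides a footprint of `L_a`
positions along the probe — on both strands for double-stranded DNA,
optionally reaching `f_a` letters into the flanks — and assigns every
window `S_x` an energy score `beta_a . X(S_x)` in units of `-ddG/RT`,
where `X` is a binary feature indicator vector: one feature per
(position, letter), plus optional (position pair, letter pair) couplings
(adjacent pairs by default; all pairs by configuration). The partition
function over bound states is the non-specific term plus
activity-weighted window sums plus, for doubly-bound configurations, a
cooperativity factor `w(d, orientation)` indexed by the spacing `d`
between the two forward-frame window starts and by whether the two
windows lie on the same strand. `w = 1` is independence, `w > 1`
cooperativity, `w = 0` a forbidden configuration. At most two proteins
are bound at once; higher-order terms are out of scope.

**Assay layer.** Selection maps `Z` to relative probe frequencies.
Cumulative rounds multiply the previous round's frequency by
`Z^rho (1+Z)^gamma`: `(rho, gamma) = (1, 0)` is the low-concentration
linear limit, `(1, -1)` adds binding saturation. Non-cumulative columns
derive each library directly from the input with per-column exponents —
the input/bound/free design uses `rho = (0, 1, 0)`,
`gamma = (0, -1, -1)`, making the bound factor `Z/(1+Z)` and the free
factor `1/(1+Z)`, i.e. the equilibrium binding probabilities with
`Z = [P]_F/K_D`. Kinetic columns select the surviving (`e^{-Z}`) or
converted (`1-e^{-Z}`) fraction of a constant-rate reaction; the two
limits are encoded exactly as `delta = +Inf / -Inf`, they always sum to
one, and we implement them (not a finite-`delta` approximation) because
assays sequence the separated fractions. Kinetic columns reference the
input (each fraction derives from the same reaction), which is the
reading consistent with fraction-sequencing designs.

**Sequencing layer.** Counts are Poisson with mean `eta_r f_{i,r}`;
profiling out each probe's input frequency analytically turns the
likelihood into a multinomial across columns,
`sum_i sum_r k_{i,r} log p_{r;i} / k_total` with
`p_{r;i} = eta_r f_{i,r} / sum_r' eta_r' f_{i,r'}`. Two consequences are
load-bearing: only observed probes enter the sum (no enumeration of the
sequence space), and the likelihood is invariant to the input-library
composition, so the input need not be random. Multiple experiments add
their log-likelihoods; coefficients can be shared across experiments,
activities can be free, constant across columns, or tied globally with a
fixed per-experiment scale (protein concentration, or exposure time for
kinetic assays), and probes can be transliterated per experiment (e.g.
`CG -> cg`) so chemically modified and unmodified pools are scored by one
model over an extended alphabet.

# Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `L` | footprint length (positions) | 8 | typical transcription-factor core site; the greedy search adjusts it |
| `f` | flank depth (letters) | 0 | flanks contribute only when the design places binding sites near the variable-region edge |
| `strands` | strands scored | 2 | double-stranded DNA; 1 for RNA/peptides |
| `rho`, `gamma` | selection exponents | 1, 0 | low-concentration enrichment; `gamma = -1` under saturation |
| `lambda` | L2 weight | 1e-6 | numerical stabilizer only; no default is prescribed by the model, so it is exposed in the configuration |
| `k_dirichlet` | pseudocount weight | 0 | 20 is the standard choice for couplings-free fits; for coupling fits use `select_dirichlet_weight()` (grid 0–2000, stabilization at adjacent-weight `r^2 > 0.8`) |
| `theta_max` | barrier location | 40 | keeps `exp()` far from overflow without constraining any realistic fit |
| seed scale | SD of random coefficient seeding | 0.01 | start near the non-specific null so the activity heuristic is meaningful |

Positive quantities (activities, cooperativities, depth normalizers) are
parameterized in log space; `eta` of the first column is gauge-fixed to 1
per experiment because only ratios are identifiable. Cooperativity grids
are structural: cells beyond `max_spacing` and closer than the clash
distance are exact zeros, not parameters. The default clash forbids only
exact overlap (`d = 0`); no finer steric rule is imposed because none is
identifiable from counts alone.

# Optimization

Modes are added sequentially. Each addition runs seven substeps:
activity heuristic (the new term is scaled to contribute about 5% of the
current mean `Z_bound`, computed on the full observed table), freeze all,
release/optimize `eta`, release/optimize the new mode's monomer
coefficients (the cooperativity grid for an interaction), greedy
exploration of frame shifts, footprint lengths and flank depths,
release couplings and position bias, release everything and polish. The
inner solver is L-BFGS (`stats::optim`) with analytic gradients for every
parameter class — monomer and coupling coefficients, activities under all
tie structures, cooperativities, position bias and depth normalizers —
verified against central differences in the test suite. Inner-solver
settings default to 500 iterations and a projected-gradient tolerance of
1e-6 (the optimization scheme itself does not prescribe these). The
greedy search accepts a candidate geometry only if it improves the
penalized objective by more than 1e-7, breaking ties toward the smaller
footprint and then the smaller flank depth (parsimony); it terminates at
the first round with no improving candidate, making it a fixed point at
an already-optimal geometry. Reverse-complement-symmetric modes are
maintained by projecting both the coefficients and their gradients onto
the symmetric subspace, so the constraint holds exactly through every
substep. Line searches that momentarily overflow are fed a large finite
penalty rather than `-Inf`; the kinetic survival branch computes its log
factor as `-Z` analytically so deep depletion cannot underflow.

# Gauge fixing and reporting

Models with pairwise couplings are over-parameterized. The exact
invariant transform adds `A` to the monomer coefficient of letter `n` at
position `x2` while subtracting `A` from every coupling `(x1, x2, *, n)`:
whenever `n` occupies `x2` exactly one coupling at `(x1, x2)` is active
and cancels the monomer change, so every sequence's score is unchanged
(`gauge_shift()`, tested exhaustively over short sequences to 1e-12). For
reporting we canonicalize to the mismatch gauge: relative to the
reference (consensus) sequence, reference-letter monomer coefficients are
zero and couplings vanish whenever either end carries a reference letter,
so single- and double-edit effects are directly readable. The map
preserves all score differences exactly and is idempotent. Information
content converts per-position Boltzmann weights to probabilities against
a uniform background over the alphabet — including for extended
(methylation-aware) alphabets, where no standard background exists and
uniform is the explicit choice.

Recovery of a ground-truth model is reported two ways. The squared
Pearson correlation of gauged coefficients (strand-flip aware: with
both-strand scoring a mode and its reverse complement are physically
identical) measures whether the *pattern* of energies is right. The
agreement (coefficient of determination about the identity line) is
stricter: gauged coefficients carry absolute RT units, so a compressed
energy scale — the signature of un-equilibrated binding kinetics —
lowers agreement while leaving the correlation high. The kinetic
robustness analysis below relies on this distinction.

# Absolute affinities and catalytic efficiencies

`kdseq_fit()` fits the three-fraction design with activities constant
across columns, recovers the net bound DNA fraction from the fitted depth
normalizers (`p(B) = (k_B/k_I)(eta_I/eta_B)`), corrects for free-protein
depletion (`[P]_F = [P]_T - [DNA]_I p(B)`), and reports per-sequence
`K_D = [P]_F/Z` in concentration units. Titration diagnostics report the
bound-protein fraction and warn at 5% (error level at 10%), the regime in
which the assay should be repeated at lower DNA concentration. The
simulator solves the coupled equilibrium for `[P]_F` by the secant method
on the bracket `[0, [P]_T]` with a bisection fallback and a relative mass
residual below 1e-9, then samples the three libraries multinomially; the
default input base composition (28.8/26.5/14.4/30.3% A/C/G/T) matches a
typical slightly AT-rich random pool. Sequence spaces up to length 12 are
enumerated exactly; longer designs use a seeded random library with
recorded composition.

`keff_fit()` maps the same machinery onto enzyme kinetics: for each
exposure time the unmodified and modified fractions are the kinetic
branches of `Z = k_eff E t`, activities are tied to exposure time (one
global efficiency scale) or left free per time point — the latter serves
as an internal consistency check, since recovered activities should come
out proportional to time. The assumption that the time-averaged enzyme
concentration equals the total is surfaced in the documentation: a lower
free concentration rescales all efficiencies globally without touching
their sequence dependence. A fixed central residue (e.g. the tyrosine of
a phosphosite library) is implemented as a frozen zero column.

# What the simulators do and do not emulate

The generators draw read counts multinomially from the exact model
frequencies: they emulate selection, fraction splitting and sequencing
depth, with reproducible per-column seeds and ground-truth digests stored
in the table metadata. They deliberately do not model PCR amplification
bias, jackpotting, sequencing errors, overdispersed count noise,
cross-well contamination, or probe-synthesis artifacts — none of which
appear in the likelihood either. Passing recovery tests on simulated data
therefore demonstrates correctness and identifiability of the estimator
under its own assumptions, not robustness to the full artifact spectrum
of real libraries; the dataset filter (`kl_enrichment_filter()`) and the
mode-quality score exist precisely because real data violate these
assumptions.

Study conditions used by the test suite and the acceptance script (sizes
chosen as the smallest that leave comfortable statistical margins):
selection recovery uses an 8-nt variable region (fully enumerable,
65,536 sequences), two selection rounds at 1e5 reads per round, and a
random 8-position energy matrix with per-position coefficient SD 1.0
(about 1 RT — a typical specific factor). The equilibrium-affinity
simulations use the AT-rich composition above, strongest-probe
`K_D = 20 nM`, `[P]_T = 100 nM`, `[DNA]_I = 20 nM` and 2-3e5 reads per
library: conditions where the strongest probes approach saturation while
the library median stays far above `[P]_T`, so titration diagnostics
pass. The kinase simulations use 5-residue peptides with a fixed central
tyrosine, ~2,000 distinct substrates, exposure times 5/20/60, and an
efficiency scale putting the median substrate near half-conversion at the
last time point.

# The kinetic robustness analysis

To ask how long an equilibrium-analyzed binding reaction must incubate,
the simulator replaces the equilibrium bound probability with the
pre-equilibrium solution under a diffusion-limited on-rate (sequence
specificity carried entirely by the off-rate):

    p(B|i, t) = [P]_T/([P]_T + K_D,i) * (1 - exp(-koffmin_t (K_D,i + [P]_T)/K_D,min))

with `koffmin_t = k_off,min t` the incubation time in units of the
slowest off-time. Short incubations suppress precisely the high-affinity
probes (small `K_D`, small exponent), compressing the top of the energy
scale while leaving the equilibrated bulk intact. Pearson correlation of
recovered coefficients is blind to this compression (it stays above 0.99
even at `koffmin_t = 0.001`); the agreement R^2 in absolute RT units is
not, and under the conditions above it crosses 0.95 exactly at
`koffmin_t = 0.1` (about 0.55 and 0.94 at 0.001 and 0.01), with large
margins on both sides and stability across seeds. The closed-form
equilibration time `t_eq = 1/(k_off (1 + [P]_T/K_D))` explains the
robustness: the probes that must be saturated for a successful assay are
exactly the ones that equilibrate faster than `1/k_off`.

# Numerical choices and degenerate inputs

Probes whose predicted frequency is zero while their count is positive
raise an error (the model is degenerate there) rather than returning
`-Inf`. Empty window sets (footprint longer than the probe) are legal and
contribute nothing. Reads containing out-of-alphabet symbols are dropped
and counted, never imputed; reads of unexpected length are likewise
dropped when a design length is declared, since padding would fabricate
sequence. Downsampling is shuffle-and-truncate with a recorded seed.
Binned diagnostics break ties by probe order so bin boundaries are
deterministic. The saturation-transform fit uses five random starts with
log-parameterized positive parameters; its detection floor `y_bg` is the
smallest signal whose called set stays within the 5% false-discovery
bound against the predicted-bound set, and a flat signal yields the
defined floor `MAFR = 1`.

# Known limitations

Cooperativity evaluation enumerates window-pair blocks and is intended
for the probe lengths where dimeric geometry is identifiable (tens of
bases), not for kilobase fragments. Overdispersion is not modeled — the
likelihood is exactly multinomial. The `delta` parameter of the kinetic
family is structural, not fitted. Three-or-more-body cooperativity is out
of scope. The information-content background for modified alphabets is
uniform by convention. Absolute efficiencies from `keff_fit()` inherit
the free-enzyme assumption above.
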