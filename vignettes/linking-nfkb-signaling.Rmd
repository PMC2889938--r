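---
title: "Methods: linking NF-κB signaling to gene responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking NF-kB signaling to gene responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models it
implements, the assumptions behind them, the tunable parameters that matter,
the numerical decisions taken where the design was genuinely open, and the
limits of what the test suite demonstrates.

# Overview

`nfkblink` connects three computations into one inverse-modeling loop:

1. **Reverse engineering**: Network Component Analysis (NCA) reconstructs the
   time-varying activity of NF-κB (and any other modelled TFs) plus gene-wise
   influence strengths from log-ratio expression time courses and a known
   regulatory topology.
2. **Forward engineering**: a mass-action kinetic model of the IKK–IκB–NF-κB
   module maps a candidate time-varying IKK input to a nuclear NF-κB
   concentration profile.
3. **Linking**: candidate IKK profiles are scored by the Pearson correlation
   between their simulated NF-κB profile and the NCA-reconstructed one; the
   best-correlated candidate is the inferred upstream input.

# Network Component Analysis

## Model and assumptions

Gene expression is modelled log-linearly: the log-ratio of gene *i* at column
*j* (a condition–time pair) is `E[i, j] = sum_k S[i, k] * A[k, j]` with
`S[i, k] = 0` unless TF *k* is a known regulator of gene *i*. The package
treats `A` as log-scale activity so that the bilinear model is exactly linear
in the measured log ratios — the conventional NCA reading. Expression values
are log₂ ratios (the microarray convention); any logs taken internally (the
simulated-concentration transform below) are natural logs, and no conversion
between the two is needed anywhere because Pearson correlation is invariant
under positive affine maps.

Multi-dose experiments are fitted **jointly**: the per-condition matrices are
concatenated column-wise (`concat_conditions()`) and one shared `S` is fitted
across all conditions. This is what makes the relative inter-dose amplitudes
of the reconstructed activity meaningful; per-condition rescaling of `A` is
deliberately *not* applied at fit time.

## Identifiability

`check_identifiability()` verifies the three standard conditions on the
support pattern: full column rank of `S`; full column rank `K − 1` of the
submatrix left after deleting any TF's column and its regulon's rows; and at
least `K` data columns. Because these are generic-rank properties, they are
tested numerically: the support is filled with independent standard-normal
draws (5 fills, fixed seed) and the rank is taken as the maximum over fills,
with the usual SVD tolerance. A single random fill already has the generic
rank with probability one; the repeats guard against an unlucky
near-singular draw.

## Solver

The paper-level description of NCA fixes the problem, not the algorithm; the
package uses the standard alternating-least-squares solver because it is
deterministic given a seed and respects the support exactly:

* initialise the non-zeros of `S` from standard normal draws;
* **activity step**: `A ← argmin ‖E − S A‖_F` (ordinary least squares; the
  columns decouple);
* **strength step**: for each gene row, restricted least squares on its
  supported entries only;
* stop when the relative decrease of the residual `‖E − S A‖_F / ‖E‖_F`
  falls below `tol`.

Each half-step solves its subproblem exactly, so the residual is
non-increasing by construction — this is asserted per iteration in the test
suite. Defaults: `tol = 1e-8`, `max_iter = 1000`, `n_restarts = 5`
(restart *r* is seeded with `seed + r − 1`; the lowest-residual restart
wins). Rank-deficient normal equations fall back to a tiny ridge
(`λ = 1e-10`) with a warning; a non-finite residual is an error. The zero
matrix is handled as an explicit degenerate case (`A = 0`, residual 0).

The scale/sign indeterminacy `S A = (S D)(D⁻¹ A)` is resolved by the
**positive-peak, max-1 convention**: each activity row is sign-flipped
(together with its `S` column) so its largest-magnitude entry is positive,
then scaled so its maximum is exactly 1. This matches the normalisation the
linker applies anyway, is idempotent, and leaves the product unchanged to
machine precision.

Edge signs in the network file are advisory (used by the generator and for
reporting); the fit is not sign-constrained, since nothing in the underlying
method description calls for constrained estimation.

## Filtering

`filter_expressed()` removes genes whose maximum |log₂ ratio| never reaches
`min_abs_logratio` (default 1.0, i.e. two-fold), then drops their edges and
any TF left without a regulon. The original gene-selection rule that reduced
the curated 87-gene network to 54 genes is not recorded anywhere usable, so
this threshold is a configurable stand-in, not a reproduction of that rule.

Missing values fail validation by default; an explicit `drop_na_genes` flag
enables gene-wise removal. Gene and TF identifiers are matched by exact,
case-sensitive string equality — alias resolution against curated databases
is out of scope.

# The kinetic module

## Structure

The bundled model (`inst/extdata/nfkb_module.yaml`) has 24 species and 72
reactions in two compartments:

* free NF-κB in cytoplasm and nucleus (2);
* free IκBα/β/ε protein in both compartments (6) and their transcripts (3);
* IκB:NF-κB complexes in both compartments (6);
* clamped IKK (1), IKK:IκB (3) and IKK:IκB:NF-κB (3) complexes.

Reaction types and their arities: association (2→1), dissociation (1→2, or
1→1 when the reaction is *catabolic* — the IκB part of a complex is
proteolysed and only the surviving partner is released), cross-compartment
transport (1→1), synthesis (0→1, optionally driven by a template species),
and degradation (1→0, optionally catalysed). Catabolic dissociations are the
standard representation of IKK-triggered and basal IκB proteolysis within
complexes; without them the module cannot be both biologically faithful and
closed over this species inventory. The model follows the canonical
asymmetry of the NF-κB system: only IκBα transcription carries the
NF-κB-inducible feedback term, IκBβ and IκBε are constitutive — which is
also what makes the reaction count per isoform asymmetric (24/23/23 plus the
two shared NF-κB shuttling reactions).

IKK is the **clamped input**: its concentration is imposed by the supplied
profile at every time and its own mass balance is external to the model.

## Rates, volumes and conservation

Every reaction is mass action: flux `= k × Π reactant concentrations`
(× the modifier concentration for template synthesis and catalysed
degradation). Concentrations are per-compartment; cross-compartment
transport flux is defined in the source compartment and scaled by the
nuclear/cytoplasmic volume ratio `kv` on the receiving side
(`/kv` entering the nucleus, `×kv` leaving it), so that volume-weighted
amounts balance. Default `kv = 0.2` (cytoplasm ≈ 5× the nuclear volume).

Declared moieties are verified at load time: the member vector, with nuclear
members weighted by `kv`, must lie in the left null space of the effective
stoichiometry matrix to 1e−9. The shipped model declares one moiety — total
NF-κB over free and complexed forms in both compartments — which is exactly
conserved because the model contains no NF-κB synthesis or degradation.
IκB totals are deliberately *not* declared: they have synthesis and
degradation and are not conserved.

## Parameters

No usable rate-constant table is printed for this module in the source
material; the shipped constants are order-of-magnitude values from the
published Hoffmann (2002) / Lipniacki (2004) family of NF-κB models
(fast IκB–NF-κB association ~1800 µM⁻¹h⁻¹, free-IκBα half-life tens of
minutes, fast nuclear import of free NF-κB, fast export of the nuclear
IκBα:NF-κB complex, IKK-complex catabolism strongest for the α isoform),
in hours and µM-like arbitrary units, with total NF-κB ≈ 0.1 µM. They were
chosen once, when the model was built, to reproduce the qualitative response
the module is known for — a resting cell with most NF-κB sequestered in the
cytoplasm, rapid nuclear accumulation on IKK activation, and IκBα-feedback
-driven post-peak decline — and every quantitative claim the package makes
about kinetics is structural (species/reaction counts), qualitative
(pulse shape, input-scaling monotonicity), conservation-based, or
self-consistent (the same model is used forward and inverse). The YAML file
is the single source of truth; users can supply their own.

## Integration

`simulate_model()` integrates with `deSolve::lsoda` (stiff-capable),
defaults `rtol = 1e-8`, `atol = 1e-12`, at ≥ 201 output points plus all
profile knots. Before stimulation the model is relaxed to its resting steady
state under the basal input (`equilibrate_model()`: repeated 400 h blocks
until `max |dy/dt| < 1e-9`), because the stimulus response is only
meaningful from a self-consistent resting cell. Trajectories are checked for
negativity beyond integrator tolerance; the conservation and
tolerance-halving convergence properties are asserted in the test suite.
The matching stage equilibrates once per distinct basal value and reuses the
resting state across all candidates.

The model can be exported as SBML Level 3 (mass-action kinetic laws, clamped
species as boundary conditions) for interoperability; import is out of scope.

# IKK profiles and the inverse search

Candidate inputs are continuous piecewise-linear curves over the knot set
{0, 0.5, 1, 2, 4, 6, 12} h. The 1 h knot is included although expression
grids omit it: the kinase-assay sampling it mirrors had it, and it gives the
inverse search freedom in the early response where the dynamics are fastest.

`generate_candidates()` renders a parametric family — linear rise from basal
to a peak height at a peak time, geometric decay per subsequent knot, and an
optional additive second wave at a chosen knot — rather than free per-knot
enumeration, which blows up combinatorially. Free profiles remain available
through direct `ikk_profile()` construction. The granularity of the original
search is unrecorded; the default grids here (4 peak times × 3 heights × 3
decays = 36 candidates) are an engineering choice sized so that neighbouring
candidates are distinguishable by their simulated responses.

## Normalisation and scoring

The NCA activity row of one condition is normalised to a unit maximum. The
simulated nuclear NF-κB series is converted to `ln(c_j / c_0)` — a log ratio
to the resting value, because that is the scale of the expression data the
NCA activities live on — with a floor `ε = 1e-6 ×` total NF-κB moiety
guarding `log(0)`, then normalised to a unit maximum when possible. Both
exact normalisation equations are unrecoverable from the source text; this
composition is the natural one, and because Pearson correlation is invariant
under positive affine transforms, the *ranking* of candidates provably does
not depend on it (asserted as a property test).

The winner is the candidate with maximal r; exact ties break toward the
smaller IKK time integral (parsimony), then candidate order. The comparison
grid includes t = 0 by default; `drop_t0 = TRUE` reproduces the five-point
variant that starts at 0.5 h — both appear in the method's own description,
so both are provided. An optional Nelder–Mead polish of the winner's knot
heights is available and off by default. A flat simulated profile makes a
candidate unscorable (excluded with `NA`); a flat target is an error.

# The synthetic-data generator

`gen_nca_instance()` draws a support with exactly the requested number of
edges (every gene regulated, every TF covered, resampled until it passes the
identifiability check), log-normal strength magnitudes (σ = 0.4 on the log
scale) with Bernoulli signs (80% activating), smooth gamma-shaped activity
pulses `(t/t_p)² exp(2(1 − t/t_p))` peaking at a chosen grid point, and adds
i.i.d. Gaussian noise (default σ = 0.1 log₂ units) to `S A`. Defaults mirror
the layout the pipeline targets: 54 genes, 77 edges, 3 TFs, three dose
conditions on the 0/0.5/2/4/6/12 h grid, with dose-scaled NF-κB amplitudes
(0.6, 0.8, 1.0) — under a 100-fold nominal dose range the peak activities
deliberately differ by well under 50%, the compressed dose response this
system shows. `gen_end_to_end()` replaces the NF-κB pulse by the forward
simulation of a known IKK input, closing the loop. Generation is
deterministic given the seed (asserted bit-exactly).

What the generator does **not** emulate: probe-level microarray noise,
platform/batch effects, correlated gene-specific noise, unmodelled
regulators and combinatorial promoter logic, or errors in the regulatory
topology itself. Passing closed-loop tests therefore demonstrates the
pipeline's internal consistency and numerical correctness — not that a real
biological experiment would satisfy the log-linear NCA model or the bundled
kinetics to the same fidelity.

# Numerical choices and degenerate inputs

* SVD-based rank with tolerance `max(dim) · eps · σ_max` everywhere a rank
  is needed.
* ALS convergence on *relative* residual decrease; residual history kept and
  checked monotone.
* Zero expression matrix → exact zero decomposition, 1 iteration; all-zero
  activity rows are an error in normalisation (nothing to scale).
* Zero-variance series: an error in `pearson_cc()` (distinct from `NA`
  propagation), a warned `NaN` in `gene_tf_correlation()`, candidate
  exclusion in matching.
* Piecewise-linear evaluation via `findInterval` is exact at knots; basal
  outside the span.
* Equilibration failure (no steady state within 4800 h) and integrator
  failure are hard errors carrying the failing time.

# Problem sizes in the tests

The suite runs the full study-scale loop (54 × 18 expression matrix, 36
candidates, three conditions) once and reuses the cached candidate
simulations; Monte-Carlo calibration of the closed loop uses 20 seeds at
noise 0.1 (winner r ≥ 0.99 expected in ≥ 18 of them), and the
noise-monotonicity sweep uses 10 seeds at each of four noise levels,
exploiting the fact that candidate forward simulations do not depend on the
expression noise. The smaller NCA unit instances (6–20 genes, 1–2 TFs) are
sized so each algebraic property is checked in milliseconds.

# Known limitations

* NCA identifiability is checked, not enforced: a user network that fails
  the rank conditions can still be fitted with `check = "warn"`/`"skip"`,
  and the activities are then not unique.
* No uncertainty quantification on `S`, `A`, or the selected IKK profile
  (no bootstrap/confidence intervals); the per-candidate r table is the only
  sensitivity report.
* The kinetic module omits A20-type negative feedback on IKK and any other
  extension beyond its 24-species inventory, and its parameters are
  order-of-magnitude literature values, not fitted constants.
* The inverse search selects from a finite candidate family; it is a
  profile-matching method, not a continuous deconvolution of IKK activity.
* Multi-TF matching is per-TF; only the NF-κB row is linked to the kinetic
  model.
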