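---
title: "Coiled-coil molecular rulers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coiled-coil molecular rulers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccruler)
```

# The ruler model

A canonical parallel two-stranded coiled-coil is a near-ideal linear
measuring stick: each residue advances the superhelical axis by ~1.46 Å,
so physical length is simply `n × 1.46 Å`. A 730-residue coil is therefore
106.6 nm long, and deleting residues shortens it in precisely calibrated
steps. `ccruler` treats this constant as a parameter
(`ruler_params(rise_per_residue = 1.46)`) so its influence can be probed,
but 1.46 Å is the default everywhere.

Two conventions matter and are used consistently:

* **Residue ranges are 1-based and inclusive**, matching the Δstart–end
  notation used for deletion constructs: Δ440–453 removes 14 residues.
* **Nominal labels round half away from zero.** The construct series that
  motivates this package labels a 14-residue (2.044 nm) deletion "Δ2 nm"
  and a 32-residue (4.672 nm) deletion "Δ5 nm"; round-half-away-from-zero
  reproduces both, round-half-even would not.

`design_truncation()` has two modes because the published construct series
is ambiguous about its own rule: the text says register was preserved, yet
only some deletion sizes (14, 70 aa) are multiples of 7. The default
`"heptad"` mode restricts deletions to whole heptads (conservative:
guarantees the downstream register); `"exact"` mode picks the residue
count closest to the target. Both are documented as interpretations, and
the published endpoints are shipped as a fixture (`rock2_constructs()`)
rather than re-derived. A related internal inconsistency in the source
material — a deletion described as "2 nm, or 31 amino acids" where the
construct table defines 14 residues ≈ 2.04 nm — is resolved in favour of
the construct table, since 31 residues would be 4.5 nm.

# Heptad propensity prediction

The predictor is the classic sliding-window scheme. For a window of
`window = 28` residues placed in one of 7 heptad frames, the score is the
**geometric mean** of per-residue propensities at their assigned heptad
positions (a–g). The geometric mean, not the arithmetic one, is
deliberate: a single strongly disfavoured residue (proline ~0.02–0.05 at
every position) collapses the window score, which is how helix breakers
should behave. Each residue takes the best score over all windows and
frames covering it; terminal residues take the max over the windows that
do cover them (no padding).

Scores become probabilities through a two-population Gaussian ratio,
P(cc | s) = f_cc(s) / (f_cc(s) + f_bg(s)), computed on the log-density
scale so extreme scores cannot underflow. The packaged calibration
(coiled-coil population N(1.60, 0.15), background N(0.90, 0.15), crossover
≈ 1.25) was placed from the score distributions of the three regimes the
packaged table produces: ideal heptads (`LAALEKE`-repeats) score ≈ 1.96,
generator-drawn heptad cores ≈ 1.53, and background/shuffled sequence
≈ 0.7–1.1 after max-inflation over frames and windows.

The propensity table itself (`extdata/cc_propensity_v1.tsv`) is a curated
synthetic table encoding the canonical position preferences — aliphatics
at a/d, charged residues at e/g, mild polar preferences at b/c/f, proline
punitive everywhere. No quantitative claims rest on its absolute values:
all tests assert *relative* properties (heptad repeats outscore their own
shuffles; predicted length, a window-level quantity, is stable under
in-class substitution), so the table can be swapped via
`propensity_table()` without touching the machinery.

Segment calling (`call_segments()`) uses threshold 0.5, minimum length 21
(three heptads — anything shorter is unreliable for *long*-coil work) and
merge gap 7 (a single-heptad stutter should not split a rod). One known
systematic: windows straddling a coil boundary still score well, so called
segments overrun true core boundaries by roughly a third of a window on
each side (~10 residues, ~1.4 nm). This inflates absolute predicted
lengths by ~2–3% but cancels in comparisons across a family, which is the
quantity the conservation analysis uses.

# Conservation analysis

`family_length_table()` runs the predictor per record and
`summarize_conservation()` reports per-group and overall mean ± sample
(n−1) s.d., matching conventional "±" reporting; single-member groups
report `NA`, never a fake 0. Pairwise identity is computed by global
alignment (identity substitution matrix, linear gap penalty) restricted to
the coil region, because the motivating observation is *per-region*:
orthologous ROCK coils are only ~33% identical while their lengths agree
to ±3.5 nm. Records that cannot be scored are flagged in the output table
rather than dropped, so a family summary can never silently lose members.

# Hydrodynamics

Two closed forms bracket the conformational interpretation of a measured
diffusion coefficient:

* rod: D = k_B T (ln p + ν(p)) / (3π η l), ν(p) = 0.312 + 0.565/p −
  0.100/p² (end-corrected, valid for p = l/d > 2; p ≤ 1 is an error and
  1 < p ≤ 2 warns);
* sphere: D = k_B T / (6π η R).

The ν coefficients are a parameter of `rod_diffusion()` so alternative
end corrections can be substituted. The headline rod geometry — l = 120 nm
(the full particle), d = 2 nm (canonical coiled-coil diameter), water at
25 °C (η = 8.9 × 10⁻⁴ Pa s) — reproduces the published 18 μm²/s and is
recorded as an assumption in the default config, since none of d, T, η are
printed alongside that number. Viscosity comes from a four-point lookup
(4, 20, 25, 37 °C); anything else must be supplied explicitly — an
empirical viscosity formula is outside what this comparison needs.

`classify_conformation()` places a measured D on the axis between the rod
limit (f = 0) and a compact-sphere limit (f = 1, radius e.g. from
`sphere_radius_from_mass()`, R = 0.066 M^⅓ nm). A measured 25 μm²/s
against rod(120, 2) and R = 4.55 nm gives f ≈ 0.19: extended, semi-rigid.
Note the ordering of the limits: a *thin rod is faster than the sphere
that circumscribes it* (D_rod/D_sphere(l/2) = ln p + ν(p) > 1 for all
p > 2) and slower than the compact sphere of equal volume; the tests pin
this ordering down because it is easy to get backwards.

# FCS model and fitting

The autocorrelation model is the standard single-component 3D diffusion
form G(τ) = (1/N)(1 + τ/τ_D)⁻¹(1 + τ/(S²τ_D))^(−1/2). No triplet term is
included: the quantities of interest are D and brightness, and triplet
blinking is a non-goal. Geometry (w₀ = 0.2 μm, S = 5 by default) is an
explicit object that every fit echoes, because D = w₀²/(4τ_D) scales with
w₀² and a silent default would be a reproducibility trap.

`fit_acf()` uses Levenberg–Marquardt least squares on a log-spaced lag
grid, unweighted unless the curve carries per-point uncertainties.
Initialization is deterministic: N from 1/G(first points), τ_D from the
lag where G falls to half amplitude. Pathological inputs (non-positive
amplitude; tail ≥ 90% of the head, i.e. no decay) return a diagnostic
failure object instead of raising — fitting is the one place where
graceful degradation matters, since batches of measured curves routinely
contain junk. Noise-free synthetic curves are recovered to solver
precision; at 2% multiplicative noise, D is recovered within 5% in ≥ 9/10
seeded replicates.

# EM morphometry and the trace generator

`contour_length()` is the curvilinear polyline sum over the ordered
digitized points. Whether published particle lengths were measured
curvilinearly or end-to-end is generally unstated; curvilinear is chosen
(and flagged here) because it is the quantity that equals the coil's
contour for a semi-rigid rod. Input traces span the coiled-coil only —
globular end lobes are excluded by the tracer — so "contour length" means
"coiled-coil length". Summaries use sample (n−1) s.d. to match "± s.d.
(n = 10)" reporting.

The generator draws 2D discrete worm-like chains (projected chains, as
appropriate for surface-adsorbed molecules): bond-angle increments with
variance `step/persistence`, segment length adjusted so the pre-noise
polyline contour equals the requested contour exactly. Digitization noise
is added as a **smooth correlated displacement** (Gaussian-kernel-smoothed
white noise, 50 nm correlation length, 1 nm s.d. by default) rather than
independent per-point jitter. This is a deliberate modelling decision:
independent 1 nm jitter at 2 nm point spacing would inflate every
segment's expected length by ~40% (E√(L² + 2·2σ²) vs L) and bias the
ensemble mean upward by tens of nanometres — a property of the noise
model, not of tracing, where error is dominated by slowly varying hand and
stage drift. Under the smooth model a single trace still carries ~1–3%
length error while the n = 10 ensemble mean is unbiased to well within the
±3.8 nm spread reported for real particle ensembles.

# Synthetic data: what it does and does not emulate

Generators are pure functions of (seed, arguments): each draws from its
own RNG stream (seed × 7919 + a per-generator tag hash, mod 2³¹−19) and
restores the caller's RNG state, so outputs are bit-reproducible and
adding a generator never shifts another's stream.

`gen_heptad_sequence()` draws a/d from {L, I, V, M}, e/g from
{E, K, R, Q}, b/c/f from an 8-letter polar set, with uniform-composition
flanks. `gen_ortholog_family()` mutates a common ancestral coil by
redrawing positions *within their heptad class* with a per-position
probability solved (by root-finding on the closed-form expected match
probability) to hit a target mean pairwise identity; the class floor is
~19.6%, below which a target is rejected as unreachable. Family members
share the coil residue count *exactly* — length conservation is imposed,
sequence divergence is simulated. Defaults mirror the motivating system:
104 heptads (728 aa ≈ 106 nm), 33% coil identity, families of 10.

What passing tests on this synthetic data show: the predictor and
summary machinery preserve an imposed length signal under realistic
sequence divergence, and recover imposed FCS/EM parameters under realistic
noise. What they do not show: that real orthologue panels have ±3.5 nm
length s.d. (that requires real sequences), that real coils lack stutters
and hendecad repeats (the generator emits perfect heptads), or that real
ACF curves contain no triplet/afterpulsing structure. The generators
validate the instruments, not the biology.

# Pipeline and provenance

`ruler_report()` chains prediction → length → full-particle estimate →
rod diffusion → truncation designs. The full-particle length adds two
configurable end-domain allowances (defaults 7 nm for the kinase-dimer
end, 6 nm for the regulatory end) to the predicted coil; with the ~107 nm
ROCK2-like coil this reproduces the ~120 nm total particle. The split is
an interpretation — only the total is constrained by imaging — and the
defaults are labelled as such in the config. Every constant entering any
reported number (rise, window, calling parameters, rod diameter, T, η,
ν coefficients, w₀, S, allowances, k_B) is echoed in the report's
provenance block, and report serialization is byte-deterministic; a test
asserts both. Configs reject unknown keys outright, trading convenience
for protection against silently misspelled constants.

Errors propagate with their stage name attached (`[input]`, `[predict]`,
`[hydrodynamics]`, ...), so a failing batch names its faulty stage.

# Problem sizes and numerical notes

The test and acceptance workloads use 10-member families of ~930-residue
sequences (5 seeds), 20-draw FCS parameter sweeps with 10 noisy
replicates, and 10-trace EM ensembles — sizes chosen to match the n = 10
scale of the motivating measurements while keeping every property check
comfortably reproducible. Tie-breaks are all deterministic: heptad-mode
design prefers the smaller deletion, modal segment frames prefer the
smaller frame, and ruler rounding is half-away-from-zero. Degenerate
inputs have defined behaviour throughout: empty segment lists have length
0, single-member groups have undefined (not zero) s.d., duplicate
consecutive trace points contribute zero length, and flat ACF curves fail
with "no decay" rather than diverging.

# Known limitations

* Predicted absolute lengths inherit the ~2–3% boundary-overrun bias
  described above; comparative quantities do not.
* The propensity table is calibrated for long, regular two-stranded
  coils; it has no notion of oligomerization state, stutters, or pairing
  register.
* The rod model is rigid: no wormlike-chain correction to D, no
  rotational coupling, no cytoplasmic crowding — the in-cell comparison
  is order-of-magnitude by construction.
* Identity targets in the family generator are expectations; realized
  identity scatters by ~1–2 percentage points at 728-residue coils.
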