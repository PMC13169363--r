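---
title: "Learning periodic polarizations: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning periodic polarizations: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polwann)
```

This vignette is the package's own account of its methods: the models it
fits, the assumptions behind them, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical decisions a maintainer would want written down.
No number quoted here is asserted anywhere except where the test suite or
`scripts/acceptance.R` computes it.

## 1. The polarization of a periodic system is circular data

For a cell with lattice vectors $a_1, a_2, a_3$ (rows of the `cell` object),
the quantum-of-polarization matrix $Q$ carries $e\,a_k$ as columns. Any two
polarizations differing by $Q n$, $n \in \mathbb{Z}^3$, are physically
identical, so the natural coordinates are the reduced polarization
$p = Q^{-1} P$ with each component wrapped into $[-1/2, 1/2)$. The wrap is
half-open and deterministic: $p = x - \mathrm{round}(x)$ with the tie at
exactly $+1/2$ mapped to $-1/2$ (`wrap_half()`), so reduction is a pure
function.

Model quality is measured with the von Mises error
$$\mathrm{vME} = 1 - \frac{1}{3N}\sum_{i}\sum_{\alpha}
\cos\!\big(2\pi(p^{\alpha}_{\mathrm{pred},i} - p^{\alpha}_{\mathrm{calc},i})\big),$$
which lives in $[0, 2]$, vanishes for perfect prediction, is maximal when
every residual component is half a quantum, and — crucially — cannot tell
branches apart, because adding integers to either argument leaves it
unchanged. Root-mean-square errors on raw $P$ have no such invariance and
would punish physically meaningless branch relabelings.

Charges are carried in units of $e$ internally; the only unit conversion,
$1\,e\text{Å} = 4.803205$ D, is applied at input/output boundaries
(`ea_to_debye()`).

## 2. Covariant kernel regression

Both learning tasks predict 3-vectors that rotate with the molecular frame:
the global cell polarization (as a sum of atom-centered dipoles) and the
per-atom Wannier displacement sums. The regressor is kernel ridge regression
with a $3\times3$-block kernel between atomic environments,
$$K(a, b) \;=\; \big(\hat\varphi_a \cdot \hat\varphi_b\big)^{\zeta - 1}\,
F_a F_b^{\mathsf T},$$
built from two channels of each environment (all neighbours within
`radial_cutoff`, minimum image):

* a **covariant channel** $F$: per (neighbour-species, radial-basis) pair,
  the $\lambda = 1$ vector coefficient $v_{s,n} = \sum_j g_n(d_j)\,\hat r_j$
  with a smooth cosine cutoff, augmented with the products
  $v_{s,n} \otimes c_{s',n'}$ against the scalar ($l = 0$) coefficients —
  power-spectrum-order features. Every column of $F$ transforms exactly like
  a vector under rotation, so covariance of the kernel, and hence exact
  equivariance of predictions, holds *by construction* rather than to some
  training tolerance. The equivariance tests at $10^{-6}$ relative pass at
  machine precision.
* an **invariant channel** $\varphi$: the rotation-invariant power spectrum
  $p_{s,n,l} = \sum_m c_{s,n,l,m}^2$ of real-spherical-harmonic coefficients
  up to `l_max`, normalized per atom; raised to $\zeta - 1$ it supplies the
  nonlinearity of the scalar kernel part.

Defaults: `radial_cutoff` 4.0 Å (covers first and most second coordination
shells at the fixture densities while staying under half the box width),
`n_radial` 6 Gaussians centered on 0.5–4.0 Å, `gaussian_width` 0.3 Å
(resolves the 0.96/1.09/1.43/1.54 Å bond-length scale), `l_max` 4, kernel
exponent `zeta` 2 (kept integer so elementwise powers of the scalar Gram
matrix stay positive semidefinite), ridge `regularization` $10^{-8}$ relative
to the mean kernel diagonal for noiseless targets. All of these are exposed
in `descriptor_config()`.

Global models use the summed-environment kernel (the frame kernel is the sum
of its atomic kernels). This is not just a convenience: it is what makes the
prediction an explicit sum of atom-centered dipoles
(`atomic_dipole_decomposition`), which the shell-resolved spectra need.
Training solves the $3F \times 3F$ symmetric block system directly; there is
no environment sparsification, because the package targets desk-scale
datasets (hundreds of frames, tens of atoms each) where full kernels are
exact and cheap.

## 3. Data-driven branch unwrapping

Raw periodic polarizations arrive on arbitrary branches. The unwrapping loop
is:

1. draw a random ~5% probe subset (`probe_fraction`) and train a probe model
   on it as-is;
2. predict the remainder and run the Hartigan dip test on each Cartesian
   component of the signed residuals $p_{\mathrm{pred}} - p_{\mathrm{calc}}$.
   A *branch-consistent* probe leaves residuals clustered at integers —
   multimodal, dip p-value below `dip_threshold` (0.05, any-component rule).
   A probe poisoned by mixed branches predicts noise and the residuals smear
   into a unimodal blob: the subset is resampled (up to `max_restarts`, 20);
3. on a multimodal verdict, each point's offset is the nearest integer to
   its signed residual; a residual within $10^{-6}$ of a half-integer is a
   genuine ambiguity and raises rather than guesses;
4. a **refinement stage**: the model is rebuilt from the *confidently*
   branched points (residual within `confident_residual` = 0.35 of an
   integer) at moderate ridge (`refine_regularization` = $10^{-2}$), and all
   offsets are re-assigned — confident points from their closed-form
   leave-one-out predictions, the rest from ordinary predictions — for up to
   `refine_passes` = 4 passes or until stable.

Two of these choices deserve their "why". The probe's default ridge is
deliberately enormous (10 relative to the kernel diagonal): its training
targets contain branch noise of order one quantum, an essentially
unlearnable component, and a lightly regularized probe simply memorizes it
and smears the residual histogram. A hard-shrunk probe only has to resolve
*relative* branches, which is all the diagnosis needs. Second, the
refinement uses leave-one-out predictions because a nearly interpolating
refit would happily confirm a point's own wrong branch; LOO breaks that
feedback, and the moderate ridge keeps every frame's leverage away from one
so the closed-form LOO stays meaningful. On the standard synthetic fixture
(200 points, offsets uniform in $[-2,2]^3$) the probe assignment alone
recovers 96–99.5% of offsets depending on the seed; with refinement,
recovery is complete for every seed tried, and a model retrained on the
unwrapped branch beats the wrapped-data model by roughly four orders of
magnitude in held-out vME.

Offsets are recoverable only modulo a single global integer vector — the
main branch itself is a gauge choice — so recovery is always scored modulo
that common shift.

Unimodal residuals that never leave $(-1/2, 1/2)$ are the signature of data
already on one branch; `unwrap_dataset()` then returns zero offsets
(idempotence) instead of restarting forever. Data whose smooth branch
genuinely spans several quanta (e.g. systems with free charges hopping
between many accessible branches) defeats any shrunken probe: every verdict
stays unimodal with large residual spread, and the loop fails loudly after
`max_restarts` with diagnostics attached. That failure mode is a documented
limit of the method, not of the implementation.

### The dip test

No dip-statistic implementation exists in the package's dependency
environment, so it is implemented from first principles in compiled code:
the dip of an empirical CDF is the smallest $t$ such that a CDF that is
convex left of its mode and concave right of it (an atom at the mode
allowed) fits within a uniform band of halfwidth $t$. Feasibility for a
given $t$ reduces to greatest-convex-minorant checks on per-point value
bands, monotone in both $t$ and the mode position, so the statistic is found
by bisection with binary searches — exact up to the $2^{-36}$ bisection
tolerance. The implementation is validated against hand-derivable closed
forms (two equal point masses give exactly $1/4$, $n$ equally spaced points
$1/(2n)$, three equal masses $1/6$, masses in a 1:3 ratio $1/8$). p-values
come from a seeded bootstrap against the uniform null (1000 resamples,
cached per sample size within a session); the uniform is the asymptotically
least favourable unimodal null, so the p-values are conservative.

The dip test is run on the *raw* signed residuals. Folding residuals into
$[-1/2,1/2)$ first would collapse the integer-separated modes onto a single
mode at zero and make multimodality undetectable — integer mode spacing is
exactly what guarantees the modes never overlap, so no folding is needed or
wanted.

## 4. Wannier centers: assignment, repair, reconstruction

Each doubly occupied Wannier center is assigned to its nearest atom
(minimum image); an exact tie (within $10^{-9}$ Å) raises. Atoms are
labeled by species plus the sorted species multiset within `label_cutoff`
(1.8 Å — generous for covalent bonds at up to ~1.6 Å, short of
hydrogen-bond partners at ~1.8–2.0 Å), and the modal center count per label
is tabulated, ties broken toward the larger count with a warning. Miscounts
are repaired by moving, along covalent bonds (perceived at 1.2× the
covalent-radius sum when not supplied), the surplus atom's center closest to
the deficit atom; the transfer conserves the total exactly, is idempotent,
and raises listing the offending atoms when no bonded surplus/deficit pair
resolves the mismatch.

The polarization can be evaluated two ways: directly from raw center
positions, $P = e\sum_i Z_i R_i - 2e\sum_j r^W_j$, or from the per-atom
bookkeeping $P = e\sum_i [(Z_i - 2N^W_i) R_i - \Delta_i]$ with
$\Delta_i = \sum_{j\in i} 2\,\delta_{ij}$. The per-atom form uses the
charge-consistent factor $2N^W_i$ (each center carries two electrons);
with that factor the two forms are one algebraic identity for *any*
ownership, which the tests assert for deliberately nonsensical assignments
as well. One caveat is inherent: displacements are minimum-image, so an
absurd owner on the far side of the cell wraps its center's displacement
and shifts $P$ by whole quanta — the identity therefore holds exactly for
compact (nearest-atom) assignments and modulo the quantum in general, which
is the only sense in which $P$ is defined anyway.

Misassigning the *count* is not harmless, unlike misassigning ownership: a
doubly occupied center predicted onto the wrong member of a 1 Å atom pair
shifts the reconstructed polarization by $2\,e$Å (9.6 D). That asymmetry —
bookkeeping is free, count prediction is not — is why the learned model
carries a per-label expected-count table alongside the displacement
regressor, and why repair matters. Valence charges default to the
pseudopotential values O:6, C:4, H:1 and are overridable.

## 5. IR spectra

`ir_spectrum()` evaluates $I(\omega) \propto \omega^2 \int
\langle P(t)\cdot P(0)\rangle e^{i\omega t}\,dt$ in the Wiener–Khinchin
form: $\omega^2$ times the squared modulus of the Fourier transform of the
Hann-windowed, mean-removed signal, summed over the three Cartesian
components, zero-padded twofold for grid refinement. This is the same
autocorrelation transform, but the periodogram arrangement guarantees
nonnegative auto-spectra *exactly* and makes the decomposition
$I = I_1 + I_2 + I_c$ (auto, auto, symmetrized cross term
$2\,\mathrm{Re}\,F_1 F_2^*$) close to machine precision — a lag-windowed
autocorrelation estimate would violate both at the percent level through
the window transform's negative sidelobes. The proportionality constant is
set to one: intensities are reported in arbitrary units, and positions,
shapes and intensity *ratios* are the contract. No quantum correction
factor is applied; the input dynamics is classical, so high-frequency line
positions inherit the classical bias and only relative shifts across
compositions should be interpreted.

Peaks are located by argmax within a search window plus three-point
quadratic refinement; a window with no interior maximum (flat, or
non-negative curvature) raises a no-peak error rather than returning a
boundary artifact. `peak_shift_series()` reports positions relative to a
stated reference concentration, whose shift is exactly zero.

## 6. Hydration structure

Hydrogen bonds use the standard liquid-water geometric convention — O···O
within 3.5 Å and H–O(donor)···O(acceptor) angle within 30° — configurable in
`hbond_criterion()`; the source data for the mixture tables does not state a
criterion, so a convention had to be chosen and exposed. A water's
participation counts bonds it donates or accepts, including bonds to ethanol
hydroxyls. The ideal-mixing baseline interpolates the mean per-water count
linearly in ethanol mole fraction between the pure-water and equimolar
endpoints, making the excess $\Delta n_{\mathrm{HB}}$ exactly zero at both
endpoints by construction.

Distances from water to ethanol are measured O(water) → nearest β-carbon
(the methyl carbon, i.e. the ethanol carbon not bonded to oxygen): the
methyl group is the hydrophobic moiety whose hydration shell is at issue,
and the hydroxyl end would conflate hydrogen bonding with hydrophobicity.
The default shell cutoff is the first minimum of the β-C–O(water) radial
distribution function computed from the analyzed trajectory (extrema located
on a lightly smoothed curve; fixed-value override supported). The excess
H-bond density bins each water's participation excess over the ideal
baseline by that distance and normalizes per spherical shell volume and per
frame; empty bins are reported as missing, never as zero.

## 7. What the synthetic generator does and does not emulate

The generator produces rigid idealized molecules (water: 0.96 Å, 104.5°;
ethanol: standard bond geometry) placed by rejection sampling with a 2.2 Å
heavy-atom exclusion at ~110 Å³ per molecule, random orientations, cubic
cells, molecules kept whole so the point-charge oracle is smooth. Wannier
sites sit at bond positions biased toward the heavy atom (0.40–0.60 Å from
it, so nearest-atom assignment reproduces the chemical expectation at zero
noise) and at two lone-pair sites per oxygen. The polarization oracle is a
fixed per-species point-charge sum (each molecule neutral) plus a smooth
exponential bond-dipole term; its charge values are arbitrary but fixed —
what the tests need is smoothness, determinism and locality, not physical
accuracy.

Defaults follow what the quantities *are* rather than what is convenient:
Wannier jitter `noise_scale` defaults to zero because first-principles
centers are deterministic functions of the geometry; jitter exists to
provoke assignment flips for the repair Monte-Carlo (at 0.15 Å roughly
one molecule in eight needs repair and a few percent raise), not to model
measurement noise. Branch offsets are drawn uniformly in
$[-\mathtt{offset\_range}, \mathtt{offset\_range}]^3$ per point, range 2 by
default.

Passing tests on these fixtures demonstrates the algebra, the symmetry
properties, the unwrapping logic and the estimators — not chemical accuracy
for real liquids. The fixtures have no liquid structure (gas-like packing),
no thermal vibrations, no polarization fluctuation spectrum beyond the
constructed lines, and oracle polarizations an order of magnitude smoother
than DFT data; held-out errors here are therefore a best case, and learning
curves on real data will sit higher.

## 8. Numerical choices and degenerate inputs

Cells must have strictly nonzero volume (checked at $10^{-10}$ relative);
descriptor cutoffs must not exceed half the smallest cell width, since
neighbour search uses the minimum image only. Kernel systems are solved
densely; a singular system at zero ridge raises advising positive
regularization. Wrap ties at exactly $+1/2$ go to $-1/2$; count ties in the
modal table go to the larger count with a warning; nearest-atom ties and
half-integer branch residuals raise. Problem sizes in the tests and the
acceptance script — 200-frame unwrapping runs with 21-atom frames, 50-frame
training sets, $2^{14}$-step trajectories, 500-fixture repair sweeps — were
chosen as the smallest sizes at which each property is cleanly measurable.
File readers reject truncated or malformed input with line context rather
than returning partial data.

## 9. Known limitations

* Unwrapping presumes one dominant smooth branch; systems with free charges
  or many thermally accessible branches defeat the probe by design, and the
  loop reports failure rather than guessing.
* The minimum-image convention limits descriptor cutoffs and RDF ranges to
  half the cell; very small or very skewed cells are rejected, not
  approximated.
* Full (unsparsified) kernels scale quadratically in atoms × frames; the
  implementation targets desk-scale datasets, not production force-field
  training.
* The Wannier route's accuracy saturates with training size faster than the
  unwrapped-polarization route when built on short-ranged features; the
  package exposes the hyperparameters but does not attempt alternative
  feature classes.
* Classical autocorrelation spectra carry no nuclear-quantum corrections;
  absolute high-frequency peak positions are systematically shifted, and
  only trends across compositions are meaningful.
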