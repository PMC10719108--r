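---
title: "Methods: serial X-ray and electron microcrystallography in microxtal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial X-ray and electron microcrystallography in microxtal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microxtal)
```

# Scope and model

`microxtal` implements the computational core of a comparison between two
ways of seeing the same small organic crystal: serial still-frame X-ray
diffraction (SX), which images the *electron density*, and 3D electron
diffraction (MicroED), which images the *Coulomb potential*.  The physics
that distinguishes the two lives in the atomic scattering factors, and
everything in the package is built from them:

* **X-ray form factors** are four-Gaussian sums
  $f_x(s) = \sum_i a_i e^{-b_i s^2} + c$ with $s = \sin\theta/\lambda$
  (Å$^{-1}$), using Cromer–Mann coefficients for neutral atoms and common
  ions, shipped as a plain-text resource.  $f_x(0)$ equals the electron
  count, which the test suite asserts for every species.
* **Electron scattering factors** come from the Mott–Bethe relation
  $f_e(s) = (Z - f_x(s)) / (8\pi^2 a_0 s^2)$, with $a_0$ the Bohr radius.
  For a formally neutral species the numerator must vanish at $s = 0$;
  we use the table's own $f_x(0)$ in place of $Z$ there, and evaluate the
  analytic limit $f_e(0) = \sum_i a_i b_i / (8\pi^2 a_0)$, so the
  table-precision deficit ($\sim 10^{-3}$ electron) cannot fake a
  divergence.  For ions the $s^{-2}$ divergence is physical and retained.
* **Partial charges** interpolate linearly between the neutral and the
  singly ionized species, $f_q = (1-|q|) f_{\mathrm{neutral}} +
  |q| f_{\mathrm{ion}}$; electron factors for charged atoms are obtained
  by Mott–Bethe conversion of the *interpolated X-ray factor*, never by
  interpolating $f_e$, which keeps the ionic divergence exact.
  Nitrogen has no standard ionic four-Gaussian entry; the N$^{+}$/N$^{-}$
  rows are synthesized by electron-count scaling of neutral N and are used
  only in negative-control scenarios.

Structure factors are computed by direct summation over symmetry operators
and sites with isotropic Debye–Waller damping $e^{-Bs^2}$,
$B = 8\pi^2\langle u^2\rangle$.  Operators for P1, P‑1 and Pbca are
hard-coded and verified by group-closure tests; systematic absences are
derived from the operators themselves (a reflection fixed by a rotation
whose intrinsic translation has a non-integral phase is absent), not from
per-group lookup rules.

# The hydrogen model

The theoretical bond profiles use the spherical 1s density
$\rho(r) = e^{-2r/a_0} / (\pi a_0^3)$, thermally smeared by convolution
with an isotropic Gaussian whose per-axis variance is
$\langle u^2\rangle = B/8\pi^2$ (the Fourier transform of the
Debye–Waller factor), and the integrated form of Poisson's equation
$\phi(\mathbf r) = Z/|\mathbf r - \mathbf r_{\mathrm{nuc}}| -
\int \rho(\mathbf r')/|\mathbf r - \mathbf r'|\, d^3 r'$.

Numerical choices:

* the unsmeared cloud potential uses the closed form
  $(1/r)\{1 - e^{-2r/a_0}(1 + r/a_0)\}$ (validated against independent
  radial quadrature to $10^{-8}$ relative);
* the smeared point-charge potential uses
  $\mathrm{erf}(r/\sqrt{2\langle u^2\rangle})/r$;
* the smeared cloud terms use adaptive radial quadrature of the
  1-D convolution identity for spherical functions, with an analytic
  $r \to 0$ branch;
* bond profiles are exact line sections of the 3-D superposition (each
  term is spherical about its own centre), so the theory curves carry no
  grid error; peaks are refined by a parabola through the three bracketing
  samples, exact for symmetric sampling.

With the electron cloud centred at 0.930 Å and the nucleus at 1.083 Å from
the parent carbon, the smeared density profile peaks at the cloud centre
while the potential profile peaks *beyond* the nucleus (1.10–1.12 Å for
$B$ between 4 and 8 Å$^2$, non-decreasing in $B$).  This ordering —
X-ray peak short of the nucleus, potential peak beyond it — is the
quantity `scripts/acceptance.R` recomputes.  The displacement amplitude
behind the published theory curve is not stated; the package default is
$B = 6$ Å$^2$, bracketed by the experimental mean displacement parameters
of the two techniques, and the acceptance computation reports the minimum
peak offset over $B \in [4, 8]$ so that the bound does not depend on the
choice.

# Maps and hydrogen-peak statistics

Hydrogen-omit difference maps use SHELX-style amplitude coefficients
$(k F_o - |F_{c,\mathrm{omit}}|) e^{i\varphi_{c,\mathrm{omit}}}$ with
$m = D = 1$ and the least-squares scale
$k = \sum|F_c||F_o| / \sum|F_o|^2$ against the full model; F(000) is never
included.  Maps are synthesized by FFT after expanding unique reflections
to the full sphere with the space-group phase shifts and Friedel
conjugates.  The synthesis default of 4 grid samples per $d_{\min}$
(2× oversampling) is adequate for visualisation and Parseval-level
checks, but peak-*position* measurement through trilinear interpolation
needs a finer grid: at 4 samples per $d_{\min}$ individual hydrogen peak
positions carry up to ±0.1 Å of interpolation error, falling to
±0.03 Å at 8 samples (the `make_paired_maps()` default) and ±0.015 Å at
12.  Peak heights are measured in σ units (map scaled to mean 0, rms 1)
above a base level.  The published definition of the base ("estimated
base density level at the bonded non-hydrogen atom") does not specify the
estimator; the default here is the profile minimum between the parent
atom and the peak, with a fixed-offset alternative (`base = "fixed"`)
available.  The observation rule is height > 1.5σ.

Per-class statistics (`summarize_h_peaks()`) report N_all, N_obs and the
mean/sd of observed offsets; paired-map deltas (`delta_peaks()`) average
per-hydrogen differences over hydrogens observed in *both* maps, so a
record missing from either map never contributes.  Peak offsets are
measured along the refined bond direction by default; this is one of two
plausible conventions (the other being the free 3-D local maximum) and is
the documented package choice.

# Partial-charge grid search

`shell_r()` monitors R1 in a low-resolution shell ($s < 0.2$ Å$^{-1}$),
the remaining shells, and overall, after re-refining the model; the low
shell is the objective because the charge signal diverges as $s^{-2}$
for electrons while high-resolution data are dominated by core scattering.
`charge_grid_search()` enumerates every combination of charges on the
requested sites (hydrogen-type sites on $[0, +1]$, halides on $[-1, 0]$,
step 0.1), re-refines each, and selects the lowest R_low with ties broken
by R_all and then by the smallest total $|q|$; a flat surface returns the
neutral assignment with a degeneracy flag.

The per-combination re-refinement is deliberately light: an overall scale
(closed form), optionally per-atom isotropic B, and optionally a bounded
coordinate polish for non-hydrogen atoms (hydrogens ride — they are too
weakly determined at ~0.9 Å resolution and would drift freely), by
L-BFGS-B with analytic gradients.  This is *not* a restrained
crystallographic engine: no geometric or displacement restraints, no
estimated standard uncertainties.  Two consequences are documented rather
than hidden.  First, the full grid uses scale-only refinement by default;
this does not affect recovery, because on noise-free data the true
assignment reaches R_low = 0 exactly and the surface degrades strictly
monotonically away from it.  Second, against noise-free *electron* data an
unrestrained refinement of a wrongly charged model visibly distorts B
values and, with coordinates free, bond lengths — a restrained engine
fitting noisy experimental data does not.  The package therefore verifies
the "charges do not move the structure" property on the X-ray arm, where
the charge signal is an order of magnitude weaker (heavy-atom shifts
< 0.02 Å, ΔB < 0.2 Å$^2$), and treats the electron-arm distortion as a
known limitation of the simplified engine.

The X-ray insensitivity scenario mirrors the serial-crystallography data
quality: counting noise with $\sigma(I) = 0.08\,I$ (overall
$I/\sigma(I) \approx 12$) on amplitudes over 9.65–0.82 Å.  On noise-free
X-ray data the charge signal, while ten times weaker than for electrons,
is still formally detectable (ΔR_low ≈ 0.004); at the experimental
counting statistics the best-versus-neutral improvement drops below
0.001, which is what "no significant improvement" operationalizes.

# Still-frame simulation and Monte-Carlo merging

The simulator draws uniformly random crystal orientations by the
normalized-quaternion method, excites a reflection when its rotated
reciprocal-lattice point lies within a Gaussian partiality slab of the
Ewald sphere, and records
$I = |F|^2 \cdot p(\varepsilon) \cdot \text{frame scale} \cdot
\text{beam scale} + \text{noise}$, with
$p(\varepsilon) = e^{-\varepsilon^2/2w^2}$ the partiality at Ewald offset
$\varepsilon$.  Defaults define the emulated data-taking regime: 50%
blank frames (the observed hit rate), slab width $w = 0.004$ Å$^{-1}$,
lognormal per-frame scales ($\sigma_{\log} = 0.3$), a detector-counts
scale of 25, and a detection threshold of 10% partiality — spots weaker
than that are below the measurable limit and are not recorded.  These
choices give tens-to-hundreds of spots per frame on the Pbca toy crystal,
matching the regime of the experiment qualitatively.

Hit filtering keeps frames with a maximum-pixel proxy above 1,000 and a
spot count within [30, 300], and always drops beam-off frames.  Merging
is the plain Monte-Carlo estimate — the unweighted mean over all
observations of each Laue-unique reflection (mmm for Pbca, Friedel pairs
merged), with the standard error of the mean as σ.  Half-sets split
deterministically by odd/even frame index.  R_split uses the
$2^{-1/2}$-corrected standard definition, CC$_{1/2}$ is the Pearson
correlation of half-set means, and R_merge the unweighted
$\sum|I_i - \langle I\rangle| / \sum I_i$; neither formula is printed in
the source study, so the community conventions are fixed here and
documented.  Negative noisy intensities are kept (not floored) before
merging.

The test suite exercises the chain end-to-end: a 4,000–5,000-frame run of
a benzene-like Pbca toy crystal reaches 100.0% completeness overall and
in the outermost shell, multiplicity above 200, and amplitude agreement
with the generating model better than R1 = 2%.  Problem sizes in the
suite (toy cells near 10–14 Å, resolution 1.2–1.4 Å, thousands of frames)
were chosen so the full suite runs in a few minutes while keeping
multiplicities in the hundreds; the merging statistics scale as
$1/\sqrt{\text{multiplicity}}$, which the suite verifies across
multiplicities 8–128.

# Synthetic structures

`build_toy_structure()` provides three deterministic fixtures: a two-atom
P1 cell, a benzene-like aromatic ring (P1 or Pbca), and a rhodamine-like
salt — 28 C, 2 N, 3 O, 31 H, a chloride and a half-occupied water oxygen
(composition C$_{28}$H$_{31}$N$_2$O$_{3.5}$Cl), whose connectivity ships
as a plain-text graph with 15 methyl, 6 methylene, 8 aromatic and 2 amide
hydrogens.  Its 3-D geometry is a packaged *synthetic idealized*
coordinate set (distance-geometry embedded and force-field minimized
once, then frozen as text); it reproduces the molecule's topology, bond
lengths and crowding, not any refined experimental structure.  The
chloride sits on a bent hydrogen bond 3.35 Å from the amide nitrogen —
deliberately off the N–H axis so that its density tail does not sit on
the measured bond profile.

What the generators deliberately do not emulate: dynamical scattering,
detector point-spread and geometry errors, mosaicity, radiation damage,
bonding (aspherical) deformation density, and indexing ambiguity
(orientations are known).  Passing tests therefore demonstrate the
correctness of the computational chain under the stated stochastic model,
not the full error budget of real measurements; in particular the
recovered hydrogen-peak shifts are clean limits of what real maps show
with additional noise.

# Degenerate inputs and edge conventions

Reflection (0,0,0) is excluded from generation, difference maps and all R
sums; F(000) contributes to a synthesis only when supplied explicitly,
and is an error for electron radiation with a net-charged model.  Maps
must satisfy the band-limit (anti-aliasing) bound or synthesis refuses.
σ-normalization of a constant map, empty resolution shells, R1 over an
empty strong subset, hydrogens with ambiguous parents, and charge
magnitudes beyond ±1 all raise errors rather than guessing.  A profile
maximum on the search-window edge is flagged as non-interior and the
hydrogen recorded as unobserved.  HKLF-4 I/O is fixed-width (3I4, 2F8.2),
honours the 0 0 0 terminator, warns about trailing records, and
round-trips bit-exactly; indices or intensities that do not fit the field
widths are errors (an opt-in rescale exists for merged output).
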