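# microxtal

Tools for comparing serial still-frame X-ray crystallography (SX) and 3D
electron diffraction (MicroED) of small organic microcrystals.

X-rays scatter off the electron density; electrons scatter off the Coulomb
potential. For hydrogen atoms the two disagree in a characteristic way: the
electron-density peak is pulled *toward* the bonded atom, while the
Coulomb-potential peak sits at or *beyond* the nucleus. `microxtal`
implements the full computational chain needed to quantify that difference
on synthetic data — atomic scattering factors for both radiations,
structure factors, omit maps, hydrogen-peak statistics, a partial-charge
grid search, and Monte-Carlo merging of still diffraction frames — for
crystallographers and methods developers who want these pieces as tested,
reusable functions rather than fragments of a processing pipeline.

## What is inside

* **Scattering factors** — four-Gaussian X-ray form factors
  `f_x(s) = Σ aᵢ exp(−bᵢ s²) + c` (s = sinθ/λ) for neutral atoms and ions,
  the Mott–Bethe conversion `f_e(s) = (Z − f_x(s)) / (8π² a₀ s²)` with an
  analytic neutral-atom limit at s = 0, linear partial-charge interpolation
  `f_q = (1−|q|) f_neutral + |q| f_ion`, and Debye–Waller damping
  `exp(−B s²)`, B = 8π²⟨u²⟩.
* **Crystal machinery** — hard-coded P1 / P‑1 / Pbca symmetry with
  operator-derived systematic absences, unique-reflection generation,
  direct-summation structure factors for either radiation, FFT map
  synthesis, hydrogen-omit difference maps `(k·Fo − |Fc,omit|)·exp(iφ_omit)`,
  σ-scaled maps, R1, and riding-hydrogen repositioning.
* **Hydrogen theory** — the smeared 1s density
  `ρ(r) = exp(−2r/a₀)/(π a₀³)` and its Coulomb potential
  `φ(r) = Z/|r − r_nuc| − ∫ ρ(r′)/|r − r′| d³r′`, as exact 1-D bond
  profiles with sub-grid peak interpolation.
* **Peak statistics** — per-hydrogen peak offsets and σ-heights in omit
  maps (observation rule: height > 1.5σ), per-bond-class summaries, and
  paired-map Δ offsets over hydrogens observed in both maps.
* **Charge search** — shell-resolved R factors (low shell s < 0.2 Å⁻¹),
  simplified scale/B/coordinate re-refinement with analytic gradients, and
  an exhaustive grid search over partial charges (step 0.1) on selected
  sites.
* **Serial merging** — hit filtering (max pixel > 1,000; 30–300 spots),
  Monte-Carlo merging (unweighted mean over Laue-equivalent observations),
  odd/even half-sets, R_split, CC½, R_merge, completeness, multiplicity.
* **Synthetic data** — seeded generators for toy crystals (including an
  idealized rhodamine-like salt, C₂₈H₃₁N₂O₃.₅Cl, with 15/6/8/2
  methyl/methylene/aromatic/amide hydrogens), rotation-style intensity
  sets, still-frame serial datasets with partiality and blank frames, and
  paired omit maps with known ground truth.
* **I/O and CLI** — SHELX HKLF-4 reflection files (bit-exact round trip),
  minimal CIF output readable by standard viewers, JSON-lines frame files,
  and a thin command-line dispatcher (`inst/cli/microxtal`) with
  `chem`, `theory`, `simulate`, `merge`, `maps`, `hpeaks`, `chargescan`
  and `stats` subcommands emitting JSON summaries.

## Worked example

Theoretical hydrogen bond profiles, then a full serial still-frame run:

```r
library(microxtal)

m <- hydrogen_bond_model(nucleus = 1.083, cloud = 0.930, B = 6)
offs <- seq(0.5, 1.9, by = 0.005)
den <- electron_density_profile(m, offs)
pot <- coulomb_potential_profile(m, offs)
cat(sprintf("density peak   %.3f A\npotential peak %.3f A\n",
            den$peak_offset, pot$peak_offset))
#> density peak   0.930 A
#> potential peak 1.112 A
```

The electron-density peak sits at the 1s cloud centre (0.930 Å from the
carbon, the X-ray view), while the thermally smeared Coulomb potential
peaks at 1.112 Å — beyond the 1.083 Å nucleus (the electron-diffraction
view). That ordering is the core prediction the package exists to test.

```r
st     <- build_toy_structure("planar_ring", sg_name = "Pbca")
cfg    <- simulation_config(n_frames = 2000, seed = 42, d_min = 1.2)
frames <- simulate_still_frames(st, cfg)
frames
#> <frame_set> 2000 frames, 55247 spots (0-72 per frame), lambda 0.827 A

merged <- monte_carlo_merge(hit_filter(frames))
merged
#> <merged_data> 511 unique reflections, mean multiplicity 108.1

cat(sprintf("R_split = %.2f%%  CC1/2 = %.4f\n",
            rsplit(merged$half1, merged$half2),
            cc_half(merged$half1, merged$half2)))
#> R_split = 6.13%  CC1/2 = 0.9979

cm <- completeness_multiplicity(merged, d_min = 1.2)
cat(sprintf("completeness %.1f%% (outer %.1f%%), multiplicity %.1f\n",
            cm$completeness, cm$completeness_outer, cm$multiplicity))
#> completeness 100.0% (outer 100.0%), multiplicity 108.1
```

Half the frames are blank (missed crystals), weak frames are removed by
the hit filter, and Monte-Carlo averaging over ~100 random-orientation
observations per unique reflection still recovers a complete dataset with
R_split ≈ 6% — the serial-crystallography regime in miniature.

See `vignettes/microxtal-methods.Rmd` for the models, conventions,
numerical choices and known limitations.

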