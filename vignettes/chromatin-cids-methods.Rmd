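---
title: "Modeling circular intensity differential scattering of chromatin solenoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling circular intensity differential scattering of chromatin solenoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidscatter)
```

## The model

`cidscatter` computes how a solenoid model of the 30 nm chromatin fiber
scatters polarized light. The fiber is a one-start helix of nucleosomes:
nucleosome k (k = 0, 1, ...) sits at azimuth `phase0 + 2πk/n` and height
`P·k/n`, at distance R from the helix axis, with n nucleosomes per turn.
The defaults are the canonical parameter set: R = 10 nm, P = 11 nm (axial
rise per *turn*), n = 6, right-handed, cylindrical nucleosomes 11 nm in
diameter and 5.5 nm high, refractive index 1.68 inside water (1.33),
illuminated at a vacuum wavelength of 300 nm. Each of those is a knob on
`solenoid_spec()`, `nucleosome_shape()` and `plane_wave()`.

The scattering problem is solved with the coupled-dipole method (the
discrete dipole approximation): the fiber volume is replaced by point
dipoles on a cubic lattice of spacing d, each with a polarizability α from
the lattice dispersion relation (LDR), and the self-consistent moments
solve

    P_i = α_i ( E_inc,i + Σ_{j≠i} G(r_i − r_j) P_j ),

with G the retarded free-space dyadic Green tensor at the medium wavenumber
k = 2π n_host / λ_vac. Far-field amplitude matrices are phased sums of the
moments; the 4×4 Mueller matrix per scattering angle follows from the
standard quadratic map, and the two observables of interest are the total
scattered intensity m11(θ) and

    CIDS(θ) = (I_L − I_R) / (I_L + I_R) = m14(θ) / m11(θ).

Because every nucleosome is isotropic and non-absorbing, all chiral
contrast comes from the *arrangement* of the scatterers, carried by the
inter-dipole coupling: switching the coupling off (`mode = "born"`,
the first Born approximation) makes CIDS vanish identically, which the
package uses as a structural null control.

### Assumptions

- Nucleosomes are homogeneous isotropic dielectrics (no birefringence, no
  absorption at the simulated wavelengths); linker DNA is not modeled.
- The host is infinite, homogeneous water; only the relative index
  m = 1.68/1.33 ≈ 1.263 and the medium wavenumber enter, and λ = 300 nm is
  taken as the vacuum wavelength.
- The fiber is rigid; orientational disorder is handled by quadrature over
  Euler angles, not by conformational sampling.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `pitch` | nm | 11 | axial rise per turn; 0 degenerates to an achiral ring |
| `radius` | nm | 10 | helix radius; 0 degenerates to a linear chain |
| `handedness` | — | right | mirror reflection flips it and the CIDS sign |
| `turns`, `nucleosomes_per_turn` | — | 1, 6 | fiber length and packing |
| `orientation_mode`, `tilt` | —, rad | radial, 0 | nucleosome axis placement |
| `dipoles_per_longest` | — | 60 | lattice cells across the longest extent |
| `lambda_vac`, `host_index` | nm, — | 300, 1.33 | illumination |
| `tol` | — | 1e-5 | relative residual of the Krylov solve |

The canonical production discretization is 60 dipoles across the longest
dimension of one turn. The package's own tests and the acceptance script
run at 16–24 dipoles per longest dimension: every symmetry-based claim
(mirror antisymmetry, the achiral nulls) is resolution-independent, and the
trend results were checked to be stable from 16 up to 48; the discrepancy
against the Lorenz–Mie oracle is already at the 0.1–0.4 % level for the
single-nucleosome sphere in this range.

## Nucleosome orientation

The classic description of the solenoid says the nucleosome faces are
parallel to the helical tangent and their normals perpendicular to the
helix axis. For nonzero pitch these two clauses overconstrain a cylinder's
orientation, so the package makes `orientation_mode = "radial"` the
default: the cylinder axis points along the local outward radial direction,
which satisfies both clauses exactly in the zero-pitch limit and keeps the
face plane containing the tangent for all pitches. `tangential` and
`axial` modes, plus a continuous `tilt` about the local reference
direction, expose the orientation degree of freedom that some fiber
variants change.

Two degenerate cases get special care:

- **R = 0.** Keeping the azimuth-rotating frames of the helical
  parameterization would leave a screw-chiral stack even though the centers
  are collinear. The default gives every nucleosome the identical frame
  (axis along +x), producing a genuinely achiral chain — this is the
  configuration whose CIDS must vanish. The rotating-frame variant stays
  available behind `rotating_frame_at_r0 = TRUE`.
- **Right-on-left stack.** `stack_opposite_handed()` places a left-handed
  turn on a right-handed one with axial offset exactly P, so the
  per-nucleosome rise continues across the junction; segment 2 is built as
  the bit-exact mirror image of segment 1 through the plane z = P(2n−1)/2n
  (11P/12 for n = 6), midway between the two turns. The composite is
  therefore *provably* achiral — its orientation-averaged CIDS cancels
  node-for-node — rather than approximately so. The equivalent
  parameterization (handedness flipped, azimuth offset 2π/n) is recorded in
  the segment metadata.

## Voxelization

`voxelize()` sets d = (largest axis-aligned extent of the union of
solids)/`dipoles_per_longest`, centers the lattice on the bounding-box
center per axis (snapping numerically-zero centers to 0), and occupies a
site iff its center lies inside at least one solid, with boundary points
counting as inside (closed solids, for determinism). Centering makes the
site set *exactly* closed under the continuous model's y → −y and z → −z
mirror symmetries, which is what turns the paper-style zero-CIDS claims
into machine-precision identities instead of discretization-limited
approximations. Overlapping nucleosomes are allowed (union semantics), as
dense fibers at small pitch visibly abut.

One visible consequence of exact-lattice arithmetic: at 11 dipoles per
diameter a sphere lands on an integer-aligned lattice whose closed-ball
count (739) sits 6 % above the continuum volume estimate — pure lattice
count fluctuation. The tests therefore assert exact agreement with an
independent brute-force point-in-solid count, and volume agreement at the
5 % level only from 16 dipoles per longest dimension upward.

## Conventions and numerical choices

- **Time and polarization.** `exp(−iωt)`; left-circular polarization is the
  Jones vector (1, +i)/√2 with Stokes V = +1, so CIDS = +m14/m11. Flipping
  either convention flips the global CIDS sign; all signs in the package
  are fixed by these two statements, and the identity between the
  Mueller-element route and the explicit two-illumination ratio is tested
  to 1e−8.
- **LDR direction factor.** The Draine–Goodman correction contains a
  direction/polarization factor S. The package default is the
  polarization-averaged, basis-invariant form S = ½ Σ a_μ²(1 − a_μ²), so
  the left- and right-circular solves of one run share the same α and the
  Born and mirror nulls hold to solver tolerance; the per-polarization form
  (`s_mode = "pol"`) and the orientation-isotropic constant S = 1/5
  (`s_mode = "iso"`) are selectable. The imaginary radiative-reaction term
  −(2/3)i(kd)³ is kept exactly, making a real-index dipole scatter without
  absorbing (Im(1/α) = −(2/3)k³ identically).
- **Solvers.** The interaction product is evaluated either as the O(N²)
  direct sum (reference) or as a block-Toeplitz lattice convolution with
  3-D FFTs on the padded bounding grid; the two agree to ~1e−15 relative,
  contract ≤ 1e−10. The coupled system is solved with BiCGSTAB (relative
  residual 1e−5 by default, the conventional coupled-dipole stopping
  magnitude) with a first-Born initial guess, or by dense LAPACK
  factorization for small systems; symmetry tests tighten `tol` as needed.
  A contrast-free model (m = 1) short-circuits to the exact zero solution.
- **Orientation averaging.** A product quadrature — uniform α, Gauss–
  Legendre in cos β, uniform γ, weights normalized to 1 — rather than any
  particular legacy integrator: a stated, testable convergence contract
  (averaged m11 stable to well under 1 % on node doubling for small
  models) replaces scheme identity. Even `n_alpha` with Gauss–Legendre β
  closes the node set under the reflection conjugation (α, β, γ) →
  (π−α, π−β, γ), which is what makes the averaged CIDS of an achiral
  particle cancel exactly. Averaged CIDS is the ratio of *averaged*
  Mueller elements, equal to the ensemble-intensity ratio
  (⟨I_L⟩−⟨I_R⟩)/(⟨I_L⟩+⟨I_R⟩), not the average of per-orientation ratios.
  Implementation-wise the particle is voxelized once and the laboratory
  frame is rotated into the particle frame per node (z-y-z intrinsic Euler
  angles; (0,0,0) aligns the incidence with the helix axis) — physically
  identical to rotating the particle, and it avoids per-orientation
  re-voxelization noise while letting one dense factorization serve all
  nodes (`s_mode = "iso"`). With per-node polarizabilities the Krylov path
  reuses one FFT kernel instead.
- **Angle grids and normalization.** Fixed-orientation runs use the full
  θ ∈ [0°, 360°) circle in the fixed xz scattering plane; averaged runs use
  [0°, 180°]. Amplitudes follow the Bohren–Huffman 2×2 layout with
  dC/dΩ = |S|²/k²; efficiencies are normalized by the equal-volume-sphere
  radius a_eff = (3Nd³/4π)^{1/3}. The Mueller map is built from the
  coherency-to-Stokes similarity transform M = A (J ⊗ J*) A⁻¹ (derived
  once numerically, cross-checked element-wise in the tests), avoiding
  hand-transcribed formula tables.

## What the geometry generator emulates — and what it does not

The geometry module doubles as the package's synthetic-data generator: its
defaults *are* the study conditions (the canonical solenoid above), and the
test fixtures — single spheres, two-dipole pairs, mini-helices — are all
built from the same code paths. It reproduces idealized, noiseless,
monodisperse fibers at exact poses. It does not emulate conformational
heterogeneity, linker DNA, two-start zig-zag topologies, anisotropic or
absorbing nucleosome material, or instrument effects (finite apertures,
detector noise). Passing tests therefore demonstrate the scattering physics
of the idealized model — symmetry nulls, mirror antisymmetry, parameter
trends, oracle agreement — not agreement with measured CIDS of real
chromatin.

## Known limitations

- Signals are weak in absolute terms (peak |CIDS| ~ 5×10⁻³ for the default
  one-turn fiber at 300 nm); experimental comparability is limited by the
  idealizations above.
- The LDR variant is plain Draine–Goodman; bit-compatibility with any
  specific legacy DDA code's polarizability/weighting options is out of
  scope, as are periodic boundaries, substrates and near-field output.
- Orientation averaging cost grows linearly with quadrature size; the dense
  multi-node path requires the shared `"iso"` polarizability (the
  approximation is ~4×10⁻⁴ relative in α at the test discretizations).
- For the right-on-left stack at a *fixed* orientation the chiral signal is
  of the same ~5×10⁻³ order as single-turn fibers, while its orientation
  average cancels to machine precision; the package treats the exact null,
  not any particular fixed-orientation magnitude, as the structural claim.

## Reproducibility

All pipelines are deterministic: rerunning any sweep reproduces its table
bit-identically, result writers emit locale-independent fixed-order text,
and the only randomness anywhere (the random site set in the solver
contract check of `scripts/acceptance.R`) is seeded from the command line.
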