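---
title: "Modeling extracellular potentials with femvc: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling extracellular potentials with femvc: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The forward problem

`femvc` computes the extracellular electric potential generated in a
volume conductor — a head, a cortical surface under an ECoG grid, or a
multi-electrode-array (MEA) chamber — by known current sources
(neuronal dipoles or stimulating electrodes). Under the quasi-static
approximation the potential obeys a Poisson equation; when capacitive
displacement currents are retained the material coefficient becomes the
complex admittivity

$$ -\nabla\cdot\big[(\sigma(\omega) + j\omega\varepsilon_0
\varepsilon_r(\omega))\,\nabla\varphi\big] = \nabla\cdot\mathbf J_p ,$$

with a homogeneous Neumann condition on the exterior boundary. The
package solves this with Lagrangian P1 (optionally P2) finite elements
on tetrahedral meshes. Complex arithmetic is carried in the *real block
formulation*: writing $y = y_r + j y_i$ and $u = u_r + j u_i$, the
assembled operator is the $2N \times 2N$ matrix
$[[A(y_r), -A(y_i)], [A(y_i), A(y_r)]]$ acting on $[u_r; u_i]$. This
was chosen over native complex matrices deliberately: each block equals
the real stiffness assembled with one coefficient field, so every block
is testable on its own, and the test suite checks the whole block solve
against a dense native-complex factorization on small meshes (at
tolerance 1e-10).

## Dielectric dispersion

Tissue spectra follow the four-term Cole-Cole model

$$\hat\varepsilon(\omega) = \varepsilon_\infty + \sum_{n=1}^{4}
\frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} +
\frac{\sigma_{ion}}{j\omega\varepsilon_0},$$

with $\varepsilon_r = \mathrm{Re}\,\hat\varepsilon$ and
$\sigma = -\omega\varepsilon_0\,\mathrm{Im}\,\hat\varepsilon$. The
complex power uses the principal branch, $j^x = e^{j\pi x/2}$, the
standard Cole-Cole convention that yields positive loss. $f = 0$ is
evaluated analytically ($\sigma = \sigma_{ion}$,
$\varepsilon_r = \varepsilon_\infty + \sum\Delta\varepsilon_n$), so no
code path ever divides by $\omega = 0$. The response is causal by
construction (each Cole-Cole term is a causal relaxation and the ionic
term is a pure conduction current), which is why Kramers-Kronig
consistency is a documented property rather than a numerical test.

Parameter sets for grey matter, white matter, CSF, cortical bone
(skull) and dry skin (scalp) are embedded as package constants from the
standard literature compilation of tissue dielectric spectra; the test
suite verifies that they reproduce the tabulated 10 MHz permittivities
(320, 176, 109, 36.8, 362) to better than 1%. Two caveats are
deliberate:

* the corresponding 10 MHz *conductivity* column printed alongside
  those permittivities in the source material (6.29, 6.16, 5.2 S/m for
  grey/white/scalp) is internally inconsistent with the dispersion
  model itself, which gives 0.29, 0.16, 0.20 S/m; the package trusts
  the model and never asserts that column;
* Ringer's solution has no published Cole-Cole set, so the packaged
  `ringer` entry is a **synthetic stand-in**: CSF-like relaxation terms
  with an ionic conductivity of 1.5 S/m (physiological saline at room
  temperature).

Users can override or extend every entry via a JSON table
(`tissue_table(overrides = ...)`). JSON (not YAML) is the configuration
format throughout the package because the deployment environment
provides a JSON parser but no YAML parser; the schema is unchanged
otherwise.

## Electrode–electrolyte interfaces

The double layer at a metal/electrolyte interface is modeled per unit
area as a constant-phase-angle pseudocapacitance
$Z_{CPA} = K(j\omega)^{-\beta}$ in parallel with the charge-transfer
resistance $R_{CT} = RT/(nF j_0)$. Defaults: $K = 1.57\,\Omega\,
\mathrm m^2\,\mathrm s^{-\beta}$, $\beta = 0.91$ (platinum-type
microelectrode empirics), $T = 310\,$K, $n = 2$,
$j_0 = 0.1\,\mathrm{A/m^2}$ (platinum-order exchange current density).
The charge-transfer defaults are assumptions — the underlying
literature discusses them but prints no values — and the two worked
impedance numbers the package reproduces (≈400 kΩ at 100 Hz, ≈6 kΩ at
10 kHz on a conical 80 μm electrode) are CPA-dominated and insensitive
to them. The wetted area of a conical recording electrode is its
lateral (slant) surface only; the base is bonded to the substrate.

The interface enters the FEM through Robin boundary conditions
$-\sigma\,\partial\varphi/\partial n = y_k(\varphi -
\varphi_{metal,k})$ on each electrode patch, with $y_k = g + jb$ the
surface admittance of the chosen network. Recording electrodes are
*floating*: their metal potential is an extra scalar unknown tied to
the tissue potential by the Lagrange constraint $\varphi_{metal} =
\frac 1S \int_S \varphi\,\mathrm dS$. A consequence worth knowing: with
this constraint a floating electrode draws exactly zero net current,
which the tests verify.

## Solvers and the potential reference

CG and GMRES are implemented in the package (the R ecosystem in the
target environment has no sparse Krylov solver), with Jacobi (default),
none, or a CHOLMOD Cholesky factorization of the real stiffness block
("chol") as preconditioners. The "chol" option is what makes
head-scale complex-block solves practical: preconditioning the block
system by its real part clusters the spectrum on a segment
$1 + j\,\lambda$ and GMRES converges in a few dozen iterations
regardless of mesh size. Complex-block and floating-electrode systems
are not symmetric positive definite, and the package *enforces* GMRES
for them.

Pure-Neumann problems are referenced to zero volume mean
($\int_\Omega \varphi\,\mathrm dx = 0$). On the GMRES path this is one
bordered Lagrange row; on the CG path the same field is obtained by
deflating the constant nullspace during the iteration and shifting the
volume-weighted mean afterwards — for consistent sources the two are
algebraically identical, and the tests check cg/gmres agreement.
Dipoles are represented as two opposite monopoles (default 100 μA, 1 mm
apart) whose loads are distributed by evaluating the basis functions at
the source positions — not by snapping to the nearest node — so source
placement accuracy does not depend on the local mesh.

## Synthetic meshes: what they emulate and what they do not

No external tetrahedral mesh generator is assumed. The layered-sphere
generator is structured: an icosphere triangulation is replicated on
graded radial shells, shell gaps are filled with prisms split into
three tets each (quad diagonals chosen through the smallest global
vertex index, which makes adjacent prisms agree and the mesh
conforming), and the core ball is a fan around the center node. All
shell nodes lie exactly on their nominal radius, so layer interfaces
(e.g. brain/CSF at 7.9 cm) are spherical up to faceting. The
slab-in-bath MEA fixture is a rectilinear grid whose lines snap to slab
and electrode-patch boundaries (patch areas are exact), each hexahedron
split into six Kuhn tetrahedra; the cylindrical bath wall of a real MEA
chamber is approximated by a rectangular prism.

These fixtures emulate the *topology and physics* of the published
geometries — four nested head compartments, a tissue slab with
electrode patches in a conducting bath — but not their meshes: no
12-million-element head, no digitized MEA chamber, no realistic
(MRI-segmented) anatomy. Anisotropic conductivity tensors are
supported and tested on synthetic meshes, but no subject-derived tensor
data ships with the package. A green test therefore establishes
correctness of the numerics on faithful stand-in geometry, not
agreement with any specific laboratory set-up.

Refinement is red-green: marked cells split 1:8 (four corner tets plus
the interior octahedron cut along its shortest diagonal,
deterministic tie-break by axis order); hanging nodes are removed by
green closures for one refined edge (bisection), two refined edges
(1:3 same-face with a smallest-vertex quad diagonal, or 1:4 for
opposite edges) and three refined edges on a face (1:4); any other
pattern promotes the cell to red until the configuration stabilizes.
Midpoints are *not* projected onto curved boundaries, so child volumes
sum exactly to the parent volume and subdomain bookkeeping is
conservative. For convergence studies an opt-in `snap_radii` argument
projects boundary-edge midpoints back onto nominated spheres; this
trades exact volume conservation for geometric fidelity and is how the
order-of-convergence test builds its nested mesh family.

## The analytic four-sphere reference

The validation oracle is the classical Legendre series for a current
dipole inside concentric spherical shells, generalized verbatim to
complex admittivities. Per harmonic $n$ the radial profile in layer $s$
is written $A_s (r/r_s)^n + B_s (r_{s-1}/r)^{n+1}$ — normalized so all
coefficients stay O(1) up to $n = 1000$ without log-space tricks — and
the $2L-1$ coefficients follow from a small dense solve per harmonic.
The dipole moment is decomposed into a radial part (zonal harmonics
$P_n$) and a tangential part (sectoral $P_n^1\cos\phi$, positive
convention without the Condon–Shortley phase); both recurrences are
upward and numerically stable here because the radial factors decay
geometrically. The implementation is validated against two independent
closed forms: the infinite-medium dipole (boundary pushed to 10 m) and
a homogeneous Neumann sphere whose coefficients are known explicitly.

The error metric is the relative difference
$RD = \frac 1N\sum_i |\phi_i - \psi_i| / \max|\psi|$ over quasi-uniform
Fibonacci-lattice points on the brain/CSF interface. The lattice is a
choice (the original work does not state its sampling); RD is
insensitive to it at these densities. Because the analytic series
carries no potential-reference constraint while the FEM field is
referenced to zero volume mean, both samples have their sample mean
removed before RD is formed. Series truncation at 1000 terms is far
converged for dipoles a few millimetres below the surface; the
truncation tail decays like $(r_{dip}/r_1)^n$, which at exactly 1 mm
depth leaves ~3e-5 after 500 terms — the tests assert depth-resolved
geometric bounds rather than a flat threshold.

For the packaged desk-scale validation (tangential dipole 5 mm deep,
10 MHz, complex admittivities), the mesh is refined in an angular cap
around the source axis intersected with a radial band spanning the
dipole and the evaluation surface. The extent of that region is a
package choice — the source publication states only a target inradius
at the region of interest, not its extent — sized to land at roughly
3×10⁵ complex-block unknowns. The resulting RD ≈ 9×10⁻⁴ is an order of
magnitude below the 0.04 acceptance bound, as expected for the deepest
(easiest) dipole.

## FEM–Fourier transient stimulation

A stimulating voltage pulse (square, alpha or single-period sine,
centered in a zero-padded record) is decomposed by a real FFT; the
frequency-domain FEM is solved once per retained frequency for unit
metal potential and scaled by the spectral coefficient (the problem is
linear), and probe time courses are rebuilt by the inverse FFT.
Choices the source material leaves open, fixed here:

* "average frequency of the pulse FFT" is defined as the
  amplitude-weighted mean $\sum f|c(f)| / \sum |c(f)|$ over positive
  frequencies — the least arbitrary reading, configurable in code;
* the DC component is solved with a purely resistive assembly (the
  Cole-Cole DC limit) and the faradaic interface branch alone, since
  both the CPA element and the $1/(j\omega)$ term diverge at DC;
* spectra are pruned at a relative threshold (default 1e-4) with the
  dropped L2 energy reported; threshold 0 recovers the exact
  50,001-frequency decomposition of a 1 s record at 10 μs sampling.

The packaged MEA demonstration runs on the slab-in-bath stand-in, so
its waveforms are qualitative mirrors of the published stimulating
electrode figure, never numeric targets. The pipeline's testable
content is structural: a dispersionless medium with a faradaic
interface transmits the pulse shape unchanged (to 1e-6 after
normalization); with a pseudocapacitive interface the waveform is
dominated by the interface (capacitive-vs-dispersive *tissue* modes
nearly overlap, within a few per cent); and Gibbs ringing ahead of the
pulse decreases with more padding and faster sampling.

## Numerical and degenerate-input policy

* Tolerances: Krylov solves default to 1e-8 relative residual;
  acceptance runs use "chol" preconditioning.
* The tetrahedron inradius is $3V/\sum_f A_f$; refinement interprets
  "minimum inradius" as *split while the inradius exceeds the
  threshold*.
* Duplicate nodes are defined at 1e-12 m; meshes are validated for
  positive orientation, facet incidence and face-sharing conformity.
* CPA at $f = 0$, nonfaradaic DC, dipoles outside the innermost
  analytic layer, unmapped subdomain markers, overlapping electrode
  patches and non-convergent solves all raise errors naming the
  offending quantity; nothing silently degrades.

## Known limitations

Only structured synthetic meshes are generated natively (arbitrary
tetrahedral meshes are accepted through MSH 2.2 input); no MRI
segmentation or realistic head geometry; MEG, inverse problems and
nonlinear (Butler–Volmer) interface kinetics are out of scope. P2
elements are implemented and tested for interpolation exactness and
linear-solution reproduction, but the validation studies all run P1.
The Fourier pipeline assembles one system per frequency rather than
caching symbolic factorizations across frequencies; at desk scale this
costs seconds, at head scale it would be the first thing to optimize.
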