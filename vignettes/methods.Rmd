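---
title: "Structural coarse-graining with cgiter: models, stabilization, constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural coarse-graining with cgiter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inverse problem

Structural coarse-graining seeks tabulated pair potentials
$u_{\alpha\beta}(r)$ whose equilibrium structure reproduces target radial
distribution functions $g_{\alpha\beta}(r)$. All potentials are stacked
into one vector $u = (u_{AA}, u_{AB}, \dots)$ over the
$n_t(n_t{+}1)/2$ unordered interactions of $n_t$ bead types, each
tabulated on a uniform grid $r_i = i\,\Delta r$ up to the cutoff
$r_\mathrm{cut}$ ($n_\mathrm{cut}$ interior points); the RDF residual is
matched up to $r_\mathrm{res} \ge r_\mathrm{cut}$. Newton's method
updates

$$u_{k+1} = u_k + J^{-1}(g_\mathrm{tgt} - g_k),$$

and the Gauss--Newton variant minimizes
$\lVert W (J\,\Delta u - (g_\mathrm{tgt}-g_k)) \rVert_2$ with a diagonal
weighting $W$, optionally subject to linear constraints
$K\,\Delta u = d$. Everything therefore hinges on the Jacobian
$J = \partial g/\partial u$, which this package obtains either from
integral-equation theory (HNC family) or from sampled particle-count
cross-correlations (IMC), or approximates diagonally (IBI / low-density).

# Integral-equation machinery

## Symmetry-reduced RISM

For molecular liquids the site--site RISM equation in Fourier space,
$\hat h' = \hat\omega'\hat c'\hat\omega' + \hat\omega'\hat c'\rho\,\hat h'$,
relates total ($h = g - 1$) and direct ($c$) correlation functions through
the intramolecular density matrix $\hat\omega'$ (a rigid site pair at
distance $b$ contributes $\sin(kb)/(kb)$; tabulated distance
distributions contribute their transform). Indistinguishable sites allow
a block-orthogonal similarity transformation that collapses the
$n_{td}\times n_{td}$ site matrices to $n_t\times n_t$ type matrices.
Because trajectory analysis produces *site-averaged* functions, the
reduced matrices are formed directly with multiplicity factors,

$$\hat H_{\alpha\beta} = \sqrt{n_\alpha n_\beta}\,\hat h_{\alpha\beta},
  \qquad
  \hat C_{\alpha\beta} = \sqrt{n_\alpha n_\beta}\,\hat c_{\alpha\beta},$$

with the density matrix in the reduced equation being the *molecular*
density of the species owning each type; the explicit site-space
transformation is never needed. `build_omega()` assembles the reduced
$\hat\Omega(k)$ the same way,
$\hat\Omega_{\alpha\beta} = (n_\alpha n_\beta)^{-1/2}
\sum_{i\in\alpha,\,j\in\beta}\hat\omega_{ij}$. These conventions are
pinned by a normative test: solving the full $3\times3$ site equation for
a rigid symmetric A--B--A trimer and the reduced $2\times2$ equation from
the same site-averaged input gives identical direct correlation
functions to $10^{-10}$.

The reduced equation is solved for the direct correlation as
$\hat C = \hat\Omega^{-1}\hat H(\hat\Omega + \rho\hat H)^{-1}$
(`direct_correlation()`). At $k = 0$ the intramolecular matrix of a rigid
molecule is rank one (all sites fully correlated), so that wave vector is
skipped; the inverse radial transform carries zero weight there, making
the omission exact rather than an approximation.

## HNC closure, initial guess, Jacobian

The hypernetted-chain closure $u = k_BT\,(h - c - \ln g)$ serves three
roles: as the initial potential guess from the full-length target RDF
(`initial_guess(method = "hnc")`, cut at $r_\mathrm{cut}$ and shifted to
zero beyond); as the closure inside the forward surrogate; and,
differentiated, as the analytic *inverse* Jacobian

$$\Big(\frac{\partial u}{\partial g}\Big)_{\alpha\beta i,\gamma\epsilon j}
 = k_BT\Big[\delta_{\alpha\beta,\gamma\epsilon}\delta_{ij}
   \Big(1 - \frac{1}{\bar g_{\alpha\beta i}}\Big)
   - \frac{\partial c_{\alpha\beta}(r_i)}{\partial h_{\gamma\epsilon}(r_j)}\Big],$$

where the diagonal uses the average $\bar g = (g_\mathrm{tgt}+g_k)/2$ of
target and current RDF — the stabilization that keeps Newton updates
bounded where the RDF rises from zero and the plain $1/g_k$ diagonal
would overreact to order-of-magnitude (but absolutely tiny) mismatches.
The derivative $\partial\hat c/\partial\hat h$ follows from perturbing
the reduced solution,
$\Delta\hat C = U\,\Delta\hat H\,W$ with
$U = \hat\Omega^{-1} - \hat C\rho$ and
$W = (\hat\Omega+\rho\hat H)^{-1}$, vectorized via
$\mathrm{vec}(UVW) = (W^\top\!\otimes U)\,\mathrm{vec}(V)$, and is
conjugated into real space by the discrete radial Fourier matrices
(`dcdh_real()`). The two orientations of each cross interaction are
merged exactly once — derivative rows averaged, columns summed — so the
matrix acts on unordered interactions. For a single bead type the whole
construction collapses to the closed form
$\partial\hat c/\partial\hat h = (1+\rho\hat h)^{-2}$, one of several
analytic anchors in the test suite; the full matrix is checked against
central finite differences of the forward solver (relative error below
$10^{-3}$ on 64-point grids, and $10^{-9}$ at matched supports).

## How the update is applied

Two lessons from implementation, documented here because the design was
genuinely open:

1. **Newton uses the closure inverse as-is.** The elements of
   $\partial u/\partial g$ above are exact for the surrogate, so the HNCN
   update is $\Delta u = (\partial u/\partial g)(g_\mathrm{tgt}-g_k)$
   applied over the full residual range and then cut and shifted at the
   cutoff. An alternative that first inverts the matrix and truncates it
   to the cutoff block was tried and rejected: the truncated problem has a
   near-null mode (a slowly varying potential component that barely moves
   the RDF inside the cutoff while distorting it outside), and Newton
   steps in that formulation drift along it — the in-cutoff residual
   converges while the potential walks away from the generating one.
   Update bins whose mean RDF lies below $10^{-8}$ are frozen: they carry
   no structural signal, and the closure diagonal there exceeds floating
   range.
2. **Gauss--Newton weights and regularization.** The default weighting is
   the onset-and-tail emphasis $W = r^2/(g_\mathrm{tgt}+10^{-30})$, with
   two numerical amendments: the denominator is floored at $10^{-8}$ so
   the weighted system stays within double range, and rows whose target
   RDF lies below the onset-extrapolation threshold get zero weight —
   those bins are synthetic (fit-generated), and chasing the mismatch
   between two extrapolation fits destabilizes the iteration. Columns of
   frozen bins are zeroed, so the least-norm solution leaves them
   untouched. The least-squares solve truncates relative singular values
   below $10^{-6}$ (`gauss_newton_step(rcond=)`); inside the closed loop
   the default is $10^{-4}$, because directions weaker than that only
   amplify forward-solver roundoff (a $10^{-10}$ cutoff, tried first,
   admitted directions with gain $\sim 10^8$ that turned residual noise
   into 20 kJ/mol potential garbage). Equality constraints are handled by
   direct elimination — QR of $K^\top$ splits the step into a particular
   solution (which satisfies $K\Delta u = d$ exactly, regardless of any
   truncation) and a null-space least-squares component — and validated
   against a dense Lagrange-multiplier solve.

## IMC

The inverse Monte Carlo Jacobian is estimated from particle-count
vectors $S$ (pair counts per distance bin): $A = -\beta\,\mathrm{Cov}(S)$
in the NVT ensemble (barostat ensembles are rejected outright — volume
scaling biases the cross-correlations), converted to RDF scale through
$S_{\alpha\beta i} = g_{\alpha\beta i}\,4\pi r_i^2\Delta r\,
N_\alpha N_\beta/(V(1+\delta_{\alpha\beta}))$. The `t-IMC` shortcut
applies the same estimator to reference-ensemble samples and reuses the
matrix. In the onset region the sampled matrix is stabilized by a
row-wise square-root interpolation toward the diagonal low-density
Jacobian $-\bar g/k_BT$ between two RDF thresholds $t_1 = 0.001$ and
$t_2 = 0.1$: below $t_1$ the row *is* the diagonal row, at or above
$t_2$ it is untouched, and the square-root weight compensates the rapid
growth of the RDF across the window. The thresholds compare against the
elementwise minimum of target and current RDF by default — the
conservative choice that triggers stabilization whenever either curve is
in its onset (configurable via `onset_policy(reference=)`).

# Onset extrapolation and metrics

Atomistic RDFs vanish at short distance and are poorly sampled where
they rise. `extrapolate_onset()` fits $-\ln g$ (the PMF in $k_BT$ units)
with $a e^{-br} + c$ over the window of RDF values
$[10^{-3}, 10^{-1}]$ by default and replaces every value below the
extrapolation threshold with $e^{-f}$, floored at $10^{-250}$ so logs
stay finite. The production default window follows common practice with
noisy data; for *noise-free* surrogate targets the well-sampled region
genuinely extends lower and the closed-loop studies here use
$[10^{-4}, 10^{-1}]$. The accuracy of the potential below the sampling
threshold is limited by this fit — about 1% of the PMF in the replaced
band — which is what the recovery metric plateaus at in the closed loop;
this is an information limit of extrapolated data, not an iteration
failure.

Convergence is tracked by
$\chi(u) = \sum_\mathrm{int}\sum_i g_\mathrm{tgt}(r_i)\,
(u_i - u_{\mathrm{ref},i})^2\,\Delta r$ (target-weighted so only sampled
regions count) and
$\chi(g) = \sum_\mathrm{int}\sum_i (g_i - g_{\mathrm{tgt},i})^2\Delta r$.
The noise measure $\sigma$ fits the last 20 points left of the cutoff
with a cubic and averages the root of the squared residuals over the
interactions; on synthetically noised RDFs it scales as
$N_\mathrm{frames}^{-1/2}$, the counting-statistics signature.

# Thermodynamic constraints

For any property $\varphi(r, g, u)$ a first-order expansion with the RDF
response neglected (good after the first iterations) yields one
constraint row $K = -\partial\varphi/\partial u$ with
$d = \varphi_k - \varphi_\mathrm{tgt}$, so $K\Delta u = d$ drives
$\varphi \to \varphi_\mathrm{tgt}$. Implemented properties:

- **virial pressure** (bar): ideal term $k_BT\sum_\alpha\rho_\alpha$ plus
  the discrete virial over half-shifted grid points, forces by centered
  differences of the tabulated potential, species pairs weighted by
  $(2-\delta_{\alpha\beta})\rho_\alpha\rho_\beta$;
- **Kirkwood--Buff integrals** (nm³; 1 nm³ = 1000 Å³):
  $G_{\alpha\beta} = \sum_i 4\pi r_i^2 (g_i - 1)\Delta r$ up to
  $r_\mathrm{res}$ — these depend on $u$ only through $g$, so the row
  chains the integral weights through the step's own Jacobian,
  $K = -(\partial G/\partial g)J$, one row per constrained interaction;
- **intermolecular potential energy per bead** (kJ/mol), the discrete
  pair-energy integral (tested only for molecules without intramolecular
  pair potentials).

All coefficient rows are exact derivatives of the discrete property
sums and are verified against central finite differences. Multiple
constraints combine; feasibility after every constrained step is
enforced to machine precision by construction.

# The surrogate forward model and toy systems

`solve_structure()` closes the reduced RISM equation with HNC and Picard-
mixes the indirect correlation $\gamma = h - c$ (default mixing 0.2,
tolerance $10^{-10}$ on the maximum RDF change; the closed-loop studies
tighten this to $10^{-12}$). If a sweep produces a non-finite iterate the
solve restarts cold with mixing reduced fourfold, twice, before giving
up. It emulates what an MD forward run provides — smooth liquid-like
RDFs with a zero onset — and is deterministic; what it does *not*
emulate is sampling noise (provided separately by
`add_sampling_noise()`, whose per-bin standard deviation follows
counting statistics), dynamic intramolecular response (the rigid
$\hat\Omega$ is static, so the true Jacobian's curved off-diagonal
structure is absent), and any closure error relative to real ensembles.
Consequently, closed-loop tests demonstrate the *algebra and stability*
of the update schemes under a consistent forward map; they do not
certify HNC accuracy for real liquids.

Built-in fixtures (`toy_systems()`), chosen once as the study
conditions:

| system | grid | state |
|---|---|---|
| `single_lj` | 1024 × 0.0025 nm, $r_\mathrm{cut}$ 1.2 nm | LJ σ 0.34 nm, ε 1 kJ/mol, ρ 8 nm⁻³, 120 K |
| `ne_ar` | 1024 × 0.0025 nm, $r_\mathrm{cut}$ 0.9 nm, $r_\mathrm{res}$ 1.4 nm | σ/ε: Ne 0.278 nm / 0.28869 kJ/mol, Ar 0.3401 nm / 0.978628 kJ/mol, geometric-mean cross terms, ρ 5+5 nm⁻³, 100 K |
| `trimer` | 1024 × 0.0025 nm, $r_\mathrm{cut}$ 1.2 nm, $r_\mathrm{res}$ 1.6 nm | rigid A–B–A, bonds 0.25 nm, ρ_mol 3 nm⁻³, 300 K |

The grid spacing sits near the fixed tabulated-potential grid of the MD
engine ecosystem (0.002 nm, the export dialect of `write_table()`);
coarser spacings leave too few points across a steep Lennard-Jones onset
for the extrapolation fit. The mixture densities are a moderate liquid
state chosen for robust HNC convergence. Oracle tests (finite-difference
Jacobians) run on 48–96-point grids; the closed-loop studies use the
1024-point fixtures and finish in well under a minute per loop on one
CPU.

# Iteration loop

`run_loop()` executes, per iteration: forward evaluation → onset
extrapolation → Jacobian construction (or reuse, for `t-` variants:
computed once from the target; when precomputed from target data the
input curves should extend to twice the output range, and shorter input
draws a warning) → constraint rows → solve → scale (default 1; 0.67
damps overshooting updates) → apply → cut and shift to zero at the
cutoff → metrics. When bonded distribution targets are present the
schedule alternates: nonbonded updates on odd iterations, distribution-
IBI on the bonded potentials on even ones — simultaneous updates
overshoot because each treats the other as fixed, producing oscillations.
A divergence detector aborts when $\chi(g)$ rises three iterations in a
row while more than tenfold above its best value, suggesting update
scaling. Identical configuration and seed give bitwise-identical metric
histories.

# Known limitations

- The HNC family assumes a homogeneous fluid and total nonbonded pair
  potentials; additional nonbonded terms (e.g. explicit charges) are out
  of scope, as are Percus--Yevick Jacobians and surface-tension
  constraints.
- Potential values below the RDF sampling threshold are extrapolation,
  accurate only to the onset-fit error.
- Closed-loop IMC requires a forward model that supplies particle-count
  statistics; the built-in surrogate provides structure only, so IMC is
  exercised against synthetic Gaussian ensembles.
- Square Newton with a short cutoff can be ill-conditioned along
  slowly-varying potential modes (see above); prefer the Gauss--Newton
  scheme with $r_\mathrm{res} > r_\mathrm{cut}$ and the default
  weighting when the cutoff truncates real structure.
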