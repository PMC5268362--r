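---
title: "Mechano-sensitive tumour angiogenesis and growth: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-sensitive tumour angiogenesis and growth: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`angiomech` simulates vascular tumour growth as four dynamically coupled
sub-models on a common 3D hexahedral finite-element tissue domain with an
embedded, non-conforming 1D capillary network: (i) explicit reaction–diffusion
biochemistry, (ii) quasi-static hyperelastic tissue mechanics with oxygen-driven
multiplicative growth, (iii) a discrete angiogenesis model (sprouting,
branching, anastomosis, wall remodelling, pressure-induced collapse), and
(iv) a coupled quasi-steady vascular/interstitial/transvascular flow solve.
This vignette documents the governing equations as implemented, every tunable
parameter with units and default, the numerical choices, and what the
desk-scale test scenarios do and do not demonstrate.

## Domain and state

The domain is a cube of host tissue (`domain$edge_length`, default 12 mm) with
a centred spherical tumour (default 1 mm diameter). All balance equations are
Lagrangian — the Laplacians act in reference coordinates — so the mesh, the
embedded network and all fields live on the undeformed configuration; deformed
geometry enters only where it matters physically (segment lengths in the flow
solve, tissue volumes in the density metrics). Elements are labelled tumour or
host by centroid; the two faces x = 0 and x = L carry the vessel inlets and
outlets and are the pinned (zero-displacement) solid boundary, the remaining
faces are traction-free. A `sinh`-graded tensor-product mesh refines the
centre: with `n_per_side = 16`, `grading = 4.6` the minimum edge is
about 0.07 mm, which respects the embedding rule that no vascular segment may
be longer than the local element edge (the maximum tip elongation per
vascular step is `v_vmax * dt_v` = 0.0625 mm).

## Biochemistry

Four normalised species: angiogenic growth factor $\tau$, oxygen $\xi$,
matrix-degrading enzyme $\mu$ (reaction–diffusion) and ECM density
$\epsilon$ (a local ODE on the host domain, $\dot\epsilon = -\delta_\epsilon
\mu \epsilon$). Production terms: hypoxic tumour cells secrete
$Q = \lambda_\tau e^{-2\xi/\bar\xi}$; the vasculature supplies oxygen at
$\lambda_\xi \rho_v$, where $\rho_v \in \{0,1\}$ flags elements containing at
least one well-perfused (mean blood speed $\ge$ 0.1 mm/s), functional
vascular node; enzyme is produced at $\lambda_{\mu c}$ by tumour cells plus
$\lambda_{\mu v} \rho_t$ by tip endothelial cells, with $\rho_t$ the
per-element tip count.

The integrator is mass-lumped forward Euler with the CFL-type bound
$\Delta t = 0.5\, h_{\min}^2 / (6 D_{\max})$, capped at the solid step; on
the default mesh this is a few seconds of simulated time. Two numerical
choices deserve note:

* The trilinear-hexahedron stiffness matrix is not an M-matrix, so sharp
  fronts produce small negative undershoots regardless of the time step.
  These are clipped to zero; a step aborts only if the clipped mass exceeds
  `clip_tol` (default $10^{-3}$) of the species total — start-up TAF fronts
  clip of order $10^{-5}$–$10^{-4}$.
* Reaction terms are evaluated at the same node and time level (no
  operator splitting), the simplest consistent explicit scheme.

Oxygen kinetics were chosen to preserve the physiological diffusion–consumption
penetration length, $\sqrt{D_\xi/\delta_\xi} = 0.2$ mm (the Krogh length),
with a sub-hour relaxation time $1/\delta_\xi$; diffusivity and consumption
are scaled down jointly ($D_\xi = 2$ mm²/day, $\delta_\xi = \lambda_\xi = 50$/day,
fixed point $\xi^* = 1$ under full perfusion) so that the explicit integrator
remains affordable while the steady oxygen field — the quantity that drives
growth and TAF production — is unchanged. TAF uses its physical diffusivity
($D_\tau = 10$ mm²/day $\approx 10^{-6}$ cm²/s) with a 1/day turnover, and
$\lambda_\tau = 100$/day puts the sprouting-permissive region
($\tau \ge \tau^* = 0.02$) roughly 2 mm into the peritumoural stroma, matching
the reported extent of angiogenic activity. The hypoxic-response scale
$\bar\xi = 0.5$ makes TAF secretion significant below about half-normal
oxygen. Concentration normalisation scales are internal to the model; only
ratios such as $\tau/\tau^*$ are meaningful.

## Solid mechanics and growth

Deformation decomposes multiplicatively, $F = F_e F_g$, with
$F_g = \lambda_g I + (\lambda_{g\xi}-\lambda_g)\, \hat n_\xi \otimes \hat n_\xi
+ (\lambda_{g\epsilon}-\lambda_g)\, \hat n_\epsilon \otimes \hat n_\epsilon$
on tumour material and $F_g = I$ in the host. Each stretch derives from a
Green–Lagrange growth strain via $\lambda = \sqrt{2\vartheta + 1}$, and each
strain follows the Gompertz-type oxygen response
$\vartheta(\xi) = \alpha\, e^{-\beta e^{-\gamma\xi}} - \alpha e^{-\beta}$.
The gradient directions in the dyads are normalised to unit vectors — the
dyad must be a pure direction; using the raw gradient would make growth scale
with the squared gradient magnitude and carry the wrong units.

Three choices define the growth history:

* **Irreversibility (ratchet).** The law gives the *total* growth strain as a
  function of the current oxygen level, so an oxygen drop (e.g. after a
  vessel collapse) would shrink the tumour. Growth is inelastic, so each
  quadrature point stores the running maximum of each strain.
* **Rate limit.** The volumetric growth rate is capped at
  $d(\ln J_g)/dt \le$ `g_max` (default 0.7/day, at most daily volume
  doubling — consistent with the reported tissue velocities of order
  0.1 mm/day). Without the cap, a freshly perfused element jumps to its full
  oxygen-saturated stretch within one hourly step.
* **Response shape.** $\alpha_g = 22$, $\beta_g = 40$, $\gamma_g = 6$ place
  the growth switch near $\xi \approx 0.6$ and give a saturated stretch
  $\lambda_g \approx 6$ (volume $\sim 250\times$), the order required to
  reach $\sim$140 mm³ from a 1 mm seed over 40 days. The directional strains
  use the same shape with small amplitude ($\alpha = 1.5$).

Both tissues are hyperelastic with the generalised polynomial energy
$W = \zeta\,[c_{10}(\bar I_1-3) + c_{20}(\bar I_1-3)^2 + c_{01}(\bar I_2-3)
+ c_{02}(\bar I_2-3)^2 + c_{11}(\bar I_1-3)(\bar I_2-3)]
+ \kappa (J-1)^2/2$, where only the isochoric part is scaled by the ECM
integrity factor $\zeta$ (equal to $\epsilon$ in the host, 1 in the tumour).
Defaults (kPa): host $c_{10}=1, c_{20}=0.5, c_{01}=0.25, \kappa=50$; tumour
twice as stiff — small-strain moduli of order 10 kPa, the soft-tissue range.
The reference second Piola–Kirchhoff stress is the standard pull-back
$J_g F_g^{-1} S_e F_g^{-T}$ with $S_e = \partial W/\partial E_e$.

The equilibrium solve is full Newton with a numerically consistent tangent
(per-element forward differences of the analytic residual, assembled in
compiled code), a backtracking line search, and *adaptive growth
continuation*: the growth field advances from the last converged state
towards the target in fractions that halve on failure and double on success;
an unconvergeable remainder (below $2^{-6}$) is carried to the next hourly
solve rather than aborting. Convergence: relative residual $10^{-8}$ or
increment $10^{-10}$.

The tissue hydrostatic pressure handed to the vessel-compression model is,
by default, the Cauchy-equivalent $-\mathrm{tr}(J^{-1} F S F^T)/3$
(compression positive), converted once to mm-Hg (× 7.50062) at the vascular
coupling; `thp_measure = "reference"` selects the literal $-\mathrm{tr}(S)/3$.

## Angiogenesis

Tip extension direction is the normalised superposition
$\hat e = \ell/\lVert\ell\rVert$, $\ell = k_\tau \nabla\tau +
k_\epsilon \nabla\epsilon - k_m t$, where $t$ is the unit eigenvector of the
smallest eigenvalue of the stress tensor (sign fixed against the previous
direction; isotropic stress falls back to it). `chemo_only` mode zeroes
$k_\epsilon$ and $k_m$. Tip speed decays with lumen radius,
$v = v_{v0} + v_{v1} e^{-R/\tilde R}$, clamped at $v_{vmax} = 0.25$ mm/day
(and enforced below the 2 µm radius cutoff); extension requires
$\tau \ge \tau^*$, a functional, non-frozen tip, and a wall pressure ratio
below the collapse threshold. A step leaving the domain is clamped to the
boundary and the node permanently frozen.

Branching is stochastic: one uniform draw per node per vascular step,
consumed in node-id order, against
$P = w_A e^{-(a-m_A)^2/2s_A^2} + w_D e^{-(d-m_D)^2/2s_D^2}$ — mode-scaled
Gaussian components in node age and network-geodesic distance to the nearest
branching node (when no branching node exists the distance component takes
its modal value; this is what lets unbranched parent vessels initiate
sprouts). Hypo-perfused vessels carry a more permissive set
($w = 0.03$ each) than well-perfused ones ($w = 0.015$), enforced by config
validation. A new branch takes the taxis direction rotated to at least 30°
from the parent direction. Tips within 40 µm of a non-adjacent functional
node anastomose.

Wall remodelling is driven by wall shear stress through the remodelling time
$t_m$: $t_{mT} = 10$ d above the radius-dependent threshold
$\bar\tau_f = 2.4\times10^{-8}/R$ mm-Hg (R in metres; equal to
$8\mu_B v_{thresh}/R$ at the 0.1 mm/s perfusion threshold), rising smoothly
to $t_{m0} = 100$ d at zero shear. With $\bar t = (t - t_g)/t_m$ the lumen
follows $R = R_{\min} + (R_{\max}-R_{\min}) e^{-11 e^{-4.4 \bar t}}$ (tips
stay at $R_{\min}$), the wall thickens linearly $h_{\min} \to h_{\max}$, and
the pore radius decays cubically $r_p^{\max} \to r_p^{\min}$. The radius law
is used as a continuous curve for all $\bar t$ (it saturates at $R_{\max}$);
a discontinuous jump to $R_{\max}$ at $\bar t = 1$ would contradict the
continuity of the other two laws. Pre-existing vessels ($t_g = 0$) never
remodel.

Compression and collapse: the wall pressure ratio
$\bar p = (p_{int} + p_h)/p_{vsc}$ is compared against the node's critical
pressure $p_c = 1 + E_w e_c / 2$, where the wall stiffness $E_w$
interpolates linearly with the remodelling level between 1.3 (nascent) and
5.22 (parent vessels), i.e. $p_c \in [1.6, 3.4]$ at the critical strain
$e_c = 0.92$. For $1 < \bar p < p_c$ the radial strain follows the smaller
root of the quadratic wall law and the effective radius is reduced
(reversibly — compression relaxes if the load does); at $\bar p \ge p_c$ the
vessel collapses permanently: radius divided by $\lambda_r = 10^3$, zero
blood pressure, exclusion from flow, sprouting and branching. Functional
nodes left without any route to an inlet or outlet collapse too, unless an
anastomosis provides a second path.

## Flow

One symmetric sparse system couples all pressures: Poiseuille conductances
$\pi R^4 / 8 \mu_B L$ on vessel segments (deformed lengths), Darcy
conductances $K_{int} A_{int}/L$ on the element-edge graph of the mesh
(with $A_{int} = 2\pi\bar R / S_{vsc}$ from the per-element vascular surface
density, falling back to the initial-lattice values where no vessel is
present), and Starling exchange $K_{vsc} A_{vsc} (p_{eff} - p_{int})$
distributing each functional node's filtration to its host element's
vertices by trilinear weights ($A_{vsc}$ = half the lateral area of the
attached segments; $K_{vsc} = \gamma_p r_p^2 / 8 \mu_B h$;
$p_{eff} = p_{vsc} - \sigma_o(\pi_{vsc} - \pi_{int})$). Dirichlet anchors:
25/10 mm-Hg at inlets/outlets, 0 at collapsed nodes, 0.1 mm-Hg for the
interstitium on the tagged faces. Wall shear stress is taken as
$\tau_f = R|\Delta p|/L$ — twice the conventional Poiseuille value, kept in
this form because the remodelling threshold coefficient is calibrated to it.
Blood viscosity $\mu_B = 3\times10^{-5}$ mm-Hg·s (4 cP) follows from that
calibration; interstitial conductivities ($10^{-5}$ host,
$3\times10^{-5}$ mm²/(mm-Hg·s) tumour), the pore fraction
$\gamma_p = 10^{-5}$ and the osmotic pair
$\sigma_o = 0.91$, $\pi_{vsc} - \pi_{int} = 5$ mm-Hg are standard
literature-order values; the resulting nascent-wall conductivity
($\sim 10^{-5}$ mm/(mm-Hg·s)) matches measured hyper-permeable tumour
vessels, and omitting the osmotic term changes interior pressures only
modestly.

## Coupling loop and initial state

Per vascular step (6 h): 6 × [one hour of biochemical sub-cycling, then a
solid solve], then the network update in the order extension → branching →
anastomosis → remodelling, the coupled flow solve, the compression/collapse
re-assessment with fresh pressures, and a flow re-solve if the topology
changed. Initial state: parallel straight capillaries on a 0.6 mm square
lattice spanning the inlet/outlet faces (30 µm lumen radius, mature walls),
rerouted radially so that no line crosses a tumour-labelled element — on a
fine mesh this footprint converges to the tumour sphere itself; $\tau = \mu
= 0$, $\xi = 1$ (host) / 0 (tumour), $\epsilon = 1$, zero deformation, and
one initial flow solve that also fixes the day-0 vascular density used as
normalisation denominator. Checkpoints carry the RNG state, so a resumed run
is bit-identical to an uninterrupted one.

## Desk-scale scenarios and what they show

The test-suite reference scenario uses the full 12 mm domain on a
centre-graded $10^3$ mesh (minimum edge 0.38 mm, which resolves the 1 mm
tumour with the avascular ring at ~0.5 mm as in the full setup), 16 simulated
days for the combined-vs-chemotaxis contrast and 12 days for the wall-stiffness
scenario, one seed per scenario (plus three seeds for the synthetic
distance-map recovery). These sizes keep the default suite within a practical
run time; they reproduce the *mechanisms* — interstitial hypertension with an
intratumoural plateau, the rising hypo-perfused fraction, growth-induced
collapse and its suppression by stiffer walls, circumferential versus radial
peritumoural vessel orientation — but not the 40-day end-point magnitudes
(normalised density ≈ 3.4, tumour volume ≈ 141 mm³), which require the full
configuration and far longer integration. Passing desk-scale tests therefore
validate the implementation and the direction of every reported effect, not
the full-scale quantitative endpoints; the two full-scale bands that are
scale-robust (plateau interstitial pressure, collapsed fraction) are met
already at desk scale.

The synthetic generator also simplifies reality in ways worth keeping in
mind: one homogenised growth factor, element-binary perfusion flags, constant
blood viscosity (no haematocrit partitioning), no lymphatics, no advection of
solutes, and an initial vasculature that is perfectly regular rather than
sampled from measured distributions.

## Known limitations

* The quality of the tumour's hypoxic core depends on the mesh resolving the
  0.2 mm oxygen boundary layer; on very coarse meshes the tumour rim
  over-oxygenates and growth starts early.
* Cross-links between the initially parallel, identically loaded capillaries
  carry little flow until remodelling breaks the symmetry, so perfusion of
  the new network builds up slowly.
* The FD element tangent makes Newton convergence linear near round-off;
  tolerances are set accordingly.
* Network data structures are grown incrementally in R; runs beyond ~10^5
  vascular nodes are better served by chunked storage.
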