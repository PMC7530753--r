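---
title: "Model and methods: a particle tube that learns peristalsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a particle tube that learns peristalsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`peristim` simulates a fluid-filled flexible tube — a crude intestine — as a
coupled particle system, and puts a reinforcement-learning agent in charge of
its contractions. Three ingredients:

**Fluid (SPH).** The luminal content is weakly compressible smoothed-particle
hydrodynamics. Pressure follows the Tait equation of state

$$P = \frac{c_0^2\,\rho_0}{7}\left[\left(\frac{\rho}{\rho_0}\right)^7 - 1\right],$$

with reference density $\rho_0 = 1000$ kg m$^{-3}$. Pairwise viscosity uses
the standard artificial-viscosity form

$$\Pi_{ij} = -a\,h\,\frac{c_0}{\rho_{ij}}\,
  \frac{\mathbf v_{ij}\cdot\mathbf r_{ij}}{r_{ij}^2 + b\,h^2},
  \qquad \rho_{ij} = \rho_i + \rho_j,$$

with smoothing length $h = 9\times10^{-3}$ m, stabiliser $b = 0.01$, and $a$
mapped from the kinematic viscosity through
$\nu_\mathrm{eff} \approx a h c_0 / (2(d+2))$ in $d = 3$ dimensions
(`viscous_alpha_from_nu()`). Forces assemble as
$\mathbf F_i = -\sum_j m_i m_j (P_i/\rho_i^2 + P_j/\rho_j^2 + \Pi_{ij})
\nabla_i W$ over a cubic-spline kernel with support $2h$. The viscous term is
applied for all pair velocities, not gated on approach: it models physical
viscosity, not a shock switch.

**Membrane (lattice springs).** The wall is a single-layer cylindrical shell
of particles joined by Hookean bonds, $F = k (r_{ij} - r_0)$ with
$k = 9\times10^{-2}$ N m$^{-1}$ and nominal spacing $r_0 = 6\times10^{-3}$ m.
Each wall particle is additionally tethered to its build position with a weak
spring $k' = 5\times10^{-4}$ N m$^{-1}$, which restores the resting shape
after a contraction. A contraction applies a constant radial force
$f_0 = 4\times10^{-4}$ N toward the tube axis to every particle of one of the
ten axial slices; the force has no axial component by construction.

**Interface.** Fluid and wall exchange (i) a repulsive potential
$U = A[1 + \cos(\pi r/r_0)]$ for $r < r_0$, $A = 2\times10^{-6}$ J, which
prevents compenetration, and (ii) the same pairwise viscous force as the
fluid, which damps slip and approximates no-slip. Wall particles carry no SPH
density; they enter $\rho_{ij}$ at $\rho_0$.

Newton's equations are integrated with velocity Verlet at
$\Delta t = 10^{-3}$ s; the box is periodic along the tube axis only, and
winding counts maintain unwrapped axial coordinates so that the
centre-of-mass bookkeeping is immune to boundary crossings.

**Controller.** Every $\Delta T = 1$ s the agent observes the 10-component
binary activation vector (which slice is contracting) and chooses the next
contraction. Q-values come from a dense 10–50–50–10 network (relu, relu,
linear) trained online with one Adam step per transition on the squared
temporal-difference error
$[r + \gamma \max_{a'} Q(s', a') - Q(s, a)]^2$, $\gamma = 0.5$, masked to the
taken action. Exploration is $\varepsilon$-greedy with $\varepsilon$ decaying
linearly from 1.0 to 0.1 over 30,000 episodes in the full schedule. The
reward of an action is the axial displacement of the fluid's centre of mass
over its one-second window; forward is positive. Episode efficiency is
summarised by the dimensionless cumulative reward
$R^* = (\Delta x_\mathrm{tot} V_\mathrm{fluid}/L)\,/\,V_\mathrm{squeezed}$:
the plug-flow-equivalent volume displaced forward over the volume squeezed
out of the contracting sections ($\approx 1$: efficient peristalsis; 0:
symmetric splitting; negative: retrograde flow). The squeezed volume per
action is the drop from each contracted slice's rest volume to its minimum
volume during the action, with slice volume estimated from the mean membrane
radius.

# Geometry presets and what they represent

`tube_preset("full")` reproduces the reference scale: a 0.6 m tube with
12,078 fluid and 2,500 membrane particles (14,578 particles, 43,734
positional degrees of freedom). The exact ring/row decomposition behind those
counts is not published; the preset documents one reconstruction — 100
membrane rings of 25, and 99 fluid planes of 122 particles on concentric
rings — and should be read as such. The printed tube diameter
($5\times10^{-3}$ m) is mutually inconsistent with the printed particle
counts, masses and spacings (12,078 particles of $2.5\times10^{-4}$ kg at
$\rho_0 = 1000$ occupy two hundred times that cylinder; the membrane spacing
$r_0$ and smoothing length $h$ both exceed it). All other printed constants
triangulate to a diameter of $5\times10^{-2}$ m — 2,500 membrane particles at
$\approx 6$ mm spacing tile exactly a $0.05\,\mathrm m \times \pi$
circumference over 0.6 m — so the package takes 0.05 m as the reference
diameter and exposes it as an ordinary geometry field.

`tube_preset("desk3d")` is the desk-scale experimental preset: a 10× shorter
tube (0.06 m) with the same diameter, the same ten slices, the same membrane
surface density (one 25-particle ring per slice, staggered), and the same
particle masses, about 1,000 particles in total. `desk3d_fast` thins the
fluid lattice slightly (≈ 800 particles) and is used for training runs;
`tiny` (≈ 270 particles) is a narrower tube for structural and bookkeeping
tests — its fluid column is too thin for clean transport physics and it is
not used for quantitative transport claims.

Desk-scale caveats, found the hard way and worth recording:

* **Fluid particle mass.** The reference model's fluid particles are heavier
  ($2.5\times10^{-4}$ kg) than a mass-density-consistent lattice would make
  them. That excess inertia is essential: with lattice-consistent masses
  ($\Delta^3\rho_0 \approx 6\times10^{-5}$ kg) the interface amplitude $A$
  cannot contain the fluid during a vigorous squeeze — wall motion launches
  the light particles ballistically through the membrane mesh. Desk presets
  therefore keep the reference particle mass for both phases.
* **Shell triangulation.** Aligned rings bonded only axially and
  circumferentially form a shear-free net that creases irreversibly when a
  slice closes. Staggering alternate rings by half a step (near-equilateral
  triangulation) gives the bond network shear stiffness, and contracted
  rings then reopen on the tether timescale ($\sqrt{m/k'} \approx 0.7$ s).
* **Deformation locality.** A membrane displacement decays along the tube
  over $\lambda \approx \Delta x\sqrt{k/k'} \approx 8$ cm. Desk tubes are
  shorter than $\lambda$, so contractions couple more globally than at full
  scale; the desk presets are demonstrations of the mechanism, not converged
  reproductions.

# Numerical choices

* $c_0$ is not a physical sound speed and is not published; the default is
  1 m s$^{-1}$, an order of magnitude above the flow speeds the desk tube
  develops (~cm s$^{-1}$), keeping the fluid weakly compressible while
  keeping interface pressures within what the repulsive barrier can hold.
  Stiffer choices raise squeeze pressures quadratically and push fluid
  through the wall mesh.
* Density is integrated with the continuity equation
  ($\dot\rho_i = \sum_j m_j \mathbf v_{ij}\cdot\nabla_i W$, wall neighbours
  included as moving boundary terms), initialised at $\rho_0$. Summation
  density is provided (`compute_density()`) for lattice calibration and
  diagnostics but is not used in the stepping loop: on a kernel-truncated
  cylinder it has a large near-wall deficit that would produce spurious
  pressure forces in an otherwise force-free initial state. With continuity
  density the built configuration carries exactly zero force.
* Pressures are clamped at zero in the force assembly. The cubic-spline
  kernel is unstable under tension (particle pairing: the kernel gradient
  vanishes at $r = 0$, so cohering pairs can merge), and a weakly
  compressible liquid cavitates rather than sustaining tension. A density
  floor of $0.1\rho_0$ likewise guards the $\rho_{ij}$ and $P/\rho^2$
  denominators through violent squeezes.
* The Tait prefactor is $c_0^2\rho_0/7$ (the standard weakly compressible
  form, dimensionally a pressure). The printed variant $c_0\rho_0/7$ is
  selectable with `sim_config(tait_mode = "as_printed")` for strict fidelity.
* Contraction switches on and off instantaneously at action boundaries; the
  1 s action window is long against the membrane's fast (bond) timescale, so
  ramping makes little difference.
* Neighbour search is a linked-cell grid with cell edge at least the
  interaction cutoff, rebuilt every step, with a direct $O(N^2)$ scan below
  1,500 particles (faster at desk scales and trivially correct); both paths
  are checked against an exhaustive reference scan in the tests.
* Action ties in greedy selection break to the lowest index; the final
  transition of each episode is treated as terminal in the Bellman target.

# Training configurations

The full schedule (30,000 episodes, $\varepsilon: 1 \to 0.1$) is the
reference configuration and is not desk-runnable; desk-scale runs shrink the
problem, not the physics:

* **Surrogate checks.** A physics-free task with the same interface
  (`surrogate_env()`): advancing the contraction one slice pays +1, holding
  pays 0, anything else −0.5, so the optimal policy is the travelling wave
  and the optimal Q-function is computable by value iteration. Agent
  correctness is asserted there: the tabular limit of the update reaches the
  value-iteration fixed point, and the network agent trained for 2,000
  episodes recovers the wave policy exactly. For these short runs the
  exploration floor is lowered to 0.02 (with the reference floor of 0.1 an
  $\varepsilon$-greedy policy cannot score above ~87% of optimum on-policy,
  regardless of what it has learned).
* **Desk physics learning.** 100 episodes of 6 one-second actions on
  `desk3d_fast` with $\Delta t = 2\times10^{-3}$ s (CFL-safe at
  $c_0 = 1$), $\varepsilon$ decaying over 70 episodes, learning rate
  $3\times10^{-3}$, and rewards scaled by 100 inside the update only:
  centre-of-mass rewards are a few millimetres, far below the network's
  initial output scale, and a run that is 300× shorter than the reference
  schedule needs order-one targets to move its weights appreciably. The run
  is compared against the random-policy baseline measured by simulation;
  trained greedy rollouts should transport fluid forward in every episode.

Problem sizes throughout (particle counts, episode counts, steps per action)
were chosen so the whole test suite and the acceptance script each run in
minutes on one CPU; they are stated alongside each experiment.

# What the desk experiments do and do not show

They do show: stable coupled dynamics under the reference force constants; a
contraction that closes a slice and reopens after release; coordinated
forward waves transporting fluid with $R^* \approx +1$ and backward waves
$\approx -1$ while random actuation averages near zero; and an agent that
discovers forward coordination from the physics alone.

They do not show: convergence with particle number, quantitative wave-speed
or efficiency agreement with the full-scale model, or robustness of the
learned policy across seeds and horizons. Sustained coherent squeezing on a
desk tube slowly extrudes fluid through the (single-layer, 6 mm mesh)
membrane — at full scale the same mesh backs onto a much deeper fluid column
— so desk transport figures are reported over short episodes from a pristine
reset. Catastrophic forgetting, visible in long online runs of the reference
model, is out of scope here: desk runs are far too short to exhibit it, and
no mitigation is implemented.

# Known limitations

* Single-layer membrane with no bending stiffness; closure mechanics near
  the axis rely on bond compression and the triangulated shell.
* The dimensionless reward's squeezed-volume denominator uses mean slice
  radii; once a slice is already partially closed at action start, repeated
  squeezing of the same slice under-counts new squeezed volume, and $R^*$
  can exceed 1 on contrived action sequences.
* The environment state (last activation vector) is not Markov for the
  physics: the fluid's momentum and the membrane's recovery state carry
  history. The agent still learns the wave, but value estimates are noisy
  by construction.
* No adaptive time stepping: configurations far outside the presets may
  need a smaller `dt` than the default.
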