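---
title: "Modelling run-and-tumble motility at a solid surface"
author: "surfdwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling run-and-tumble motility at a solid surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfdwell)
```

## The model

Peritrichous bacteria such as *Escherichia coli* alternate between two
motility states. During a **run** all flagella rotate counterclockwise and
the cell swims smoothly at speed $V$; its heading $\hat e$ drifts slowly by
rotational diffusion with coefficient $D_r$. During a **tumble** the
flagellar bundle disperses: the cell centroid is modelled as translational
Brownian motion with coefficient $D_t$ while the heading reorients quickly
with coefficient $D_\theta$. The fraction of time spent tumbling is the
**tumble bias** (TB), the phenotype axis of every analysis in this package.

State switching is a two-state Markov chain. The total switching frequency
is quadratic in tumble bias,

$$SF(TB) = \frac{\omega}{4} - \omega\left(TB - \tfrac12\right)^2
        = \omega\, TB\,(1 - TB),$$

and splits into Poisson rates $k_{RT} = SF / (2(1 - TB)) = \omega TB/2$
(run to tumble) and $k_{TR} = SF / (2\,TB) = \omega(1 - TB)/2$ (tumble to
run). Dwell times in either state are therefore exponential, and
$k_{RT}/(k_{RT}+k_{TR})$ recovers TB exactly. TB of exactly 0 or 1 is
treated as a frozen phenotype (a smooth swimmer or a tumble-locked cell);
no rate decomposition exists there and the simulator simply never
switches.

Near a solid wall three empirical rules are added:

* a running cell whose centroid reaches the wall aligns instantly with the
  surface plane (polar angle $\varphi \equiv \pi/2$), keeping the azimuth
  of its lateral heading;
* while surface-bound it circles **clockwise** (viewed from above, $+z$
  into the liquid) with angular speed $\Omega = V/R$ perturbed by $D_r$,
  the signature of hydrodynamic coupling between the counter-rotating cell
  body, flagella and wall;
* a tumble releases the cell; its centroid diffuses with $z$ reflected at
  the wall ($z \ge 0$), which is the only escape mechanism.

A trajectory starts on the surface with uniform azimuth, its initial state
drawn Bernoulli(TB), and integrates until $z$ first exceeds the bulk
criterion (escape) or a time cap is reached (censored).

## Parameters

| field | symbol | default | units | meaning |
|---|---|---|---|---|
| `swim_speed` | $V$ | 19 | µm s⁻¹ | run speed near the surface |
| `tumble_diffusion` | $D_t$ | 6.61 | µm² s⁻¹ | tumble translational diffusion |
| `run_rot_diffusion` | $D_r$ | 0.062 | rad² s⁻¹ | run rotational diffusion |
| `tumble_rot_diffusion` | $D_\theta$ | 3.5 | rad² s⁻¹ | tumble rotational diffusion |
| `char_frequency` | $\omega$ | 9.27 | s⁻¹ | switching-frequency scale |
| `curvature_radius` | $R$ | 25 | µm | surface circling radius (15–35 physiological) |
| `z_surface` | — | 3 | µm | surface-interaction height criterion |
| `z_bulk` | — | 8 | µm | bulk height criterion |
| `dt` | — | 10⁻³ | s | integration step |
| `t_cap` | — | 300 | s | per-trajectory time cap |

$V$, $D_t$, $\omega$, $R$ and the height criteria are measured quantities
of the system being modelled. $D_r$ and $D_\theta$ are *assumptions*: the
run value is the classic free-swimming rotational diffusion of *E. coli*
(about 0.062 rad² s⁻¹), and the tumble value corresponds to a typical
tumble reorienting by roughly 70° in about a tenth of a second
($\langle\Delta\hat e^2\rangle \approx 4 D_\theta t$). Both are exposed in
the configuration and all downstream tolerances are wide enough to absorb
plausible alternatives. The packaged file
`inst/extdata/default_params.json` is the single source of truth for the
defaults; `motility_params()` reads it and validates the invariants
($z_{bulk} > z_{surface} > 0$, $dt < 1/\omega$, positivity).

## Numerical scheme

The SDEs are integrated by Euler–Maruyama with a fixed step and per-step
Bernoulli switching (probability rate × dt). Orientation diffusion acts as
independent Gaussian increments in the tangent plane of $\hat e$ followed
by renormalization, which is accurate for $D\,dt \ll 1$ (here
$D_\theta dt = 3.5\times10^{-3}$). In the planar surface process
(`simulate_surface_process`) the heading is a single azimuth and tumble
reorientation acts on it directly; in the 3D simulator the full unit
vector diffuses, since a tumble explores all of orientation space.
Convergence is policed by a property test: halving `dt` moves bin-mean
residence times by less than 5% at 3000 events per arm.

Each trajectory draws from an independent RNG stream derived from
`(seed, stream)`, so ensembles are reproducible and order-independent.
Retained samples default to 0.04 s spacing (the camera frame interval the
synthetic generator emulates); the integration step itself is 1 ms.

Surface contact is the exact event $z \le 0$ after a run step; the 3 µm
criterion is an *analysis* threshold applied afterwards, not a dynamical
capture zone. On alignment the azimuth is inherited from the lateral
projection of $\hat e$ (uniform redraw only in the measure-zero vertical
case), preserving heading memory across the contact.

## The synthetic experiment

`camera_sample()` decimates a trajectory to a fixed frame grid (25
frames s⁻¹ by default, nearest retained sample, no interpolation),
truncates at the 207 s acquisition cap, and can add independent Gaussian
localization noise per frame and axis (defaults
$\sigma_{xy} = 0$, $\sigma_z = 0$; 0.1 µm and 0.3 µm are realistic
sub-resolution values when noise is wanted). It emulates frame-rate
sampling, finite acquisition and localization error. It does **not**
emulate image formation, tracking failures, cell–cell collisions or drift,
so tests passing on synthetic tracks say nothing about the robustness of
a tracking pipeline — only about the analysis stages downstream of it.

`generate_interval_sequence()` draws alternating exponential run/tumble
dwell sequences from the chain's rates, starting from the stationary law;
it is the ground-truth generator for the switching-frequency and
interval-distribution analyses.

## Residence-time analysis

An arrival–escape event is $z > 8\,\mu m \to z < 3\,\mu m \to
z > 8\,\mu m$; the surface residence time $T_s$ is the interval between
the first and last crossings of 3 µm. Crossing times use the first sample
on the far side without interpolation, so the same rule serves simulated
and camera-sampled tracks; the bias is one sample interval, far below
typical $T_s$. Simulated trajectories start on the surface, so their
clock starts at time zero — a stated convention, since an arrival leg
does not exist for them.

Events that never escape before the cap are *censored*: they are excluded
from bin means and their fraction is reported per bin. This mirrors the
acquisition-cap bias of capped recordings — bins at very low tumble bias
underestimate the true mean because exactly the longest events are cut.
Under the default parameters censoring is negligible above TB ≈ 0.01 at a
300 s cap and grows rapidly below it ($T_s \to \infty$ as TB → 0).

The knee of the mean-$T_s$ curve is operationalized as: plateau level =
mean of bin means with centers in (0.5, 1]; the transition is the
smallest bin center whose mean is within 25% above that level. The 25% is
a named constant (`transition_tolerance`), chosen because the curve drops
by multiples of the plateau level across the knee, so the result is
insensitive to the exact value.

Sensitivity to the height criteria, measured by re-detecting one ensemble:
moving `z_surface` within 2.5–3.5 µm changes bin means by under 3%;
moving `z_bulk` within 7–9 µm changes them by up to ~8%, because the bulk
criterion decides which upward excursion counts as the escape. Both are
asserted as properties at 5% and 10% respectively.

## Surface diffusivity

During residence periods the motion is quasi-planar, and its efficiency
is summarised by an effective diffusivity $D_{xy}$ fitted from
$MSD_{xy} = 4 D_{xy} t$. The ensemble MSD anchors each residence segment
at its own start (one displacement per segment per lag): segments are
short and non-stationary at onset, and the initial relaxation this
retains is exactly what the three-phase rule excises.

The running diffusion constant $RDC(t) = MSD/4t$ separates three phases:
relaxation (I), a flat diffusive stretch (II), and a data-starved tail
(III). Phase II opens at the first *sustained* convergence of the
window-averaged RDC (relative change between consecutive 1 s windows
below `slope_tol` = 0.05, holding for a further 1 s of lags) and closes at
the last lag whose segment count reaches `count_floor`
(= max(50, 5% of the bin)). Per-lag RDC noise at desk scale defeats a
rule that demands flatness at every single lag, which is why the
criterion acts on window averages; bins whose noise still defeats the
nominal tolerance retry with it doubled (at most quadrupled) and report
the tolerance used. The fit itself is unweighted least squares through
the origin. Because the true MSD has a negative offset of order the
correlation time $\tau$, an origin-anchored fit over a window at lags
$\bar t$ carries a small negative bias of order $\tau/\bar t$; the window
rule keeps $\bar t \gg \tau$, and the residual bias is part of the
honest scatter of the scaled-down pipeline.

## Closed-form diffusivity and the correction factor

For the strictly planar process (perpetual circling runs, planar
diffusive tumbles) the long-time diffusivity has a closed form,

$$D_{xy} = TB\,D_t + \frac{V^2}{2}(1 - TB)\,
  \frac{A B}{A^2 V^2/R^2 + B^2},
  \qquad A = D_\theta + k_{TR},\quad
  B = D_r k_{TR} + D_\theta k_{RT} + D_r D_\theta,$$

whose two terms are the tumble and run contributions. The endpoints are
implemented as analytic limits rather than $\varepsilon$-evaluation:
at $TB = 1$ the run term vanishes and $D_{xy} = D_t$; as $TB \to 0$,
$B \to D_r A$ and the common $A^2$ cancels, leaving
$(V^2/2)\,D_r/(V^2/R^2 + D_r^2)$ (about 19.25 µm² s⁻¹ at the defaults).
The grouping of the printed form is confirmed by a stochastic oracle:
the Taylor–Kubo estimate on the planar process agrees with the formula
within a few percent across tumble bias (asserted at 10%).

The Taylor–Kubo estimator integrates the empirical velocity
autocorrelation, $D = \tfrac12\int_0^\infty \langle \vec v(0)\cdot\vec
v(t)\rangle\,dt$ — the normalization consistent with $MSD = 4Dt$ in two
dimensions, which the implementation cross-checks at run time against the
long-lag $MSD/4t$ of the same input. The autocorrelation is computed by
FFT and integrated by trapezoid to the lag where it decays below 1% of
its initial value; non-decaying (ballistic) input raises a divergence
flag instead of a number.

The closed form assumes the cell circles for the whole of every run. In
the 3D simulation brief off-surface runs are straighter, so the simulated
$D_{xy}$ exceeds the formula near the peak; the mismatch is absorbed by
scaling the radius to $C R$ with a single correction factor $C > 1$,
fitted by grid search over [1, 2] (step 0.01, parabolic refinement)
against the simulated curve on TB ∈ [0.1, 0.9]. The endpoint bins are
excluded because low-TB bins are censoring-dominated and at high TB the
tumble term leaves $C$ no leverage. Tighter circling (smaller $R$) makes
straight off-surface excursions relatively more valuable, so $C$ grows
as $R$ shrinks.

## Problem sizes

The package's standard runs use: 330 trajectories per 0.05-wide TB bin
for the residence curve (≥ 300 uncensored events per bin above
TB = 0.05); 5000 trajectories per bin — the study scale — for the
reproduction script's diffusivity curve at $R = 25$ µm, and 2000 per bin
for the three-radius comparison in the test suite; 800 planar
trajectories of 50 s per tumble bias for the oracle comparison; and 3000
events per arm for the step-halving convergence check. The top of the
$D_{xy}$ curve at $R = 25$ µm is flat: bin centers 0.125–0.225 agree
within about 2% (≈115 µm² s⁻¹), so the argmax bin varies among them
between realisations even at full scale, with the $R = 15$ and 35 µm
curves peaking at 0.225 and 0.175.

## Known limitations

* The wall model is a half-space: no chamber ceiling, no hydrodynamic
  force field, no flagellar mechanics — entrapment and circling are
  imposed as rules, which is the point of a phenomenological model but
  limits extrapolation beyond the measured observables.
* $D_r$ and $D_\theta$ are literature-plausible assumptions, not fitted
  values; quantities that depend on them only through the run term (the
  residence plateau, the peak location) are robust, but absolute
  $D_{xy}$ values at low tumble bias shift with them.
* Censored events are excluded rather than modelled, so very-low-TB bin
  means are biased low by construction, as in capped recordings.
* The origin-anchored MSD fit under-estimates $D_{xy}$ slightly when the
  fitting window is short relative to the correlation time (high tumble
  bias at desk scale); the window heuristic flags bins whose window fails
  to reach twice the mean residence time.
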