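# surfdwell

Run-and-tumble motility of bacteria near solid surfaces.

Swimming *Escherichia coli* accumulate at walls: hydrodynamic and steric
interactions trap a running cell at the surface and force it onto
clockwise circular paths, and only tumbles — modelled here as
translational Brownian motion of the cell centroid with steric hindrance
(`z ≥ 0`) — let it escape back into the bulk. How long a cell dwells at
the surface, and how much surface area it explores while there, both
depend on its **tumble bias** (TB), the fraction of time spent tumbling.
`surfdwell` is for quantitative microbiologists and biophysicists who
want to simulate and analyse this trade-off.

## The model

A two-state Markov switching process with total switching frequency
quadratic in tumble bias,

    SF(TB) = ω/4 − ω (TB − 1/2)²  =  ω · TB · (1 − TB),
    k_RT = SF / (2(1 − TB)) = ω·TB/2,     k_TR = SF / (2·TB) = ω·(1 − TB)/2,

drives transitions between

* **runs** — speed `V`, heading rotational diffusion `D_r`; at the
  surface the run circles clockwise with angular speed `Ω = V/R`;
* **tumbles** — centroid Brownian motion with coefficient `D_t`, fast
  heading diffusion `D_θ`, `z` reflected at the wall.

Defaults (`V = 19 µm/s`, `D_t = 6.61 µm²/s`, `ω = 9.27 s⁻¹`, `R = 25 µm`)
live in a packaged JSON configuration. Downstream analyses reproduce the
model's headline behaviour: the mean surface residence time `T_s`
(interval between first and last crossings of 3 µm within an
arrival–escape event bounded by 8 µm crossings) drops sharply with TB and
plateaus near 4 s above TB ≈ 0.25, while the effective surface
diffusivity `D_xy` (from `MSD_xy = 4 D_xy t` during residence periods)
peaks near that same tumble bias — the mean TB of wild-type cells. A
closed-form planar diffusivity and a fitted curvature correction factor
`C` (`R → C·R`) connect theory and simulation.

## Worked example

```r
library(surfdwell)
p <- motility_params()                       # packaged defaults

tr <- simulate_trajectory(0.25, p, seed = 1) # one cell, TB = 0.25
attr(tr, "stop_reason")                      # "escape"
detect_residence(tr, p$z_surface, p$z_bulk)
#>    t_s censored no_event   tb t_start t_last_below t_escape
#> 1 2.68    FALSE    FALSE 0.25       0         2.68     3.51

ens <- simulate_residence_ensemble(c(0.125, 0.275, 0.575), 200, p, seed = 1)
residence_curve(ens$events)
#>   tb_center mean_ts sem_ts   n n_censored censored_fraction
#> 1     0.125    6.16  0.376 200          0                 0
#> 2     0.275    3.56  0.229 200          0                 0
#> 3     0.575    3.30  0.212 200          0                 0

dxy_closed_form(0.25, p)                 # 89.49 um^2/s (planar theory)
dxy_closed_form(0.25, p, r_scale = 1.3)  # 116.91 um^2/s (corrected radius)
```

The cell released at the surface with TB = 0.25 stayed 2.68 s below the
3 µm criterion and escaped past 8 µm at 3.51 s. Across bins, rarely
tumbling cells (TB ≈ 0.125) dwell almost twice as long as cells at or
above the wild-type tumble bias, whose mean residence has already reached
its plateau. The closed form gives the planar diffusion coefficient of
the same phenotype; scaling the circling radius by the correction factor
`C ≈ 1.3` accounts for the straighter off-surface run segments of the
full 3D motion.

The full pipeline (residence curve, diffusivity curve, theory curve,
correction factor, summary JSON) runs from one configuration object:

```r
cfg <- run_config(seed = 1)
run_pipeline(cfg, "out_dir")
```

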