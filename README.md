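# atrisim

Multi-scale simulation of left atrial function in a closed-loop
cardiovascular system model.

## The problem

Over one cardiac cycle the left atrium (LA) successively acts as a
*reservoir* (storing pulmonary venous return while the mitral valve is
closed), a *conduit* (passively feeding the left ventricle after mitral
opening) and a *pump* (contracting at end-diastole). The time-varying
elastance concept that serves the left ventricle (LV) well is a poor fit
for the atrium — its elastance curve is bimodal and its load independence
is doubtful. `atrisim` takes the alternative route: both LA and LV
pressures are *derived from a sarcomere model*, so chamber behaviour
emerges from contraction physiology instead of being prescribed.

The package is aimed at computational physiologists and modellers who need
a lumped closed-loop heart/circulation testbed whose atrium actually
reproduces the a/v pressure waves, E/A transmitral filling and the
figure-eight atrial pressure-volume (PV) loop, and who want to run
preload-reduction (vena cava occlusion, IVCO) experiments *in silico*.

## The model in brief

* **Calcium driver.** Per chamber, a smooth two-cosine pulse
  `Ca(t)`: rise to `Ca_max` over `T1`, decay over `T2`, zero in diastole;
  the atrial transient leads ventricular activation by `s = 0.085` s.
* **Sarcomere.** Four-state troponin/cross-bridge kinetics
  (`T → TCa → TCa* → T* → T`, rates `Y1 Ca`, `Y2·exp(−R(L−La)²)`, `Y3`,
  `Y4` forward; `Z1`, `Z2`, `Z3 Ca` backward), cross-bridge elongation
  `dh/dt = dL/dt − B(h − h_c)`, velocity-dependent detachment
  `Yd(dX/dt)²`. Active force `F_a = A(TCa* + T*)h`, passive `F_b = K(L −
  L0)`, in mN/mm².
* **Chamber.** Hemispheric geometry `V = (2/3)πR³`, sarcomere-wall
  coupling `L = L0·R/R0`, and Laplace's law `P = 2·F·t_wall/R` (kPa →
  mmHg).
* **Circulation.** Four passive elastance chambers (`P = E·V`), a
  three-Gaussian time-varying-elastance right ventricle, seven Poiseuille
  resistances, four diode valves, continuity everywhere; 273 ml of
  stressed blood volume conserved exactly.
* **Analysis.** Fiducial points A–F on the LA/LV pressure traces (wave
  peaks, onsets, valve crossovers), the eight standard preload-response
  indices, PV-loop lobe decomposition by self-intersection + shoelace
  area, and E/A-wave fusion detection.

All parameter defaults are the published dog calibration; see
`?cvs_params` and the methods vignette
(`vignettes/atrial-function-model.Rmd`) for units, conventions and design
rationale.

## Worked example

```r
library(atrisim)

params <- cvs_params()                 # published defaults; override by name
sim <- run_to_steady_state(params)     # ~35 cycles to the limit cycle
sim
#> <cvs_simulation> 1 cycle(s), 901 samples, converged to periodic steady state

glance(sim)[, c("cycles_run", "P_ao_sys", "P_ao_dia", "P_pa_sys", "P_pa_dia")]
#>   cycles_run P_ao_sys P_ao_dia P_pa_sys P_pa_dia
#> 1         35   118.81    70.31    78.88    60.26
```

Aortic pressure settles near 119/70 mmHg and pulmonary artery pressure near
79/60 mmHg. The hemodynamic indices of the steady cycle:

```r
t(round(compute_indices(sim), 2))
#> max_a_wave_pressure                 7.97
#> max_v_wave_pressure                13.60
#> min_ventricular_pressure            4.51
#> end_diastolic_ventricular_pressure  9.19
#> slope_a_wave                       36.61
#> slope_v_wave                       16.57
#> max_early_gradient                  1.90
#> max_late_gradient                   2.66
```

i.e. an atrial a wave peaking at 8.0 mmHg, a v wave at 13.6 mmHg, LV
pressures spanning 4.5 (early-diastolic minimum) to 9.2 mmHg
(end-diastolic), and transmitral gradients below 3 mmHg. The simulated
vena-cava-occlusion experiment (fourfold pulmonary resistance, indices read
on the fifth beat) lowers *all eight* indices, as observed experimentally:

```r
tidy(run_ivco(params, baseline = sim))
#>                          measurement  units baseline  ivco decreased
#> 1                max_a_wave_pressure   mmHg     7.97  6.67      TRUE
#> 2                max_v_wave_pressure   mmHg    13.60 11.21      TRUE
#> 3           min_ventricular_pressure   mmHg     4.51  3.27      TRUE
#> 4 end_diastolic_ventricular_pressure   mmHg     9.19  7.71      TRUE
#> 5                       slope_a_wave mmHg/s    36.61 33.80      TRUE
#> 6                       slope_v_wave mmHg/s    16.57 12.85      TRUE
#> 7                 max_early_gradient   mmHg     1.90  1.65      TRUE
#> 8                  max_late_gradient   mmHg     2.66  2.33      TRUE
```

The atrial PV trajectory closes into the physiological figure eight, with
the active ("a") lobe at lower volumes, and the E and A transmitral waves
are fused (no diastasis at a 0.45 s period):

```r
extract_pv_loop(sim)
#> <pv_loop> figure-eight (two lobes)
mitral_wave_features(sim)
#>   e_flow e_time a_flow a_time inter_min fused
#> 1   68.4  0.338   95.7  0.384      64.4 TRUE
```

`autoplot(sim)`, `plot_pv_loop(sim)` and `plot_mitral_flow(sim)` draw the
corresponding ggplot figures. A command-line front end with `simulate`,
`ivco`, `indices` and `fixtures` subcommands is installed at
`inst/cli/atrisim.R`; runs are configured with flat YAML key-value files
mirroring the parameter registry, and every run writes a CSV trace plus a
JSON metadata sidecar sufficient to reproduce it.

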