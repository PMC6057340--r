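# dynpet — direct parametric reconstruction of dynamic PET data

`dynpet` estimates voxel-wise kinetic parameter maps **directly from
dynamic PET sinogram counts**, instead of the conventional route of
reconstructing each time frame first and fitting a kinetic model to the
noisy voxel time-activity curves (TACs) afterwards. It is aimed at
researchers in PET pharmacokinetics who want a complete, desk-scale,
reproducible 2D implementation of direct parametric reconstruction: a
tomographic simulator, the reconstruction algorithm, and the evaluation
metrics, all in one package.

## The method

Sinogram counts in LOR *i* and frame *m* are Poisson,

  y<sub>im</sub> ~ Poisson( Σ<sub>j</sub> p<sub>ij</sub> x<sub>jm</sub> + r<sub>im</sub> ),

where `p_ij` is the detection probability (geometry × attenuation),
`x_jm` the activity in voxel *j*, and `r_im` the expected scatter+randoms.
Each voxel's activity follows a two-tissue compartment model
`x_jm = f(t_m, θ_j)` with θ = [K1, k2, k3, k4, fv]. The package alternates
two conditional maximizations (an iterated-conditional-modes scheme):

1. **Kinetic fit** — given the provisional activity x̂, every voxel's θ is
   updated by bounded nonlinear least squares
   (0 ≤ k ≤ 10 min⁻¹, 0 ≤ fv ≤ 1):
   θ̂<sub>j</sub> = argmin Σ<sub>m</sub> ( x̂<sub>jm</sub> − f(t<sub>m</sub>, θ<sub>j</sub>) )².
2. **Activity update** — starting from the model prediction
   x̄<sub>jm</sub> = f(t<sub>m</sub>, θ̂<sub>j</sub>), a small number of MLEM
   sub-iterations (default 2) pull the activity toward the Poisson data:
   x̂<sub>jm</sub> ← (x̄<sub>jm</sub>/Σ<sub>i</sub>p<sub>ij</sub>) Σ<sub>i</sub> p<sub>ij</sub> y<sub>im</sub> / (Σ<sub>j′</sub> p<sub>ij′</sub> x̄<sub>j′m</sub> + r<sub>im</sub>).

The kinetic model is evaluated **analytically**: the two-tissue impulse
response is rewritten as α₁e^(−β₁t) + α₂e^(−β₂t) (the auxiliary
parameterization, with β₁,₂ the eigen-rates of the compartment system),
and its convolution with the Feng bolus plasma model

  C<sub>p</sub>(t) = (A₁(t−t₀) − A₂ − A₃)e^(−λ₁(t−t₀)) + A₂e^(−λ₂(t−t₀)) + A₃e^(−λ₃(t−t₀))

is expanded in closed form, so no numerical convolution is ever needed
during fitting. The final model is

  C<sub>T</sub>(t) = (1−f<sub>v</sub>) [C<sub>p</sub> ⊗ (α₁e^(−β₁t) + α₂e^(−β₂t))](t) e^(−d<sub>k</sub>t) + f<sub>v</sub> C<sub>p</sub>(t),

with d<sub>k</sub> = ln 2 / 109.8 min⁻¹ for ¹⁸F. The clinically used
net-influx macroparameter K<sub>i</sub> = K₁k₃/(k₂+k₃) is derived from the
final maps.

## Worked example

Simulate the packaged brain-like phantom on the desk-scale geometry
(64×64 grid, 70 cm FOV, 95 radial bins × 96 angles, the 24-frame/40-min
clinical schedule), add 10 % scatter+randoms, and reconstruct ten outer
iterations:

```r
library(dynpet)

cfg <- load_config()              # packaged defaults
ex  <- build_experiment(cfg)      # system matrix, phantom, input model

dyn <- simulate_activity(ex$ph, ex$fi, ex$fs, ex$dk)
sg  <- simulate_sinograms(ex$sm, dyn, noise_fraction = 0.1, seed = 1)
st  <- icm_em(ex$sm, sg, ex$fi, ex$fs, ex$dk, recon_config(n_outer = 10))

roi_stats(st$maps, ex$ph$label)[c(1, 5, 7, 11), ]
```

```
   region parameter       mean         sd n_voxels
1    gray        K1 0.67093010 0.08402795      600
5    gray        fv 0.09432455 0.03636398      600
7   white        K1 0.42736109 0.05399116      660
11  white        fv 0.11083826 0.03222377      660
```

The gray-matter ROI mean of the K1 map (0.671 ml·min⁻¹·g⁻¹) recovers the
simulated ground truth 0.6805 to 1.4 %, the white-matter mean (0.427)
recovers 0.4091 to 4.5 % (the residual bias is partial-volume spill-in at
region boundaries at this coarse grid), and the gray-matter blood volume
fraction (0.094) recovers 0.0985 to 4 %. The per-iteration Poisson
log-likelihood trace is in `st$loglik`; `norm_loglik(st$loglik)` rescales
it to [0, 1] and shows convergence well before ten iterations.

Maps, traces and provenance can be written with
`write_outputs(st, "outdir", config = cfg)` (NIfTI maps with the physical
voxel size, CSV trace, RDS container). A three-command CLI wraps the same
pipeline:

```sh
Rscript inst/cli/dynpet.R simulate    --seed 1 --noise 0.1 --out sim
Rscript inst/cli/dynpet.R reconstruct --data sim --iters 10 --out maps
Rscript inst/cli/dynpet.R evaluate    --data sim --maps maps --out metrics.csv
```

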