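# hyperdr

Task-driven spectral data reduction for hyperspectral image segmentation.

## The problem

Hyperspectral cubes carry hundreds of spectral bins per pixel (X-ray
energies in keV, reflectance wavelengths in nm). Segmenting them with a
CNN directly is expensive, and generic reducers - PCA, NMF - routinely
discard the sparse spectral features the task actually needs: a K-edge
discontinuity of a target element, a narrow reflectance difference, while
keeping noise-dominated bins. `hyperdr` implements a learned alternative:
a per-pixel linear spectral reduction subnetwork

    z_i[j] = LeakyReLU_a( sum_k W_i[j,k] z_{i-1}[k] + b_i[j] ),   a = 0.01

(spectral 1x1 convolutions, reduction list `D = [Nb, ..., Nr]`, zero
initialization) is attached in front of a segmentation CNN and the pair is
trained end to end with ADAM on the segmentation loss:

    min_{theta, phi}  sum_i  L( F'_theta( G_phi(x_i) ), P(y_i) )

so that reduction to `Nr = 1` or `2` channels preserves exactly the
spectral structure the task depends on. Two backbones are provided - a
mixed-scale dense network (depth 100, width 1, dilations cycling 1..10,
cross-entropy) and a two-level U-Net (base width 128, bilinear
upsampling, mean of BCE and soft dice) - plus PCA/NMF/LDA baselines
fitted on subsampled pixels, and two self-contained simulators (cone-beam
X-ray cylinder phantoms with Beer-Lambert attenuation, Poisson noise and
flatfield correction; reflectance disk scenes under a solar irradiance
spectrum with water-absorption bands and Gaussian noise) so every claim
is exercisable without downloads. Evaluation uses average class accuracy,
the mean over classes of per-class recall `TP_c / (TP_c + FN_c)`.

All forward/backward passes are authored in the package (C++ cores via
Rcpp); gradients are verified against finite differences in the tests.

## Worked example

Simulate a desk-scale clean two-material X-ray dataset (25 images of
128x128 pixels, 100 bins over 13-70 keV; 120 cylinders per phantom, two
of them silver, the rest cadmium), train the reduction jointly with a
depth-30 MSD backbone, and evaluate:

```r
library(hyperdr)

ds <- to_absorbance(build_xray_dataset(
  xray_config(desk_scale = TRUE, mode = "few", noise = FALSE), seed = 1))

cfg <- train_config(epochs = 150, lr = 5e-3, augment = FALSE,
                    n_train = 15, n_val = 5, n_test = 5, seed = 1)
model <- train_segmenter(ds, reduction_scheme(c(100, 2)), "msd", cfg,
                         backbone_config = msd_config(depth = 30))
evaluate_model(model, ds)   # test split by default
```

which prints (numbers from this exact run, about 6 minutes on one CPU):

```
eval_report: average class accuracy 0.9915 over 5 images
  background   recall 0.9961
  silver       recall 0.9869
```

i.e. 99.61% of background pixels and 98.69% of silver-silhouette pixels
are recovered, averaging to 99.15% - the learned 2-channel reduction plus
a small MSD separates the two silver cylinders from the 118 cadmium ones
on clean data. (`to_absorbance` feeds the network `-log` transmittance,
which is linear in material path length under Beer-Lambert physics.)
Inspecting the learned spectral weights shows why:

```r
wc <- extract_weight_curves(model$reduction, ds$grid)
which.max(abs(wc$curves[1, ]))
#> [1] 23
band_index(ds$grid, kedge_energy(47))
#> [1] 22
```

the reduction concentrates its largest weight on bin 23 - the first bin
above the silver K-edge (25.51 keV, bin 22), i.e. the narrow energy
window where silver already attenuates strongly but the cadmium
confounder (K-edge 26.71 keV) does not yet. That edge straddle is exactly
the spectral feature that separates the target from 118 near-identical
cylinders.

A thin CLI wraps the same functions
(`inst/cli/hyperdr simulate-xray | simulate-remote | fit-baseline |
train | evaluate | inspect-weights | export-reduction | apply-reduction |
repeat`).

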