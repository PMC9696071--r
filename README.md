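# dentalseg

Trainable cascade attention networks for multi-class segmentation of dental
lesions in intraoral photographs, in R.

Automated screening of intraoral photographs must delineate lesions —
dental calculus, gingivitis, tartar and worn enamel surfaces — at pixel
level, fast, even though several lesion types look very much like healthy
tooth tissue. `dentalseg` is aimed at researchers in biomedical image
analysis who want a fully inspectable, CPU-reproducible implementation of a
real-time-oriented cascade segmentation architecture and its evaluation
protocol, including a seeded synthetic scene generator that stands in for
clinical data that cannot be shared.

## The model

An image cascade network (ICNet-style) processes the input at three scales:
a deep residual branch on the half-scale image (stride 8), a dilated
continuation on downsampled features (stride 16), and a light three-block
branch on the full image (stride 8). Cascade feature fusion (CFF) merges
the branches — coarse features are upsampled 2×, refined by a dilated 3×3
convolution and summed with 1×1-projected fine features — with auxiliary
classifiers for deep supervision. Training minimizes the weighted
multi-branch cross-entropy

&nbsp;&nbsp;&nbsp;&nbsp;L = W₁L₁ + W₂L₂ + W₃L₃, (W₁, W₂, W₃) = (1, 0.4, 0.16).

Two modifications define the improved network:

* **CBAM attention** at five sites (last three low-branch and last two
  medium-branch bottleneck units): channel gating
  Mc = σ(MLP(AvgPool F) + MLP(MaxPool F)) followed by spatial gating
  Ms = σ(f([AvgPool F′; MaxPool F′])), where the spatial convolution f is,
  in the improved design, **two stacked 3×3 dilation-2 convolutions**
  instead of one 7×7 kernel — 54 instead of 98 weights per module, i.e.
  +180 instead of +400 parameters network-wide over the single dilated-3×3
  baseline.
* **Asymmetric convolutions**: the 3×3 kernels of those same units are
  factorized into 3×1 followed by 1×3 (6 instead of 9 weights per channel
  pair), offsetting the attention cost.

Around the network the package provides ACE automatic color equalization
for overexposed photographs (Rc(p) = Σⱼ r(I(p) − I(j))/d(p, j) with
r(x) = clip(x/T, −1, 1), then linear dynamic-range restoration),
confusion-matrix metrics (pixel accuracy, mean IoU, macro F1), VOC-style
mask I/O, a class-imbalanced synthetic intraoral scene generator, and a
train/evaluate/predict pipeline with a brightness-robustness mode
(0.7×/1.0×/1.3×). The conv-net engine itself — convolution, batch
normalization, attention, bilinear resampling, and their reverse-mode
gradients — is implemented in R with Rcpp kernels and validated against
finite differences; no external deep-learning framework is required.

## Worked example

Parameter accounting for the spatial-attention ablation:

```r
library(dentalseg)
attention_ablation_report(n_modules = 5)
#>             variant params_per_module added_params receptive_field
#> 1             conv7                98          400               7
#> 2          conv3_d2                18            0               5
#> 3 stacked2_conv3_d2                54          180               9
```

`added_params` is the network-wide parameter increment over the dilated-3×3
baseline across the five attention sites; the stacked variant costs 180
extra weights versus 400 for the 7×7 kernel. `receptive_field` is the
standard stacked-convolution formula value (note the stacked pair covers 9,
not 7).

Generate a synthetic dataset, train a small improved network for five
epochs, and evaluate across brightness levels:

```r
dir <- tempfile("demo")
man <- make_dataset(20, scene_spec(seed = 42, size = 64), dir = dir,
                    oversample_rare = 3)
cfg <- network_config(base_size = 64, width = 8, fuse_channels = 16, seed = 5)
fit <- train_network(cfg, man, train_config(batch_size = 4, max_epochs = 5,
                                            seed = 3))
round(fit$log[, c("epoch", "train_loss", "train_acc", "val_loss", "val_acc")], 3)
#>   epoch train_loss train_acc val_loss val_acc
#> 1     1      2.493     0.463    2.055   0.618
#> 2     2      2.013     0.709    1.571   0.894
#> 3     3      1.600     0.889    1.330   0.932
#> 4     4      1.410     0.923    1.203   0.945
#> 5     5      1.310     0.929    1.202   0.945

evaluate_network(fit$net, man, split = "test", brightness = c(0.7, 1.0, 1.3))
#>   brightness       acc      miou        f1 n_images n_pixels
#> 1        0.7 0.9580078 0.3193359 0.3261845        2     8192
#> 2        1.0 0.9533691 0.3177897 0.3253760        2     8192
#> 3        1.3 0.9565430 0.3188477 0.3259296        2     8192
```

The log shows the weighted cascade loss falling and pixel accuracy rising
epoch over epoch; the evaluation table reports pixel accuracy, mean IoU and
macro F1 of one accumulated confusion matrix per brightness factor on the
held-out split. After only five epochs at this tiny scale the network
already places lesion classes (mean IoU ≈ 0.32 over the classes present);
these synthetic-data numbers are illustrative and not comparable to results
on clinical photographs. `predict_file(fit$net, man$image[1], "mask.png",
overlay_path = "overlay.png")` writes a class-id mask and a VOC-color
overlay.

Thin command-line wrappers live in `inst/cli/`: `lesion-synth.R` (dataset
generation), `lesion-seg.R` (train/eval/predict with a YAML config) and
`ace-enhance.R` (ACE on a single image).

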