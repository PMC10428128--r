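# conegain

How much information about the colored surfaces in a scene reaches an
observer through their cone photoreceptors — and how much of it is lost
in red-green color vision deficiency or cone monochromacy?

`conegain` answers this at the receptor level. A scene is a distribution
of spectral radiances $L(u,v;\lambda)$; an observer with corneal cone
sensitivities $S_c(\lambda)$ receives excitations
$q_c = \int L(\lambda) S_c(\lambda)\,d\lambda$ perturbed by Weber-scaled
Gaussian noise ($y_c = q_c(1 + w_c \epsilon)$, with $w_L = 0.02$ the
headline level). The information available is the mutual information
$I(X;Y)$ in bits between radiance vectors $X$ and noisy excitations $Y$;
$N = 2^I$ is the effective number of distinguishable surfaces, and a
deficiency's loss is $\Delta I = I - I'$, a paired comparison on the
same pixels and noise field.

The package provides, as testable R functions:

* a **cone model** with normal, hybrid (log-wavelength-shifted),
  dichromatic and monochromatic pigment complements (peaks 559/530/426,
  hybrids 536 and 549 nm) and Weber-fraction noise (0.018/0.019/0.087
  class scaling);
* **information estimators**: a Kozachenko–Leonenko kNN
  mutual-information estimator with subsample-extrapolation offset,
  validated against Gaussian closed forms, plus an exact-channel
  plug-in route for the Weber-Gaussian cone channel that remains
  accurate in the strong-dependence regime of real scenes;
* **uniformization** of surface frequencies by sup-metric thinning and
  gamut-maximizing unions across scenes;
* **colorimetry**: CAM02-UCS scene descriptors (variance partition,
  chroma/lightness, major chromatic axis) and dichromatic
  confusion-axis directions at the adapting white;
* **statistics**: percentile-bootstrap intervals, logit-share
  regressions, and linear-circular regression for axial data;
* a calibrated **synthetic hyperspectral scene generator** (dominant
  lightness variance, controllable chromatic axis and variance shares,
  Zipf-skewed surface frequencies, bounded gamut) so the entire
  pipeline is testable without image downloads;
* **IO** for ENVI and plain-text hyperspectral cubes, with the
  conditioning steps real sets need (band resampling, 2×2 spatial
  averaging, dark-offset subtraction, pixel sampling, sky cropping).

## Worked example

```r
library(conegain)

# a natural-like synthetic scene: 77% lightness variance, chromatic
# variance concentrated near the yellow-blue axis, skewed frequencies
img <- generate_scene(scene_spec(width = 96, height = 96, seed = 1))

u <- scene_ucs(img)
round(variance_partition(u), 3)
#> lightness        rg        yb
#>     0.784     0.073     0.143

information_loss(img, "protanope", n = 2000, seed = 1)
#> <delta_i protanope: 0.945 bits (se 0.017) of 6.906; 48.0% fewer
#>  distinguishable surfaces>

information_loss(img, "deuteranomal", n = 2000, seed = 1)
#> <delta_i deuteranomal: 0.276 bits (se 0.013) of 6.906; 17.4% fewer
#>  distinguishable surfaces>

confusion_axis_direction("protan")   # degrees from the a'_M axis
#> [1] 11.71333
```

Read: this scene offers a normal trichromat about 6.9 bits — roughly
120 distinguishable surfaces. A protanope loses ~0.9 bits (about half
the distinguishable surfaces), a deuteranomal observer only ~0.28 bits;
losses rank deuteranomaly < protanomaly < deuteranopia < protanopia
across the suite, and monochromats lose two to three times more than
dichromats. Thinning scene spectra toward uniform frequencies
(`thin_spectra()`, `adaptive_thin()`) raises both the information
available and the losses; `run_analysis()` orchestrates the whole
comparison (raw/thinned/union conditions, observers, noise levels) into
one table, with `summarize_losses()` and `regression_suite()` producing
the group means and the regressions of loss on redness-greenness share
and on chromatic-axis direction.

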