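---
title: "Methods: estimating the scene information available to color-deficient observers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the scene information available to color-deficient observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

How much do the noisy responses of retinal cone photoreceptors tell an
observer about the colored surfaces in front of them, and how much of
that is lost when one cone class is absent (dichromacy), replaced by a
spectrally shifted hybrid pigment (anomalous trichromacy), or when only
a single class remains (cone monochromacy)?

`conegain` treats a scene as a distribution of spectral radiances
$L(u,v;\lambda)$ over pixels. An observer with corneal cone spectral
sensitivities $S_c(\lambda)$ receives, at each point, excitations

$$ q_c = \int L(\lambda)\, S_c(\lambda)\, d\lambda, \qquad
   c \in \{\mathrm{L}, \mathrm{M}, \mathrm{S}\}, $$

computed by trapezoid quadrature on the scene's wavelength grid
(`cone_excitations()`). Phototransduction noise is modelled as Gaussian
with standard deviation proportional to the local excitation
(`noise_model()`, `add_cone_noise()`): $y_c = q_c (1 + w_c\,\epsilon)$
with $\epsilon \sim N(0,1)$ independent per sample and cone class. The
Weber fraction is quoted for L cones ($w_\mathrm{L} = 0.02$ by default,
a practical minimum; 0.01 and 0.05 are the other levels swept) and
scaled for M and S by the ratios of the increment-threshold fractions
0.018, 0.019 and 0.087.

With $X$ the radiance vector and $Y$ the noisy excitation vector, the
information available at the receptor level is the mutual information
$I(X;Y)$ in bits; $N = 2^I$ is the effective number of distinguishable
surfaces, and the loss under a deficiency is $\Delta I = I - I'$, with
$100(1 - 2^{-\Delta I})$ the percentage reduction in distinguishable
surfaces. Both estimates of a pair are computed on the same sampled
pixels and the same underlying L/M/S noise field, so the difference is a
paired comparison (`information_loss()`).

## Observers

`make_observer()` builds the seven observer types from the package's
cone fundamentals: a normal trichromat with pigment peaks at 559, 530
and 426 nm; protanopes ({M, S}) and deuteranopes ({L, S}); protanomals
(M at 530 plus a hybrid at 536 in the L slot), deuteranomals (L at 559
plus a hybrid at 549 in the M slot); and M- or L-cone monochromats. The
S pigment is never altered in the red-green deficiencies. Hybrid
pigments are derived by `shift_pigment()`: the template is smoothed by a
quadratic loess fit of sensitivity against log wavelength (bandwidth
chosen by 10-fold cross-validation over spans 0.08–0.35) and translated
along the log-wavelength axis until the peak lands on the target;
optical density is held constant, and the shift acts on the corneal
sensitivity directly. A hybrid takes the Weber noise class of the slot
it occupies (the L and M fractions differ by only ~5%, so this choice
is immaterial; it matters only that the hybrid's noise draw is
independent of its parent cone's).

The shipped fundamentals are **synthetic**: Govardovskii-template
pigment shapes with peaks placed at the corneal values above
(`cone_fundamental_table()`,
`inst/extdata/cone_fundamentals_synthetic.csv`). They reproduce the
peak placements, widths and log-wavelength shift behaviour that the
analysis depends on, but they are not measured human fundamentals, and
no pre-receptoral (lens, macular) filtering is modelled separately.

## Information estimation

Two estimator routes are provided.

**The generic route** (`kl_mutual_information()`, `method = "knn"`)
estimates $I = h(X) + h(Y) - h(X,Y)$ with Kozachenko–Leonenko
kth-nearest-neighbour entropies (`kl_entropy()`), $k = 3$ by default.
Coordinates are standardized per dimension; exact ties are broken by a
deterministic additive jitter at $10^{-9}$ of the coordinate scale. The
finite-sample error is removed by a matched-Gaussian offset: the same
estimator, at the same $n$ and $k$, is run on Gaussian surrogates with
the data's joint covariance, whose true mutual information is known in
closed form, and its mean error is subtracted. (A nested-subsample
$1/n$ extrapolation was evaluated first and rejected for this route: it
amplifies realization noise by roughly a factor of two, which is what
limits accuracy at $n = 10^4$ where the bias itself is already small.)
This route is validated against Gaussian closed forms (independence,
correlated pairs, additive channels) to within 0.1 bits at $n = 10^4$
for $k \in \{1, 3, 5\}$.

**The channel route** (`method = "channel"`, the default for scenes)
exploits two exact identities. First, $Y$ depends on $X$ only through
the noiseless excitations $q = S^\top X$, so $I(X;Y) = I(q;Y)$ — the
excitations are a sufficient statistic. Second, the conditional density
of $Y$ given $q$ is known in closed form (diagonal Gaussian with SDs
$w_c q_c$), so

$$ I = h(Y) - h(Y \mid q), \qquad
   h(Y \mid q) = \sum_c \left[ \tfrac12 \log_2 2\pi e + \log_2 w_c +
   \mathrm{E}\log_2 q_c \right], $$

and $h(Y)$ is a Monte-Carlo average of the exact mixture output density
over the sampled source, evaluated by a small compiled kernel. Its only
systematic error is the finite size of the sampled source; a $1/n$
extrapolation over the full sample, its two disjoint halves, and its
four disjoint quarters (block-averaged, weighted by size) removes most
of it, and the spread is taken from half-sample re-estimates.

The channel route exists because the generic route fails on realistic
scene data. Scene radiance vectors live near a low-dimensional smooth
manifold (natural reflectances are low-dimensional), and at 2% noise
$Y$ is nearly a deterministic function of $X$: in this strong-dependence
regime nearest-neighbour distances never resolve the noise scale at
feasible sample sizes, and the three-entropy estimator returns badly
biased, even negative, information differences. The channel route was
validated against an exact oracle — deterministic quadrature of the
mixture output density in one dimension, and a high-replication
Monte-Carlo evaluation over all scene pixels in general — and agrees to
a few hundredths of a bit; the two routes also agree on weak-dependence
cases where the generic estimator is reliable. All of these checks are
in the test suite.

## Uniformization by thinning

The information available from a scene depends on the frequencies of
its surfaces, not just its gamut. To separate the two, `thin_spectra()`
removes spectra lying within sup-metric distance
$d(l_r, l_s) = \sup_\lambda |l_r(\lambda) - l_s(\lambda)|$ of retained
ones, visiting spectra in a seeded random order (the order changes which
spectra survive; order-sensitive results are reported seed-averaged).
`adaptive_thin()` raises $d$ along a grid until the information estimate
stabilizes (default tolerance 0.05 bits) while at least 500 spectra
remain, recording the full history. `union_gamut()` concatenates
thinned sets across scenes and thins once more, giving the
gamut-maximizing condition. The pipeline (`run_analysis()`) instead
picks each scene's radius by bisection to a retained-count window
(500–1000 by default): an information-free proxy for the stability rule
that keeps a full suite tractable and avoids coupling the thinning to
the quantity being measured.

## Colorimetric descriptors

Scene color structure is described — never fed into the information
estimates — in CAM02-UCS: lightness $J'$, redness-greenness $a'_M$,
yellowness-blueness $b'_M$ (`scene_ucs()`). The descriptors are the
variance partition across the three axes (`variance_partition()`), the
chroma-to-lightness ratio (`chroma_lightness_ratio()`), and the major
chromatic axis, the leading principal direction of the $(a', b')$
covariance folded to $[0°, 180°)$ (`major_chromatic_axis()`).

CIECAM02 viewing conditions default to a 6500 K daylight white,
adapting luminance 64 cd/m², background luminance factor 20, average
surround, and full chromatic adaptation; scenes carry no absolute
photometric calibration, so each scene's 99th-percentile luminance is
anchored to the adapting white. All of these are package choices
(`viewing_conditions()` exposes them) — the analysis itself does not
depend on them, since the descriptors are descriptive only.

Dichromatic confusion-axis directions at the origin
(`confusion_axis_direction()`) are obtained by constructing the
confusion line through the adapting white toward the copunctal point in
CIE 1931 (x, y) — protan (0.747, 0.253), deutan (1.400, −0.400), tritan
(0.171, 0.000), standard literature constants — mapping closely spaced
points at fixed luminance into CAM02-UCS, and taking the symmetric
finite-difference tangent, which is stable over at least two orders of
magnitude of step size.

Two further colorimetric components are analytic stand-ins rather than
shipped tables: the CIE 1931 color-matching functions use the
multi-lobe piecewise-Gaussian fits of Wyman, Sloan and Shirley (2013),
accurate to about 1% of peak; and `daylight_spectrum()` builds a
Planckian radiator times a quadratic wavelength correction solved so
that the chromaticity lands exactly on the CIE daylight locus. Both are
amply accurate for variance shares, axes and confusion angles; neither
claims table-level fidelity for demanding colorimetry.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure of natural
hyperspectral scenes that the analysis depends on, without claiming to
reproduce any real image set's absolute information values:

* **Lightness dominance.** A spatially smoothed log-normal shading
  field (default log-SD 0.35) multiplies every pixel's radiance,
  reflecting illumination and geometry as the dominant source of
  variance. Default variance shares are 77% lightness, 8%
  redness-greenness, 15% yellowness-blueness, with the major chromatic
  axis at 90° (the yellow-blue direction).
* **Low-dimensional smooth reflectances.** Materials are built on a
  7-function basis (a constant plus six Gaussian bumps), clipped to
  [0, 1]; chromatic placement inverts a local linearization of the
  CAM02-UCS mapping about a neutral gray under the scene illuminant.
* **Uneven surface frequencies.** Material frequencies follow a Zipf
  law with exponent `frequency_skew` (default 1; the acceptance suite
  uses 1.2), so a single knob controls how uneven the surface
  frequencies are; realized counts are recorded in the image metadata.
* **Bounded gamut.** Reflectance clipping bounds the reachable chroma;
  targets that cannot be realized for the given `gamut_scale` raise an
  error rather than being silently clamped.
* **Calibration.** Because the mapping from generator knobs to realized
  CAM02-UCS statistics is nonlinear, an internal loop (at most six
  iterations) measures the realized shares with the package's own
  colorimetry and rescales the material chromatic covariance — and the
  mean chromatic offset, which is calibrated so the median
  chroma-to-lightness ratio hits 0.25, the colorfulness typical of
  natural scenes — until the targets are met. Recovery is within
  ±0.05 per share for scenes of 64×64 pixels and larger.
* **Sensor noise.** A small (0.3%) multiplicative per-band noise keeps
  radiance vectors full-rank, as camera noise does in real images.

What the generator does **not** emulate: spatial texture statistics,
specular highlights, sky, interreflections, or the particular gamuts of
any published image set. Passing the property suite on these scenes
shows that the pipeline responds correctly to controlled color
statistics; it does not certify absolute information values for real
scenes.

`generate_palette()` provides the approximately uniform counterpart: a
golden-angle spiral in the chromatic plane crossed with a lightness
ramp, giving near-uniform nearest-neighbour spacing in CAM02-UCS, with
`gamut_scale = 0` degenerating to an achromatic lightness series.
`palette_radiance_set()` multiplies a palette by its illuminant so it
can be analyzed as a single scene.

## Statistical analysis

Group means are compared with Efron's percentile bootstrap
(`percentile_bootstrap_ci()`, 1000 case resamples by default;
nonparametric throughout). Regressions of losses on scene structure use
the logit of variance shares (`logit()` refuses boundary values rather
than silently clamping) with a case-bootstrap gradient interval
(`linear_regression()`). Directional structure uses linear-circular
regression with axial doubling (`circular_linear_regression()`): angles
defined modulo 180° are doubled onto the circle, the response is
regressed on the cosine and sine of the doubled angle, and fitted
extremum directions are folded back; the fitted maximum and minimum are
90° apart by construction, and $R^2$ is the ordinary coefficient of
determination of the two-regressor model.

## Problem sizes and numerical choices

The default test and acceptance runs use 72×72-pixel scenes, 2000–2500
sampled pixels per estimate, two half-sample replicates for spreads,
and a 20-scene suite for the seed-averaged property checks — sizes at
which the channel estimator is within a few hundredths of a bit of its
oracle. Other fixed choices: neighbour order $k = 3$ (oracles must pass
for $k \in \{1,3,5\}$); subsample extrapolation over $n/2^m$; thinning
count floor 500 and stability tolerance 0.05 bits; loess span grid
0.08–0.35; tie-breaking jitter at $10^{-9}$ of coordinate scale;
sampling without replacement from images when enough pixels exist
(repeated pixels are exact duplicates that would otherwise lean on the
jitter contract).

## Known limitations

* Losing a cone class costs a little information even on achromatic
  scenes: with independent per-cone noise, three cones sample lightness
  redundantly, so a trichromat keeps an SNR-pooling advantage of up to
  $\tfrac12 \log_2 (\sum_c w_c^{-2} / \sum_{c'} w_{c'}^{-2})$ (about
  0.5 bits for a protanope at the default Weber fractions) that has
  nothing to do with color. The idealization "no chromatic content,
  hence no loss" holds only up to this term.
* Information is quantified at the cone-excitation level only; no
  postreceptor coding, spatial pooling, or task model is included (by
  the data-processing inequality, later stages can only lose more).
* The cone fundamentals, color-matching functions and daylight spectra
  are analytic stand-ins, as described above.
* The generic kNN route underestimates information in strong-dependence
  regimes; it is retained for comparison and for data where no channel
  model is known, but scene results should use the channel route.
* Synthetic scenes are statistical surrogates; comparisons with real
  hyperspectral sets additionally require those data and their
  calibration details (e.g., the dark-noise estimator used for
  wide-range sets is not uniquely determined).
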