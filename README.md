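# mwcompass

The Milky Way as a blur-tolerant visual compass.

Nocturnal dung beetles hold a straight course on moonless nights by reading
the orientation of the Milky Way — a large, dim, extended band that their
highly sensitive but low-acuity superposition eyes can see even while the
retinal image is smeared by locomotion. Point-like stars do not survive
that smearing; the band does. `mwcompass` is an R implementation of the
computational side of this story, for researchers in biomimetic navigation
and computational sensory ecology:

* a **synthetic night-sky generator** — a Gaussian-profile galactic band
  with an along-axis intensity gradient, a seeded star field, adjustable
  light-pollution background (Bortle-scale-like), rendered inside a
  circular field of view, plus seeded rotation sequences;
* a **stochastic motion-blur model** — random-walk point-spread functions
  whose path budget, step lengths (`Beta(1,30)`-scaled) and triangular
  turning angles are governed by a single intensity parameter, applied by
  reflect-padded convolution;
* the **band-orientation estimator**: per-channel median filtering, Otsu
  thresholding by between-class variance maximisation,

  σ²_B(t) = ω₀(μ₀ − μ_T)² + ω₁(μ₁ − μ_T)²,

  morphological mask refinement (disc dilation, small-object removal), and
  the major-axis angle of the dominant component from its normalised
  second central moments (μxx = Σx²/N + 1/12, μyy = Σy²/N + 1/12,
  μxy = Σxy/N about the centroid);
* a **Radon-transform baseline** that reports the angle of the sinogram's
  global maximum over a 1° grid;
* a **rotation-under-blur benchmark**: 12 seeded 72-frame sequences at 5°
  steps, two blur realisations per sequence, signed axial errors wrapped
  to [−90°, 90°), per-set and pooled statistics, error histograms, all
  reproducible byte-for-byte from one master seed.

## Worked example

```r
library(mwcompass)

model <- sky_model(band_angle_deg = 40, seed = 2)   # band at 40 degrees
img   <- render_sky(model)                          # 400 x 400, 8-bit

mwoa_angle(img)
#> [1] 40.12244
radon_angle(img)
#> [1] 41

kern <- make_blur_kernel(blur_spec(intensity = 0.5, kernel_size = 100,
                                   seed = 7))
point_source_attenuation(kern)
#> [1] 0.01428448

blurred <- apply_blur(img, kern)
mwoa_angle(blurred)
#> [1] 39.92185
```

The moment pipeline recovers the 40° band within 0.13° on the clean
render. The blur kernel attenuates a point source's peak to 1.4 % of its
original value — a star effectively vanishes — yet the band's estimated
orientation moves by only 0.2°. That asymmetry is the package's central
quantitative claim, and `run_benchmark()` measures it systematically:

```r
res <- run_benchmark(bench_config(master_seed = 1))
res
#> Rotation benchmark: 12 sets x 72 frames x 2 blur realisation(s)
#>   mwoa  per-set MAE: min 0.057  max 0.560 deg; pooled MAE 0.225 deg
#>   radon per-set MAE: min 0.398  max 1.675 deg; pooled MAE 0.884 deg
```

Per-set MAE is the mean absolute axial error of the 144 scored frames of
a set (72 frames × 2 blur realisations). The moment estimator stays well
under the Radon baseline on every set.

A thin command-line front end is installed with the package
(`system.file("cli", "mwnav", package = "mwcompass")`) with subcommands
`simulate-sky`, `make-kernel`, `blur`, `estimate` and `benchmark`; YAML
configuration files are validated against the documented schema
(`load_config()`).

## Layout

```
R/                  implementation (sky simulator, blur model, estimators,
                    benchmark, I/O)
src/                compiled kernels: Radon projection, bilinear rotation,
                    reflect-border convolution, 8-connected labelling
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, parameters, design choices
inst/cli/mwnav      command-line front end
scripts/acceptance.R  benchmark reproduction script
```
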