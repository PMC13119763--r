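# thermafoot

Quantitative clinical thermography for low-cost long-wavelength infrared
(LWIR) cameras, aimed at diabetic-foot assessment, where a bilateral
plantar temperature difference of about 2 °C is a clinically meaningful
warning sign. Consumer radiometric cameras (160×120 microbolometer plus a
visible camera in one housing) can detect such differences — but only
after their systematic errors are corrected. This package implements the
full processing chain:

1. **Decoding** of radiometric containers: the embedded 16-bit detector
   counts (raw block or 16-bit PNG payload, byte order normalized), the
   Planck calibration metadata, and the visible image.
2. **Vignetting correction in the radiometric domain.** The measured
   signal is modelled as `R = G · R*` with a smooth multiplicative gain
   `G`. Per flat-field epoch: pixelwise median over the frames, optional
   quantile clamp, Gaussian smoothing (σ ≈ 4 px), unit-median
   normalization. Across epochs: pixelwise-median *master gain* when the
   inter-epoch log-gain RMS is small, geometric (log-domain)
   interpolation otherwise.
3. **Planck/atmospheric inversion** to temperature:
   `T = PB / log(PR1 / (PR2 (Robj + PO)) + PF) − 273.15`, with
   `Robj = R*/(ε τ Wt) − Ratm − Ropt − Rrefl`, the two-exponential
   atmospheric transmission τ(distance, water-vapour pressure), and skin
   emissivity ε = 0.98. The exact forward model is also provided, so the
   round trip is exact to < 1e-9 °C.
4. **Hybrid marker detection**: white 10 mm disks in the visible image
   (disk/ring contrast score + geometric validation) and their diffuse
   "thermal hill" imprints in the temperature image (grayscale-opening
   background removal, relief thresholding, component filtering,
   relief-weighted sub-pixel barycentres).
5. **Constrained RANSAC matching** of the two marker sets (scale-free
   neighbour signatures, orientation and positive-determinant
   constraints that make mirrored correspondences impossible, rank
   monotonicity, optimal one-to-one assignment) and **registration** of
   the visible image onto the thermal frame (affine / projective /
   degree-2 polynomial), plus the mm-per-pixel scale from the known
   marker diameter.
6. A **synthetic-scene simulator** with exact ground truth (gain field,
   temperature map, marker centres in both modalities, the plane-induced
   VIS→LWIR map) for every validation in the test suite.

## Worked example

Simulate a session (vignetted, noisy LWIR frame + visible image of a
marker scene), build a gain model from synthetic flat fields, and run the
full chain:

```r
library(thermafoot)

params <- radiometricParams()            # Planck + atmosphere constants
gainTruth <- makeGain(amplitude = 0.1, seed = 3)   # ±10% vignetting

# three flat-field epochs -> per-epoch gains -> master gain
gains <- lapply(1:3, function(k) {
  st <- makeFlatStack(gainTruth, planckForward(28, params), Nk = 16,
                      seed = 10 + k, params = params, epoch = k)
  buildGain(robustFlat(st, clamp = FALSE), sigma = 4, epoch = k)
})
master <- masterGain(gains)

# a marker scene rendered through the same gain
sc <- makeBimodalScene(nMarkers = 8, seed = 11, gain = gainTruth,
                       params = params)
tImg <- frameToTemperature(sc$frame, master, params)
sqrt(mean((tempValues(tImg) - sc$truth@tMap)^2))   # RMS error, degC

lwir <- detectLwirMarkers(tImg)
vis  <- detectVisMarkers(sc$vis)
m    <- ransacMatch(as.matrix(lwir[, c("x", "y")]),
                    as.matrix(vis[, c("x", "y")]), seed = 11)
m
tf <- fitTransform(as.matrix(vis[m@pairs[, 2], c("x", "y")]),
                   as.matrix(lwir[m@pairs[, 1], c("x", "y")]))
sqrt(mean(tf@residuals^2))                 # registration residual, LWIR px
mmPerPixel(vis)                            # mm per VIS pixel
```

Printed output of this exact script:

```
[1] 0.07874601
CorrespondenceSet: 8 pairs, residual RMS 0.224 px, rho_x=1.000 rho_y=1.000
[1] 0.07919453
[1] 1.130085
```

Reading: after flat-field correction the temperature map is accurate to
0.079 °C RMS (the NETD of this camera class is 0.07 K, so the correction
adds very little on top of the detector noise floor); all 8 markers are
matched one-to-one with perfect rank ordering (residual 0.22 VIS px);
the fitted VIS→LWIR affine has a residual of 0.079 LWIR px ≈ 0.25 mm;
and one VIS pixel spans 1.13 mm at the sole plane, so distances and
areas on the foot can be measured metrically.

A command-line front end over the same functions is installed under
`exec/thermafoot` (subcommands: `decode`, `flatfield`, `temperature`,
`markers`, `match`, `simulate`, `run`).

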