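---
title: "Frequency-multiplexed videography: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-multiplexed videography: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framecodec)
```

This vignette is the package's own account of the science it implements:
the forward and inverse model of the codec, the Kerr-gate simulator that
provides physically motivated ground truth, the tunable parameters and the
numerical choices behind them, and the limits of what the synthetic tests
demonstrate.

## 1. The multiplexing model

A sequence of nonnegative intensity frames $F_i(x,y)$, $i = 1..N$, is
encoded into a single exposure by sinusoidal structured illumination:

$$ S(x,y) \;=\; \sum_{i=1}^{N} F_i(x,y)\,
   \bigl[\,1 + m_i \cos\!\bigl(2\pi\,\nu_i\!\cdot\!(x,y) + \varphi_i\bigr)\bigr], $$

where $\nu_i$ is the carrier frequency in cycles/pixel, $m_i \in (0,1]$
the modulation depth (fringe contrast) and $\varphi_i$ the fringe phase at
pixel $(0,0)$. Coordinates are 0-based, row-major, origin top-left; $x$ is
the column index and $y$ the row index. In reciprocal space each term
contributes the frame's baseband spectrum at the origin plus two copies of
amplitude $m_i/2$ at $\pm\nu_i$. Because image content concentrates near
DC, the annulus between the baseband and the optical cutoff is empty real
estate that the carriers can colonise.

The illumination is $1 + m\cos(\cdot)$, not $\cos(\cdot)$ alone: physical
light is nonnegative. No renormalisation by $(1+m)$ is applied at encode;
the decoder's factor $2/m$ restores per-frame amplitude, so brightness
bookkeeping lives in exactly one place.

The sensor model (`sensor_model()`) auto-exposes $S$ so its maximum maps
to the full-well capacity, optionally applies Poisson shot noise and
Gaussian read noise in electrons, clips to the full well, and floors to
the ADC's $2^B - 1$ levels (floor models ADC truncation; clip-then-floor
keeps the maximum representable). The auto-exposure gain (DN per input
intensity unit) is recorded on the exposure object: a synthetic pipeline
may use it to report decoded frames in input units, whereas a real decode,
where the gain is unknowable, uses gain 1 and reports camera units.
Because all frames share one full well, $N$ spatially overlapping frames
on a $B$-bit sensor keep $B - \log_2 N$ bits each
(`effective_bit_depth(16, 8)` is 13).

## 2. The decoder: 2D spatial lock-in

For each carrier the decoder computes

$$ \hat F_i(x,y) \;=\; \frac{2}{m_i}\,\Bigl|\,
   \mathcal{F}^{-1}\!\bigl[\,W(k)\; \mathcal{F}\bigl[S\,
   e^{-2\pi i\,\nu_i\cdot(x,y)}\bigr]\bigr]\Bigr|, $$

clipped at zero. Three choices deserve comment.

**Demodulation by phase ramp.** The classical description — isolate the
sideband with a band-pass around $\nu_i$, then translate it to the origin
— is implemented as multiplication by $e^{-2\pi i \nu_i\cdot(x,y)}$
*before* the transform. For carriers on integer DFT bins this is the same
re-indexing; for the realistic case of incommensurate carriers (real
gratings do not care about our pixel count) it is the *only* exact
translation, since off-grid shifts cannot be expressed as a permutation of
FFT bins. It also makes the frequency-domain path mathematically identical
to a spatial lock-in (demodulate, then convolve with the window's spatial
kernel); the test suite verifies this equivalence to $10^{-9}$ against a
direct $O(N^4)$ convolution oracle that never calls an FFT.

**Magnitude, not real part.** After demodulation the wanted term is
$\tfrac{m}{2} F_i\, e^{i\varphi_i}$. Taking the modulus removes the
dependence on the absolute fringe phase $\varphi_i$, which is generally
unknown in an experiment (it shifts with grating alignment). The price is
a rectification bias where the true signal is near zero and noise
dominates; for the high-contrast regimes simulated here it is negligible.

**The window sets the resolution.** `band_filter()` offers a Gaussian
(default, $\sigma = r/2$, truncated at $3\sigma$), a radial Tukey (flat
over $(1-a)r$, default taper $a = 0.5$), and a hard disk. The Gaussian has
the gentlest stopband skirts (best crosstalk) but attenuates in-band
content; the Tukey passes band-limited content essentially untouched and
is what the round-trip tests use; the hard window maximises passband at
the cost of ringing. A two-point target separated by $s$ pixels is
resolved roughly when $s \gtrsim 1/(2r)$, and the property tests confirm
the transition is monotone in $r$.

**Carrier detection.** `detect_carriers()` subtracts the image mean,
apodises with a Tukey taper (0.2), and picks local maxima of the centred
magnitude spectrum in the upper half-plane (one per conjugate pair)
outside a DC exclusion disk, refining each peak with a 3×3 centroid to
sub-bin precision. Mean subtraction matters: the DC peak of a windowed
image otherwise scatters sidelobe maxima across the spectrum. A peak must
exceed both $5\times$ the median magnitude and $10^{-9}$ of the maximum —
the absolute guard keeps floating-point dust on an exactly empty spectrum
from ever qualifying. Detection is honest about its limits: a smooth
unmodulated image whose borders have been apodised still carries taper
sidelobes above the median threshold, so "no carriers" is only guaranteed
to raise an error for featureless inputs.

## 3. Packing carriers in reciprocal space

`plan_codebook()` places carriers on concentric rings inside the annulus
$[r_0 + r,\; \mathrm{otf} - r]$. Separations are *conjugate-aware*: the
constraint $\min\|{\pm}\nu_i - {\pm}\nu_j\| \ge 2r$ counts each carrier's
mirror image, because for real images both sidebands are live. Angles are
uniform over $[0,\pi)$ — conjugate symmetry halves the usable range — and
rings are at least one separation apart radially, so the per-ring and
cross-ring constraints decouple. The construction uses the smallest number
of rings whose capacity covers the request and fills outer rings first
(larger circumference, and high-frequency carriers preserve detail
better). A guard factor (default 1.1) widens the minimum separation to
leave room for finite window skirts; tangent filter disks ($2r$ exactly)
are a worst case the validator still accepts.

This is a deterministic lower bound on the true packing optimum, which is
all the $N \le 16$ regime needs: at detector scale
($r = 0.02$, $r_0 = 0.05$, cutoff 0.45) the ring construction holds 156
carriers, an order of magnitude beyond what the demonstrations use.

## 4. The Kerr-gate light-in-flight generator

The generator is first-class, tested code — the study conditions, not a
disposable fixture. It emulates the pump–probe geometry of a femtosecond
videography experiment:

- **Pump**: a temporally Gaussian pulse (intensity FWHM 125 fs by
  default), propagating along $+x$ at $c/n$ with $n = 1.63$ (CS₂), with a
  transverse Gaussian profile (1/e² waist 0.25 mm) that may diverge
  linearly along $y$. In 125 fs it advances
  $c/n \times 125\,\mathrm{fs} \approx 23\,\mu\mathrm{m}$, i.e. ~3 pixels
  on a 7 mm field imaged onto 1002 pixels.
- **Gate**: the pump-induced birefringence is the pump intensity convolved
  with a normalised exponential relaxation kernel,
  $G = \tau^{-1}\int_{-\infty}^{t} I(t')\,e^{-(t-t')/\tau}\,dt'$, with
  $\tau$ the orientational relaxation time (default 1.6 ps, a typical CS₂
  value; never asserted against, only exercised through limits). Because
  the pump is temporally Gaussian at any fixed point, $G$ has an exact
  exponentially-modified-Gaussian closed form, evaluated stably via the
  scaled complementary error function with an asymptotic branch for small
  $\tau$ and a pure-exponential branch deep in the tail. $\tau = 0$
  reduces to the instantaneous intensity. The tests pit this closed form
  against adaptive quadrature of the defining integral ($10^{-8}$) and
  check the delta-kernel limit and the $e^{-t/\tau}$ tail slope.
- **Read**: temporally Gaussian pulses along $+z$, spatially uniform over
  the aperture; the camera integrates
  $S(x,y) = \int\!\!\int I_\mathrm{read}(z,t)\, G(x,y,z,t)\, dz\, dt$
  by midpoint quadrature (time step = pulse duration / 10; the z voxel
  must give ≥ 4 samples across the read pulse length or the quadrature is
  refused). The integral factorises into a BLAS matrix product over
  $(t, z) \times (t, x)$ plus separable transverse profiles, so a
  detector-scale frame (1002 × 1004 px, 256 z-planes, ~700 time steps)
  takes well under a second.

One property the normalised kernel does *not* have: total imaged signal
is not monotone in $\tau$. The kernel integrates to one, so at any fixed
point the time-integrated gate is $\tau$-independent; relaxation
*redistributes* signal into a trailing skirt behind the pump front, and
whatever part of that skirt leaves the pump's transverse footprint or the
cell is lost to the camera. The skirt itself — strictly more energy behind
the front at every trailing position than with $\tau = 0$ — is the tested,
physically meaningful signature.

**What the generator does not emulate**: diffraction from apertures (the
experimental ring structure on the beam rim), group-velocity dispersion,
absorption, pump depletion, polarisation transfer through the crossed
polarisers (the gate is linearised in $G$; a $\sin^2$ nonlinearity is a
small-retardance limit away), and camera optics beyond ideal z-projection.
Passing round trips on this generator therefore demonstrate the codec and
the geometric gate physics, not radiometric fidelity to any particular
experiment.

## 5. Numerical choices and degenerate inputs

- Frequencies are cycles/pixel everywhere internally; `lp_per_mm()`
  converts through the pixel pitch for physical reporting.
- Non-integer fringe periods across the image are allowed; the resulting
  Dirichlet leakage decays as $1/N$ and is mitigated at *decode*
  (apodisation before detection; window skirts at extraction), never by
  constraining the encoder. The constant-frame round-trip error is ~1% at
  128² and ~0.6% at 256² for this reason.
- A 5-pixel border is excluded from all quantitative metrics: circular
  convolution wraps the window kernel around the frame edge.
- Validation is strict and early: zero-depth carriers (no sideband to
  recover), carriers beyond Nyquist or inside the baseband, overlapping
  or duplicate carriers (reported with both indices), empty frame lists,
  shape mismatches, all-zero truth in NRMSE, extrapolating time queries,
  and quadrature grids too coarse for the pulse all raise typed errors
  (`framecodec_validation` / `framecodec_infeasible`, which the CLI maps
  to exit codes 2 and 3).
- Noise is drawn under the sensor's own seed with the caller's RNG state
  saved and restored: identical inputs give bit-identical exposures and
  no side effects on the session.
- Temporal interpolation (`reconstruct_wavefront()`) is per-pixel along
  $t$: linear by default (convex, artifact-free), with a
  monotonicity-limited (Fritsch–Carlson) cubic Hermite option. Queries at
  sample times return stored frames bit-exactly. Motion-compensated
  interpolation is deliberately out of scope — nothing in the intensity
  data licenses a flow model.
- `crosstalk_matrix()` regresses each decoded frame onto all truth frames
  (least squares over the border-excluded interior): a perfect decode
  yields the identity; all-zero truth channels are dropped and receive
  zero coefficients rather than poisoning the system.

## 6. Problem sizes in the tests

The suite exercises 128–256 px frames for round trips (four carriers,
NRMSE < 0.01, blank-channel crosstalk < 0.02), 32 px images against the
$O(N^4)$ lock-in oracle, the full 1002 × 1004 detector for 16-carrier
detection and the 3-pixel streak displacement, 100 randomized feasible
packing geometries with exhaustive conjugate-pair verification, and a
z–t quadrature refinement (halved steps, < 1% change) on a grid that
resolves the beam waist. These sizes keep the complete suite around
15 seconds while covering every contract at, or above, the scale of the
physical detector that motivated them.

## 7. Known limitations

- Decode quality presumes frame content is band-limited within the filter
  passband *and* dark near the field borders; bright content cut by the
  frame edge throws axis-aligned leakage ridges through reciprocal space
  that can intersect other carriers. Real beam images vignette naturally;
  synthetic fixtures in the tests do so explicitly.
- Relative normalisation of frames decoded from read pulses of unequal
  energy is under-determined by the data; per-frame gain is exposed as an
  argument rather than guessed.
- The ring packer is a constructive lower bound, not an optimiser, and
  does not adapt carrier placement to image spectra.
- The simulator's geometry is fixed to pump ∥ x, read ∥ z (the detector's
  projection axis); other orthogonal arrangements are rejected rather
  than silently rotated.
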