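---
title: "Concomitant-field compensation for spiral-ring TSE: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concomitant-field compensation for spiral-ring TSE: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(springrio)
```

## The problem

Turbo spin-echo (TSE) imaging with annular spiral-ring readouts collects one
annulus of k-space per spin echo: spiral-in rings early in the train, one
self-retraced in/out ring through the k-space center at the effective echo
time, and spiral-out rings late in the train. Because every ring has a
different gradient waveform and the waveforms are temporally asymmetric, the
concomitant (Maxwell) fields that necessarily accompany the imaging
gradients accrue a different quadratic phase in every echo spacing. The
echo-to-echo phase differences violate the CPMG condition, mix spin-echo and
stimulated-echo pathways destructively, and cannot be repaired after the
fact in reconstruction. The effect scales as $g^2/B_0$, so low-field systems
(0.55 T, 1.5 T) with moderate-to-strong readout gradients are the most
affected.

The lowest-order Maxwell field of a gradient $(g_x,g_y,g_z)$ at position
$(x,y,z)$ is

$$B_c = \frac{g_z^2}{8B_0}(x^2+y^2) + \frac{g_x^2+g_y^2}{2B_0}z^2
      - \frac{g_xg_z}{2B_0}xz - \frac{g_yg_z}{2B_0}yz,$$

with self-squared terms (first two) and quadratic cross-terms (last two).
The package implements a two-stage compensation: *sequence-based*
modifications that restore CPMG along the train, and *reconstruction-based*
conjugate-phase correction of the residual intra-readout phase from both the
concomitant field and B0 inhomogeneity.

## Ring design

`design_ring_set()` partitions the k-space disk $[0, k_{max}]$,
$k_{max}=1/(2\,\text{pixel})$, into one annulus per echo and designs an
Archimedean spiral segment per annulus (`n_shots` rotated interleaves,
composite radial pitch $1/\mathrm{FOV}$). Segments are traversed at
constant path speed with raised-cosine entry/exit ramps and a centripetal
slew allowance near the center; gradients are produced from central
differences of the spiral law so trapezoidal integration of the gradient
reproduces the analytic trajectory without a half-raster bias. Spiral-in
rings are the time-reversed, polarity-negated spiral-out waveform of their
annulus, and the central ring plays a negated-reversed half followed by the
half itself, so its in half exactly retraces its out half through $k=0$.

**Annulus partition.** The default `partition = "balanced"` chooses annulus
areas proportional to the sampling time each ring receives (the central
retraced annulus counts double because it is traversed twice). This
equalizes the per-ring gradient amplitude, which (a) minimizes the largest
per-ring concomitant integral — directly easing both the bipolar
compensation budget and the polynomial order needed by the conjugate-phase
tables — and (b) keeps every ring comfortably inside the amplitude/slew
budget. `"equal-width"` and `"equal-area"` partitions are available;
equal-width concentrates path length in the outer annuli and reproduces the
qualitative pattern that outer rings accrue several times more Maxwell
phase than inner ones.

**Acquisition windows.** The ADC window of each ring covers the
constant-speed plateau; the slew-limited ramps play but are not sampled
(they advance the trajectory by well under one radial pitch). The
self-retraced central ring is additionally split into four sampling
segments — two per half, with the slow gradient reversal around $k=0$ at
segment boundaries. This matters for the Chebyshev tables below: over each
segment the scaled time parameter is a low-order smooth function of
normalized time, which a 15-term polynomial approximates to $<10^{-3}$;
over the whole retraced readout the reversal produces a sharp kink that
would need roughly four times the polynomial order.

**Density compensation.** Sample weights are the polar area elements
(path spacing × radial pitch), with retraced rings receiving half weight,
an exact per-shell radial renormalization (the path-pitch model degrades
within a few pitches of $k=0$), and a strictly positive floor at the
k-space center. A brute-force grid-Voronoi mode (`"voronoi-grid"`) is
provided and is used as the independent oracle in the tests.

## Sequence-based compensation

`compensate_sequence()` implements the five sequence modifications:

1. **Crusher balancing** — the left crusher of the first refocusing pulse is
   resized (amplitude/duration trade at fixed zeroth moment) so the
   slice-axis self-squared integral of the excitation interval equals half
   that of every refocusing interval.
2. **Reference integral** — rather than literally topping each echo spacing
   up to $M_{max}/2$ per half (which is unattainable when a ring's pre/post
   echo-center split is asymmetric), the package computes per axis the
   largest half-interval self-squared integral $H$ over the train
   (including prephasers and rewinders) and uses $H$ as the constant
   half-interval target; for symmetric rings $H = M_{max}/2$ exactly.
3. **Bipolar pairs** — zero-net-moment trapezoid pairs in reserved 2.5 ms
   slots before and after each readout raise each half interval (refocusing
   pulse to echo center, echo center to next pulse) to exactly $H$ per
   axis. Amplitudes are solved on the raster, so the accumulated phase
   crosses zero at each spin-echo center to machine precision. The
   excitation interval is brought to $H$ by four equal pairs.
4. **Polarity reversal with exact trim** — the fourth pair of each echo
   spacing (readout axis 2, post-readout slot) is polarity-reversed to
   self-balance the bipolar quadratic cross-terms. Because the pre- and
   post-readout pair amplitudes differ in general, a plain reversal cancels
   the cross integral only approximately; the package additionally
   projects each slot's axis-2 waveform onto the subspace orthogonal to the
   axis-1 pair (superposing a half-duration trim pair on the self-squared
   isocontour), which zeroes $\int g_1 g_2\,dt$ in every echo spacing
   identically while preserving all self-squared integrals.
5. **Timing** — the bipolar slots (2.5 ms before and after each readout)
   are reserved in the layout of both the compensated and the
   uncompensated sequence, so comparisons are at matched echo spacing.

The outcome contract — Maxwell phase $-\phi$ at the start and $+\phi$ at the
end of every echo spacing with a constant $\phi$, and zero at every
spin-echo center — is verified by `echo_train_phase()`, which integrates the
instantaneous Maxwell field over the full event timeline with a sign flip at
each refocusing pulse.

## EPG simulation

`epg_echo_train()` is a standard extended-phase-graph evolution
(RF mixing, relaxation over half echo spacings, one configuration-order
shift per half interval), with the spatially local Maxwell phase entering as
a bulk rotation of the transverse configurations per half interval. The
pathway-dependent sign alternation emerges from the RF mixing itself, so
the *unconjugated* per-interval increments are supplied (from
`epg_phase_schedule()`). Conventions: 90° excitation about an axis 90° from
the refocusing axis (CPMG); refocusing flip configurable, with 150° used in
the pathway studies as a proxy for a slice-profile-averaged nominal 180°
pulse. The implementation is vectorized over probe locations/pixels, and a
brute-force Bloch isochromat ensemble (`isochromat_echo_train()`, uniform
0–2π crusher dephasing per half interval) provides an independent oracle;
the two agree to machine precision once the ensemble resolves all populated
configuration orders.

## Forward simulation

`simulate_kspace()` evaluates the discrete pixel sum of the signal model per
echo: trajectory encoding, B0 phase $e^{-i\Delta\omega(r)t}$ with $t$
referenced to each spin-echo center, and concomitant phase split into the
echo-train pathway value at the echo center plus the intra-readout term
$\Delta\omega_c(r)\,t_{c,j}(t)$. The offset-frequency map
$\Delta\omega_c(r)=\frac{\gamma g_m^2}{4B_0}(F_1X^2+\dots+F_6XY)$ uses
orientation constants derived by expanding the Maxwell field under the
spiral quadrature assumption ($g_X^2+g_Y^2=g_0^2(t)$, in-plane cross
products averaging out) and rotating the resulting quadratic form into the
logical frame; the factorization is verified against brute-force time
integration in the tests. The reference amplitude $g_m$ is the protocol's
gradient budget (21 mT/m) — the product $\Delta\omega_c\,t_c$ is invariant
to this convention.

**Scaled time.** Internally $t_{c,j}$ is re-centered at the temporal
spin-echo center of each readout, where the spin echo forms by RF timing and
where the bipolar apportioning zeroes the total phase; for
amplitude-symmetric rings this equals the $-M_j/2$ re-centering
(`scaled_time(mode = "tse", ref = "half-integral")`), which is also
exposed. Echo-train weighting is either full per-pixel EPG (flip-angle and
Maxwell-pathway dependent complex amplitudes) or plain $T_2$ decay with the
conjugated pathway phase. Compensation is designed on the first
interleave's per-axis integrals; for quadrature spirals with at least one
turn per ring the per-axis integrals are nearly rotation-invariant, so the
same bipolars serve all interleaves.

## Reconstruction

`gridding_recon()` is the density-compensated adjoint non-uniform DFT. The
conjugate-phase correction expands the demodulation exponential per
acquired segment $j$ in Chebyshev polynomials of the segment's normalized
time $u$:

$$e^{+i[\Delta\omega\,t(u) + \Delta\omega_c\,t_{c,j}(u)]}
  \approx \sum_{k=0}^{N-1} h_k T_k(u) - \tfrac{1}{2}h_0,$$

with coefficients interpolated at $N$ Chebyshev nodes and tabulated on a
regular (B0 offset × concomitant offset) Hz grid
(`build_coefficient_table()`; nearest-node lookup, 1 Hz default pitch). The
base images (`base_images()`) are adjoint transforms with $T_k(u)$ time
weights; the $T_k$ basis is used rather than monomials $u^k$ because it is
numerically stable at $N=15$ and makes the $-\tfrac{1}{2}h_0$ convention
exact by construction, with order 0 equal to the plain gridding
reconstruction. Tables are per ring segment, since the scaled time is
ring-specific; a sampled audit enforces the $10^{-3}$ max-modulus
approximation contract and raises an error naming the worst node if the
order is insufficient.

`linear_corrections()` removes the constant and in-plane-linear parts of
both maps before the table step — constants by exact per-sample
demodulation (with $t$ for B0 and $t_{c,j}$ for the concomitant term),
linear parts as time-dependent trajectory shifts — which shrinks the
off-center concomitant range to that of an isocenter slice.

`semiauto_deblur()` reconstructs candidates $m(r;\Delta\omega_i)$ over a
constant-shift grid (default −60…60 Hz in 10 Hz steps) added to the
low-resolution constraint map, smooths each candidate's squared magnitude
with a circularly symmetric Gaussian, and selects per pixel the shift
maximizing the local energy, ties broken toward the smallest
$|\Delta\omega_i|$; the selected shifts form the high-resolution field map.
The kernel default is $\sigma=8$ pixels at the desk matrix of 64: the
window must be wider than the off-resonance point spread, otherwise pixels
near tissue edges reward maximal spreading instead of focus. (At a 64
matrix a $\sigma=4$ window is comparable to the spread itself and
mis-assigns a third of the pixels; this was established with the
constant-offset recovery diagnostic.) An optional 3×3 median filter on the
shift map is off by default.

## What the synthetic data does and does not emulate

The generator reproduces the physics the method addresses — ring-resolved
concomitant phase pathways, CPMG violation and its EPG consequences, B0
blur, dual-TE calibration — on 2D pixel grids with pixel-center sums (no
intravoxel dephasing), single-coil reception, no noise unless requested, no
chemical shift, motion, eddy currents or gradient nonlinearity. Passing
tests therefore demonstrate the correctness and internal consistency of the
design/compensation/reconstruction chain under the stated model, not
robustness to those unmodeled effects. Desk-scale studies use a 64×64
Shepp-Logan-like head at full spatial resolution (0.71 mm pixels, FOV
scaled down to 45 mm, 2 interleaves) so gradient amplitudes — and hence
concomitant fields — are realistic while adjoint transforms stay cheap;
protocol-scale checks (phase nulling, cross-term balance, coefficient
tables) run on the full 230 mm field-of-view designs, where no image
reconstruction is required.

## Numerical choices and limitations

- Raster 10 µs; all gradient integrals by trapezoidal quadrature; every
  trapezoid lobe carries explicit zero end samples so embedded and
  stand-alone integrals agree exactly.
- $\gamma = 2.675\times10^8\,$rad s⁻¹ T⁻¹; SI units throughout
  (T/m, s, cycles/m; maps in Hz at user surfaces, rad/s internally).
- Even echo-train lengths place the central ring at echo `etl/2` behind an
  explicit flag (the 0.55 T protocol uses ETL 8 with effective TE
  $4\times$ESP).
- Quadratic cross-terms are excluded from the pathway phase by default
  (spiral rings self-balance them by polarity alternation) and includable
  by flag for bipolar audits.
- The crusher/slice model is a simplified trapezoid set — enough to carry
  the interval-balancing contract, not a full slice-profile model.
- Conjugate-phase correction is a point-wise demodulation; for smooth,
  low-amplitude B0 maps its cross-pixel residual can rival the blur it
  removes, while the removal of the (much larger) constant and linear
  components in `linear_corrections()` and of the concomitant term is
  exact. Iterative model-based reconstruction is out of scope.
- k-space corners are never sampled (disk coverage), so reconstructions are
  compared against references with the same sampling operator, or against
  smooth phantoms, in quality tests.
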