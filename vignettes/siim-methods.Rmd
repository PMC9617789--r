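---
title: "Signal-intensity-informed encoding and self-supervised unrolled reconstruction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-intensity-informed encoding and self-supervised unrolled reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: the
forward models and their assumptions, the tunable parameters that matter,
what the synthetic phantom emulates (and deliberately does not), the
numerical choices, and the design decisions that were genuinely open.

## 1. Forward models

**Conventional SMS encoding.** One time frame of one SMS slice group is
modeled as

$$ y_c \;=\; M_\Omega \sum_{i=1}^{n_\text{sms}} P_i \, F \, S_{c}^{(i)}\, x_i \;+\; n, $$

where $x_i$ is the complex image of simultaneously excited slice $i$,
$S^{(i)}_c$ the (per-slice) sensitivity of coil $c$, $F$ the unitary 2-D
DFT (DC-centered at index $\lfloor N/2\rfloor$), $P_i$ the CAIPIRINHA
per-line phase (slice $i$, $j$-th sampled line:
$2\pi i j\,\cdot\text{fov\_shift}$, i.e. a FOV-shift of the aliased slice
position), and $M_\Omega$ the uniform step-$R$ sampling mask restricted to
the asymmetric partial-Fourier window. Assumptions: Cartesian sampling, no
field inhomogeneity or gradient delays, coil maps static across frames.
Partial Fourier is modeled purely as non-acquisition — no homodyne/POCS
completion — because the protocol folds it into the net acceleration and the
reconstruction chain never exploits conjugate symmetry.

**SIIM encoding.** With a per-frame, per-slice nonnegative diagonal
intensity image $L$, the signal-intensity-informed operator is $H = E\,L$.
The unknown of the $H$ system has flat contrast across frames; for the
unregularized least-squares problems the solutions obey
$\hat x_\text{reg} = L\,\hat x_\text{SIIM}$ *exactly* whenever $E^HE$ is
invertible. This identity is a runtime-verifiable property
(`verify_siim_identity()`), and is the basis for restoring physical signal
units after reconstruction. Note the identity genuinely requires
well-posedness: with partial Fourier (or too few coils) $E^HE$ is singular
and the two minimum-norm solutions differ — the package's identity tests
therefore use fully sampled phase-encode windows with enough coils.

**Intensity maps.** $L$ is built exactly the way a scanner-side pipeline
would: split slice-GRAPPA separation of the collapsed frame, central
`calib_size` (default 24×24) k-space block, separable Blackman apodization
against ringing, zero-padding, unitary inverse FFT, magnitude of the SENSE-1
combination. $L$ is floored at `1e-3 * max(L)` per slice so that division
by $L$ (and the $H$ adjoint) is well conditioned; background pixels of a
low-resolution magnitude image otherwise approach zero.

## 2. Calibration

**ESPIRiT** (kernel 6×6, row-space threshold 0.02, eigenvalue crop 0.95,
single map set) estimates coil maps from the central 24×24 calibration
region; maps are normalized to $\sum_c |S_c|^2 = 1$ on the support and
phase-referenced to coil 1. These are the reference defaults of the original
eigenvalue-based autocalibration method.

**Split slice-GRAPPA.** Separation kernels predict each slice's k-space
from the CAIPI-modulated superposition, with the *split* constraint that
single-slice inputs from other slices map to zero (leakage blocking). Two
non-obvious choices, both config-exposed:

* *Kernel geometry.* Default 5 (readout) × 7 (phase-encode taps, spaced $R$
  lines). The ky tap count bounds the Fourier harmonics of the effective
  unmixing weights over the reduced FOV, so it must grow with $R$: 5 taps
  are demonstrably insufficient at $R=4$ while wide kernels overfit short
  calibrations — 7 taps with a mild ridge (1e-6, relative) was the robust
  middle on calibrations of ≥ 48 lines.
* *Feasibility.* On the $R$-spaced acquired grid the kernel must resolve
  $n_\text{sms}\times R$ superposed signals per aliased pixel; with
  $3\times4=12$ this requires an array of more than 12 channels. The
  acceptance phantom therefore uses a 30-channel two-ring array of localized
  loop elements, matching the channel counts used clinically for this
  protocol; 8-coil configurations are reserved for the network experiments
  at milder acceleration.

In-plane GRAPPA kernels (5×4 sources, per anatomical slice) fill the
skipped lines after separation; separation-first ordering is the default.
The calibration scan itself is simulated with full readout resolution and
~1/3 phase-encode resolution (k-space `nx × min(ny, 56)`), mirroring a
separate low-resolution calibration acquisition; the 24×24 `calib_size` is
only the ESPIRiT/intensity-map crop.

## 3. Classical reconstructions

`cg_least_squares()` solves $(A^HA + \mu I)x = A^Hy + \mu z$ by conjugate
gradients (matrix-free, complex). LLR applies proximal-gradient iterations
with singular-value soft thresholding of 8×8 block Casorati matrices
(random cyclic shifts by default; a fixed partition makes the objective
provably monotone). L+S decomposes the series into a globally low-rank part
and a temporally-FFT-sparse part with joint ISTA steps of size 0.5 — the
coupled smooth term has Lipschitz constant 2 when $\|A^HA\|\le 1$, so this
step guarantees monotone descent. All thresholds are *relative* (to the
largest initial singular value / spectral magnitude) because the in-vivo
tuned values are not published; they are config-exposed and logged.

## 4. Unrolled network and self-supervised training

The regularizer is a residual CNN on two-channel (re/im) images: input
convolution (2→F), `n_blocks` residual blocks (conv→ReLU→conv→×0.1, plus
skip), output convolution (F→2), and a global input→output skip; all
kernels 3×3; one weight set shared across unrolls. The SMS slice stack is
concatenated along readout before entering the network. The full-size
configuration is 15 blocks × 64 channels; block/channel counts are
config-exposed because the scaled-down CPU experiments use smaller nets.
The reference parameter count printed for the full architecture does not
match 15 blocks of two 64×64 convolutions (it matches roughly half the
depth), so the parameter count is intentionally *not* a package invariant —
`resnet_n_params()` reports whatever the configuration implies.

Each unroll solves the quadratic-penalty data-fidelity subproblem by CG.
The penalty $\mu$ is a single trainable scalar, softplus-parameterized for
positivity. Backpropagation is hand-written: through the CG solve via the
implicit-function theorem ($M = A^HA+\mu I$ is Hermitian, so the adjoint
pass is another $M$-solve), through the CNN via Rcpp convolution kernels.
Gradients are verified against central finite differences to <1e-3
(machine-precision agreement when CG is run to convergence; with truncated
CG the implicit gradient is the standard approximation).

**Multi-mask SSDU.** The acquired set $\Omega$ is split into $K$ pairs
$(\Theta_k, \Lambda_k)$, $\Lambda_k$ holding fraction $\rho$ of the points,
drawn with a Gaussian center preference (bandwidth 0.5 of the grid — wide
enough that 10 masks cover >95% of eligible points) while a protected
central box (half-side 4) always stays in $\Theta_k$. Data consistency only
ever sees $\Theta_k$ — the operator's mask is restricted, so zeroing
measurements on $\Lambda_k$ provably cannot change the network output (an
exact, tested invariant). The loss on $\Lambda_k$ is the normalized
$\ell_1$–$\ell_2$ compound $\|e\|_2/\|y\|_2 + \|e\|_1/\|y\|_1$. Defaults
$\rho = 0.4$, $K = 6$; optimizer Adam at 5e-4 (2e-3 for the short
scaled-down runs), batch = one slice-group frame. Training is bit-exactly
deterministic given the seed.

## 5. The numerical phantom: what it emulates, what it does not

Parametric ellipses (body, RV and LV blood pools, myocardial ring) with
gamma-variate first-pass dynamics (shape 3, scale 1.5 frames; delays
RV/LV/myocardium 2/4/8 frames; amplitudes 0.9/1.0/0.35 over baselines
0.10–0.15, emulating saturation-prepared contrast) plus a recirculation
plateau of 25% of peak (time constant 12 frames) — first-pass signal does
not return to the pre-contrast baseline, and the late-phase SNR floor
matters for the low-SNR comparisons. 40 frames. Coils are localized loops
on two rings with through-slice sensitivity variation (footprint
$1.9/\sqrt{n_c}$ in normalized units); through-slice variation is what
makes SMS separation possible at all, and element size shrinking with
channel count mirrors real arrays. Complex Gaussian k-space noise with
$\sigma = 0.05$ per sampled point puts peak-LV SNR near 22 and late-phase
SNR near 7. A smooth object phase and per-slice geometry changes are
included.

Not emulated: respiratory/cardiac motion (calibration and dynamics share
one motion state), dark-rim/Gibbs physiology, realistic anatomy beyond
ellipses, $T_1/T_2^*$ signal equations, and the reader-study endpoints. A
green phantom test therefore establishes operator/algorithm correctness and
the *relative* behavior of the methods under controlled SNR variation — not
clinical image quality.

## 6. Scaled-down end-to-end experiment

The acceptance comparison trains both network variants on one phantom:
64×64, SMS=2 (FOV/2 shifts), R=2 with 6/8 partial Fourier, 8 coils,
3 unrolls × 5 CG iterations, 2 residual blocks × 8 channels, 50 Adam steps,
frames 6–40 as the sample pool, 3 seeds. These sizes are chosen purely for
the single-CPU runtime budget; the architecture and protocol scale up by
configuration. Evaluation: PSNR on the 5 late (lowest-SNR) frames against
the noiseless truth, with the zero-filled adjoint $E^Hy$ as the floor
baseline, and the temporal flatness property — the coefficient of variation
of LV-ROI means of unregularized flat-contrast solutions across frames is
smaller than that of conventional solutions.

## 7. Numerical choices and degenerate inputs

* FFTs are unitary and DC-centered; Parseval-based tests are exact.
* CG stops on the relative normal-equation residual; non-convergence is
  flagged in the report, never raised.
* The intensity-map floor (1e-3 relative) bounds the conditioning of $H$;
  an unfloored zero entry is an error in `restore_intensity()`.
* All-zero calibration or k-space frames are errors; empty ROIs and
  held-out sets are errors.
* Ridge factors in GRAPPA fits are relative to the trace of the normal
  matrix, making them scale-invariant.
* SSIM uses a 7×7 uniform window with the standard constants and the joint
  maximum as dynamic range (making it symmetric); PSNR uses the reference
  maximum of the magnitude image.
* The zero-phase uptake-curve filter is a Hamming-windowed sinc (11 taps,
  cutoff 0.15 cycles/frame, DC gain exactly 1) applied forward-backward.

## 8. Known limitations

* Split slice-GRAPPA quality degrades sharply below ~16 channels at
  SMS=3×R=4 (a rank limit, not an implementation artifact); the
  8-coil small-matrix configurations are not expected to produce clean
  separations and are not used for that purpose.
* The unregularized identity $\hat x_\text{reg} = L\hat x_\text{SIIM}$ does
  not hold in the null space of a partial-Fourier/undersampled $E$; the
  package verifies it on well-posed instances only.
* Training at full protocol size (160×120, 30 coils, 15×64 network, 10
  unrolls) is supported by the code but far outside a single-CPU test
  budget; conclusions at the scaled-down size are directional.
* The CLI is a thin orchestration layer; long-running experiment
  configurations should be driven from R directly.
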