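---
title: "Methods and design notes for condensakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for condensakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensakit)
```

condensakit quantifies liquid–liquid phase separation (LLPS) of
intrinsically disordered protein regions — the androgen-receptor
activation domain is the motivating system — and its modulation by small
molecules. It covers five measurement families: condensate and nuclear
cluster image quantification, cloud-point extraction from turbidity
ramps, dense/light-phase partition coefficients, FRAP recovery kinetics,
and ligand–protein contact analysis of molecular-dynamics trajectories,
plus the statistical layer these assays need. Every estimator has a
matching synthetic-data generator with recorded ground truth, so the
whole pipeline is testable by parameter recovery without any external
data.

This vignette explains the models, the tunable parameters that matter,
the numerical choices, and what the synthetic tests do and do not show
about real data.

## Turbidity cloud points

A protein solution in the LCST regime turns turbid on heating; the
absorbance at 340 nm as a function of temperature is sigmoidal, and the
cloud point $T_c$ is defined as the temperature of the maximum of the
first derivative of that curve. `cloud_point()` smooths the curve with a
centered moving average (`smooth_window`, default 5 points — enough to
tame instrument noise on a 0.2 °C grid without flattening a ~1 °C
transition), differentiates with centered finite differences on the
actual grid, and reports the derivative maximum.

Two guards matter in practice. A *flat* flag is raised when the
derivative peak does not exceed five times the derivative noise floor;
the floor is the MAD of the derivative after discarding its top
quartile, so the transition peak cannot inflate its own detection
threshold wherever it sits on the ramp. An *edge* flag is raised when
the maximum lands on the first or last usable grid point, meaning the
transition was not fully sampled. The statistic is invariant to affine
transforms of the absorbance (baseline offsets, gain), which the test
suite asserts.

At 2% absorbance noise (relative to a unit-amplitude transition) the
estimator's Monte-Carlo standard deviation is about 0.35 °C over 200
replicates — comfortably below the 0.5 °C a 1 °C min⁻¹ ramp can claim.

## Partition coefficients

After inducing phase separation and centrifuging, the dense phase is
too concentrated to inject directly, so it is diluted (the default
dilution factor is 9, i.e. diluted nine times) before HPLC
quantification. `partition_coefficient()` computes
$P = c_\mathrm{dense,measured} \cdot D / c_\mathrm{light}$. With one
measurement per phase and supplied standard deviations, the s.e. of $P$
comes from the first-order delta method; with three or more replicate
pairs the replicate-level mean and s.d. are preferred, matching how
triplicate measurements are normally reported.
`calibration_concentration()` inverse-predicts concentrations from a
linear peak-area calibration (four standards are typical) and flags
extrapolation beyond the calibrated range.

## FRAP: double normalization and recovery fitting

Three ROI traces are recorded: the bleached region, the whole cell, and
a background region outside cells. Double normalization,

$$N(t) = \frac{(I_\mathrm{bleach}-I_\mathrm{bg})/(I_\mathrm{whole}-I_\mathrm{bg})}
{\left\langle (I_\mathrm{bleach}-I_\mathrm{bg})/(I_\mathrm{whole}-I_\mathrm{bg}) \right\rangle_\mathrm{pre}},$$

cancels acquisition photobleaching (which attenuates both cellular ROIs
equally) and normalizes the pre-bleach level to 1. `fit_recovery()`
then fits the single-exponential model
$N(t) = I_0 + (F_\infty - I_0)(1 - e^{-kt})$ to the post-bleach frames,
with $t = 0$ fixed at the first post-bleach frame. The mobile fraction
is $(F_\infty - I_0)/(1 - I_0)$ and $t_{1/2} = \ln 2 / k$. A
double-exponential was deliberately not offered: the downstream
reporting convention is a single (mobile fraction, $t_{1/2}$) pair, and
a second component is not identifiable at typical noise on 200-frame
traces. Initial guesses are deterministic ($I_0$ from the first
post-bleach point, $F_\infty$ from the last 10% of frames, $k$ from the
observed time to half-recovery), so fits are reproducible without a
stochastic restart policy. Degenerate inputs are handled explicitly: a
flat post-bleach trace returns mobile fraction 0 with an `immobile`
flag rather than a failed fit, and a trace with no bleach at all
($N \equiv 1$) is an error because $I_0 = 1$ makes the mobile fraction
singular.

The generator defaults mirror a typical live-cell protocol: 20
pre-bleach and 200 post-bleach frames at 180 ms intervals. Noiseless
round trips recover parameters to well under 1% everywhere. At 2%
noise, a single trace in the hardest corner (mobile fraction 0.2, where
the recovery amplitude is only ~0.18 of the signal) carries 12–18%
irreducible statistical error; the recovery check therefore pools 15
traces per condition and averages the fitted parameters, which is how
FRAP statistics are produced in practice (per-condition cell counts of
15 or more, results combined per condition). With pooling, worst-case
error across the 5×5 (mobile fraction × half-time) grid is under 6%.

## Imaging

All imaging operations use pixel-center coordinates, 0-based indices
with y increasing downward, and report areas in both px² and physical
units via the pixel size (nm), which every `image_stack` carries.
Where the original workflows had manual steps (ROI drawing, nucleus
exclusion), those become explicit inputs so runs are deterministic.

**Nuclear segmentation** (`segment_nuclei()`): median filter →
background subtraction (Gaussian estimate) → Otsu or local adaptive
threshold → connected components. Touching nuclei are *not* split — the
source workflows exclude problematic nuclei rather than watershed them
— and over-merged objects can be removed with the `max_area` ceiling.
Dark interior holes (nucleoli) stay excluded from the mask unless their
mean intensity reaches `hole_fill_frac` (default 0.5) of the parent
nucleus mean; the exclusion criterion is parameterized because the
original description does not specify one.

**Granularity** (`granularity()`): the within-nucleus intensity
standard deviation, a proxy for sub-resolution clustering. The
population s.d. (divisor $n$) is used; with thousands of pixels per
nucleus the sample/population distinction is immaterial, but fixing it
makes results bit-reproducible. The implementation is checked exactly
against a brute-force pixel loop.

**Condensate counting** (`detect_condensates()`): per timepoint, a
maximum-intensity z-projection is masked by the cytosol (the supplied
nuclear ROIs removed), thresholded (fixed AU value or Otsu), and
connected components above `min_area` are counted and sized; the count
density is count per µm² of cytosol.

**Translocation traces** (`translocation_trace()`): per-frame sum
z-projection, optional translation-only registration to frame 1 by
integer-pixel correlation search (rotation is unnecessary for nuclear
drift on these timescales), then the mean gray value in the nuclear and
cytosolic ROIs. The reported statistic is the bounded form
$I_\mathrm{nuc}/(I_\mathrm{nuc}+I_\mathrm{cyto}) \in [0,1]$; the
unbounded ratio $I_\mathrm{nuc}/I_\mathrm{cyto}$ is recoverable from
the two reported means if preferred.

**Nuclear cluster detection** (`detect_nuclear_clusters()`): nuclei
from the DNA counterstain (Otsu), then rolling-ball background
subtraction on the signal channel with ball radius = 8 × the resolution
limit (48 nm at super-resolution, i.e. 8 px at 48 nm px⁻¹). The rolling
ball is implemented as grayscale opening with a ball-height structuring
element. For the detection threshold after subtraction we use robust
background statistics — median + 5×MAD of the corrected image within
nuclei — rather than Otsu: cluster pixels occupy well under 1% of the
nuclear area, so a bimodality criterion like Otsu degenerates to
splitting the noise distribution and floods the field with false
positives; the 5×MAD rule matches the 5σ contrast at which the
detection suite demands ≥95% recall. Otsu remains available via
`threshold = "otsu"`.

**Droplet partitioning** (`quantify_droplet_partitioning()`): droplets
are segmented on the channel-sum image with a fixed lower threshold
given on the 8-bit scale (default 3, the "(3,255)" convention, rescaled
proportionally for 16-bit data). "Larger than 0.1 µm" is interpreted as
equivalent *diameter*, not area — 0.1 µm² of area would be sub-pixel at
the stated resolutions. Per-droplet mean intensity of the channel of
interest and a normalized cross-section profile of the largest droplet
are reported.

## MD contact analysis

`contact_matrix()` marks a residue as contacting the ligand in a frame
when any heavy (non-hydrogen) atom of the residue is within 6.0 Å —
inclusive; exact ties are measure-zero in real trajectories — of any
ligand heavy atom, with minimum-image wrapping when box vectors are
supplied. Hydrogens are identified by the element field, falling back
to the leading letter of the atom name for PDB dialects without element
columns. Topologies are read from PDB (via bio3d) or plain atom tables;
frames from DCD, a `frame,atom,x,y,z` text table, or an in-memory
array. The implementation is validated against an all-pairs
distance-loop oracle on randomized toy systems, including periodic
ones.

`blocking_se()` implements Flyvbjerg–Petersen blocking: successive
pairwise block averaging, with the s.e. at each level
$\sqrt{c_0/(n-1)}$ and its own uncertainty $\mathrm{se}/\sqrt{2(n-1)}$.
The reported value is the plateau: the first level whose increase to
the next level falls within that uncertainty, with a conservative
fallback (maximum s.e. among levels retaining ≥32 blocks) when no
plateau is found. On two-state chains with known integrated
autocorrelation time $\tau$, the plateau reproduces
$\sqrt{p(1-p)(1+2\tau)/n}$ within 15%.

`simulated_kd()` converts a bound fraction to a dissociation constant
for a single protein–ligand pair in a closed cubic box of side $L$:
$C_0 = 1/(N_A L^3)$, and mass action with $[P] = [L] = (1-f_B)C_0$,
$[PL] = f_B C_0$ gives $K_D = C_0 (1-f_B)^2 / f_B$. For $L$ = 7.5 nm,
$C_0$ = 3.936 mM, and $f_B = 0.5$ maps to $K_D$ = 1.968 mM. The
conversion from bound fraction to $K_D$ is not uniquely fixed by the
source description (a volume correction excluding the protein, for
instance, would shift it by a constant factor), so both the raw bound
fraction and the derived $K_D$ are always reported, keeping the
conversion auditable. When replica metadata is present only the 300 K
ground replica should be analyzed; stride is a parameter because
per-frame versus strided evaluation is a trajectory-format detail.

## Statistics

**Granularity model** (`granularity_model()`): ordinary least squares
of `intensity_sd ~ mean_intensity * group + replicate` — the s.d. as
response; mean intensity, group, their interaction, and biological
replicate as fixed effects. Replicate enters as a fixed covariate (a
random effect is not part of the stated design). The per-group slope
difference versus the control is the interaction coefficient, and the
family of slope contrasts is Dunnett-adjusted. With a single replicate
level the replicate term is dropped with a warning rather than fitting
a rank-deficient design.

**Dunnett adjustment** (`dunnett_adjust()`): two-sided p-values from
the maximum-modulus multivariate-t distribution with the contrast
correlation matrix. There is no closed form for general correlation, so
the tail probability is computed by seeded Monte-Carlo integration
(default 10⁵ draws, ~10⁻³ accuracy; the seed is an explicit argument so
runs are reproducible). A family of one reduces exactly to the
two-sided t-test; independent contrasts approach the Šidák bound; and
the adjusted p is floored at the raw p. Null calibration is checked by
simulation: two groups generated from identical parameters reject at
≈ the nominal α.

**Dose–response** (`fit_log_logistic()`): the three-parameter
log-logistic with lower limit 0, $f(x) = d / (1 + \exp(b(\ln x - \ln
e)))$ — the `drc` LL.3 convention, so $e$ is the IC50. Zero-dose
controls are retained as observations of the upper limit $d$ (the
$x \to 0$ limit of the model) rather than dropped. IC10 is defined as
the dose giving 10% inhibition relative to $d$ (the ED-style
convention): $f = 0.9d$ gives $\mathrm{IC10} = e \cdot 9^{-1/b}$.
Dose-independent responses raise an error instead of returning an
unidentifiable fit.

`chrom_logd()` ($0.0857 \cdot \mathrm{CHI} - 2$), `fold_change_ddct()`
($2^{-\Delta\Delta C_t}$) and `ovoid_volume()` (length × width ×
height × 0.5236) are thin, exact implementations of their printed
formulas, kept in the package so the full analysis chain is scriptable
and testable in one place.

## The synthetic-data generators

Every generator is a pure function of its arguments including the seed
(the caller's RNG state is untouched), returns the `ground_truth` used
to produce the data, and can serialize it to a YAML sidecar. Noise is
additive Gaussian everywhere: the estimators are tested by parameter
recovery, not by noise realism, and a Poisson shot-noise model would
buy realism the tests do not use. Images are 16-bit; the measurement
operations accept 8- and 16-bit.

Deliberate idealizations, which bound what passing tests show about
real data:

* Nuclei are uniform ellipses; the PSF is applied to the cluster/spot
  layer only (spot width and PSF width add in quadrature), so a
  spot-free nucleus has exactly zero within-mask s.d. and granularity
  recovery can be asserted exactly. Real nuclei have textured
  chromatin backgrounds.
* Condensate kinetics are schematic — Poisson nucleation with linear
  area growth — not physical coarsening (no Ostwald ripening, no
  fusion events in the generator even though fusion occurs in cells).
* Turbidity curves are exact logistics; real ramps can be asymmetric.
* The contact generator emits contacts from a latent two-state Markov
  chain. Its default residue profile anchors the first residue at
  contact probability 1 — a bound pose always touches its primary
  binding residue — so the observable bound fraction (fraction of
  frames with ≥1 contact) equals the chain's stationary value
  $f_B^* = (1-p_{uu})/((1-p_{bb})+(1-p_{uu}))$. For other profiles the
  truth additionally records
  $f_B^{obs} = f_B^* (1 - \prod_i (1-p_i))$.
* The trajectory-file fixture alternates a bound and an unbound ligand
  pose by rigid translation; it exercises the file-format and
  cutoff-geometry paths, not conformational sampling.

No generator parameter encodes noise magnitudes from the motivating
experiments (none are published); noise levels are explicit arguments,
and the recovery claims above state the level at which they hold.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a laptop-class
single core: 10⁵-frame contact chains, 200-replicate turbidity Monte
Carlo, 500 log-logistic fits, 200–500 null simulations for the
granularity model, 15-trace FRAP pooling, and 128–256 px synthetic
fields. The full suite runs in about a minute; the acceptance script
in seconds.

## Known limitations

3-D segmentation, FLIM photon filtering, deconvolution, diffusion-type
FRAP models, phase-diagram reconstruction, and running or
parameterizing MD simulations are out of scope. The Dunnett adjustment
is Monte-Carlo, so adjusted p-values carry ~10⁻³ integration noise;
extremely small p-values are reported at the raw-p floor rather than
resolved. Registration is integer-pixel; sub-pixel drift biases ROI
means by at most one pixel row or column.
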