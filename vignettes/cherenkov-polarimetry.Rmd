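---
title: "Polarization-resolved Cherenkov dosimetry: methods and model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarization-resolved Cherenkov dosimetry: methods and model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherenkovpol)
```

This vignette records the physical model, the measurement chain, the
synthetic-data generator, and the numerical choices behind `cherenkovpol`.
It is the methods reference for the package; the README shows usage.

# 1. Physical model

## Cherenkov emission

A charged particle with speed $\beta = v/c$ in a medium of refractive
index $n$ emits Cherenkov light when $\beta n > 1$, on a cone of half
angle $\cos\theta_c = 1/(\beta n)$ about the particle direction. For
electrons this gives a kinetic-energy threshold

$$E_{min} = m_0 c^2\left(\frac{1}{\sqrt{1 - 1/n^2}} - 1\right),$$

about 264 keV in water ($n = 1.33$) and 149 keV in polyvinyl-toluene
plastic scintillator ($n = 1.58$). As $\beta \to 1$ the cone opens to its
maximum, $\arccos(1/n) \approx 41^\circ$ in water.

```{r}
cherenkov_threshold_energy(1.33)
cherenkov_threshold_energy(1.58)
cherenkov_angle(1, 1.33)
```

The photon yield per path length follows the Frank–Tamm expression
restricted to a wavelength band $[\lambda_1, \lambda_2]$:

$$\frac{dN}{dx} = 2\pi\alpha \left(1 - \frac{1}{\beta^2 n^2}\right)
  \left(\frac{1}{\lambda_1} - \frac{1}{\lambda_2}\right),$$

about 249 photons/cm in 400–800 nm at $\beta = 1$ in water. The band
400–800 nm is a package choice representing a visible-light camera; it
scales the absolute counts only, never the angular or polarization
structure.

## Polarization

Cherenkov light is fully linearly polarized at emission: for particle
direction $\hat u$ and photon direction $\hat k$, the electric-field
direction is the normalized component of $\hat u$ perpendicular to
$\hat k$, i.e. it lies in the $(\hat u, \hat k)$ plane
(`photon_polarization_vector()`). Multiple scattering of the electrons
randomizes $\hat u$, so the *aggregate* light observed from a pixel is
only partially polarized; the measurable degree of linear polarization
(DoLP) decreases as the secondary-electron fleet becomes more isotropic —
hence lower DoLP for photon beams (whose Compton electrons start with a
spread of angles) than for electron beams.

# 2. Polarimetry: the four-angle Malus decomposition

An acquisition is a set of frames behind a linear polarizer at
$\alpha_0 \in \{0, 45, 90, 135\}^\circ$. A pixel receiving polarized
intensity $I_{pol}$ at angle $\psi$ plus unpolarized intensity
$I_{unpol}$ records

$$I(\alpha_0) = I_{pol}\cos^2(\alpha_0 - \psi) + \tfrac{1}{2} I_{unpol}.$$

With the four canonical angles this inverts in closed form via the linear
Stokes parameters $Q = I_0 - I_{90}$, $U = I_{45} - I_{135}$:

$$I_{pol} = \sqrt{Q^2 + U^2}, \qquad
  \psi = \tfrac{1}{2}\,\mathrm{atan2}(U, Q), \qquad
  I_{unpol} = I_0 + I_{90} - I_{pol},$$

$$\mathrm{DoLP} = 100\,\frac{I_{pol}}{I_{pol} + I_{unpol}} \ \%,$$

with $\psi \in (-90, 90]^\circ$ (AoLP). `solve_four_angles()` implements
this and additionally reports the consistency residual
$|(I_0 + I_{90}) - (I_{45} + I_{135})|$, which is zero for any exact
Malus signal and flags pixels corrupted by noise or spikes. For polarizer
angle sets other than the canonical four, the same model is fit by linear
least squares in $(1, \cos 2\alpha_0, \sin 2\alpha_0)$, refined with
`minpack.lm::nlsLM` if the linear solution violates physical bounds.

Limiting cases used as anchors: equal frames give DoLP = 0; a pure
$\cos^2$ curve with zero offset gives DoLP = 100; unpolarized light
transmits one half on average over polarizer angle.

# 3. Image preparation

`preprocess_frames()` applies, in order:

1. **Temporal median** over the burst of `n_frames` frames per polarizer
   angle — removes radiation-induced transient spikes.
2. **Background subtraction** of a median dark frame, scaled by the
   exposure ratio when exposures differ (a warning reports the ratio);
   the fraction of negative pixels after subtraction is attached as an
   attribute for QA.
3. **Flat-field division** by a vignetting surface, normalized to 1 at
   the optical center. The surface model is
   $A / (1 + r^2/f^2)^2$ (a $\cos^4$-type falloff with focal parameter
   $f$ in pixels), fit with `nlsLM`.

The order matters: the median must precede subtraction so spikes cannot
bias the background estimate, and the flat must be applied to
background-free data. Because DoLP and AoLP are ratios of frames taken
through the same optics, they are exactly invariant to any common flat
field; the flat matters for intensity-based dose metrics.

# 4. Angular Monte Carlo

`transport_electron()` is a condensed-history loop with these choices:

* **Step length** 0.1 cm (1 mm). At each step the electron loses
  $S(E)\,\rho\,\Delta x$ of kinetic energy using collision stopping
  powers log-interpolated from an embedded water table (values following
  the NIST ESTAR tabulation, 100 keV–30 MeV).
* **Multiple scattering** by the Highland formula,
  $\theta_0 = \frac{13.6\ \mathrm{MeV}}{\beta p c}\sqrt{t}\,
  (1 + 0.038 \ln t)$ with $t$ the step in radiation lengths
  ($X_0 = 36.08$ g/cm² for water); two independent Gaussian projected
  angles are applied per step.
* **Emission**: if above threshold, a Poisson number of photons with
  Frank–Tamm mean is emitted mid-step on the exact analytic cone at
  $\theta_c(E)$, with uniform azimuth; each photon records position,
  direction, polarization vector, and the electron energy at generation.
  With `scattering = FALSE` the trajectory stays straight, so every
  photon's polar angle must equal $\theta_c$ of its recorded energy —
  the package's machine-precision MC oracle.
* Transport ends below threshold or on leaving the tank.

Photon beams (`transport_photon_primary()`) use a single-scatter
approximation: an interaction depth drawn from exponential attenuation
(embedded water $\mu/\rho$ table following NIST XCOM), a Compton electron
sampled by Kahn's rejection method for the Klein–Nishina distribution
(electron angle from $\tan\theta_e = \frac{1}{(1+\alpha)\tan(\theta_\gamma/2)}$),
then electron transport as above. Beam spectra are collapsed to effective
monoenergetic values (6 MV → 2 MeV, 18 MV → 5 MeV); pair production and
bremsstrahlung are ignored. These simplifications preserve the feature
that matters here — photon-beam secondaries start with a broad angular
spread, electrons with a narrow one — at desk-scale cost.

`score_distributions()` histograms photon directions into polar bins
(default 1° over [0, 180]) and azimuth bins (default 5°) for voxels
centered on requested (depth, off-axis) positions, optionally keeping
only photons heading toward the camera hemisphere ($\hat k_y > 0$, the
default, since only that light is imaged). Densities are normalized per
degree; an empty voxel falls back to a uniform density and is flagged.

Coordinate frame throughout: $z$ = depth along the beam, $y$ = toward the
camera, $x$ = lateral; tank 15 × 15 × 20 cm³, beam entering at the
center of the top face.

# 5. Geometry and anisotropy correction

The camera sits at $L = 50$ cm from the beam axis at tank mid-depth
(10 cm). Each pixel maps to tank coordinates (depth, lateral) and to
viewing angles

$$\theta_{cam} = 90^\circ + \arctan\frac{depth - 10}{L}, \qquad
  \phi_{cam} = \arctan\frac{lateral}{L},$$

i.e. a pixel at mid-depth on axis views at exactly 90° polar. The
correction map divides out the anisotropy of emission:

$$C_\theta(i,j) = \frac{\bar P_\theta}{P_\theta(\theta_{cam}(i,j))},
  \qquad
  C_\phi(i,j) = \frac{\bar P_\phi}{P_\phi(\phi_{cam}(i,j))},$$

where $P_\theta, P_\phi$ are the scored densities and $\bar P$ their
means over the sampled angular span — so corrections average to 1 and
rescale relative shape only. For electron beams the densities are
linearly interpolated between scored depths (the angular structure
evolves quickly with depth); for photon beams a single central
distribution is used (it is nearly depth-stationary past buildup).
Corrections are capped at 10 with a QA flag counting capped pixels. The
corrected polarized image is $I_{pol} \cdot C_\theta \cdot C_\phi$,
masked to the tank.

# 6. Dose metrics

`extract_ppdd()` averages the image over a lateral window (default the
central 60 % of the field) and normalizes to 100 at the maximum —
percent depth dose. `extract_profile()` takes a lateral cut at a depth
(with optional depth averaging), normalized to 100 on axis.
`fwhm_field_size()` finds the two 50 %-crossings by linear interpolation.
`difference_stats()` interpolates the reference onto the measured
positions and reports mean/sd of the difference in percentage points —
the headline accuracy numbers.

# 7. Synthetic data generator

`scenario()` fixes every knob; `generate_ground_truth()` builds the
noise-free fields; `render_stack()` produces frames. What is emulated,
with defaults (all package choices unless stated):

| Parameter | Default | Meaning |
|---|---|---|
| `image_size` | 110 × 84 px | rows = depth, cols = lateral |
| `pixel_scale` | 2 mm/px | covers the full 20 × 15 cm tank face |
| `dolp` | beam preset | 42 (6 MeV), 47 (18 MeV), 29 (6 MV), 33 (18 MV), 0 (`unpolarized`) % — the measured beam dependence |
| `aolp_max` | 35° | AoLP magnitude cap in the penumbra |
| `counts_scale` | 2×10⁴ | expected counts at the dose maximum |
| `background` | 100 | ambient pedestal (counts) |
| `read_noise` | 5 | Gaussian read noise sd (counts) |
| `spike_rate` | 10⁻⁴ | per-pixel transient-spike probability |
| `n_frames` | 10 | burst length per polarizer angle |
| `vignette_f` | 2.5 × max dim | flat-field focal parameter (px) |
| `exposure` | 30 | nominal exposure (s), carried in metadata |

**Dose model.** Photon beams use
$D(z) = (1 - e^{-az}) e^{-bz}$ with $b$ fixed (0.040 / 0.025 cm⁻¹) and
$a$ solved by `uniroot` so the maximum sits at $z = 1.2$ cm (6 MV) or
3.05 cm (18 MV). Electron beams use a plateau-plus-sigmoid falloff with
the appropriate practical range. Lateral shape is a flat top with
Gaussian penumbra at the preset field size (5 × 5 cm photons,
6 × 6 cm electrons).

**Polarization fields.** DoLP is uniform at the preset. AoLP is 0 on
axis and ramps linearly in the penumbra to $\pm$`aolp_max` (sign by
side), via $t = \mathrm{clamp}((0.8 - rel)/0.6, 0, 1)$ on the relative
lateral dose — a simple monotone ramp standing in for the observed
penumbra rotation; its exact shape is a generator choice.

**Rendering.** Total light is dose × optional anisotropy weight ×
`counts_scale`, split into polarized/unpolarized parts by DoLP, passed
through Malus for each polarizer angle, multiplied by the vignette,
offset by background, then Poisson-sampled with Gaussian read noise and
salted with spikes, per frame. The anisotropy weight is the *reciprocal*
of the correction map built from the supplied MC distributions, so that
the correction machinery, fed those same distributions, exactly undoes
it — this plumbing closure is what the end-to-end acceptance test
checks, on top of noiseless round trips that recover DoLP/AoLP to
1e-10.

**Disk layout.** `write_acquisition()` stores each angle's burst as a
multi-page 32-bit-float TIFF (`angle_000.tiff`, …), plus
`background.tiff`, `flat.tiff` and a `stack.yaml` sidecar carrying
angles, exposure and the `counts_max` scale (the TIFF writer stores
floats in [0, 1]). `read_acquisition()` inverts it.

# 8. Pipeline and numerical choices

`run_pipeline()` chains: MC (`simulate_beam`) → score → ground truth →
render (with reciprocal-correction weighting) → optional TIFF round trip
→ preprocess/measure → four-angle solve → correction → PPDD/profile
metrics, returning a report with `dolp_roi`, `d_max_cm`,
`field_size_cm`, `ppdd_diff_corrected` / `ppdd_diff_raw`,
`profile_diff_corrected`, the curves, and a manifest.

Default problem sizes are deliberately desk-scale: 800–2000 primaries
(≈ 10⁵–10⁶ photons, seconds of runtime), scoring depths of
0.5–2.5 cm (6 MeV) or 0.5–7 cm (18 MeV) plus off-axis positions at
±2 cm. All stochastic stages take explicit seeds; identical seeds give
identical output.

Numerical notes: stopping powers and attenuation interpolate linearly in
log–log space; angular densities are per-degree so bin widths cancel;
the AoLP wrap at ±90° is handled by minimal-angle differences in tests;
fits start from closed-form linear estimates so `nlsLM` only refines.
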