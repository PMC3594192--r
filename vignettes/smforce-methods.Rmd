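---
title: "Models and methods in smforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in smforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smforce)
```

`smforce` analyses single-molecule pulling experiments in which two peptides
— one on an AFM tip, one on a substrate, each coupled through a PEG(3400)
linker — are allowed to bind and are then pulled apart at constant speed.
This vignette documents the models, the estimators, the synthetic-data
generator that stands in for instrument data, and the numerical choices
behind each, in enough detail that any of them can be audited or swapped.

## Calibration

Forces are derived from the photodiode signal as
`F = signal × sensitivity × k`. The sensitivity (nm per signal unit) is the
inverted least-squares slope of the deflection signal against piezo
displacement in the hard-contact region, where tip deflection equals piezo
motion; a near-zero slope (|slope| < 1e-10) is rejected as "no contact".
The spring constant uses the thermal-tune idea in its time-domain form: for
a harmonic cantilever at temperature $T$, equipartition gives
$\langle d^2\rangle = k_B T / k$, so $k = k_B T / \mathrm{Var}(d)$ with the
variance taken after mean removal (population divisor). We deliberately use
the variance route rather than fitting a harmonic-oscillator line shape to
the power spectrum: the synthetic deflection record is white by
construction, the two are equivalent for it, and the variance route is
exact and parameter-free. A PSD fit can be substituted behind
`fit_spring_constant()` without touching anything downstream. `kBT()` uses
$k_B = 1.380649 \times 10^{-2}$ pN·nm/K, i.e. $k_B T \approx 4.11$ pN·nm at
the 298 K default (room-temperature incubation and measurement).

## Worm-like chain and rupture events

Tether elasticity is the Marko–Siggia interpolation

$$F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

strictly increasing in the extension $x$ and divergent as $x \to L_c$. Both
the persistence length $L_p$ and the contour length $L_c$ are free
parameters of the fit (`fit_wlc()`): which of them the instrument software
holds fixed is generally not reported, and leaving both free is the
conservative choice. The fit is Levenberg–Marquardt (`minpack.lm::nls.lm`)
on the residual $F_{\text{model}} - F$, with box constraints
$L_p \in [0.02, 10]$ nm and $L_c$ between just above the largest observed
extension and twenty times it, and a deterministic ladder of five starts
($L_c$ initialised at the rupture extension divided by 0.95, 0.92, 0.85,
0.75, 0.65; $L_p$ at 0.38 nm, the PEG/polypeptide scale); the lowest
residual wins. Extension is tip–sample separation, $x = z - z_0 - F/k$:
the cantilever deflects toward the surface by $F/k$ while pulling. Two
numerical details matter here:

* **Contact point.** $z_0$ is found on the approach by walking from the
  free end until the force exceeds 3× the baseline noise SD for five
  consecutive samples (one sample suffices when noise is zero), then
  refined by intersecting the fitted contact line with zero force. The
  refinement makes $z_0$ precise to a small fraction of a sample even at
  noise levels where a single threshold crossing is metres of jitter.
* **Errors in variables.** Because the measured force enters the extension,
  force noise becomes regressor noise and attenuates the steep part of the
  branch, biasing the fitted force at rupture low. The deflection
  correction therefore uses a running-median-smoothed force (window 11
  samples); the residual is still computed against the raw force.

Rupture detection works on the baseline-corrected retract (line fitted to
the outer 25% of the z range and subtracted). An event must (i) drop by at
least 5× the noise SD within 3 samples, (ii) *stay* down — the median of
samples 2–12 after the peak must sit at least the same threshold below it —
and (iii) be preceded by rising tether force (strictly monotone over 10
samples in the noiseless case; otherwise a fitted slope over the preceding
50 samples with t > 2). Condition (ii) is what separates a rupture from a
transient noise dip on a rising branch; without it, false events
concentrate exactly where real tethers are. Candidates within 5 samples are
merged keeping the largest drop. The detection-level force estimate is the
drop magnitude (peak minus post-rupture median); when the WLC fit of the
stretch succeeds (RMS residual below 5× noise SD), the reported rupture
force is instead the fitted branch evaluated at the rupture position
(midway between the last attached and first detached sample), which
averages the noise over the whole stretch. A guard (|refined − drop| < 6×
noise SD) falls back to the drop magnitude when the fit is off, e.g. for
the superposed first event of a double tether.

An event is *specific* when its rupture distance lies in 10–60 nm — the
window spanned by PEG(3400)+peptide tethers of ~35 nm contour length with
their length inhomogeneity — and its WLC residual is below 10 pN RMS.
Shorter distances are surface adhesion; longer ones are not compatible with
the tether.

## Rupture-force statistics

The rupture-force histogram (10 pN bins by default, matching how such
histograms are usually displayed) is fitted with
$A_1 g(\mu_1,\sigma_1) + A_2 g(\mu_2,\sigma_2)$ by unweighted
Levenberg–Marquardt least squares on the bin counts. Fitting binned counts
rather than maximising a mixture likelihood on the raw forces is a
deliberate fidelity choice — it is how these histograms are analysed in
practice — and a Poisson-weighted option exists (`weighted = TRUE`) but is
off by default. Initial means come from the two best-separated local maxima
of the lightly smoothed histogram; if only one mode is found the fit falls
back to the 25%/75% force quantiles and flags the result (`single_mode`).
Restarts use a fixed ladder of mean offsets (0, ±1, ±2 bins) plus one
quantile-based start; being deterministic, the fit never touches the RNG.
Components are always reported ordered by mean, so the labelling is
invariant to swapped starting guesses. Area fractions are
$a_i = A_i\sigma_i / \sum_j A_j\sigma_j$, effective counts $N a_i$, and the
quoted standard errors $\sigma_i/\sqrt{N a_i}$.

Two statistical caveats are worth stating plainly, because they follow from
the method itself and not from any implementation detail. First, the
effective-counts SE describes within-component dispersion; when the two
components overlap strongly it *understates* the sampling spread of the
fitted means — the binned least-squares estimator's replicate-to-replicate
SD can be several times the quoted SE. Second, at small event counts (one
experiment's ~100–150 specific events) the six-parameter fit is weakly
identified: one component can widen to cover the whole histogram, and
peak-position estimates carry sampling SDs of several piconewtons. The
package's property tests therefore check *unbiasedness over replicates*
(mean of 50 fitted means at n = 2000) rather than pretending single-shot
precision the estimator does not have.

The multiple-tether correction assumes tether attachments per approach are
Poisson with rate $\lambda$. The observed yield $y$ (fraction of cycles
with ≥1 event) fixes $\lambda = -\ln(1-y)$, and the probability that an
observed event involves two or more tethers is the conditional

$$p = \frac{1 - e^{-\lambda}(1+\lambda)}{1 - e^{-\lambda}},$$

which vanishes like $\lambda/2$ at low yield and evaluates to ~0.075 at
14.3% yield and ~0.12 at 22.1% yield. The $\lfloor p\,n\rfloor$ highest
forces are then discarded (floor, in the absence of a stated rounding
rule), keeping the rest in order. Note the tension with the generator
below: when two tethers have distinct contour lengths they rupture at
distinct piezo positions and are *resolved* as two separate events, so in
the synthetic world the discard step removes legitimate high forces and
nudges the fitted upper peak down; the correction targets truly
simultaneous ruptures, which require near-equal tether lengths. The mean
rupture force in `summarize_condition()` is computed on the forces it is
given — i.e. after the discard when used in the standard chain — and the
condition comparison propagates SEs in quadrature, using a binomial
$\sqrt{a(1-a)/N}$ for the area-fraction delta since the effective-counts
formula does not cover it.

## AFM image quantification

`flatten()` removes the background plane. The plane is first fitted on
pixels below the image median + 1 SD so that tall features do not drag it
up; because that one-sided cut truncates the noise distribution
asymmetrically (biasing the fitted offset by ~0.3 of the noise SD), up to
three refinement passes re-fit on a symmetric ±2 SD band around the
background median and re-zero on that median. The refinement converges to a
stable zero level, so flattening an already-flat image changes it by only a
few percent of the pixel noise. `segment_features()` thresholds at
max(3× background SD, 0.5 nm) and labels 4-connected components
(`EBImage::bwlabel`), discarding components under 4 pixels.

`measure_features()` reports, per feature: area; mean height; length and
width as the extents of the pixel cloud along its principal axes (plus one
pixel, for the half-pixel borders); aspect ratio; and two height readouts.
The *maximum height* is refined by fitting a local quadratic surface on the
5×5 window around the apex pixel and reading its peak — taking the raw
pixel maximum over a noisy feature selects positive noise excursions and
overestimates heights by roughly the noise SD, while the quadratic is exact
on noiseless dome apexes and averages the noise down (the refinement falls
back to the fitted window value, or the raw apex at image borders, when the
surface is not concave). The *crest height* is the mean over
one-pixel-wide slabs along the major axis of each slab's maximum — the
natural height of a ridge, robust to the ridge being only ~3 pixels wide.
Heights for oligomers and amorphous aggregates are per-feature maxima;
fibril heights are crest means. Whether a reported "mean height" in the
literature is a mean of per-feature maxima or a mean over feature pixels is
usually ambiguous; the per-feature maximum convention is implemented and
flagged here.

Classification is a deterministic, total three-way rule with thresholds
kept in `morphology_thresholds()` rather than hard-coded: *fibril* if
aspect ratio ≥ 5 and length ≥ 100 nm; *amorphous* if maximum height ≥ 6 nm,
aspect ratio < 5 and area ≥ 10⁴ nm²; otherwise *oligomer*. The thresholds
are chosen to separate the described morphologies — ~3 nm round caps,
4.5–7.2 nm ridges up to 3 µm, ~9.3 nm large blobs — and are not themselves
measured quantities. A small tall blob (under the area threshold) therefore
classifies as an oligomer by this rule.

## The synthetic-data generator

The generator emulates the study conditions, not an instrument. Rupture
forces are i.i.d. draws from a two-component Gaussian mixture; the
component means are the experimentally established quantities (66/132 pN
control, 83/164 pN with copper), while the weights and widths are fixture
constants chosen once — w₁ = 0.5 (control) and 0.35 (copper, reflecting the
redistribution of events toward the high-force peak), σ = 20 and 30 pN so
that the two peaks overlap the way published rupture-force histograms do.
They are stand-ins, not measurements. Tether attachment is Poisson with
λ = 0.155 by default, giving the ~14% specific yield; contour lengths are
Gaussian (35 ± 5 nm, the PEG(3400)+peptide scale with linker
inhomogeneity); persistence length 0.38 nm; retraction 400 nm/s. Each
tether contributes a WLC branch computed against true extension (the
deflection correction is applied in the forward model too, by
parameterising in extension and interpolating onto the piezo grid),
truncated at its rupture force with a one-sample return to baseline;
multiple tethers superpose; Gaussian force noise (3 pN default) and a
linear baseline tilt (0.05 pN/nm) are added. Contour lengths whose rupture
point would leave the scanned range are resampled.

The default sampling rate is 20 kHz (0.02 nm per sample at 400 nm/s).
This is a discretization argument: near rupture the branch is steep
(dF/dz of order 20 pN/nm at the simulated force range), so the last sample
before an instantaneous rupture undershoots the true rupture force by
about dF/dz × Δz; at 0.02 nm that is a few tenths of a piconewton,
comfortably below the force scale of interest, and the rate is realistic
for force spectroscopy hardware.

Thermal records are i.i.d. Gaussian with variance $k_B T/k$ — stationary
and exactly equipartition-consistent, but white: no cantilever resonance,
no 1/f noise. Topographs place paraboloid caps (oligomers), half-cylinder
ridges (fibrils) and unions of 4–6 overlapping equal-height caps
(amorphous blobs) on a tilted plane (0.5 nm/µm) with Gaussian pixel noise
(0.3 nm), uniformly at random without overlap; ridges are placed longest
first and overlap is checked as thick-segment distance with a 30 nm
margin, with an error after 500 failed tries per feature.

What the generator deliberately omits — and hence what recovery tests do
*not* demonstrate about real data: loading-rate dependence of rupture
forces (a single pulling speed is modelled), piezo hysteresis and drift,
hydrodynamic and 1/f cantilever noise, surface adhesion peaks, tip
convolution and feature curvature in images, and real fibril curvature
(ridges are straight). Passing recovery tests shows the estimators are
correct for the stated generative model at the stated noise levels, not
that they are robust to every instrument artefact.

## Orchestration and reproducibility

`run_study()` chains both conditions through simulate → analyze →
condition statistics → comparison, plus the image time course, expanding
one master seed into fixed per-stage sub-seeds (offsets 101/202/303…) so
stages can be rerun independently; rerunning with the same seed reproduces
every table bit for bit. The package exposes all of this as ordinary R
functions returning tibbles — the natural interface for an analysis
package — with plain-text I/O (`write_experiment()`, `read_force_curves()`,
`write_topograph()`, `report_study()`) for exchange with other tools.

Problem sizes in the shipped tests were chosen to exercise each estimator
at meaningful statistics while keeping a full run fast on one core:
mixture recovery at 2000 draws (and 50 replicates for unbiasedness),
end-to-end pulling at 400–1000 curves, noise robustness at 500 curves,
false-positive rates over 1000 baseline-only traces, and 500×500-pixel
(5×5 µm) topographs.

## Known limitations

* Both WLC parameters free means $L_p$ and $L_c$ are strongly correlated
  on short stretches; $L_c$ is the stable readout, $L_p$ is not.
* The first event of a superposed double tether is fitted against a
  two-tether force sum with a single WLC; its geometry (not its force,
  which is a clean drop magnitude) is unreliable and its residual flag
  usually marks it.
* The effective-counts SE is the conventional quote, not a sampling SD;
  see the caveats above for when the distinction matters.
* Image segmentation is threshold-based: features merging below the
  threshold, or dimmer than 2× the threshold, are not guaranteed to be
  counted correctly.
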