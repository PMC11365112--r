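---
title: "Time-resolved tryptophan fluorescence analysis with trpfluor"
author: "trpfluor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved tryptophan fluorescence analysis with trpfluor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpfluor)
```

## Scope

`trpfluor` analyzes time-correlated single-photon counting (TCSPC)
experiments on tryptophan-labelled membrane-active peptides titrated with
phospholipid liposomes.  One intrinsic fluorophore supports several
complementary readouts, and the package implements the complete chain for
each of them:

* **decay fitting** — multi-exponential iterative-reconvolution fits of
  photon-count histograms;
* **TRES / TDFS** — time-resolved emission spectra, their center of
  gravity $\nu(t)$ and width FWHM$(t)$, and the dipolar-relaxation fit;
* **anisotropy** — a global fit of polarized decays for the rotational
  correlation time $\varphi$ and limiting anisotropy $r_\infty$;
* **quenching** — a two-step global Stern–Volmer fit of an acrylamide
  titration for the apparent quenching constant $k_q$;
* **leakage** — calcein lifetime unmixing into entrapped and released
  populations;
* **partitioning** — a global fit of steady-state intensity titrations
  for the dissociation constant $K_d$, with support-plane (NSSR)
  confidence intervals, and the partition-weighted decomposition of any
  observable into aqueous and membrane-bound endpoints.

Because raw TCSPC data of this kind are rarely deposited, the package
also ships a seeded synthetic-data generator that emulates each
experiment with the statistical structure the analyses assume, so the
entire pipeline is testable end to end.

## Models

### Fluorescence decay and reconvolution

The intensity decay is modelled as a sum of up to three exponentials,

$$F(t) = \sum_{i=1}^{3} A_i \, e^{-t/\tau_i},$$

with the amplitude-averaged lifetime
$\tau_\mathrm{av} = \sum A_i \tau_i / \sum A_i$.  A TCSPC histogram is
the convolution of $F$ with the instrument response function (IRF) plus
a constant background, sampled with Poisson noise.  `trpfluor` fits in
counts space by reconvolution: the model is convolved with the measured
IRF (linear, zero-padded convolution — no circular wraparound, so decay
tails cannot alias into $t \approx 0$) and compared with the histogram
under Neyman weights $\sigma_k^2 = \max(y_k, 1)$, the convention of
commercial TCSPC software.  A Poisson-deviance objective is available
via `mle = TRUE`.

Numerically the fit uses variable projection: the lifetimes and a
bounded IRF time shift ($\pm 5$ bins; real TCSPC alignment drifts) are
the only nonlinear parameters, while amplitudes and background are
solved at every step by clamped weighted linear least squares.  Five
deterministic, dispersed log-spaced lifetime sets start the optimizer;
the best objective wins, so fits are reproducible without a random seed.
Components whose fitted lifetimes agree within 5% are merged.  The
default fit window opens 0.5 ns before the IRF peak and runs to the end
of the grid.

Amplitudes are constrained non-negative by default.  For
wavelength-resolved decays this constraint must be dropped
(`nonneg = FALSE`): while the emission band sweeps to the red, red-edge
decays *rise* before they decay, and a rise term is a negative
pre-exponential.  This is standard practice in time-dependent
fluorescence shift work, and the TRES stage uses it automatically.

### Time-resolved emission spectra

Spectra are assembled at chosen delays from the *fitted*, IRF-free
decays (the raw-counts route is available for diagnostics).  The
spectral center of gravity is computed exactly as an intensity-weighted
mean of $1/\lambda$,

$$\nu(t) = \frac{\sum_\lambda I(\lambda, t)\,\lambda^{-1}}
               {\sum_\lambda I(\lambda, t)},$$

on the measured wavelength grid — no resampling onto a uniform
wavenumber axis, which would demand a Jacobian convention the
center-of-gravity definition does not require.  The relaxation of the
environment is then summarized by the monoexponential law

$$\nu(t) = C e^{-t/t_\mathrm{relax}} + \nu_\infty,$$

where $t_\mathrm{relax}$ is the dipolar relaxation time and
$\nu_\infty$ the limiting relaxation level: lower $\nu_\infty$ means a
more polar, more relaxed environment.  The estimate of the *total*
shift from nonpolar-solvent reference spectra is deliberately not
implemented — it is not applicable to peptides of this kind — so
$\nu_\infty$ carries the polarity information and $C$ only the
detectable part of the shift.  The fit is unweighted (no per-point
errors exist for $\nu(t)$) and can be restricted to a window, which is
needed when $\nu(t)$ rises again at late times (aggregating peptides in
buffer show this).

FWHM$(t)$ is measured on the wavenumber axis by linear interpolation of
the half-maximum crossings, taking the outermost crossing on each flank
when noise produces several.  A time-constant FWHM indicates
homogeneous, continuous relaxation; a transient FWHM maximum reveals
two sub-populations relaxing at different rates — the signature used to
detect "relaxation by water recruitment" for deeply inserted
tryptophans.

The heavy-water ratio
$R_{D/H} = t_\mathrm{relax}(\mathrm{D_2O}) / t_\mathrm{relax}(\mathrm{H_2O})$
distinguishes relaxation by water reorientation
($R_{D/H} \approx 1.5$ for fully exposed Trp) from relaxation against
polar peptide or lipid groups ($R_{D/H} \approx 1$).

### Anisotropy

Polarized decays at emission polarizer angle $\theta$ follow

$$I(\theta, t) = \frac{k(\theta)}{3} \sum_i A_i e^{-t/\tau_i}
  \left[1 + (3\cos^2\theta - 1)\,(B e^{-t/\varphi} + r_\infty)\right],$$

with the detection matching factor
$k(\theta)/3 = \cos^2\theta + \sin^2\theta / G$.  The three printed
special cases pin this form: 1 at vertical, $1/G$ at horizontal, and
$(2+G)/(3G)$ at the magic angle $\arccos(1/\sqrt 3) \approx 54.74^\circ$
(angles are taken as given; $54.7^\circ$ inputs are not snapped to the
exact magic angle).  $G$ is a measured instrument property and is never
fitted.  $B$, $\varphi$ and $r_\infty$ are shared globally across all
angles; lifetimes come in fixed from a magic-angle or TRES analysis and
only the amplitudes are re-fitted.  Fitting happens in counts space by
reconvolution, which keeps Poisson weighting valid — the textbook
$r(t)$ construction $(I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$ is
implemented as `construct_anisotropy_decay()` and serves as an
independent cross-check, not as the estimator.  The between-channel
scaling is fixed by the measured $G$ inside $k(\theta)/3$; free
per-curve scales are available (`fit_scales = TRUE`) for instruments
whose throughput deviates from it, but they are off by default — with
only two polarizer angles a free scale leaves $r_\infty$ identified
solely by shape modulation depths, which degrades endpoint recovery.
$r_0 = B + r_\infty > 0.4$ (the one-photon limit) warns rather than
fails so that unphysical fit excursions stay visible.

### Quenching

The collisional quencher acrylamide accelerates the decay:

$$F_q(t) = F_0(t)\, e^{-t\, k_q [Q]}.$$

Following the two-step protocol, every decay in the titration is first
fitted empirically by tri-exponential reconvolution; the deconvoluted
decays are then reconstructed and all $[Q] > 0$ curves are fitted
jointly with only $k_q$ free and $F_0$ fixed to the zero-quencher
reconstruction.  The step-2 objective is unweighted least squares on the
reconstructed curves over $[0, 5\max\tau_i]$ — reconstruction exists
precisely to escape per-photon weighting.  $k_q$ is constrained
non-negative; a negative unconstrained optimum raises a data-quality
warning.  Bulk $[Q]$ is used as given, so $k_q$ is an *apparent*
constant that reports the exposure of the fluorophore to the aqueous
quencher; no partitioning correction is applied.

### Leakage

Calcein self-quenches at the ~70 mM concentration entrapped in
liposomes ($\tau \approx 0.4$ ns) and recovers its ~4 ns lifetime upon
release.  A two-component reconvolution fit separates the amplitudes,
and leakage is

$$L = \frac{B_F - B_{F0}}{(B_F - B_{F0}) + Q_\mathrm{stat} B_E},$$

with $B_{F0}$ the free-dye baseline of a no-peptide control and
$Q_\mathrm{stat} = 1.2 \pm 0.2$ an empirical static-quenching
correction.  Noise can push $L$ outside $[0, 1]$; values are clamped
with the event flagged, and the $\pm 0.2$ uncertainty of
$Q_\mathrm{stat}$ is propagated into a reported band.

### Partitioning

Steady-state intensities along a lipid titration follow

$$I'(c_L) = \frac{K c_L}{1 + K c_L} I'_{100}
          + \left(1 - \frac{K c_L}{1 + K c_L}\right) I'_{0},$$

fitted globally over wavelengths with one shared partition coefficient
$K$ and free per-wavelength endpoints (wavelengths weighted equally —
the convention is unstated upstream, and equal weighting is the neutral
choice); $K_d = 1/K$.  Confidence comes from support-plane analysis: the
normalized sum of squared residuals NSSR$(K_d)$ = SSR$(K_d)$/SSR(best)
is profiled over 81 log-spaced trial values spanning a factor 10 either
side of the optimum, re-optimizing the endpoints at each trial value,
and the interval is read off at the conventional cutoff NSSR = 1.5.
These profiles are often flat near the optimum, and the resulting wide
intervals are a faithful report of that.

Any observable $p$ measured along the titration decomposes as

$$p^{obs}(c_L) \approx X_p^m\, p^m + (1 - X_p^m)\, p^{aq}, \qquad
  X_p^m = \frac{c_L / K_d}{1 + c_L / K_d},$$

with $K_d$ *fixed* from the steady-state experiment — co-fitting it
with the endpoints is degenerate (a diagnostic co-fit mode exists for
sensitivity checks only).  The bound peptide-to-lipid mole ratio inside
the membrane, $R_b = X_p^m c_P / c_L$, converts sample composition into
the local perturbant density; for 6.6 µM peptide and $K_d$ = 20 µM it
is 0.13 at 30 µM lipid and 0.06 at 90 µM.

## The synthetic-data generator

`scenario_from_table()` builds per-peptide parameter sets.  The
quantities an experiment of this kind actually pins down — $K_d$ and
the $r_\infty$ and $\nu_\infty$ endpoints in water and membrane — are
set to characteristic reference values for the four Trp-substituted
viscosin analogs (L1W, V4W, L5W, L7W).  Everything else is an invented,
physically plausible default, flagged `"invented"` in the attached
provenance map:

* lifetimes $A = (0.45, 0.35, 0.20)$, $\tau = (0.6, 2.0, 4.5)$ ns —
  a typical Trp triple in the 0.3–6 ns range;
* rotational correlation times 0.3 ns (aqueous) and 2.5 ns (membrane);
* relaxation amplitudes/times $C = 1.0\times10^3$ cm$^{-1}$, 0.5 ns
  (aqueous) and $C = 0.5\times10^3$ cm$^{-1}$, 3 ns (membrane);
* spectral band: Gaussian in wavenumber with constant
  $\sigma = 2100$ cm$^{-1}$, i.e. FWHM $\approx 4.9\times10^3$
  cm$^{-1}$, matching typical Trp emission width.  The Gaussian shape
  makes the center-of-gravity and FWHM oracles analytic;
* apparent quenching constant 2.0 ns$^{-1}$M$^{-1}$.

The V4W scenario defaults to a two-fraction relaxation
(`hetero_fraction = 0.5`, `t_relax_slow = 10` ns): both fractions share
$\nu_\infty$ and differ only in rate — the minimal mechanism that
produces the transient FWHM maximum characteristic of water
recruitment.

Counting statistics are Poisson per bin.  Within a polarized set, a
quench titration, or a TRES dataset, all curves share *one* intensity
scale (the brightest peaks at `peak_counts`): the between-curve ratios
are exactly what the global fits estimate, so per-curve rescaling would
destroy the signal.  Steady-state titration noise is multiplicative
Gaussian with a CV (analog detection), not Poisson.  Every generator is
seeded and bit-reproducible.

The default acquisition grid is 0–50 ns in 4096 bins
($dt \approx 0.012$ ns) with a 0.25-ns FWHM Gaussian IRF centered at
2 ns — wide enough to resolve the 0.4-ns calcein component.  The test
suite and worked examples mostly use 512- or 1024-bin (and for calcein
2048-bin) variants of the same span, which resolve everything the
scenarios contain while keeping reconvolution fits fast; these problem
sizes are stated here as the package's choices.

What the generator does *not* emulate: pile-up, dead time,
afterpulsing, dark counts, wavelength-dependent detector sensitivity or
IRF shape, and scattering-light contamination of steady-state spectra
(partition inputs are declared "corrected").  Passing tests therefore
demonstrate the correctness of the estimators under the stated
statistical model, not robustness to every instrumental artifact.

## Numerical choices and degenerate inputs

* **TRES spectra times.**  Spectra are evaluated from fitted decays, so
  they are reliable only over delays the data actually constrain.  The
  package's convention is to assemble spectra up to $\approx 2.5\times$
  the longest fluorescence lifetime (e.g. 0.2–12 ns for the 4.5-ns
  default triple); beyond that the reconstructions are extrapolations
  and the center of gravity drifts systematically.  For fast relaxation
  ($t_\mathrm{relax} \lesssim 2$ ns) log-spaced delays concentrate the
  points where $\nu(t)$ actually moves.
* **Relaxation fit.**  A coarse log grid over $t_\mathrm{relax}$ (with
  $C$, $\nu_\infty$ solved linearly at each trial) seeds a
  Levenberg–Marquardt refinement; a fitted $C < 0$ (rising trend) warns
  and flags the result rather than failing.
* **NSSR intervals.**  Crossings of the cutoff are located by linear
  interpolation between grid points; a side that never crosses is
  reported at the grid bound with an open-interval flag.
* **Leakage** clamps to $[0,1]$ with a logged flag; silent out-of-range
  fractions would corrupt summaries.
* **Degenerate anisotropy** ($B \approx 0$): $\varphi$ is flagged
  unconstrained instead of being reported as meaningful.
* **Flat partition-weighted data**: both endpoints collapse to the
  common mean rather than erroring.
* **Merged lifetimes**: fitted components within 5% relative lifetime
  are merged, because nearly degenerate pairs are a re-parameterization
  of one component.

## Known limitations

* Lifetimes are fitted per wavelength independently; no global linked-
  lifetime analysis across the emission band.
* Single-rotator anisotropy only (one $\varphi$ plus offset); no
  associated anisotropy or wobble-in-cone geometry.
* No static-quenching or transient (Smoluchowski) terms in the
  quenching model; $k_q$ is apparent by construction.
* The three-exponential empirical representation of relaxing
  wavelength-resolved decays is approximate; with realistic band widths
  the residual bias in $t_\mathrm{relax}$ recovery is at the few-percent
  level (the acceptance checks quantify it), but very narrow bands or
  very slow relaxation relative to the lifetimes will stress it.
* Endpoint leakage only; no kinetic leakage time courses or
  graded-versus-all-or-none analysis.

## A worked example

```{r example, eval = FALSE}
library(trpfluor)

report <- run_pipeline(list(
  seed = 42, peptide_id = "V4W", n_bins = 1024L,
  stages = c("decay", "tres", "anisotropy", "partition", "decompose")))

report$summary
```

The report collects every fitted parameter with the stage it came from;
two runs of the same configuration produce identical reports.
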