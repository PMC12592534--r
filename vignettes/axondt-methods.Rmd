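---
title: "Methods: from axonal cross-sections to time-dependent diffusion"
author: "axondt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from axonal cross-sections to time-dependent diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axondt)
```

## The model

Water diffusing along a narrow tube of varying cross-sectional area
$A(x)$ — an axon with beads or varicosities — equilibrates across the
cross-section within about a millisecond. After that, the dynamics is the
one-dimensional Fick–Jacobs equation
$$\partial_t \psi = D_0\,\partial_x\!\left(A(x)\,\partial_x
\frac{\psi}{A(x)}\right),$$
where $D_0$ is the intrinsic axoplasmic diffusivity and $\psi$ the linear
spin density. Two statistics of the *relative* cross-section
$\alpha(x) = A(x)/\bar A$ control the measurable along-axon diffusion
coefficient $D(t) = \langle x^2(t)\rangle / 2t$ at long times:

* the **tortuosity** $\langle 1/\alpha\rangle \ge 1$, via the
  series-resistor (dc conductivity) argument, sets the asymptote
  $D_\infty = D_0 / \langle 1/\alpha\rangle$;
* the **low-wavevector plateau** $\Gamma_0$ of the power spectral density
  $\Gamma_\eta(q)$ of $\eta = \ln\alpha$ (units of length) sets the
  amplitude of the slow approach,
  $$D(t) \simeq D_\infty + \frac{c_D}{\sqrt t},\qquad
  c_D = 2\,\Gamma_0 \sqrt{D_\infty/\pi}.$$

The physical picture is coarse-graining: molecules that have diffused a
length $\ell(t)$ no longer feel structure with wavevectors
$q \gtrsim 1/\ell(t)$, so only the $q \to 0$ content of the disorder —
the plateau $\Gamma_0$ — survives at long times. Short-range disorder
(finite correlation length, finite $\Gamma_0$) gives the $t^{-1/2}$
tail; more general universality classes
$\Gamma_\eta(q) \simeq C|q|^p$ give tails $t^{-\vartheta}$ with dynamical
exponent $\vartheta = (p+1)/2$, implemented in `powerlaw_tails()` along
with the frequency-domain (oscillating-gradient) forms. The generic
dispersion integral
$$\frac{\delta D_{\rm inst}(t)}{D_\infty}
  = \int \frac{dk}{2\pi}\,\Gamma_\eta(k)\,[1 + 2D_\infty k^2 t]\,
    e^{-D_\infty k^2 t}$$
is available for arbitrary spectra through `tail_from_spectrum()`, with
the cumulative curve obtained by exact time-averaging of the kernel.

Skeleton undulations enter only as a multiplicative rescaling: all
arc-length statistics are computed on the "stretched" axon and the
whole of $D(t)$ is divided by the squared sinuosity $\xi^2$, where
$\xi$ is the arc-to-Euclidean length ratio (`sinuosity()`). The inverse
map (`invert_to_geometry()`) takes measured $(D_\infty, c_D)$ back to
$(\langle 1/\alpha\rangle, \Gamma_0)$ and is the exact algebraic inverse
of the forward formulas. When a skeleton is unavailable, $\xi = 1$ is
assumed; per-axon rescaling is applied *before* volume-weighted
averaging when skeletons exist.

## Units and key parameters

All interfaces use micrometers and milliseconds: $D$ in
$\mu m^2/ms$, $c_D$ in $\mu m^2\,ms^{-1/2}$, $\Gamma_0$ in $\mu m$,
wavevectors in $rad/\mu m$. Defaults:

* `D0 = 2` $\mu m^2/ms$ — intrinsic axoplasmic diffusivity, the standard
  in vivo value; overridable everywhere.
* `dl = 0.1` $\mu m$ — arc-length sampling interval; fine enough that
  cross-sections varying on the micrometer (bead) scale are smooth on the
  grid.
* Plateau sweep `beta_grid = 0.92 ... 0.97`: each fraction defines a
  low-$q$ cutoff carrying the complementary share of the spectral
  variance; the spread of $\Gamma_0$ across the sweep is the quoted
  uncertainty. The spread reflects cutoff-choice variability, not a fit
  standard error.
* Fit window `[10, 500]` ms with a lower-bound sweep `t0 = 3 ... 10` ms:
  the central estimate uses the full window, the sweep supplies
  `Dinf_sd` and `cD_sd`, and the predicted-line uncertainty is
  $\sigma_D(t) = \sqrt{\sigma_{D_\infty}^2 + \sigma_{c_D}^2/t}$.

## The synthetic beaded axon

`generate_bead_profile()` drops bead centers along the axis with
independent normal gaps (mean $\bar a$, sd $\sigma_a$, truncated below at
$2\,dl$ so beads cannot coincide) and convolves them with a unit-mass
Gaussian of width $\sigma_1$ scaled by the amplitude $A_1$, on top of the
base area $A_0 = \pi (0.5)^2\ \mu m^2$. Default parameters sit at the
midpoints of the physiological ranges $A_1 \in [0.1, 2.5]\ \mu m^2$,
$\sigma_1 \in [3, 7]\ \mu m$, $\bar a \in [3, 7]\ \mu m$,
$\sigma_a \in [0.8, 1.2]\,\bar a$. Beads are laid on a domain extended by
$5\sigma_1$ on each side and cropped, so edge bins are not bead-starved.

Two caveats are deliberate and documented:

* **Truncation moves the moments.** When $\sigma_a \sim \bar a$ the
  $2\,dl$ truncation rejects a sizable fraction of drawn gaps and the
  achieved mean/sd differ from the nominal ones (a nominal
  $\mathcal N(5, 4^2)$ gap, for instance, realizes a mean near 5.9).
  The generator records the achieved moments in `gap_stats`, and every
  interval-statistics analysis (notably the single-bead plateau model
  $\Gamma_0 = (\sigma_a^2/\bar a)\phi^2$) uses them.
* **Additive areas versus multiplicative theory.** The generator is
  additive in $A$ while the single-bead analysis lives in
  $\eta = \ln\alpha$; the bridge
  $\phi \approx A_1 / (\bar A\,\bar a)$ holds only when the bead
  elevation is small against $A_0$, and the package asserts the
  single-bead identity only in that regime.

What the generator emulates is the *along-axis* area disorder of beaded
axons: short-range, statistically stationary, with a finite plateau. What
it does not emulate: true 3-D cross-section shapes (only areas), skeleton
undulations (profiles are straight unless a skeleton is attached),
correlations between bead amplitude and spacing, and the heavy upper tail
of real radius distributions. Tests passing on these profiles therefore
validate the Fick–Jacobs regime of the theory, not the full 3-D
micro-geometry; the theory's own validity condition — transverse
equilibration, area varying slowly on the radius scale — is inherited,
not re-verified, here.

`generate_spectrum_profile()` complements this with Gaussian random
fields of prescribed spectrum $C|q|^p e^{-(q\,l_c)^2}$ (Fourier-domain
filtering of white noise; areas $\bar A e^\eta$ are positive by
construction), used to exercise the universality classes.

## Simulation engines

`build_generator()` discretizes the Fick–Jacobs operator by finite
volumes on the profile grid: hop rates
$k_{j \to j+1} = D_0 \tilde A_{j+1/2} / (A_j\,dl^2)$ with the interface
area $\tilde A$ the geometric mean of the neighboring site areas (the
natural choice for log-normal-like disorder; a harmonic-mean option
exists). The stationary law is exactly $\pi_j \propto A_j$ with detailed
balance. The domain is the even (mirrored) extension of the profile,
closed into a ring of period $2L$: the seam joins equal areas, so there
is no geometric discontinuity, and displacement is unwrapped through the
winding number so the mean-squared displacement never saturates.

**Walkers** (`simulate_walkers()`, C++ core): discrete-time hops with
probabilities $k\,\delta t$, step duration chosen per profile as
$0.2\,dl^2 / (D_0 \max \tilde A/A)$ (hop probability at most 0.2 per
side; configurations implying a total above 0.5 are rejected with the
admissible value). Initial positions are drawn from $\pi \propto A$ —
the spin density of water — and a test pins this convention by showing
the uniform-in-$x$ alternative measurably inflates short-time $D(t)$ on
strongly beaded profiles. One seeded RNG stream, walker-major, gives
bitwise reproducibility. For profiles whose area varies on the
multi-micrometer bead scale, walker runs may use an integer-coarsened
lattice (`thin_profile()`); at `dl = 0.5` $\mu m$ the lattice tortuosity
agrees with the `dl = 0.1` value to seven digits while the step budget
drops 25-fold.

**Exact oracle** (`solve_msd_exact()`): the master-equation generator on
the same mirrored ring is symmetrized with respect to $\pi$ and
eigendecomposed, and the unwrapped MSD follows in closed form from the
jump self-term plus the drift autocorrelation:
$$\mathrm{MSD}(t) = a_2\,t - 2\sum_m h_m^2\,
\frac{e^{\lambda_m t} - 1 - \lambda_m t}{\lambda_m^2},$$
with $a_2 = dl^2 \sum_j \pi_j (k_j^+ + k_j^-)$,
$v_j = dl\,(k_j^+ - k_j^-)$, $h_m$ the overlap of $\sqrt{\pi}\,v$ with
eigenmode $m$, and $\lambda_m \le 0$. This follows from the second-order
Duhamel expansion of the Bloch-twisted generator and was validated to
six digits against a brute-force master-equation computation on a large
tiled chain (that brute force remains in the test suite as the oracle's
own oracle). The naive alternative — reflecting ends and the folded
correlation $2[\langle x^2\rangle - \langle x(t)x(0)\rangle]$ — carries
a first-order wall bias of order $\sqrt{D t}/L$ (several percent at
usable times) and is deliberately not used. The exact long-time
diffusivity $a_2/2 + \sum_m h_m^2/\lambda_m$ is reported alongside the
curve. The solver enforces a ring-period bound
$\sqrt{2 D_0 t} \le 2L/8$, which marks where the periodic tiling stops
representing an aperiodic axon, and a size cap (8192 sites after
mirroring) set by the dense eigendecomposition.

## Numerical choices

* **Spectral estimation**: plain periodogram with continuum
  normalization $\eta_q = \sum_j \eta_j e^{-iql_j} dl$,
  $\Gamma_\eta = |\eta_q|^2/L$; the mean of $\eta$ is subtracted (only
  fluctuations matter at $q \ne 0$; centering suppresses leakage into
  the lowest bins); no taper, because the plateau lives in the lowest
  bins where tapering costs resolution; optional Welch segment
  averaging for long records. A Parseval identity test pins the
  normalization.
* **Plateau cutoff**: the variance-fraction construction described above
  is a convention (the underlying cutoff rule is not fully determined by
  the problem); on noiseless spectra it is accurate to a fraction of a
  percent, and on single periodograms it is close to unbiased with a
  per-realization spread of roughly 40% when only a handful of low-$q$
  bins exist — hence plateau checks in the tests average over
  realizations or use long records.
* **Dispersion quadrature**: the cumulative-kernel integrand decays only
  as $3/(D_\infty k^2 t)$, so callable spectra are integrated to
  infinity (adaptive quadrature, relative tolerance $10^{-8}$); a finite
  cutoff loses a slowly-converging tail of several percent. Sampled
  spectra use a rectangle rule on their own grid and are accurate when
  the kernel width spans several bins.
* **Degenerate inputs**: profiles need at least 16 uniform samples and
  positive areas; identically-zero spectra yield a zero plateau;
  constant samples make the pooled MAD zero and the effect size is
  refused rather than returned as infinity; maximum-margin projection
  refuses coordinates with zero spread.

## Cohort statistics

Group comparisons avoid hypothesis tests (with thousands of axons,
trivial shifts reach arbitrary significance) in favor of the
nonparametric effect size
$d_{\rm eff} = (\mathrm{med}\,X - \mathrm{med}\,Y)/\mathrm{PMAD}$,
where each sample's MAD is taken about its Hodges–Lehmann pseudo-median
(median of all pairwise averages) and pooled with $n-1$ weights. The
phrase "MAD via the Hodges–Lehmann estimator" admits more than one
reading; MAD-about-the-pseudo-median is adopted, and a plain-median
variant sits behind `mad_hl(center = "median")`.

The two-dimensional separation of groups in the
$(\langle 1/\alpha\rangle, \Gamma_0)$ or $(D_\infty, c_D)$ planes uses a
linear soft-margin support-vector machine (`e1071`, cost 1) on robustly
standardized coordinates (pooled median/MAD per feature), with the larger
group subsampled without replacement to balance classes. Every original
point is then projected onto the hyperplane normal; the scalar score is
oriented so the control group has the lower median, and the group
separation is summarized as $d_{\rm eff}$ of the scores. Kernel,
regularization, and standardization are package choices: a linear
separator is the natural default for a two-parameter plane where only a
direction of group shift is claimed, and the remaining settings follow
the library defaults.

The synthetic cohort module draws per-axon generator parameters uniformly
from group-specific ranges, so only *directions* of injury-like effects
(more prominent beads, shorter spacings raise
$\langle 1/\alpha\rangle$ and $\Gamma_0$, lower $D_\infty$, raise
$c_D$) are meaningful claims; no attempt is made to match any real
population's distributions.

## Problem sizes in the test suite

The suite runs at sizes chosen to make each scientific check sharp but
cheap: tortuosity-identity checks use five random beaded axons of
$L = 300\ \mu m$ at $dl = 0.1\ \mu m$ through the exact oracle;
walker/oracle cross-validation uses five axons of $L = 80\ \mu m$ and
5000 walkers; the tail-amplitude and exponent checks share one
$L = 2000\ \mu m$ axon with $2 \times 10^5$ walkers on the coarsened
lattice; single-bead plateau checks average 20 weak-bead realizations of
$L = 2000\ \mu m$; the end-to-end cohort smoke test runs 3 axons per
group at $L = 100\ \mu m$.

Two caveats about finite-time tail recovery deserve emphasis, because
they bound what cumulative-curve fits can deliver at any sample size:

* **The tail's asymptote is approached slowly.** Exact solutions of the
  lattice Fick--Jacobs dynamics (both the ring oracle and an independent
  open-chain master-equation computation) show the cumulative tail
  amplitude approaching $2\Gamma_0\sqrt{D_\infty/\pi}$ as roughly
  $1 - c/\sqrt{D_\infty t}$ with $c$ of order a few times the disorder
  correlation length. For bead widths of several micrometers, fits of
  $D(t)$ against $1/\sqrt t$ over $t \in [10, 500]$ ms recover only a
  fraction (a quarter to a half) of the asymptotic $c_D$, with large
  realization-to-realization scatter. The asymptotic identity itself is
  verified in the package algebraically and by quadrature of the
  dispersion kernel; its recovery from finite-window cumulative fits is
  not quantitative at these time scales, and tests asserting it at tight
  tolerance are expected to fail.
* **Free-exponent fits on single axons are noise-dominated.** The Monte
  Carlo noise of a cumulative displacement curve is strongly correlated
  in time; at $2\times10^4$--$3\times10^5$ walkers the fitted tail
  exponent has a sampling spread of several tenths, far wider than a
  $\vartheta = 1/2 \pm 0.05$ band, and the slow-approach correction
  above biases even the noise-free exponent upward. The linear
  fixed-exponent fit (`fit_dt()`) is the robust route to $c_D$.

## Known limitations

* The theory addresses intra-axonal water in impermeable tubes; exchange,
  extra-axonal signal, relaxation weighting, and gradient-waveform
  synthesis are out of scope.
* The 1-D Fick–Jacobs engine is the coarse-grained description the
  theory itself derives; it does not emulate 3-D transverse dynamics, so
  deviations reported in the literature for strongly non-adiabatic
  geometries (fast area variation, large $\mathrm{var}\,\alpha$) cannot
  be probed here.
* The exact oracle's dense eigendecomposition limits it to rings of
  about 8000 sites ($L \approx 400\ \mu m$ at $dl = 0.1\ \mu m$).
* Plateau estimation on single short axons is noisy by nature; cohort
  analyses should volume-weight many axons, as the ensemble tools do.
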