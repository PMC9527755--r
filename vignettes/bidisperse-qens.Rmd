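---
title: "Separating two proteins' short-time diffusion from joint QENS spectra"
author: "biqens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating two proteins' short-time diffusion from joint QENS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crowded protein solutions are polydisperse: the interior of a cell mixes
macromolecules of very different hydrodynamic sizes.  The simplest
controllable model of that situation is a binary aqueous mixture of two
well-characterised proteins — serum albumin (BSA, ~66.4 kDa) and
polyclonal immunoglobulin (Ig, ~150 kDa) — at adjustable total volume
fraction $\varphi$ and mixing ratio $y = \varphi_{BSA}/\varphi$.
High-resolution neutron backscattering (IN16B-like: $0.2 \le q \le 1.9$
Å$^{-1}$, $|\hbar\omega| \le 30\,\mu$eV) resolves the quasi-elastic
broadening caused by nanosecond diffusion, and because the incoherent
signal is dominated by the proteins' hydrogens, both label-free species
contribute simultaneously.  biqens implements the analysis that separates
their apparent short-time self-diffusion coefficients from such joint
spectra, and the bidisperse hard-sphere colloid theory they are compared
against.  The original neutron data are not public, so a synthetic-data
module generates spectra with the exact statistical structure the fits
assume; every stage is validated by parameter recovery.

## Spectral model

At each momentum transfer $q$ the measured spectrum is modelled as the
instrument resolution $\mathcal{R}_q$ (a sum of two zero-centred
Gaussians, fitted on vanadium) convolved with protein and solvent terms.
The monodisperse-average model uses one global Lorentzian:

$$S(q,\omega) = \mathcal{R}_q \otimes \Big\{\beta(q)\big[A_0(q)\,
L(\omega;\gamma_{glob}) + (1-A_0(q))\,L(\omega;\gamma_{glob}+\gamma_{int})
\big] + S_{solv}\Big\},$$

with $L(\omega;\gamma) = \gamma/[\pi(\gamma^2+\omega^2)]$ and
$\gamma_{glob} = \hbar D q^2$ (Fickian).  The bidisperse model replaces
the single global line with a cross-section-weighted pair,

$$A_0(q)\big[s_{BSA} L(\gamma_{BSA}) + s_{Ig} L(\gamma_{Ig})\big],
\qquad \gamma_i = \hbar D^{(i)} q^2,\quad D^{(Ig)} < D^{(BSA)},$$

sharing one internal line and one EISF averaged over both proteins: the
energy window does not allow a per-species separation of the internal
dynamics.  The weights follow from molar concentrations and per-molecule
incoherent cross sections, $s_i \propto c_i\,\sigma_i / M_w^i$, and are
fixed by the known sample composition, so the bidisperse fit has exactly
one more free parameter than the average fit.

Key conventions (the underlying experimental papers leave them open; each
is a package design decision):

* **Internal line composition.** The internal Lorentzian is evaluated
  with width $\gamma_{base} + \gamma_{int}$ (global and internal
  processes convolved, widths additive), with $\gamma_{base}$ the broader
  of the global lines.  A `standalone` mode (width $\gamma_{int}$ alone,
  required to exceed the global width) is available as a switch.
* **Solvent scaling.** The D$_2$O line is fitted once on the pure-solvent
  measurement and frozen; its amplitude is scaled by $(1-\varphi)$
  (volume displaced by protein), width unchanged.  Amplitude-only scaling
  is the simplest volume-exclusion rule; it is config-overridable.
* **Units.** $q$ in Å$^{-1}$, $\omega$ in $\mu$eV, $D$ in Å$^2$/ns;
  $\gamma[\mu\mathrm{eV}] = \hbar D q^2$ with
  $\hbar = 0.6582119569\,\mu$eV·ns (CODATA, verified against
  $\hbar = 6.582119569\times10^{-16}$ eV·s).

## Fitting

The objective everywhere is the Poisson deviance ($-2\log L$ up to a
data-only constant), reported as $\chi^2_\nu$ = deviance/dof.  Counts are
integers and peak at $\sim10^4$; a Gaussian least-squares treatment would
be adequate at the peak but wrong in the low-count wings that carry much
of the width information.

The global fits share the diffusion coefficients across all $q$
simultaneously.  Their implementation:

* Shared parameters (one or two $D$, jump-diffusion internal parameters
  $D_{int}, \tau$) are optimized on log scales by Nelder–Mead with a BFGS
  refinement, with seeded multi-starts (relative tolerance $10^{-8}$).
  The ordering $D^{(Ig)} < D^{(BSA)}$ is enforced by fitting
  $(D^{(Ig)}, \Delta>0)$ with $D^{(BSA)} = D^{(Ig)} + \Delta$.
* Per-$q$ nuisance amplitudes $(\beta A_0, \beta(1-A_0))$ are profiled
  out inside the objective by a small identity-link Poisson IRLS with
  nonnegativity (active set).  The monotone non-increasing constraint on
  $A_0(q)$ is enforced by a weighted pool-adjacent-violators projection
  of the profiled $A_0$, followed by a one-amplitude refit at the pooled
  values.  (Parametrizing $A_0$ by cumulative decrements inside the outer
  optimizer is equivalent on data where the constraint binds weakly, and
  roughly twenty times slower.)
* Uncertainties come from a finite-difference Hessian of the profiled
  deviance (cov $= 2H^{-1}$), delta-method-transformed to the $D$ scale;
  intervals default to 68%.  In repeated synthetic experiments these
  intervals cover the generating values at roughly their nominal rate
  (the acceptance suite measures this).
* $\chi^2_\nu$ uses an *effective* dof: only channels with expected
  counts $\ge 0.5$ are counted.  Channels with vanishing expectation
  contribute essentially zero deviance and would deflate the statistic
  far below 1 on sharply peaked spectra.

The q-wise average fits (per-$q$ free $\gamma_{glob}, \gamma_{int},
\beta, A_0$) feed the Fickian check: a weighted straight-line fit of
$\gamma_{glob}$ against $q^2$ through the origin, with per-point
residuals reported.  When the true width at the highest $q$ becomes
comparable to the $\pm30\,\mu$eV window, the per-$q$ estimator turns
bimodal: a fraction of realizations collapses the global width low, the
quasi-elastic wings being absorbed by the internal line.  The *mean*
fitted width at the highest $q$ is then biased low — the window-induced
deviation from $\gamma = Dq^2$ that narrow-window backscattering data
show, reproduced here as a sign property.

## The synthetic world

The generators state one coherent experiment; these values are fixed
once and are not tuned per test:

* Instrument: 16 detectors over $0.2$–$1.9$ Å$^{-1}$, $\pm30\,\mu$eV,
  1024 uniform channels by default (tests use fewer channels/q to stay
  fast — a statement about runtime, not physics).
* Resolution: two Gaussians, $\sigma = 0.4$ and $1.2\,\mu$eV, area ratio
  80/20 — a sharp core on a broad pedestal, widths of order $1\,\mu$eV.
* Sample counting: protein peak channel $\approx 10^4$ expected counts.
  Calibrations are measured generously, as shared runs in a real campaign
  are: vanadium peak $10^5$, D$_2$O line area $2\times10^5$ (an in-window
  pedestal of $\sim$1–2% of the protein peak), empty can 2
  counts/channel (aluminium is a weak scatterer; the can must sit well
  below the solvent level or can-subtraction clipping distorts the
  Poisson statistics).
* Dynamics: $D^{(BSA)} = 4.5$, $D^{(Ig)} = 1.5$ Å$^2$/ns (concentrated
  mixture scale), internal jump diffusion $D_{int} = 100$ Å$^2$/ns,
  $\tau = 0.1$ ns, EISF $p = 0.4$, $\phi_{methyl} = 0.3$, $R = 10$ Å,
  methyl H–H distance $a = 1.715$ Å (fixed).
* Solvent width: $\hbar D_{D_2O} q^2$ with $D_{D_2O} = 187$ Å$^2$/ns.

Expected counts are exact channel integrals of the continuous model
(3-point Gauss–Legendre per channel); the fit bases use a 2-point rule
(relative error $\sim3\times10^{-4}$, far below counting noise).  Counts
are Poisson draws under explicit seeds; no hidden RNG state.

What a green test does *not* establish: the generator emulates counting
statistics, resolution shape, solvent background and the two-protein
line structure, but not detector efficiency maps, multiple scattering,
coherent-scattering contributions, anisotropic Ig shape or patchy
interactions.  Agreement on synthetic data bounds implementation error,
not these physical effects.

## The colloid theory chain

Dilute-limit anchors are Stokes–Einstein,
$D_t^0 = k_BT/6\pi\eta R_H$ and $D_r^0 = k_BT/8\pi\eta R_H^3$, with the
D$_2$O viscosity from a documented Vogel fit
($\eta = 0.017706\,e^{675.4/(T-134.4)}$ mPa·s, matching 1.247/1.095/0.969
mPa·s at 20/25/30 °C).  Normalized short-time diffusivities of a
bidisperse hard-sphere suspension are evaluated from a coefficient table
as polynomials in total volume fraction, with first-order coefficients
composition-weighted over pairwise terms $\alpha(\lambda)$ that depend on
the crowder/tracer size ratio $\lambda$.

**The shipped table is a synthetic stand-in**
(`inst/extdata/hs_pair_coefficients_synthetic.csv`): the published
Stokesian-dynamics polynomials are in a supplement that cannot be
redistributed here, so the package defines the evaluation contract and
ships a table constructed from known limits — the monodisperse virial
coefficients ($\alpha_t(1) = -1.8315$, $\alpha_r(1) = -0.631$, quadratic
terms $+0.88$ and $-0.726$) and the effective-medium (Einstein viscosity)
limit $\alpha \to -2.5$ as $\lambda \to 0$, with $|\alpha|$ decreasing
for larger crowders.  This reproduces, exactly, the dilute, equal-radius
and pure-composition limits, and qualitatively the central ordering: in a
mixture the smaller species diffuses faster, the larger slower, than in
its own monodisperse solution at the same total $\varphi$.  Users with
access to the published coefficients can drop in their own CSV.

The apparent diffusion coefficient collapses rotation and translation
into one number: a uniform rigid sphere contributes
$S(q,\omega) = \sum_l B_l(qR) L(\omega;\Gamma_l)$ with
$\Gamma_l = \hbar(D_tq^2 + l(l+1)D_r)$ and incoherent weights
$B_l(x) = 3(2l+1)\int_0^1 j_l^2(xu)u^2\,du$ (64-point Gauss–Legendre);
$D(q)$ is the half-width of that superposition divided by $\hbar q^2$
(root-finding), and the reported $D$ is the unweighted mean over the
instrument $q$ grid (the per-$q$ values are nearly constant and are
retained).  The series is truncated when the residual weight drops below
$10^{-6}$, with a hard cap of $l = 400$: Ig-sized spheres at
$q = 1.9$ Å$^{-1}$ need $l > qR \approx 100$ terms.

Because the hydrodynamic volume fraction
$\phi_{theo} = \sum_i n_i \frac{4}{3}\pi R_{H,i}^3$ maps onto the
experimental $\varphi = \sum_i c_i\nu_i$ only for pure solutions, mixture
predictions are renormalized:
$D_{theo}(\varphi) = [D^i_{mix}(\phi_{theo}) / D^i_{mono}(\phi_{theo})]
\times D^i_{pure}(\varphi)$, which is exact at $y = 0$ and $1$ by
construction.  The default hydrodynamic radii are 33 Å (BSA) and 45 Å
(Ig) — effective hard-sphere values just above the dry-volume radii (27
and 35 Å), chosen so that $\phi_{theo}$ stays inside the coefficient
table's fitted range over the experimental grid; the renormalization
cancels the absolute radius scale to first order.  Pure-solution curves
$D^i_{pure}(\varphi)$ are required inputs in a real analysis
(experimental parametrizations); the synthetic studies use the
self-consistent curves generated by the theory itself, which makes the
pure-solution limits exact identities.

## Numerical choices

* Voigt profiles are evaluated analytically through the Faddeeva
  function $w(z)$: Weideman's 64-term rational approximation, switching
  to a Laplace continued fraction for $|z| > 8$ (relative error
  $\sim10^{-14}$ against an independent implementation).  An FFT/
  quadrature convolution serves as the test oracle, never the
  implementation.
* Lorentzian widths are optimized in log space; EISF fractions through a
  logit map.  Ties in the bidisperse pair are impossible by the
  $\Delta > 0$ parametrization; coalescence ($\Delta$ within errors of 0)
  is flagged `degenerate` rather than suppressed.
* Degenerate inputs: zero-protein spectra leave $\beta \approx 0$ and are
  flagged; solvent widths far beyond the window are reported as fitted
  (only the in-window level is identifiable, and only it matters
  downstream); negative channels after can subtraction are clipped at
  zero with a logged count.
* The pipeline derives per-stage seeds from one root seed; reruns are
  bit-identical.

## Limitations

* The q-wise width estimator near the window edge is bimodal (see
  above); single-realization widths at the highest $q$ should be read
  with their error bars, as the original analyses do.
* The pair-coefficient table is synthetic (limits-correct, magnitudes
  approximate); quantitative theory-experiment comparisons on real data
  require the published coefficients.
* The per-molecule cross-section calculator reproduces neither shipped
  default constant exactly: a plain all-H Sears-table sum over sequence
  hydrogens gives $\sim3.7\times10^5$ barn for BSA against the
  $4.64\times10^5$ barn default taken from the original analysis, whose
  hydrogen/water convention is not stated.  The calculator therefore
  reports its breakdown and is a cross-check, not the source of the
  defaults — only the *ratio* of the two cross sections enters the
  weights, and the defaults keep that ratio consistent with the original
  analysis.
* HDF5 and TOML interfaces are not provided (no reader available in the
  dependency environment); spectra exchange as long-format CSV and
  configurations as JSON.
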