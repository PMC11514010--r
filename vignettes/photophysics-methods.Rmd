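---
title: "Rate models behind agphot: radiative, intersystem-crossing and internal-conversion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate models behind agphot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agphot)
```

## The problem

Few-atom silver clusters templated by short DNA oligonucleotides
(Ag~N~-DNA) are bright, tunable fluorophores. Their fluorescence
quantum yield is set by a kinetic competition out of the emissive S~1~
state between three parallel first-order channels: radiative decay
(`k_r`), intersystem crossing to a long-lived dark triplet (`k_ISC`),
and internal conversion to the ground state (`k_IC`):

$$\mathrm{QYF} = \frac{k_r}{k_r + k_{ISC} + k_{IC}}, \qquad
  \tau = \frac{1}{k_r + k_{ISC} + k_{IC}}.$$

agphot takes per-emitter excited-state quantities from quantum-chemical
calculations — excitation energies of S~1~ and the low triplets at the
S~0~- and S~1~-optimized geometries, oscillator strengths, the
S~1~/T~1~ spin–orbit coupling matrix element (SOCME), optionally an
S~1~→S~0~ nonadiabatic coupling (NACME) — and turns them into rate
constants, yields and lifetimes. Four reference emitters ship with the
package: two cluster families, each with a guanine-containing strand
and an inosine-substituted variant.

## Radiative rate: Strickler–Berg

`strickler_berg_rate()` implements the vacuum single-transition form

$$k_r = \frac{\tilde\nu^2 f}{1.499\ \mathrm{cm^{-2}\,s}},$$

with $\tilde\nu$ the emission wavenumber and $f$ the oscillator
strength at the S~1~-optimized geometry. This form, without a
refractive-index factor, reproduces the packaged reference rate
constants from their own printed energies and oscillator strengths to
better than 2 % (three of the four to better than 0.5 %), so it is the
convention those reference values were produced with. A solvent
refractive-index factor $n^2$ is available as an explicit option,
default off.

## Intersystem crossing: golden rule with a Marcus–Levich–Jortner FCWD

The S~1~→T~1~ rate is a Fermi golden rule expression

$$k_{ISC} = 4\pi^2 c\, |\langle S_1|H_{SO}|T_1\rangle|^2\,
  \mathrm{FCWD}(\Delta E_{ST}),$$

with the coupling in cm^−1^, $c$ in cm/s and the Franck–Condon
weighted density of states (FCWD) a per-cm^−1^ density, so the product
is s^−1^. The FCWD is modelled in Marcus–Levich–Jortner form — one
effective quantum accepting mode (quantum $\hbar\omega$ =
`mode_energy`, Huang–Rhys factor $S$) plus a classical low-frequency
bath (reorganization energy $\lambda$ = `reorg_low`) at temperature
$T$:

$$\mathrm{FCWD}(\Delta E) = \sum_{n\ge 0} e^{-S}\frac{S^n}{n!}
  \frac{1}{\sqrt{4\pi\lambda k_BT}}
  \exp\!\left[-\frac{(\Delta E - n\hbar\omega - \lambda)^2}
  {4\lambda k_BT}\right].$$

This is a declared surrogate: the exact rate expressions used to
produce the reference `k_ISC` values are not available, so the MLJ
form is used as the standard effective model of this class, and
`calibrate_fcwd()` pins its parameters to observed (SOCME, gap,
k~ISC~) points by least squares in log rate. The reference `k_ISC` and
`k_IC` values are therefore treated as *inputs* carried with
provenance `"supplied"`, not as exact reproduction targets; a
calibrated FCWD reproduces all four reference k~ISC~ values within a
factor of 1.1 and is monotone decreasing across the observed gap
window 0.23–0.39 eV, i.e. it respects the energy-gap law the reference
data show (`k_ISC/SOCME²` falls by a factor of ~6 from 0.23 to
0.39 eV).

Parameter defaults (all configuration, never hard-wired into results):
`mode_energy` 1400 cm^−1^ (a typical ring-stretch accepting quantum),
`huang_rhys` 1, `reorg_low` 800 cm^−1^, `temperature` 298.15 K,
`n_max` 100. $k_B$ is taken as 0.695035 cm^−1^/K. Numerical choices:
the vibronic sum is truncated at `n_max` with a Poisson tail-mass
check (a warning above 10^−12^); each vibronic line is an exact
unit-area Gaussian, so the FCWD normalizes to 1 over the gap axis and
negative (inverted-regime) gaps are handled without clamping. The
calibration optimizer is L-BFGS-B on log-parameters with fixed bounds
and start, followed by a deterministic Nelder–Mead polish — the
surface is flat in log rate near the optimum and the polish settles
the convergence flag without moving a good fit. With two free
parameters and points at only two distinct gaps the problem is
declared underdetermined and refused rather than silently regularized.

## Internal conversion: X–H accepting modes

S~1~→S~0~ internal conversion is modelled in the X–H promoting-mode
approximation: the electronic gap is deposited into a few quanta of
high-frequency, strongly anharmonic X–H stretches (X = C, N, O). For
each mode class $(m_i, \omega_i, \chi_i)$ — count, fundamental,
Morse anharmonicity — the accepting quantum number $n_i$ is the bound
Morse level $E(n) = \omega n - \omega\chi n(n+1)$ closest to the gap
(levels beyond the ladder turnover at $n \approx 1/2\chi$ are past
dissociation and excluded), the Franck–Condon factor is the Poisson
weight $e^{-S_i} S_i^{n_i}/n_i!$ with effective Huang–Rhys
$S_i = n_i\chi_i$ (anharmonicity is what turns on the high overtones;
the factor vanishes in the harmonic limit, as it must), and classes
add as independent channels with a $1/\omega_i$ final-state density:

$$k_{IC} = 4\pi^2 c\,V^2 \sum_i m_i\,
  \frac{e^{-S_i}S_i^{n_i}/n_i!}{\omega_i}, \qquad
  V = \mathrm{NACME}\times 219{,}474.6\ \mathrm{cm^{-1}}.$$

The rate is quadratic in the coupling and non-increasing in the gap
(the energy-gap law; piecewise-constant between ladder steps). It is
evaluated in the zero-temperature limit — X–H quanta of ~3000 cm^−1^
against $k_BT \approx 207$ cm^−1^ make hot-band corrections of order
$e^{-14}$. Because the reference data include `k_IC` but not the NACME
behind it, `compute_rates()` uses the computed-from-NACME path only
when a descriptor carries both a NACME and a mode inventory, and
otherwise falls back to the supplied value — never a silent default,
and always labelled.

The default inventory (20 C–H at 2900 cm^−1^, χ = 0.019; 10 N–H at
3400 cm^−1^, χ = 0.021; 6 O–H at 3600 cm^−1^, χ = 0.024) is a generic
nucleobase-plus-water environment near the chromophore, with textbook
stretch fundamentals and anharmonicities. With a weak coupling of
5×10^−5^ a.u. — the synthetic generator's default, consistent with the
near-complete localization of the S~1~→S~0~ orbitals on the metal
cluster — it puts $k_{IC}$ at a gap of 1.67 eV in the 10^5^–10^7^
s^−1^ window, the scale the reference emitters show.

## Supplied vs computed rates

The reference descriptors carry their externally calculated rate table
as `supplied_rates`. `compute_rates()` and `yield_table()` take
`prefer = "supplied"` (default) or `"computed"`: the first reproduces
the reference table channel-for-channel (the printed quantum yields 8,
16, 22, 34 % round-trip exactly under half-up integer rounding); the
second recomputes everything computable from the descriptor's own
energies and couplings, which for the radiative channel lands within
2 % of the supplied values but for ISC depends on the FCWD calibration.
Every entry is provenance-labelled so the two never mix silently. One
consequence of working from printed, 3-digit-rounded inputs: the
computed Strickler–Berg rate for the Ag16 inosine variant (1.52×10^8^
s^−1^ from E = 1.66 eV, f = 1.27) sits 1.4 % under its supplied value,
enough to move its rounded yield from 16 % to 15 % — which is why the
supplied path is the default for table reproduction.

## Spectra

`broaden()` renders stick spectra with unit-area Gaussian (default,
FWHM 0.15 eV) or Lorentzian shapes on an energy grid (default 2000
points spanning the lines ± 5 FWHM); Gaussian broadening conserves the
summed stick weight to the quadrature error, and the Lorentzian's
grid-truncation loss is measurable via `spectrum_area()`. Broadening
is always performed on the energy axis; `convert_axis()` relabels to
nm or cm^−1^ pointwise without Jacobian reweighting, the common
TD-DFT plotting convention (the width/shape used for any particular
published figure is generally unstated, so no quantitative match to a
figure is attempted).

## Structure toolkit

`superpose()` is the Kabsch algorithm: SVD of the coordinate
covariance with the determinant sign fix, so the returned rotation is
always proper (det = +1) even for reflected or near-degenerate point
sets (the latter are flagged). Atom correspondence is by list
order/selection only. Each selection in `rmsd_report()` is fitted
independently, which is what makes a tight metal-core RMSD coexist
with a large all-atom RMSD when the ligands reorganize. RMSDs are
unweighted (a mass-weighting flag is deliberately reserved rather than
guessed). Distance cutoffs in `bond_table()` and `contact_report()`
are closed (≤), and contact distances are reported to 0.01 Å.

## Synthetic data

The generators exist so every code path is testable without external
data, and their defaults are fixed to the reference regime: S~1~
energies 1.6–2.3 eV, S~1~–T~1~ gaps 0.2–0.4 eV, SOCMEs 2–4.1 cm^−1^,
oscillator strengths 0.8–1.4. Generated k~ISC~ values are manufactured
from a known FCWD truth so calibration can be validated in closed
loop; toy structure pairs apply a known random rigid transform plus
per-subset Gaussian jitter so subset superposition has a constructed
ground truth. What the generators deliberately do *not* emulate:
DFT-level errors in energies or couplings, realistic DNA geometry, or
correlated noise between emitters — so passing closed-loop tests
demonstrates the correctness of the inference machinery, not the
accuracy of any electronic-structure input.

## Problem sizes and determinism

All shipped analyses are desk-scale: four reference emitters, vibronic
sums of ≤ 500 terms, calibrations over ≤ 20 points, toy structures of
≤ 36 atoms. Every stochastic artifact flows from one explicit integer
seed through a local RNG stream that does not disturb the caller's
random state; the same seed yields byte-identical descriptor and
structure files.

## Known limitations

The MLJ-FCWD and X–H models are effective surrogates with calibrated
parameters, not reproductions of any particular program's rate
expressions; absolute k~ISC~/k~IC~ from first principles are out of
scope, as are Herzberg–Teller corrections, reverse ISC, triplet decay
kinetics, temperature-dependent radiative rates, and any
electronic-structure computation itself. Experimental reference values
stored in descriptors are never used in computation.

## A worked example

```{r example}
fx <- load_table1_fixtures()
tab <- yield_table(fx)
tab[, c("name", "k_r", "k_isc", "k_ic", "qyf_percent", "lifetime")]
```

```{r calibrate}
pts <- tibble::tibble(
  socme = tab$socme,
  gap = tab$gap_s1_t1,
  k_isc = tab$k_isc
)
fit <- calibrate_fcwd(pts)
glance(fit)
```
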