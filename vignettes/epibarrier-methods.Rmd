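---
title: "Models and numerical choices in epibarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in epibarrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibarrier)
```

This vignette is the package's own account of the statistics and physics it
implements: what each model assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and where a genuinely open design choice was settled one way
rather than another.

## 1. Calling transcriptionally active genes

### The model

Bulk RNA-seq reports a nonzero read count for many genes that a cell is not
meaningfully transcribing, because the assay is very sensitive. Across all
genes, the density of log2-transformed expression (TPM or FPKM) is
bimodal: a low mode of inactive genes (background, leaky transcription)
and a high mode of active genes, each well approximated by a Gaussian in
log2 space. The package models the *binned* density — gene counts per
0.1 log2 unit, values rounded half away from zero to one decimal — as

$$f(x) = A_a e^{-(x-\mu_a)^2/2\sigma_a^2} + A_i e^{-(x-\mu_i)^2/2\sigma_i^2},$$

fitted by unweighted nonlinear least squares. The amplitudes $A_a, A_i$
are curve heights in gene-count units, not normalised mixture weights: the
decision rule is stated on gene *rates* (how many active vs inactive genes
sit at a given expression level), so the natural scale is the density's
own y axis. Genes with exactly zero expression are excluded before the log
transform — no pseudocount is added, because a pseudocount would inject a
spurious spike into the inactive mode — and are reported as their own
`"zero"` class.

### The cutoff

`activity_threshold()` places the cutoff $x^*$ where the active curve is
$r$ times the inactive curve ($r = 5$ by default). Taking logs turns
$A_a\phi_a(x) = r A_i \phi_i(x)$ into a quadratic in $x$ (linear when
$\sigma_a = \sigma_i$), solved in closed form and cross-checked in the
test suite against a brute-force grid search at $10^{-4}$ resolution.

Root selection deserves care. When $\sigma_a \ge \sigma_i$ the log-ratio
parabola opens upward, the larger root is returned, and the ratio stays
$\ge r$ for every higher expression value — the cutoff is a clean lower
bound. When the fitted active component is *narrower* than the inactive
one the ratio falls back below $r$ at some higher $x$. If that fall-back
happens within the active component's support, no usable cutoff exists and
the function raises an error. But on sampled data with genuinely
equal-width components, the fitted $\sigma_a$ lands a hair below
$\sigma_i$ about half the time, and the fall-back then sits at absurdly
high expression (hundreds of log2 units) where both curves are numerically
zero. The rule is therefore: accept the lower crossing when the fall-back
lies beyond $\mu_a + 6\sigma_a$; error otherwise. Without this guard the
caller would fail on half of all realistic inputs for a purely numerical
reason.

Classification is strict: a gene exactly at the cutoff is inactive. The
combined call across the TPM and FPKM channels is `"active"` only when
both per-metric calls are active — the conservative conjunction — with an
`"either"` mode available; the two channels rank genes almost identically,
so the choice rarely matters, but the conjunction is the defensible
default when the two analyses are presented as independent confirmations.

### Numerical choices

* The fit uses `minpack.lm::nls.lm` on the residual function directly,
  not an `nls`-style model object, because the model-object route rejects
  zero-residual problems ("singular gradient") and a noise-free density —
  the natural correctness probe — is exactly such a problem.
* Initialisation is deterministic: the two highest-count local-maximum
  bins separated by at least 1 log2 unit seed the means, their counts seed
  the amplitudes, both sigmas start at 1.0 log2 units (the typical width
  of either mode). No random restarts, so a given density always yields
  the same fit.
* Bounds: amplitudes $\ge 0$, sigmas $\ge 10^{-3}$. Components are
  labelled by fitted mean (larger = active), never by parameter order.
* Rounding to one decimal is half-away-from-zero, applied to the log2
  value; bin assignment is insensitive to the tie-break except for values
  landing exactly on a .05 boundary.
* The fit requires at least 6 non-empty bins — two three-parameter
  components need at least that many constraints.

## 2. Dilution potentials and the GHK inversion

For a monovalent NaCl gradient, the Goldman-Hodgkin-Katz voltage equation
reduces to

$$V = \frac{RT}{F}\,\ln\frac{\beta\,[\mathrm{Na}]_{ap} + [\mathrm{Cl}]_{bl}}
                             {\beta\,[\mathrm{Na}]_{bl} + [\mathrm{Cl}]_{ap}},
\qquad \beta = P_{Na}/P_{Cl}.$$

The sign convention is fixed operationally: with the apical side diluted
(default bath 75 mM apical / 150 mM basolateral NaCl, 310.15 K), a
cation-selective epithelium gives a negative potential and an
anion-selective one a positive potential; $\beta = 1$ gives exactly 0 mV.
$V$ is strictly decreasing in $\beta$ and bounded by the two Nernst
potentials $\pm(RT/F)\ln 2 \approx \pm 18.5$ mV, approached as $\beta \to
\infty$ or $0$. Because the exponentiated equation is linear in $\beta$,
the inversion is closed-form; forward-then-inverse round-trips to
$10^{-9}$ relative accuracy over $\beta \in [0.05, 20]$, and potentials at
or beyond a Nernst limit raise an out-of-range error rather than returning
a negative ratio.

Assumptions: concentrations, not thermodynamic activities, enter the
equation (no activity-coefficient correction — at 75–150 mM the
correction would shift ratios by a few percent, and applying it only makes
sense if the original measurement protocol did); the mannitol used to
balance osmolarity is electroneutral and ignored; only the Na/Cl bi-ionic
case is handled.

The selectivity classification compares $\beta$ with the neutral-pore
baseline — the free-solution mobility ratio of the two ions,
$50.11/75.23 = 0.666$: a pore with no charge preference passes ions in
proportion to their diffusive mobilities. Above the baseline is
cation-selective, below is anion-selective, equality within $10^{-6}$
relative is neutral. The baseline is conventionally quoted as 0.66; note
that is a truncation of 0.666, not a half-up rounding.

`conductance_from_iv()` applies Ohm's law to a single voltage/current
pair; multi-point I–V regression is out of scope. Replicate summaries
report mean ± SD, with SD reported as `NA` (not 0) for single-record
groups to avoid spurious precision.

## 3. TER and tracer flux

TER subtracts the mean bare-filter resistance and multiplies by the growth
area (default 1.12 cm², the nominal area of a 12-mm insert); a reading
below the blank mean yields a negative TER that is flagged, not clamped —
it means a damaged monolayer, and hiding it would be worse. Papp uses the
linear sink-regime formula $P_{app} = (dQ/dt)/(A C_o)$ with defaults
matching a standard protocol (250 µl of 200 µM tracer apically, 1 ml
basal, 2 h, 37 °C); no back-flux or donor-depletion correction is applied,
which is adequate while the transported fraction stays small (a few
percent). Fluorescence converts to amount through a single linear
calibration factor (intensity per mol cm⁻³ times the basal volume);
readings below the blank clamp to zero with a warning so noise at the
detection limit cannot produce negative permeabilities. TER and
conductance are mutually consistent: `TER = 1000 / G_t` for the same
epithelium.

## 4. What the synthetic generators emulate

Each generator is the exact inverse of its analysis stage, under one
seeded RNG that is restored afterwards, so identical configurations give
byte-identical outputs and zero-noise settings round-trip the true
parameters to solver tolerance.

* `simulate_expression_table()` draws a zero-expression fraction, then
  2^x with x from the active or inactive Gaussian; FPKM is a scaled copy
  of TPM with small lognormal jitter so the two channels can agree or
  disagree controllably. Defaults — 20,000 genes, 20 % zeros, active mode
  at log2 = 5 (σ 1.5), inactive at 0 (σ 1.0), 55 % of non-zero genes
  active — give the clean bimodal density a good bulk RNA-seq experiment
  shows. What it does **not** emulate: count noise at low expression,
  heavy right tails, library-size effects, or any correlation structure
  between genes; a passing recovery test shows the caller works when the
  two-Gaussian model holds, not that real densities obey that model.
* `simulate_ussing_runs()` adds the blank-filter offset and additive
  Gaussian noise (the simplest model consistent with replicate SDs) to
  the forward GHK potential, and produces Ohm's-law-consistent V/I pairs
  for a 0.0707 cm² chamber window (3-mm circular aperture). Electrode
  drift, junction potentials, and solution-resistance series errors are
  not modelled.
* `simulate_plate_assay()` draws blank and cell resistances
  (cell = blank mean + TER/area + noise) and basal-chamber intensities
  (blank + gain × concentration + noise). Tracer binding, monolayer edge
  leak, and nonlinear reader response are not modelled.

## 5. Pipeline and problem sizes

`run_pipeline()` validates its whole configuration before writing
anything, runs the selected stages, and writes a JSON manifest carrying
the parameters, seed, package version, and MD5 checksum of every output —
but no timestamp, so a rerun of the same configuration is byte-identical.

The test suite exercises the mixture recovery at 20,000 genes, the GHK
round-trip at 100 log-spaced ratios, and Monte-Carlo histogram checks at
50,000 draws; these sizes put sampling error comfortably below the
asserted tolerances (e.g. the fitted means land within 0.1 log2 units,
against a standard error of ~0.01) while keeping the whole suite in a few
seconds.

## Known limitations

* The activity caller assumes exactly two Gaussian modes; densities with a
  shoulder of moderately expressed genes or a non-Gaussian inactive mode
  will fit poorly and the residual norm should be inspected (or the fit
  plotted with `plot_density_fit()`).
* The GHK inversion yields only the Na/Cl permeability *ratio*; absolute
  permeabilities would require conductance partitioning that is out of
  scope.
* Papp is single-timepoint; kinetic (multi-timepoint) flux fitting is not
  implemented.
* An EM fit on raw (unbinned) log2 values would be a natural alternative
  to least squares on the histogram; the histogram route was chosen
  because the decision rule is stated on the density's count scale, and
  binning at 0.1 log2 units loses essentially nothing at 20,000 genes.
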