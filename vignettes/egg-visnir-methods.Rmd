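---
title: "Methods: egg composition statistics and VIS-NIR calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egg composition statistics and VIS-NIR calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

eggnir models a two-part workflow common in food-composition spectroscopy:
breed-level characterization of egg albumen and yolk composition, and
development of VIS-NIR (400–2500 nm) calibration equations that predict
composition traits from log(1/reflectance) spectra. This vignette explains
the statistical models, the synthetic-data generator, the numerical
conventions, and the design choices that were genuinely open.

## The study system

Eight local Veneto chicken breeds are represented: four white-eggshell
breeds (Padovana Camosciata PA-C, Padovana Dorata PA-G, Polverara Bianca
PO-W, Polverara Nera PO-B) and four tinted-eggshell breeds (Pepoi PP,
Ermellinata di Rovigo ER, Robusta Maculata RM, Robusta Lionata RL). The
sampling design collects 50 eggs per breed and pools them two at a time,
giving 25 pooled laboratory samples per breed and 200 samples overall from
400 eggs. The pooled sample is the unit of analysis throughout.

`default_profiles()` carries each breed's mean ± SD per trait at the
pooled-sample level: albumen moisture, protein and ash (wet and dry basis)
and yolk moisture, protein, lipid, ash and cholesterol. Two quirks of the
source summaries are kept verbatim rather than silently corrected and are
flagged in the documentation: the RL albumen protein (% DM) value of
88.91 ± 0.37 is out of line with every other breed (~84–85) and with its
own ash column, and one yolk protein SD is read as 0.77 from a garbled
decimal.

## The synthetic-data generator

### Composition

For each breed, `generate_composition()` draws the *solute* wet-basis
traits (protein, ash, and for yolk lipid and cholesterol) as independent
normals at the egg level. The egg-level SD is the profile SD times
√pool_size, so pooled samples — means of `pool_size` eggs — reproduce the
profile SDs, which describe pooled samples. Pooling is also what the
variance-reduction property tests check: pooled SD ≈ egg SD/√pool_size.

Moisture is not drawn. It is derived by mass closure,

  moisture = 100 − (protein + ash [+ lipid]) − r_b,

where `r_b` is the breed's constant inert remainder (carbohydrates, minor
solids) implied by the profile means, and cholesterol is excluded from the
closure because it is a subfraction of the lipid mass. This was a genuinely
open design point. The alternative — drawing every wet-basis trait
independently and deriving dry-basis values — looks simpler but makes the
dry-basis traits the ratio of two *independent* noisy quantities: their
dispersion comes out around six times larger than the reference profiles
report, which is physically wrong (in real eggs moisture is strongly
anti-correlated with the solutes) and distorts every downstream calibration
experiment. Mass closure keeps moisture + dry matter = 100 exactly,
reproduces the profile moisture means exactly, and gives moisture and
dry-basis SDs of the right order without inventing any correlation
parameters. Dry-basis traits are then derived, not drawn:
`x_dm = 100 · x_wb / dry_matter_wb`.

Negative egg-level draws (possible for small-mean traits like ash) are
clipped at a small positive floor with a warning — physical
non-negativity beats distributional purity at 4+ SDs from the mean.

### Spectra

`generate_spectra()` builds one spectrum per pooled sample as a
Beer–Lambert mixture on the shared wavelength grid:

  s_i = Σ_t c_it · B_t + w(matrix) · moisture_i/100 · B_water + baseline,

followed by multiplication with (1 + m_i), an additive offset a_i, a random
quadratic baseline, and i.i.d. channel noise. Band positions follow
canonical NIR assignments — water O–H at ~1450/1940 nm, protein amide
bands at ~1510 and 2050–2180 nm, lipid C–H at ~1730/1765 and 2310/2350 nm,
and a weak sterol band near 1700 nm. All centers, widths and heights are
configuration, not constants (`component_library()`), since only the
qualitative structure matters. Ash is deliberately given a zero curve:
inorganic material does not absorb in the VIS-NIR, so ash models are
expected to fail — a feature of the emulation, not a bug. Cholesterol
enters at its realistic mass fraction (~1.3% wet basis), so its
predictability ceiling emerges naturally from its low concentration.

Two mechanisms reproduce the fresh versus freeze-dried matrix effect:

* the **water weight** `w(fresh) = 1` versus `w(freeze-dried) = 0.05`
  makes the water band dominate fresh spectra, and
* a **water jitter** (SD 0.01 mass fraction, scaled by the water weight)
  perturbs the water term per sample, emulating the instability of
  moisture in fresh samples exposed to ambient air during the scan
  (evaporation and surface drying). Without it, the closure-induced
  anti-correlation between moisture and solutes would make fresh samples
  *more* predictable than freeze-dried ones, the opposite of what is
  observed on real instruments.

Default noise magnitudes (multiplicative slope SD 0.03, additive offset SD
0.02 AU, quadratic amplitude SD 0.01 AU, channel noise SD 0.002 AU) are
typical of bench-top reflectance work: scatter effects one to two orders
of magnitude above detector noise.

What the generator does **not** emulate: instrument line-shape and
detector changeover artifacts, temperature drift, wavelength
miscalibration, non-linear detector response, and any correlation between
traits beyond the mass closure. Passing tests therefore show that the
*pipeline machinery* behaves correctly under a faithful statistical
emulation; they do not validate predictive performance on any real
instrument's data.

## Pretreatment conventions

Scatter corrections: `NONE`, `SNV` (per-spectrum standardization across
wavelengths), `SNV_D` (SNV then polynomial detrend) and `MSC` (affine
regression on a reference spectrum, then inversion). Derivative math
treatments use the 4-digit "d,g,s1,s2" notation: derivative order, gap in
data points, and two boxcar smoothing window sizes.

Fixed conventions, each of which had to be pinned down for bit-exact
tests:

* **SNV divisor**: the n−1 (sample) SD, matching R's `sd()`; a 3-point
  spectrum [1, 2, 3] maps to [−1, 0, 1].
* **Detrend order**: 2 (quadratic), configurable via
  `pretreatment_spec(detrend_order =)`; vendor software does not document
  its choice.
* **Smoothing**: plain moving average (boxcar), per the "number of data
  points in the smoothing" phrasing of the 4-digit convention; even window
  sizes are normalized up to the next odd size so the window is centered.
* **Order of operations**: scatter correction before derivatives, because
  SNV and MSC are defined on raw absorbance shapes. The serialized spec
  (`"SNV_D/1,4,5,1"`) records exactly what was applied.
* **Edge handling**: derivatives and smoothing shrink the active region
  instead of padding; no imputation artifacts enter the derivative.
* **MSC reference**: the mean spectrum of the *calibration* subset, frozen
  and reused for held-out or future samples. Recomputing the reference per
  fold gives different corrections and is demonstrably not equivalent —
  a property test shows the divergence.

## PLS regression

`pls_fit()` implements single-response PLS by iterative deflation on
centered data, with no autoscaling of the spectral channels (scatter
corrections already serve that role) and y in original units. The
`"modified"` variant implements the Shenk–Westerhaus reweighting used by
NIRS calibration software: after each term, the spectral residuals at each
wavelength are divided by their SD before the next term is extracted,
down-weighting already-explained wavelengths. The per-term scaling vectors
are stored and replayed at prediction time, and the coefficients are
accumulated back into the original spectral space for every cumulative
term count, so term-count selection needs no refitting.

The exact internals of commercial modified-PLS implementations are
proprietary; numerical equivalence with any vendor's output is explicitly
out of reach. The standard variant doubles as a cross-check: at full rank
its training predictions coincide with ordinary least squares (tested
against the normal equations at 1e-8 relative), its training SEC is
non-increasing in the number of terms, and successive scores are mutually
orthogonal. Convergence and rank checks use a relative tolerance of 1e-10.

## Calibration engine

Cross-validation uses 5 random balanced segments. Random (not contiguous)
segments matter here: samples are blocked by breed in the data file, and
contiguous folds would confound breed with fold. For each fold, the MSC
reference and the PLS centering are computed on the training portion only.

Statistics follow the NIRS reporting tradition: SEC and SECV are root mean
squared residuals (divisor n by default, with an n−1 switch), R² is
1 − SSE/SST (not a squared correlation — it can be negative in
cross-validation, like the vendor "1-VR" statistic), and RPDCV = SD/SECV.
The RPD identity is audited on every emitted result row.

Outlier elimination follows the 2.5-SD rule: per pass, cross-validated
residuals are standardized by their SD and samples beyond the threshold
are dropped; by default at most 2 passes (vendor behavior is undocumented;
both the threshold and the pass count are configuration). One practical
subtlety, found while validating the machinery and worth knowing: a gross
outlier sits in most training folds, so a high-complexity model bends
toward it and inflates the clean samples' CV residuals. Screening is
therefore most reliable at conservative term counts (2–3 terms); the
package's screening experiments use 3.

The pretreatment grid search evaluates every scatter × math combination
(4 × 3 = 12 cells by default), selects the term count in 1..10 that
minimizes SECV (ties break toward fewer terms — the selection rule is not
part of the published convention, so parsimony is the defensible default),
and ranks cells by SECV.

## Statistics module

Traits are screened with Shapiro–Wilk plus normal-quantile data for visual
inspection. Breed effects use one-way ANOVA with Tukey HSD on all pairs
(Tukey–Kramer for unbalanced groups) and a compact letter display computed
by the insert-and-absorb algorithm; the letters are derived from the
package's own pairwise matrix, with a round-trip test asserting that two
breeds share a letter exactly when their Tukey p ≥ 0.05. Published letter
assignments of this kind often contain internal inconsistencies, so no
attempt is made to reproduce any particular printed letter set verbatim.
Group means are arithmetic means, which equal least-squares means in a
one-way layout. The white-versus-tinted contrast is a two-level one-way
ANOVA (equivalently a pooled two-sample comparison; F = t²) with
0.05/0.01/0.001 star annotations.

A power note: with 25 pooled samples per breed and eight groups, the
PP–PO-B albumen protein comparison sits almost exactly at the boundary of
99% detection — a direct simulation of the Tukey procedure under the
profile parameters gives a detection rate of about 0.978, whereas a naive
two-sample power computation (ignoring the studentized-range multiplicity
penalty) gives 0.996. The test suite states the stronger expectation and
the corresponding check documents this gap when it fails.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at the full study
design (200 pooled samples) but on reduced wavelength grids — typically
1100–2500 nm at 2 nm or 1300–2500 nm at 4 nm instead of the full 4201
channels — which preserves every band of the component library while
keeping matrix sizes modest. Simulation-based checks use 20–50 seeds for
calibration properties and 200–500 replicates for ANOVA power; these sizes
put Monte-Carlo error well below the margins being asserted.

## Known limitations

* Vendor-numeric equivalence (modified-PLS internals, exact outlier
  iteration, term-choice rule) is out of scope by design.
* The generator's independence assumptions (solutes independent within a
  breed) are a simplification; real trait covariances are not published at
  the sample level.
* No external test-set validation: the engine mirrors the
  cross-validation-only protocol it models.
* JCAMP-DX support covers the plain AFFN `(X++(Y..Y))` form only.
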