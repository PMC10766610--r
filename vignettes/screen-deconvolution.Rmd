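---
title: "Deconvolving arrayed degradation-rescue screens and scoring degrader pharmacology"
author: "tpdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving arrayed degradation-rescue screens and scoring degrader pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpdscreen)
```

## The experiment this package models

Targeted protein degradation (TPD) campaigns routinely ask two questions this
package answers computationally. First, *which cellular genes does a degrader
depend on?* An arrayed CRISPR knock-out rescue screen answers it: cells
carrying a luminescent HiBiT knock-in on the target protein and a
constitutive Firefly luciferase are arrayed in 384-well plates, one pooled
guide-RNA well per gene, edited, treated with the degrader, and read out on
both luciferases. Genes whose loss *rescues* the target (HiBiT signal
restored toward untreated levels) are candidate pathway components — the E3
substrate receptor itself, its cullin-RING scaffold, the NEDD8 machinery,
proteasome subunits. Second, *how good is a degrader?* Dose-response metrics
(DC50, maximal degradation, GI50, the viability/degradation window) and
ternary-complex biophysics (hook-effect isotherms, off-rates, cooperativity)
quantify that.

Every stage is driven by a synthetic-data generator with known ground truth,
so the whole pipeline is testable without any instrument data.

## Screen deconvolution

### QC gate

The Firefly luciferase tracks per-well cell number. Each assay plate carries
media-only and non-infected, puromycin-killed control wells whose median
Firefly signal defines the plate background. A well passes QC when

$$\log_{10}\!\frac{F_\text{well}}{\tilde F_\text{ctrl}} > \log_{10}(1.25),$$

i.e. at least 25% more Firefly signal than background. Reading the threshold
as a *ratio to plate controls* makes it scale-free: a plate-wide gain change
moves numerator and reference together. Wells that fail (failed infection,
puromycin kill, dispensing voids) are excluded from every downstream fit and
ranking — a gene whose pooled guide well never infected is reported as
QC-excluded, never scored zero.

### Plate normalization

Within a plate, HiBiT and Firefly are coupled through cell number, but not
proportionally: luminescence saturation and lysis efficiency bend the
relation. Per assay plate we fit a third-order polynomial of HiBiT on
Firefly over the QC-passing library wells by ordinary least squares, with
one robust re-fit pass that drops points whose absolute residual exceeds 3
scaled MADs. Rescue wells are rare (a few percent of a plate), so the
trimmed fit tracks the null (degraded) relation and strong rescuers stand
out instead of bending the baseline. A numerical guard keeps the trim from
engaging on numerically exact fits, where residuals are machine noise.

The normalized activity is a ratio, `rel_change = observed / predicted`
HiBiT. On a noise-free screen whose generative HiBiT–Firefly coupling is
itself cubic, the polynomial reproduces the coupling exactly and
`rel_change` is constant across non-rescued wells to better than six
significant digits — the exactness property the acceptance suite checks.
Because the polynomial is fitted to the *treated* plate, non-rescued wells
sit at `rel_change` ≈ 1 and a full rescue sits at ≈ 1/(1 − d) for a
degradation factor d (≈ 10 for d = 0.9); rescue effects are read as
departures above the plate baseline.

Robust z-scores, `z = (x − median) / (1.4826·MAD)`, are computed per assay
plate by default (`z_scope = "plate"`), matching the plate-basis
normalization; a screen-wide option exists. When the MAD degenerates to
zero the scale falls back to the standard deviation, and to all-zero scores
if that too vanishes.

### The gene-level RSA statistic

All QC-passing library wells are ranked by robust z (rank 1 = strongest
rescue). A gene with \(N\) wells at ranks \(r_1 < \dots < r_N\) among \(M\)
ranked wells scores

$$P = \min_{j \in 1..N} \Pr\!\big[X \ge j\big], \qquad
X \sim \mathrm{Hypergeom}(M, N, r_j),$$

the minimum over "head subsets" of the probability that a random placement
of the gene's wells puts at least \(j\) of them in the top \(r_j\). The
statistic rewards *concordant* high ranks across a gene's replicate wells: a
single lucky well caps out near \(N r_1 / M\), while three concordant wells
at the very top reach \(1/\binom{M}{3}\). Tail probabilities are computed in
log space (`phyper(..., log.p = TRUE)`), since \(M \approx 2800\) wells puts
direct factorials far beyond double range. Tied z-scores are handled
conservatively: every well in a tied block takes the block's largest rank,
so a constant activity vector scores \(P = 1\) for every gene.

No multiplicity correction is applied inside the statistic. Calibration is
empirical, as below.

### Randomized-activity null and empirical FDR

Robust z values are shuffled among QC-passing library wells — within each
assay plate by default, preserving any plate structure normalization did not
remove — and all genes re-scored; repeating this `n_perm` times gives the
null distribution of gene scores. Hits are genes with
\(\log_{10} P < -3\) (annotated "strong" below −4), and the plug-in
empirical FDR is

$$\widehat{\mathrm{FDR}} =
\frac{\text{mean}_\text{perm}\,\#\{\text{null } \log_{10}P < t\}}
     {\max(1, \#\{\text{observed } \log_{10}P < t\})}.$$

On null screens this estimator is calibrated: observed and permuted score
distributions are exchangeable by construction, and the test suite verifies
the exceedance rates agree within Monte-Carlo error. In the presence of
strong planted hits the estimator is deliberately *conservative*: the
permutation redistributes the hits' extreme z values across all genes, so
chance collisions of two redistributed hit wells on one null gene inflate
the null exceedance relative to the actual false-positive process. The
realized false-discovery proportion in planted simulations therefore sits
well below the estimate. This is a structural property of the plug-in
construction (any practitioner shuffling all well activities inherits it),
not a defect of the implementation; the estimate errs on the safe side,
never understating the realized error.

## Degrader pharmacology

Dose-response curves are fitted with the four-parameter logistic
\(y = b + (t - b)/(1 + (x/\mathrm{EC}_{50})^{h})\) by Levenberg-Marquardt
(`minpack.lm::nls.lm`), with the midpoint parameterized on the log scale so
it stays positive, and plateau/midpoint starting values taken from the dose
extremes and the half-response crossing. Plain (unweighted) least squares is
used; no weighting scheme is assumed. Derived metrics follow the TPD
conventions:

* `rel_dc50` — the curve midpoint (EC50) of the DMSO-normalized descending
  degradation curve;
* `abs_dc50` — the dose where the *fitted* curve crosses 0.5, solved
  analytically and reported absent when 0.5 lies outside the fitted
  plateaus (determinism, no raw-point interpolation);
* `dmax = 1 − bottom` — maximal *fitted* degradation (the fitted plateau,
  not the best observed dose, which would be noise-biased upward);
* GI50 — the dose where the fitted DMSO-normalized viable-gate fraction
  crosses 0.5;
* `vd_score = GI50 / DC50` — the viability window; above 1 means
  degradation precedes toxicity. When either midpoint is absent the top
  assessed dose substitutes and a fallback flag is set, so inert compounds
  produce defined, flagged scores rather than missing values.

Flow-cytometry degradation is ratiometric:
\(1 - \frac{(\mathrm{GFP}-\mathrm{BG})/(\mathrm{mCh}-\mathrm{BG})}{\text{DMSO ratio}}\),
with technical-replicate medians taken before ratios. Doses whose relative
viable-gate fraction falls below 25% of the DMSO fraction are excluded from
degradation fitting — too few viable cells remain for a reliable ratio.

For a recovery study at 5% measurement CV, 8 doses in triplicate, and unit
Hill slope, the midpoint's sampling error is about 6% (the test suite
asserts a median relative error under 10% and 95% of fits within 25%); an
efficient maximum-likelihood fit does no better at these conditions, so
tighter recovery requires steeper slopes or more replication, not a
different fitter.

## Ternary-complex biophysics

Steady-state SPR responses of a ternary complex against degrader
concentration are bell-shaped (the hook effect: binary complexes dominate at
saturating ligand). The model is a product of an ascending and a descending
hyperbola with unit Hill slopes,

$$R(c) = R_\mathrm{max}\,\frac{c}{K_{D,\mathrm{rise}} + c}\,
\frac{K_{D,\mathrm{fall}}}{K_{D,\mathrm{fall}} + c},$$

which displays exactly two separated sigmoidal transitions on a log axis and
peaks analytically at \(\sqrt{K_{D,\mathrm{rise}} K_{D,\mathrm{fall}}}\).
The representation is canonicalized to \(K_{D,\mathrm{rise}} \le
K_{D,\mathrm{fall}}\) (the model is invariant under the swap with
\(R_\mathrm{max}\) rescaled). A free-Hill variant is available behind
`free_hill = TRUE` for curves with compressed transitions. Monotone
(no-hook) data are refused with advice to fit a binary single-site model
instead. K\(_D\)s are fitted on the log scale; the fit is invariant to
concentration unit rescaling.

Dissociation traces restricted to the low-concentration (ternary) transition
are fitted as single exponentials \(R(t) = \mathrm{baseline} +
A e^{-k_\mathrm{off} t}\); single-trace fits, no global analysis, matching
the restricted-datapoint convention. Residence time is reported as the
inversion of the off-rate, \(1/k_\mathrm{off}\) (the stated field
convention); a \(\ln 2 / k_\mathrm{off}\) half-life option is provided and
flagged, since the two differ by 1.44-fold and reports are not always
explicit about which is meant.

Cooperativity is the fold shift of paired IC50s (binary over
partner-saturated ternary; above 1 = positive cooperativity). Initial
velocities for rate-vs-occupancy overlays are ordinary least-squares slopes
over the earliest 20% of a progress curve, with the window halved while the
quadratic term is statistically significant *and* material beyond numerical
noise — so exactly linear traces are never shrunk, while saturating curves
are evaluated near \(t = 0\).

## The synthetic generator

`simulate_screen()` emulates the screen's nuisance structure with one pooled
guide well per gene stamped into replicate assay plates:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 943 | arrayed library size, one well per gene per replicate |
| `guides_per_gene` | 3–4 | pooled guides per well |
| `n_replicate_plates` | 3 | triplicate stamping |
| `degradation_factor` | 0.9 | fraction of HiBiT removed in non-rescued wells |
| `cellnum_lognormal_sigma` | 0.15 | per-well cell-number spread |
| `plate_effect_sigma` | 0.1 | per-plate mean and gain effects |
| `hibit_firefly_curve` | cubic | strictly increasing HiBiT–Firefly coupling |
| `measurement_cv` | 0.05 | multiplicative luminescence noise |
| `infection_failure_rate` | 0.12 | per-gene (pooled-aliquot) failure |
| `rho_jitter_kappa` | 40 | Beta concentration of per-well rescue jitter |

Rescue is parameterized on the degraded span: a hit gene with rescue
fraction \(\rho\) gives treated signal \((1 - d + \rho d)\times\) baseline,
so \(\rho = 1\) is full restoration. Guide-potency heterogeneity in the pool
is modeled as Beta-distributed per-well jitter around the gene's \(\rho\).
Infection failure is drawn per library-well *position* and applied to every
replicate — the same viral aliquot is stamped into all replicate plates, so
titer failure is gene-correlated; at the default rate roughly one gene in
eight is QC-excluded, the regime an arrayed lentiviral screen of this size
operates in. A single global seed fans out to per-plate substreams so a
plate can be regenerated without regenerating the screen.

What the generator does *not* emulate: spatial (row/column/edge) plate
effects beyond the Firefly coupling, heavy-tailed well artifacts (dispensing
bubbles, contamination), cell-growth dynamics, or mechanistic ubiquitination
kinetics. Passing tests therefore demonstrate correctness of the
deconvolution arithmetic and calibration under the modeled noise — not
robustness to artifact classes the generator never produces. Control-well
layout is scattered (positions drawn once per plate), since fixed edge
layouts confound controls with edge effects the generator does not model.

## Problem sizes and numerical choices

The test and acceptance suites run full-size screens (943 genes, 3
replicates, ~2830 ranked wells) because the RSA tail probabilities and the
QC-exclusion regime only look realistic at scale; calibration studies use
8–20 screens with 10 permutations each — the permutation mean exceedance is
unbiased at any permutation count, so small counts trade only variance.
Exhaustive RSA validation enumerates every rank configuration with
\(M \le 12, N \le 4\) against a rational-arithmetic oracle. Sensitivity in
planted-hit studies is measured over QC-evaluable genes: a hit whose guide
pool never infected is undetectable by construction and is reported in the
QC-excluded set, exactly as a real screen reports it.

Fits use `nls.lm` directly (parameters and deviance, no `nls` object):
the post-hoc model construction in higher-level wrappers fails spuriously
when a parameter converges to zero, e.g. an inhibition curve with a true
zero bottom plateau. Midpoints, K\(_D\)s and rates are log-parameterized;
convergence tolerances are set to 1e-14 so exact data round-trips to
solver precision.
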