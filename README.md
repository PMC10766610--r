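# tpdscreen

Hit calling for arrayed CRISPR knock-out **rescue screens** read out by a
dual HiBiT/Firefly luminescence reporter, and pharmacology metrics for
**targeted protein degradation** (TPD). The package is for groups running
degrader campaigns: the screen side identifies which cellular genes a
degrader's activity depends on (E3 receptor, cullin-RING components, NEDD8
machinery, proteasome subunits); the pharmacology side quantifies how well a
degrader works (DC50/Dmax, GI50, viability window, ternary-complex
biophysics).

## What it computes

**Screen deconvolution** (`analyze_screen()` / `run_pipeline()`):

1. *QC gate* — a well passes when its Firefly signal exceeds the plate's
   media/non-infected control median by `log10(F/F_ctrl) > log10(1.25)`;
   failing wells are excluded from all fitting and ranking.
2. *Plate normalization* — per assay plate, a robustly re-fitted
   third-order polynomial of HiBiT on Firefly removes cell-number and plate
   effects; the normalized activity is `rel_change = observed/predicted`.
3. *Robust z* — `(x − median)/(1.4826·MAD)` per plate.
4. *Gene-level RSA statistic* — wells ranked screen-wide; a gene with wells
   at ranks `r_1 < … < r_N` among `M` scores

   ```
   log10 P = log10 min_j  P[ X ≥ j ],   X ~ Hypergeom(M, N, r_j)
   ```

   computed in log space (`M ≈ 2800` makes factorials overflow), with
   conservative tie handling.
5. *Randomized-activity null* — robust z shuffled within plates, genes
   re-scored `n_perm` times; hits are genes below `log10 P < −3` (strong
   below −4) and the plug-in empirical FDR is
   `mean null exceedance / observed exceedance`.

**Degrader pharmacology** (`fit_4pl()`, `vd_score()`, …): four-parameter
logistic fits with relative DC50 (curve midpoint), absolute DC50 (fitted
0.5 crossing, solved analytically), Dmax (fitted plateau), GI50 from
viable-gate fractions with a 25%-of-DMSO exclusion floor, ratiometric
(GFP−BG)/(mCherry−BG) degradation, percent inhibition, dual-reporter
ratios, and the viability window `V/D = GI50/DC50` with top-dose fallback.

**Ternary biophysics** (`fit_bell()`, `fit_dissociation()`, …): hook-effect
isotherms fitted as a product of hyperbolas
`R(c) = Rmax · c/(Kd_rise + c) · Kd_fall/(Kd_fall + c)` giving two apparent
K_Ds and an analytic peak at their geometric mean; restricted 1:1
dissociation fits with residence time `1/koff`; cooperativity fold shifts;
initial-velocity estimation with curvature-aware window shrinking.

**Synthetic data** (`simulate_screen()`, `simulate_dose_response()`,
`simulate_flow_ratiometric()`, `simulate_ternary_isotherm()`): generators
with known ground truth for every stage — a 943-gene arrayed library, 3–4
pooled guides per gene, triplicate 384-well plates, log-normal cell
numbers, plate effects, a cubic HiBiT–Firefly coupling, gene-correlated
infection failure, and planted rescue genes.

## Worked example

```r
library(tpdscreen)

# a full-size screen with two full rescuers and one partial rescuer planted
hits <- setNames(c(1, 1, 0.7), c("G0101", "G0400", "G0777"))
sim  <- simulate_screen(screen_sim_config(n_genes = 943, hit_genes = hits, seed = 7))
an   <- analyze_screen(sim$wells, library = sim$library, n_perm = 20, seed = 2)
an$result
#> hit_call_result: 3 hit(s) at log10 P < -3 (3 strong), 97 QC-excluded gene(s)
#>   empirical FDR: 53.3% (mean null exceedance 1.60 over 20 permutations)
head(an$result$hits[c("gene_id", "rsa_log10p", "max_rel_change", "strength")])
#>   gene_id rsa_log10p max_rel_change strength
#> 1   G0101  -8.832750      10.757909   strong
#> 2   G0400  -8.133780      10.361747   strong
#> 3   G0777  -7.510531       8.936725   strong
```

All three planted rescuers are recovered as strong hits: full rescuers show
a ~10-fold relative HiBiT change over the degraded baseline (degradation
factor 0.9), the partial (ρ = 0.7) rescuer ~9-fold. 97 genes sit behind the
Firefly QC gate (the generator's gene-correlated infection-failure regime),
and the empirical FDR is honest about a 3-hit screen: ~1.6 null genes per
permutation exceed the threshold, so a 3-gene hit list carries substantial
plug-in FDR — screens with ~30 hits operate near 5–7%.

```r
d <- simulate_dose_response(bottom = 0.1, top = 1, ec50 = 0.09, hill = 1,
                            doses = 10^seq(-3, 1, length.out = 8),
                            cv = 0.05, n_rep = 3, seed = 11)
fit_4pl(d$dose, d$response)
#> dose_response_fit (n=24): bottom=0.09504 top=0.9973 ec50=0.08182 hill=0.922
#>   rel DC50=0.08182  abs DC50=0.1023  Dmax=0.905  RSS=0.00927

vd_score(gi50 = 1.20, dc50 = 0.09, top_dose = 25)
#> viability_window: V/D = 13.33 (GI50 1.2 / DC50 0.09)

iso <- simulate_ternary_isotherm(0.01, 1, rmax = 50,
                                 concentrations = 10^seq(-4, 2, length.out = 16),
                                 cv = 0.03, seed = 3)
fit_bell(iso$conc, iso$response)
#> ternary_fit (n=16): Kd(app, rise)=0.01018  Kd(app, fall)=0.9576
#>   rmax=50.66  peak at 0.09875  RSS=6.06
```

The 4PL fit recovers a 90 nM midpoint within its ~6% sampling error at 5%
noise; the V/D window of 13.3 means degradation occurs 13-fold below toxic
concentrations; the bell fit recovers both apparent K_Ds of a hook-effect
isotherm and places the peak at their geometric mean (0.1 µM).

The file-based pipeline (`run_pipeline()`) reads a YAML config plus plate
and library CSVs and writes normalized wells, plate polynomials, gene
scores, a hit list and an FDR report, each stamped with the configuration
hash and seed; reruns are byte-identical.

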