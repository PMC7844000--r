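---
title: "Automated genotoxicity calling from high-content micronucleus screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated genotoxicity calling from high-content micronucleus screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmscreen)
```

## The workflow and its assumptions

`ivmscreen` implements a three-step, fully rule-based analysis of in vitro
micronucleus (IVM) screening plates. Everything is anchored to within-plate
controls, which makes the calls robust to run-to-run drift: the solvent
(DMSO) wells set the expected cell number and the micronucleus baseline, and
the aneugen (Paclitaxel) and clastogen (Etoposide) control wells set the
scale of the two mechanism hallmark features. The workflow assumes each
plate carries its full control block (14 solvent + 12 + 12 mechanism
controls) and refuses to run otherwise — there is no cross-plate borrowing.

**Step 1 — CC50 exemplar selection.** Cytogenetic guidance caps the analysed
dose at roughly 50% cytotoxicity, because excessive cytotoxicity itself
produces DNA damage. Per dose-response replicate, wells with an
observed/expected cell ratio at or below `cc50_ratio = 0.5` are flagged
cytotoxic. The boundary is deliberately *inclusive*: the formula-level rule
("ratio ≤ 0.5") wins over prose that speaks of "greater than 50% reduction",
and a config key exists should a user disagree. A single cytotoxic flag
between two non-cytotoxic neighbours is smoothed away as a well-level
artifact; smoothing reads the original label vector (not a cascading
in-place scan), which makes it order-independent and idempotent, and
endpoint labels are never touched. The exemplar is the lowest cytotoxic
concentration, or the highest tested concentration for a non-cytotoxic
series.

**Precipitation masking.** Precipitated compound is segmented as a flood of
spurious "micronuclei". A concentration whose MN/well count jumps by at
least `jump_factor = 10` over the next lower dose *and* exceeds
`mn_floor = 1000` MN/well is masked, and the exemplar becomes the highest
concentration below the lowest masked dose — masking truncates the series
even past an earlier cytotoxic flag, because nothing at or above the
precipitation onset can be trusted. Both thresholds are this package's
defaults (the underlying observation is anecdotal: a jump from 50 to 15,000
MN/well on a two-fold dose increase) and are exposed in `ivm_config()`. With
a zero previous count the ratio test is vacuous and the floor alone decides.
Masking everything yields an "undetermined" compound, which propagates to
the report rather than erroring. A pre-set `masked` column in the input well
table is honoured as additional upstream QC. Note one consequence of the
truncation rule: adding a mask to an *unmasked* series can move the exemplar
*up* (from the first cytotoxic dose to the highest dose below the mask);
within already-masked series, more masking only lowers it.

**Step 2 — genotoxicity flagging.** The exemplar well's micronuclei per cell
are divided by the plate solvent mean; folds at or above 3 are positive,
between 2 and 3 borderline, below 2 negative. The published wording leaves
exactly 3.0 unassigned ("≥ 2 – < 3" borderline vs "> 3" positive); we assign
it to positive so the categories partition the line, and the boundary is
configurable. The per-well statistic defaults to mean MN per cell; the
proportion of micronucleated cells is available via
`genotox_metric = "mn_cell_fraction"` since the published description
alternates between the two. Replicates are aggregated by averaging the
determined folds and re-classifying the mean. Borderline compounds proceed
to mechanism scoring.

**Step 3 — mechanism scoring.** For each plate, `fit_control_gaussian()`
computes the sample mean and SD (n−1 denominator) of the control wells'
hallmark values — F1 (kinetochore-positive MN per cell, aneugenicity) on the
aneugen controls, F2 (γH2AX foci per nucleus, clastogenicity) on the
clastogen controls — and widens the SD three-fold. `mechanism_score()` is the
Gaussian PDF at the compound's hallmark value divided by the PDF maximum,
clamped to 1.0 at or above the control mean; in closed form
`exp(-(x - mu)^2 / (2 * (3 s)^2))`, so normalisation constants cancel and an
independent `dnorm()` evaluation serves as a test oracle rather than the
implementation. The 3× widening makes the score forgiving: a compound 3
control-SDs below the control mean still scores `exp(-1/2) ≈ 0.61`.
Replicate scores are averaged. The final label rule is this package's own
(the published account reports three-class results but not the mapping):
negative-flagged compounds are negative regardless of scores; both scores at
or above `mixed_threshold = 0.5` give "mixed"; otherwise the larger score
wins, with exact sub-threshold ties undetermined. Both raw scores are always
reported so users can re-map. Scoring uses the hallmark values of the same
exemplar well that produced the genotoxicity flag.

## Cell-cycle deconvolution

Single-cell integrated Hoechst intensity is a DNA-content readout, so
classical flow-cytometry deconvolution applies. `fit_cellcycle()` models the
intensity distribution of solvent-control cells as a Dean–Jett–Fox-style
mixture: a Gaussian G1 (2N) peak at `mu_g1`, a Gaussian G2 (4N) peak fixed
at `peak_ratio * mu_g1`, a shared noise SD `sigma` across the whole range,
and S-phase mass between the peaks. Fixing the peak *position* ratio
(default 2.0) is our reading of the fixed "G1 to G2 peak ratio"; the phrase
could also mean peak heights, so the ratio is a config key. Treated wells
are then classified with the solvent-fitted model.

The objective function is not specified in the published description, so we
chose a binned multinomial negative log-likelihood over `n_bins = 256`
histogram bins, with the S component uniform on `[mu_g1, mu_g2]` — the
simplest single scalar objective that mirrors Dean–Jett–Fox practice — and
minimise all free parameters (log `mu_g1`, log `sigma`, softmax weights)
simultaneously with Nelder–Mead (`stats::optim`), as specified.
Initialisation is deterministic: `mu_g1` starts at the histogram mode, and
also at mode/`peak_ratio` because in G2-arrested populations the tallest
peak is the 4N peak; the candidate whose fitted G1 peak stays inside the
data range wins, with ties going to the mode-as-G1 reading. `sigma` starts
at `0.1 * mu_g1` and weights at coarse band counts. No random restarts, so
refits are bit-identical.

Classification uses fixed bands of ±2 SD: below `mu_g1 - 2σ` Sub-G1, within
2σ of the G1 peak G1, strictly between the band edges S, within 2σ of the G2
peak G2, above `mu_g2 + 2σ` >4N. The published band list omits an explicit
G1 clause; we read that as a typo and define G1 as "within 2σ of the G1
peak", with exact band edges resolving to the inner (peak) class per the
"within" wording. Bands are checked for overlap (`mu_g2 - 2σ ≤ mu_g1 + 2σ`
is an error: the S band would be empty). Sub-G1 and >4N cells are not
excluded from the fit; they sit in the tails of the fitted components, which
is adequate for solvent-control material where both fractions are small.

**What "recovery" means here.** The ±2σ band rule is part of the estimator:
even with the true parameters it assigns ~5% of G1-generated cells to
Sub-G1/S tails, and a substantial part of a uniform S component to the G1/G2
bands. Parameter-recovery checks therefore compare fractions obtained by
classifying cells with the *fitted* parameters against classifying the same
cells with the *generating* parameters — the error attributable to
estimation, propagated through the fixed rule — not against the latent
generating phase labels, which no band rule could match for wide S
components.

## The synthetic screen: what it emulates, and what a green test means

`simulate_screen()` emulates post-segmentation feature tables, never images.
Its stated world: 384-well plates with the published control block; 15
geometrically spaced doses from 1 nM to 1 mM (half-log steps over six
decades yield only 13 points, so we honour the point count and the range
with ratio `10^(6/14)` and record the grid in metadata); duplicate series;
~1500 cells per solvent well (750 seeded, one doubling); a 3% endogenous
micronucleated-cell frequency. Free parameters the published account does
not state were fixed once at plausible values: solvent F1 = 0.01 kt⁺ MN per
cell (roughly a third of endogenous MN carrying a kinetochore), solvent
F2 = 1.0 foci per nucleus, 10% lognormal noise on hallmark features,
negative-binomial cell counts (size 50), and control hallmark shifts of 4×
over solvent. Cytotoxicity is a decreasing Hill curve; MN and hallmark
induction follow a Hill curve whose EC50 precedes the cytotoxic EC50
three-fold, so effects are near-maximal at the CC50 exemplar, as genuine
screen positives behave. Precipitation inflates the MN count of affected
wells discontinuously (≥ 10-fold) while cell counts stay continuous, and is
opt-in (`precipitation_rate`, default 0, or an explicit
`precipitation_conc` per profile).

The generator does **not** emulate: spatial plate effects (edge evaporation,
dispense gradients), correlated well failures, compound fluorescence
interference, metabolic activation, or treated-well cell-cycle shifts (all
wells share the solvent mixture unless simulated directly with
`simulate_intensities()`). A green end-to-end test therefore establishes
that the decision rules recover class structure from data that *obeys the
workflow's own model of the assay* — it is a property-based surrogate for,
not a reproduction of, performance on a real proprietary screen, whose
headline numbers depend on a compound set we cannot access.

## Numerical choices and degenerate inputs

* Wells with zero cells carry `mn_per_cell = 0` by convention and are
  excluded from fold-change computation (a replicate whose exemplar has no
  cells is undetermined); the cytotoxicity signal of the empty well is kept.
* A zero solvent MN baseline returns an `Inf` fold with a warning rather
  than erroring.
* Zero spread in control hallmark values (degenerate plate) is an error
  instructing the user to jitter or override, not a silent division by zero.
* Report serialisation is fixed at 6 significant digits, making re-runs
  byte-comparable.
* All randomness in the package lives in the generator behind explicit
  seeds, with the caller's RNG state restored; the analysis path is
  deterministic.

## Known limitations

* The mechanism label map (argmax with a 0.5 mixed gate) is a design choice
  on top of the published scores; mixed-mode calling in particular is
  unvalidated against real mixed-mechanism compounds.
* The per-well pan-γH2AX fraction is carried through as a passthrough
  feature only; no biology is attached to it.
* No curve-fit IC50/EC50 estimation: the CC50 rule is threshold-based by
  design, and its resolution is limited to the dose grid.
* Cell-cycle fitting assumes a dominant 2N population in solvent wells;
  heavily aneuploid lines violate the fixed-ratio assumption.
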