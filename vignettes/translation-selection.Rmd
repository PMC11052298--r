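---
title: "Quantifying selection on bacterial translation machinery across generation times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying selection on bacterial translation machinery across generation times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transelect)
```

## The scientific question

Bacterial generation times span three orders of magnitude, from ~10 minutes
in *Vibrio natriegens* to about a week in *Mycobacterium leprae*. A cell
that must duplicate its proteome in minutes is under far stronger selection
to optimise translation — initiation, elongation and termination — than one
that has days. `transelect` quantifies the genomic footprints this
differential selection leaves on the translation machinery itself, and
relates them to the *rank* of generation time (RankGT, 1 = fastest), since
absolute generation times are noisy but their order is robust:

* **machinery investment** — the number of rrn operons (counted as 16S rRNA
  gene copies; one 16S per operon) and tRNA genes, modelled as
  floor-exponential decays `N = floor + a e^{-b x}` in the rank `x`. The
  floor is 1 for rrn operons (no genome translates without one) and a free
  parameter `c` for tRNA genes (a minimal decoding set);
* **initiation** — AUG start-codon usage (AUG%), Shine–Dalgarno (SD)
  signals in the 60 nt upstream of the start codon, and the secondary
  structure that can bury them;
* **elongation** — codon adaptation via the index of translation
  efficiency (I\_TE) and the anticodon repertoire of the tRNA gene pool
  (effective number of anticodons, N\_AC);
* **termination** — UAA stop-codon usage (UAA%), the stop codon with the
  lowest readthrough error rate.

Each signal is contrasted between highly expressed genes (HEGs: ribosomal
proteins, RNA polymerase core, elongation factors) and the remaining genes
(REST), because selection acts hardest where the flux is highest.

## Statistical models

**Class-contrast OLS.** AUG%, UAA% and the structure summary MeanMFE are
modelled as `response ~ RankGT + GC% + GE` (for MeanMFE also `GC%:GE`),
where GE is the expression dummy (HEG = 0, REST = 1) and genomic GC% is a
mutation-bias control: GC-rich genomes drift towards GUG starts and
UAG/UGA stops regardless of selection. `ols_fit()` reports coefficients,
standard errors from the unbiased residual variance, t statistics,
two-tailed p values and R²; `derive_class_equations()` substitutes the
dummy to give one linear equation per class. Where a signed prediction is
declared (MeanMFE should *decrease* with rank), the one-tailed p = p/2 is
reported alongside, never silently.

**Rank analyses.** DITE = mean I\_TE(HEG) − mean I\_TE(REST) is a
species-level selection measure that cancels shared mutation bias; it is 0
under no selection. Because neither DITE nor generation time is on an
interval scale, both are midranked (`rank_transform()`, ties averaged) and
related by simple OLS on ranks.

**Floor-exponential fits.** `fit_floor_exponential()` exploits that the
model is linear in `(c, a)` given `b`: the residual sum of squares is
profiled over `b`, with a documented multi-start grid
(b ∈ 0.05, 0.1, 0.2, 0.5, 1, 2) each refined by one-dimensional local
optimisation and the best RSS kept. This is deterministic, needs no global
solver, and the refined RSS can never exceed the best grid start. The fit
is unweighted and `c` unconstrained (a negative `ĉ` would be reported, not
clipped). On the packaged nine-species counts the free floor estimates
ĉ ≈ 29.9, i.e. ~30 tRNA genes as the minimal pool.

## I_TE and the effective number of anticodons

I\_TE generalises the codon adaptation index by correcting for the
mutation background: for codon `c` in synonymous family `S`,
`raw(c) = (p_HEG(c) + ε) / (p_bg(c) + ε)` and weights are renormalised to
max 1 per family; a gene's score is the geometric mean of weights over its
codons (first codon, stop codon and the single-codon families Met/Trp are
excluded). The default background is the codon distribution expected from
genome-wide GC at each codon position; the REST-gene codon table can be
selected instead. The pseudo-frequency ε defaults to 0.5/(family count),
preventing zero weights. A codon favoured merely because the genome is
AT-rich therefore earns no credit — only enrichment in HEGs *beyond*
mutational expectation does.

`effective_number()` implements Wright's homozygosity-based effective
number over synonymous families (2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆): 20 at
minimal diversity, 61 at uniform sense-codon usage (values above 61 are
clamped). The default F is the bias-corrected `(n Σp² − 1)/(n − 1)`;
families with n ≤ 1 or F ≤ 0 are excluded from their class mean, a missing
class-3 mean is imputed as (F̄₂ + F̄₄)/2 and other gaps from adjacent class
means — standard effective-number practice. For **tRNA pools**, however,
families hold only 2–7 gene copies, and there the corrected estimator
degenerates: an evenly covered family of two or three genes returns F = 0
and is discarded, which systematically erases exactly the diversity signal
of interest; published anticodon effective numbers (up to 59.4 from
45-gene pools, near the 61 ceiling) are only attainable with the plain
homozygosity Σp². `trna_effective_number()` therefore defaults to
`n_correction = FALSE` (flag to restore the corrected form), counts one
unit per tRNA gene (copy-number weighting, with a `distinct` flag), and
keeps initiator Met tRNAs in the Met family by default.

## Secondary-structure scans

Minimum folding energy (MFE, kcal/mol, ≤ 0; 0 = no structure) is computed
over a 40-nt window sliding in 1-nt steps. The scan sequence for the start
anchor is 60 nt of upstream context plus the first 61 nt of CDS (121 nt;
start codon at sites 61–63); for the stop anchor, the last 60 nt of CDS
plus 60 nt downstream (stop codon at sites 58–60). A window's energy is
reported at its mid site (window start + 19). Aggregated curves carry
normal-approximation 95% limits (mean ± 1.96·SE), and MeanMFE is the mean
of the aggregated curve over mid-window sites 46–65, the stretch spanning
the SD region and the start codon. Two anchor conventions circulate for
the start codon (sites 61–63 versus 58–60); this package fixes start =
61–63 with the 46–65 summary window, records that choice here, and does
not silently change it. Genes lacking 60 nt of flanking context are
excluded with a logged count. Whether MeanMFE should average per-gene
curves or pool all windows is ambiguous in the field; the default is the
mean of the per-site mean curve, which weights genes equally at every
site.

Two folding engines share one contract (deterministic per engine,
temperature fixed at 37 °C — the panel's optimal growth temperatures are
30–37 °C). The **builtin** engine, the package default, is a Zuker-style
dynamic program over a compact nearest-neighbour parameter set:
Watson–Crick + GU stacking energies, hairpin/bulge/internal loop length
penalties with Jacobson–Stockmayer extrapolation, affine multiloop costs,
minimum hairpin loop 3, interior loops capped at 30 unpaired bases, no
dangles. It is exact under its own energy model: the test suite checks it
against exhaustive structure enumeration (all nested structures of every
test sequence ≤ 18 nt, scored by loop decomposition with the same tables,
via `fold_params()`) to 1e-9. The **vienna** engine shells out to
ViennaRNA's RNAfold for full Turner-parameter energies. The builtin engine
is the default — its results are identical on every installation, whereas
external-binary versions drift — and no cross-species conclusion here
depends on absolute energies, only on contrasts computed with one engine.

## SD signals

`positional_frequencies()` and `pwm_scores()` profile the 60 nt upstream
of the start codon, right-aligned so site 60 abuts the start codon;
shorter upstreams contribute only to the sites they cover, and ambiguity
codes are excluded per-site (both conventions are choices, recorded here).
PWM scores are log₂ odds against a background (default: the pooled
composition of the sequences themselves; a genome-wide background can be
passed), with a total pseudocount of 1 spread proportionally to the
background so absent bases stay finite. `c_vs_u_test()` is the
likelihood-ratio G-test on C vs U counts in the SD window (default sites
45–55, configurable): since SD sequences are G-rich, selection against
stable structure predicts C (the G-pairing base) to be avoided more than
U. `d_to_start()` reports the distance from the 3′ end of the best
antiparallel Watson–Crick + GU match of the anti-SD (default 3′-terminal
core `CCUCCUUA`, written 5′→3′; minimum 4 consecutive pairs; ties resolved
towards the start codon) to the first base of the start codon. Matching is
by pairing run length, not hybridisation free energy — a deliberate
non-goal.

## The synthetic panel generator

Real cross-species claims need genomes with known ground truth.
`generate_panel()` emits annotated GenBank genomes whose features follow
the generative models the analysis assumes, plus a manifest sufficient to
recompute every expected summary without re-parsing. Defaults encode the
nine-species study conditions: ranks 1–9; the panel's genomic GC targets;
rrn counts `round(1 + 14.6 e^{-0.27x})` and tRNA counts
`round(30 + 130 e^{-0.27x})` (least-squares fits of the reference counts);
start/stop codon probabilities from the per-class linear models
(AUG%: intercepts 125.86/116.68, slopes −2.54·rank, −0.52·GC;
UAA%: 197.95/180.60, −3.78, −2.22), clamped to [0.01, 0.99] because the
linear forms are descriptive and unbounded; 60 HEGs + 600 REST genes per
species with in-frame lengths uniform on 300–1500 nt (desk-scale speed);
codon bias as a per-family mixture — with probability
`s = 0.70 − 0.065(rank−1)` (REST: 35% of that) emit the family's optimal
codon, else draw from the GC-conditioned background; an `AGGAGG` SD motif
ending 7 ± 2 nt before the start codon with per-base fidelity 0.95 (HEG) /
0.65 (REST); ~30% of CDSs on the minus strand; two flagged pseudogenes per
species. The tRNA pool spreads family sizes evenly and, within a family of
`n` genes, places `1 + round(conc·(n−1))` copies on the major anticodon
(the Watson–Crick partner of the optimal codon) with the remainder cycling
the other anticodons, `conc = 0.80 − 0.075(rank−1)`; this makes the
N\_AC-versus-rank trend structural rather than a noisy by-product of
random draws. An optional structure-weakening mode re-samples a gene's
upstream until the 40-nt window over the SD/start region folds no more
stably than a class threshold, producing the weaker HEG initiation
structure the selection hypothesis predicts; it is off by default because
it multiplies generation cost by the folding step. `null_panel()` switches
codon selection off and removes the SD motif entirely, calibrating the
null behaviour of DITE, PWM scores and MeanMFE class differences.

What the generator does *not* emulate — operon structure, realistic
intergenic architecture, amino-acid composition, phylogenetic correlation
between species — bounds what passing tests show: they validate the
pipeline's correctness and sensitivity under the assumed generative
models, not the biological claims on real genomes, which require the
RefSeq genomes themselves.

## Numerical and testing choices

Identical config and seed give byte-identical GenBank output. Test-suite
problem sizes are chosen for desk-scale runs: a shared 6-species panel
(15 + 60 genes per species, constant GC to isolate rank effects) for
property tests; a 9 × (60 + 600) panel at one fixed seed for parameter
recovery; null panels of 200 + 200 (codon adaptation) and 500 + 500
(structure/PWM) genes. Start/stop codon model recovery is checked with
exact binomial probabilities rather than the normal "3 SD" rule, which is
invalid at clamped probabilities near 0.99 with 60 genes. The published
interaction model for MeanMFE is reproduced to the propagation bound of
its inputs' printed 4-dp rounding (5·10⁻⁴), the start-codon model exactly
to 5 decimals from the printed counts. Degenerate fits (constant
response), singular designs, empty classes and missing anticodons all
fail loudly or are flagged, never imputed silently.

## Limitations

Nine species are few, and ranked regression assumes rank differences are
comparable across the scale; phylogenetically independent contrasts are
out of scope, so residual phylogenetic correlation (three mycobacteria)
is not corrected. The HEG list is a pattern-based approximation
(ribosomal proteins, RNA polymerase core, elongation factors) and fully
overridable. The builtin folding engine's parameter set is compact, not
the full Turner model; absolute MFE values differ from RNAfold's, though
contrasts agree in direction. Real-genome reproduction of the published
per-species tables requires downloading the annotated RefSeq genomes and
is supported by `run_pipeline()` but not performed here.
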