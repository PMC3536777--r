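# trtargets

Analysis pipeline for dissecting how the two thyroid hormone receptor
subtypes, TRα and TRβ, regulate target genes when over-expressed in a
cultured cell background (parental / TRα / TRβ lines, ± the hormone T3).
The package is aimed at transcriptomics analysts working with nuclear
receptor time-course, cycloheximide and dose-response designs, and at
methodologists who want a fully simulated, ground-truth-labelled testbed
for such pipelines.

## What it computes

**Differential expression.** Genes are fit with a cell-means linear model
per time point, with empirical-Bayes variance moderation: per-gene
variances are assumed drawn from a scaled inverse-χ² prior, its parameters
(d₀, s₀²) are estimated by moment-matching `log s²`, and each gene's
variance is shrunk to the posterior mean

    s̃²_g = (d₀·s₀² + df·s²_g) / (d₀ + df)

Two contrast families separate the study's two questions: the *unliganded
effect* (receptor vs parental, vehicle) and the *ligand interaction*
[(receptor, T3) − (receptor, vehicle)] − [(parental, T3) − (parental,
vehicle)]. Moderated t statistics on df + d₀ degrees of freedom are
BH-adjusted; a gene is significant when ≥ 2-fold with adjusted p ≤ 0.05
(both boundaries inclusive).

**Pattern classification.** Each significant gene's (unliganded, ligand)
fold-change vector is clamped into [0.5, 2] and assigned the nearest of
nine archetypes (Euclidean distance in linear fold space): RR = (0.5, 0.5),
RO = (0.5, 1), RI = (0.5, 2), OR = (1, 0.5), OO = (1, 1), OI = (1, 2),
IR = (2, 0.5), IO = (2, 1), II = (2, 2). OO (no response) is recorded but
excluded from the reported table.

**Direct-target calling.** From the cycloheximide (CHX) arm, the
persistence ratio Δ_CHX / Δ_free compares the T3 increment under
translation blockade with the free T3 increment; persistence ≥ 100% calls
a direct target, ≤ 25% an indirect (secondary) one, the middle band
"attenuated".

**Subtype comparison.** Gate-passing counts per receptor and time,
fold–fold Pearson correlation and total-least-squares slope of β on α,
kinetic classes (α-early, β-late preferential, concordant), and
direction-stratified overlap counts.

**Dose response.** Four-parameter Hill fits
`y = bottom + (top − bottom)·dʰ/(dʰ + EC50ʰ)` per gene per receptor with a
multistart profiled optimizer and replicate-bootstrap EC50 intervals; the
β/α EC50 ratio flags subtype-shifted genes when its interval excludes 1.

**Synthetic study generator.** `sim_config()` + `draw_gene_effects()` +
`simulate_timecourse()/simulate_chx_arm()/simulate_dose_series()` emulate
the full factorial design — archetype mixture, α-early/β-late kinetic
weights, a late TRβ-preferential subset, direct/indirect CHX behaviour,
per-receptor EC50s in 0.1–32 nM, and per-gene noise from the same
inverse-χ² hierarchy the moderation assumes — with ground-truth labels
shipped alongside every matrix.

## Worked example

The `analysis/` directory is the narrative workflow (each stage writes
tables under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/05_subtype_kinetics.R
```

which prints, for the bundled configuration (2000 genes, seed 1234):

```
simulated 2000 genes: 192 (10%) T3-responsive, 19 late TRbeta-preferential, 78% of responsive direct
...
per-time concordance (n_alpha / n_beta / overlap / r / slope):
   3 h    84   23   17  r=0.86  slope=0.52
   6 h    75   63   44  r=0.90  slope=0.88
  24 h    53  126   51  r=0.91  slope=1.70
kinetic classes: alpha_early=68, beta_late=34, concordant=23, discordant_other=15
```

Read: TRα responses dominate at 3 h (84 vs 23 gate-passing genes), TRβ at
24 h (126 vs 53), and the 24 h fold–fold slope of 1.70 > 1 reflects the
late-emerging TRβ-preferential subset — while the high correlation (r ≈
0.9) shows both subtypes regulate the same genes in the same directions.
The equivalent single call in R is `run_pipeline(sim_config(seed = 1))`.

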