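# kodepletion

Analysis of **knockout-depletion experiments**: in a naturally competent
bacterium, an essential gene is replaced by a resistance cassette, and the
already-synthesized protein pool is diluted by growth until its
concentration falls below the level required for function, at which point
growth arrests. The fold dilution tolerated before arrest measures the
protein's **overabundance**

    o = C0 / C_A,

the ratio of the endogenous concentration to the concentration at arrest.
The package is for researchers analyzing such experiments at either scale,
and for anyone wanting a tested reference implementation of the models
behind them:

* **Single-cell branch** — from lineage track tables (cell id, parent,
  time, area): the dilution law `C(t)/C0 = V0/V(t)`, the areal growth
  rate `k(t) = d/dt ln A(t)`, a threshold fitness-landscape fit, and
  elongation/septation arrest times.
* **Library branch (TFNseq-style)** — from insertion count matrices
  (genes x timepoints): relative-abundance trajectories, three nested
  trajectory models (*no effect*, *sufficiency*, *overabundance*) fitted
  by binomial maximum likelihood, model selection by two successive
  likelihood-ratio tests, and overabundance from the arrest time via
  `o = exp(k0 * T)`.
* **RLTO model** — the robustness–load trade-off prediction of optimal
  overabundance versus transcription: with gamma (bursty) expression
  noise of shape equal to the message number `mu_m`, fitness
  `F(o) = (1 - eps*o) * (1 - P_a(mu_m, o))` is maximized over `o`,
  predicting vast excess (>10x) for low-expression genes, near
  sufficiency for high-expression genes, and a one-message-per-cycle
  transcription floor.
* **Genome-wide synthesis** — message numbers from RNA-seq counts,
  binned transcription–overabundance trends (quantile and log-width
  binning), Kolmogorov–Smirnov subgroup comparisons, summary statistics,
  and KDE surfaces for figures.
* **Simulators** for all inputs (count matrices, microcolony lineages,
  RNA-seq counts), so every estimator is testable without any external
  data.

## Worked example

The end-to-end demonstration simulates a 200-gene genome (half
nonessential; 69% of essential genes overabundant, 31% sufficient, with
four anchor genes carrying measured transcription levels), two replicate
depletion libraries, and an RNA-seq run, then analyzes them:

```r
library(kodepletion)
cfg <- pipeline_config(out_dir = "demo_out", seed = 1)
rep <- run_pipeline(cfg)

ess <- rep$records[rep$records$essential, ]
sum(ess$model == "overabundance")   # 69
sum(ess$model == "sufficiency")     # 31
round(rep$summary$median_o, 2)      # 14.27
rep$records[rep$records$gene_id %in% c("dnaA", "dnaN", "ftsN", "murA"),
            c("gene_id", "model", "log10_o")]
#>     gene_id         model log10_o
#> 1      dnaA   sufficiency   0.000
#> 2      dnaN overabundance   1.488
#> 99     ftsN overabundance   2.598
#> 100    murA overabundance   0.706
```

The classifier returns the constructed 69/31 class split exactly, and the
anchor genes' recovered log10 overabundances (0, 1.488, 2.598, 0.706)
match their simulated values (0, 1.5, 2.6, 0.7) to within sequencing
noise. The median essential overabundance of this genome is 14-fold:
most essential proteins tolerate an order of magnitude of dilution before
growth arrests. The RLTO prediction computed alongside
(`rep$rlto`) gives an optimal overabundance of ~95-fold at one message
per cell cycle, falling to 1.17-fold at 1000 messages, with the
admissibility floor at one message — overabundance is a low-expression
phenomenon.

Outputs are TSV files plus a JSON manifest (package version, seeds,
thresholds, config hash) under `out_dir`; reruns with the same
configuration are byte-identical.

Single-cell example:

```r
cfg <- sim_config(k0 = 1, partition_cv = 0.05)
tree <- simulate_microcolony(o_true = 10, k0 = 1, cfg, t_max = 3.5)
fl <- fitness_landscape(tree)
fl$o_hat        # ~10 (within 5%)
fl$k_plateau    # ~1.0/h, flat until the arrest threshold
```

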