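# phypif

Quantitative modelling of phytochrome B (PhyB) → PIF3 light signalling in
Arabidopsis and of the nuclear genes PIF3 represses in darkness — the sigma
factors (SIGs), polymerase-associated proteins (PAPs) and PRIN2 that the
plastid-encoded RNA polymerase needs before chloroplast development can
start. The package is aimed at plant systems biologists who want to
simulate, calibrate or test this signalling chain against fold-change
expression time courses, and at anyone who needs its building blocks:
closed-form photoreceptor kinetics, quasi-steady-state model reduction,
repressor-occupancy gene expression, one-parameter-per-gene fitting, and
exact G-box/PBE-box promoter scanning.

## The model

Light drives the inactive Pr form of PhyB to the active Pfr form. With fast
photoequilibration the total pool (relative to its dark steady state) obeys

d[PhyB]/dt = γ_Pr (1 − Q_Pfr [PhyB]),  [PhyB](0) = 1,

with Q_Pfr = (1 + Γ_Pfr K_Pfr)/(1 + K_Pfr) and Pfr fraction
R_Pfr = K_Pfr/(1 + K_Pfr); the solution is
[PhyB](t) = 1/Q_Pfr + (1 − 1/Q_Pfr) e^(−Q_Pfr γ_Pr t). Red-light defaults:
K_Pfr = 7 (R_Pfr = 0.875), Q_Pfr = 8.75, Q_Pfr γ_Pr = 3 ln2 /day (8-h PhyB
half-life). Pfr-bound PIF3 is phosphorylated and degraded, giving the reduced
dynamics

d[PIF]/dt = γ_PIF (1 − [PIF] − R_PP [PhyB]² [PIF]²),

with interaction strength R_PP = 350 and γ_PIF R_PP = 96 /day (15-min PIF3
half-life). A PIF3-repressed transcript X follows
d[X]/dt = γ (φ(t) − [X]) with occupancy factor
φ = (K_PIF + 1)/(K_PIF + [PIF]²), shared γ = 4 ln2 /day (6-h transcript
half-life), and one dissociation constant K_PIF per gene (SIG2 0.32, SIG6
0.22, PAP1 0.35, PAP2 0.12, PAP5 0.48, PRIN2 0.09). Fast/slow/combined
closed forms, the unreduced three-variable PIF3 system, quadrature oracles,
weighted least-squares fitting of K_PIF and of the mutant PhyB abundance
factor q, and both-strand exact motif scanning complete the pipeline. See
`vignettes/phy-pif-signalling.Rmd` for the full account.

## Worked example

```r
library(phypif)

# forward-simulate the six genes for a week of constant light
sim <- simulate_genes(times = seq(0, 7, by = 0.02))
peak_metrics(sim, "PRIN2")
#> $t_peak
#> [1] 0.98
#> $fold_peak
#> [1] 9.752992

# recover a dissociation constant from noisy synthetic qPCR replicates
sc  <- synthetic_config(seed = 42, noise_cv = 0.10)   # 9 replicates/point
fit <- fit_kpif(gen_expression_series(sc, gene_params("PAP2", 0.12)))
fit
#> Fit of K_PIF: estimate 0.120708 (loss 1.957, 80 evaluations, bounds [0.0001, 10])

# scan synthetic promoters for PIF3-binding motifs
pr   <- gen_promoters(synthetic_config(seed = 1))
hits <- scan_motifs(pr)
head(presence_table(hits, seq_ids = names(pr)), 3)
#>   seq_id G-box PBE-box n_hits
#> 1   SIG1 FALSE    TRUE      1
#> 2   SIG2 FALSE    TRUE      1
#> 3   SIG3 FALSE    TRUE      1
```

PRIN2 — the gene with the strongest dark repression (K_PIF = 0.09) — peaks
about 9.8-fold just before day 1; genes with weaker repression peak lower
and slightly later (PAP5, K_PIF = 0.48, peaks 2.9-fold). The fit recovers
the generating K_PIF = 0.12 to within 1% from 9 noisy replicates per time
point, and the scanner reports each planted motif with its strand and
ATG-relative offset.

The numbered drivers under `analysis/` run the full workflow and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate_signalling.R   # trajectories + closed-form checks
Rscript analysis/02_gene_expression.R       # six-gene profiles, peaks, phyB mutant
Rscript analysis/03_fit_expression.R        # synthetic data, K_PIF and q recovery
Rscript analysis/04_motif_scan.R            # promoter generation + motif scan
```

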