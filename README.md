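# embryomech

Mechanical simulation of blastomere arrangement in nematode eggshells.

Early nematode embryos pack their first four cells (ABa, ABp, EMS, P2)
into characteristic arrangements — pyramid, diamond, T-shaped, linear —
that correlate with how elongated the eggshell is. `embryomech` is for
developmental biophysicists who want to ask, in silico, how much of that
diversity pure mechanics explains: it simulates the blastomeres as soft
spheres moving by overdamped Langevin dynamics

r_i(t + Δt) = r_i(t) + F_i Δt + ξ,   Δt = 5 s, Var(ξ_k) = 0.027 µm²

inside a rigid ellipsoidal eggshell, with programmed cell divisions and a
contact-graph classifier of the resulting four-cell pattern.

Two force laws are built in. The **repulsion-only (RO)** model lets cells
push on each other (constant force F₀ at deep overlap, decaying linearly
to zero at contact loss d = Rᵢ+Rⱼ) and on the shell. The **asymmetric
attraction (AA)** model adds an adhesion well: the pairwise force crosses
zero at d = α(Rᵢ+Rⱼ) and is attractive up to contact loss, with a pair
specific stable repulsion ratio α — 0.90 for the weakly adhesive EMS–P2
contact, 0.75 for all other pairs (α = 1 recovers RO). Eggshell aspect
ratio (AR = lx/ly) sweeps at constant shell volume, 30 replicates per AR,
reproduce the published phase behaviour of both models: the RO diamond
plateau at AR 1.4–2.0 collapsing to linear above 2.0, and the much wider
diamond regime of the AA model with linear arrangements only past AR 3.1.

## Worked example

```r
library(embryomech)

# one wild-type AA replicate at the wild-type aspect ratio
res <- run_replicate(ar = 1.6, model = "AA", seed = 1)
res$pattern
#> [1] "diamond"
res$state
#> embryo_state at t = 1020 s, 4 cell(s) in eggshell: lx = 24.33 um,
#>   ly = lz = 15.21 um (AR = 1.6, V = 23562 um^3)
#>   label         x       y       z radius volume
#> 1   ABa -13.76262  0.2543 -0.1427  11.95   7153
#> 2   ABp   1.83449 -0.9964 -6.6510  11.18   5853
#> 3   EMS   0.06544  0.8076  7.6001  10.75   5202
#> 4    P2  15.62141  0.2634  0.3227   9.39   3468

# replicated repulsion-only sweep at two aspect ratios
sw <- ar_sweep("RO", ar_values = c(1.6, 2.2), n_reps = 30, master_seed = 1)
subset(as.data.frame(sw), count > 0)
#>  model orientation_class  ar pattern count fraction n_reps master_seed
#>     RO             T-div 1.6 diamond    30        1     30           1
#>     RO             T-div 2.2  linear    30        1     30           1
```

The replicate lands in the diamond arrangement: ABa anterior, P2
posterior, ABp and EMS flanking, with every contact present except
ABa–P2. The sweep shows the RO phase change: at AR 1.6 all 30 replicates
are diamonds; at AR 2.2 all 30 are linear chains.

A command-line front end with `simulate`, `sweep`, `classify` and
`calibrate` subcommands lives at `inst/cli/embryomech.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/embryomech.R", package="embryomech"))') sweep --model ro --reps 30 ...`).
The frozen default configuration is `default_config()` /
`inst/extdata/default_config.json`; see the vignette
(`vignettes/cell-arrangement-model.Rmd`) for what every parameter means
and how the unpublished constants were calibrated and frozen.

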