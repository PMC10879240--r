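# raftscape

Lipid rafts are cholesterol- and sphingolipid-enriched membrane
microdomains that organize neuronal signalling. In amyotrophic lateral
sclerosis (ALS), spinal-cord lipid rafts undergo a coordinated
remodelling — cholesteryl esters rise sharply, sulfatides and
phosphatidylethanolamine fall, arachidonic acid and the n-9 monoenes
rise — with measurable consequences for membrane order. raftscape is an
R toolkit for exactly this kind of analysis: it takes per-subject raft
composition profiles (a fatty-acid table in mol% and a lipid-class
table in % of total lipid, for ALS cases and NSL controls) and carries
them through four connected stages:

1. **Derived indexes** (`lipid_core`): unsaturation index
   UIx = Σ %·double bonds; peroxidability index
   PIx = 0.025·monoenes + 1·dienes + 2·trienes + 4·tetraenes +
   6·pentaenes + 8·hexaenes; Sat/Unsat; CHO/SE; the
   anionic-to-zwitterionic phospholipid ratio (PG+PI+PS)/(PC+PE);
   totals by series, chain length and plasmalogen-derived DMAs.
2. **Effect-size statistics** (`stats_pipeline`): Mann–Whitney U
   (exact for small tie-free samples), Cohen's d forest tables with
   95% CIs and the |d| > 0.8 large-effect flag, varimax-rotated PCA
   lipid signatures with factor-score ANOVA, per-group correlation
   heatmaps (r, R², Cohen's q for group differences), and the ANCOVA
   slope-heterogeneity F for the cholesterol–cholesteryl-ester
   regression.
3. **Microviscosity** (`viscosity`): the Perrin relation
   η = C·r/(r0 − r) between TMA-DPH steady-state anisotropy and
   apparent microviscosity (defaults r0 = 0.362, C = 2.4 poise), its
   exact inverse, a linear composition→viscosity regression
   (fit/predict), and the group fluidity contrast on the 1/η scale.
4. **Membrane simulation** (`raft_abm`): an agent-based 2D lattice
   membrane with seven lipid groups (CHO, SE, DHA, n-6 LCPUFA, MUFA,
   SFA, SL), conservative Kawasaki–Metropolis exchange dynamics,
   local-order raft detection with flood-fill component labelling, and
   raft vs non-raft mobility from tagged-agent mean squared
   displacements.

Because the original per-subject measurements are unpublished, the
package also ships a **synthetic cohort generator**
(`synthetic_cohort`): a logistic-normal compositional model whose
defaults plant the reported ALS/NSL mean ratios (SE ×3.23, sulfatides
×0.821, arachidonate ×1.165, …) and the reported group-specific
correlation remodelling (PE–arachidonate +0.72 in NSL vs −0.94 in ALS,
PS–DHA −0.97 in ALS), with observed-scale calibration against
compositional closure. Every downstream stage is tested by recovering
what the generator plants.

## Worked example

```r
library(raftscape)

cfg    <- default_cohort_config(n_nsl = 200, n_als = 200, seed = 42)
cohort <- generate_cohort(cfg)

ft <- forest_table(cohort)
subset(ft, token %in% c("SE", "SULF", "20:4n-6", "sat_unsat_ratio",
                        "anionic_zwitterionic_ratio"))
#>                       token     d  p_value pct_change large_effect
#>                     20:4n-6 -1.02 4.67e-20       15.6         TRUE
#>                        SULF  1.40 1.46e-32      -18.9         TRUE
#>                          SE -5.60 4.83e-67      219.7         TRUE
#>             sat_unsat_ratio  3.37 2.23e-65      -18.7         TRUE
#>  anionic_zwitterionic_ratio -2.75 7.27e-59       31.9         TRUE
```

The sign convention is NSL − ALS: cholesteryl esters (SE, +219.7%
in ALS) plot negative, sulfatides (−18.9%) positive, and all five
variables clear the large-effect threshold.

```r
aniso <- generate_anisotropy(cohort, default_viscosity_params(cfg),
                             noise_sd = 0.002, seed = 43)
eta <- setNames(perrin_viscosity(aniso$r), aniso$subject_id)
compare_group_viscosity(cohort, eta = eta)
#> eta NSL 3.093 P, eta ALS 2.693 P, fluidity change +14.9%, d = 3.37
```

The ALS membranes are less viscous; on the reciprocal (fluidity) scale
that is a +14.9% increase.

```r
acfg <- abm_config(default_composition("NSL", cfg), lattice_size = 64)
nsl <- simulate_group(default_composition("NSL", cfg), acfg,
                      n_replicates = 3, seed = 7)
als <- simulate_group(default_composition("ALS", cfg), acfg,
                      n_replicates = 3, seed = 7)
round(rbind(NSL = nsl$mean, ALS = als$mean), 3)
#>     n_rafts mean_size area_fraction mobility_raft mobility_nonraft
#> NSL   4.667   553.171         0.558         0.658            0.762
#> ALS  18.667    87.359         0.385         0.753            0.886
```

The ALS composition produces many small rafts instead of a few large
ones, a lower raft membrane fraction, and higher raft mobility — the
predicted "more mobile, small-sized rafts" phenotype.

A YAML-driven end-to-end run (simulate → stats → viscosity → abm) is
available through `run_pipeline()` / `render_report()` or the thin CLI
at `inst/cli/raftscape.R`:

```sh
Rscript inst/cli/raftscape.R all --seed 17 --out results/
```

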