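# Example raftscape pipeline configuration.
# Run: Rscript inst/cli/raftscape.R all --config pipeline-example.yaml
seed: 17
out_dir: raftscape_out
stages: [simulate, stats, viscosity, abm]
cohort:
  n_nsl: 50        # subjects per group; the study itself had 6 NSL / 4 ALS
  n_als: 50
  cv: 0.15         # dispersion of the disease-reactive lipid species
viscosity:
  noise_sd: 0.002  # anisotropy measurement noise (dimensionless)
abm:
  lattice_size: 32
  sweeps_burnin: 500
  sweeps_measure: 50
  replicates: 3
  temperature: 1.0
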