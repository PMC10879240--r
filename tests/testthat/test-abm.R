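nsl_comp <- c(CHO = 0.32, SE = 0.025, DHA = 0.06, N6LCPUFA = 0.049,
              MUFA = 0.144, SFA = 0.202, SL = 0.20)

test_that("profile-to-composition mapping is scaled and closed", {
  lc <- c(CHO = 50, SM = 30, SULF = 10, OTHER_SL = 10)
  comp <- composition_from_profiles(c("16:0" = 100), lc)
  expect_equal(unname(comp["CHO"]), 0.5)
  expect_equal(unname(comp["SL"]), 0.5)
  expect_equal(unname(comp["SFA"]), 0)  # no phospholipid share to scale into
  expect_equal(sum(comp), 1)

  cfg <- fast_cohort_config()
  for (gl in c("NSL", "ALS")) {
    expect_equal(sum(default_composition(gl, cfg)), 1, tolerance = 1e-12)
  }
  # equal class shares and equal fatty-acid group shares -> uniform 1/7
  lc_eq <- c(CHO = 1, SE = 1, SM = 1, PC = 4)
  fa_eq <- c("22:6n-3" = 1, "20:4n-6" = 1, "18:1n-9" = 1, "16:0" = 1)
  comp_eq <- composition_from_profiles(fa_eq, lc_eq)
  expect_equal(unname(comp_eq), rep(1 / 7, 7), tolerance = 1e-12)
  expect_error(composition_from_profiles(c("16:0" = 1),
                                         c(PC = 0)), "all-zero")
})

test_that("largest-remainder initialization fills the lattice exactly", {
  cfg <- abm_config(nsl_comp, lattice_size = 16, seed = 3)
  st <- init_membrane(cfg)
  counts <- tabulate(st$groups, nbins = 7)
  expect_equal(sum(counts), 16^2)
  expect_equal(counts, raftscape:::largest_remainder(cfg$composition, 256))
  # exact fractions give exact counts
  frac <- c(CHO = 0.5, SE = 0.3, DHA = 0.2, N6LCPUFA = 0, MUFA = 0,
            SFA = 0, SL = 0)
  expect_equal(raftscape:::largest_remainder(frac, 100), c(50, 30, 20, 0, 0, 0, 0))
  # single-species membrane
  one <- c(CHO = 0, SE = 0, DHA = 0, N6LCPUFA = 0, MUFA = 0, SFA = 0, SL = 1)
  st1 <- init_membrane(abm_config(one, lattice_size = 16, seed = 1))
  expect_true(all(st1$groups == 7))
})

test_that("Kawasaki dynamics conserve composition and accept all J = 0 moves", {
  cfg <- abm_config(nsl_comp, lattice_size = 24,
                    interaction = matrix(0, 7, 7,
                                         dimnames = list(lipid_groups(),
                                                         lipid_groups())),
                    seed = 4)
  st <- init_membrane(cfg)
  before <- tabulate(st$groups, nbins = 7)
  st2 <- step_kawasaki(st, cfg, 50)
  expect_equal(tabulate(st2$groups, nbins = 7), before)
  expect_equal(unname(st2$acceptance[["overall"]]), 1.0)
  # agent identities are a permutation; displacements move
  expect_setequal(as.vector(st2$agents), seq_len(24^2))
  expect_gt(mean(st2$dx^2 + st2$dy^2), 0)
})

test_that("energy relaxes under attractive interactions at low temperature", {
  cfg <- abm_config(nsl_comp, lattice_size = 24, temperature = 0.1, seed = 6)
  st <- init_membrane(cfg)
  st <- step_kawasaki(st, cfg, 200, record_energy = TRUE)
  e <- st$energy_trace
  # long-run mean energy decreases from the random start
  expect_lt(mean(e[151:200]), mean(e[1:20]))
  # monotone apart from thermal fluctuation: late window never exceeds early
  expect_lt(min(e[151:200]), min(e[1:20]))
})

test_that("raft detection matches the independent flood-fill reference exactly", {
  skip_if_not_installed("igraph")
  cfg <- abm_config(nsl_comp, lattice_size = 16, seed = 8)
  raft_codes <- which(lipid_groups() %in% c("CHO", "SFA", "SL"))
  set.seed(99)
  for (rep in 1:12) {
    # random lattices spanning sparse to dense raft-former occupancy
    p <- stats::runif(1, 0.2, 0.8)
    groups <- matrix(sample(c(1, 7, 5), 256, replace = TRUE,
                            prob = c(p / 2, p / 2, 1 - p)), 16, 16)
    st <- list(groups = groups)
    mine <- detect_rafts(structure(st, class = "membrane_state"), cfg)
    ref <- reference_detect(groups, raft_codes, cfg$raft_theta,
                            cfg$raft_min_size)
    expect_equal(sort(as.integer(mine$size_distribution)),
                 sort(as.integer(ref$sizes)))
    expect_equal(mine$area_fraction, ref$area_fraction)
    expect_identical(canonical_labels(mine$labels),
                     canonical_labels(ref$labels))
  }
})

test_that("raft summaries are internally consistent at the extremes", {
  one_sl <- c(CHO = 0, SE = 0, DHA = 0, N6LCPUFA = 0, MUFA = 0, SFA = 0,
              SL = 1)
  cfg <- abm_config(one_sl, lattice_size = 16, seed = 2)
  det <- detect_rafts(init_membrane(cfg), cfg)
  expect_equal(det$n_rafts, 1)
  expect_equal(det$area_fraction, 1)
  expect_equal(unname(det$raft_composition["SL"]), 1)

  one_mufa <- c(CHO = 0, SE = 0, DHA = 0, N6LCPUFA = 0, MUFA = 1, SFA = 0,
                SL = 0)
  cfg2 <- abm_config(one_mufa, lattice_size = 16, seed = 2)
  det2 <- detect_rafts(init_membrane(cfg2), cfg2)
  expect_equal(det2$n_rafts, 0)
  expect_equal(det2$area_fraction, 0)
})

test_that("J = 0 occupancy stays indistinguishable from a fresh shuffle", {
  zero_j <- matrix(0, 7, 7, dimnames = list(lipid_groups(), lipid_groups()))
  ok <- 0
  for (s in 1:5) {
    cfg <- abm_config(nsl_comp, lattice_size = 32, interaction = zero_j,
                      seed = 100 + s)
    st <- step_kawasaki(init_membrane(cfg), cfg, 100)
    # chi-square on per-group counts in the left vs right lattice half
    half <- st$groups[, 1:16]
    counts <- rbind(tabulate(half, 7), tabulate(st$groups[, 17:32], 7))
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    if (p > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("stronger cholesterol-sphingolipid attraction does not shrink rafts", {
  areas <- vapply(c(0, -1, -2), function(jj) {
    vals <- vapply(1:3, function(s) {
      J <- default_interaction()
      J["CHO", "SL"] <- J["SL", "CHO"] <- jj
      cfg <- abm_config(nsl_comp, lattice_size = 32, interaction = J,
                        sweeps_burnin = 300, seed = 200 + s)
      st <- step_kawasaki(init_membrane(cfg), cfg, cfg$sweeps_burnin)
      detect_rafts(st, cfg)$area_fraction
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(areas) >= -0.02))  # non-decreasing up to MC noise
})

test_that("mobility separates raft from non-raft populations", {
  cfg <- abm_config(nsl_comp, lattice_size = 32, sweeps_burnin = 300,
                    sweeps_measure = 50, seed = 9)
  st <- step_kawasaki(init_membrane(cfg), cfg, cfg$sweeps_burnin)
  mob <- mobility_stats(st, cfg, cfg$sweeps_measure)
  # condensed raft phase is less mobile than the disordered surroundings
  expect_lt(mob$mobility_raft, mob$mobility_nonraft)
  expect_error(mobility_stats(st, cfg, 5), ">= 10")

  # J = 0: homogeneous dynamics, raft and non-raft mobility within 5%
  # (averaged over seeds to push Monte-Carlo noise below the band)
  zero_j <- matrix(0, 7, 7, dimnames = list(lipid_groups(), lipid_groups()))
  ratios <- vapply(1:8, function(s) {
    cfg0 <- abm_config(nsl_comp, lattice_size = 48, interaction = zero_j,
                       sweeps_burnin = 50, sweeps_measure = 100,
                       seed = 10 + s)
    st0 <- step_kawasaki(init_membrane(cfg0), cfg0, cfg0$sweeps_burnin)
    mob0 <- mobility_stats(st0, cfg0, cfg0$sweeps_measure)
    mob0$mobility_raft / mob0$mobility_nonraft
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("replicated simulation is seed-deterministic", {
  cfg <- abm_config(nsl_comp, lattice_size = 16, sweeps_burnin = 50,
                    sweeps_measure = 20, seed = 12)
  a <- simulate_group(nsl_comp, cfg, n_replicates = 2, seed = 77)
  b <- simulate_group(nsl_comp, cfg, n_replicates = 2, seed = 77)
  expect_identical(a, b)
  c_ <- simulate_group(nsl_comp, cfg, n_replicates = 2, seed = 78)
  expect_false(identical(a$mean, c_$mean))
  expect_named(a$mean, c("n_rafts", "mean_size", "area_fraction",
                         "mobility_raft", "mobility_nonraft"))
})
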